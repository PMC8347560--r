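#' Label motifs with their mRNA region
#'
#' A transcript annotation partitions each transcript into 5'-UTR
#' \code{[0, utr5_end)}, CDS \code{[utr5_end, cds_end)} and 3'-UTR
#' \code{[cds_end, length)}. A motif is labelled by the region containing its
#' start position; motifs that extend past their region's end are flagged as
#' boundary-spanning but keep the start-based label.
#'
#' @param motifs Motif data.frame with \code{transcript_id}, \code{start},
#'   \code{end}.
#' @param annotation Data.frame with columns \code{transcript_id},
#'   \code{utr5_end}, \code{cds_end}, \code{length} (0-based half-open
#'   prefix boundaries: \code{0 <= utr5_end <= cds_end <= length}).
#' @return \code{motifs} with added \code{region} (\code{"UTR5"},
#'   \code{"CDS"} or \code{"UTR3"}) and logical \code{spans_boundary}.
#' @export
annotate_region <- function(motifs, annotation) {
  validate_annotation(annotation)
  idx <- match(motifs$transcript_id, annotation$transcript_id)
  if (anyNA(idx))
    stop_("no annotation for transcript(s): ",
          paste(utils::head(unique(motifs$transcript_id[is.na(idx)]), 5),
                collapse = ", "))
  a <- annotation$utr5_end[idx]
  b <- annotation$cds_end[idx]
  L <- annotation$length[idx]
  if (any(motifs$start >= L))
    stop_("motif start beyond transcript length")
  region <- ifelse(motifs$start < a, "UTR5",
                   ifelse(motifs$start < b, "CDS", "UTR3"))
  region_end <- ifelse(region == "UTR5", a, ifelse(region == "CDS", b, L))
  motifs$region <- region
  motifs$spans_boundary <- motifs$end > region_end
  motifs
}

validate_annotation <- function(annotation) {
  need <- c("transcript_id", "utr5_end", "cds_end", "length")
  if (!all(need %in% names(annotation)))
    stop_("annotation must have columns: ", paste(need, collapse = ", "))
  with(annotation, {
    if (any(utr5_end < 0 | utr5_end > cds_end | cds_end > length))
      stop_("invalid annotation: need 0 <= utr5_end <= cds_end <= length")
  })
  invisible(annotation)
}

#' Per-region motif counts, proportions and per-kilobase densities
#'
#' Counts motifs per mRNA region, the proportion of all motifs falling in
#' each region, and the region density: motifs per kilobase of total region
#' sequence (count / total nt of the region class x 1000). Counts and
#' densities can rank the regions differently — many motifs in a long region
#' class may still mean a low density.
#'
#' @inheritParams annotate_region
#' @return Data.frame with one row per region: \code{region}, \code{count},
#'   \code{proportion}, \code{region_nt}, \code{density_per_kb}.
#' @export
region_counts_density <- function(motifs, annotation) {
  validate_annotation(annotation)
  if (!"region" %in% names(motifs) && nrow(motifs) > 0)
    motifs <- annotate_region(motifs, annotation)
  regions <- c("UTR5", "CDS", "UTR3")
  nt <- c(UTR5 = sum(annotation$utr5_end),
          CDS = sum(annotation$cds_end - annotation$utr5_end),
          UTR3 = sum(annotation$length - annotation$cds_end))
  count <- vapply(regions, function(r) sum(motifs$region == r), numeric(1))
  total <- sum(count)
  data.frame(
    region = regions,
    count = as.integer(count),
    proportion = if (total > 0) count / total else rep(0, 3),
    region_nt = as.integer(nt[regions]),
    density_per_kb = ifelse(nt[regions] > 0, count / nt[regions] * 1e3, NA),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Average motif density over a region class
#'
#' The background density: total motif nucleotides within the region class
#' divided by the total length of that region class, per kilobase
#' (\code{l / L x 1000}). Motif intervals are clipped to the region.
#'
#' @inheritParams annotate_region
#' @param region Region class (\code{"UTR5"}, \code{"CDS"}, \code{"UTR3"}).
#' @return A scalar density (nt of motif per kb of region).
#' @export
background_density <- function(motifs, annotation, region = "UTR5") {
  validate_annotation(annotation)
  bounds <- region_bounds(annotation, region)
  Ltot <- sum(bounds$hi - bounds$lo)
  if (Ltot == 0) return(NA_real_)
  idx <- match(motifs$transcript_id, bounds$transcript_id)
  lo <- pmax(motifs$start, bounds$lo[idx])
  hi <- pmin(motifs$end, bounds$hi[idx])
  l <- sum(pmax(0, hi - lo))
  l / Ltot * 1e3
}

region_bounds <- function(annotation, region) {
  region <- match.arg(region, c("UTR5", "CDS", "UTR3"))
  data.frame(
    transcript_id = annotation$transcript_id,
    lo = switch(region, UTR5 = 0L * annotation$utr5_end,
                CDS = annotation$utr5_end, UTR3 = annotation$cds_end),
    hi = switch(region, UTR5 = annotation$utr5_end,
                CDS = annotation$cds_end, UTR3 = annotation$length),
    stringsAsFactors = FALSE)
}

#' Relative motif density profile aligned to transcript 5' ends
#'
#' Aligns all transcripts to their 5' end (or, with
#' \code{align = "start_codon"}, to their start codon, scanning upstream) and
#' computes the relative density at each 1-based position i:
#' \deqn{d_i = G_i / T_i \times 10^3}
#' where \eqn{G_i} is the number of motifs at position i and \eqn{T_i} the
#' number of transcripts long enough to have position i. By default a motif
#' counts at every position it covers (occupancy); with
#' \code{count_mode = "start"} it counts only at its start. The average
#' density over a whole region class ([background_density()]) is attached
#' when \code{background_region} is given.
#'
#' @inheritParams annotate_region
#' @param window Profile depth in nt (default 300).
#' @param align \code{"five_prime"} (positions downstream of the 5' end) or
#'   \code{"start_codon"} (positions upstream of the start codon).
#' @param count_mode \code{"occupancy"} or \code{"start"}.
#' @param background_region Region class for the background line, or
#'   \code{NULL} to skip.
#' @return An object of class \code{"density_profile"}: a list with
#'   \code{profile} (data.frame \code{position}, \code{G}, \code{T},
#'   \code{d}), \code{background}, \code{align}, \code{count_mode}.
#' @export
relative_density_5p <- function(motifs, annotation, window = 300,
                                align = c("five_prime", "start_codon"),
                                count_mode = c("occupancy", "start"),
                                background_region = "UTR5") {
  align <- match.arg(align)
  count_mode <- match.arg(count_mode)
  validate_annotation(annotation)
  stopifnot(window >= 1)
  len <- switch(align, five_prime = annotation$length,
                start_codon = annotation$utr5_end)
  Tv <- vapply(seq_len(window), function(i) sum(len >= i), numeric(1))
  G <- numeric(window)
  if (nrow(motifs) > 0) {
    a5 <- annotation$utr5_end[match(motifs$transcript_id,
                                    annotation$transcript_id)]
    for (k in seq_len(nrow(motifs))) {
      pos0 <- if (count_mode == "start") motifs$start[k]
              else motifs$start[k]:(motifs$end[k] - 1L)
      i <- if (align == "five_prime") pos0 + 1L else a5[k] - pos0
      i <- i[i >= 1L & i <= window]
      G[i] <- G[i] + 1
    }
  }
  d <- ifelse(Tv > 0, G / Tv * 1e3, NA_real_)
  bg <- if (!is.null(background_region))
    background_density(motifs, annotation, background_region)
  structure(list(
    profile = data.frame(position = seq_len(window), G = G, T = Tv, d = d),
    background = bg, align = align, count_mode = count_mode,
    window = window), class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Relative density profile (%s-aligned, %s counting, %d nt)\n",
              x$align, x$count_mode, x$window))
  cat(sprintf("  peak d = %.3g at position %d; background = %s\n",
              max(x$profile$d, na.rm = TRUE),
              x$profile$position[which.max(x$profile$d)],
              if (is.null(x$background)) "not computed"
              else sprintf("%.3g", x$background)))
  invisible(x)
}

#' Plot a relative density profile
#'
#' @param x A \code{density_profile} object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$profile$position, x$profile$d, type = "l",
                 col = "steelblue", lwd = 2,
                 xlab = if (x$align == "five_prime")
                   "distance to 5' end (nt)"
                 else "distance upstream of start codon (nt)",
                 ylab = "relative density (per kb)", ...)
  if (!is.null(x$background))
    graphics::abline(h = x$background, col = "darkorange", lty = 3, lwd = 2)
  invisible(x)
}

#' Distances of motifs to the ends of their region
#'
#' For each motif contained in the given region: the distance from the
#' region's 5' end to the motif start and from the motif end to the region's
#' 3' end. \code{dist5 + dist3 + width} equals the region length for every
#' contained motif.
#'
#' @inheritParams annotate_region
#' @param region Region class to measure within.
#' @return Data.frame with \code{transcript_id}, \code{start}, \code{end},
#'   \code{dist5}, \code{dist3} and logical \code{contained}; distances are
#'   \code{NA} for motifs not fully contained.
#' @export
distance_to_ends <- function(motifs, annotation, region = "UTR5") {
  validate_annotation(annotation)
  bounds <- region_bounds(annotation, region)
  idx <- match(motifs$transcript_id, bounds$transcript_id)
  lo <- bounds$lo[idx]
  hi <- bounds$hi[idx]
  contained <- motifs$start >= lo & motifs$end <= hi
  data.frame(
    transcript_id = motifs$transcript_id,
    start = motifs$start, end = motifs$end,
    dist5 = ifelse(contained, motifs$start - lo, NA_integer_),
    dist3 = ifelse(contained, hi - motifs$end, NA_integer_),
    contained = contained, stringsAsFactors = FALSE)
}

# Logical coverage vectors (one per transcript) from feature intervals.
coverage_list <- function(features, transcript_lengths, ids = NULL) {
  ids <- ids %||% unique(features$transcript_id)
  cov <- lapply(ids, function(id) logical(transcript_lengths[[id]]))
  names(cov) <- ids
  for (k in seq_len(nrow(features))) {
    id <- features$transcript_id[k]
    if (!id %in% ids) next
    cov[[id]][(features$start[k] + 1L):features$end[k]] <- TRUE
  }
  cov
}

# Shared offset-profile engine: fraction of anchors whose position + offset
# is covered by a feature, among anchors for which that position exists.
offset_profile <- function(anchors, cov, transcript_lengths, offsets) {
  num <- den <- numeric(length(offsets))
  for (id in unique(anchors$transcript_id)) {
    a <- anchors$pos[anchors$transcript_id == id]
    L <- transcript_lengths[[id]]
    cv <- cov[[id]] %||% logical(L)
    for (j in seq_along(offsets)) {
      p <- a + offsets[j]
      ok <- p >= 0L & p < L
      den[j] <- den[j] + sum(ok)
      num[j] <- num[j] + sum(cv[p[ok] + 1L])
    }
  }
  list(num = num, den = den,
       density = ifelse(den > 0, num / den, NA_real_))
}

#' Metagene profile of feature density around anchor positions
#'
#' For every signed offset in \code{[-flank, flank]}, the fraction of
#' anchors whose position + offset is covered by a feature interval, among
#' anchors for which that offset is still on-transcript. A control profile
#' is computed identically on an equal number of uniformly placed anchors
#' drawn from \code{control_space} with a fixed seed.
#'
#' @param anchors Data.frame \code{transcript_id}, \code{pos} (0-based
#'   anchor positions).
#' @param features Data.frame \code{transcript_id}, \code{start}, \code{end}
#'   (0-based half-open intervals).
#' @param transcript_lengths Named vector/list of transcript lengths.
#' @param flank Half-window in nt.
#' @param control_space Optional interval data.frame (same columns as
#'   \code{features}) from which control anchors are drawn, e.g. the 3'-UTR
#'   intervals; \code{NULL} skips the control.
#' @param seed Seed for control anchor placement.
#' @return An object of class \code{"anchor_profile"}: list with
#'   \code{profile} (data.frame \code{offset}, \code{density},
#'   \code{control_density}), \code{n_anchors}, \code{flank}.
#' @export
metagene_profile <- function(anchors, features, transcript_lengths, flank,
                             control_space = NULL, seed = 1) {
  stopifnot(flank > 0)
  if (nrow(anchors) == 0) stop_("zero anchors supplied")
  offsets <- seq.int(-flank, flank)
  ids <- union(unique(anchors$transcript_id),
               unique(features$transcript_id))
  cov <- coverage_list(features, transcript_lengths, ids)
  obs <- offset_profile(anchors, cov, transcript_lengths, offsets)
  ctrl <- rep(NA_real_, length(offsets))
  if (!is.null(control_space)) {
    ca <- with_seed(seed, random_anchors(control_space, nrow(anchors)))
    ctrl <- offset_profile(ca, cov, transcript_lengths, offsets)$density
  }
  structure(list(
    profile = data.frame(offset = offsets, density = obs$density,
                         control_density = ctrl),
    n_anchors = nrow(anchors), flank = flank, seed = seed),
    class = "anchor_profile")
}

# n anchor positions uniform over a set of intervals (weighted by length).
random_anchors <- function(space, n) {
  w <- space$end - space$start
  if (any(w <= 0)) stop_("control space has empty intervals")
  row <- sample.int(nrow(space), n, replace = TRUE, prob = w)
  data.frame(
    transcript_id = space$transcript_id[row],
    pos = space$start[row] +
      floor(stats::runif(n) * w[row]),
    stringsAsFactors = FALSE)
}

#' Aggregate an anchor profile into fixed-width bins
#'
#' @param x An \code{anchor_profile} object.
#' @param bin Bin width in nt (default 20).
#' @return Data.frame \code{offset_from}, \code{offset_to}, \code{density},
#'   \code{control_density} (bin means).
#' @export
bin_anchor_profile <- function(x, bin = 20) {
  p <- x$profile
  grp <- floor((p$offset + x$flank) / bin)
  agg <- function(v) tapply(v, grp, mean, na.rm = TRUE)
  lo <- tapply(p$offset, grp, min)
  hi <- tapply(p$offset, grp, max)
  data.frame(offset_from = as.integer(lo), offset_to = as.integer(hi),
             density = as.numeric(agg(p$density)),
             control_density = as.numeric(agg(p$control_density)),
             row.names = NULL)
}

#' @export
print.anchor_profile <- function(x, ...) {
  cat(sprintf("Metagene profile: %d anchors, flank %d nt\n",
              x$n_anchors, x$flank))
  cat(sprintf("  mean density %.4g (control %.4g)\n",
              mean(x$profile$density, na.rm = TRUE),
              mean(x$profile$control_density, na.rm = TRUE)))
  invisible(x)
}

#' Plot a metagene anchor profile
#'
#' @param x An \code{anchor_profile} object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.anchor_profile <- function(x, ...) {
  p <- x$profile
  ylim <- range(c(p$density, p$control_density), na.rm = TRUE)
  graphics::plot(p$offset, p$density, type = "l", col = "goldenrod3",
                 lwd = 2, ylim = ylim, xlab = "offset from anchor (nt)",
                 ylab = "feature density", ...)
  if (!all(is.na(p$control_density)))
    graphics::lines(p$offset, p$control_density, col = "steelblue",
                    lwd = 2, lty = 2)
  invisible(x)
}

#' Probability of forming an observed G-quadruplex downstream of anchors
#'
#' In fixed-width bins downstream of a set of anchor positions, the forming
#' probability is the occupancy density of observed motifs divided by the
#' occupancy density of putative motifs in the same bin:
#' \deqn{p_i = d_i / d'_i.}
#' Because observed motifs are a subset of putative motifs and both
#' densities use identical counting, \eqn{p_i \in [0, 1]}. Bins where the
#' putative density is zero are undefined (\code{NA}) and excluded from
#' trend testing.
#'
#' @param og4,putative Motif data.frames; the observed set must be a subset
#'   of the putative set by \code{(transcript_id, start, end)}.
#' @param anchors Data.frame \code{transcript_id}, \code{pos}.
#' @param transcript_lengths Named vector/list of transcript lengths.
#' @param depth Total downstream depth in nt (default 200).
#' @param bin Bin width in nt (default 20).
#' @return An object of class \code{"forming_probability"}: a list with
#'   \code{bins} (data.frame \code{bin}, \code{from}, \code{to},
#'   \code{d_obs}, \code{d_put}, \code{p}) and the call parameters.
#' @export
forming_probability <- function(og4, putative, anchors, transcript_lengths,
                                depth = 200, bin = 20) {
  for (k in seq_len(nrow(og4))) {
    same <- putative$transcript_id == og4$transcript_id[k]
    if (!any(same & putative$start <= og4$start[k] &
             putative$end >= og4$end[k]))
      stop_("observed motifs must be a subset of putative motifs")
  }
  if (nrow(anchors) == 0) stop_("zero anchors supplied")
  offsets <- seq_len(depth)
  ids <- unique(c(anchors$transcript_id, putative$transcript_id))
  cov_o <- coverage_list(og4, transcript_lengths, ids)
  cov_p <- coverage_list(putative, transcript_lengths, ids)
  obs <- offset_profile(anchors, cov_o, transcript_lengths, offsets)
  put <- offset_profile(anchors, cov_p, transcript_lengths, offsets)
  grp <- rep(seq_len(depth %/% bin), each = bin)[seq_len(depth)]
  sum_by <- function(v) as.numeric(tapply(v, grp, sum))
  den <- sum_by(obs$den)
  d_obs <- ifelse(den > 0, sum_by(obs$num) / den, NA_real_)
  d_put <- ifelse(den > 0, sum_by(put$num) / den, NA_real_)
  p <- ifelse(!is.na(d_put) & d_put > 0, d_obs / d_put, NA_real_)
  if (all(is.na(p)))
    stop_("all bins undefined: no putative motif occupancy downstream of anchors")
  nb <- max(grp)
  structure(list(
    bins = data.frame(bin = seq_len(nb), from = (seq_len(nb) - 1L) * bin + 1L,
                      to = seq_len(nb) * bin, d_obs = d_obs, d_put = d_put,
                      p = p),
    depth = depth, bin = bin, n_anchors = nrow(anchors)),
    class = "forming_probability")
}

#' @export
print.forming_probability <- function(x, ...) {
  cat(sprintf("Forming probability downstream of %d anchors (%d nt, %d-nt bins)\n",
              x$n_anchors, x$depth, x$bin))
  print(round(x$bins$p, 3))
  invisible(x)
}

#' Plot forming probability per bin
#'
#' @param x A \code{forming_probability} object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.forming_probability <- function(x, ...) {
  b <- x$bins
  graphics::plot((b$from + b$to) / 2, b$p, type = "b", pch = 19,
                 col = "firebrick",
                 xlab = "distance downstream of anchor (nt)",
                 ylab = "forming probability p", ...)
  invisible(x)
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test. The score is
#' \eqn{S = \sum_{j > i} \mathrm{sign}(x_j - x_i)}; its variance under the
#' null is \eqn{[n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18} summed over tie
#' groups of size t; the continuity-corrected normal deviate is
#' \eqn{z = (S - 1)/\sqrt{\mathrm{var}S}} for positive S (symmetric for
#' negative, 0 for S = 0); the p-value is the two-sided normal tail.
#'
#' @param x Numeric series (at least 4 finite values). A constant series
#'   yields S = 0, p = 1.
#' @return An object of class \code{"mk_test"}: list with \code{S},
#'   \code{varS}, \code{z}, \code{p.value}, \code{n}.
#' @examples
#' mann_kendall(c(0.1, 0.15, 0.12, 0.2, 0.25, 0.24, 0.3, 0.33, 0.35, 0.4))
#' @export
mann_kendall <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4 || anyNA(x) || any(!is.finite(x)))
    stop_("Mann-Kendall test needs at least 4 finite values and no NA")
  n <- length(x)
  S <- sum(sign(outer(x, x, "-")[lower.tri(diag(n))]))
  ties <- table(x)
  ties <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (S > 0) (S - 1) / sqrt(varS)
       else if (S < 0) (S + 1) / sqrt(varS)
       else 0
  p <- if (varS == 0) 1 else min(1, 2 * stats::pnorm(-abs(z)))
  structure(list(S = S, varS = varS, z = z, p.value = p, n = n),
            class = "mk_test")
}

#' @export
print.mk_test <- function(x, ...) {
  cat("Mann-Kendall trend test (continuity-corrected normal approximation)\n")
  cat(sprintf("  n = %d, S = %g, var(S) = %g, z = %.4f, p = %.4g\n",
              x$n, x$S, x$varS, x$z, x$p.value))
  invisible(x)
}
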