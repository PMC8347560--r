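#' Configuration for the synthetic transcriptome generator
#'
#' Collects and validates every parameter of the synthetic data model: a
#' transcriptome with 5'-UTR/CDS/3'-UTR structure and planted canonical
#' G-quadruplex motifs of known folded status; Poisson RT-stop counts with a
#' DMS-dependent signal at A/C positions that is attenuated inside folded
#' motifs; a log-normal expression table with a multiplicative shift for
#' transcripts carrying a folded motif in their 3'-UTR; and anchor-site
#' tracks (miRNA target sites with a motif-overlap enrichment knob, poly(A)
#' sites with an exclusion radius around motifs).
#'
#' @param n_transcripts Number of transcripts.
#' @param utr5_len,cds_len,utr3_len Integer ranges \code{c(lo, hi)} in nt;
#'   CDS endpoints must be multiples of 3.
#' @param gc_background Background GC fraction in (0, 1).
#' @param n_g4_per_region Named counts of motifs to plant per transcript in
#'   each region, \code{c(utr5 = ., cds = ., utr3 = .)}.
#' @param frac_folded Probability that a planted motif is folded.
#' @param lambda_bg Poisson mean of background RT stops per position.
#' @param lambda_dms Poisson mean of additional DMS-induced stops at fully
#'   accessible A/C positions; must exceed \code{lambda_bg}.
#' @param protection Accessibility multiplier in \code{[0, 1)} applied at
#'   A/C positions inside folded motifs (0 = full protection).
#' @param expr_mu,expr_sigma Log-normal expression parameters (meanlog,
#'   sdlog).
#' @param expr_effect Multiplicative expression shift for transcripts with a
#'   folded motif in their 3'-UTR.
#' @param n_mirna_per_transcript,mirna_site_len,mirna_enrichment,mirna_flank
#'   miRNA-site track: sites per transcript, site length, fraction of sites
#'   placed to overlap a motif window, and the half-width of that window.
#' @param n_polya_per_transcript,polya_exclusion Poly(A)-site track: sites
#'   per transcript and the exclusion radius (nt) around motifs.
#' @param seed RNG seed; all outputs are bit-reproducible given the config.
#' @return A validated list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_transcripts = 200,
                             utr5_len = c(100L, 300L),
                             cds_len = c(300L, 900L),
                             utr3_len = c(400L, 1200L),
                             gc_background = 0.45,
                             n_g4_per_region = c(utr5 = 1L, cds = 0L,
                                                 utr3 = 1L),
                             frac_folded = 0.5,
                             lambda_bg = 1, lambda_dms = 20,
                             protection = 0.1,
                             expr_mu = 3, expr_sigma = 1, expr_effect = 2,
                             n_mirna_per_transcript = 3L,
                             mirna_site_len = 7L,
                             mirna_enrichment = 0.3, mirna_flank = 25L,
                             n_polya_per_transcript = 1L,
                             polya_exclusion = 50L,
                             seed = 1L) {
  cfg <- as.list(environment())
  for (r in c("utr5_len", "cds_len", "utr3_len")) {
    v <- cfg[[r]]
    if (length(v) != 2 || v[1] > v[2] || v[1] < 1)
      stop_("'", r, "' must be a non-empty positive range c(lo, hi)")
  }
  if (any(cfg$cds_len %% 3 != 0))
    stop_("'cds_len' range endpoints must be multiples of 3")
  if (gc_background <= 0 || gc_background >= 1)
    stop_("'gc_background' must be in (0, 1)")
  if (length(n_g4_per_region) != 3 || any(n_g4_per_region < 0))
    stop_("'n_g4_per_region' must be three non-negative counts (utr5, cds, utr3)")
  names(cfg$n_g4_per_region) <- c("utr5", "cds", "utr3")
  if (frac_folded < 0 || frac_folded > 1)
    stop_("'frac_folded' must be in [0, 1]")
  if (lambda_dms <= lambda_bg)
    stop_("'lambda_dms' must exceed 'lambda_bg'")
  if (protection < 0 || protection >= 1)
    stop_("'protection' must be in [0, 1)")
  if (n_transcripts < 1) stop_("'n_transcripts' must be positive")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic transcriptome configuration\n")
  cat(sprintf("  %d transcripts; UTR5 %d-%d, CDS %d-%d, UTR3 %d-%d nt; GC %.2f\n",
              x$n_transcripts, x$utr5_len[1], x$utr5_len[2],
              x$cds_len[1], x$cds_len[2], x$utr3_len[1], x$utr3_len[2],
              x$gc_background))
  cat(sprintf("  motifs per region (utr5/cds/utr3): %d/%d/%d, frac folded %.2f\n",
              x$n_g4_per_region[1], x$n_g4_per_region[2],
              x$n_g4_per_region[3], x$frac_folded))
  cat(sprintf("  stops: bg %g, dms %g, protection %.2f; seed %d\n",
              x$lambda_bg, x$lambda_dms, x$protection, x$seed))
  invisible(x)
}

# A random canonical motif: tracts of 3 (occasionally 4) Gs, loops of 1-7 nt
# drawn from {A, C, T} so planted coordinates are unambiguous under the
# maximal-tract scanning rule.
random_motif_seq <- function() {
  tracts <- sample(3:4, 4, replace = TRUE, prob = c(0.85, 0.15))
  loops <- sample(1:7, 3, replace = TRUE)
  parts <- character(7)
  parts[c(1, 3, 5, 7)] <- vapply(tracts, function(t)
    strrep("G", t), character(1))
  parts[c(2, 4, 6)] <- vapply(loops, function(l)
    paste(sample(c("A", "C", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  paste(parts, collapse = "")
}

# Non-overlapping placements of widths `w` inside [lo, hi), each with >= gap
# nt between placements; returns starts aligned with `w`, or NULL when no
# placement is found within `tries` attempts.
place_nonoverlap <- function(w, lo, hi, gap = 30L, tries = 50L) {
  for (t in seq_len(tries)) {
    starts <- integer(0)
    ok <- TRUE
    for (k in seq_along(w)) {
      room <- hi - w[k]
      if (room < lo) return(NULL)
      cand <- lo + sample.int(room - lo + 1L, 1L) - 1L
      prev <- seq_along(starts)
      clash <- any(cand < starts + w[prev] + gap &
                   starts < cand + w[k] + gap)
      if (clash) {
        ok <- FALSE
        break
      }
      starts <- c(starts, cand)
    }
    if (ok) return(starts)
  }
  NULL
}

#' Generate a synthetic transcriptome with planted G-quadruplex motifs
#'
#' Builds transcripts of random background composition, plants canonical
#' motifs at known coordinates in the requested regions, and suppresses
#' accidental canonical matches near planted motifs by rejection sampling:
#' each transcript is resampled until the scanner recovers every planted
#' motif exactly and finds no other motif within 30 nt of one. The full
#' sequence is then re-scanned and the truth table reconciled to the actual
#' scan result, so accidental motifs elsewhere are recorded (as unplanted,
#' unfolded putatives) rather than silently ignored.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with \code{sequences} (named character vector),
#'   \code{annotation} (transcript region boundaries) and \code{truth}
#'   (data.frame \code{transcript_id}, \code{start}, \code{end},
#'   \code{region}, \code{folded}, \code{planted}).
#' @export
generate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, generate_transcriptome_impl(cfg))
}

generate_transcriptome_impl <- function(cfg) {
  n <- cfg$n_transcripts
  ids <- sprintf("TX%04d", seq_len(n))
  u5 <- sample_int_range(n, cfg$utr5_len[1], cfg$utr5_len[2])
  cds <- sample_int_range(n, cfg$cds_len[1], cfg$cds_len[2], by = 3L)
  u3 <- sample_int_range(n, cfg$utr3_len[1], cfg$utr3_len[2])
  L <- u5 + cds + u3
  p_base <- c(A = (1 - cfg$gc_background) / 2, C = cfg$gc_background / 2,
              G = cfg$gc_background / 2, T = (1 - cfg$gc_background) / 2)
  sequences <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    bounds <- list(utr5 = c(0L, u5[i]), cds = c(u5[i], u5[i] + cds[i]),
                   utr3 = c(u5[i] + cds[i], L[i]))
    res <- NULL
    for (try in 1:100) {
      res <- build_transcript(L[i], bounds, cfg, p_base)
      if (!is.null(res)) break
    }
    if (is.null(res))
      stop_("could not generate transcript ", ids[i],
            " satisfying the planted-motif constraints after 100 attempts")
    sequences[i] <- res$seq
    tr <- res$truth
    if (nrow(tr) > 0) tr$transcript_id <- ids[i]
    truth[[i]] <- tr
  }
  names(sequences) <- ids
  annotation <- data.frame(transcript_id = ids, utr5_end = u5,
                           cds_end = u5 + cds, length = L,
                           stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth)
  truth <- truth[, c("transcript_id", "start", "end", "region", "folded",
                     "planted")]
  rownames(truth) <- NULL
  list(sequences = sequences, annotation = annotation, truth = truth)
}

# One attempt at a transcript: background sequence + planted motifs; NULL if
# the scan does not reconcile with the planting (rejection sampling).
build_transcript <- function(L, bounds, cfg, p_base) {
  chars <- sample(names(p_base), L, replace = TRUE, prob = p_base)
  planted <- data.frame(start = integer(), end = integer(),
                        region = character(), stringsAsFactors = FALSE)
  for (r in c("utr5", "cds", "utr3")) {
    k <- cfg$n_g4_per_region[[r]]
    if (k == 0) next
    seqs <- vapply(seq_len(k), function(.) random_motif_seq(), character(1))
    w <- nchar(seqs)
    lo <- bounds[[r]][1] + 1L   # 1 nt non-G flank inside the region
    hi <- bounds[[r]][2] - 1L
    if (hi - lo < max(w))
      stop_("region '", r, "' (", bounds[[r]][2] - bounds[[r]][1],
            " nt) too short for a planted motif of ", max(w), " nt")
    starts <- place_nonoverlap(w, lo, hi, gap = 30L)
    if (is.null(starts)) return(NULL)
    for (k2 in seq_len(k)) {
      s <- starts[k2]
      m <- seqs[k2]
      wk <- w[k2]
      chars[(s + 1L):(s + wk)] <- strsplit(m, "")[[1]]
      # guarantee maximal outer tracts with non-G flanks
      chars[s] <- sample(c("A", "C", "T"), 1)
      if (s + wk + 1L <= L) chars[s + wk + 1L] <- sample(c("A", "C", "T"), 1)
      planted <- rbind(planted, data.frame(start = s, end = s + wk,
                                           region = toupper(sub("utr", "UTR", r)),
                                           stringsAsFactors = FALSE))
    }
  }
  sq <- paste(chars, collapse = "")
  found <- scan_g4(c(x = sq))
  pk <- paste(planted$start, planted$end)
  fk <- paste(found$start, found$end)
  if (!all(pk %in% fk)) return(NULL)
  # reject accidental motifs within 30 nt of a planted motif
  extra <- found[!fk %in% pk, , drop = FALSE]
  if (nrow(extra) > 0 && nrow(planted) > 0) {
    near <- outer(extra$start, planted$end + 30L, "<") &
            outer(extra$end, planted$start - 30L, ">")
    if (any(near)) return(NULL)
  }
  if (nrow(planted) > 0) {
    truth <- data.frame(transcript_id = NA_character_,
                        start = planted$start, end = planted$end,
                        region = planted$region,
                        folded = stats::runif(nrow(planted)) < cfg$frac_folded,
                        planted = TRUE, stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(transcript_id = character(), start = integer(),
                        end = integer(), region = character(),
                        folded = logical(), planted = logical(),
                        stringsAsFactors = FALSE)
  }
  if (nrow(extra) > 0) {
    reg <- ifelse(extra$start < bounds$utr5[2], "UTR5",
                  ifelse(extra$start < bounds$cds[2], "CDS", "UTR3"))
    truth <- rbind(truth, data.frame(
      transcript_id = NA_character_, start = extra$start, end = extra$end,
      region = reg, folded = FALSE, planted = FALSE,
      stringsAsFactors = FALSE))
  }
  truth <- truth[order(truth$start), , drop = FALSE]
  list(seq = sq, truth = truth)
}

#' Simulate treated and control RT-stop tracks
#'
#' The generative inverse of the probing chemistry: the control track is
#' Poisson(\code{lambda_bg}) at every position; the treated track adds
#' DMS-induced stops at A/C positions, Poisson(\code{lambda_bg} +
#' \code{lambda_dms} x a) with accessibility a = \code{protection} inside
#' folded motifs and a = 1 elsewhere; G/T positions carry background only.
#'
#' @param sequences,truth From [generate_transcriptome()].
#' @param cfg The same [synthetic_config()].
#' @return List with named lists \code{treated} and \code{control} of
#'   integer count vectors.
#' @export
simulate_rtstops <- function(sequences, truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed + 1L, {
    treated <- control <- vector("list", length(sequences))
    names(treated) <- names(control) <- names(sequences)
    for (id in names(sequences)) {
      chars <- strsplit(sequences[[id]], "", fixed = TRUE)[[1]]
      L <- length(chars)
      acc <- rep(1, L)
      tm <- truth[truth$transcript_id == id & truth$folded, , drop = FALSE]
      for (k in seq_len(nrow(tm)))
        acc[(tm$start[k] + 1L):tm$end[k]] <- cfg$protection
      lam_t <- cfg$lambda_bg +
        ifelse(chars %in% c("A", "C"), cfg$lambda_dms * acc, 0)
      treated[[id]] <- stats::rpois(L, lam_t)
      control[[id]] <- stats::rpois(L, cfg$lambda_bg)
    }
    list(treated = treated, control = control)
  })
}

#' Simulate a TPM-like expression table
#'
#' Log-normal baseline expression; transcripts carrying a folded motif in
#' their 3'-UTR are shifted by the multiplicative \code{expr_effect}; values
#' are renormalized to sum to one million (TPM convention).
#'
#' @param truth,annotation From [generate_transcriptome()].
#' @param cfg The same [synthetic_config()].
#' @return Data.frame \code{transcript_id}, \code{tpm}, and logical
#'   \code{og4_utr3} (the planted group label).
#' @export
simulate_expression <- function(truth, annotation, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed + 2L, {
    ids <- annotation$transcript_id
    base <- stats::rlnorm(length(ids), meanlog = cfg$expr_mu,
                          sdlog = cfg$expr_sigma)
    carriers <- unique(truth$transcript_id[truth$folded &
                                             truth$region == "UTR3"])
    grp <- ids %in% carriers
    val <- base * ifelse(grp, cfg$expr_effect, 1)
    data.frame(transcript_id = ids, tpm = val / sum(val) * 1e6,
               og4_utr3 = grp, stringsAsFactors = FALSE)
  })
}

#' Simulate miRNA target-site and poly(A) anchor tracks
#'
#' miRNA sites are placed in 3'-UTRs; a configurable fraction is placed to
#' overlap the window around a motif (the enrichment knob), the rest
#' uniformly. Poly(A) sites are placed uniformly over the 3'-UTR positions
#' that have no motif nucleotide within the exclusion radius (the depletion
#' knob); an exclusion radius that leaves no legal position on some
#' transcript is an explicit failure.
#'
#' @param truth,annotation From [generate_transcriptome()].
#' @param cfg The same [synthetic_config()].
#' @return List with \code{mirna} (BED-like data.frame
#'   \code{transcript_id}, \code{start}, \code{end}, \code{name},
#'   \code{score}, \code{strand}) and \code{polya} (data.frame
#'   \code{transcript_id}, \code{pos}).
#' @export
simulate_anchor_sites <- function(truth, annotation, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed + 3L, {
    mirna <- list()
    polya <- list()
    for (i in seq_len(nrow(annotation))) {
      id <- annotation$transcript_id[i]
      lo <- annotation$cds_end[i]
      hi <- annotation$length[i]
      tm <- truth[truth$transcript_id == id, , drop = FALSE]
      tm3 <- tm[tm$region == "UTR3", , drop = FALSE]
      # miRNA sites
      sl <- cfg$mirna_site_len
      if (hi - lo > sl && cfg$n_mirna_per_transcript > 0) {
        starts <- vapply(seq_len(cfg$n_mirna_per_transcript), function(.) {
          enr <- nrow(tm3) > 0 && stats::runif(1) < cfg$mirna_enrichment
          if (enr) {
            k <- sample.int(nrow(tm3), 1)
            a <- max(lo, tm3$start[k] - cfg$mirna_flank)
            b <- min(hi - sl, tm3$end[k] + cfg$mirna_flank - sl)
            if (b < a) enr <- FALSE
          }
          if (!enr) {
            a <- lo
            b <- hi - sl
          }
          a + sample.int(b - a + 1L, 1L) - 1L
        }, integer(1))
        mirna[[id]] <- data.frame(
          transcript_id = id, start = starts, end = starts + sl,
          name = sprintf("mir_%s_%d", id, seq_along(starts)),
          score = 0L, strand = "+", stringsAsFactors = FALSE)
      }
      # poly(A) sites
      if (cfg$n_polya_per_transcript > 0) {
        legal <- rep(TRUE, hi - lo)   # positions lo..hi-1
        for (k in seq_len(nrow(tm))) {
          a <- max(lo, tm$start[k] - cfg$polya_exclusion)
          b <- min(hi - 1L, tm$end[k] - 1L + cfg$polya_exclusion)
          if (b >= a) legal[(a - lo + 1L):(b - lo + 1L)] <- FALSE
        }
        pos_ok <- (lo:(hi - 1L))[legal]
        if (length(pos_ok) == 0)
          stop_("poly(A) exclusion radius ", cfg$polya_exclusion,
                " nt leaves no legal placement in the 3'-UTR of ", id)
        pos <- pos_ok[sample.int(length(pos_ok),
                                 min(cfg$n_polya_per_transcript,
                                     length(pos_ok)))]
        polya[[id]] <- data.frame(transcript_id = id, pos = sort(pos),
                                  stringsAsFactors = FALSE)
      }
    }
    bind <- function(x) {
      if (length(x) == 0) return(NULL)
      out <- do.call(rbind, x)
      rownames(out) <- NULL
      out
    }
    list(mirna = bind(mirna), polya = bind(polya))
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_transcriptome()], [simulate_rtstops()],
#' [simulate_expression()] and [simulate_anchor_sites()] under the
#' configured seed.
#'
#' @param cfg A [synthetic_config()].
#' @return List with \code{sequences}, \code{annotation}, \code{truth},
#'   \code{stops} (treated/control), \code{expression}, \code{anchors}
#'   (mirna/polya) and \code{config}.
#' @export
simulate_dataset <- function(cfg) {
  tx <- generate_transcriptome(cfg)
  stops <- simulate_rtstops(tx$sequences, tx$truth, cfg)
  expression <- simulate_expression(tx$truth, tx$annotation, cfg)
  anchors <- simulate_anchor_sites(tx$truth, tx$annotation, cfg)
  c(tx, list(stops = stops, expression = expression, anchors = anchors,
             config = cfg))
}
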