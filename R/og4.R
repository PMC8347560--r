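#' Protection score of a motif on a reactivity track
#'
#' A folded G-quadruplex shields its nucleotides from DMS, so reactivity
#' inside a folded motif is depressed relative to the rest of the
#' transcript. The protection score is the mean reactivity over defined A/C
#' positions inside the motif divided by the mean over all defined A/C
#' positions of the transcript (plus a small \code{epsilon} for stability).
#' Scores near 0 indicate protection (folding); scores near 1 indicate
#' accessibility.
#'
#' @param start,end Motif coordinates (0-based, half-open).
#' @param theta Reactivity vector for the transcript (\code{NA} at G/T).
#' @param epsilon Stabilizing constant in the denominator (default 1e-6).
#' @param min_ac Minimum defined A/C positions inside the motif for the score
#'   to be defined (default 1).
#' @return The score, or \code{NA} when fewer than \code{min_ac} defined
#'   positions fall inside the motif.
#' @export
protection_score <- function(start, end, theta, epsilon = 1e-6,
                             min_ac = 1) {
  if (start < 0 || end > length(theta))
    stop_("motif [", start, ",", end, ") outside track bounds")
  inside <- theta[(start + 1L):end]
  inside <- inside[!is.na(inside)]
  if (length(inside) < min_ac) return(NA_real_)
  all_def <- theta[!is.na(theta)]
  mean(inside) / (mean(all_def) + epsilon)
}

#' Classify putative motifs as observed (OG4) or unfolded (UG4)
#'
#' Each putative motif is called observed when its protection score is
#' defined and at most \code{tau_fold}; every other putative motif —
#' including motifs with no reactivity track or too few defined positions —
#' is unfolded, so the observed and unfolded sets always partition the
#' putative set. Motifs without usable data are flagged.
#'
#' An external constrained-folding engine can replace the protection-score
#' rule: \code{engine} is a function \code{(sequence, constraints, motifs)}
#' returning one logical ("quadruplex formed") per motif row; it is called
#' per transcript with the reactivity vector as the constraint. If the
#' engine throws, the pipeline falls back to the protection score with a
#' notice.
#'
#' @param motifs Putative motif data.frame from [scan_g4()].
#' @param tracks Named list of reactivity vectors ([compute_reactivity_tracks()]).
#' @param tau_fold Protection-ratio threshold (default 0.5); a motif is
#'   observed when score \eqn{\le} \code{tau_fold}.
#' @param min_ac,epsilon Passed to [protection_score()].
#' @param engine Optional external folding engine (see Details).
#' @param sequences Named character vector of sequences; required when an
#'   engine is supplied.
#' @return A list with \code{og4}, \code{ug4} (motif data.frames with
#'   \code{score}, \code{flag} and \code{status} columns) and \code{scores}
#'   (all putative motifs with scores and flags).
#' @export
call_og4 <- function(motifs, tracks, tau_fold = 0.5, min_ac = 1,
                     epsilon = 1e-6, engine = NULL, sequences = NULL) {
  stopifnot(tau_fold > 0, tau_fold < 1)
  n <- nrow(motifs)
  score <- rep(NA_real_, n)
  flag <- rep("ok", n)
  for (i in seq_len(n)) {
    th <- tracks[[motifs$transcript_id[i]]]
    if (is.null(th)) {
      flag[i] <- "no-track"
      next
    }
    score[i] <- protection_score(motifs$start[i], motifs$end[i], th,
                                 epsilon = epsilon, min_ac = min_ac)
    if (is.na(score[i])) flag[i] <- "no-data"
  }
  observed <- !is.na(score) & score <= tau_fold

  if (!is.null(engine)) {
    eng <- try_engine(engine, motifs, tracks, sequences)
    if (!is.null(eng)) observed <- eng
  }

  out <- motifs
  out$score <- score
  out$flag <- flag
  out$status <- ifelse(observed, "observed", "unfolded")
  og4 <- out[observed, , drop = FALSE]
  ug4 <- out[!observed, , drop = FALSE]
  rownames(og4) <- rownames(ug4) <- NULL
  list(og4 = og4, ug4 = ug4, scores = out)
}

# Run an external folding engine per transcript; NULL on failure (fallback).
try_engine <- function(engine, motifs, tracks, sequences) {
  if (is.null(sequences))
    stop_("'sequences' is required when an external engine is supplied")
  res <- try({
    observed <- logical(nrow(motifs))
    for (id in unique(motifs$transcript_id)) {
      idx <- which(motifs$transcript_id == id)
      observed[idx] <- as.logical(engine(sequences[[id]], tracks[[id]],
                                         motifs[idx, , drop = FALSE]))
    }
    observed
  }, silent = TRUE)
  if (inherits(res, "try-error") || anyNA(res)) {
    message("external folding engine unavailable or failed; ",
            "falling back to protection score")
    return(NULL)
  }
  res
}

#' Detect observed RNA G-quadruplexes from sequences and DMS-seq counts
#'
#' The central estimator of the package: scans the transcriptome for
#' canonical G-quadruplex motifs, computes DMS reactivities from treated and
#' control RT-stop tracks, scores each motif's protection, and classifies
#' every putative motif as observed (OG4) or unfolded (UG4). When a region
#' annotation is supplied, motifs are labelled with their mRNA region.
#'
#' @param sequences Named character vector of transcript sequences.
#' @param treated,control Named lists of per-position RT-stop count vectors.
#' @param annotation Optional annotation data.frame (see
#'   [annotate_region()]).
#' @param tau_fold,min_ac,epsilon,engine Passed to [call_og4()].
#' @param cap,pct_window,min_ac_track Passed to
#'   [compute_reactivity_tracks()] (\code{min_ac_track} is its
#'   \code{min_ac}).
#' @return An object of class \code{"og4_fit"}: a list with \code{motifs}
#'   (all putative motifs with scores, flags, status and, if annotated,
#'   region), \code{og4}, \code{ug4}, \code{theta} (reactivity tracks),
#'   \code{params} and \code{n_transcripts}.
#' @seealso [call_og4()], [scan_g4()], [compute_reactivity()]
#' @examples
#' cfg <- synthetic_config(n_transcripts = 20)
#' sim <- simulate_dataset(cfg)
#' fit <- detect_og4(sim$sequences, sim$stops$treated, sim$stops$control,
#'                   annotation = sim$annotation)
#' fit
#' @export
detect_og4 <- function(sequences, treated, control, annotation = NULL,
                       tau_fold = 0.5, min_ac = 1, epsilon = 1e-6,
                       engine = NULL, cap = 7, pct_window = c(0.02, 0.08),
                       min_ac_track = 10) {
  motifs <- scan_g4(sequences)
  theta <- compute_reactivity_tracks(treated, control, sequences, cap = cap,
                                     pct_window = pct_window,
                                     min_ac = min_ac_track)
  calls <- call_og4(motifs, theta, tau_fold = tau_fold, min_ac = min_ac,
                    epsilon = epsilon, engine = engine,
                    sequences = sequences)
  all <- calls$scores
  if (!is.null(annotation) && nrow(all) > 0)
    all <- annotate_region(all, annotation)
  structure(list(
    motifs = all,
    og4 = all[all$status == "observed", , drop = FALSE],
    ug4 = all[all$status == "unfolded", , drop = FALSE],
    theta = theta,
    params = list(tau_fold = tau_fold, min_ac = min_ac, epsilon = epsilon,
                  cap = cap, pct_window = pct_window,
                  min_ac_track = min_ac_track),
    n_transcripts = length(sequences)),
    class = "og4_fit")
}

#' @export
print.og4_fit <- function(x, ...) {
  cat("Observed RNA G-quadruplex detection\n")
  cat(sprintf("  transcripts scanned: %d (%d with reactivity)\n",
              x$n_transcripts, length(x$theta)))
  cat(sprintf("  putative motifs: %d | observed (OG4): %d | unfolded (UG4): %d\n",
              nrow(x$motifs), nrow(x$og4), nrow(x$ug4)))
  cat(sprintf("  protection threshold tau_fold = %g\n", x$params$tau_fold))
  invisible(x)
}

#' @export
summary.og4_fit <- function(object, ...) {
  m <- object$motifs
  reg <- if ("region" %in% names(m)) table(m$region[m$status == "observed"])
  structure(list(
    n_putative = nrow(m), n_og4 = nrow(object$og4),
    n_ug4 = nrow(object$ug4),
    score_quantiles = stats::quantile(m$score, c(.05, .25, .5, .75, .95),
                                      na.rm = TRUE),
    flags = table(m$flag),
    og4_by_region = reg,
    motif_summary = summarize_motifs(object$og4),
    params = object$params), class = "summary.og4_fit")
}

#' @export
print.summary.og4_fit <- function(x, ...) {
  cat("Summary of OG4 detection\n")
  cat(sprintf("  putative: %d  OG4: %d  UG4: %d\n",
              x$n_putative, x$n_og4, x$n_ug4))
  cat("  protection score quantiles:\n")
  print(round(x$score_quantiles, 3))
  cat("  data flags:\n")
  print(x$flags)
  if (!is.null(x$og4_by_region)) {
    cat("  OG4 counts by region:\n")
    print(x$og4_by_region)
  }
  ms <- x$motif_summary
  if (ms$n > 0)
    cat(sprintf("  OG4 loop composition: %.1f%% total loop < 10 nt, %.1f%% all loops <= 3 nt\n",
                100 * ms$frac_total_loop_lt10, 100 * ms$frac_all_loops_le3))
  invisible(x)
}

#' Plot protection scores of an OG4 detection
#'
#' Histogram of per-motif protection scores with the calling threshold.
#'
#' @param x An \code{og4_fit} object.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.og4_fit <- function(x, ...) {
  s <- x$motifs$score
  s <- s[!is.na(s)]
  if (length(s) == 0) stop_("no defined protection scores to plot")
  graphics::hist(s, breaks = 30, col = "grey85", border = "white",
                 main = "Motif protection scores",
                 xlab = "protection score (motif / transcript reactivity)",
                 ...)
  graphics::abline(v = x$params$tau_fold, col = "firebrick", lwd = 2,
                   lty = 2)
  invisible(x)
}
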