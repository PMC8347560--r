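#' Count reverse-transcription stops from read 5' positions
#'
#' In DMS probing, reverse transcription stalls one nucleotide before the
#' methylated base, so a read whose 5' end maps at position p reports a stop
#' at p - 1. Reads mapping at position 0 have no upstream base and are
#' dropped.
#'
#' @param read_positions Integer vector of 0-based 5'-end mapping positions.
#' @param transcript_length Transcript length in nucleotides.
#' @return Integer vector of per-position stop counts (length
#'   \code{transcript_length}); the sum equals the number of retained reads.
#' @examples
#' count_rt_stops(c(5, 5, 9), 20)
#' @export
count_rt_stops <- function(read_positions, transcript_length) {
  if (any(read_positions < 0 | read_positions >= transcript_length))
    stop_("read position outside transcript bounds [0, ",
          transcript_length, ")")
  keep <- read_positions > 0
  counts <- tabulate(read_positions[keep], nbins = transcript_length)
  as.integer(counts)
}

#' Compute DMS reactivities from treated and control RT-stop tracks
#'
#' Per-transcript reactivity in the structure-probing convention: (1) each
#' track is scaled to equal library depth (divided by its own total stops and
#' multiplied by the geometric mean of the two totals); (2) the raw signal at
#' each A/C position is \code{max(0, ln(t' + 1) - ln(c' + 1))}; (3) all raw
#' values are divided by the mean of the values ranked between the 2nd and
#' 8th percentile from the top (2--8\% normalization); (4) values are clipped
#' to \code{[0, cap]}. Reactivity is defined only at A and C — DMS methylates
#' unpaired adenines and cytosines — so G/T positions carry \code{NA}.
#'
#' A transcript is skipped (returns \code{NULL}, with a warning) when either
#' track has zero total stops or when fewer than \code{min_ac} A/C positions
#' are available.
#'
#' @param treated,control Non-negative count vectors of equal length.
#' @param sequence The transcript sequence (same length), used to mask G/T.
#' @param cap Upper bound on reactivity (default 7).
#' @param pct_window Two fractions giving the top-rank normalization window
#'   (default \code{c(0.02, 0.08)}).
#' @param min_ac Minimum number of A/C positions (default 10).
#' @return Numeric vector of reactivities with \code{NA} at G/T positions,
#'   or \code{NULL} if the transcript is skipped.
#' @export
compute_reactivity <- function(treated, control, sequence, cap = 7,
                               pct_window = c(0.02, 0.08), min_ac = 10) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars[chars == "U"] <- "T"
  L <- length(chars)
  if (length(treated) != L || length(control) != L)
    stop_("treated/control track length does not match sequence length")
  tot_t <- sum(as.numeric(treated))
  tot_c <- sum(as.numeric(control))
  if (tot_t == 0 || tot_c == 0) {
    warning("transcript skipped: a track has zero total stops",
            call. = FALSE)
    return(NULL)
  }
  ac <- chars %in% c("A", "C")
  if (sum(ac) < min_ac) {
    warning("transcript skipped: fewer than ", min_ac,
            " defined A/C positions", call. = FALSE)
    return(NULL)
  }
  gm <- sqrt(tot_t * tot_c)
  tp <- treated / tot_t * gm
  cp <- control / tot_c * gm
  raw <- pmax(0, log(tp + 1) - log(cp + 1))
  raw[!ac] <- NA_real_
  theta <- raw / react_norm_factor(raw[ac], pct_window)
  pmin(theta, cap)
}

# Mean of the defined values ranked in the (lo, hi] top-percentile window;
# falls back to the single top value on very short tracks and to 1 when the
# window mean is zero (all-zero signal stays zero).
react_norm_factor <- function(vals, pct_window = c(0.02, 0.08)) {
  n <- length(vals)
  srt <- sort(vals, decreasing = TRUE)
  lo <- floor(pct_window[1] * n) + 1L
  hi <- max(lo, ceiling(pct_window[2] * n))
  f <- mean(srt[lo:hi])
  if (!is.finite(f) || f <= 0) 1 else f
}

#' Compute reactivity tracks for a set of transcripts
#'
#' Applies [compute_reactivity()] to every transcript present in all three
#' inputs; transcripts that are skipped are dropped from the result.
#'
#' @param treated,control Named lists of count vectors.
#' @param sequences Named character vector of transcript sequences.
#' @inheritParams compute_reactivity
#' @return Named list of reactivity vectors.
#' @export
compute_reactivity_tracks <- function(treated, control, sequences, cap = 7,
                                      pct_window = c(0.02, 0.08),
                                      min_ac = 10) {
  ids <- intersect(intersect(names(treated), names(control)),
                   names(sequences))
  out <- lapply(ids, function(id)
    compute_reactivity(treated[[id]], control[[id]], sequences[[id]],
                       cap = cap, pct_window = pct_window, min_ac = min_ac))
  names(out) <- ids
  out[!vapply(out, is.null, logical(1))]
}
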