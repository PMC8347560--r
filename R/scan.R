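#' Scan transcript sequences for canonical RNA G-quadruplex motifs
#'
#' Finds all occurrences of the canonical RG4 motif
#' \code{G(x)N(1-7)G(x)N(1-7)G(x)N(1-7)G(x)} with \code{x >= 3}: four
#' G-tracts of at least three guanines separated by three loops of 1--7
#' nucleotides. G-tracts are maximal G-runs, so a loop never begins or ends
#' with a guanine that could extend an adjacent tract, and a run longer than
#' three contributes its full length to the tract. Matches are reported
#' leftmost-first and non-overlapping: at each viable start the parse takes
#' the nearest admissible G-run for every subsequent tract, and scanning
#' resumes after the match end. With \code{report_overlaps = TRUE} a match is
#' reported at every viable start regardless of overlap.
#'
#' The number of G-quartets of a motif is taken as the minimum of its four
#' tract lengths.
#'
#' @param sequences Named character vector of sequences over A/C/G/T
#'   (lowercase and U accepted; U is mapped to T). A single unnamed string is
#'   given the id \code{"seq1"}.
#' @param report_overlaps Logical; report a match at every viable start
#'   instead of applying the non-overlap rule.
#' @return A data.frame with one row per motif: \code{transcript_id},
#'   \code{start}, \code{end} (0-based, half-open), \code{width},
#'   \code{sequence}, tract lengths \code{tract1..tract4}, \code{quartets},
#'   loop lengths \code{loop1..loop3}, and \code{status} (\code{"putative"}).
#' @examples
#' scan_g4(c(tx1 = "GGGAGGGAGGGAGGG"))
#' @export
scan_g4 <- function(sequences, report_overlaps = FALSE) {
  if (!is.character(sequences) || length(sequences) == 0)
    stop_("'sequences' must be a non-empty character vector")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  out <- lapply(names(sequences), function(id)
    scan_g4_one(sequences[[id]], id, report_overlaps))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# IUPAC codes other than A/C/G/T/U are tolerated and treated as non-G.
.iupac <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V")

scan_g4_one <- function(sequence, id, report_overlaps) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars[chars == "U"] <- "T"
  bad <- which(!chars %in% .iupac)
  if (length(bad) > 0)
    stop_("non-IUPAC character '", chars[bad[1]], "' in sequence '", id,
          "' at position ", bad[1] - 1L, " (0-based)")
  empty <- data.frame(
    transcript_id = character(), start = integer(), end = integer(),
    width = integer(), sequence = character(),
    tract1 = integer(), tract2 = integer(), tract3 = integer(),
    tract4 = integer(), quartets = integer(),
    loop1 = integer(), loop2 = integer(), loop3 = integer(),
    status = character(), stringsAsFactors = FALSE)
  n <- length(chars)
  if (n < 15L) return(empty)

  # maximal G-runs of length >= 3 are the only admissible tracts
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)              # 1-based inclusive
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 3L
  rs <- starts[keep] - 1L                # 0-based start
  re <- ends[keep]                       # 0-based exclusive end
  m <- length(rs)
  if (m < 4L) return(empty)

  # nearest-first depth-first completion: tracts k+1..4 from run index > i
  complete <- function(i, depth) {
    if (depth == 0L) return(integer(0))
    js <- which(rs - re[i] >= 1L & rs - re[i] <= 7L)
    for (j in js[js > i]) {
      rest <- complete(j, depth - 1L)
      if (!is.null(rest)) return(c(j, rest))
    }
    NULL
  }

  hits <- list()
  limit <- 0L
  for (i in seq_len(m)) {
    if (!report_overlaps && rs[i] < limit) next
    chain <- complete(i, 3L)
    if (is.null(chain)) next
    idx <- c(i, chain)
    tr <- re[idx] - rs[idx]
    lp <- rs[idx[-1]] - re[idx[-4]]
    hits[[length(hits) + 1L]] <- data.frame(
      transcript_id = id, start = rs[i], end = re[idx[4]],
      width = re[idx[4]] - rs[i],
      sequence = paste(chars[(rs[i] + 1L):re[idx[4]]], collapse = ""),
      tract1 = tr[1], tract2 = tr[2], tract3 = tr[3], tract4 = tr[4],
      quartets = min(tr),
      loop1 = lp[1], loop2 = lp[2], loop3 = lp[3],
      status = "putative", stringsAsFactors = FALSE)
    if (!report_overlaps) limit <- re[idx[4]]
  }
  if (length(hits) == 0) return(empty)
  do.call(rbind, hits)
}

#' Loop-composition labels for G-quadruplex motifs
#'
#' Encodes the three loops of each motif as \code{"Loop_X_Y"} where X is the
#' loop index (1--3) and Y its length in nucleotides, the encoding used in
#' loop-composition summaries.
#'
#' @param motifs A motif data.frame from [scan_g4()] (columns
#'   \code{loop1..loop3}).
#' @return A character matrix with one row per motif and three columns.
#' @examples
#' m <- scan_g4(c(tx = "GGGAGGGTTTGGGTTGGG"))
#' loop_labels(m)
#' @export
loop_labels <- function(motifs) {
  ll <- as.matrix(motifs[, c("loop1", "loop2", "loop3")])
  out <- matrix(sprintf("Loop_%d_%d", rep(1:3, each = nrow(ll)), ll),
                nrow = nrow(ll))
  colnames(out) <- c("loop1", "loop2", "loop3")
  rownames(out) <- NULL
  out
}

#' Derive unfolded G-quadruplexes as putative minus observed
#'
#' The unfolded set (UG4) is the exact set difference of the putative motif
#' set and the observed (folded in-cell) set, keyed by
#' \code{(transcript_id, start, end)}. Observed must be a subset of putative.
#'
#' @param putative,observed Motif data.frames.
#' @return The rows of \code{putative} absent from \code{observed}, with
#'   \code{status} set to \code{"unfolded"}.
#' @export
derive_ug4 <- function(putative, observed) {
  pk <- motif_key(putative)
  ok <- motif_key(observed)
  stray <- setdiff(ok, pk)
  if (length(stray) > 0)
    stop_("observed motifs absent from putative set: ",
          paste(utils::head(stray, 5), collapse = ", "))
  ug4 <- putative[!pk %in% ok, , drop = FALSE]
  if (nrow(ug4) > 0) ug4$status <- "unfolded"
  rownames(ug4) <- NULL
  ug4
}

#' Summarize a motif set
#'
#' Tabulates motif lengths, quartet numbers and loop composition, and the
#' two headline loop fractions: motifs whose total loop length is below
#' 10 nt, and motifs all three of whose loops are at most 3 nt.
#'
#' @param motifs A motif data.frame from [scan_g4()]; may be empty.
#' @return A list with \code{n}, \code{length_hist}, \code{quartet_hist},
#'   \code{loop_composition} (counts per \code{Loop_X_Y} label),
#'   \code{frac_total_loop_lt10} and \code{frac_all_loops_le3}.
#' @export
summarize_motifs <- function(motifs) {
  if (nrow(motifs) == 0) {
    return(list(n = 0L, length_hist = table(integer()),
                quartet_hist = table(integer()),
                loop_composition = table(character()),
                frac_total_loop_lt10 = NA_real_,
                frac_all_loops_le3 = NA_real_))
  }
  total_loop <- motifs$loop1 + motifs$loop2 + motifs$loop3
  all_le3 <- motifs$loop1 <= 3 & motifs$loop2 <= 3 & motifs$loop3 <= 3
  list(
    n = nrow(motifs),
    length_hist = table(motifs$width),
    quartet_hist = table(motifs$quartets),
    loop_composition = table(as.vector(loop_labels(motifs))),
    frac_total_loop_lt10 = mean(total_loop < 10),
    frac_all_loops_le3 = mean(all_le3))
}
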