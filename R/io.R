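# File formats: FASTA for sequences (via Biostrings); tab-delimited tables
# for everything else. All transcript coordinates are 0-based, half-open;
# strand in transcript space is always "+".

#' Read transcript sequences from FASTA
#'
#' Sequences are uppercased and U is mapped to T (the internal alphabet is
#' DNA-style, matching reference transcriptome FASTA files); a note is
#' emitted when U bases are present.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  if (any(grepl("U", out, fixed = TRUE))) {
    message("FASTA contains U bases; mapping U -> T")
    out <- gsub("U", "T", out, fixed = TRUE)
  }
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write transcript sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

read_tsv_checked <- function(path, cols) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(cols %in% names(df)))
    stop_("malformed file '", path, "': expected columns ",
          paste(cols, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write a transcript region annotation table
#'
#' Tab-delimited with header \code{transcript_id utr5_end cds_end length}:
#' 0-based half-open prefix boundaries partitioning each transcript into
#' 5'-UTR, CDS and 3'-UTR.
#'
#' @param path File path.
#' @return \code{read_annotation()} returns the validated data.frame.
#' @export
read_annotation <- function(path) {
  validate_annotation(read_tsv_checked(
    path, c("transcript_id", "utr5_end", "cds_end", "length")))
}

#' @rdname read_annotation
#' @param annotation Annotation data.frame.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv(validate_annotation(annotation), path)
}

#' Read or write RT-stop count tracks
#'
#' Tab-delimited with header \code{transcript_id position count}; positions
#' are 0-based and dense (every position of each transcript is written).
#'
#' @param path File path.
#' @param lengths Optional named vector of transcript lengths used to pad
#'   tracks whose trailing positions are absent.
#' @return \code{read_rtsc()} returns a named list of integer count vectors.
#' @export
read_rtsc <- function(path, lengths = NULL) {
  df <- read_tsv_checked(path, c("transcript_id", "position", "count"))
  if (any(df$count < 0) || any(df$position < 0))
    stop_("malformed file '", path, "': negative position or count")
  out <- lapply(split(df, df$transcript_id), function(d) {
    L <- if (!is.null(lengths)) lengths[[d$transcript_id[1]]]
         else max(d$position) + 1L
    v <- integer(L)
    v[d$position + 1L] <- as.integer(d$count)
    v
  })
  out[unique(df$transcript_id)]
}

#' @rdname read_rtsc
#' @param tracks Named list of count vectors.
#' @export
write_rtsc <- function(tracks, path) {
  df <- do.call(rbind, lapply(names(tracks), function(id)
    data.frame(transcript_id = id,
               position = seq_along(tracks[[id]]) - 1L,
               count = tracks[[id]], stringsAsFactors = FALSE)))
  write_tsv(df, path)
}

#' Read or write reactivity tracks
#'
#' Tab-delimited with header \code{transcript_id position theta}; undefined
#' (G/T) positions are written as \code{NA}. Values round-trip bit-exactly.
#'
#' @param path File path.
#' @return \code{read_react()} returns a named list of numeric vectors.
#' @export
read_react <- function(path) {
  df <- read_tsv_checked(path, c("transcript_id", "position", "theta"))
  out <- lapply(split(df, df$transcript_id), function(d) {
    v <- rep(NA_real_, max(d$position) + 1L)
    v[d$position + 1L] <- as.numeric(d$theta)
    v
  })
  out[unique(df$transcript_id)]
}

#' @rdname read_react
#' @param tracks Named list of reactivity vectors.
#' @export
write_react <- function(tracks, path) {
  df <- do.call(rbind, lapply(names(tracks), function(id)
    data.frame(transcript_id = id,
               position = seq_along(tracks[[id]]) - 1L,
               theta = sprintf("%.17g", tracks[[id]]),
               stringsAsFactors = FALSE)))
  df$theta[df$theta == "NA"] <- "NA"
  write_tsv(df, path)
}

#' Read or write BED6 intervals in transcript coordinates
#'
#' Six columns without header: transcript id, start, end (0-based,
#' half-open), name, score, strand (always \code{"+"} in transcript space).
#' Records with \code{start >= end} or negative start are rejected.
#'
#' @param path File path.
#' @return \code{read_bed()} returns a data.frame with columns
#'   \code{transcript_id}, \code{start}, \code{end}, \code{name},
#'   \code{score}, \code{strand}.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop_("malformed BED file '", path, "': fewer than 6 columns")
  df <- df[, 1:6]
  names(df) <- c("transcript_id", "start", "end", "name", "score", "strand")
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad) > 0)
    stop_("malformed BED record in '", path, "' at line ", bad[1],
          ": start >= end or negative start")
  df
}

#' @rdname read_bed
#' @param intervals Data.frame with at least \code{transcript_id},
#'   \code{start}, \code{end}; \code{name}/\code{score}/\code{strand} are
#'   filled with defaults when absent.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(
    transcript_id = intervals$transcript_id,
    start = intervals$start, end = intervals$end,
    name = intervals$name %||% ".",
    score = intervals$score %||% 0L,
    strand = intervals$strand %||% "+", stringsAsFactors = FALSE)
  if (any(df$start >= df$end | df$start < 0))
    stop_("refusing to write invalid BED intervals (start >= end)")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a motif set as BED6
#'
#' The name field encodes quartets and loop lengths as
#' \code{G4|q{quartets}|l{l1,l2,l3}}; the score is the quartet number.
#'
#' @param motifs Motif data.frame from [scan_g4()].
#' @param path Output path.
#' @export
write_motifs_bed <- function(motifs, path) {
  motifs$name <- sprintf("G4|q%d|l%d,%d,%d", motifs$quartets,
                         motifs$loop1, motifs$loop2, motifs$loop3)
  motifs$score <- motifs$quartets
  motifs$strand <- "+"
  write_bed(motifs, path)
}

#' Read or write an expression table
#'
#' Tab-delimited with header \code{transcript_id tpm}.
#'
#' @param path File path.
#' @return \code{read_expression()} returns the data.frame.
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path, c("transcript_id", "tpm"))
  if (any(!is.finite(df$tpm)) || any(df$tpm < 0))
    stop_("malformed expression file '", path,
          "': TPM must be finite and non-negative")
  df
}

#' @rdname read_expression
#' @param expression Data.frame \code{transcript_id}, \code{tpm}.
#' @export
write_expression <- function(expression, path) {
  write_tsv(expression[, c("transcript_id", "tpm")], path)
}
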