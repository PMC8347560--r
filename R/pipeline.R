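#' Run the full detection-and-profiling workflow
#'
#' Ties the stages together in order — motif scan, reactivity computation,
#' observed/unfolded call, positional profiling, expression sampling — from
#' files on disk to an output directory, with a plain-text run log recording
#' parameters and seeds. Stages communicate only through the documented file
#' formats; a stage failure halts the run naming the stage.
#'
#' @param config A named list (or path to a YAML file) with input paths —
#'   \code{fasta}, \code{annotation}, \code{treated_rtsc},
#'   \code{control_rtsc} required; \code{expression}, \code{mirna_bed},
#'   \code{polya_tsv} optional — and stage parameters (all optional):
#'   \code{tau_fold} (0.5), \code{cap} (7), \code{window} (300),
#'   \code{mirna_flank} (100), \code{polya_flank} (200), \code{bin} (20),
#'   \code{tpm_threshold} (1), \code{n_rounds} (1000), \code{seed} (1).
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the fitted \code{og4_fit} object, the
#'   profiling results, the sampling result (if expression was supplied) and
#'   the output paths.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  defaults <- list(tau_fold = 0.5, cap = 7, window = 300,
                   mirna_flank = 100, polya_flank = 200, bin = 20,
                   tpm_threshold = 1, n_rounds = 1000, seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  for (f in c("fasta", "annotation", "treated_rtsc", "control_rtsc")) {
    if (is.null(cfg[[f]])) stop_("config is missing required path '", f, "'")
    if (!file.exists(cfg[[f]]))
      stop_("input path '", f, "' does not exist: ", cfg[[f]])
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("rg4scope pipeline run")
  logf("package version: %s", as.character(utils::packageVersion("rg4scope")))
  logf("started: %s", format(Sys.time()))
  for (k in names(cfg)) logf("param %s = %s", k, paste(cfg[[k]], collapse = ","))

  stage <- function(name, expr) {
    logf("== stage: %s ==", name)
    tryCatch(expr, error = function(e)
      stop_("pipeline halted at stage '", name, "': ", conditionMessage(e)))
  }

  paths <- list()
  inputs <- stage("load", {
    sequences <- read_fasta(cfg$fasta)
    annotation <- read_annotation(cfg$annotation)
    lengths <- stats::setNames(annotation$length, annotation$transcript_id)
    treated <- read_rtsc(cfg$treated_rtsc, lengths)
    control <- read_rtsc(cfg$control_rtsc, lengths)
    list(sequences = sequences, annotation = annotation, lengths = lengths,
         treated = treated, control = control)
  })

  fit <- stage("scan+reactivity+call", {
    detect_og4(inputs$sequences, inputs$treated, inputs$control,
               annotation = inputs$annotation, tau_fold = cfg$tau_fold,
               cap = cfg$cap)
  })
  stage("write calls", {
    paths$motifs <- file.path(outdir, "motifs.tsv")
    write_tsv(fit$motifs, paths$motifs)
    paths$og4_bed <- file.path(outdir, "og4.bed")
    paths$ug4_bed <- file.path(outdir, "ug4.bed")
    if (nrow(fit$og4) > 0) write_motifs_bed(fit$og4, paths$og4_bed)
    if (nrow(fit$ug4) > 0) write_motifs_bed(fit$ug4, paths$ug4_bed)
    paths$react <- file.path(outdir, "reactivity.tsv")
    write_react(fit$theta, paths$react)
  })

  prof <- stage("profiling", {
    out <- list()
    out$regions <- region_counts_density(fit$og4, inputs$annotation)
    paths$regions <- file.path(outdir, "region_summary.tsv")
    write_tsv(out$regions, paths$regions)
    utr5_og4 <- fit$og4[fit$og4$region == "UTR5", , drop = FALSE]
    out$five_prime <- relative_density_5p(utr5_og4, inputs$annotation,
                                          window = cfg$window)
    paths$five_prime <- file.path(outdir, "five_prime_profile.tsv")
    write_tsv(out$five_prime$profile, paths$five_prime)
    if (!is.null(cfg$mirna_bed)) {
      sites <- read_bed(cfg$mirna_bed)
      anchors <- data.frame(
        transcript_id = fit$og4$transcript_id,
        pos = floor((fit$og4$start + fit$og4$end) / 2))
      utr3 <- region_bounds(inputs$annotation, "UTR3")
      names(utr3)[2:3] <- c("start", "end")
      out$mirna_profile <- metagene_profile(
        anchors, sites, inputs$lengths, flank = cfg$mirna_flank,
        control_space = utr3, seed = cfg$seed)
      paths$mirna_profile <- file.path(outdir, "mirna_metagene.tsv")
      write_tsv(out$mirna_profile$profile, paths$mirna_profile)
    }
    if (!is.null(cfg$polya_tsv)) {
      pa <- read_tsv_checked(cfg$polya_tsv, c("transcript_id", "pos"))
      utr3 <- region_bounds(inputs$annotation, "UTR3")
      names(utr3)[2:3] <- c("start", "end")
      out$polya_profile <- metagene_profile(
        pa, fit$og4, inputs$lengths, flank = cfg$polya_flank,
        control_space = utr3, seed = cfg$seed)
      paths$polya_profile <- file.path(outdir, "polya_metagene.tsv")
      write_tsv(out$polya_profile$profile, paths$polya_profile)
      out$forming <- forming_probability(fit$og4, fit$motifs, pa,
                                         inputs$lengths,
                                         depth = cfg$polya_flank,
                                         bin = cfg$bin)
      paths$forming <- file.path(outdir, "forming_probability.tsv")
      write_tsv(out$forming$bins, paths$forming)
      pb <- out$forming$bins$p
      if (sum(!is.na(pb)) >= 4) {
        out$trend <- mann_kendall(pb[!is.na(pb)])
        logf("forming-probability trend: S = %g, p = %.4g",
             out$trend$S, out$trend$p.value)
      }
    }
    out
  })

  sampling <- NULL
  if (!is.null(cfg$expression)) {
    sampling <- stage("sampling", {
      expr <- read_expression(cfg$expression)
      keep <- filter_expressed(expr, cfg$tpm_threshold)
      expr <- expr[expr$transcript_id %in% keep, , drop = FALSE]
      utr3_og4_tx <- unique(fit$og4$transcript_id[fit$og4$region == "UTR3"])
      grp <- expr$transcript_id %in% utr3_og4_tx
      if (sum(grp) == 0 || sum(!grp) < 2) {
        logf("sampling skipped: degenerate group sizes (%d vs %d)",
             sum(grp), sum(!grp))
        NULL
      } else {
        res <- random_sampling_test(
          stats::setNames(expr$tpm[grp], expr$transcript_id[grp]),
          stats::setNames(expr$tpm[!grp], expr$transcript_id[!grp]),
          n_rounds = cfg$n_rounds, seed = cfg$seed)
        paths$sampling <- file.path(outdir, "sampling_pvalues.tsv")
        write_tsv(data.frame(round = seq_along(res$p), p = res$p),
                  paths$sampling)
        logf("sampling: %d/%d rounds with p < %g", res$n_significant,
             res$n_rounds, res$alpha)
        res
      }
    })
  }
  logf("finished: %s", format(Sys.time()))
  invisible(list(fit = fit, profiles = prof, sampling = sampling,
                 paths = paths, config = cfg))
}
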