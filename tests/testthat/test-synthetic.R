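test_that("configuration invariants are enforced", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(cds_len = c(300, 901)), "multiples of 3")
  expect_error(synthetic_config(utr5_len = c(300, 100)), "range")
  expect_error(synthetic_config(lambda_dms = 0.5, lambda_bg = 1), "exceed")
  expect_error(synthetic_config(protection = 1), "protection")
  expect_error(synthetic_config(frac_folded = 1.2), "frac_folded")
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- synthetic_config(n_transcripts = 10, seed = 1)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_rtstops(a$sequences, a$truth, cfg),
                   simulate_rtstops(b$sequences, b$truth, cfg))
  expect_identical(simulate_anchor_sites(a$truth, a$annotation, cfg),
                   simulate_anchor_sites(b$truth, b$annotation, cfg))
  c_ <- generate_transcriptome(synthetic_config(n_transcripts = 10, seed = 2))
  expect_false(identical(a$sequences, c_$sequences))
})

test_that("nothing is planted when all region counts are zero", {
  cfg <- synthetic_config(n_transcripts = 10,
                          n_g4_per_region = c(0, 0, 0), seed = 3)
  tx <- generate_transcriptome(cfg)
  expect_equal(sum(tx$truth$planted), 0L)
})

test_that("scan of generated sequences reconciles exactly with truth", {
  cfg <- synthetic_config(n_transcripts = 30,
                          n_g4_per_region = c(1, 1, 2), seed = 4)
  tx <- generate_transcriptome(cfg)
  found <- scan_g4(tx$sequences)
  expect_setequal(motif_keys(found), motif_keys(tx$truth))
  # planted motifs carry the region class they were planted in
  ann <- annotate_region(tx$truth, tx$annotation)
  expect_equal(ann$region, tx$truth$region)
  # planted motifs never overlap on a transcript
  for (id in unique(tx$truth$transcript_id)) {
    tm <- tx$truth[tx$truth$transcript_id == id, ]
    tm <- tm[order(tm$start), ]
    if (nrow(tm) > 1) expect_true(all(tm$start[-1] >= tm$end[-nrow(tm)]))
  }
})

test_that("unsatisfiable planting fails naming the constraint", {
  cfg <- synthetic_config(n_transcripts = 2, utr5_len = c(10L, 10L),
                          n_g4_per_region = c(1, 0, 0), seed = 1)
  expect_error(generate_transcriptome(cfg), "too short")
})

test_that("RT-stop counts follow the stated Poisson means", {
  cfg <- synthetic_config(n_transcripts = 60, protection = 0.1,
                          lambda_bg = 1, lambda_dms = 20,
                          frac_folded = 1, seed = 5)
  tx <- generate_transcriptome(cfg)
  st <- simulate_rtstops(tx$sequences, tx$truth, cfg)
  inside <- out_ac <- out_gt <- ctrl <- numeric(0)
  diff_gt <- numeric(0)
  for (id in names(tx$sequences)) {
    chars <- strsplit(tx$sequences[[id]], "")[[1]]
    fold <- rep(FALSE, length(chars))
    tm <- tx$truth[tx$truth$transcript_id == id & tx$truth$folded, ]
    for (k in seq_len(nrow(tm))) fold[(tm$start[k] + 1):tm$end[k]] <- TRUE
    ac <- chars %in% c("A", "C")
    inside <- c(inside, st$treated[[id]][ac & fold])
    out_ac <- c(out_ac, st$treated[[id]][ac & !fold])
    diff_gt <- c(diff_gt, st$treated[[id]][!ac] - st$control[[id]][!ac])
    ctrl <- c(ctrl, st$control[[id]])
  }
  # closed-form Poisson means: 1 + 20*0.1 = 3 inside, 1 + 20 = 21 outside
  expect_gt(length(out_ac), 1e4)
  expect_lt(abs(mean(inside) - 3), 3 * sqrt(3 / length(inside)))
  expect_lt(abs(mean(out_ac) - 21), 3 * sqrt(21 / length(out_ac)))
  expect_lt(abs(mean(ctrl) - 1), 3 * sqrt(1 / length(ctrl)))
  # treated - control at G/T has mean 0 (background only)
  expect_lt(abs(mean(diff_gt)), 3 * stats::sd(diff_gt) / sqrt(length(diff_gt)))
  expect_true(all(st$treated[[1]] >= 0) && all(st$control[[1]] >= 0))
})

test_that("full protection with no background silences folded motifs", {
  cfg <- synthetic_config(n_transcripts = 10, protection = 0,
                          lambda_bg = 0, lambda_dms = 20,
                          frac_folded = 1, seed = 6)
  tx <- generate_transcriptome(cfg)
  st <- simulate_rtstops(tx$sequences, tx$truth, cfg)
  for (id in unique(tx$truth$transcript_id)) {
    tm <- tx$truth[tx$truth$transcript_id == id & tx$truth$folded, ]
    for (k in seq_len(nrow(tm)))
      expect_true(all(st$treated[[id]][(tm$start[k] + 1):tm$end[k]] == 0))
  }
})

test_that("expression table is TPM-normalized with the planted group effect", {
  cfg <- synthetic_config(n_transcripts = 400, expr_effect = 2, seed = 7)
  tx <- generate_transcriptome(cfg)
  ex <- simulate_expression(tx$truth, tx$annotation, cfg)
  expect_equal(sum(ex$tpm), 1e6, tolerance = 1e-9)
  expect_gt(sum(ex$og4_utr3), 20)
  p <- stats::wilcox.test(ex$tpm[ex$og4_utr3], ex$tpm[!ex$og4_utr3],
                          alternative = "greater", exact = FALSE)$p.value
  expect_lt(p, 0.01)
  # null case: no effect, groups indistinguishable
  cfg0 <- synthetic_config(n_transcripts = 400, expr_effect = 1, seed = 8)
  tx0 <- generate_transcriptome(cfg0)
  ex0 <- simulate_expression(tx0$truth, tx0$annotation, cfg0)
  p0 <- stats::ks.test(ex0$tpm[ex0$og4_utr3],
                       ex0$tpm[!ex0$og4_utr3])$p.value
  expect_gt(p0, 0.01)
})

test_that("poly(A) anchors respect the exclusion radius around motifs", {
  cfg <- synthetic_config(n_transcripts = 30, polya_exclusion = 50, seed = 9)
  tx <- generate_transcriptome(cfg)
  an <- simulate_anchor_sites(tx$truth, tx$annotation, cfg)
  for (k in seq_len(nrow(an$polya))) {
    id <- an$polya$transcript_id[k]
    p <- an$polya$pos[k]
    tm <- tx$truth[tx$truth$transcript_id == id, ]
    if (nrow(tm) > 0)
      expect_true(all(p < tm$start - 50 | p > tm$end - 1 + 50))
  }
  # impossible exclusion: 3'-UTR fully blanketed by the radius
  cfg_bad <- synthetic_config(n_transcripts = 5, utr3_len = c(120L, 150L),
                              n_g4_per_region = c(0, 0, 1),
                              polya_exclusion = 200L, seed = 10)
  expect_error(simulate_anchor_sites(
    generate_transcriptome(cfg_bad)$truth,
    generate_transcriptome(cfg_bad)$annotation, cfg_bad),
    "no legal placement")
})

test_that("miRNA enrichment knob shifts sites toward motif windows", {
  mk <- function(enr, seed) {
    cfg <- synthetic_config(n_transcripts = 60, mirna_enrichment = enr,
                            n_mirna_per_transcript = 4, seed = seed)
    tx <- generate_transcriptome(cfg)
    an <- simulate_anchor_sites(tx$truth, tx$annotation, cfg)
    hits <- 0
    for (k in seq_len(nrow(an$mirna))) {
      id <- an$mirna$transcript_id[k]
      tm <- tx$truth[tx$truth$transcript_id == id &
                       tx$truth$region == "UTR3", ]
      if (nrow(tm) > 0 &&
          any(an$mirna$start[k] < tm$end + 25 &
              an$mirna$end[k] > tm$start - 25))
        hits <- hits + 1
    }
    hits / nrow(an$mirna)
  }
  expect_gt(mk(0.8, 11), mk(0, 11) + 0.2)
})
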