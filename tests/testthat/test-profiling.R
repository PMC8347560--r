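ann1 <- data.frame(transcript_id = c("t1", "t2"),
                   utr5_end = c(50L, 100L), cds_end = c(350L, 400L),
                   length = c(500L, 900L), stringsAsFactors = FALSE)

test_that("motifs are labelled by start position, spanning flagged", {
  m <- data.frame(transcript_id = c("t1", "t1", "t1", "t2"),
                  start = c(10L, 49L, 400L, 350L),
                  end = c(25L, 70L, 420L, 380L))
  lab <- annotate_region(m, ann1)
  expect_equal(lab$region, c("UTR5", "UTR5", "UTR3", "CDS"))
  expect_equal(lab$spans_boundary, c(FALSE, TRUE, FALSE, FALSE))
  bad <- data.frame(transcript_id = "t1", start = 500L, end = 515L)
  expect_error(annotate_region(bad, ann1), "beyond transcript length")
  expect_error(annotate_region(m, data.frame(transcript_id = "t1",
                                             utr5_end = 60, cds_end = 50,
                                             length = 100)),
               "invalid annotation")
})

test_that("region proportions normalize and densities follow count/kb", {
  # 2 motifs in 1000 nt of UTR5 -> density 2.0 per kb
  ann <- data.frame(transcript_id = c("a", "b"), utr5_end = c(400L, 600L),
                    cds_end = c(700L, 1200L), length = c(1200L, 2000L))
  m <- data.frame(transcript_id = c("a", "b", "a"),
                  start = c(10L, 20L, 800L), end = c(25L, 35L, 820L))
  rc <- region_counts_density(m, ann)
  expect_equal(rc$count[rc$region == "UTR5"], 2L)
  expect_equal(rc$density_per_kb[rc$region == "UTR5"], 2.0)
  expect_equal(sum(rc$proportion), 1)
  counts <- c(10, 5, 85)
  expect_equal(counts / sum(counts), c(0.10, 0.05, 0.85))
  # empty motif set -> zeros, not an error
  rc0 <- region_counts_density(m[0, ], ann)
  expect_true(all(rc0$count == 0))
})

test_that("counts can rank regions differently from densities", {
  # 3'-UTR numerous but 5'-UTR dense
  cfg <- synthetic_config(n_transcripts = 40, utr5_len = c(60L, 80L),
                          utr3_len = c(900L, 1200L),
                          n_g4_per_region = c(1, 0, 2), seed = 12)
  tx <- generate_transcriptome(cfg)
  rc <- region_counts_density(tx$truth, tx$annotation)
  expect_equal(rc$region[which.max(rc$count)], "UTR3")
  expect_equal(rc$region[which.max(rc$density_per_kb)], "UTR5")
})

test_that("five-prime relative density follows d_i = G_i/T_i x 1000", {
  ann <- data.frame(transcript_id = "t1", utr5_end = 100L, cds_end = 200L,
                    length = 400L)
  m <- data.frame(transcript_id = "t1", start = 20L, end = 35L)
  pr <- relative_density_5p(m, ann, window = 50)
  d <- pr$profile$d
  expect_equal(d[21:35], rep(1000, 15))   # covered 1-based positions
  expect_equal(d[c(1:20, 36:50)], rep(0, 35))
  expect_true(all(pr$profile$T == 1))
  # start counting mode: only the start position registers
  pr_s <- relative_density_5p(m, ann, window = 50, count_mode = "start")
  expect_equal(which(pr_s$profile$d > 0), 21L)
  # T_i decreases as transcripts run out
  ann2 <- rbind(ann, data.frame(transcript_id = "t2", utr5_end = 10L,
                                cds_end = 20L, length = 30L))
  pr2 <- relative_density_5p(m, ann2, window = 50)
  expect_equal(pr2$profile$T, c(rep(2, 30), rep(1, 20)))
  expect_false(is.unsorted(rev(pr2$profile$T)))
})

test_that("background density follows l/L x 1000 and the mean identity", {
  # l = 500 motif nt over L = 100,000 nt of region -> 5.0 per kb
  ann <- data.frame(transcript_id = sprintf("t%03d", 1:200),
                    utr5_end = 500L, cds_end = 800L, length = 1300L)
  m <- data.frame(transcript_id = sprintf("t%03d", 1:25),
                  start = 100L, end = 120L)   # 25 x 20 nt = 500 nt
  expect_equal(background_density(m, ann, "UTR5"), 5.0)
  # every transcript covers the window -> mean(d) equals the windowed
  # background (Eq1/Eq2 consistency)
  pr <- relative_density_5p(m, ann, window = 500)
  expect_equal(mean(pr$profile$d), background_density(m, ann, "UTR5"))
})

test_that("start-codon alignment scans upstream of the CDS", {
  ann <- data.frame(transcript_id = "t1", utr5_end = 100L, cds_end = 200L,
                    length = 300L)
  # motif ending flush at the start codon: upstream offsets 1..15 covered
  m <- data.frame(transcript_id = "t1", start = 85L, end = 100L)
  pr <- relative_density_5p(m, ann, window = 50, align = "start_codon")
  expect_equal(which(pr$profile$d > 0), 1:15)
})

test_that("distances to region ends satisfy the conservation identity", {
  ann <- data.frame(transcript_id = "t1", utr5_end = 100L, cds_end = 200L,
                    length = 300L)
  m <- data.frame(transcript_id = rep("t1", 3),
                  start = c(20L, 0L, 150L), end = c(35L, 15L, 170L))
  d <- distance_to_ends(m, ann, region = "UTR5")
  expect_equal(d$dist5[1], 20L)
  expect_equal(d$dist3[1], 65L)
  expect_equal(d$dist5[2], 0L)            # flush at the 5' end
  expect_false(d$contained[3])            # CDS motif skipped with flag
  ok <- d$contained
  expect_equal(d$dist5[ok] + d$dist3[ok] + (d$end - d$start)[ok],
               rep(100L, sum(ok)))
})

test_that("metagene density is 1 when features blanket every anchor", {
  lens <- c(t1 = 1000L)
  anchors <- data.frame(transcript_id = "t1", pos = c(300L, 500L, 700L))
  feats <- data.frame(transcript_id = rep("t1", 3),
                      start = c(290L, 490L, 690L), end = c(311L, 511L, 711L))
  pr <- metagene_profile(anchors, feats, lens, flank = 10)
  expect_equal(pr$profile$density, rep(1, 21))
  expect_error(metagene_profile(anchors[0, ], feats, lens, flank = 10),
               "zero anchors")
})

test_that("independently placed features give a flat profile near its control", {
  set.seed(21)
  lens <- stats::setNames(rep(2000L, 30), sprintf("t%02d", 1:30))
  anchors <- data.frame(
    transcript_id = rep(names(lens), each = 5),
    pos = sample(200:1800, 150, replace = TRUE))
  fs <- sample(0:1950, 120, replace = TRUE)
  feats <- data.frame(transcript_id = sample(names(lens), 120, replace = TRUE),
                      start = fs, end = fs + 50L)
  space <- data.frame(transcript_id = names(lens), start = 0L, end = 2000L)
  pr <- metagene_profile(anchors, feats, lens, flank = 100,
                         control_space = space, seed = 1)
  p_hat <- mean(pr$profile$density)
  se <- sqrt(p_hat * (1 - p_hat) / 150)
  expect_true(all(abs(pr$profile$density - p_hat) < 5 * se))
  expect_lt(abs(mean(pr$profile$control_density) - p_hat), 4 * se)
  # binned aggregation preserves the overall mean
  b <- bin_anchor_profile(pr, bin = 20)
  expect_lt(abs(mean(b$density) - p_hat), 0.01)
})

test_that("forming probability is the OG4/putative density ratio per bin", {
  lens <- c(t1 = 600L)
  anchors <- data.frame(transcript_id = "t1", pos = 100L)
  put <- data.frame(transcript_id = "t1", start = 100L, end = 300L)
  # OG4 = putative -> p = 1 in defined bins
  fp1 <- forming_probability(put, put, anchors, lens)
  expect_true(all(fp1$bins$p[!is.na(fp1$bins$p)] == 1))
  # OG4 empty -> p = 0
  fp0 <- forming_probability(put[0, ], put, anchors, lens)
  expect_true(all(fp0$bins$p[!is.na(fp0$bins$p)] == 0))
  # OG4 covering 5 of the 20 occupied downstream nt in the bin -> p = 0.25
  og <- data.frame(transcript_id = "t1", start = 100L, end = 106L)
  fp <- forming_probability(og, put, anchors, lens, depth = 20, bin = 20)
  expect_equal(fp$bins$p[1], 0.25)
  # subset precondition
  stray <- data.frame(transcript_id = "t1", start = 400L, end = 420L)
  expect_error(forming_probability(stray, put, anchors, lens), "subset")
  expect_true(all(fp1$bins$p >= 0 & fp1$bins$p <= 1, na.rm = TRUE))
})

test_that("Mann-Kendall statistic and p-value follow the stated dialect", {
  # strictly increasing: all 45 pairs concordant
  expect_equal(mann_kendall(1:10)$S, 45)
  # constant series
  mk_c <- mann_kendall(rep(2, 6))
  expect_equal(mk_c$S, 0)
  expect_equal(mk_c$p.value, 1)
  expect_error(mann_kendall(1:3), "at least 4")
  # reversal negates S, preserves p
  x <- c(3, 1, 4, 1.5, 5, 9, 2.6, 5.3, 5.8, 9.7)
  a <- mann_kendall(x)
  b <- mann_kendall(rev(x))
  expect_equal(b$S, -a$S)
  expect_equal(b$p.value, a$p.value)
  # invariant under strictly monotone transforms
  expect_equal(mann_kendall(exp(x))$p.value, a$p.value)
  expect_equal(mann_kendall(x)$S, mann_kendall(rank(x))$S)
  # tie-corrected variance, hand-computed for one tie group of 2 at n=5:
  # (5*4*15 - 2*1*9)/18 = 15.666...
  expect_equal(mann_kendall(c(1, 2, 2, 3, 4))$varS, 282 / 18)
})

test_that("Mann-Kendall S agrees with Kendall tau from cor.test", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(8:15, 1))
    n <- length(x)
    S_tau <- unname(cor.test(seq_along(x), x,
                             method = "kendall")$estimate) * n * (n - 1) / 2
    expect_equal(mann_kendall(x)$S, round(S_tau))
  }
})
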