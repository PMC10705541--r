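mk_ctss <- function(pos, count, strand = "+", chrom = "c1") {
  tibble::tibble(chrom = chrom, pos = pos, strand = strand, count = count)
}

test_that("TPM normalisation conserves a million and splits proportionally", {
  single <- tpm_normalize(mk_ctss(100, 7))
  expect_equal(single$tpm, 1e6)
  pair <- tpm_normalize(mk_ctss(c(100, 200), c(5, 5)))
  expect_equal(pair$tpm, c(5e5, 5e5))
  withr::local_seed(2)
  big <- tpm_normalize(mk_ctss(sample(1:10000, 500), sample(1:50, 500, TRUE)))
  expect_equal(sum(big$tpm), 1e6, tolerance = 1e-6)
})

test_that("CTSS clustering links by gap, keeps strong singletons, picks the dominant TSS", {
  # gap 15 <= 20: one cluster, dominant at the higher-TPM position
  x <- tpm_normalize(mk_ctss(c(100, 115), c(10, 5)))
  cl <- cluster_ctss(x, threshold_tpm = 1, max_dist = 20, keep_singletons_above = 5)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$dominant_pos, 100)
  expect_equal(c(cl$start, cl$end), c(100, 116))

  # gap 30 > 20: two clusters (both multi-position to survive singleton removal)
  y <- tpm_normalize(mk_ctss(c(100, 101, 130, 131), c(5, 5, 5, 5)))
  expect_equal(nrow(cluster_ctss(y)), 2)

  # singleton TPM rule: 2e5 TPM kept, weak one removed at a high threshold
  z <- mk_ctss(c(100, 500), c(1, 99))
  z <- tpm_normalize(z)   # TPMs 1e4 and 9.9e5
  kept <- cluster_ctss(z, threshold_tpm = 1, max_dist = 20,
                       keep_singletons_above = 5e5)
  expect_equal(kept$dominant_pos, 500)
})

test_that("dominant-TSS ties resolve to the 5'-most position on the cluster strand", {
  tie_plus <- tpm_normalize(mk_ctss(c(200, 210), c(5, 5)))
  expect_equal(cluster_ctss(tie_plus)$dominant_pos, 200)
  tie_minus <- tpm_normalize(mk_ctss(c(200, 210), c(5, 5), strand = "-"))
  expect_equal(cluster_ctss(tie_minus)$dominant_pos, 210)
})

test_that("clustering is order-independent and assigns each CTSS once", {
  withr::local_seed(41)
  x <- mk_ctss(sort(sample(1:5000, 300)), sample(1:20, 300, TRUE),
               strand = sample(c("+", "-"), 300, TRUE))
  shuffled <- x[sample.int(nrow(x)), ]
  a <- cluster_ctss(tpm_normalize(x))
  b <- cluster_ctss(tpm_normalize(shuffled))
  expect_equal(a, b)
  # each retained CTSS inside at most one cluster extent (same strand)
  tx <- tpm_normalize(x)
  tx <- tx[tx$tpm >= 1, ]
  covering <- vapply(seq_len(nrow(tx)), function(i) {
    sum(a$chrom == tx$chrom[i] & a$strand == tx$strand[i] &
          a$start <= tx$pos[i] & tx$pos[i] < a$end)
  }, integer(1))
  expect_true(all(covering <= 1))
})

test_that("promoter windows are strand-oriented with the TSS at offset zero", {
  genome <- c(c1 = "ACGTACGTACGTACGTACGT")
  cl <- tibble::tibble(cluster_id = c("p", "m"), chrom = "c1",
                       strand = c("+", "-"), dominant_pos = c(10, 10))
  w <- promoter_windows(cl, genome, width = 3)
  expect_equal(nchar(w$seq), c(7, 7))
  expect_equal(w$seq[1], substr(genome[["c1"]], 8, 14))
  expect_equal(w$seq[2], rc(substr(genome[["c1"]], 8, 14)))
  # TSS base at string position width+1 matches the genome (strand-aware)
  expect_equal(substr(w$seq[1], 4, 4), substr(genome[["c1"]], 11, 11))
  expect_equal(substr(w$seq[2], 4, 4), rc(substr(genome[["c1"]], 11, 11)))
  # truncation at the chromosome end is flagged and padded
  edge <- promoter_windows(tibble::tibble(cluster_id = "e", chrom = "c1",
                                          strand = "+", dominant_pos = 1),
                           genome, width = 3)
  expect_true(edge$truncated)
  expect_equal(substr(edge$seq, 1, 2), "NN")
})

test_that("element density recovers planted element positions", {
  withr::local_seed(61)
  inr <- pwm_from_consensus("INRlike", "TCAGTT")
  dpe <- pwm_from_consensus("DPElike", "AGACGT")
  W <- 100
  mk_win <- function(i) {
    s <- random_seq(2 * W + 1)
    substr(s, W + 1, W + 6) <- "TCAGTT"          # INR at offset 0
    substr(s, W + 29, W + 34) <- "AGACGT"        # DPE at +28
    s
  }
  windows <- tibble::tibble(cluster_id = sprintf("w%03d", 1:150),
                            chrom = "c1", strand = "+", tss = 0,
                            seq = vapply(1:150, mk_win, ""),
                            truncated = FALSE)
  dens <- element_density(windows, list(INRlike = inr, DPElike = dpe),
                          p_threshold = 0.003, background = rep(0.25, 4))
  di <- dens$density[dens$density$motif == "INRlike", ]
  dd <- dens$density[dens$density$motif == "DPElike", ]
  expect_equal(di$offset[which.max(di$count)], 0)
  expect_equal(dd$offset[which.max(dd$count)], 28)
  expect_true(all(dens$presence$INRlike))
  # no hits -> empty density
  none <- element_density(windows[1, ], pwm_from_consensus("x", "AAAAAAAAAAAA"),
                          p_threshold = 1e-7, background = rep(0.25, 4))
  expect_equal(nrow(none$density), 0)
  expect_false(any(none$presence$x))
})

test_that("element enrichment matches hand-computed odds ratios", {
  equal_rate <- element_enrichment(rep(c(TRUE, FALSE), 50), rep(c(TRUE, FALSE), 50))
  expect_equal(equal_rate$odds_ratio, 1)
  hand <- element_enrichment(c(rep(TRUE, 50), rep(FALSE, 50)),
                             c(rep(TRUE, 20), rep(FALSE, 80)))
  expect_equal(hand$odds_ratio, 4.0)
  zero <- element_enrichment(rep(TRUE, 10), rep(FALSE, 10))
  expect_identical(zero$odds_ratio, Inf)
  expect_true(zero$degenerate || zero$odds_ratio == Inf)
})

test_that("dominant-TSS / peak overlap uses half-open containment", {
  cl <- tibble::tibble(cluster_id = c("a", "b", "c"), chrom = "c1",
                       strand = "+", dominant_pos = c(100, 199, 200))
  peaks <- tibble::tibble(chrom = "c1", start = 100, end = 200)
  ov <- cage_tss_overlap(cl, peaks)
  expect_equal(ov$in_peak, c(TRUE, TRUE, FALSE))
  none <- cage_tss_overlap(cl, peaks[0, ])
  expect_false(any(none$in_peak))

  withr::local_seed(71)
  layout <- tiny_layout(50000)
  pk <- random_intervals(40, layout, max_len = 400)
  cl2 <- tibble::tibble(cluster_id = sprintf("t%d", 1:200), chrom = "chrT",
                        strand = "+", dominant_pos = sample(0:49999, 200))
  got <- cage_tss_overlap(cl2, pk)$in_peak
  want <- vapply(cl2$dominant_pos, function(p)
    any(pk$start <= p & p < pk$end), TRUE)
  expect_equal(got, want)
})

test_that("dominant TSSs are recovered within 5 bp for planted CAGE data", {
  b <- simulate_bundle(sim_config(seed = 5, n_genes = 300, n_chroms = 2,
                                  chrom_length = 500000,
                                  n_fragments_chip = 1000,
                                  n_fragments_input = 1000))
  cl <- cluster_ctss(tpm_normalize(b$ctss))
  hit <- vapply(seq_len(nrow(cl)), function(i) {
    same <- b$genes[b$genes$chrom == cl$chrom[i] & b$genes$strand == cl$strand[i], ]
    nrow(same) && min(abs(same$tss - cl$dominant_pos[i])) <= 5
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})
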