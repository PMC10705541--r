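test_that("merge produces the minimal cover, including book-ended intervals", {
  x <- tibble::tibble(chrom = "c", start = c(0, 5), end = c(10, 15))
  expect_equal(interval_merge(x),
               tibble::tibble(chrom = "c", start = 0, end = 15))
  y <- tibble::tibble(chrom = "c", start = c(0, 10), end = c(10, 20))
  expect_equal(interval_merge(y),
               tibble::tibble(chrom = "c", start = 0, end = 20))
})

test_that("merged footprint equals the per-base occupancy oracle on random sets", {
  withr::local_seed(42)
  layout <- tiny_layout(50000, c("c1", "c2"))
  x <- random_intervals(1000, layout, max_len = 200)
  m <- interval_merge(x)
  expect_equal(sum(m$end - m$start), oracle_merged_bp(x, layout))
  # disjoint and not even book-ended after merging
  for (part in split(m, m$chrom)) {
    if (nrow(part) > 1) expect_true(all(part$start[-1] > part$end[-nrow(part)]))
  }
})

test_that("jaccard matches hand values and the boolean-array oracle", {
  a <- tibble::tibble(chrom = "c", start = 0, end = 100)
  b <- tibble::tibble(chrom = "c", start = 50, end = 150)
  expect_equal(interval_jaccard(a, b), 50 / 150)
  expect_equal(interval_jaccard(a, a), 1.0)
  disj <- tibble::tibble(chrom = "c", start = 500, end = 600)
  expect_equal(interval_jaccard(a, disj), 0)
  expect_error(interval_jaccard(a[0, ], a[0, ]), "undefined")

  withr::local_seed(7)
  layout <- tiny_layout(20000, c("c1", "c2"))
  for (i in 1:3) {
    x <- random_intervals(300, layout, max_len = 150)
    y <- random_intervals(300, layout, max_len = 150)
    expect_equal(interval_jaccard(x, y), oracle_jaccard(x, y, layout))
    expect_equal(interval_jaccard(x, y), interval_jaccard(y, x))
  }
})

test_that("overlap counting uses >=1 shared base and matches brute force", {
  a <- tibble::tibble(chrom = "c", start = 0, end = 10)
  b <- tibble::tibble(chrom = "c", start = 9, end = 20)
  expect_equal(unlist(count_overlapping(a, b)[c("n_a_hit", "n_b_hit")]),
               c(n_a_hit = 1L, n_b_hit = 1L))
  b2 <- tibble::tibble(chrom = "c", start = 10, end = 20)
  expect_equal(unlist(count_overlapping(a, b2)[c("n_a_hit", "n_b_hit")]),
               c(n_a_hit = 0L, n_b_hit = 0L))

  withr::local_seed(19)
  layout <- tiny_layout(5000, c("c1", "c2"))
  x <- random_intervals(80, layout, max_len = 60)
  y <- random_intervals(80, layout, max_len = 60)
  got <- count_overlapping(x, y)
  want <- oracle_count_overlapping(x, y)
  expect_equal(c(n_a_hit = got$n_a_hit, n_b_hit = got$n_b_hit), want)
})

test_that("relative distance reproduces hand cases and the naive oracle", {
  anchors <- tibble::tibble(chrom = "c", pos = c(0, 100))
  at_anchor <- tibble::tibble(chrom = "c", start = 95, end = 105)  # midpoint 100
  expect_equal(reldist(at_anchor, anchors)$values, 0)
  halfway <- tibble::tibble(chrom = "c", start = 45, end = 55)     # midpoint 50
  expect_equal(reldist(halfway, anchors)$values, 0.5)
  quarter <- tibble::tibble(chrom = "c", start = 20, end = 30)     # midpoint 25
  expect_equal(reldist(quarter, anchors)$values, 0.25)

  withr::local_seed(23)
  layout <- tiny_layout(100000)
  x <- random_intervals(400, layout, max_len = 50)
  anc <- tibble::tibble(chrom = "chrT", pos = sort(sample(0:99999, 60)))
  r <- reldist(x, anc)
  expect_equal(sort(r$values), sort(oracle_reldist(x, anc)))
  expect_equal(sum(r$histogram$count), r$n)
  expect_true(all(r$values >= 0 & r$values <= 0.5))
})

test_that("reldist is flat under independence and near zero when planted at anchors", {
  withr::local_seed(101)
  layout <- tiny_layout(10000000)
  n <- 5000
  x <- random_intervals(n, layout, max_len = 100)
  anc <- tibble::tibble(chrom = "chrT", pos = sort(sample(0:9999999, 2000)))
  r <- reldist(x, anc)
  gof <- chisq.test(r$histogram$count)
  expect_gt(gof$p.value, 0.01)

  # sensitivity: midpoints within +/-50 bp of anchors 10 kb apart
  pos <- seq(5000, 9995000, by = 10000)
  jitter <- sample(-50:50, length(pos), replace = TRUE)
  planted <- tibble::tibble(chrom = "chrT", start = pos + jitter - 10,
                            end = pos + jitter + 10)
  rp <- reldist(planted, tibble::tibble(chrom = "chrT", pos = pos))
  expect_lt(mean(rp$values), 0.05)
})

test_that("reldist requires two anchors somewhere", {
  x <- tibble::tibble(chrom = "c", start = 0, end = 10)
  expect_error(reldist(x, tibble::tibble(chrom = "c", pos = 5)), ">= 2 anchors")
})

test_that("peak classification is a partition with TSS precedence", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "c", strand = c("+", "-"),
    start = c(1000, 5000), end = c(3000, 7000),
    tss = c(1000, 6999), tts = c(2999, 5000),
    orf_start = NA_real_, orf_end = NA_real_)
  peaks <- tibble::tibble(
    chrom = "c",
    start = c(900, 1500, 8000, 6950),
    end = c(1100, 1600, 8100, 7050))
  cls <- classify_peaks(peaks, genes)
  # spans TSS + exon -> TSS; wholly inside gene -> gene_body; outside -> intergenic
  expect_equal(cls$class, c("TSS", "gene_body", "intergenic", "TSS"))
  expect_equal(cls$nearest_gene[3], "gB")
  expect_equal(cls$dist_to_tss[3], 8050 - 6999)

  withr::local_seed(5)
  layout <- tiny_layout(20000)
  rnd <- random_intervals(200, layout, max_len = 300)
  got <- classify_peaks(rnd, genes)
  expect_equal(got$class, oracle_classify(rnd, genes))
  expect_equal(sum(table(got$class)), nrow(rnd))
})

test_that("equidistant nearest-TSS ties go to the lexicographically smaller gene id", {
  genes <- tibble::tibble(
    gene_id = c("gB", "gA"), chrom = "c", strand = "+",
    start = c(2000, 0), end = c(3000, 1000),
    tss = c(2000, 0), tts = c(2999, 999),
    orf_start = NA_real_, orf_end = NA_real_)
  peak <- tibble::tibble(chrom = "c", start = 995, end = 1005)  # midpoint 1000
  expect_equal(classify_peaks(peak, genes)$nearest_gene, "gA")
})

test_that("overlap_fisher builds the documented synthetic 2x2 table", {
  layout <- tiny_layout(10000)
  a <- tibble::tibble(chrom = "chrT",
                      start = c(100, 600, 1100, 1600, 2100),
                      end = c(200, 700, 1200, 1700, 2200))
  b <- tibble::tibble(chrom = "chrT",
                      start = c(150, 650, 1150, 5000, 6000),
                      end = c(250, 750, 1250, 5100, 6100))
  res <- overlap_fisher(a, b, layout)
  # hand-constructed: 3 overlap events, 2 A-only, 2 B-only; merged union has
  # 7 blocks of mean width (3*150 + 4*100)/7; n22 = round(10000/mean) - 7
  mean_w <- (3 * 150 + 4 * 100) / 7
  expect_equal(res$table[1, ], c(3, 2))
  expect_equal(res$table[2, 1], 2)
  expect_equal(res$table[2, 2], round(10000 / mean_w) - 7)
  expect_equal(res$p_value, oracle_fisher_p(res$table[1, 1], res$table[1, 2],
                                            res$table[2, 1], res$table[2, 2]),
               tolerance = 1e-9)

  ident <- overlap_fisher(a, a, layout)
  expect_identical(ident$odds_ratio, Inf)
  expect_equal(ident$table[1, 2], 0)
  expect_equal(ident$table[2, 1], 0)

  disj <- overlap_fisher(a, b[4:5, ], layout)
  expect_lt(disj$odds_ratio, 1)
})
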