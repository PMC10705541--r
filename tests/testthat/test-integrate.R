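test_that("DE classification applies joint padj and fold-change cutoffs", {
  de <- tibble::tibble(
    gene_id = c("otu", "vas", "GAL4", "drop", "nofilter", "dn"),
    base_mean = 10,
    log2fc = c(2.41, 0.15, 0.33, -0.7, 3, -1.2),
    padj = c(1e-4, 0.03, 0.18, 0.04, NA, 0.01))
  cls <- classify_de(de)
  got <- setNames(as.character(cls$de_class), cls$gene_id)
  expect_equal(got[["otu"]], "up")
  expect_equal(got[["vas"]], "not_de")    # significant but tiny fold change
  expect_equal(got[["GAL4"]], "not_de")   # insignificant
  expect_equal(got[["drop"]], "down")
  expect_equal(got[["nofilter"]], "not_de")  # missing padj
  expect_equal(got[["dn"]], "down")
  # boundary values are exclusive
  edge <- classify_de(tibble::tibble(gene_id = "e", base_mean = 1,
                                     log2fc = 0.5, padj = 0.01))
  expect_equal(as.character(edge$de_class), "not_de")
})

genes_fix <- tibble::tibble(
  gene_id = c("g1", "g2", "g3"), chrom = "c1", strand = c("+", "-", "+"),
  start = c(100, 500, 900), end = c(300, 700, 1100),
  tss = c(100, 699, 900), tts = c(299, 500, 1099),
  orf_start = NA_real_, orf_end = NA_real_)

test_that("gene binding modes nest correctly and match brute force", {
  peaks <- tibble::tibble(chrom = "c1", start = c(250, 650), end = c(350, 698))
  expect_equal(bind_genes(peaks, genes_fix, "any_overlap"), c("g1", "g2"))
  expect_equal(bind_genes(peaks, genes_fix, "tss_overlap"), character())
  tss_peak <- tibble::tibble(chrom = "c1", start = 699, end = 700)
  expect_equal(bind_genes(tss_peak, genes_fix, "tss_overlap"), "g2")

  withr::local_seed(17)
  layout <- tiny_layout(1200)
  for (i in 1:5) {
    pk <- random_intervals(30, layout, max_len = 100)
    pk$chrom <- "c1"
    any_hit <- bind_genes(pk, genes_fix, "any_overlap")
    tss_hit <- bind_genes(pk, genes_fix, "tss_overlap")
    expect_true(all(tss_hit %in% any_hit))
    brute_any <- genes_fix$gene_id[vapply(seq_len(3), function(g)
      any(pk$start < genes_fix$end[g] & genes_fix$start[g] < pk$end), TRUE)]
    brute_tss <- genes_fix$gene_id[vapply(seq_len(3), function(g)
      any(pk$start <= genes_fix$tss[g] & genes_fix$tss[g] < pk$end), TRUE)]
    expect_equal(any_hit, sort(brute_any))
    expect_equal(tss_hit, sort(brute_tss))
  }
})

test_that("fisher_2x2 matches hypergeometric enumeration across random tables", {
  expect_equal(fisher_2x2(10, 10, 10, 10)$odds_ratio, 1)
  expect_equal(fisher_2x2(10, 10, 10, 10)$p_value, 1)
  withr::local_seed(29)
  for (i in 1:60) {
    n <- sample(4:100, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c_ <- cuts[3] - cuts[2]; d <- n - cuts[3]
    res <- fisher_2x2(a, b, c_, d)
    expect_equal(res$p_value, oracle_fisher_p(a, b, c_, d), tolerance = 1e-9)
  }
  expect_identical(fisher_2x2(5, 0, 3, 2)$odds_ratio, Inf)
  expect_true(fisher_2x2(0, 0, 0, 5)$degenerate)
})

test_that("published-scale tables give the published odds ratios", {
  expect_equal(round(fisher_2x2(666, 1632, 1328, 7178)$odds_ratio, 2), 2.21)
  expect_equal(round(fisher_2x2(564, 1734, 2360, 6146)$odds_ratio, 2), 0.85)
  expect_equal(round(fisher_2x2(1409, 585, 4073, 4737)$odds_ratio, 1), 2.8)
  expect_equal(round(fisher_2x2(625, 2299, 4857, 3023)$odds_ratio, 2), 0.17)
  # sample OR and conditional-MLE OR agree to 2 d.p. on these tables
  for (cells in list(c(666, 1632, 1328, 7178), c(564, 1734, 2360, 6146),
                     c(1409, 585, 4073, 4737), c(625, 2299, 4857, 3023))) {
    samp <- fisher_2x2(cells[1], cells[2], cells[3], cells[4])$odds_ratio
    mle <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$estimate
    expect_equal(round(samp, 2), round(unname(mle), 2))
  }
})

test_that("binding x DE association reconstructs tables from gene lists", {
  fix <- paper_marginals_fixture()
  cls <- classify_de(fix$de_table)
  assoc <- binding_de_association(cls, fix$bound_genes)
  expect_equal(as.vector(t(assoc$up$table)), c(666, 1632, 1328, 7178))
  expect_equal(round(assoc$up$odds_ratio, 2), 2.21)
  expect_lt(assoc$up$p_value, 0.01)
  expect_equal(as.vector(t(assoc$down$table)), c(564, 1734, 2360, 6146))
  expect_equal(round(assoc$down$odds_ratio, 2), 0.85)
  expect_warning(binding_de_association(cls, character()), "empty bound")

  sets <- gene_set_overlap(cls, fix$embryo_set)
  expect_equal(as.vector(t(sets$up$table)), c(1409, 585, 4073, 4737))
  expect_equal(round(sets$up$odds_ratio, 1), 2.8)
  expect_equal(as.vector(t(sets$down$table)), c(625, 2299, 4857, 3023))
  expect_equal(round(sets$down$odds_ratio, 2), 0.17)
  expect_warning(gene_set_overlap(cls, fix$universe), "whole universe")
})

test_that("planted binding/up odds ratios are recovered within 2 SE", {
  within_2se <- function(res, theta) {
    tab <- res$up$table
    se <- sqrt(sum(1 / tab))
    abs(log(res$up$odds_ratio) - log(theta)) <= 2 * se
  }
  cover <- logical(0)
  for (theta in c(1, 2, 4)) {
    for (s in 1:20) {
      b <- simulate_bundle(sim_config(
        seed = 1000 * theta + s, n_chroms = 1, chrom_length = 250000,
        n_genes = 150, gene_length_mean = 700, de_or = theta,
        n_fragments_chip = 200, n_fragments_input = 200,
        cage_tags_per_tss = 1))
      cls <- classify_de(b$de_table)
      assoc <- binding_de_association(cls, b$truth$bound_genes)
      cover <- c(cover, within_2se(assoc, theta))
    }
  }
  expect_gte(mean(cover), 0.9)
})

test_that("term enrichment applies the custom background and Bonferroni", {
  background <- sprintf("g%03d", 1:200)
  terms <- list(t1 = background[1:20], t2 = background[21:60],
                t3 = background[190:200], outside = c("x1", "x2"))
  res <- term_enrichment(query = background[1:20], annotations = terms,
                         background = background)
  expect_false("outside" %in% res$term)       # no background members
  expect_equal(res$term[1], "t1")             # the fully-hit term is top
  expect_equal(res$overlap[res$term == "t1"], 20)
  expect_equal(res$p_adjusted, pmin(1, res$p_value * nrow(res)))
  one <- term_enrichment(background[1:10], terms["t1"], background)
  expect_equal(one$p_adjusted, one$p_value)   # Bonferroni identity for 1 term

  withr::local_seed(37)
  anns <- lapply(1:50, function(i) sample(background, 30))
  names(anns) <- sprintf("T%02d", 1:50)
  q <- sample(background, 40)
  res50 <- term_enrichment(q, anns, background)
  naive <- vapply(names(anns), function(t) {
    a <- length(intersect(q, anns[[t]]))
    min(1, 50 * stats::fisher.test(matrix(c(a, length(q) - a,
                                            length(anns[[t]]) - a,
                                            200 - length(q) - length(anns[[t]]) + a),
                                          2, byrow = TRUE),
                                   alternative = "greater")$p.value)
  }, numeric(1))
  expect_equal(sort(res50$p_adjusted), sort(unname(naive)), tolerance = 1e-9)
})
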