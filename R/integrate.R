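#' Classify genes as up, down, or not differentially expressed
#'
#' Applies the joint significance and effect-size rule used for calling
#' differential expression from a DESeq2-style results table: `up` when
#' `padj < padj_max` and `log2fc > abs_log2fc_min`, `down` symmetric, and
#' `not_de` otherwise.  Genes with missing `padj` (removed by independent
#' filtering) are `not_de`.
#'
#' @param de DE tibble (needs `gene_id`, `log2fc`, `padj`).
#' @param padj_max Adjusted p-value cutoff (default 0.05).
#' @param abs_log2fc_min Absolute log2 fold-change cutoff, exclusive
#'   (default 0.5).
#' @return The input with a `de_class` factor column
#'   (`up`/`down`/`not_de`).
#' @export
classify_de <- function(de, padj_max = 0.05, abs_log2fc_min = 0.5) {
  if (!all(c("gene_id", "log2fc", "padj") %in% names(de))) {
    abort("`de` must have columns gene_id, log2fc, padj")
  }
  sig <- !is.na(de$padj) & de$padj < padj_max
  cls <- ifelse(sig & de$log2fc > abs_log2fc_min, "up",
                ifelse(sig & de$log2fc < -abs_log2fc_min, "down", "not_de"))
  mutate(de, de_class = factor(cls, levels = c("up", "down", "not_de")))
}

#' Genes bound by a peak set
#'
#' `any_overlap`: a gene is bound when any peak shares at least one base with
#' its transcribed extent.  `tss_overlap`: a peak must contain the gene's TSS
#' base (`start <= tss < end`).  `tss_overlap` is always a subset of
#' `any_overlap`.
#'
#' @param peaks Interval tibble.
#' @param genes Gene-model tibble.
#' @param mode `"any_overlap"` (default) or `"tss_overlap"`.
#' @return A character vector of bound gene ids.
#' @export
bind_genes <- function(peaks, genes, mode = c("any_overlap", "tss_overlap")) {
  mode <- arg_match(mode)
  check_intervals(peaks, arg = "peaks")
  if (!nrow(peaks) || !nrow(genes)) return(character())
  gp <- as_granges(peaks[c("chrom", "start", "end")])
  target <- if (mode == "any_overlap") {
    as_granges(genes[c("chrom", "start", "end")])
  } else {
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$tss + 1, genes$tss + 1))
  }
  bound <- suppressWarnings(GenomicRanges::countOverlaps(target, gp)) > 0
  sort(unique(genes$gene_id[bound]))
}

#' Construct a 2x2 Fisher contingency result
#'
#' The p-value is the two-sided Fisher exact probability (the sum of
#' hypergeometric probabilities of tables at most as probable as the
#' observed one, via [stats::fisher.test()]).  The reported odds ratio is
#' the sample cross-product ratio `a*d / (b*c)`, not the conditional MLE:
#' `Inf` when a zero in `b` or `c` makes the cross-product unbounded, `NaN`
#' (flagged) in the doubly degenerate case.
#'
#' @param a,b,c,d Non-negative integer cell counts, laid out as
#'   rows = condition 1 (yes/no), columns = condition 2 (yes/no).
#' @param alternative Passed to [stats::fisher.test()] (default two-sided).
#' @return An object of class `contingency_result`: `table`, `odds_ratio`,
#'   `p_value`, `universe_size`, `direction`, `degenerate`.
#' @export
fisher_2x2 <- function(a, b, c, d, alternative = "two.sided") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("cell counts must be non-negative integers")
  }
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  ad <- a * d; bc <- b * c
  or <- if (bc == 0 && ad == 0) NaN else if (bc == 0) Inf else ad / bc
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  structure(list(table = tab, odds_ratio = or, p_value = p,
                 universe_size = sum(cells),
                 direction = if (is.nan(or)) NA_character_
                             else if (or > 1) "enriched"
                             else if (or < 1) "depleted" else "none",
                 degenerate = is.nan(or)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("<contingency_result>\n")
  print(x$table)
  cat(sprintf("  odds ratio = %s, p = %.4g (%s), n = %d\n",
              format(x$odds_ratio, digits = 4), x$p_value,
              x$direction %||% "degenerate", x$universe_size))
  invisible(x)
}

#' Association between binding and differential expression
#'
#' For each DE direction, builds the 2x2 table over the expressed-gene
#' universe: `a` = bound genes in that direction, `b` = bound genes not in
#' it, `c` = unbound genes in it, `d` = the remainder, and applies
#' [fisher_2x2()].  An odds ratio above 1 for the `up` direction means bound
#' genes preferentially respond positively.
#'
#' @param declass Output of [classify_de()].
#' @param bound Character vector of bound gene ids.
#' @param universe Gene universe (default: all genes in `declass`).
#' @return A named list of contingency results, one per direction
#'   (`up`, `down`).
#' @export
binding_de_association <- function(declass, bound,
                                   universe = declass$gene_id) {
  d <- declass[declass$gene_id %in% universe, , drop = FALSE]
  if (!length(bound)) {
    warn("empty bound gene set: odds ratios undefined")
  }
  is_bound <- d$gene_id %in% bound
  out <- list()
  for (dir in c("up", "down")) {
    in_dir <- d$de_class == dir
    out[[dir]] <- fisher_2x2(sum(is_bound & in_dir), sum(is_bound & !in_dir),
                             sum(!is_bound & in_dir), sum(!is_bound & !in_dir))
  }
  out
}

#' Association between differential expression and a gene set
#'
#' For each DE direction: `a` = genes in that direction and in the set, `b` =
#' in the direction but not the set, `c` = in the set but not the direction,
#' `d` = the remainder of the universe.
#'
#' @param declass Output of [classify_de()].
#' @param set Character vector of gene ids (e.g. maternally deposited genes).
#' @param universe Gene universe (default: all genes in `declass`).
#' @return A named list of contingency results (`up`, `down`).
#' @export
gene_set_overlap <- function(declass, set, universe = declass$gene_id) {
  d <- declass[declass$gene_id %in% universe, , drop = FALSE]
  in_set <- d$gene_id %in% set
  if (all(in_set)) warn("gene set covers the whole universe: degenerate table")
  out <- list()
  for (dir in c("up", "down")) {
    in_dir <- d$de_class == dir
    out[[dir]] <- fisher_2x2(sum(in_dir & in_set), sum(in_dir & !in_set),
                             sum(!in_dir & in_set), sum(!in_dir & !in_set))
  }
  out
}

#' Term enrichment with a custom background and Bonferroni correction
#'
#' Over-representation of a query gene set in each annotation term,
#' restricted to a custom background universe: per term a one-sided Fisher
#' exact test (enrichment) on `(query & term, query & !term, term & !query,
#' rest)`, Bonferroni-corrected across the tested terms.  Terms with no
#' background members are skipped.
#'
#' @param query Character vector of gene ids.
#' @param annotations Named list: term id -> character vector of member
#'   genes.
#' @param background Character vector; the statistical domain (universe).
#' @return A tibble sorted by adjusted p: `term`, `term_size`, `query_size`,
#'   `overlap`, `odds_ratio`, `p_value`, `p_adjusted`.
#' @export
term_enrichment <- function(query, annotations, background) {
  background <- unique(background)
  query <- intersect(unique(query), background)
  rows <- purrr::imap(annotations, function(members, term) {
    members <- intersect(unique(members), background)
    if (!length(members)) return(NULL)
    a <- length(intersect(query, members))
    b <- length(query) - a
    c_ <- length(members) - a
    d <- length(background) - a - b - c_
    fr <- fisher_2x2(a, b, c_, d, alternative = "greater")
    tibble(term = term, term_size = length(members),
           query_size = length(query), overlap = a,
           odds_ratio = fr$odds_ratio, p_value = fr$p_value)
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(term = character(), term_size = integer(),
                  query_size = integer(), overlap = integer(),
                  odds_ratio = numeric(), p_value = numeric(),
                  p_adjusted = numeric()))
  }
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  arrange(out, .data$p_adjusted, .data$p_value)
}
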