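#' Merge an interval set into its minimal non-overlapping cover
#'
#' Overlapping and book-ended (abutting) intervals are collapsed, per
#' chromosome.  Extra columns are dropped: a merged interval no longer
#' corresponds to a single input record.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`).
#' @return A sorted interval tibble whose intervals are disjoint.
#' @examples
#' interval_merge(tibble::tibble(chrom = "c", start = c(0, 5), end = c(10, 15)))
#' @export
interval_merge <- function(x) {
  check_intervals(x)
  if (!nrow(x)) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  red <- GenomicRanges::reduce(as_granges(x[c("chrom", "start", "end")]),
                               min.gapwidth = 1L)
  arrange(granges_to_tbl(red), .data$chrom, .data$start)
}

# Internal: total bp covered by the merged set.
covered_bp <- function(x) {
  m <- interval_merge(x)
  sum(m$end - m$start)
}

#' Base-pair Jaccard index of two interval sets
#'
#' The genomic Jaccard statistic: base pairs of intersection divided by base
#' pairs of union, after merging each set (bedtools `jaccard` semantics).
#' Symmetric and in \[0, 1\].
#'
#' @param a,b Interval tibbles on the same genome layout.
#' @return A single number.  Both sets empty is undefined and an error.
#' @export
interval_jaccard <- function(a, b) {
  check_intervals(a, arg = "a"); check_intervals(b, arg = "b")
  if (!nrow(a) && !nrow(b)) {
    abort("jaccard of two empty interval sets is undefined")
  }
  ga <- GenomicRanges::reduce(as_granges(a[c("chrom", "start", "end")]), min.gapwidth = 1L)
  gb <- GenomicRanges::reduce(as_granges(b[c("chrom", "start", "end")]), min.gapwidth = 1L)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  inter / uni
}

#' Count intervals of each set hit by the other
#'
#' An interval is "hit" when it shares at least one base with any interval of
#' the other set; half-open abutment is not overlap.
#'
#' @param a,b Interval tibbles.
#' @return A tibble with one row: `n_a`, `n_a_hit`, `n_b`, `n_b_hit`, and the
#'   hit fractions `frac_a`, `frac_b`.
#' @export
count_overlapping <- function(a, b) {
  check_intervals(a, arg = "a"); check_intervals(b, arg = "b")
  if (!nrow(a) || !nrow(b)) {
    return(tibble(n_a = nrow(a), n_a_hit = 0L, n_b = nrow(b), n_b_hit = 0L,
                  frac_a = ifelse(nrow(a) > 0, 0, NA_real_),
                  frac_b = ifelse(nrow(b) > 0, 0, NA_real_)))
  }
  ga <- as_granges(a[c("chrom", "start", "end")])
  gb <- as_granges(b[c("chrom", "start", "end")])
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
  n_a_hit <- length(unique(S4Vectors::queryHits(hits)))
  n_b_hit <- length(unique(S4Vectors::subjectHits(hits)))
  tibble(n_a = nrow(a), n_a_hit = n_a_hit, n_b = nrow(b), n_b_hit = n_b_hit,
         frac_a = n_a_hit / nrow(a), frac_b = n_b_hit / nrow(b))
}

#' Relative distance of intervals to anchor positions
#'
#' For each interval midpoint lying between two flanking anchors on its
#' chromosome, the relative distance is the distance to the nearer anchor
#' divided by the inter-anchor span: uniform on \[0, 0.5\] when intervals and
#' anchors are spatially independent, and concentrated near 0 when intervals
#' track the anchors (bedtools `reldist` semantics).  Midpoints outside the
#' anchor span, and chromosomes with fewer than two anchors, are skipped and
#' counted in `n_skipped`.
#'
#' @param x Interval tibble.
#' @param anchors Tibble of anchor positions with columns `chrom`, `pos`.
#' @param bin_width Histogram bin width on the relative-distance axis.
#' @param use Which point represents an interval: its midpoint (default) or
#'   its `summit` column.
#' @return An object of class `reldist_result`: a list with `values` (per
#'   measured interval), `histogram` (tibble of `bin_lo`, `bin_hi`, `count`,
#'   `freq`), `n`, `n_skipped`.
#' @export
reldist <- function(x, anchors, bin_width = 0.01, use = c("midpoint", "summit")) {
  use <- arg_match(use)
  check_intervals(x)
  if (!all(c("chrom", "pos") %in% names(anchors))) {
    abort("`anchors` must have columns `chrom` and `pos`")
  }
  anchor_by <- lapply(split(anchors$pos, anchors$chrom), function(p) sort(unique(p)))
  usable <- names(anchor_by)[lengths(anchor_by) >= 2]
  if (!length(usable)) {
    abort("no chromosome has >= 2 anchors; relative distance is undefined")
  }
  mid <- if (use == "summit") {
    if (!"summit" %in% names(x)) abort("`x` has no `summit` column")
    x$summit
  } else {
    (x$start + x$end) / 2
  }
  vals <- numeric(0)
  n_skipped <- 0L
  for (chrom in unique(x$chrom)) {
    pos <- anchor_by[[chrom]]
    m <- mid[x$chrom == chrom]
    m <- m[!is.na(m)]
    if (is.null(pos) || length(pos) < 2) {
      n_skipped <- n_skipped + length(m)
      next
    }
    inside <- m >= pos[1] & m <= pos[length(pos)]
    n_skipped <- n_skipped + sum(!inside)
    m <- m[inside]
    if (!length(m)) next
    # index of left flanking anchor (right-closed: midpoint == anchor -> 0)
    li <- findInterval(m, pos, rightmost.closed = TRUE)
    li[li == length(pos)] <- length(pos) - 1
    L <- pos[li]; R <- pos[li + 1]
    vals <- c(vals, unname(pmin(m - L, R - m) / (R - L)))
  }
  breaks <- seq(0, 0.5, by = bin_width)
  if (max(breaks) < 0.5) breaks <- c(breaks, 0.5)
  counts <- if (length(vals)) {
    tabulate(pmin(findInterval(vals, breaks, rightmost.closed = TRUE),
                  length(breaks) - 1), nbins = length(breaks) - 1)
  } else {
    integer(length(breaks) - 1)
  }
  hist <- tibble(bin_lo = head(breaks, -1), bin_hi = tail(breaks, -1),
                 count = counts,
                 freq = if (length(vals)) counts / length(vals) else 0)
  structure(list(values = vals, histogram = hist, n = length(vals),
                 n_skipped = n_skipped),
            class = "reldist_result")
}

#' @export
print.reldist_result <- function(x, ...) {
  cat(sprintf("<reldist_result> n = %d measured, %d skipped; mean = %.4f\n",
              x$n, x$n_skipped, mean(x$values)))
  invisible(x)
}

#' Classify peaks against gene models
#'
#' Each peak is assigned exactly one class with the precedence TSS >
#' gene body > intergenic: `TSS` if the peak overlaps the TSS base of any
#' gene (`start <= tss < end`), else `gene_body` if it overlaps any gene's
#' transcribed extent, else `intergenic`.  The nearest TSS (by distance from
#' the peak midpoint, ties broken by the lexicographically smaller gene id)
#' is reported for every peak.
#'
#' @param peaks Interval tibble.
#' @param genes Gene-model tibble from [read_gtf()].
#' @return The peak tibble with columns `class`, `nearest_gene`,
#'   `dist_to_tss` added; class counts are available via `dplyr::count()`.
#' @export
classify_peaks <- function(peaks, genes) {
  check_intervals(peaks, arg = "peaks")
  if (!nrow(peaks)) {
    return(mutate(peaks, class = character(), nearest_gene = character(),
                  dist_to_tss = numeric()))
  }
  gp <- as_granges(peaks[c("chrom", "start", "end")])
  gtss <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$tss + 1, genes$tss + 1))
  gext <- as_granges(genes[c("chrom", "start", "end")])
  hit_tss <- suppressWarnings(GenomicRanges::countOverlaps(gp, gtss)) > 0
  hit_body <- suppressWarnings(GenomicRanges::countOverlaps(gp, gext)) > 0
  cls <- ifelse(hit_tss, "TSS", ifelse(hit_body, "gene_body", "intergenic"))
  mid <- (peaks$start + peaks$end) / 2
  # nearest TSS, ties by lexicographically smaller gene_id
  ord <- order(genes$chrom, genes$tss, genes$gene_id)
  g <- genes[ord, ]
  nearest_gene <- character(nrow(peaks))
  dist_to_tss <- numeric(nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    gi <- which(g$chrom == chrom)
    pi <- which(peaks$chrom == chrom)
    if (!length(gi)) {
      nearest_gene[pi] <- NA_character_
      dist_to_tss[pi] <- NA_real_
      next
    }
    tss <- g$tss[gi]
    ids <- g$gene_id[gi]
    for (k in pi) {
      d <- abs(tss - mid[k])
      best <- which(d == min(d))
      pick <- best[order(ids[best])][1]
      nearest_gene[k] <- ids[pick]
      dist_to_tss[k] <- d[pick]
    }
  }
  mutate(peaks, class = cls, nearest_gene = nearest_gene, dist_to_tss = dist_to_tss)
}

#' Genome-wide Fisher test of peak-set overlap
#'
#' Tests whether two peak sets co-occur more often than expected from their
#' genomic footprint, with the bedtools-`fisher`-style synthetic null: the
#' 2x2 table is built from `n11` = number of overlapping A-B pairs, `n12` =
#' A intervals with no overlap, `n21` = B intervals with no overlap, and
#' `n22` = `max(0, G/mean_width - n11 - n12 - n21)` where `G` is the genome
#' length and `mean_width` the mean interval width over the merged union of
#' A and B.  The full table is returned so callers can substitute their own
#' null.
#'
#' @param a,b Interval tibbles.
#' @param layout Genome layout (supplies `G`).
#' @return A contingency result (see [fisher_2x2()]).
#' @export
overlap_fisher <- function(a, b, layout) {
  check_layout(layout)
  check_intervals(a, layout, arg = "a"); check_intervals(b, layout, arg = "b")
  ga <- as_granges(a[c("chrom", "start", "end")])
  gb <- as_granges(b[c("chrom", "start", "end")])
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
  n11 <- length(hits)
  n12 <- nrow(a) - length(unique(S4Vectors::queryHits(hits)))
  n21 <- nrow(b) - length(unique(S4Vectors::subjectHits(hits)))
  merged <- interval_merge(bind_rows(a[c("chrom", "start", "end")],
                                     b[c("chrom", "start", "end")]))
  mean_width <- mean(merged$end - merged$start)
  G <- sum(layout$size)
  n22 <- max(0, round(G / mean_width) - n11 - n12 - n21)
  fisher_2x2(n11, n12, n21, n22)
}
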