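# Independent brute-force oracles and fixture builders used across the
# suite.  Oracles work on per-base boolean arrays or exhaustive enumeration
# and share no code with the implementation they check.

tiny_layout <- function(len = 1000, chroms = "chrT") {
  genome_layout(chroms, rep(len, length(chroms)))
}

random_intervals <- function(n, layout, max_len = 100) {
  chrom <- sample(layout$chrom, n, replace = TRUE)
  len <- setNames(layout$size, layout$chrom)[chrom]
  start <- floor(runif(n) * (len - max_len))
  width <- 1 + floor(runif(n) * max_len)
  dplyr::arrange(tibble::tibble(chrom = chrom, start = start,
                                end = pmin(start + width, len)),
                 chrom, start)
}

# boolean per-base occupancy of a set, as a list of logical vectors
occupancy <- function(x, layout) {
  out <- lapply(setNames(layout$size, layout$chrom), function(L) logical(L))
  for (i in seq_len(nrow(x))) {
    out[[x$chrom[i]]][(x$start[i] + 1):x$end[i]] <- TRUE
  }
  out
}

oracle_merged_bp <- function(x, layout) {
  sum(vapply(occupancy(x, layout), sum, numeric(1)))
}

oracle_jaccard <- function(a, b, layout) {
  oa <- occupancy(a, layout); ob <- occupancy(b, layout)
  inter <- sum(mapply(function(p, q) sum(p & q), oa, ob))
  uni <- sum(mapply(function(p, q) sum(p | q), oa, ob))
  inter / uni
}

oracle_count_overlapping <- function(a, b) {
  hit_a <- logical(nrow(a)); hit_b <- logical(nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        hit_a[i] <- TRUE; hit_b[j] <- TRUE
      }
    }
  }
  c(n_a_hit = sum(hit_a), n_b_hit = sum(hit_b))
}

oracle_reldist <- function(x, anchors) {
  vals <- numeric(0)
  for (i in seq_len(nrow(x))) {
    pos <- sort(unique(anchors$pos[anchors$chrom == x$chrom[i]]))
    if (length(pos) < 2) next
    m <- (x$start[i] + x$end[i]) / 2
    if (m < pos[1] || m > pos[length(pos)]) next
    below <- pos[pos <= m]; above <- pos[pos >= m]
    L <- max(below); R <- min(above)
    if (L == R) { vals <- c(vals, 0); next }
    vals <- c(vals, min(m - L, R - m) / (R - L))
  }
  vals
}

oracle_classify <- function(peaks, genes) {
  vapply(seq_len(nrow(peaks)), function(i) {
    on_chrom <- genes[genes$chrom == peaks$chrom[i], ]
    tss_hit <- any(on_chrom$tss >= peaks$start[i] & on_chrom$tss < peaks$end[i])
    if (tss_hit) return("TSS")
    body_hit <- any(on_chrom$start < peaks$end[i] & peaks$start[i] < on_chrom$end)
    if (body_hit) "gene_body" else "intergenic"
  }, "")
}

# exhaustive 4^w enumeration of log-odds scores under a background
oracle_score_table <- function(p) {
  M <- log2((p$probs + p$pseudocount * p$background) / p$background)
  w <- ncol(M)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  score <- rowSums(matrix(M[cbind(as.vector(grid), rep(seq_len(w), each = nrow(grid)))],
                          nrow = nrow(grid)))
  prob <- apply(matrix(p$background[as.vector(grid)], nrow = nrow(grid)), 1, prod)
  list(kmer = apply(grid, 1, function(r) paste(c("A", "C", "G", "T")[r], collapse = "")),
       score = score, prob = prob)
}

oracle_scan_hits <- function(p, s, p_threshold, background) {
  # all-position scorer with enumeration p-values, forward and reverse
  tab <- oracle_score_table(pwm(p$name, p$probs, background, p$pseudocount))
  pv_of <- function(sc) sum(tab$prob[tab$score >= sc - 1e-9])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  w <- ncol(p$probs)
  chars <- strsplit(s, "")[[1]]
  hits <- list()
  for (i in seq_len(nchar(s) - w + 1)) {
    win <- chars[i:(i + w - 1)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    for (str in c("+", "-")) {
      word <- if (str == "+") win else rev(unname(comp[win]))
      sc <- sum(vapply(seq_len(w), function(j) {
        b <- match(word[j], c("A", "C", "G", "T"))
        log2((p$probs[b, j] + p$pseudocount * background[b]) / background[b])
      }, numeric(1)))
      if (pv_of(sc) <= p_threshold) {
        hits[[length(hits) + 1]] <- tibble::tibble(start = i - 1, strand = str, score = sc)
      }
    }
  }
  if (length(hits)) dplyr::arrange(dplyr::bind_rows(hits), start, strand)
  else tibble::tibble(start = numeric(), strand = character(), score = numeric())
}

# two-sided Fisher p by direct hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
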