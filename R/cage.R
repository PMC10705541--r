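#' Tags-per-million normalisation of CTSS counts
#'
#' Adds a `tpm` column: `count / library_size * 1e6`, where the library size
#' is the total tag count of the table.  The `tpm` column sums to 1e6.
#'
#' @param ctss CTSS tibble (`chrom`, `pos`, `strand`, `count`).
#' @return The input with a `tpm` column added.
#' @export
tpm_normalize <- function(ctss) {
  if (!all(c("chrom", "pos", "strand", "count") %in% names(ctss))) {
    abort("`ctss` must have columns chrom, pos, strand, count")
  }
  total <- sum(ctss$count)
  if (total <= 0) abort("CTSS table has no tags")
  mutate(ctss, tpm = .data$count / total * 1e6)
}

#' Cluster CTSS positions into tag clusters with a dominant TSS
#'
#' Positions at or above `threshold_tpm` are linked into a cluster when they
#' share chromosome and strand and the gap to the nearest retained neighbour
#' is at most `max_dist` bp (single-linkage distance clustering).
#' Single-position clusters are dropped unless their TPM reaches
#' `keep_singletons_above`.  The dominant TSS is the position of maximum TPM,
#' ties resolved to the 5'-most position on the cluster strand.
#'
#' @param ctss CTSS tibble; a `tpm` column is added via [tpm_normalize()] if
#'   absent.
#' @param threshold_tpm Minimum per-position TPM to enter clustering.
#' @param max_dist Maximum linking distance in bp.
#' @param keep_singletons_above Singleton clusters at or above this TPM are
#'   kept; below it they are removed.
#' @return A tibble of tag clusters: `cluster_id`, `chrom`, `strand`,
#'   `start`, `end` (half-open), `n_ctss`, `total_tpm`, `dominant_pos`,
#'   `dominant_tpm`.
#' @export
cluster_ctss <- function(ctss, threshold_tpm = 1, max_dist = 20,
                         keep_singletons_above = 5) {
  if (!"tpm" %in% names(ctss)) ctss <- tpm_normalize(ctss)
  keep <- ctss[ctss$tpm >= threshold_tpm, , drop = FALSE]
  if (!nrow(keep)) {
    return(tibble(cluster_id = character(), chrom = character(),
                  strand = character(), start = numeric(), end = numeric(),
                  n_ctss = integer(), total_tpm = numeric(),
                  dominant_pos = numeric(), dominant_tpm = numeric()))
  }
  keep <- arrange(keep, .data$chrom, .data$strand, .data$pos)
  grp <- paste(keep$chrom, keep$strand)
  new_cluster <- c(TRUE, diff(keep$pos) > max_dist | grp[-1] != grp[-length(grp)])
  cid <- cumsum(new_cluster)
  out <- keep |>
    mutate(.cid = cid) |>
    group_by(.data$.cid) |>
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      start = min(.data$pos), end = max(.data$pos) + 1,
      n_ctss = dplyr::n(), total_tpm = sum(.data$tpm),
      dominant_pos = {
        best <- which(.data$tpm == max(.data$tpm))
        p <- .data$pos[best]
        if (.data$strand[1] == "+") min(p) else max(p)
      },
      dominant_tpm = max(.data$tpm),
      .groups = "drop"
    )
  out <- out[!(out$n_ctss == 1 & out$total_tpm < keep_singletons_above), , drop = FALSE]
  out |>
    arrange(.data$chrom, .data$start) |>
    mutate(cluster_id = sprintf("TC%05d", row_number()), .before = 1) |>
    select(-".cid")
}

#' Extract strand-oriented promoter windows around dominant TSSs
#'
#' For each cluster the genomic window `dominant_pos +/- width` is extracted
#' (length `2 * width + 1`) and reverse-complemented for minus-strand
#' clusters, so that string position `width + 1` is the TSS base and smaller
#' offsets are upstream.  Windows truncated by a chromosome end are flagged
#' and padded with `N`.
#'
#' @param clusters Tag-cluster tibble from [cluster_ctss()] (or any tibble
#'   with `cluster_id`, `chrom`, `strand`, `dominant_pos`).
#' @param genome A named `DNAStringSet` (or character vector) of chromosome
#'   sequences.
#' @param width Half-window width in bp (default 200).
#' @return A tibble: `cluster_id`, `chrom`, `strand`, `tss`, `seq`,
#'   `truncated`.
#' @export
promoter_windows <- function(clusters, genome, width = 200) {
  seqs <- if (inherits(genome, "DNAStringSet")) as.character(genome) else genome
  out <- purrr::pmap(list(clusters$cluster_id, clusters$chrom,
                          clusters$strand, clusters$dominant_pos),
    function(id, chrom, strand, pos) {
      s <- seqs[[chrom]]
      if (is.null(s)) abort(sprintf("chromosome `%s` not in genome", chrom))
      len <- nchar(s)
      a <- pos - width; b <- pos + width
      lo <- max(0, a); hi <- min(len - 1, b)
      win <- substr(s, lo + 1, hi + 1)
      pad_l <- lo - a; pad_r <- b - hi
      win <- paste0(strrep("N", pad_l), win, strrep("N", pad_r))
      if (strand == "-") {
        win <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
      }
      tibble(cluster_id = id, chrom = chrom, strand = strand, tss = pos,
             seq = toupper(win), truncated = (pad_l + pad_r) > 0)
    })
  bind_rows(out)
}

#' Positional density of promoter elements around the TSS
#'
#' Scans each oriented promoter window with each motif at its p-value
#' threshold and histograms hit start offsets relative to the TSS (negative
#' = upstream) at 1 bp resolution, alongside per-window presence calls.
#'
#' @param windows Promoter-window tibble from [promoter_windows()].
#' @param pwms Named list of [pwm()] objects.
#' @param p_threshold Single threshold or named vector/list per motif.
#' @param background Optional fixed background for scanning; `NULL` estimates
#'   it from the windows.
#' @return A list with `density` (tibble `motif`, `offset`, `count`),
#'   `presence` (tibble `cluster_id` x motif logical columns), and `hits`
#'   (all hits with `offset`).
#' @export
element_density <- function(windows, pwms, p_threshold = 0.003,
                            background = NULL) {
  if (inherits(pwms, "pwm")) pwms <- setNames(list(pwms), pwms$name)
  width <- (nchar(windows$seq[1]) - 1) / 2
  seqs <- setNames(windows$seq, windows$cluster_id)
  thr <- function(nm) {
    if (length(p_threshold) == 1 && is.null(names(p_threshold))) return(as.numeric(p_threshold))
    if (!nm %in% names(p_threshold)) abort(sprintf("no p_threshold for motif `%s`", nm))
    as.numeric(p_threshold[[nm]])
  }
  all_hits <- purrr::imap(pwms, function(p, nm) {
    scan_motifs(p, seqs, p_threshold = thr(nm), background = background)
  })
  hits <- bind_rows(all_hits)
  hits$offset <- if (nrow(hits)) hits$start - width else numeric(0)
  dens <- hits |>
    count(.data$motif, .data$offset, name = "count")
  presence <- tibble(cluster_id = windows$cluster_id)
  for (nm in names(pwms)) {
    presence[[nm]] <- presence$cluster_id %in% hits$chrom[hits$motif == nm]
  }
  list(density = dens, presence = presence, hits = as_tibble(hits))
}

#' Fisher enrichment of a promoter element between two window groups
#'
#' Builds the 2x2 presence/absence table of one motif between two promoter
#' groups (e.g. factor-bound vs unbound promoters, or two tissues) and
#' applies the two-sided Fisher exact test with the sample odds ratio.
#'
#' @param presence_a,presence_b Logical vectors (or one-column data frames)
#'   of per-window element presence in groups a and b.
#' @return A contingency result (see [fisher_2x2()]); `odds_ratio > 1` means the element is more
#'   frequent in group a.
#' @export
element_enrichment <- function(presence_a, presence_b) {
  pa <- as.logical(unlist(presence_a)); pb <- as.logical(unlist(presence_b))
  fisher_2x2(sum(pa), sum(!pa), sum(pb), sum(!pb))
}

#' Partition dominant TSSs by peak overlap
#'
#' Tests each cluster's dominant TSS base for containment in any peak
#' (`start <= pos < end`), the anchor partition behind TSS-centred heatmaps
#' of bound vs unbound promoters.
#'
#' @param clusters Tag-cluster tibble with `chrom`, `dominant_pos`.
#' @param peaks Interval tibble.
#' @return The clusters tibble with a logical `in_peak` column.
#' @export
cage_tss_overlap <- function(clusters, peaks) {
  check_intervals(peaks, arg = "peaks")
  in_peak <- rep(FALSE, nrow(clusters))
  if (nrow(peaks) && nrow(clusters)) {
    gt <- GenomicRanges::GRanges(clusters$chrom,
                                 IRanges::IRanges(clusters$dominant_pos + 1,
                                                  clusters$dominant_pos + 1))
    gp <- as_granges(peaks[c("chrom", "start", "end")])
    in_peak <- suppressWarnings(GenomicRanges::countOverlaps(gt, gp)) > 0
  }
  mutate(clusters, in_peak = in_peak)
}
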