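#' Configuration for the synthetic regulatory-genomics bundle
#'
#' Defines the statistical structure of a simulated study of a TSS-proximal
#' transcription factor: genes laid out on both strands of a random genome, a
#' fraction of them carrying a binding peak over the TSS with the core
#' binding motif written into the sequence near the peak centre, ChIP
#' fragments enriched over peaks against a uniform input, CAGE 5'-tags
#' geometrically spread around each TSS, and differential-expression labels
#' drawn so that binding and up-regulation have a planted odds ratio.
#'
#' Defaults describe a desk-scale study in which the qualitative structure of
#' an ovary TF occupancy experiment holds: a strong majority of peaks at
#' TSSs, a several-fold ChIP enrichment, a binding/up-regulation odds ratio
#' near 2.2, baseline up-regulation of about 16% among unbound genes, about
#' 27% down-regulated genes overall, and a maternal-set odds ratio of 2.8
#' given up-regulation.
#'
#' @param seed Integer seed; fully determines the bundle.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Number of genes (placed without overlap, both strands).
#' @param gene_length_mean Mean gene length in bp.
#' @param frac_bound Fraction of genes with a planted peak over the TSS.
#' @param peak_width_mean,peak_width_sd Peak width distribution in bp.
#' @param motif Core binding motif (IUPAC consensus) written into bound
#'   peaks.
#' @param motif_offset_sd SD (bp) of the planted motif centre around the
#'   peak centre.
#' @param chip_enrichment Fold coverage enrichment of ChIP over background
#'   within peaks.
#' @param n_fragments_chip,n_fragments_input Fragment counts.
#' @param fragment_length Fixed fragment length in bp.
#' @param cage_tags_per_tss Expected CAGE tag count per expressed gene.
#' @param cage_spread Geometric success probability for the tag offset from
#'   the true TSS (larger = tighter).
#' @param de_or Planted odds ratio of up-regulation given binding.
#' @param frac_up_unbound Baseline up-regulation rate among unbound genes.
#' @param frac_down Overall down-regulation rate (among non-up genes).
#' @param embryo_or Planted odds ratio of maternal-set membership given
#'   up-regulation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2, chrom_length = 300000,
                       n_genes = 200, gene_length_mean = 1500,
                       frac_bound = 0.3,
                       peak_width_mean = 400, peak_width_sd = 80,
                       motif = "TAACGGT", motif_offset_sd = 20,
                       chip_enrichment = 5,
                       n_fragments_chip = 30000, n_fragments_input = 30000,
                       fragment_length = 200,
                       cage_tags_per_tss = 50, cage_spread = 0.3,
                       de_or = 2.2, frac_up_unbound = 0.16, frac_down = 0.27,
                       embryo_or = 2.8) {
  cfg <- as.list(environment())
  fracs <- c(frac_bound, frac_up_unbound, frac_down)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (de_or < 0 || embryo_or < 0) abort("planted odds ratios must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a self-contained regulatory-genomics bundle
#'
#' Generates, from a [sim_config()], an in-memory bundle with the structure
#' the analysis assumes: genome sequence (i.i.d. uniform bases, so motif-scan
#' false-positive rates match their analytic p-values), gene models, peaks
#' over bound TSSs with the motif planted near the peak centre, ChIP/input
#' fragments, CTSS tag counts, a DE table realising the planted
#' binding/up-regulation odds ratio, a maternal gene set, and truth tables
#' for every planted quantity.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_bundle`: `layout`, `genome` (DNAStringSet),
#'   `genes`, `peaks`, `fragments_chip`, `fragments_input`, `ctss`,
#'   `de_table`, `gene_sets`, `truth`, `config`.
#' @export
simulate_bundle <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- sprintf("chrS%d", seq_len(cfg$n_chroms))
  layout <- genome_layout(chroms, rep(cfg$chrom_length, cfg$n_chroms))

  # --- genome sequence ---
  seqs <- lapply(chroms, function(ch) {
    sample(DNA_BASES, cfg$chrom_length, replace = TRUE)
  })
  names(seqs) <- chroms

  # --- non-overlapping gene placement on a jittered grid, both strands ---
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  slot_len <- floor(cfg$chrom_length / max(per_chrom))
  if (slot_len < cfg$gene_length_mean * 2) {
    abort("infeasible gene placement: too many genes for the genome size")
  }
  genes <- list()
  gi <- 0
  for (ci in seq_along(chroms)) {
    for (k in seq_len(per_chrom[ci])) {
      gi <- gi + 1
      len <- round(cfg$gene_length_mean * runif(1, 0.6, 1.4))
      pad <- slot_len - len
      start <- (k - 1) * slot_len + sample.int(max(1, floor(pad / 2)), 1) +
        floor(pad / 4)
      strand <- sample(c("+", "-"), 1)
      genes[[gi]] <- tibble(
        gene_id = sprintf("g%04d", gi), chrom = chroms[ci], strand = strand,
        start = start, end = start + len,
        tss = if (strand == "+") start else start + len - 1,
        tts = if (strand == "+") start + len - 1 else start,
        orf_start = start + round(len * 0.2),
        orf_end = start + round(len * 0.8)
      )
    }
  }
  genes <- bind_rows(genes)

  # --- bound genes: peak over the TSS, motif planted near the peak centre ---
  n_bound <- round(cfg$frac_bound * nrow(genes))
  bound_idx <- sort(sample.int(nrow(genes), n_bound))
  mot <- strsplit(cfg$motif, "")[[1]]
  peaks <- list()
  motif_truth <- list()
  for (j in seq_along(bound_idx)) {
    g <- genes[bound_idx[j], ]
    wpk <- max(length(mot) + 10, round(rnorm(1, cfg$peak_width_mean, cfg$peak_width_sd)))
    pstart <- max(0, round(g$tss - wpk / 2))
    pend <- min(cfg$chrom_length, pstart + wpk)
    centre <- floor((pstart + pend) / 2)
    moff <- round(rnorm(1, 0, cfg$motif_offset_sd))
    mstart <- centre + moff - floor(length(mot) / 2)
    mstart <- max(0, min(cfg$chrom_length - length(mot), mstart))
    # write the motif consensus into the genome (forward strand)
    idx <- (mstart + 1):(mstart + length(mot))
    plant <- mot
    plant[plant == "N"] <- sample(DNA_BASES, sum(plant == "N"), replace = TRUE)
    seqs[[g$chrom]][idx] <- plant
    peaks[[j]] <- tibble(chrom = g$chrom, start = pstart, end = pend,
                         name = sprintf("peak%04d", j), score = 0,
                         strand = ".", summit = centre)
    motif_truth[[j]] <- tibble(peak = sprintf("peak%04d", j),
                               gene_id = g$gene_id, motif_start = mstart,
                               motif_centre = mstart + floor(length(mot) / 2),
                               peak_centre = centre, offset = moff)
  }
  peaks <- bind_rows(peaks)
  motif_truth <- bind_rows(motif_truth)
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))

  # --- ChIP and input fragments ---
  draw_fragments <- function(n, enriched) {
    # point-source binding model: an enriched fragment centres on the bound
    # site (the planted motif) plus Gaussian shearing noise, truncated to the
    # peak; the mixture weight q is set so mean coverage over the peak
    # footprint is ~chip_enrichment x background
    f_bp <- if (nrow(peaks)) sum(peaks$end - peaks$start) / sum(layout$size) else 0
    E <- if (enriched) cfg$chip_enrichment else 1
    q <- if (f_bp > 0) (E - 1) * f_bp / (1 + (E - 1) * f_bp) else 0
    in_peak <- runif(n) < q
    chrom <- sample(layout$chrom, n, replace = TRUE,
                    prob = layout$size / sum(layout$size))
    centre <- floor(runif(n) * (setNames(layout$size, layout$chrom)[chrom]))
    if (any(in_peak)) {
      pk <- sample.int(nrow(peaks), sum(in_peak), replace = TRUE,
                       prob = peaks$end - peaks$start)
      site <- motif_truth$motif_centre[pk]
      ctr <- round(site + rnorm(sum(in_peak), 0, cfg$peak_width_mean / 4))
      chrom[in_peak] <- peaks$chrom[pk]
      centre[in_peak] <- pmax(peaks$start[pk], pmin(peaks$end[pk] - 1, ctr))
    }
    start <- pmax(0, centre - floor(cfg$fragment_length / 2))
    end <- pmin(rep(cfg$chrom_length, n), start + cfg$fragment_length)
    sort_intervals(tibble(chrom = chrom, start = start, end = end), layout)
  }
  fragments_chip <- draw_fragments(cfg$n_fragments_chip, enriched = TRUE)
  fragments_input <- draw_fragments(cfg$n_fragments_input, enriched = FALSE)

  # --- CAGE tags: geometric spread around each TSS, strand-aware ---
  ctss <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    n_tags <- stats::rpois(1, cfg$cage_tags_per_tss)
    if (n_tags == 0) next
    off <- rgeom(n_tags, cfg$cage_spread) * sample(c(-1L, 1L), n_tags, replace = TRUE)
    pos <- pmax(0, pmin(cfg$chrom_length - 1, g$tss + off))
    tab <- table(pos)
    ctss[[i]] <- tibble(chrom = g$chrom, pos = as.integer(names(tab)),
                        strand = g$strand, count = as.integer(tab))
  }
  ctss <- bind_rows(ctss) |>
    group_by(.data$chrom, .data$pos, .data$strand) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$chrom, .data$pos, .data$strand)

  # --- DE labels with the planted binding/up odds ratio ---
  p0 <- cfg$frac_up_unbound
  odds1 <- cfg$de_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  is_bound <- seq_len(nrow(genes)) %in% bound_idx
  up <- rbinom(nrow(genes), 1, ifelse(is_bound, p1, p0)) == 1
  down <- !up & rbinom(nrow(genes), 1,
                       min(1, cfg$frac_down / (1 - mean(c(p0, p1))))) == 1
  lfc <- numeric(nrow(genes))
  padj <- numeric(nrow(genes))
  lfc[up] <- 0.5 + abs(rnorm(sum(up), 1, 0.5))
  lfc[down] <- -(0.5 + abs(rnorm(sum(down), 1, 0.5)))
  lfc[!up & !down] <- rnorm(sum(!up & !down), 0, 0.2)
  padj[up | down] <- runif(sum(up | down), 0, 0.049)
  padj[!up & !down] <- runif(sum(!up & !down), 0.05, 1)
  de_table <- tibble(gene_id = genes$gene_id,
                     base_mean = exp(rnorm(nrow(genes), 5, 1.5)),
                     log2fc = round(lfc, 4), padj = signif(padj, 4))

  # --- maternal ("embryo") gene set with planted odds ratio given up ---
  pm0 <- 0.35
  oddsm <- cfg$embryo_or * pm0 / (1 - pm0)
  pm1 <- oddsm / (1 + oddsm)
  in_embryo <- rbinom(nrow(genes), 1, ifelse(up, pm1, pm0)) == 1
  gene_sets <- list(embryo_0_2h = genes$gene_id[in_embryo])

  truth <- list(
    bound_genes = genes$gene_id[is_bound],
    de_labels = tibble(gene_id = genes$gene_id,
                       label = ifelse(up, "up", ifelse(down, "down", "not_de")),
                       bound = is_bound, in_embryo = in_embryo),
    motifs = motif_truth,
    params = cfg
  )
  structure(list(layout = layout, genome = genome, genes = genes,
                 peaks = peaks, fragments_chip = fragments_chip,
                 fragments_input = fragments_input, ctss = ctss,
                 de_table = de_table, gene_sets = gene_sets, truth = truth,
                 config = cfg),
            class = "sim_bundle")
}

#' Write a simulated bundle to disk in standard formats
#'
#' Emits FASTA, GTF, narrowPeak, fragment BED, CTSS TSV, DE TSV, a gene-set
#' file, and `truth/*.tsv` under `dir`.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  g <- bundle$genes
  gtf <- c(
    sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            g$chrom, g$start + 1, g$end, g$strand, g$gene_id, g$gene_id),
    sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            g$chrom, g$orf_start + 1, g$orf_end, g$strand, g$gene_id, g$gene_id)
  )
  readr::write_lines(gtf, file.path(dir, "annotation.gtf"))
  p <- bundle$peaks
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s\t%d\t.\t0\t-1\t-1\t%d",
            p$chrom, p$start, p$end, p$name, round(p$score),
            p$summit - p$start),
    file.path(dir, "peaks.narrowPeak"))
  write_bed(bundle$fragments_chip, file.path(dir, "fragments_chip.bed"))
  write_bed(bundle$fragments_input, file.path(dir, "fragments_input.bed"))
  readr::write_tsv(bundle$ctss, file.path(dir, "cage.ctss.tsv"), col_names = FALSE)
  readr::write_tsv(bundle$de_table, file.path(dir, "de_table.tsv"))
  write_gene_sets(bundle$gene_sets, file.path(dir, "gene_sets.tsv"))
  readr::write_tsv(bundle$truth$de_labels, file.path(dir, "truth", "de_labels.tsv"))
  readr::write_tsv(bundle$truth$motifs, file.path(dir, "truth", "motifs.tsv"))
  readr::write_lines(bundle$truth$bound_genes, file.path(dir, "truth", "bound_genes.txt"))
  invisible(dir)
}

#' Deterministic fixture carrying the published gene-count marginals
#'
#' Builds synthetic gene lists whose joint counts equal a published
#' binding-by-expression study design: 10,804 expressed genes of which 1,994
#' are up- and 2,924 down-regulated; 2,298 genes bound, 666 of them up and
#' 564 down; and a maternal 0-2 h embryo set intersecting the up/down/not-DE
#' classes in 1,409 / 625 / 3,448 genes.  Running [classify_de()],
#' [binding_de_association()] and [gene_set_overlap()] on this fixture
#' reproduces the published odds ratios end to end.
#'
#' @param n_expressed,n_up,n_down Marginal totals.
#' @param n_bound,n_bound_up,n_bound_down Binding counts.
#' @param n_embryo_up,n_embryo_down,n_embryo_notde Embryo-set intersections.
#' @return A list: `de_table`, `bound_genes`, `embryo_set`, `universe`.
#' @export
paper_marginals_fixture <- function(n_expressed = 10804, n_up = 1994,
                                    n_down = 2924, n_bound = 2298,
                                    n_bound_up = 666, n_bound_down = 564,
                                    n_embryo_up = 1409, n_embryo_down = 625,
                                    n_embryo_notde = 3448) {
  ids <- sprintf("g%05d", seq_len(n_expressed))
  n_notde <- n_expressed - n_up - n_down
  cls <- c(rep("up", n_up), rep("down", n_down), rep("not_de", n_notde))
  de_table <- tibble(
    gene_id = ids, base_mean = 100,
    log2fc = ifelse(cls == "up", 1, ifelse(cls == "down", -1, 0)),
    padj = ifelse(cls == "not_de", 0.5, 0.001)
  )
  up_ids <- ids[cls == "up"]; down_ids <- ids[cls == "down"]
  notde_ids <- ids[cls == "not_de"]
  bound_genes <- c(head(up_ids, n_bound_up), head(down_ids, n_bound_down),
                   head(notde_ids, n_bound - n_bound_up - n_bound_down))
  embryo_set <- c(head(up_ids, n_embryo_up), head(down_ids, n_embryo_down),
                  head(notde_ids, n_embryo_notde))
  list(de_table = de_table, bound_genes = bound_genes,
       embryo_set = embryo_set, universe = ids)
}
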