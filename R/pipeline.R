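#' Packaged promoter and binding motifs
#'
#' Loads the MEME-format motif models shipped with the package: the core
#' TF binding motif and its variants, and consensus-derived models of the
#' canonical core-promoter elements (INR, TATA, DPE, MTE, M1BP).  The
#' letter-probability values are IUPAC-consensus reconstructions (see the
#' shipped file headers), not experimentally fitted matrices.
#'
#' @param which `"all"`, `"tf"` (binding-motif variants) or `"promoter"`
#'   (core-promoter elements).
#' @return A named list of [pwm()] objects.
#' @export
packaged_motifs <- function(which = c("all", "tf", "promoter")) {
  which <- arg_match(which)
  path <- function(f) system.file("extdata", "motifs", f, package = "promint")
  tf <- read_meme_motifs(path("tf_binding_motifs.meme"))
  pr <- read_meme_motifs(path("core_promoter_elements.meme"))
  switch(which, all = c(tf, pr), tf = tf, promoter = pr)
}

#' Read a simulated bundle back from disk
#'
#' Counterpart of [write_bundle()]: loads the standard-format files of a
#' bundle directory through the package's readers.
#'
#' @param dir Bundle directory.
#' @param layout Genome layout; reconstructed from the FASTA when `NULL`.
#' @return A list with the same data fields as a `sim_bundle` (no truth).
#' @export
read_bundle <- function(dir, layout = NULL) {
  genome <- read_fasta(file.path(dir, "genome.fa"))
  if (is.null(layout)) {
    layout <- genome_layout(names(genome), Biostrings::width(genome))
  }
  list(layout = layout, genome = genome,
       genes = read_gtf(file.path(dir, "annotation.gtf"), layout),
       peaks = read_bed(file.path(dir, "peaks.narrowPeak"), layout),
       fragments_chip = read_bed(file.path(dir, "fragments_chip.bed"), layout),
       fragments_input = read_bed(file.path(dir, "fragments_input.bed"), layout),
       ctss = read_ctss(file.path(dir, "cage.ctss.tsv"), layout),
       de_table = read_de_table(file.path(dir, "de_table.tsv")),
       gene_sets = read_gene_sets(file.path(dir, "gene_sets.tsv")))
}

#' Run the integrative promoter analysis end to end
#'
#' Executes the full pipeline on a bundle (a `sim_bundle`, the output of
#' [read_bundle()], or a bundle directory path): peak classification against
#' the gene models, relative distance of peaks to TSS/ORF-midpoint/TTS
#' anchors, motif scanning and motif-in-peak statistics, BPM-normalised
#' ChIP-minus-input coverage with a TSS-centred profile, CAGE clustering
#' with dominant-TSS/peak overlap, DE classification, and the binding and
#' gene-set contingency statistics.  Deterministic given its inputs.
#'
#' @param bundle Bundle list or directory path.
#' @param motif_pwm PWM used for genome scanning (default: the packaged core
#'   TF motif).
#' @param scan_p Motif-scan p-value threshold.
#' @param bin_size Coverage track bin size (bp).
#' @param flank Profile flank (bp) either side of the TSS.
#' @param profile_bin Profile column width (bp).
#' @param de_padj_max,de_lfc_min DE classification cutoffs.
#' @return A list of class `promint_report` with per-stage results and a
#'   flat `summary` list of the headline numbers, each named for the
#'   operation that produced it.
#' @export
run_pipeline <- function(bundle,
                         motif_pwm = NULL,
                         scan_p = 2e-4,
                         bin_size = 5, flank = 2000, profile_bin = 25,
                         de_padj_max = 0.05, de_lfc_min = 0.5) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  if (is.null(motif_pwm)) {
    # a sim_bundle knows its planted motif; otherwise fall back to the
    # packaged core binding motif
    motif_pwm <- if (!is.null(bundle$config$motif)) {
      pwm_from_consensus("core", bundle$config$motif)
    } else {
      packaged_motifs("tf")[["tf_core"]]
    }
  }
  genes <- bundle$genes
  peaks <- bundle$peaks

  cls <- classify_peaks(peaks, genes)
  class_counts <- table(factor(cls$class, c("TSS", "gene_body", "intergenic")))

  tss_anchors <- tibble(chrom = genes$chrom, pos = genes$tss)
  rd_tss <- reldist(peaks, tss_anchors)

  hits <- scan_motifs(motif_pwm, bundle$genome, p_threshold = scan_p)
  mip <- motifs_in_peaks(hits, peaks)

  chip <- coverage_from_fragments(bundle$fragments_chip, bundle$layout, bin_size)
  input <- coverage_from_fragments(bundle$fragments_input, bundle$layout, bin_size)
  diff_track <- track_compare(chip, input, "subtract")
  tss_profile <- reference_point_matrix(
    diff_track,
    tibble(chrom = genes$chrom, pos = genes$tss, strand = genes$strand),
    flank_up = flank, flank_down = flank, bin = profile_bin)

  clusters <- cluster_ctss(tpm_normalize(bundle$ctss))
  clusters <- cage_tss_overlap(clusters, peaks)

  declass <- classify_de(bundle$de_table, de_padj_max, de_lfc_min)
  bound <- bind_genes(peaks, genes, mode = "any_overlap")
  assoc <- binding_de_association(declass, bound)
  set_assoc <- lapply(bundle$gene_sets, function(s) gene_set_overlap(declass, s))

  pm <- profile_means(tss_profile)
  summary <- list(
    n_peaks = nrow(peaks),
    class_counts = as.list(class_counts),
    frac_tss = unname(class_counts[["TSS"]] / max(1, nrow(peaks))),
    reldist_mean_tss = if (rd_tss$n) mean(rd_tss$values) else NA_real_,
    frac_peaks_with_motif = mip$frac_with_motif,
    profile_max_position = pm$position[which.max(pm$signal)],
    n_tag_clusters = nrow(clusters),
    n_clusters_in_peak = sum(clusters$in_peak),
    n_genes_bound = length(bound),
    de_counts = as.list(table(declass$de_class)),
    or_bound_up = assoc$up$odds_ratio,
    or_bound_down = assoc$down$odds_ratio,
    or_sets = lapply(set_assoc, function(a)
      list(up = a$up$odds_ratio, down = a$down$odds_ratio))
  )
  structure(list(peak_classes = cls, reldist_tss = rd_tss, motif_hits = hits,
                 motifs_in_peaks = mip, tss_profile = tss_profile,
                 clusters = clusters, de = declass, bound_genes = bound,
                 binding_de = assoc, gene_set_assoc = set_assoc,
                 summary = summary),
            class = "promint_report")
}

#' @export
print.promint_report <- function(x, ...) {
  s <- x$summary
  cat("<promint_report>\n")
  cat(sprintf("  peaks: %d (TSS %d / gene_body %d / intergenic %d)\n",
              s$n_peaks, s$class_counts$TSS, s$class_counts$gene_body,
              s$class_counts$intergenic))
  cat(sprintf("  mean reldist to TSS: %.3f; peaks with motif: %.1f%%\n",
              s$reldist_mean_tss, 100 * s$frac_peaks_with_motif))
  cat(sprintf("  tag clusters: %d (%d in peaks); bound genes: %d\n",
              s$n_tag_clusters, s$n_clusters_in_peak, s$n_genes_bound))
  cat(sprintf("  binding x DE odds ratios: up %.2f, down %.2f\n",
              s$or_bound_up, s$or_bound_down))
  invisible(x)
}

#' Write a pipeline report summary as JSON
#'
#' @param report A `promint_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report$summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
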