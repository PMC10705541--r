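#' Read intervals from a BED or narrowPeak file
#'
#' Reads BED3+ or ENCODE narrowPeak (BED6+4) into a tidy interval tibble.
#' Coordinates are kept in their native 0-based half-open frame and intervals
#' are sorted by layout chromosome order, then start.  For narrowPeak input
#' the summit (column 10, offset from `start`) is converted to an absolute
#' genomic position; an offset of -1 (summit not called) becomes `NA`.
#'
#' @param path Path to a tab-separated BED3+/narrowPeak file.
#' @param layout Genome layout from [genome_layout()]; every interval must lie
#'   within its chromosome, and unknown chromosomes are an error (silent
#'   dropping would corrupt genome-wide statistics).
#' @return A tibble with columns `chrom`, `start`, `end`, and, when the input
#'   carries them, `name`, `score`, `strand`, `summit`.
#' @export
read_bed <- function(path, layout) {
  check_layout(layout)
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("%s: line %d has fewer than 3 tab-separated columns",
                  path, lineno[which(nf < 3)[1]]))
  }
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")
  x <- tibble(
    chrom = col(1),
    start = suppressWarnings(as.numeric(col(2))),
    end = suppressWarnings(as.numeric(col(3)))
  )
  bad <- which(is.na(x$start) | is.na(x$end))
  if (length(bad)) {
    abort(sprintf("%s: line %d has non-numeric start/end", path, lineno[bad[1]]))
  }
  if (min(nf) >= 6) {
    x$name <- col(4)
    x$score <- suppressWarnings(as.numeric(col(5)))
    x$strand <- col(6)
  }
  if (min(nf) >= 10) {
    off <- suppressWarnings(as.numeric(col(10)))
    x$summit <- ifelse(is.na(off) | off < 0, NA_real_, x$start + off)
  }
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    abort(sprintf("%s: line %d: start >= end (%s:%s-%s)", path, lineno[bad[1]],
                  x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  miss <- setdiff(unique(x$chrom), layout$chrom)
  if (length(miss)) {
    abort(sprintf("%s: line %d references chromosome `%s` absent from the layout",
                  path, lineno[which(x$chrom %in% miss)[1]], miss[1]))
  }
  len <- setNames(layout$size, layout$chrom)
  over <- which(x$start < 0 | x$end > len[x$chrom])
  if (length(over)) {
    abort(sprintf("%s: line %d: interval %s:%s-%s outside chromosome bounds",
                  path, lineno[over[1]], x$chrom[over[1]], x$start[over[1]], x$end[over[1]]))
  }
  sort_intervals(x, layout)
}

#' Write intervals to a BED file
#'
#' Writes `chrom`, `start`, `end` (plus `name`, `score`, `strand` when
#' present) as tab-separated BED.  Canonical BED3 input round-trips through
#' [read_bed()] byte-identically.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  # BED has no ragged rows: truncate at the first optional column not present
  want <- c("chrom", "start", "end", "name", "score", "strand")
  keep <- want[seq_len(max(which(want %in% cols)))]
  if (!all(keep %in% cols)) keep <- c("chrom", "start", "end")
  fmt <- do.call(paste, c(lapply(keep, function(k) {
    v <- x[[k]]
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else v
  }), sep = "\t"))
  readr::write_lines(fmt, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses GTF (1-based, closed) gene annotation into one strand-aware gene
#' model per gene in the package's 0-based half-open frame.  The gene extent
#' is the union of its transcripts (or of its `gene` feature when no
#' transcripts are annotated), the TSS is the 5'-most transcript start on the
#' gene strand, the TTS the 3'-most end, and the ORF extent is the union of
#' CDS features (`NA` for non-coding genes).
#'
#' @param path Path to a GTF file.
#' @param layout Genome layout; features on unknown chromosomes are an error.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (transcribed extent, half-open), `tss`, `tts` (single base
#'   positions), `orf_start`, `orf_end`.
#' @export
read_gtf <- function(path, layout) {
  check_layout(layout)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = as.character(gr$gene_id)
  )
  miss <- setdiff(unique(df$chrom), layout$chrom)
  if (length(miss)) {
    abort(sprintf("%s: chromosome(s) not in layout: %s", path,
                  paste(miss, collapse = ", ")))
  }
  no_strand <- df$strand == "*"
  if (any(no_strand)) {
    dropped <- unique(df$gene_id[no_strand])
    warn(sprintf("%s: skipping %d gene(s) without strand: %s", path,
                 length(dropped), paste(head(dropped, 5), collapse = ", ")))
    df <- df[!df$gene_id %in% dropped, , drop = FALSE]
  }
  tx_types <- c("transcript", "mRNA")
  extent_src <- if (any(df$type %in% tx_types)) df[df$type %in% tx_types, ] else df[df$type == "gene", ]
  if (!nrow(extent_src)) extent_src <- df
  genes <- extent_src |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    )
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    orf <- cds |>
      group_by(.data$gene_id) |>
      summarise(orf_start = min(.data$start), orf_end = max(.data$end), .groups = "drop")
    genes <- left_join(genes, orf, by = "gene_id")
  } else {
    genes$orf_start <- NA_real_
    genes$orf_end <- NA_real_
  }
  genes <- mutate(genes,
    tss = ifelse(.data$strand == "+", .data$start, .data$end - 1),
    tts = ifelse(.data$strand == "+", .data$end - 1, .data$start)
  )
  out <- select(genes, "gene_id", "chrom", "strand", "start", "end",
                "tss", "tts", "orf_start", "orf_end")
  check_intervals(out, layout, arg = "genes")
  sort_intervals(out, layout)
}

#' Read a differential-expression results table
#'
#' Reads a tab-separated table with header columns `gene_id`, `base_mean`,
#' `log2fc`, `padj` (DESeq2-style results).  `padj` may be `NA` for genes
#' removed by independent filtering.
#'
#' @param path Path to the TSV file.
#' @return A tibble with those four columns.
#' @export
read_de_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    base_mean = readr::col_double(),
    log2fc = readr::col_double(),
    padj = readr::col_double()
  ), progress = FALSE)
  need <- c("gene_id", "base_mean", "log2fc", "padj")
  if (!all(need %in% names(x))) {
    abort(sprintf("%s: expected header columns %s", path, paste(need, collapse = ", ")))
  }
  if (anyDuplicated(x$gene_id)) {
    abort(sprintf("%s: duplicated gene_id `%s`", path,
                  x$gene_id[anyDuplicated(x$gene_id)]))
  }
  ok <- is.na(x$padj) | (x$padj >= 0 & x$padj <= 1)
  if (!all(ok)) {
    abort(sprintf("%s: line %d: padj outside [0, 1]", path, which(!ok)[1] + 1L))
  }
  x[need]
}

#' Read CAGE 5'-tag counts (CTSS)
#'
#' Reads a headerless tab-separated CTSS table: `chrom`, `pos` (0-based base
#' position of the capped 5' end), `strand`, `count`.
#'
#' @param path Path to the CTSS TSV.
#' @param layout Optional genome layout for coordinate validation.
#' @return A tibble with columns `chrom`, `pos`, `strand`, `count`.
#' @export
read_ctss <- function(path, layout = NULL) {
  x <- readr::read_tsv(path, col_names = c("chrom", "pos", "strand", "count"),
                       col_types = "cicd", progress = FALSE)
  bad <- which(is.na(x$pos) | is.na(x$count) | x$count <= 0 |
                 x$count != floor(x$count) | !x$strand %in% c("+", "-"))
  if (length(bad)) {
    abort(sprintf("%s: line %d: malformed CTSS record", path, bad[1]))
  }
  if (anyDuplicated(x[c("chrom", "pos", "strand")])) {
    abort(sprintf("%s: duplicated (chrom, pos, strand) record", path))
  }
  if (!is.null(layout)) {
    check_layout(layout)
    miss <- setdiff(unique(x$chrom), layout$chrom)
    if (length(miss)) abort(sprintf("%s: chromosome(s) not in layout: %s",
                                    path, paste(miss, collapse = ", ")))
    len <- setNames(layout$size, layout$chrom)
    if (any(x$pos < 0 | x$pos >= len[x$chrom])) {
      abort(sprintf("%s: CTSS position outside chromosome bounds", path))
    }
  }
  arrange(x, .data$chrom, .data$pos, .data$strand)
}

#' Read a bedGraph file into a coverage track
#'
#' bedGraph records are 0-based half-open with a value per interval.  The
#' track stores, per chromosome, the mean per-base value within fixed-width
#' bins (see [coverage_track()]).
#'
#' @param path Path to a bedGraph file.
#' @param layout Genome layout.
#' @param bin_size Track bin width in bp (default 1: exact per-base values).
#' @return A `coverage_track` object.
#' @export
read_bedgraph <- function(path, layout, bin_size = 1) {
  check_layout(layout)
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       col_types = "cddd", comment = "#", progress = FALSE)
  bad <- which(is.na(x$start) | is.na(x$end) | is.na(x$value) | x$start >= x$end)
  if (length(bad)) abort(sprintf("%s: line %d: malformed bedGraph record", path, bad[1]))
  check_intervals(x, layout, arg = path)
  track_from_values(x, layout, bin_size)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued bins are merged into runs; zero-valued runs are
#' omitted.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  bs <- track$bin_size
  rows <- purrr::imap(track$values, function(v, chrom) {
    if (!length(v)) return(NULL)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0, head(ends, -1))
    len <- track$layout$size[match(chrom, track$layout$chrom)]
    tibble(chrom = chrom, start = starts * bs, end = pmin(ends * bs, len),
           value = r$values) |>
      filter(.data$value != 0)
  })
  out <- bind_rows(rows)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read motifs in MEME format
#'
#' Parses MEME motif format (version 4+) letter-probability matrices over the
#' DNA alphabet into a list of [pwm()] objects.  A `Background letter
#' frequencies` block, when present, becomes each motif's background model;
#' otherwise the background is uniform.
#'
#' @param path Path to a MEME motif file.
#' @param pseudocount Pseudocount fraction stored on each PWM (see [pwm()]).
#' @return A named list of `pwm` objects.
#' @export
read_meme_motifs <- function(path, pseudocount = 0.001) {
  lines <- readr::read_lines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    j <- bg_i[1] + 1
    toks <- strsplit(trimws(lines[j]), "\\s+")[[1]]
    if (length(toks) >= 8) {
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      names(vals) <- toupper(toks[seq(1, 7, by = 2)])
      bg <- vals[c("A", "C", "G", "T")]
    }
  }
  motif_i <- grep("^MOTIF\\b", lines)
  if (!length(motif_i)) abort(sprintf("%s: no MOTIF records found", path))
  out <- list()
  for (mi in motif_i) {
    name <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    li <- grep("^letter-probability matrix", lines[mi:length(lines)])[1]
    if (is.na(li)) abort(sprintf("%s: motif `%s` lacks a letter-probability matrix", path, name))
    li <- mi + li - 1
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[li]))
    if (is.na(w) || w < 1) abort(sprintf("%s: motif `%s`: cannot parse width", path, name))
    rows <- lines[(li + 1):(li + w)]
    mat <- t(vapply(seq_along(rows), function(k) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(rows[k]), "\\s+")[[1]]))
      if (length(v) != 4 || anyNA(v)) {
        abort(sprintf("%s: line %d: malformed probability row for motif `%s`",
                      path, li + k, name))
      }
      v
    }, numeric(4)))
    rownames(mat) <- NULL
    probs <- t(mat)          # 4 x w, rows A C G T
    if (any(abs(colSums(probs) - 1) > 0.01)) {
      abort(sprintf("%s: motif `%s`: probability columns do not sum to 1", path, name))
    }
    probs <- sweep(probs, 2, colSums(probs), "/")  # absorb printed rounding
    rownames(probs) <- c("A", "C", "G", "T")
    out[[name]] <- pwm(name, probs, background = bg, pseudocount = pseudocount)
  }
  out
}

#' Write motifs in MEME format
#'
#' @param pwms A list of [pwm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  hdr <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
           "Background letter frequencies",
           sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]), "")
  body <- purrr::map(pwms, function(p) {
    c(sprintf("MOTIF %s", p$name),
      sprintf("letter-probability matrix: alphabet= 4 w= %d nsites= 20 E= 0", ncol(p$probs)),
      apply(p$probs, 2, function(col) sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])),
      "")
  })
  readr::write_lines(c(hdr, unlist(body)), path)
  invisible(path)
}

#' Read gene sets
#'
#' One set per line: the set name, a tab, then tab-separated member gene ids.
#'
#' @param path Path to the gene-set file.
#' @return A named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2)
  if (length(short)) abort(sprintf("%s: line %d: gene set with no members", path, short[1]))
  setNames(lapply(fields, function(f) unique(f[-1])),
           vapply(fields, `[[`, "", 1))
}

#' Write gene sets
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  readr::write_lines(
    vapply(names(sets), function(n) paste(c(n, sets[[n]]), collapse = "\t"), ""),
    path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the named
#' `DNAStringSet` the motif and promoter modules consume.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
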