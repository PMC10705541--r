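#' Construct a coverage track
#'
#' A coverage track holds, per chromosome, the mean per-base signal within
#' consecutive fixed-width bins (`ceiling(size / bin_size)` bins per
#' chromosome).  Storing means rather than sums keeps the values on the same
#' scale as the underlying per-base signal regardless of bin width.
#'
#' @param values Named list (one numeric vector per chromosome).
#' @param layout Genome layout.
#' @param bin_size Bin width in bp.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, layout, bin_size) {
  check_layout(layout)
  for (chrom in layout$chrom) {
    want <- ceiling(layout$size[layout$chrom == chrom] / bin_size)
    if (is.null(values[[chrom]])) values[[chrom]] <- numeric(want)
    if (length(values[[chrom]]) != want) {
      abort(sprintf("track vector for %s has length %d, expected %d",
                    chrom, length(values[[chrom]]), want))
    }
  }
  structure(list(values = values[layout$chrom], layout = layout,
                 bin_size = bin_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), bin %d bp, total mass %.4g\n",
              nrow(x$layout), x$bin_size, track_sum(x)))
  invisible(x)
}

#' Total of all bin values in a track
#' @param track A `coverage_track`.
#' @return A single number.
#' @export
track_sum <- function(track) sum(vapply(track$values, sum, numeric(1)))

# Internal: per-base value tibble (chrom,start,end,value) -> track.
track_from_values <- function(x, layout, bin_size) {
  vals <- list()
  for (chrom in layout$chrom) {
    len <- layout$size[layout$chrom == chrom]
    nb <- ceiling(len / bin_size)
    base <- numeric(len)
    xs <- x[x$chrom == chrom, , drop = FALSE]
    if (nrow(xs)) {
      # difference array over bases, then cumulative sum
      d <- numeric(len + 1)
      add_s <- tapply(xs$value, xs$start, sum)
      add_e <- tapply(xs$value, xs$end, sum)
      d[as.integer(names(add_s)) + 1] <- d[as.integer(names(add_s)) + 1] + as.numeric(add_s)
      d[as.integer(names(add_e)) + 1] <- d[as.integer(names(add_e)) + 1] - as.numeric(add_e)
      base <- cumsum(d[seq_len(len)])
    }
    idx <- rep(seq_len(nb), each = bin_size, length.out = len)
    vals[[chrom]] <- as.numeric(rowsum(base, idx)) / bin_size
  }
  coverage_track(vals, layout, bin_size)
}

#' Binned coverage from sequenced fragments
#'
#' Each fragment contributes 1 to every bin it overlaps, weighted by the
#' fraction of the bin it covers, so a fragment spanning two bins equally
#' contributes 0.5 to each and the total track mass equals total fragment bp
#' divided by the bin width.
#'
#' @param fragments Interval tibble of fragments.
#' @param layout Genome layout.
#' @param bin_size Bin width in bp (default 5).
#' @return A `coverage_track`.
#' @export
coverage_from_fragments <- function(fragments, layout, bin_size = 5) {
  check_intervals(fragments, layout, arg = "fragments")
  track_from_values(mutate(fragments[c("chrom", "start", "end")], value = 1),
                    layout, bin_size)
}

#' Bins-per-million normalisation
#'
#' Scales a track so all bins sum to one million (the deepTools BPM
#' normalisation), making tracks of different sequencing depth comparable.
#'
#' @param track A `coverage_track`.
#' @return A BPM-scaled `coverage_track`.
#' @export
bpm_normalize <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  tot <- track_sum(track)
  if (tot == 0) abort("cannot BPM-normalise an all-zero track")
  track$values <- lapply(track$values, function(v) v / tot * 1e6)
  track
}

#' Compare a ChIP track with its input control
#'
#' Both tracks are BPM-normalised first, then combined bin-wise:
#' `subtract` gives ChIP minus input (may be negative), `log2ratio` gives
#' `log2((chip + c) / (input + c))` with pseudocount `c`.
#'
#' @param chip,input `coverage_track`s on the same layout and bin size.
#' @param operation `"subtract"` (default) or `"log2ratio"`.
#' @param pseudocount Pseudocount for the log2 ratio.
#' @return A `coverage_track` of the comparison values.
#' @export
track_compare <- function(chip, input, operation = c("subtract", "log2ratio"),
                          pseudocount = 1) {
  operation <- arg_match(operation)
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (chip$bin_size != input$bin_size ||
      !identical(chip$layout$chrom, input$layout$chrom)) {
    abort("`chip` and `input` must share layout and bin size")
  }
  chip <- bpm_normalize(chip)
  input <- bpm_normalize(input)
  vals <- purrr::map2(chip$values, input$values, function(a, b) {
    if (operation == "subtract") a - b
    else log2((a + pseudocount) / (b + pseudocount))
  })
  coverage_track(vals, chip$layout, chip$bin_size)
}

# Internal: integral of per-base track signal over [a, b), clipped to the
# chromosome; relies on bin values being per-base means.
range_integral <- function(cumv, v, bin_size, len, a, b) {
  a <- max(0, min(a, len)); b <- max(0, min(b, len))
  if (b <= a) return(0)
  at <- function(x) {
    k <- floor(x / bin_size)
    full <- if (k > 0) cumv[k] * bin_size else 0
    part <- if (k < length(v)) (x - k * bin_size) * v[k + 1] else 0
    full + part
  }
  at(b) - at(a)
}

#' Anchor-centred profile matrix
#'
#' Builds the reference-point matrix of deepTools `computeMatrix
#' reference-point`: one row per anchor, columns of `bin` bp spanning
#' `flank_up` bp upstream to `flank_down` bp downstream, oriented 5' to 3'
#' by the anchor strand (upstream on the left).  Bins beyond chromosome ends
#' are zero (missing data as zero).  Values are mean per-base signal per bin.
#'
#' @param track A `coverage_track`.
#' @param anchors Tibble with columns `chrom`, `pos`, and optionally `strand`
#'   (defaults to `+`) and `name`.
#' @param flank_up,flank_down Flank widths in bp (default 2000).
#' @param bin Column width in bp (default 25).
#' @return An object of class `profile_matrix` with fields `values` (matrix),
#'   `anchors`, and the parameters.
#' @export
reference_point_matrix <- function(track, anchors, flank_up = 2000,
                                   flank_down = 2000, bin = 25) {
  stopifnot(inherits(track, "coverage_track"))
  if ((flank_up + flank_down) %% bin != 0) {
    abort("`flank_up + flank_down` must be a multiple of `bin`")
  }
  if (!"strand" %in% names(anchors)) anchors$strand <- "+"
  ncol_ <- (flank_up + flank_down) / bin
  mat <- matrix(0, nrow = nrow(anchors), ncol = ncol_)
  cums <- lapply(track$values, cumsum)
  lens <- setNames(track$layout$size, track$layout$chrom)
  for (i in seq_len(nrow(anchors))) {
    chrom <- anchors$chrom[i]
    v <- track$values[[chrom]]
    if (is.null(v)) abort(sprintf("anchor chromosome `%s` not in track", chrom))
    minus <- identical(anchors$strand[i], "-")
    left <- anchors$pos[i] - (if (minus) flank_down else flank_up)
    row <- vapply(seq_len(ncol_), function(k) {
      range_integral(cums[[chrom]], v, track$bin_size, lens[[chrom]],
                     left + (k - 1) * bin, left + k * bin) / bin
    }, numeric(1))
    mat[i, ] <- if (minus) rev(row) else row
  }
  structure(list(values = mat, anchors = as_tibble(anchors),
                 mode = "reference_point", flank_up = flank_up,
                 flank_down = flank_down, bin = bin, body_length = NULL),
            class = "profile_matrix")
}

#' Scaled gene-body (metagene) profile matrix
#'
#' The deepTools `computeMatrix scale-regions` operation: each gene body is
#' linearly rescaled to `body_length` bp, flanks are kept unscaled, and rows
#' are oriented 5' to 3' by gene strand.
#'
#' @param track A `coverage_track`.
#' @param genes Gene-model tibble (needs `chrom`, `start`, `end`, `strand`).
#' @param body_length Common scaled body length in bp (default 4000).
#' @param bin Column width in bp (default 25).
#' @param flank_up,flank_down Unscaled flank widths in bp (default 2000).
#' @return A `profile_matrix` with `mode = "scale_regions"`.
#' @export
scale_regions_matrix <- function(track, genes, body_length = 4000, bin = 25,
                                 flank_up = 2000, flank_down = 2000) {
  stopifnot(inherits(track, "coverage_track"))
  if (body_length %% bin != 0 || flank_up %% bin != 0 || flank_down %% bin != 0) {
    abort("`body_length` and flanks must be multiples of `bin`")
  }
  n_up <- flank_up / bin; n_body <- body_length / bin; n_down <- flank_down / bin
  mat <- matrix(0, nrow = nrow(genes), ncol = n_up + n_body + n_down)
  cums <- lapply(track$values, cumsum)
  lens <- setNames(track$layout$size, track$layout$chrom)
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    v <- track$values[[chrom]]
    gs <- genes$start[i]; ge <- genes$end[i]
    minus <- identical(genes$strand[i], "-")
    ri <- function(a, b) range_integral(cums[[chrom]], v, track$bin_size,
                                        lens[[chrom]], a, b)
    up_left <- gs - (if (minus) flank_down else flank_up)
    n_left <- if (minus) n_down else n_up
    n_right <- if (minus) n_up else n_down
    left_part <- vapply(seq_len(n_left), function(k)
      ri(up_left + (k - 1) * bin, up_left + k * bin) / bin, numeric(1))
    L <- ge - gs
    body <- vapply(seq_len(n_body), function(k) {
      a <- gs + (k - 1) / n_body * L
      b <- gs + k / n_body * L
      if (b > a) ri(a, b) / (b - a) else 0
    }, numeric(1))
    right_part <- vapply(seq_len(n_right), function(k)
      ri(ge + (k - 1) * bin, ge + k * bin) / bin, numeric(1))
    row <- c(left_part, body, right_part)
    mat[i, ] <- if (minus) rev(row) else row
  }
  structure(list(values = mat,
                 anchors = tibble(chrom = genes$chrom,
                                  pos = ifelse(genes$strand == "-",
                                               genes$end - 1, genes$start),
                                  strand = genes$strand,
                                  name = if ("gene_id" %in% names(genes))
                                    genes$gene_id else as.character(seq_len(nrow(genes)))),
                 mode = "scale_regions", flank_up = flank_up,
                 flank_down = flank_down, bin = bin, body_length = body_length),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %s: %d anchors x %d bins (%d bp/bin)\n",
              x$mode, nrow(x$values), ncol(x$values), x$bin))
  invisible(x)
}

#' Row ordering for profile heatmaps
#'
#' Returns the permutation that sorts matrix rows in descending order of
#' their maximum (deepTools `plotHeatmap --sortUsing max`) or sum; ties keep
#' the original anchor order.
#'
#' @param m A `profile_matrix` or plain matrix.
#' @param by `"max"` (default) or `"sum"`.
#' @return An integer permutation of the row indices.
#' @export
order_rows <- function(m, by = c("max", "sum")) {
  by <- arg_match(by)
  values <- if (inherits(m, "profile_matrix")) m$values else m
  stat <- if (by == "max") apply(values, 1, max) else rowSums(values)
  order(-stat)  # radix order is stable: ties keep anchor order
}

#' Mean profile across anchors
#'
#' @param m A `profile_matrix`.
#' @return A tibble with `position` (bp relative to the anchor / scaled gene)
#'   and `signal` (column means).
#' @export
profile_means <- function(m) {
  stopifnot(inherits(m, "profile_matrix"))
  if (m$mode == "reference_point") {
    pos <- seq(-m$flank_up + m$bin / 2, m$flank_down - m$bin / 2, by = m$bin)
  } else {
    pos <- seq(m$bin / 2, by = m$bin, length.out = ncol(m$values)) - m$flank_up
  }
  tibble(position = pos, signal = colMeans(m$values))
}
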