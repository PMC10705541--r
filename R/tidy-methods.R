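#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a contingency result
#'
#' One row per cell of the 2x2 table, broom-style.
#'
#' @param x A contingency result as returned by [fisher_2x2()].
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `count`.
#' @exportS3Method generics::tidy
tidy.contingency_result <- function(x, ...) {
  tibble(row = rep(c("yes", "no"), each = 2),
         col = rep(c("yes", "no"), 2),
         count = as.vector(t(x$table)))
}

#' One-row summary of a contingency result
#'
#' @param x A contingency result as returned by [fisher_2x2()].
#' @param ... Unused.
#' @return A one-row tibble: `odds_ratio`, `p_value`, `direction`,
#'   `universe_size`.
#' @exportS3Method generics::glance
glance.contingency_result <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p_value = x$p_value,
         direction = x$direction, universe_size = x$universe_size)
}

#' Tidy a relative-distance result
#'
#' @param x A `reldist_result`.
#' @param ... Unused.
#' @return The histogram tibble (`bin_lo`, `bin_hi`, `count`, `freq`).
#' @exportS3Method generics::tidy
tidy.reldist_result <- function(x, ...) x$histogram

#' One-row summary of a relative-distance result
#'
#' @param x A `reldist_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_skipped`, `mean_reldist`.
#' @exportS3Method generics::glance
glance.reldist_result <- function(x, ...) {
  tibble(n = x$n, n_skipped = x$n_skipped,
         mean_reldist = if (x$n) mean(x$values) else NA_real_)
}

#' Plot a relative-distance histogram
#'
#' Under spatial independence the relative-distance density is flat at the
#' dashed reference line; enrichment near anchors piles mass toward 0.
#'
#' @param object A `reldist_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.reldist_result <- function(object, ...) {
  h <- object$histogram
  expected <- 1 / nrow(h)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$freq)) +
    ggplot2::geom_col(width = h$bin_hi[1] - h$bin_lo[1], fill = "grey35") +
    ggplot2::geom_hline(yintercept = expected, linetype = "dashed") +
    ggplot2::labs(x = "relative distance", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot the mean profile of a profile matrix
#'
#' @param object A `profile_matrix`.
#' @param ... Unused.
#' @return A ggplot object of the column-mean signal against position.
#' @exportS3Method ggplot2::autoplot
autoplot.profile_matrix <- function(object, ...) {
  pm <- profile_means(object)
  gg <- ggplot2::ggplot(pm, ggplot2::aes(x = .data$position, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (object$mode == "reference_point")
                    "distance from anchor (bp)" else "metagene position (bp)",
                  y = "mean signal") +
    ggplot2::theme_minimal()
  if (object$mode == "reference_point") {
    gg <- gg + ggplot2::geom_vline(xintercept = 0, linetype = "dashed")
  }
  gg
}

#' Plot promoter-element positional density
#'
#' @param density Density tibble from [element_density()] (`motif`, `offset`,
#'   `count`).
#' @param smooth_bw Width of the rolling mean (bp) applied per motif for
#'   display; 1 disables smoothing.
#' @return A ggplot object, one panel per motif.
#' @export
plot_element_density <- function(density, smooth_bw = 5) {
  d <- density |>
    group_by(.data$motif) |>
    arrange(.data$offset, .by_group = TRUE) |>
    mutate(smoothed = if (smooth_bw > 1)
      as.numeric(stats::filter(.data$count, rep(1 / smooth_bw, smooth_bw),
                               sides = 2)) else .data$count) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = .data$smoothed)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~motif, scales = "free_y") +
    ggplot2::labs(x = "offset from TSS (bp)", y = "hit density") +
    ggplot2::theme_minimal()
}

#' Heatmap of a profile matrix
#'
#' Rows are anchors (ordered with [order_rows()]), columns are positions.
#'
#' @param m A `profile_matrix`.
#' @param order_by Row ordering statistic (see [order_rows()]).
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(m, order_by = "max") {
  perm <- order_rows(m, by = order_by)
  vals <- m$values[perm, , drop = FALSE]
  pm <- profile_means(m)
  df <- tidyr::expand_grid(row = seq_len(nrow(vals)),
                           col = seq_len(ncol(vals)))
  df$position <- pm$position[df$col]
  df$signal <- vals[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = -.data$row,
                                   fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position (bp)", y = "anchors", fill = "signal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
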