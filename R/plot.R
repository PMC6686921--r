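POP_PALETTE <- c(`1` = "#1f77b4", `2` = "#8c564b", `3` = "#2ca02c",
                 `4` = "#9467bd", `5` = "#e377c2", `6` = "#ff7f0e",
                 `7` = "#17becf", `8` = "#d62728", `9` = "#7f7f7f",
                 Unassigned = "#000000")

#' Diagnostic scatter plots of ancestry scores
#'
#' Three views: GD2 vs GD1 (with the reference triangle), GD3 vs GD1
#' (out-of-plane separation of multi-way admixture), and GD4 vs GD1 (with the
#' two cutoff curves that separate South Asians, Asian-Pacific Islanders and
#' Latin Americans). Every subject in the table is drawn once; an optional
#' seeded subsample caps overplotting on large cohorts.
#'
#' @param scores data.frame from [compute_cohort_scores()] /
#'   [assign_population()].
#' @param axes character pair, one of `c("GD1","GD2")`, `c("GD1","GD3")`,
#'   `c("GD1","GD4")`.
#' @param frame0 optional `triadmix_frame`; draws the reference triangle on
#'   the (GD1, GD2) view.
#' @param cutoffs optional cutoff list; draws the separating curves on the
#'   (GD1, GD4) view.
#' @param color_by column used for point colour (default `pop_label` when
#'   present).
#' @param max_points optional cap; a seeded random subsample of this size is
#'   plotted.
#' @param seed seed for the subsample.
#' @return a ggplot object.
#' @export
plot_scores <- function(scores, axes = c("GD1", "GD2"), frame0 = NULL,
                        cutoffs = NULL, color_by = NULL, max_points = NULL,
                        seed = 1L) {
  valid <- list(c("GD1", "GD2"), c("GD1", "GD3"), c("GD1", "GD4"))
  if (!any(vapply(valid, identical, logical(1), y = as.character(axes)))) {
    stop("axes must be one of (GD1,GD2), (GD1,GD3), (GD1,GD4)")
  }
  if (nrow(scores) == 0L) stop("empty score table")
  if (!all(axes %in% names(scores))) stop("requested axes not in table")
  if (!is.null(cutoffs) && !identical(as.character(axes), c("GD1", "GD4"))) {
    stop("cutoff-curve overlay is only valid on the (GD1, GD4) view")
  }
  df <- scores
  if (!is.null(max_points) && nrow(df) > max_points) {
    df <- with_seed(seed, df[sample.int(nrow(df), max_points), , drop = FALSE])
  }
  if (is.null(color_by)) {
    color_by <- if ("pop_label" %in% names(df)) "pop_label" else NULL
  }

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]],
                                        y = .data[[axes[2]]]))
  if (!is.null(color_by)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[color_by]]),
                                 size = 0.7, alpha = 0.7)
    if (identical(color_by, "pop_label")) {
      pal <- stats::setNames(unname(POP_PALETTE), c(POP_LABELS, "Unassigned"))
      p <- p + ggplot2::scale_colour_manual(values = pal, drop = TRUE)
    }
  } else {
    p <- p + ggplot2::geom_point(size = 0.7, alpha = 0.7)
  }

  if (!is.null(frame0) && identical(as.character(axes), c("GD1", "GD2"))) {
    tri <- as.data.frame(frame0$vertices2d[c("E", "F", "A", "E"), ])
    names(tri) <- c("x", "y")
    p <- p + ggplot2::geom_path(data = tri,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                inherit.aes = FALSE, colour = "black")
  }
  if (!is.null(cutoffs)) {
    gd1r <- range(df$GD1, na.rm = TRUE)
    gd4r <- range(df$GD4, na.rm = TRUE)
    x <- seq(gd1r[1], gd1r[2], length.out = 200)
    sas <- data.frame(x = x,
                      y = cutoffs$sas_a * (x - cutoffs$sas_x0)^2 + cutoffs$sas_c)
    y <- seq(gd4r[1], gd4r[2], length.out = 200)
    api <- data.frame(x = cutoffs$api_a * y^2 + cutoffs$api_c, y = y)
    p <- p +
      ggplot2::geom_line(data = sas, ggplot2::aes(x = .data$x, y = .data$y),
                         inherit.aes = FALSE, colour = "cyan3") +
      ggplot2::geom_line(data = api, ggplot2::aes(x = .data$x, y = .data$y),
                         inherit.aes = FALSE, colour = "cyan4")
  }
  p + ggplot2::theme_bw() +
    ggplot2::labs(x = axes[1], y = axes[2])
}

#' Render a score plot to an image file
#'
#' @param scores,axes,frame0,cutoffs,color_by,max_points,seed passed to
#'   [plot_scores()].
#' @param file output path; format from extension (png, svg, pdf).
#' @param width,height,dpi device settings.
#' @return `file`, invisibly.
#' @export
save_score_plot <- function(scores, file, axes = c("GD1", "GD2"),
                            frame0 = NULL, cutoffs = NULL, color_by = NULL,
                            max_points = NULL, seed = 1L,
                            width = 6, height = 5, dpi = 150) {
  p <- plot_scores(scores, axes = axes, frame0 = frame0, cutoffs = cutoffs,
                   color_by = color_by, max_points = max_points, seed = seed)
  ggplot2::ggsave(file, p, width = width, height = height, dpi = dpi)
  invisible(file)
}
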