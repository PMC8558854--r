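## broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a barrier estimate
#'
#' @param x a [barrier_estimate()].
#' @param ... unused.
#' @return one row per residue: `residue`, `dtss` (and `dtss_crystal`
#'   when present).
#' @export
tidy.barrier_estimate <- function(x, ...) x$contributions

#' @rdname tidy.barrier_estimate
#' @return for `glance()`: a one-row tibble with `b0`, `sum_dtss`,
#'   `total` (kcal/mol) and `n_residues`.
#' @export
glance.barrier_estimate <- function(x, ...) {
  tibble(b0 = x$b0, sum_dtss = x$sum_dtss, total = x$total,
         n_residues = nrow(x$contributions))
}

#' Tidy a MULTISCAN result
#'
#' @param x a [multiscan()] result.
#' @param ... unused.
#' @return per-site tibble with the chosen rotamer and its DTSS.
#' @export
tidy.multiscan_result <- function(x, ...) {
  as_tibble(x)[, c("site_id", "type", "rotamer_id", "dtss")]
}

#' @rdname tidy.multiscan_result
#' @return for `glance()`: one row with `objective`, `dtss_total`,
#'   `pair_total` (kcal/mol), `mode`, `n_sites` and `n_moves` (iterative
#'   mode only, else `NA`).
#' @export
glance.multiscan_result <- function(x, ...) {
  tr <- attr(x, "trace")
  tibble(objective = attr(x, "objective"),
         dtss_total = attr(x, "dtss_total"),
         pair_total = attr(x, "pair_total"),
         mode = attr(x, "mode"), n_sites = nrow(x),
         n_moves = if (is.null(tr)) NA_integer_ else nrow(tr))
}

#' Plot a slice of a catalytic-field grid
#'
#' Raster of `Delta_S` in the grid plane nearest `z`: blue regions reward
#' a positive charge (positive `Delta_S`), red a negative one. Masked
#' nodes are blank.
#'
#' @param object a [static_field()] grid.
#' @param z slice height (angstrom); default the mid-plane.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.field_grid <- function(object, z = NULL, ...) {
  zs <- sort(unique(object$z))
  if (is.null(z)) z <- zs[ceiling(length(zs) / 2)]
  zsel <- zs[which.min(abs(zs - z))]
  df <- object[object$z == zsel, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$delta_s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac",
                                  name = expression(Delta[S])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = sprintf("Catalytic field, z = %.2f Å", zsel),
                  subtitle = "kcal/(mol e); blue favours +1 e, red favours -1 e") +
    ggplot2::theme_minimal()
}

#' Plot per-residue DTSS contributions
#'
#' @param object a [barrier_estimate()] or [multiscan()] result.
#' @param ... unused.
#' @return a ggplot bar chart; bars below zero lower the barrier.
#' @export
autoplot.barrier_estimate <- function(object, ...) {
  df <- object$contributions
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$residue, .data$dtss),
                                   y = .data$dtss, fill = .data$dtss < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "DTSS (kcal/mol)",
                  title = sprintf("B0 = %.2f, B0 + ΣDTSS = %.2f kcal/mol",
                                  object$b0, object$total)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.barrier_estimate
#' @export
autoplot.multiscan_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$site_id, .data$dtss),
                                   y = .data$dtss, fill = .data$dtss < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "DTSS (kcal/mol)",
                  title = sprintf("MULTISCAN objective %.2f kcal/mol (%s)",
                                  attr(object, "objective"), attr(object, "mode"))) +
    ggplot2::theme_minimal()
}
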