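#' Tidy a binned trend
#'
#' @param x a [binned_trend] object.
#' @param ... unused.
#' @return the bins as a tibble (k, center, mean_y, count).
#' @export
tidy.binned_trend <- function(x, ...) x$bins

#' @rdname tidy.binned_trend
#' @return `glance()` returns a one-row tibble with the OLS fit through
#'   the bin means (slope, intercept, r_squared; NA without a fit),
#'   the number of occupied bins, residues and the bin width.
#' @export
glance.binned_trend <- function(x, ...) {
  tibble(slope = x$fit$slope %||% NA_real_,
         intercept = x$fit$intercept %||% NA_real_,
         r_squared = x$fit$r_squared %||% NA_real_,
         n_bins = nrow(x$bins), n = x$n, bin_width = x$bin_width)
}

#' Tidy a capsid comparison
#'
#' @param x a [compare_capsid()] result.
#' @param ... unused.
#' @return `tidy()` returns the paired per-residue z-scores; `glance()`
#'   a one-row summary (model, subunit, r, n).
#' @export
tidy.capsid_comparison <- function(x, ...) as_tibble(x$pair)

#' @rdname tidy.capsid_comparison
#' @export
glance.capsid_comparison <- function(x, ...) {
  tibble(model = x$model, subunit = x$subunit, r = x$r, n = x$n)
}

#' Tidy a batch summary
#'
#' @param x a [batch_compare()] result.
#' @param ... unused.
#' @return `tidy()` returns the per-structure correlation rows; `glance()`
#'   one row with per-model mean correlations and the failure count.
#' @export
tidy.batch_summary <- function(x, ...) x$per_structure

#' @rdname tidy.batch_summary
#' @export
glance.batch_summary <- function(x, ...) {
  wide <- stats::setNames(as.list(x$averages$mean_r),
                          paste0("mean_r_", x$averages$model))
  as_tibble(c(wide, list(n_structures = nrow(x$per_structure),
                         n_failures = nrow(x$failures))))
}

#' Plot a binned conservation trend
#'
#' Bin means of the structural z-score against conservation-bin centers,
#' point size showing occupancy, with the OLS line when available.
#'
#' @param object a [binned_trend] object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.binned_trend <- function(object, ...) {
  p <- ggplot2::ggplot(object$bins,
                       ggplot2::aes(x = .data$center, y = .data$mean_y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$count), alpha = 0.8) +
    ggplot2::labs(x = "conservation z (bin center)",
                  y = "mean structural z",
                  size = "residues",
                  subtitle = if (!is.null(object$fit))
                    sprintf("slope %.3f, r^2 = %.4f",
                            object$fit$slope, object$fit$r_squared)
                  else "no fit (< 2 usable bins)") +
    ggplot2::theme_minimal()
  if (!is.null(object$fit)) {
    p <- p + ggplot2::geom_abline(slope = object$fit$slope,
                                  intercept = object$fit$intercept,
                                  linetype = 2)
  }
  p
}

#' Plot a profile comparison
#'
#' The classic side-by-side profile view: structural z-scores (solid)
#' and conservation z-scores (dotted) along the chain, with the Pearson
#' correlation in the subtitle.
#'
#' @param object a [compare_capsid()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.capsid_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object$pair), c("x", "y"),
                              names_to = "series", values_to = "z")
  long$series <- ifelse(long$series == "x", "conservation",
                        paste0("structure (", object$model, ")"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$seq_num, y = .data$z,
                                     linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = stats::setNames(c(3, 1), c("conservation",
                                          paste0("structure (", object$model, ")")))) +
    ggplot2::labs(x = "residue number", y = "z-score", linetype = NULL,
                  subtitle = sprintf("Pearson r = %.3f over %d residues",
                                     object$r, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a structural profile along the chain
#'
#' @param profile a structural profile tibble.
#' @return a ggplot of value against residue number, one facet per
#'   subunit when several are present.
#' @export
plot_profile <- function(profile) {
  p <- ggplot2::ggplot(as_tibble(profile),
                       ggplot2::aes(x = .data$seq_num, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue number",
                  y = attr(profile, "kind") %||% "value") +
    ggplot2::theme_minimal()
  if (length(unique(profile$subunit)) > 1) {
    p <- p + ggplot2::facet_wrap(~subunit)
  }
  p
}
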