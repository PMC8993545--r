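#' Plot ROC or precision-recall curves of a cross-validation run
#'
#' Curves come from the pooled out-of-fold scores, the same pooling used for
#' [glance.sidefx_cv()].
#'
#' @param object A `sidefx_cv` object from [run_cross_validation()].
#' @param type `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sidefx_cv <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    rc <- roc_curve(object$score, object$label)
    ggplot2::ggplot(rc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::coord_equal() +
      ggplot2::labs(
        x = "1 - specificity", y = "sensitivity",
        title = sprintf("ROC (AUROC = %.3f)",
                        auroc(object$score, object$label))
      ) +
      ggplot2::theme_minimal()
  } else {
    pc <- pr_curve(object$score, object$label)
    ggplot2::ggplot(pc, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(
        x = "recall", y = "precision",
        title = sprintf("PR (AUPR = %.3f)", aupr(object$score, object$label))
      ) +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.sidefx_cv
#' @export
plot_roc <- function(object, ...) autoplot(object, type = "roc", ...)

#' @rdname autoplot.sidefx_cv
#' @export
plot_pr <- function(object, ...) autoplot(object, type = "pr", ...)

#' Plot a sweep report
#'
#' One point per dataset and a crossbar at the cross-dataset mean, by sampling
#' scheme, facetted by classifier when several were swept.
#'
#' @param object A `sidefx_sweep` tibble from [run_sweep()].
#' @param metric Metric column to plot (default `"mcc"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sidefx_sweep <- function(object, metric = "mcc", ...) {
  stopifnot(metric %in% names(object))
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$scheme, y = .data[[metric]])
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick", linewidth = 0.3) +
    ggplot2::labs(x = "sampling scheme", y = metric) +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(object$classifier) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$classifier))
  }
  p
}
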