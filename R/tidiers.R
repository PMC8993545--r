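#' Tidy and glance methods for cross-validation results
#'
#' `tidy()` reports the six scalar metrics per fold; `glance()` pools the
#' out-of-fold scores into one report row (metrics plus AUROC/AUPR) together
#' with the run configuration.
#'
#' @param x A `sidefx_cv` object from [run_cross_validation()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sidefx_cv <- function(x, ...) {
  x |>
    as_tibble() |>
    dplyr::group_by(.data$fold) |>
    dplyr::reframe(metrics_report(.data$score, .data$label)) |>
    dplyr::arrange(.data$fold)
}

#' @rdname tidy.sidefx_cv
#' @export
glance.sidefx_cv <- function(x, ...) {
  cfg <- attr(x, "config")
  spec <- attr(x, "spec")
  dplyr::bind_cols(
    tibble(scheme = cfg$scheme, classifier = spec$name,
           k = attr(x, "k"), seed = attr(x, "seed")),
    metrics_report(x$score, x$label)
  )
}

#' Tidy and glance methods for fitted classifiers
#'
#' `tidy()` lists the hyperparameters recorded on the spec (one row each);
#' `glance()` gives a one-row summary of the model.
#'
#' @param x A `sidefx_model` from [fit_classifier()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sidefx_model <- function(x, ...) {
  p <- x$spec$params
  tibble(
    parameter = c("seed", names(p)),
    value = as.character(c(x$spec$seed, unlist(p)))
  )
}

#' @rdname tidy.sidefx_model
#' @export
glance.sidefx_model <- function(x, ...) {
  tibble(
    classifier = x$spec$name,
    n_features = length(x$feature_names),
    approximate = x$spec$approximate,
    seed = x$spec$seed
  )
}
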