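#' Assign stratified cross-validation folds
#'
#' Samples are partitioned into `k` folds separately within each class, so
#' fold sizes differ by at most one per class and every sample is tested
#' exactly once.
#'
#' @param pairs Pair tibble with a `label` column.
#' @param k Number of folds (default 10).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return `pairs` with an integer `fold` column in `1..k`.
#' @export
make_folds <- function(pairs, k = 10, seed = 1L) {
  counts <- table(pairs$label)
  if (any(counts[counts > 0] < k)) {
    abort(sprintf("every class needs at least k = %d samples for %d folds",
                  k, k))
  }
  fold <- integer(nrow(pairs))
  withr::with_seed(seed, {
    for (lv in unique(pairs$label)) {
      idx <- which(pairs$label == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  dplyr::mutate(pairs, fold = fold)
}

#' Leakage-aware k-fold cross-validation of the full pipeline
#'
#' For each fold, the training annotation table is rebuilt from the
#' training-fold positive pairs only; candidate lists and features are then
#' recomputed for both partitions, the classifier is fitted on the training
#' fold and the held-out fold is scored. A test-fold positive pair therefore
#' never contributes to any candidate list used to score it (asserted inside
#' the loop), and each sample is scored exactly once.
#'
#' @param pairs One benchmark dataset: tibble `drug`, `side_effect`, `label`.
#' @param matrices Named list of [assoc_matrix()] objects keyed by type.
#' @param config A [sampling_config()].
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @return A `sidefx_cv` tibble: the pairs plus `fold`, `score`, `pred`
#'   columns, with the run configuration attached as attributes. [tidy()]
#'   gives per-fold metrics, [glance()] the pooled report, [autoplot()] the
#'   ROC/PR curves.
#' @export
run_cross_validation <- function(pairs, matrices, config, spec, k = 10,
                                 seed = 1L) {
  folded <- make_folds(pairs, k = k, seed = seed)
  se_universe <- unique(pairs$side_effect)
  out <- vector("list", k)
  for (f in seq_len(k)) {
    train <- folded[folded$fold != f, , drop = FALSE]
    test <- folded[folded$fold == f, , drop = FALSE]
    train_ann <- train |>
      dplyr::filter(.data$label == "positive") |>
      dplyr::select("drug", "side_effect")
    # leakage contract: no held-out positive may sit in the training table
    leaked <- dplyr::semi_join(
      dplyr::filter(test, .data$label == "positive"), train_ann,
      by = c("drug", "side_effect")
    )
    if (nrow(leaked) > 0) {
      abort("leakage: a test-fold positive pair is in the training annotations")
    }
    train_x <- build_features(train, train_ann, matrices, config,
                              side_effect_universe = se_universe)
    test_x <- build_features(test, train_ann, matrices, config,
                             side_effect_universe = se_universe)
    model <- fit_classifier(train_x, spec)
    out[[f]] <- dplyr::mutate(test, score = predict_scores(model, test_x))
  }
  res <- dplyr::bind_rows(out) |>
    dplyr::mutate(pred = factor(
      ifelse(.data$score >= 0.5, "positive", "negative"), levels = PAIR_LEVELS
    ))
  structure(res, class = c("sidefx_cv", class(res)),
            config = config, spec = spec, k = k, seed = seed)
}

#' Confusion-matrix counts at a score threshold
#'
#' Scores at or above the threshold predict positive (the boundary is
#' inclusive).
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels True labels (factor or character, `positive`/`negative`).
#' @param threshold Decision threshold, default 0.5.
#' @return One-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) abort("cannot count an empty prediction set")
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length")
  }
  pos <- as.character(labels) == "positive"
  pred <- scores >= threshold
  tibble(
    tp = sum(pred & pos), fp = sum(pred & !pos),
    tn = sum(!pred & !pos), fn = sum(!pred & pos)
  )
}

#' The six scalar classification metrics
#'
#' Sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TN+FN)(TN+FP)(TP+FN)(TP+FP))`, precision
#' `TP/(TP+FP)`, and F1 `2*precision*recall/(precision+recall)`. Any 0/0
#' (including a zero MCC denominator) returns 0 so sweeps stay total.
#'
#' @param counts Confusion counts from [confusion_counts()] (or any list with
#'   `tp`, `fp`, `tn`, `fn`).
#' @return One-row tibble with columns `sn`, `sp`, `acc`, `mcc`, `precision`,
#'   `f1`.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  total <- tp + fp + tn + fn
  if (total <= 0) abort("confusion counts sum to zero")
  div <- function(num, den) ifelse(den == 0, 0, num / den)
  sn <- div(tp, tp + fn)
  sp <- div(tn, tn + fp)
  acc <- (tp + tn) / total
  mcc <- div(tp * tn - fp * fn,
             sqrt((tn + fn) * (tn + fp) * (tp + fn) * (tp + fp)))
  prec <- div(tp, tp + fp)
  f1 <- div(2 * prec * sn, prec + sn)
  tibble(sn = sn, sp = sp, acc = acc, mcc = mcc, precision = prec, f1 = f1)
}

# distinct-threshold sweep shared by the ROC and PR curves: one point per
# unique score, cumulative counts taken at the last index of each tie group
threshold_sweep <- function(scores, labels) {
  pos <- as.character(labels) == "positive"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to sweep thresholds")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- pos[ord]
  last <- !duplicated(s, fromLast = TRUE)
  tibble(
    threshold = s[last],
    tp = cumsum(y)[last],
    fp = cumsum(!y)[last],
    n_pos = n_pos,
    n_neg = n_neg
  )
}

#' ROC and precision-recall curves with their areas
#'
#' `roc_curve()` sweeps all distinct score thresholds and reports
#' (1-specificity, sensitivity) points; `auroc()` is the trapezoidal area,
#' which (with tied scores grouped) equals the Mann-Whitney pairwise-win
#' fraction with ties counting one half. `pr_curve()` reports
#' (recall, precision) points and `aupr()` the step-wise interpolated area
#' (average precision); linear interpolation in PR space would overestimate
#' the area.
#'
#' @param scores Numeric scores.
#' @param labels True labels (`positive`/`negative`); both classes required.
#' @return Curve functions: a tibble of curve points. Area functions: a single
#'   number in `[0, 1]`.
#' @export
roc_curve <- function(scores, labels) {
  sw <- threshold_sweep(scores, labels)
  tibble(threshold = c(Inf, sw$threshold),
         fpr = c(0, sw$fp / sw$n_neg),
         tpr = c(0, sw$tp / sw$n_pos))
}

#' @rdname roc_curve
#' @export
auroc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2)
}

#' @rdname roc_curve
#' @export
pr_curve <- function(scores, labels) {
  sw <- threshold_sweep(scores, labels)
  tibble(threshold = sw$threshold,
         recall = sw$tp / sw$n_pos,
         precision = sw$tp / (sw$tp + sw$fp))
}

#' @rdname roc_curve
#' @export
aupr <- function(scores, labels) {
  pc <- pr_curve(scores, labels)
  sum(diff(c(0, pc$recall)) * pc$precision)
}

#' Full metrics report for one set of scored pairs
#'
#' @param scores,labels Out-of-fold scores and true labels.
#' @param threshold Decision threshold for the scalar metrics.
#' @return One-row tibble: `n`, the six scalar metrics, `auroc`, `aupr`.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5) {
  dplyr::bind_cols(
    tibble(n = length(scores)),
    compute_metrics(confusion_counts(scores, labels, threshold)),
    tibble(auroc = auroc(scores, labels), aupr = aupr(scores, labels))
  )
}

#' Average metric reports across benchmark datasets
#'
#' Arithmetic mean of every numeric metric column, grouped by any non-metric
#' identifier columns (e.g. scheme and classifier).
#'
#' @param reports Tibble of per-dataset report rows (as from [run_sweep()]).
#' @param by Character vector of grouping columns; defaults to the identifier
#'   columns present among `scheme`, `classifier`.
#' @return Tibble with one row per group: mean metrics plus `n_datasets`.
#' @export
aggregate_metrics <- function(reports, by = NULL) {
  if (is.null(by)) by <- intersect(c("scheme", "classifier"), names(reports))
  metric_cols <- intersect(
    c("sn", "sp", "acc", "mcc", "precision", "f1", "auroc", "aupr"),
    names(reports)
  )
  reports |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      dplyr::across(dplyr::all_of(metric_cols), mean),
      .groups = "drop"
    )
}
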