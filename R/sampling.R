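#' Configure the feature-sampling scheme
#'
#' Controls how each pair's candidate feature list (one per association type)
#' is turned into a fixed-width feature vector.
#'
#' * `single`: the classical baseline; only the top (largest) value of each
#'   list is taken — one feature per association type.
#' * `discrete`: values at fixed rank positions of the sorted list — the top
#'   value plus the values at the top p% places for each percentage in
#'   `positions`. The rank for percentage p on a list of length L is
#'   `max(1, ceiling(p/100 * L))`.
#' * `continuous`: for each q in `q_values`, the top `max(1, ceiling(q/100*L))`
#'   values are selected and aggregated to one feature (arithmetic mean by
#'   default), or zero-padded to `pad_width` values when
#'   `aggregation = "padded"`.
#'
#' @param scheme One of `"single"`, `"discrete"`, `"continuous"`.
#' @param positions For the discrete scheme: a vector containing `"top"` plus
#'   percentages in `(0, 100]`; default `c("top", 5, 10, 15, 20)`.
#' @param q_values For the continuous scheme: percentages in `(0, 100]`;
#'   default 20.
#' @param types Active association types, a subset of
#'   `c("f", "s", "a", "tm", "t")` kept in that fixed order.
#' @param aggregation Continuous-scheme width rule: `"mean"` (default) or
#'   `"padded"`.
#' @param pad_width Number of values kept per (type, q) under
#'   `aggregation = "padded"`.
#' @return A `sampling_config` object.
#' @export
sampling_config <- function(scheme = c("single", "discrete", "continuous"),
                            positions = c("top", 5, 10, 15, 20),
                            q_values = 20,
                            types = ASSOC_TYPES,
                            aggregation = c("mean", "padded"),
                            pad_width = 5) {
  scheme <- match.arg(scheme)
  aggregation <- match.arg(aggregation)
  types <- ASSOC_TYPES[ASSOC_TYPES %in% types]
  if (length(types) == 0) abort("at least one association type must be active")
  positions <- as.character(positions)
  if (scheme == "discrete") {
    if (!"top" %in% positions) abort("discrete positions must include 'top'")
    pct <- suppressWarnings(as.numeric(setdiff(positions, "top")))
    if (anyNA(pct) || any(pct <= 0) || any(pct > 100)) {
      abort("discrete percentage positions must lie in (0, 100]")
    }
  }
  q_values <- as.numeric(q_values)
  if (scheme == "continuous" &&
      (length(q_values) == 0 || any(q_values <= 0) || any(q_values > 100))) {
    abort("q values must lie in (0, 100]")
  }
  structure(
    list(scheme = scheme, positions = positions, q_values = q_values,
         types = types, aggregation = aggregation, pad_width = pad_width),
    class = "sampling_config"
  )
}

#' @export
print.sampling_config <- function(x, ...) {
  detail <- switch(x$scheme,
    single = "top value only",
    discrete = paste0("positions ", paste(x$positions, collapse = ", ")),
    continuous = paste0("q = ", paste(x$q_values, collapse = ", "),
                        " (", x$aggregation, ")")
  )
  cat(sprintf("<sampling_config> %s scheme, %s; types %s\n",
              x$scheme, detail, paste(x$types, collapse = ",")))
  invisible(x)
}

# per-type feature labels for a config, e.g. f_top, f_p5, f_q20
feature_labels <- function(config) {
  per_type <- switch(config$scheme,
    single = "top",
    discrete = ifelse(config$positions == "top", "top",
                      paste0("p", config$positions)),
    continuous = if (config$aggregation == "mean") {
      paste0("q", config$q_values)
    } else {
      as.vector(t(outer(paste0("q", config$q_values),
                        seq_len(config$pad_width), paste, sep = "_")))
    }
  )
  as.vector(t(outer(config$types, per_type, paste, sep = "_")))
}

#' Build the candidate feature list for one pair
#'
#' For the pair `<d, s>` and one association type, let S be the set of
#' training drugs annotated with side effect s, excluding d itself. The
#' candidate list holds the association scores between d and every drug in S,
#' sorted in decreasing order. It is empty when no other training drug has the
#' side effect.
#'
#' @param drug,side_effect The pair's drug and side effect identifiers.
#' @param annotations Training annotation tibble (`drug`, `side_effect`);
#'   must already exclude any test-fold positives (the caller's contract).
#' @param matrix An [assoc_matrix()] covering the pair's drug and the drugs
#'   annotated with the side effect.
#' @return Numeric vector sorted non-increasing (possibly empty).
#' @export
build_candidate_list <- function(drug, side_effect, annotations, matrix) {
  s_drugs <- annotations$drug[annotations$side_effect == side_effect]
  s_drugs <- setdiff(unique(s_drugs), drug)
  if (length(s_drugs) == 0) return(numeric(0))
  missing <- setdiff(c(drug, s_drugs), rownames(matrix))
  if (length(missing) > 0) {
    abort(paste0("drug absent from association matrix: ", missing[1]))
  }
  sort(unname(matrix[drug, s_drugs]), decreasing = TRUE)
}

#' Feature selectors over a sorted candidate list
#'
#' `select_single()` returns the top value (0 for an empty list).
#' `select_discrete()` returns the values at the requested rank positions,
#' where percentage p maps to rank `max(1, ceiling(p/100 * L))` on a list of
#' length L (all zeros for an empty list). `select_continuous()` selects the
#' top `max(1, ceiling(q/100 * L))` values per q and aggregates them to the
#' arithmetic mean (or zero-pads them to `pad_width` values).
#'
#' @param values Numeric vector sorted non-increasing (a candidate list).
#' @return `select_single()`: one value; `select_discrete()`: one value per
#'   position; `select_continuous()`: one value per q (`"mean"`), or
#'   `pad_width` values per q (`"padded"`).
#' @examples
#' select_single(c(0.9, 0.7, 0.2)) # 0.9
#' select_discrete(c(0.9, 0.7, 0.2), c("top", 5, 10, 15, 20)) # all 0.9
#' select_continuous(c(0.9, 0.7, 0.2), 100) # 0.6
#' @export
select_single <- function(values) {
  if (length(values) == 0) 0 else values[1]
}

#' @rdname select_single
#' @param positions Vector of `"top"` and/or percentages in `(0, 100]`.
#' @export
select_discrete <- function(values, positions = c("top", 5, 10, 15, 20)) {
  positions <- as.character(positions)
  if (length(values) == 0) return(rep(0, length(positions)))
  ranks <- vapply(positions, function(p) {
    if (p == "top") 1L
    else min(length(values),
             max(1L, rank_at_percent(as.numeric(p), length(values))))
  }, integer(1))
  unname(values[ranks])
}

#' @rdname select_single
#' @param q Percentages in `(0, 100]`, one selection per q.
#' @param aggregation `"mean"` or `"padded"` (see [sampling_config()]).
#' @param pad_width Values kept per q under `"padded"`.
#' @export
select_continuous <- function(values, q = 20, aggregation = "mean",
                              pad_width = 5) {
  out <- lapply(q, function(qi) {
    if (length(values) == 0) {
      top <- numeric(0)
    } else {
      m <- min(length(values), max(1L, rank_at_percent(qi, length(values))))
      top <- values[seq_len(m)]
    }
    if (aggregation == "mean") {
      if (length(top) == 0) 0 else mean(top)
    } else {
      c(top, rep(0, pad_width))[seq_len(pad_width)]
    }
  })
  unname(unlist(out))
}

# rank of the "top p%" place on a list of length L: ceiling(p/100 * L),
# with an epsilon so that exact multiples are not pushed up by one ulp
rank_at_percent <- function(p, L) {
  as.integer(ceiling(p / 100 * L - 1e-9))
}

# apply the config's selector to one candidate list
apply_selector <- function(values, config) {
  switch(config$scheme,
    single = select_single(values),
    discrete = select_discrete(values, config$positions),
    continuous = select_continuous(values, config$q_values,
                                   config$aggregation, config$pad_width)
  )
}

#' Build the feature matrix for a set of pairs
#'
#' For every pair and every active association type, the candidate feature
#' list is built from the training annotations ([build_candidate_list()]) and
#' reduced to features under the configured sampling scheme. Columns are
#' grouped by association type in the fixed order f, s, a, tm, t, then by
#' position/q; row order matches the input pair order.
#'
#' @param pairs Tibble with columns `drug`, `side_effect` and optionally
#'   `label` (carried through).
#' @param annotations Training annotation tibble; must exclude all test-fold
#'   positive pairs when used inside cross-validation.
#' @param matrices Named list of [assoc_matrix()] objects keyed by type tag;
#'   must cover every active type and every drug appearing in `pairs` or
#'   `annotations`.
#' @param config A [sampling_config()].
#' @param side_effect_universe Optional character vector of admissible side
#'   effects; a pair naming one outside it is an error.
#' @return A tibble: `drug`, `side_effect`, `label` (if present), then one
#'   numeric column per feature.
#' @export
build_features <- function(pairs, annotations, matrices, config,
                           side_effect_universe = NULL) {
  stopifnot(inherits(config, "sampling_config"))
  missing_types <- setdiff(config$types, names(matrices))
  if (length(missing_types) > 0) {
    abort(paste0("no association matrix supplied for type: ",
                 paste(missing_types, collapse = ", ")))
  }
  if (!is.null(side_effect_universe)) {
    unknown <- setdiff(unique(pairs$side_effect), side_effect_universe)
    if (length(unknown) > 0) {
      abort(paste0("side effect outside the annotation universe: ",
                   unknown[1]))
    }
  }
  for (k in config$types) {
    miss <- setdiff(unique(pairs$drug), rownames(matrices[[k]]))
    if (length(miss) > 0) {
      abort(paste0("drug absent from '", k, "' association matrix: ", miss[1]))
    }
  }

  ann_by_se <- split(annotations$drug, annotations$side_effect)
  labels <- feature_labels(config)
  width <- length(labels)
  feats <- matrix(0, nrow(pairs), width)

  # group pairs by side effect: S is shared within a group, so one submatrix
  # lookup per (side effect, type) serves all its pairs
  groups <- split(seq_len(nrow(pairs)), pairs$side_effect)
  per_type <- width %/% length(config$types)
  for (se in names(groups)) {
    idx <- groups[[se]]
    s_all <- unique(ann_by_se[[se]])
    for (ti in seq_along(config$types)) {
      m <- matrices[[config$types[ti]]]
      cols <- (ti - 1L) * per_type + seq_len(per_type)
      for (i in idx) {
        d <- pairs$drug[i]
        s_drugs <- setdiff(s_all, d)
        v <- if (length(s_drugs) == 0) numeric(0) else
          sort(unname(m[d, s_drugs]), decreasing = TRUE)
        feats[i, cols] <- apply_selector(v, config)
      }
    }
  }
  colnames(feats) <- labels
  keep <- intersect(c("drug", "side_effect", "label"), names(pairs))
  dplyr::bind_cols(pairs[, keep], as_tibble(feats))
}

#' Write or read a feature matrix as TSV
#'
#' Header columns are `drug`, `side_effect`, `label`, then the feature labels
#' (`<type>_<position-or-q>`); feature values round-trip at full double
#' precision.
#'
#' @param features Feature tibble from [build_features()].
#' @param path TSV file path.
#' @export
write_features <- function(features, path) {
  out <- features
  if ("label" %in% names(out)) out$label <- as.character(out$label)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if ("label" %in% names(tab)) {
    tab$label <- factor(tab$label, levels = PAIR_LEVELS)
  }
  tab
}
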