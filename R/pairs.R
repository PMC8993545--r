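#' Read a drug to side-effect annotation table
#'
#' Flat SIDER-like export: one `drug_id<TAB>side_effect_id` line per known
#' drug/side-effect annotation. Duplicated lines collapse to one annotation.
#'
#' @param path TSV file path (no header).
#' @return A tibble with columns `drug` and `side_effect`, one row per
#'   annotation.
#' @export
read_annotations <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_names = c("drug", "side_effect"),
    col_types = readr::cols(.default = readr::col_character())
  )
  dplyr::distinct(tab)
}

#' Drop side effects annotated to too few drugs
#'
#' Rarely observed side effects carry too little training signal: any side
#' effect annotated to fewer than `min_drugs` drugs is removed from every
#' drug's annotation set (the default keeps side effects seen on at least six
#' drugs, i.e. those annotated to no more than five drugs are excluded).
#' Drugs left without any side effect are dropped from the table.
#'
#' @param annotations Annotation tibble (`drug`, `side_effect`).
#' @param min_drugs Minimum number of annotated drugs a side effect needs to
#'   be retained (default 6).
#' @return The filtered annotation tibble.
#' @export
filter_rare_side_effects <- function(annotations, min_drugs = 6) {
  stopifnot(min_drugs >= 1)
  annotations |>
    dplyr::add_count(.data$side_effect, name = ".n_drugs") |>
    dplyr::filter(.data$.n_drugs >= min_drugs) |>
    dplyr::select(-".n_drugs")
}

#' Drop drugs not covered by enough association sources
#'
#' Real association sources rarely cover every drug. A drug is kept when it
#' appears in at least `min_sources` of the supplied association matrices
#' (by default all of them, mirroring a benchmark built only on fully
#' characterised drugs).
#'
#' @param annotations Annotation tibble (`drug`, `side_effect`).
#' @param matrices Named list of [assoc_matrix()] objects.
#' @param min_sources Minimum number of matrices a drug must appear in
#'   (default: all supplied).
#' @return The filtered annotation tibble.
#' @export
filter_drugs_by_coverage <- function(annotations, matrices,
                                     min_sources = length(matrices)) {
  stopifnot(length(matrices) >= 1, min_sources >= 1,
            min_sources <= length(matrices))
  coverage <- vapply(unique(annotations$drug), function(d) {
    sum(vapply(matrices, function(m) d %in% rownames(m), logical(1)))
  }, integer(1))
  keep <- names(coverage)[coverage >= min_sources]
  dplyr::filter(annotations, .data$drug %in% keep)
}

#' Enumerate the positive drug/side-effect pairs
#'
#' Every annotation becomes one positive classification sample: the pair
#' `<drug, side effect>` labelled positive.
#'
#' @param annotations Annotation tibble (`drug`, `side_effect`).
#' @return Tibble with columns `drug`, `side_effect`, `label` where `label` is
#'   a factor with levels `negative`, `positive`.
#' @export
build_positive_pairs <- function(annotations) {
  annotations |>
    dplyr::distinct(.data$drug, .data$side_effect) |>
    dplyr::mutate(label = factor("positive", levels = PAIR_LEVELS))
}

#' Sample random negative drug/side-effect pairs
#'
#' Draws `n` distinct pairs uniformly at random (without replacement) from the
#' cells of the drug-by-side-effect grid that are not annotated, and labels
#' them negative. The drug and side-effect universes are those present in
#' `annotations` (i.e. the entities surviving upstream filters).
#'
#' @param annotations Annotation tibble defining positives and the universe.
#' @param n Number of negative pairs to draw.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Tibble with columns `drug`, `side_effect`, `label`.
#' @export
sample_negative_pairs <- function(annotations, n, seed) {
  drugs <- sort(unique(annotations$drug))
  ses <- sort(unique(annotations$side_effect))
  pos <- dplyr::distinct(annotations, .data$drug, .data$side_effect)
  capacity <- length(drugs) * length(ses) - nrow(pos)
  if (n > capacity) {
    abort(sprintf(
      "cannot draw %d negatives: only %d non-positive cells exist", n, capacity
    ))
  }
  # index the full grid column-major and sample from the non-positive cells
  pos_idx <- match(pos$drug, drugs) +
    (match(pos$side_effect, ses) - 1L) * length(drugs)
  free <- setdiff(seq_len(length(drugs) * length(ses)), pos_idx)
  picked <- withr::with_seed(seed, sample(free, n))
  tibble(
    drug = drugs[(picked - 1L) %% length(drugs) + 1L],
    side_effect = ses[(picked - 1L) %/% length(drugs) + 1L],
    label = factor("negative", levels = PAIR_LEVELS)
  )
}

#' Assemble benchmark datasets (one positive set, several negative sets)
#'
#' Each dataset pairs the full positive set with its own random negative set
#' of equal size, mirroring the usual protocol of evaluating over several
#' negative draws (datasets DS_1..DS_n) and averaging.
#'
#' @param annotations Annotation tibble (already filtered).
#' @param n_datasets Number of datasets to build (default 5).
#' @param seeds Integer vector of length `n_datasets`, one seed per negative
#'   set.
#' @return Tibble with columns `drug`, `side_effect`, `label`, `dataset`
#'   (integer index starting at 1).
#' @export
assemble_datasets <- function(annotations, n_datasets = 5,
                              seeds = seq_len(n_datasets)) {
  if (length(seeds) != n_datasets) {
    abort("`seeds` must supply exactly one seed per dataset")
  }
  if (anyDuplicated(seeds)) {
    warn("duplicate seeds: some datasets will share identical negative sets")
  }
  positives <- build_positive_pairs(annotations)
  purrr::map_dfr(seq_len(n_datasets), function(i) {
    negatives <- sample_negative_pairs(annotations, nrow(positives), seeds[i])
    dplyr::bind_rows(positives, negatives) |>
      dplyr::mutate(dataset = i)
  })
}

#' @rdname assemble_datasets
#' @param datasets A dataset tibble from `assemble_datasets()`.
#' @param path Output TSV path (columns drug, side_effect, label, dataset).
#' @export
write_dataset_manifest <- function(datasets, path) {
  readr::write_tsv(
    dplyr::mutate(datasets, label = as.character(.data$label)), path
  )
  invisible(path)
}
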