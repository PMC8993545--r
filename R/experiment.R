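#' Run a sweep of sampling schemes and classifiers over benchmark datasets
#'
#' Every combination of sampling variant, classifier, and benchmark dataset is
#' evaluated by k-fold cross-validation ([run_cross_validation()]). All
#' variants share one fold-seed series per dataset, so scheme comparisons
#' differ only in the features.
#'
#' @param datasets Dataset tibble from [assemble_datasets()] (columns `drug`,
#'   `side_effect`, `label`, `dataset`).
#' @param matrices Named list of [assoc_matrix()] objects keyed by type.
#' @param schemes Named list of [sampling_config()] objects; names label the
#'   report rows.
#' @param classifiers Character vector of roster names (see
#'   [classifier_roster()]).
#' @param k Folds per cross-validation run (default 10).
#' @param seed Base seed for folds and classifier randomness.
#' @return A `sidefx_sweep` tibble: one row per (scheme, classifier, dataset)
#'   with `n`, the six scalar metrics, `auroc`, `aupr`.
#' @export
run_sweep <- function(datasets, matrices, schemes,
                      classifiers = "random_forest", k = 10, seed = 1L) {
  if (length(schemes) == 0) abort("`schemes` must name at least one variant")
  if (is.null(names(schemes)) || any(!nzchar(names(schemes)))) {
    abort("`schemes` must be a named list")
  }
  purrr::walk(schemes, function(s) {
    if (!inherits(s, "sampling_config")) {
      abort("every scheme must be a sampling_config()")
    }
  })
  roster <- classifier_roster()$name
  unknown <- setdiff(classifiers, roster)
  if (length(unknown) > 0) {
    abort(paste0("unknown classifier name: ", paste(unknown, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(
    scheme = names(schemes), classifier = classifiers,
    dataset = sort(unique(datasets$dataset))
  )
  rows <- purrr::pmap_dfr(grid, function(scheme, classifier, dataset) {
    pairs <- datasets[datasets$dataset == dataset,
                      c("drug", "side_effect", "label")]
    cv <- run_cross_validation(
      pairs, matrices, schemes[[scheme]],
      classifier_spec(classifier, seed = seed + dataset),
      k = k, seed = seed + dataset
    )
    dplyr::bind_cols(
      tibble(scheme = scheme, classifier = classifier, dataset = dataset),
      metrics_report(cv$score, cv$label)
    )
  })
  structure(rows, class = c("sidefx_sweep", class(rows)), seed = seed, k = k)
}

# default scheme list used by run_experiment when the config names none
default_schemes <- function() {
  list(
    single = sampling_config("single"),
    discrete = sampling_config("discrete"),
    continuous_q20 = sampling_config("continuous", q_values = 20)
  )
}

# turn one config entry (list with scheme/positions/q/types/...) into a
# sampling_config; `name` only used for error messages
parse_scheme <- function(entry, name) {
  if (inherits(entry, "sampling_config")) return(entry)
  if (is.null(entry$scheme)) {
    abort(paste0("scheme entry '", name, "' lacks a `scheme` field"))
  }
  args <- list(scheme = entry$scheme)
  if (!is.null(entry$positions)) args$positions <- unlist(entry$positions)
  if (!is.null(entry$q)) args$q_values <- unlist(entry$q)
  if (!is.null(entry$types)) args$types <- unlist(entry$types)
  if (!is.null(entry$aggregation)) args$aggregation <- entry$aggregation
  if (!is.null(entry$pad_width)) args$pad_width <- entry$pad_width
  do.call(sampling_config, args)
}

#' Run a configured experiment end to end
#'
#' Reads (or takes) a configuration, obtains the world (generated
#' synthetically or loaded from files), assembles the benchmark datasets, runs
#' the sweep, and optionally writes the per-dataset report, the cross-dataset
#' means, and a structured run log.
#'
#' @param config A list, or path to a YAML file, with fields:
#'   `world` (either [world_config()] arguments or `files: dir` pointing at
#'   [write_world()] output), `filter_min_drugs` (default 6), `n_datasets`
#'   (default 5), `dataset_seeds`, `schemes` (named list of scheme entries
#'   with fields `scheme`, `positions`, `q`, `types`), `classifiers`,
#'   `k_folds` (default 10), `seed` (default 1), `out` (optional output
#'   directory).
#' @return List with `report` (per-dataset rows), `summary` (cross-dataset
#'   means), and `log` (seeds, sizes, backend parameters).
#' @export
run_experiment <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  k <- as.integer(config$k_folds %||% 10L)
  n_datasets <- as.integer(config$n_datasets %||% 5L)
  min_drugs <- as.integer(config$filter_min_drugs %||% 6L)
  dataset_seeds <- as.integer(
    unlist(config$dataset_seeds %||% (seed * 1000L + seq_len(n_datasets)))
  )

  world_cfg <- config$world %||% list()
  if (!is.null(world_cfg$files)) {
    world <- read_world(world_cfg$files)
  } else {
    world_cfg$seed <- world_cfg$seed %||% seed
    world <- generate_world(do.call(world_config, world_cfg))
  }

  schemes <- config$schemes %||% default_schemes()
  if (length(schemes) == 0) abort("config lists no schemes to sweep")
  if (is.null(names(schemes))) {
    names(schemes) <- paste0("scheme_", seq_along(schemes))
  }
  schemes <- purrr::imap(schemes, parse_scheme)
  classifiers <- unlist(config$classifiers %||% "random_forest")

  annotations <- filter_rare_side_effects(world$annotations, min_drugs)
  datasets <- assemble_datasets(annotations, n_datasets, dataset_seeds)
  report <- run_sweep(datasets, world$matrices, schemes, classifiers,
                      k = k, seed = seed)
  summary <- aggregate_metrics(report)

  log <- list(
    seed = seed, k_folds = k, n_datasets = n_datasets,
    dataset_seeds = dataset_seeds,
    n_positive_pairs = sum(datasets$dataset == 1 &
                             datasets$label == "positive"),
    n_drugs = length(unique(annotations$drug)),
    n_side_effects = length(unique(annotations$side_effect)),
    schemes = lapply(schemes, unclass),
    classifiers = lapply(
      classifiers, function(nm) unclass(classifier_spec(nm, seed = seed))
    )
  )
  out <- list(report = report, summary = summary, log = log)
  if (!is.null(config$out)) write_report(out, config$out)
  out
}

#' Write an experiment report to disk
#'
#' Emits `report.tsv` (per-dataset rows), `summary.tsv` (cross-dataset means),
#' and `run_log.json` into `dir`.
#'
#' @param result Output of [run_experiment()], or a `sidefx_sweep` tibble.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  if (inherits(result, "sidefx_sweep")) {
    result <- list(report = result, summary = aggregate_metrics(result),
                   log = list(seed = attr(result, "seed"),
                              k_folds = attr(result, "k")))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(as_tibble(result$report), file.path(dir, "report.tsv"))
  readr::write_tsv(result$summary, file.path(dir, "summary.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(report = as.data.frame(result$report),
           summary = as.data.frame(result$summary)),
      file.path(dir, "report.json"), digits = NA, pretty = TRUE
    )
    jsonlite::write_json(result$log, file.path(dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
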