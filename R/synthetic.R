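#' Configure a synthetic drug/side-effect world
#'
#' The generator plants cluster structure that makes similarity-to-annotated-
#' drugs predictive: drugs fall into clusters, each side effect has a home
#' cluster, annotations are much more likely inside the home cluster, and
#' informative association types score within-cluster pairs higher than
#' between-cluster pairs. Defaults give a clearly signal-bearing world of
#' modest size.
#'
#' @param n_drugs,n_side_effects,n_clusters World dimensions (defaults 60
#'   drugs, 20 side effects, 4 clusters).
#' @param within_cluster_sim,between_cluster_sim Mean similarity of
#'   within-cluster and between-cluster drug pairs for informative types
#'   (defaults 0.8 and 0.2); a signal-bearing world needs within > between.
#' @param sim_noise_sd Gaussian noise added to each pairwise score before
#'   clipping to `[0, 1]` (default 0.05).
#' @param annotation_prob_in_cluster,annotation_prob_background Probability
#'   that a drug is annotated with a side effect homed in its own cluster
#'   (default 0.7) versus any other cluster (default 0.05).
#' @param informative_types Association types that carry the planted cluster
#'   signal (default all five); the rest are drawn cluster-independent.
#' @param seed Integer seed; the world is fully deterministic given the seed.
#' @return A `world_config` list.
#' @export
world_config <- function(n_drugs = 60, n_side_effects = 20, n_clusters = 4,
                         within_cluster_sim = 0.8, between_cluster_sim = 0.2,
                         sim_noise_sd = 0.05,
                         annotation_prob_in_cluster = 0.7,
                         annotation_prob_background = 0.05,
                         informative_types = ASSOC_TYPES,
                         seed = 1L) {
  cfg <- list(
    n_drugs = as.integer(n_drugs),
    n_side_effects = as.integer(n_side_effects),
    n_clusters = as.integer(n_clusters),
    within_cluster_sim = within_cluster_sim,
    between_cluster_sim = between_cluster_sim,
    sim_noise_sd = sim_noise_sd,
    annotation_prob_in_cluster = annotation_prob_in_cluster,
    annotation_prob_background = annotation_prob_background,
    informative_types = ASSOC_TYPES[ASSOC_TYPES %in% informative_types],
    seed = as.integer(seed)
  )
  probs <- c(cfg$within_cluster_sim, cfg$between_cluster_sim,
             cfg$annotation_prob_in_cluster, cfg$annotation_prob_background)
  if (any(probs < 0) || any(probs > 1)) {
    abort("similarity means and annotation probabilities must lie in [0, 1]")
  }
  if (cfg$n_clusters > cfg$n_drugs || cfg$n_clusters < 1) {
    abort("need 1 <= n_clusters <= n_drugs")
  }
  if (cfg$sim_noise_sd < 0) abort("sim_noise_sd must be non-negative")
  structure(cfg, class = "world_config")
}

#' Generate a synthetic world
#'
#' @param config A [world_config()].
#' @return List with elements `annotations` (tibble `drug`, `side_effect`),
#'   `matrices` (named list of five [assoc_matrix()] objects), `clusters`
#'   (named integer vector: drug to cluster), `se_clusters` (named integer
#'   vector: side effect to home cluster), and `config`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  drugs <- sprintf("D%03d", seq_len(config$n_drugs))
  ses <- sprintf("SE%03d", seq_len(config$n_side_effects))
  clusters <- setNames(
    rep_len(seq_len(config$n_clusters), config$n_drugs), drugs
  )
  withr::with_seed(config$seed, {
    se_clusters <- setNames(
      sample(seq_len(config$n_clusters), config$n_side_effects,
             replace = TRUE),
      ses
    )
    # annotations: Bernoulli per (drug, side effect) cell
    grid <- tidyr::expand_grid(drug = drugs, side_effect = ses)
    p <- ifelse(clusters[grid$drug] == se_clusters[grid$side_effect],
                config$annotation_prob_in_cluster,
                config$annotation_prob_background)
    annotations <- grid[runif(nrow(grid)) < p, ]

    same <- outer(clusters, clusters, "==")
    matrices <- lapply(setNames(ASSOC_TYPES, ASSOC_TYPES), function(k) {
      base <- if (k %in% config$informative_types) {
        ifelse(same, config$within_cluster_sim, config$between_cluster_sim)
      } else {
        matrix(config$between_cluster_sim, config$n_drugs, config$n_drugs)
      }
      noise <- matrix(rnorm(config$n_drugs^2, 0, config$sim_noise_sd),
                      config$n_drugs)
      noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
      m <- pmax(pmin(base + noise, 1), 0)
      diag(m) <- 1
      dimnames(m) <- list(drugs, drugs)
      assoc_matrix(m, k)
    })
    list(annotations = as_tibble(annotations), matrices = matrices,
         clusters = clusters, se_clusters = se_clusters, config = config)
  })
}

#' A fixed, hand-checkable five-drug world
#'
#' Constants are frozen in source so every candidate list and feature value
#' downstream can be re-derived by hand: side effect `s1` is annotated to
#' `d2`, `d3`, `d4` and `s2` to `d1`, `d5`; the fingerprint scores of `d1`
#' against `d2`, `d3`, `d4` are 0.9, 0.2, 0.7, so the candidate list of the
#' pair `(d1, s1)` under type `f` is `c(0.9, 0.7, 0.2)`.
#'
#' @return List with `annotations` and `matrices` shaped like
#'   [generate_world()] output.
#' @export
worked_fixture <- function() {
  drugs <- paste0("d", 1:5)
  sym <- function(vals) {
    m <- matrix(0, 5, 5, dimnames = list(drugs, drugs))
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    diag(m) <- 1
    m
  }
  # upper triangle filled column-by-column:
  # (1,2) (1,3) (2,3) (1,4) (2,4) (3,4) (1,5) (2,5) (3,5) (4,5)
  f <- sym(c(0.9, 0.2, 0.6, 0.7, 0.5, 0.4, 0.1, 0.3, 0.2, 0.8))
  tm <- sym(c(0.8, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  t_ <- sym(c(0.4, 0.6, 0.3, 0.5, 0.2, 0.1, 0.2, 0.4, 0.3, 0.6))
  s <- f / 2; diag(s) <- 1
  a <- f / 4; diag(a) <- 1
  matrices <- list(
    f = assoc_matrix(f, "f"), s = assoc_matrix(s, "s"),
    a = assoc_matrix(a, "a"), tm = assoc_matrix(tm, "tm"),
    t = assoc_matrix(t_, "t")
  )
  annotations <- tibble(
    drug = c("d2", "d3", "d4", "d1", "d5"),
    side_effect = c("s1", "s1", "s1", "s2", "s2")
  )
  list(annotations = annotations, matrices = matrices)
}

#' Write a world to disk in the formats the loaders consume
#'
#' Emits `annotations.tsv` (flat drug/side-effect lines) and one
#' `assoc_<type>.tsv` per association matrix into `dir`.
#'
#' @param world Output of [generate_world()] or [worked_fixture()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(world$annotations, file.path(dir, "annotations.tsv"),
                   col_names = FALSE)
  for (k in names(world$matrices)) {
    write_assoc_matrix(world$matrices[[k]],
                       file.path(dir, paste0("assoc_", k, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_world
#' @export
read_world <- function(dir) {
  matrices <- lapply(setNames(ASSOC_TYPES, ASSOC_TYPES), function(k) {
    read_assoc_matrix(file.path(dir, paste0("assoc_", k, ".tsv")), k)
  })
  list(
    annotations = read_annotations(file.path(dir, "annotations.tsv")),
    matrices = matrices
  )
}
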