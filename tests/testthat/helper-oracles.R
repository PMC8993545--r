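# Brute-force oracles, deliberately written element-by-element so they stay
# independent of the vectorised implementation paths they check.

oracle_tanimoto <- function(a, b) {
  u <- unique(c(a, b))
  if (length(u) == 0) return(0)
  hits <- 0
  for (x in u) if (any(a == x) && any(b == x)) hits <- hits + 1
  hits / length(u)
}

oracle_cosine <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 || length(b) == 0) return(0)
  dot <- 0
  for (x in a) if (any(b == x)) dot <- dot + 1
  dot / (sqrt(length(a)) * sqrt(length(b)))
}

oracle_atc <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 || length(b) == 0) return(0)
  total <- 0
  for (l in c(1, 3, 4, 5, 7)) {
    pa <- unique(substr(a, 1, l))
    pb <- unique(substr(b, 1, l))
    inter <- 0
    for (x in pa) if (any(pb == x)) inter <- inter + 1
    total <- total + inter / (length(pa) + length(pb) - inter)
  }
  total / 5
}

# re-derive one candidate list by scanning the annotation rows
oracle_candidate_list <- function(drug, side_effect, annotations, m) {
  s_drugs <- character(0)
  for (i in seq_len(nrow(annotations))) {
    d2 <- annotations$drug[i]
    if (annotations$side_effect[i] == side_effect && d2 != drug &&
        !(d2 %in% s_drugs)) {
      s_drugs <- c(s_drugs, d2)
    }
  }
  if (length(s_drugs) == 0) return(numeric(0))
  unname(sort(vapply(s_drugs, function(d2) m[drug, d2], numeric(1)),
              decreasing = TRUE))
}

oracle_metrics <- function(tp, fp, tn, fn) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  sn <- safe(tp, tp + fn)
  sp <- safe(tn, tn + fp)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  den <- sqrt(tn + fn) * sqrt(tn + fp) * sqrt(tp + fn) * sqrt(tp + fp)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  prec <- safe(tp, tp + fp)
  f1 <- safe(2 * prec * sn, prec + sn)
  c(sn = sn, sp = sp, acc = acc, mcc = mcc, precision = prec, f1 = f1)
}

# Mann-Whitney pairwise-win fraction (ties count one half)
oracle_auroc <- function(scores, labels) {
  pos <- scores[as.character(labels) == "positive"]
  neg <- scores[as.character(labels) == "negative"]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# a random small world: arbitrary annotations plus one random symmetric matrix
random_small_world <- function(n_drugs, n_ses, seed) {
  withr::with_seed(seed, {
    drugs <- paste0("d", seq_len(n_drugs))
    ses <- paste0("s", seq_len(n_ses))
    grid <- expand.grid(drug = drugs, side_effect = ses,
                        stringsAsFactors = FALSE)
    ann <- tibble::as_tibble(grid[runif(nrow(grid)) < 0.4, ])
    m <- matrix(runif(n_drugs^2), n_drugs, dimnames = list(drugs, drugs))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    list(annotations = ann, matrix = assoc_matrix(round(m, 3), "f"),
         drugs = drugs, ses = ses)
  })
}

# small separable feature set for classifier smoke tests
toy_training_set <- function(n = 40, seed = 7) {
  withr::with_seed(seed, {
    y <- rep(c("positive", "negative"), each = n / 2)
    x1 <- ifelse(y == "positive", 0.75, 0.25) + rnorm(n, 0, 0.08)
    x2 <- ifelse(y == "positive", 0.7, 0.3) + rnorm(n, 0, 0.12)
    tibble::tibble(
      feat_a = pmin(1, pmax(0, x1)),
      feat_b = pmin(1, pmax(0, x2)),
      label = factor(y, levels = c("negative", "positive"))
    )
  })
}
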