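balanced_pairs <- function(n_per_class) {
  tibble::tibble(
    drug = paste0("d", seq_len(2 * n_per_class)),
    side_effect = "s1",
    label = factor(rep(c("positive", "negative"), each = n_per_class),
                   c("negative", "positive"))
  )
}

test_that("folds form a stratified partition, deterministic per seed", {
  pairs <- balanced_pairs(50)
  folded <- make_folds(pairs, k = 10, seed = 4)
  expect_setequal(unique(folded$fold), 1:10)
  sizes <- table(folded$fold, folded$label)
  expect_true(all(sizes == 5)) # 50 + 50 split into ten folds of 5 + 5
  expect_identical(folded, make_folds(pairs, k = 10, seed = 4))
  expect_false(identical(folded$fold, make_folds(pairs, 10, seed = 5)$fold))
  expect_error(make_folds(balanced_pairs(6), k = 10), "at least k")
})

test_that("confusion counts follow the inclusive-positive threshold rule", {
  labels <- factor(c("positive", "positive", "negative"),
                   c("negative", "positive"))
  counts <- confusion_counts(c(0.9, 0.2, 0.1), labels)
  expect_equal(as.list(counts), list(tp = 1L, fp = 0L, tn = 1L, fn = 1L))

  perfect <- confusion_counts(c(0.9, 0.8, 0.1), labels)
  expect_equal(perfect$fp + perfect$fn, 0)

  all_pos <- confusion_counts(c(0.9, 0.2, 0.1), labels, threshold = 0)
  expect_equal(all_pos$tn, 0)
  expect_equal(compute_metrics(all_pos)$sp, 0)

  expect_error(confusion_counts(numeric(0), factor(character(0))), "empty")
})

test_that("metric formulas agree with naive recomputation to 1e-12", {
  withr::with_seed(2024, {
    got <- want <- matrix(NA_real_, 1000, 6)
    for (i in 1:1000) {
      cts <- sample(0:40, 4, replace = TRUE)
      if (sum(cts) == 0) cts[1] <- 1L
      got[i, ] <- unlist(compute_metrics(
        list(tp = cts[1], fp = cts[2], tn = cts[3], fn = cts[4])
      ))
      want[i, ] <- oracle_metrics(cts[1], cts[2], cts[3], cts[4])
    }
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got[, 4] >= -1 & got[, 4] <= 1)) # MCC range
    expect_true(all(got[, -4] >= 0 & got[, -4] <= 1)) # the other five
  })

  perfect <- compute_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$f1, 1)

  hand <- compute_metrics(list(tp = 3, fp = 1, tn = 2, fn = 2))
  expect_equal(hand$mcc, 4 / sqrt(240))

  # F1 from precision 0.75 and recall 0.6
  expect_equal(compute_metrics(list(tp = 3, fp = 1, tn = 4, fn = 2))$f1,
               2 * 0.75 * 0.6 / (0.75 + 0.6))
})

test_that("AUROC equals the Mann-Whitney pairwise-win fraction", {
  labels <- function(n_pos, n_neg) {
    factor(rep(c("positive", "negative"), c(n_pos, n_neg)),
           c("negative", "positive"))
  }
  expect_equal(auroc(c(0.9, 0.8, 0.1), labels(2, 1)), 1)
  expect_equal(auroc(c(0.9, 0.1, 0.5), labels(2, 1)), 0.5)

  withr::with_seed(7, {
    for (i in 1:200) {
      n_pos <- sample(2:12, 1)
      n_neg <- sample(2:12, 1)
      # coarse grid forces plenty of tied scores
      scores <- sample(seq(0, 1, 0.125), n_pos + n_neg, replace = TRUE)
      y <- labels(n_pos, n_neg)
      expect_equal(auroc(scores, y), oracle_auroc(scores, y))
    }
  })
  expect_error(auroc(c(0.3, 0.4), labels(2, 0)), "both classes")
})

test_that("AUROC and AUPR match an independent implementation", {
  withr::with_seed(31, {
    y <- factor(rep(c("positive", "negative"), c(40, 60)),
                c("negative", "positive"))
    scores <- ifelse(y == "positive", rnorm(100, 0.65, 0.2),
                     rnorm(100, 0.35, 0.2))
    got <- auroc(scores, y)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = scores, levels = c("negative", "positive"),
      direction = "<", quiet = TRUE
    )))
    expect_equal(got, ref, tolerance = 1e-10)
  })
})

test_that("curves are monotone in the threshold sweep", {
  withr::with_seed(13, {
    y <- factor(rep(c("positive", "negative"), each = 30),
                c("negative", "positive"))
    scores <- runif(60)
    rc <- roc_curve(scores, y)
    expect_true(all(diff(rc$fpr) >= 0))
    expect_true(all(diff(rc$tpr) >= 0))
    expect_equal(rc$fpr[1], 0)
    expect_equal(rc$tpr[nrow(rc)], 1)
    pc <- pr_curve(scores, y)
    expect_true(all(diff(pc$recall) >= 0))
    expect_true(all(pc$precision >= 0 & pc$precision <= 1))
  })
})

test_that("shuffled labels give null AUROC and MCC", {
  withr::with_seed(2000, {
    n <- 2000
    scores <- runif(n)
    y <- factor(sample(rep(c("positive", "negative"), n / 2)),
                c("negative", "positive"))
    expect_gt(auroc(scores, y), 0.45)
    expect_lt(auroc(scores, y), 0.55)
    mcc <- compute_metrics(confusion_counts(scores, y))$mcc
    expect_lt(abs(mcc), 0.1)
  })
})

test_that("cross-validation scores each sample exactly once, without leakage", {
  fx <- generate_world(world_config(n_drugs = 30, n_side_effects = 8,
                                    seed = 42))
  ann <- filter_rare_side_effects(fx$annotations)
  ds <- assemble_datasets(ann, 1, seeds = 5)
  pairs <- ds[ds$dataset == 1, c("drug", "side_effect", "label")]
  cv <- run_cross_validation(pairs, fx$matrices, sampling_config("single"),
                             classifier_spec("logistic"), k = 5, seed = 2)
  # partition: every input pair scored exactly once
  expect_equal(nrow(cv), nrow(pairs))
  expect_equal(
    dplyr::arrange(as_tibble(cv)[, 1:3], drug, side_effect, label),
    dplyr::arrange(pairs, drug, side_effect, label),
    ignore_attr = TRUE
  )
  expect_true(all(!is.na(cv$score)))
  expect_setequal(unique(cv$fold), 1:5)

  # leakage contract, re-derived outside the loop: for every fold the
  # training annotation table excludes that fold's positives
  for (f in unique(cv$fold)) {
    train_ann <- cv[cv$fold != f & cv$label == "positive",
                    c("drug", "side_effect")]
    test_pos <- cv[cv$fold == f & cv$label == "positive",
                   c("drug", "side_effect")]
    expect_equal(
      nrow(dplyr::semi_join(test_pos, train_ann,
                            by = c("drug", "side_effect"))),
      0
    )
  }
})

test_that("all-zero association matrices give all-zero features and null MCC", {
  fx <- generate_world(world_config(n_drugs = 30, n_side_effects = 8,
                                    seed = 8))
  ann <- filter_rare_side_effects(fx$annotations)
  ds <- assemble_datasets(ann, 1, seeds = 3)
  pairs <- ds[ds$dataset == 1, c("drug", "side_effect", "label")]
  drugs <- rownames(fx$matrices$f)
  zero <- matrix(0, length(drugs), length(drugs),
                 dimnames = list(drugs, drugs))
  zeros <- lapply(setNames(c("f", "s", "a", "tm", "t"),
                           c("f", "s", "a", "tm", "t")),
                  function(k) assoc_matrix(zero, k))
  feats <- build_features(pairs, ann, zeros, sampling_config("discrete"))
  expect_true(all(as.matrix(feats[, -(1:3)]) == 0))
  cv <- run_cross_validation(pairs, zeros, sampling_config("single"),
                             classifier_spec("random_forest"), k = 5, seed = 2)
  mcc <- compute_metrics(confusion_counts(cv$score, cv$label))$mcc
  expect_lt(abs(mcc), 0.15)
})

test_that("tidy/glance/aggregate summarise cross-validation runs", {
  fx <- generate_world(world_config(n_drugs = 30, n_side_effects = 8,
                                    seed = 21))
  ann <- filter_rare_side_effects(fx$annotations)
  ds <- assemble_datasets(ann, 2, seeds = 8:9)
  cv <- run_cross_validation(ds[ds$dataset == 1, 1:3], fx$matrices,
                             sampling_config("single"),
                             classifier_spec("logistic"), k = 5, seed = 2)
  td <- tidy(cv)
  expect_equal(nrow(td), 5)
  expect_true(all(c("fold", "mcc", "auroc") %in% names(td)))
  gl <- glance(cv)
  expect_equal(gl$n, nrow(cv))
  expect_equal(gl$scheme, "single")

  # aggregation: plain arithmetic mean of per-dataset rows
  reports <- tibble::tibble(scheme = "single", classifier = "logistic",
                            dataset = 1:2, mcc = c(0.5, 0.7),
                            auroc = c(0.8, 0.9))
  agg <- aggregate_metrics(reports)
  expect_equal(agg$mcc, 0.6)
  expect_equal(agg$auroc, 0.85)
  expect_equal(agg$n_datasets, 2L)
  one <- aggregate_metrics(reports[1, ])
  expect_equal(one$mcc, 0.5)
})
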