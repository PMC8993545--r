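test_that("candidate lists sort scores of co-annotated drugs, excluding self", {
  fx <- worked_fixture()
  expect_equal(build_candidate_list("d1", "s1", fx$annotations, fx$matrices$f),
               c(0.9, 0.7, 0.2))
  # self-exclusion: d2 carries s1, so its own list uses only d3 and d4
  expect_equal(build_candidate_list("d2", "s1", fx$annotations, fx$matrices$f),
               sort(c(fx$matrices$f["d2", "d3"], fx$matrices$f["d2", "d4"]),
                    decreasing = TRUE))
  # side effect with no other annotated training drug: empty list
  expect_equal(build_candidate_list("d1", "s2",
                                    fx$annotations[fx$annotations$drug == "d1", ],
                                    fx$matrices$f),
               numeric(0))
  expect_error(
    build_candidate_list("dX", "s1", fx$annotations, fx$matrices$f),
    "absent"
  )
})

test_that("candidate lists match brute-force re-derivation on random worlds", {
  for (seed in 1:8) {
    w <- random_small_world(n_drugs = sample(4:10, 1), n_ses = sample(2:6, 1),
                            seed = seed)
    for (d in w$drugs) {
      for (s in w$ses) {
        expect_equal(
          build_candidate_list(d, s, w$annotations, w$matrix),
          oracle_candidate_list(d, s, w$annotations, w$matrix)
        )
      }
    }
  }
})

test_that("selectors reproduce the hand-derived worked examples", {
  lst <- c(0.9, 0.7, 0.2)

  expect_equal(select_single(lst), 0.9)
  expect_equal(select_single(numeric(0)), 0)
  expect_equal(select_single(0.4), 0.4)

  # L = 3: every percentage position <= 33% clamps to rank 1
  expect_equal(select_discrete(lst, c("top", 5, 10, 15, 20)), rep(0.9, 5))
  # L = 20: ranks 1, 1, 2, 3, 4
  lst20 <- seq(1, 0.05, by = -0.05)
  expect_equal(select_discrete(lst20, c("top", 5, 10, 15, 20)),
               lst20[c(1, 1, 2, 3, 4)])
  expect_equal(select_discrete(numeric(0), c("top", 5, 10, 15, 20)), rep(0, 5))

  expect_equal(select_continuous(lst, 100), 0.6)
  expect_equal(select_continuous(lst, 20), 0.9)
  expect_equal(select_continuous(numeric(0), 50), 0)

  # padded aggregation keeps the raw top values, zero-filled to fixed width
  expect_equal(select_continuous(lst, 100, aggregation = "padded",
                                 pad_width = 5),
               c(0.9, 0.7, 0.2, 0, 0))
})

test_that("selector refinement properties hold on random sorted lists", {
  withr::with_seed(99, {
    for (i in 1:40) {
      lst <- sort(runif(sample(1:25, 1)), decreasing = TRUE)
      L <- length(lst)
      # q small enough to pick exactly one value equals the single selector
      expect_equal(select_continuous(lst, 100 / L), select_single(lst))
      # mean over top-m is non-increasing in m for a sorted list
      means <- vapply(seq_len(L), function(m) mean(lst[seq_len(m)]),
                      numeric(1))
      expect_true(all(diff(means) <= 1e-12))
      # discrete: top feature >= any percentage-position feature
      feats <- select_discrete(lst, c("top", 5, 25, 50, 75, 100))
      expect_true(all(feats[1] >= feats[-1]))
    }
  })
})

test_that("sampling_config validates its inputs", {
  expect_error(sampling_config("discrete", positions = c(5, 10)), "top")
  expect_error(sampling_config("discrete", positions = c("top", 0)), "\\(0, 100]")
  expect_error(sampling_config("discrete", positions = c("top", 101)), "\\(0, 100]")
  expect_error(sampling_config("continuous", q_values = 0), "\\(0, 100]")
  expect_error(sampling_config("single", types = character(0)), "at least one")
  expect_error(sampling_config("nearest"), "arg")
})

test_that("feature matrices have the fixed layout and deterministic rows", {
  fx <- worked_fixture()
  pairs <- tibble::tibble(
    drug = c("d1", "d1", "d5"),
    side_effect = c("s1", "s1", "s2"),
    label = factor(c("positive", "positive", "negative"),
                   levels = c("negative", "positive"))
  )

  single <- build_features(pairs, fx$annotations, fx$matrices,
                           sampling_config("single"))
  expect_equal(ncol(single), 3 + 5)
  expect_named(single, c("drug", "side_effect", "label",
                         paste0(c("f", "s", "a", "tm", "t"), "_top")))

  disc <- build_features(pairs, fx$annotations, fx$matrices,
                         sampling_config("discrete"))
  expect_equal(ncol(disc), 3 + 25)
  # type-major column grouping, fixed order f, s, a, tm, t
  expect_equal(names(disc)[4:8], c("f_top", "f_p5", "f_p10", "f_p15", "f_p20"))
  expect_equal(names(disc)[24:28],
               c("t_top", "t_p5", "t_p10", "t_p15", "t_p20"))

  cont <- build_features(pairs, fx$annotations, fx$matrices,
                         sampling_config("continuous", q_values = c(20, 100)))
  expect_equal(ncol(cont), 3 + 10)

  # identical pairs give identical rows
  expect_identical(disc[1, ], disc[2, ])

  # hand-derived values: (d1, s1) under f has list [0.9, 0.7, 0.2]
  expect_equal(disc$f_top[1], 0.9)
  expect_equal(unlist(disc[1, 4:8], use.names = FALSE), rep(0.9, 5))
  expect_equal(cont$f_q100[1], 0.6)
  expect_equal(cont$f_q20[1], 0.9)
  # s and a matrices are scaled copies of f: scaling carries to features
  expect_equal(disc$s_top[1], 0.45)
  expect_equal(disc$a_top[1], 0.225)

  # restricted type set keeps the fixed order and drops the rest
  sub <- build_features(pairs, fx$annotations, fx$matrices,
                        sampling_config("single", types = c("t", "f")))
  expect_named(sub, c("drug", "side_effect", "label", "f_top", "t_top"))
})

test_that("feature building validates drugs, side effects, and matrices", {
  fx <- worked_fixture()
  pairs <- tibble::tibble(drug = "dX", side_effect = "s1")
  expect_error(
    build_features(pairs, fx$annotations, fx$matrices,
                   sampling_config("single")),
    "dX"
  )
  pairs2 <- tibble::tibble(drug = "d1", side_effect = "sX")
  expect_error(
    build_features(pairs2, fx$annotations, fx$matrices,
                    sampling_config("single"),
                    side_effect_universe = c("s1", "s2")),
    "sX"
  )
  expect_error(
    build_features(pairs2, fx$annotations, fx$matrices["f"],
                   sampling_config("single")),
    "no association matrix"
  )
})

test_that("feature tables round-trip through TSV", {
  fx <- worked_fixture()
  pairs <- tibble::tibble(
    drug = c("d1", "d3"), side_effect = c("s1", "s2"),
    label = factor(c("positive", "negative"), c("negative", "positive"))
  )
  feats <- build_features(pairs, fx$annotations, fx$matrices,
                          sampling_config("continuous", q_values = 30))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(feats, path)
  back <- read_features(path)
  expect_equal(as.data.frame(back), as.data.frame(feats))
})
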