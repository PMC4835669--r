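test_that("profile distances reproduce the published 4D anchors", {
  d <- profile_distances(study_aspect_summary())
  expect_equal(round(d["anger", "fear"], 1), 11.3)
  expect_equal(round(d["guilt", "disappointment"], 1), 3.2)
  expect_equal(round(d["happiness", "hate"], 1), 100.9)
  expect_equal(attr(d, "scale_max"), 200)  # 100 * sqrt(4)
})

test_that("profile distances are a metric with the documented extremes", {
  base <- data.frame(emotion = rep(c("a", "b"), each = 4),
                     aspect = rep(c("valence", "arousal", "control", "utility"), 2),
                     mean = c(rep(10, 4), rep(10, 4)), sd = 0, n = 5L)
  s <- structure(base, class = c("aspect_summary", "data.frame"),
                 emotions = c("a", "b"),
                 aspects = c("valence", "arousal", "control", "utility"))
  expect_equal(profile_distances(s)["a", "b"], 0)  # identical profiles

  s$mean[s$emotion == "a"] <- 0
  s$mean[s$emotion == "b"] <- 100  # differ by 100 on every aspect
  expect_equal(profile_distances(s)["a", "b"], 200)

  # triangle inequality on random summaries (Euclidean by construction)
  set.seed(11)
  for (rep in 1:5) {
    k <- 6
    sm <- structure(
      data.frame(emotion = rep(letters[1:k], each = 4),
                 aspect = rep(c("valence", "arousal", "control", "utility"), k),
                 mean = runif(4 * k, 0, 100), sd = 0, n = 3L),
      class = c("aspect_summary", "data.frame"),
      emotions = letters[1:k],
      aspects = c("valence", "arousal", "control", "utility"))
    d <- profile_distances(sm)
    for (i in 1:k) for (j in 1:k) for (l in 1:k)
      expect_lte(d[i, j], d[i, l] + d[l, j] + 1e-9)
  }
})

test_that("profile distances require four aspects unless generalized", {
  x <- toy_dataset()
  s <- aspect_summary(x)
  s3 <- s[s$aspect != "utility", ]
  attr(s3, "aspects") <- c("valence", "arousal", "control")
  attr(s3, "emotions") <- attr(s, "emotions")
  class(s3) <- class(s)
  expect_error(profile_distances(s3), "4 aspects")
  d3 <- profile_distances(s3, generalized = TRUE)
  expect_equal(attr(d3, "scale_max"), 100 * sqrt(3))
})

test_that("aspect correlations match a first-principles rank oracle", {
  # 5-participant toy table, hand-checkable
  set.seed(3)
  arr <- array(runif(5 * 4 * 4, 0, 100), dim = c(5, 4, 4),
               dimnames = list(paste0("p", 1:5), c("w", "x", "y", "z"),
                               c("valence", "arousal", "control", "utility")))
  x <- rating_dataset(arr)
  r <- aspect_correlations(x, "arousal", method = "spearman")
  for (i in 1:4) for (j in 1:4)
    expect_equal(r[i, j], oracle_spearman(arr[, i, "arousal"], arr[, j, "arousal"]),
                 tolerance = 1e-12)

  # identical ratings -> r = 1; strictly decreasing transform -> r = -1
  arr[, "x", "valence"] <- arr[, "w", "valence"]
  arr[, "y", "valence"] <- 100 - 0.9 * arr[, "w", "valence"]
  x2 <- rating_dataset(arr)
  r2 <- aspect_correlations(x2, "valence")
  expect_equal(r2["w", "x"], 1)
  expect_equal(r2["w", "y"], -1)

  # zero variance is an undefined coefficient, named
  arr[, "z", "control"] <- 50
  expect_error(aspect_correlations(rating_dataset(arr), "control"), "'z'")
})

test_that("correlation-to-proximity map hits the stated anchors and is monotone", {
  r <- matrix(c(1, 1, 0, -1,
                1, 1, 0.5, 0,
                0, 0.5, 1, -0.25,
                -1, 0, -0.25, 1), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d <- cor_to_prox(r)
  expect_equal(d["a", "c"], 1)   # r = 0 -> 1
  expect_equal(d["a", "d"], 2)   # r = -1 -> 2
  expect_equal(d["a", "b"], 0)   # r = 1 -> 0
  expect_equal(d["b", "c"], 0.5) # linearity
  expect_equal(attr(d, "scale_max"), 2)
  expect_equal(unname(diag(d)), rep(0, 4))

  # strictly decreasing, maps [-1, 1] onto [0, 2]
  rs <- seq(-1, 1, by = 0.05)
  ds <- 1 - rs
  expect_true(all(diff(ds) < 0))
  expect_equal(range(ds), c(0, 2))
})

test_that("mds_sources composes the per-aspect operations consistently", {
  x <- toy_dataset(n = 8)
  src <- mds_sources(x)
  expect_length(src, 4L)
  expect_named(src, dimnames(x)$aspect)
  for (a in names(src)) {
    expect_identical(rownames(src[[a]]), dimnames(x)$emotion)
    direct <- cor_to_prox(aspect_correlations(x, a))
    expect_equal(unclass(src[[a]]), unclass(direct))
  }

  # an aspect copied participant-wise yields an identical source matrix
  arr <- unclass(x)
  arr[, , "utility"] <- arr[, , "valence"]
  src2 <- mds_sources(rating_dataset(arr))
  expect_equal(unclass(src2$utility), unclass(src2$valence), ignore_attr = TRUE)
})

test_that("aspect independence applies the Bonferroni rule and detects dependence", {
  x <- toy_dataset(n = 30, emotions = letters[1:8])
  rep <- aspect_independence(x)
  expect_equal(nrow(rep), 6L)
  expect_equal(rep$p_adjusted, pmin(1, rep$p * 6))

  arr <- unclass(x)
  arr[, , "utility"] <- arr[, , "valence"]  # exact copy
  rep2 <- aspect_independence(rating_dataset(arr))
  row <- rep2[rep2$aspect_a == "valence" & rep2$aspect_b == "utility", ]
  expect_equal(row$r, 1)
  expect_lt(row$p_adjusted, 1e-10)

  rep3 <- aspect_independence(x, unit = "emotion_means")
  expect_equal(nrow(rep3), 6L)
  expect_equal(rep3$n, rep(8L, 6))
})

test_that("familywise type-I rate under the null stays at the nominal level", {
  # independent aspects; any significant adjusted p is a familywise error
  set.seed(2024)
  reps <- 1000
  n_part <- 25; n_emo <- 8
  hits <- 0L
  for (i in seq_len(reps)) {
    arr <- array(runif(n_part * n_emo * 4, 0, 100), dim = c(n_part, n_emo, 4),
                 dimnames = list(paste0("p", 1:n_part), paste0("e", 1:n_emo),
                                 c("valence", "arousal", "control", "utility")))
    rep_i <- aspect_independence(rating_dataset(arr, check = FALSE))
    hits <- hits + any(rep_i$significant)
  }
  rate <- hits / reps
  # Bonferroni FWER <= 0.05; binomial 3-sigma envelope around the nominal rate
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("proximity matrices survive a CSV round trip with metadata", {
  d <- profile_distances(study_aspect_summary())
  f <- withr::local_tempfile(fileext = ".csv")
  write_proximity(d, f)
  d2 <- read_proximity(f)
  expect_equal(unclass(d2), unclass(d), tolerance = 1e-5)
  expect_equal(attr(d2, "kind"), "profile_distance")
  expect_equal(attr(d2, "scale_max"), 200)
  expect_error(proximity_matrix(matrix(c(0, 1, 2, 0), 2, 2), "profile_distance"),
               "symmetric")
  expect_error(proximity_matrix(matrix(c(1, 1, 1, 1), 2, 2), "profile_distance"),
               "diagonal")
})
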