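test_that("cosine similarity and average difference match hand values", {
  expect_equal(cosine_similarity(c(3, 4), c(4, 3)), 24 / 25)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(5, 2, 9), c(5, 2, 9)), 1.0)
  expect_equal(average_difference(c(2, 4), c(4, 4)), -1)
  expect_equal(average_difference(c(5, 2, 9), c(5, 2, 9)), 0)
  expect_equal(average_difference(c(4, 7) + 3, c(4, 7)), 3)   # constant shift
  expect_error(cosine_similarity(1:3, 1:4), "lengths differ")
  expect_error(average_difference(1:3, 1:4), "lengths differ")
  expect_error(cosine_similarity(c(0, 0), c(1, 2)), "all-zero")
})

test_that("metrics equal explicit-loop oracles to 1e-12 on random series", {
  set.seed(101)
  for (i in 1:100) {
    T_ <- sample(3:60, 1)
    a <- sample(0:50, T_, replace = TRUE) + 1
    s <- sample(0:50, T_, replace = TRUE) + 1
    expect_equal(cosine_similarity(a, s), brute_cos(a, s), tolerance = 1e-12)
    expect_equal(average_difference(a, s), brute_avg(a, s), tolerance = 1e-12)
  }
})

test_that("metric symmetries hold: scale invariance and antisymmetry", {
  set.seed(102)
  for (i in 1:20) {
    a <- runif(15, 1, 100); s <- runif(15, 1, 100); c0 <- runif(1, 0.1, 10)
    expect_equal(cosine_similarity(c0 * a, s), cosine_similarity(a, s),
                 tolerance = 1e-12)
    expect_equal(average_difference(a, s), -average_difference(s, a),
                 tolerance = 1e-12)
    expect_true(cosine_similarity(a, s) > 0 && cosine_similarity(a, s) <= 1)
  }
})

test_that("normalization centers each metric over subtypes", {
  expect_equal(normalize_metrics(c(0.2, 0.4, 0.6)), c(-0.2, 0, 0.2))
  expect_equal(normalize_metrics(5), 0)
  set.seed(103)
  v <- runif(9)
  expect_equal(sum(normalize_metrics(v)), 0, tolerance = 1e-12)
})

test_that("ensemble aggregation uses the population standard deviation", {
  expect_equal(aggregate_ensemble(c(1, 3)), c(mean = 2, sd = 1))
  expect_equal(aggregate_ensemble(rep(4, 6))[["sd"]], 0)
  expect_equal(aggregate_ensemble(7), c(mean = 7, sd = 0))
})

test_that("compare_subtypes centers ensemble means and keeps one row per subtype", {
  ref <- c(10, 10, 10, 2)
  sizes <- list(
    "0" = list(c(10, 10, 10, 2), c(10, 10, 10, 2)),
    "1" = list(c(1, 1, 1, 1), c(2, 2, 1, 1)),
    "2" = list(c(10, 10, 2, 2), c(10, 10, 10, 2))
  )
  m <- compare_subtypes(sizes, ref)
  expect_equal(nrow(m), 3L)
  expect_equal(sum(m$n_cos_sim), 0, tolerance = 1e-12)
  expect_equal(sum(m$n_avg_diff), 0, tolerance = 1e-12)
  expect_equal(m$cos_sim[1], 1.0)
  expect_equal(m$cos_sim_sd[1], 0)
  expect_true(m$avg_diff[2] < m$avg_diff[1])
})

test_that("ranking orders by the average of the two metric ranks", {
  m <- tibble::tibble(
    subtype_id = c("0", "1", "2"),
    n_cos_sim = c(-0.2, 0.0, 0.2),
    n_avg_diff = c(-5, 2, 3)
  )
  r <- rank_subtypes(m, stable = TRUE)
  expect_s3_class(r, "subtype_ranking")
  expect_equal(r$subtype_id, c("0", "1", "2"))
  expect_equal(r$rank, 1:3)
  expect_equal(glance(r)$top_subtype, "0")

  # lowest in both metrics is rank 1 ("malicious")
  m2 <- tibble::tibble(subtype_id = c("a", "b"),
                       n_cos_sim = c(0.1, -0.1), n_avg_diff = c(4, -4))
  expect_equal(rank_subtypes(m2)$subtype_id[1], "b")

  # full ties resolve by subtype id order
  m3 <- tibble::tibble(subtype_id = c("s2", "s1", "s3"),
                       n_cos_sim = 0, n_avg_diff = 0)
  expect_equal(rank_subtypes(m3)$subtype_id, c("s1", "s2", "s3"))

  expect_warning(rank_subtypes(m, stable = FALSE), "NOT stable")
})

test_that("tidy and autoplot work on rankings", {
  m <- tibble::tibble(subtype_id = c("0", "1"),
                      n_cos_sim = c(-0.1, 0.1), n_avg_diff = c(-2, 2))
  r <- rank_subtypes(m)
  td <- tidy(r)
  expect_false(inherits(td, "subtype_ranking"))
  expect_true(all(c("rank", "rank_cos", "rank_avg") %in% names(td)))
  p <- ggplot2::autoplot(r)
  expect_s3_class(p, "ggplot")
})
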