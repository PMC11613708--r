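test_that("adjust_scores matches the closed-form OLS oracle and falls back", {
  withr::with_seed(5, {
    x <- runif(5, 100, 500)
    y <- 0.2 - 0.0003 * x + rnorm(5, sd = 0.01)
    got <- adjust_scores(y, x)
    expect_equal(as.numeric(got), brute_ols_resid(y, x), tolerance = 1e-10)
    expect_equal(attr(got, "method"), "ols")
  })
  # perfectly linear raw -> all residuals 0
  x <- c(10, 20, 30, 40)
  expect_equal(as.numeric(adjust_scores(0.5 - 0.01 * x, x)),
               rep(0, 4), tolerance = 1e-12)
  # two observations would be fit exactly: fallback mean-centers instead
  got <- adjust_scores(c(0.3, 0.5), c(10, 99))
  expect_equal(as.numeric(got), c(-0.1, 0.1))
  expect_equal(attr(got, "method"), "centering")
  # constant covariate: fallback
  got <- adjust_scores(c(0.1, 0.4, 0.4), c(7, 7, 7))
  expect_equal(attr(got, "method"), "centering")
  expect_equal(as.numeric(got), c(-0.2, 0.1, 0.1))
  expect_error(adjust_scores(c(0.1, 0.2), c(1, 2, 3)), "lengths differ")
})

test_that("finalize_scores scales, inverts, and handles degeneracy", {
  expect_equal(finalize_scores(c(-0.2, 0, 0.3)), c(1.0, 0.6, 0.0))
  expect_warning(out <- finalize_scores(0.7), "0.5")
  expect_equal(out, 0.5)
  # ordering of final is the exact reverse of ordering of adjusted
  withr::with_seed(11, {
    for (i in 1:10) {
      adj <- rnorm(sample(3:12, 1))
      fin <- finalize_scores(adj)
      expect_true(all(fin >= 0 & fin <= 1))
      expect_equal(order(fin), rev(order(adj)))
      expect_equal(min(fin), 0)
      expect_equal(max(fin), 1)
    }
  })
})

test_that("subsample_groups honours size rules and is deterministic", {
  grouping <- data.frame(
    cell_id = paste0("c", 1:291),
    group = rep(c("big", "small", "tiny"), c(250, 40, 1)))
  expect_warning(reps <- subsample_groups(grouping, size = 100, seed = 4),
                 "tiny")
  big <- reps[reps$group == "big", ]
  expect_equal(as.integer(table(big$replicate)), rep(100L, 5))
  expect_true(all(!duplicated(big[big$replicate == 2, "cell_id"])))
  small <- reps[reps$group == "small", ]
  expect_equal(nrow(small), 40)
  expect_equal(unique(small$replicate), 1L)
  expect_false("tiny" %in% reps$group)
  expect_equal(attr(reps, "skipped"), "tiny")

  again <- suppressWarnings(subsample_groups(grouping, size = 100, seed = 4))
  expect_identical(reps, again)
  other <- suppressWarnings(subsample_groups(grouping, size = 100, seed = 5))
  expect_false(identical(reps$cell_id, other$cell_id))
  expect_error(subsample_groups(grouping, size = 1), "at least 2")
})

test_that("compute_epichaos per-row raw matches independent recomputation", {
  m <- rand_bin(60, 18, density = 0.35, seed = 21)
  grouping <- data.frame(cell_id = colnames(m),
                         group = rep(c("g1", "g2", "g3"), each = 6))
  sc <- compute_epichaos(m, grouping, subsample = FALSE)
  expect_equal(nrow(sc), 3)
  for (i in seq_len(nrow(sc))) {
    cells <- grouping$cell_id[grouping$group == sc$group[i]]
    want <- brute_raw(m, cells)
    expect_equal(sc$raw[i], want$raw, tolerance = 1e-12)
    expect_equal(sc$mean_count[i], want$mean_count, tolerance = 1e-12)
  }
  expect_equal(as.numeric(adjust_scores(sc$raw, sc$mean_count)), sc$adjusted)
  expect_equal(finalize_scores(sc$adjusted), sc$epichaos)
  expect_true(all(sc$epichaos >= 0 & sc$epichaos <= 1))
})

test_that("identically composed groups score within subsampling noise", {
  withr::with_seed(31, {
    p <- runif(200, 0.1, 0.5)
    m <- matrix(rbinom(200 * 90, 1, p), 200, 90,
                dimnames = list(NULL, paste0("c", 1:90)))
  })
  grouping <- data.frame(cell_id = colnames(m),
                         group = rep(c("a", "b", "c"), each = 30))
  sc <- compute_epichaos(m, grouping, subsample = TRUE, subsample_size = 20,
                         seed = 2)
  expect_equal(nrow(sc), 15)
  within_sd <- mean(tapply(sc$raw, sc$group, sd))
  between <- diff(range(tapply(sc$raw, sc$group, mean)))
  expect_lt(between, 4 * within_sd)
})

test_that("compute_epichaos is deterministic given the seed", {
  m <- rand_bin(80, 60, seed = 8)
  grouping <- data.frame(cell_id = colnames(m),
                         group = rep(c("a", "b"), each = 30))
  a <- compute_epichaos(m, grouping, subsample_size = 25, seed = 77)
  b <- compute_epichaos(m, grouping, subsample_size = 25, seed = 77)
  expect_identical(a, b)
  d <- compute_epichaos(m, grouping, subsample_size = 25, seed = 78)
  expect_false(identical(a$raw, d$raw))
})

test_that("compute_epichaos validates input and skips unscorable groups", {
  m <- rand_bin(20, 6, seed = 2)
  expect_error(compute_epichaos(m, data.frame(cell_id = "nope", group = "g"),
                                subsample = FALSE), "absent")
  g <- data.frame(cell_id = colnames(m),
                  group = c(rep("ok", 5), "lonely"))
  expect_warning(sc <- compute_epichaos(m, g, subsample = FALSE), "lonely")
  expect_equal(sc$group, "ok")
  expect_error(
    suppressWarnings(compute_epichaos(
      m, data.frame(cell_id = colnames(m)[1], group = "x"),
      subsample = FALSE)),
    "at least 2 cells")
})

test_that("missing-value policies score methylation-style matrices", {
  withr::with_seed(13, {
    m <- matrix(rbinom(50 * 20, 1, 0.4), 50, 20,
                dimnames = list(NULL, paste0("c", 1:20)))
    full <- m
    # one feature missing in 30% of cells (dropped), scattered NAs elsewhere
    m[1, 1:6] <- NA
    m[cbind(sample(2:50, 15), sample(1:20, 15, replace = TRUE))] <- NA
  })
  g <- data.frame(cell_id = colnames(m), group = rep(c("a", "b"), each = 10))
  sc <- compute_epichaos(m, g, subsample = FALSE, na_policy = "drop")
  expect_equal(attr(sc, "dropped_features"), 1L)
  expect_equal(nrow(sc), 2)
  sc2 <- compute_epichaos(m, g, subsample = FALSE, na_policy = "pairwise",
                          pairwise_min_obs = 10)
  expect_true(all(is.finite(sc2$raw)))
  # without missing values both policies reduce to the standard path
  base <- compute_epichaos(full, g, subsample = FALSE)
  expect_equal(compute_epichaos(full, g, subsample = FALSE,
                                na_policy = "pairwise")$raw, base$raw)
})
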