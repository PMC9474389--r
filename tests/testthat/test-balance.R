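test_that("split extraction records (n, i) for subtrees of four or more tips", {
  bal4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  s <- extract_splits(bal4)
  expect_equal(nrow(s), 1L)
  expect_equal(s$n, 4L)
  expect_equal(s$i, 2L)

  cat4 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  s2 <- extract_splits(cat4)
  expect_equal(s2$n, 4L)
  expect_true(s2$i %in% c(1L, 3L))

  bal8 <- ape::read.tree(text = paste0(
    "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);"))
  s3 <- extract_splits(bal8)
  expect_equal(sort(s3$n), c(4L, 4L, 8L))
  expect_equal(s3$i[s3$n == 8L], 4L)
  expect_equal(s3$i[s3$n == 4L], c(2L, 2L))

  # pooling across trees
  expect_equal(nrow(extract_splits(list(bal4, bal8))), 4L)
  expect_error(extract_splits(ape::read.tree(text = "(A:1,B:1,C:1);")),
               "binary")
})

test_that("exact split probabilities normalise and are symmetric", {
  expect_equal(log_qn_exact(4, 1, 0), log(1 / 3))
  expect_equal(log_qn_exact(5, 2, 1), log(3 / 11))  # exact integer-Gamma fractions

  set.seed(201)
  for (r in seq_len(20)) {
    n <- sample(4:60, 1)
    beta <- runif(1, -1.9, 9)
    lq <- log_qn_exact(n, seq_len(n - 1), beta)
    expect_equal(sum(exp(lq)), 1, tolerance = 1e-10)
    expect_equal(lq, rev(lq))  # i <-> n - i symmetry
  }
  expect_error(log_qn_exact(5, 2, -2), "> -2")
  expect_error(log_qn_exact(5, 5, 0), "1:\\(n-1\\)")
})

test_that("approximate split probabilities match the exact form where claimed", {
  # identical (uniform) at beta = 0
  expect_equal(log_qn_approx(7, 1:6, 0), log_qn_exact(7, 1:6, 0))
  lq <- log_qn_approx(9, 1:8, -1)
  expect_equal(lq, rev(lq))
  expect_equal(sum(exp(lq)), 1, tolerance = 1e-12)
  # large n: within 1% of the exact form
  n <- 2000L
  rel <- abs(exp(log_qn_approx(n, 1:(n - 1), -1)) /
             exp(log_qn_exact(n, 1:(n - 1), -1)) - 1)
  expect_lt(max(rel), 0.01)
})

test_that("beta MLE agrees with a dense grid search and flags boundaries", {
  single_bal <- structure(data.frame(n = 4L, i = 2L),
                          class = c("split_set", "data.frame"))
  e <- beta_mle(single_bal)
  expect_equal(e$beta_hat, 10)  # a lone balanced split pushes beta upward
  expect_true(e$boundary)

  single_unbal <- structure(data.frame(n = 4L, i = 1L),
                            class = c("split_set", "data.frame"))
  e2 <- beta_mle(single_unbal)
  expect_equal(e2$beta_hat, -2 + 1e-6)
  expect_true(e2$boundary)

  set.seed(202)
  grid <- seq(-2 + 1e-6, 10, length.out = 1e4)
  for (r in seq_len(20)) {
    n <- sample(4:12, 5, replace = TRUE)
    s <- structure(data.frame(n = n, i = vapply(n, function(k)
      sample(seq_len(k - 1), 1), integer(1))),
      class = c("split_set", "data.frame"))
    e <- beta_mle(s)
    ll <- vapply(grid, function(b) phasetree:::beta_loglik(s, b), numeric(1))
    expect_lt(abs(e$beta_hat - grid[which.max(ll)]), 2 * (grid[2] - grid[1]))
  }
  expect_error(beta_mle(structure(data.frame(n = integer(0), i = integer(0)),
                                  class = c("split_set", "data.frame"))),
               "empty")
})

test_that("profile confidence intervals sit at the chi-square cutoff", {
  set.seed(203)
  trees <- simulate_trees(wt_model("exponential", rate = 1), 40, 100)
  s <- extract_splits(trees)
  est <- beta_ci(s, beta_mle(s))
  expect_true(est$lower <= est$beta_hat && est$beta_hat <= est$upper)
  expect_true(is.finite(est$se) && est$se > 0)
  cut <- stats::qchisq(0.95, 1) / 2
  for (b in c(est$lower, est$upper)) {
    drop <- est$loglik - phasetree:::beta_loglik(s, b)
    expect_equal(drop, cut, tolerance = 0.05)  # grid resolution
  }
  # information accumulates: a quarter of the data gives a wider interval
  s_small <- extract_splits(trees[1:25])
  est_small <- beta_ci(s_small, beta_mle(s_small))
  expect_gt(est_small$upper - est_small$lower, est$upper - est$lower)
})

test_that("treeset beta is less upward-biased than per-tree medians", {
  # speciation times from the slowly-absorbing 4-phase Coxian chain
  d <- coxian_ph(c(2, 1.1, 1.01, 0.001), ps = c(0.5, 1 / 1.1, 1 / 1.01))
  set.seed(204)
  trees <- simulate_trees(wt_model("coxian", dist = d), 25, 150)
  pooled <- beta_mle(extract_splits(trees))
  per_tree <- vapply(trees, function(t) beta_mle(extract_splits(t))$beta_hat,
                     numeric(1))
  expect_lt(pooled$beta_hat, stats::median(per_tree))
})

test_that("speciation mode has little effect on treeset balance", {
  d <- coxian_ph(c(2, 1.1, 1.01, 0.001), ps = c(0.5, 1 / 1.1, 1 / 1.01))
  set.seed(205)
  sym <- beta_mle(extract_splits(simulate_trees(d, 30, 150, mode = "symmetric")))
  asym <- beta_mle(extract_splits(simulate_trees(d, 30, 150, mode = "asymmetric")))
  expect_lt(abs(sym$beta_hat - asym$beta_hat), 0.4)
})

test_that("gamma statistic matches hand arithmetic and the reference implementation", {
  # g2 = g3 = 1: gamma = (2 - 2.5) / (5 sqrt(1/12))
  expect_equal(gamma_statistic(three_tip_tree()),
               (2 - 2.5) / (5 * sqrt(1 / 12)), tolerance = 1e-12)

  set.seed(206)
  trees <- simulate_trees(wt_model("exponential", rate = 1), 30, 20)
  for (tr in trees) {
    g <- gamma_statistic(tr)
    expect_equal(g, ape::gammaStat(tr$recon), tolerance = 1e-9)
    scaled <- tr$recon
    scaled$edge.length <- scaled$edge.length * 3.7
    expect_equal(gamma_statistic(scaled), g, tolerance = 1e-9)
  }
  expect_error(gamma_statistic(ape::read.tree(text = "(A:1,B:1);")), "3 tips")
  expect_error(gamma_statistic(ape::read.tree(text = "((A:1,B:2):1,C:2);")),
               "ultrametric")
})
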