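test_that("phase-type tree likelihood reduces to the exponential case", {
  b <- toy_branches()
  expect_equal(loglik_ph(b, coxian_ph(1)), -3)                      # e^-1 three times
  expect_equal(loglik_ph(b, coxian_ph(1), with_permutations = TRUE), -3)

  set.seed(301)
  for (lam in c(0.3, 1, 4)) {
    bd <- branch_data(internal = rexp(7, 1), pendant = rexp(8, 1))
    expect_equal(loglik_ph(bd, coxian_ph(lam)), loglik_exp(bd, lam),
                 tolerance = 1e-10)
  }

  # survival floor: absurdly long branch under a fast distribution
  bad <- branch_data(internal = 1e6, pendant = 1)
  ll <- loglik_ph(bad, coxian_ph(5))
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "diagnostics")$n_internal_floored, 1L)
})

test_that("treeset likelihood is the order-invariant sum of per-tree terms", {
  set.seed(302)
  d <- ph_dec(0.3, 0.78, 10)
  bs <- lapply(1:3, function(i)
    branch_data(internal = rexp(4, 2), pendant = rexp(5, 2)))
  expect_equal(loglik_treeset(bs[[1]], d), as.numeric(loglik_ph(bs[[1]], d)))
  total <- loglik_treeset(bs, d)
  expect_equal(total, sum(vapply(bs, function(b) as.numeric(loglik_ph(b, d)),
                                 numeric(1))))
  for (r in seq_len(10))
    expect_equal(loglik_treeset(sample(bs), d), total)
  # pooled-product oracle: single branch_data with everything concatenated
  pooled <- branch_data(internal = unlist(lapply(bs, `[[`, "internal")),
                        pendant = unlist(lapply(bs, `[[`, "pendant")))
  expect_equal(total, as.numeric(loglik_ph(pooled, d)))
})

test_that("exponential likelihood matches scalar arithmetic and its MLE", {
  b <- toy_branches()
  expect_equal(loglik_exp(b, 1), -3)
  expect_equal(loglik_exp(b, 2), log(2) - 6)

  set.seed(303)
  bd <- branch_data(internal = rexp(20, 2), pendant = rexp(21, 2))
  lam_hat <- bd$k / (sum(bd$internal) + sum(bd$pendant))
  grid <- seq(lam_hat / 3, lam_hat * 3, length.out = 2000)
  ll <- vapply(grid, function(l) loglik_exp(bd, l), numeric(1))
  expect_equal(grid[which.max(ll)], lam_hat, tolerance = 1e-2)
  expect_true(all(ll <= loglik_exp(bd, lam_hat)))
})

test_that("weibull likelihood matches hand evaluation and nests the exponential", {
  b <- toy_branches()
  # psi = 2, phi = 1: density log(2 * 1 * e^-1), survival e^-1 twice
  expect_equal(loglik_weibull(b, 2, 1), log(2) - 3)
  set.seed(304)
  bd <- branch_data(internal = rexp(9), pendant = rexp(4))
  for (phi in c(0.5, 1, 3))
    expect_equal(loglik_weibull(bd, 1, phi), loglik_exp(bd, 1 / phi),
                 tolerance = 1e-12)
  shuf <- branch_data(internal = sample(bd$internal), pendant = sample(bd$pendant))
  expect_equal(loglik_weibull(shuf, 1.7, 0.8), loglik_weibull(bd, 1.7, 0.8))
  expect_error(loglik_weibull(bd, -1, 1), "> 0")
})

test_that("extinction probability has the right limits and analytic continuation", {
  expect_equal(extinct_prob(c(0, 1, 10), 1, 0), rep(0, 3))
  expect_equal(extinct_prob(500, 1, 0.5), 0.5, tolerance = 1e-6)  # -> mu/lambda
  expect_equal(extinct_prob(1, 1, 1), 0.5)                        # lambda z/(1+lambda z)
  # the lambda = mu limit continues the generic formula
  expect_equal(extinct_prob(1, 1, 1 - 1e-7), 0.5, tolerance = 1e-6)
  expect_equal(extinct_prob(1, 1, 1 + 1e-7), 0.5, tolerance = 1e-6)
  expect_equal(extinct_prob(0, 2, 1.5), 0)
})

test_that("internal-branch probability satisfies its defining equations", {
  expect_equal(g_branch(c(0.5, 2), 1, 3, 0), exp(-3 * c(0.5, 2)))
  expect_equal(g_branch(0, 2, 1, 0.5), 1)

  # ODE dG/dz = -(lambda+mu) G + 2 lambda G E(z+x), finite-difference residual
  zz <- seq(0.05, 5, by = 0.05); h <- 1e-4
  for (lm in list(c(1, 0.5), c(2, 1.9), c(1, 0))) {
    x <- 1
    dG <- (g_branch(zz + h, x, lm[1], lm[2]) - g_branch(zz - h, x, lm[1], lm[2])) / (2 * h)
    rhs <- -(lm[1] + lm[2]) * g_branch(zz, x, lm[1], lm[2]) +
      2 * lm[1] * g_branch(zz, x, lm[1], lm[2]) * extinct_prob(zz + x, lm[1], lm[2])
    expect_lt(max(abs(dG - rhs)), 1e-6)
  }

  # renewal-equation self-consistency at (1, 0.5, x = 1, b = 1) by quadrature
  lam <- 1; mu <- 0.5; x <- 1; bb <- 1
  rhs <- exp(-(lam + mu) * bb) + integrate(function(u)
    exp(-(lam + mu) * (bb - u)) * lam * 2 * g_branch(u, x, lam, mu) *
      extinct_prob(u + x, lam, mu), 0, bb, rel.tol = 1e-10)$value
  expect_equal(g_branch(bb, x, lam, mu), rhs, tolerance = 1e-8)

  # lambda = mu continuation
  expect_equal(g_branch(1, 2, 1, 1), ((1 + 2) / (1 + 3))^2, tolerance = 1e-10)
})

test_that("pendant-branch probability satisfies its defining equations", {
  expect_equal(d_pendant(1, 1, 0), exp(-1))
  expect_equal(d_pendant(0, 2, 1.3), 1)
  expect_equal(d_pendant(2, 1, 1), 1 / (1 + 2)^2, tolerance = 1e-10)

  zz <- seq(0.05, 5, by = 0.05); h <- 1e-4
  for (lm in list(c(1, 0.5), c(2, 1.9), c(1, 0))) {
    dD <- (d_pendant(zz + h, lm[1], lm[2]) - d_pendant(zz - h, lm[1], lm[2])) / (2 * h)
    rhs <- (-(lm[1] + lm[2]) + 2 * lm[1] * extinct_prob(zz, lm[1], lm[2])) *
      d_pendant(zz, lm[1], lm[2])
    expect_lt(max(abs(dD - rhs)), 1e-6)
  }

  # independent RK4 integration of the ODE from D(0) = 1 at (1, 0.5)
  times <- seq(0, 2, by = 1e-3)
  ode <- rk4(function(t, y) (-(1 + 0.5) + 2 * 1 * extinct_prob(t, 1, 0.5)) * y,
             1, times)
  expect_equal(d_pendant(2, 1, 0.5), ode[length(ode)], tolerance = 1e-8)
})

test_that("birth-death tree likelihood assembles its factors correctly", {
  set.seed(305)
  tr <- simulate_tree(wt_model("exponential", rate = 1), 10)
  b <- classify_branches(tr$recon, include_root_edge = TRUE)
  expect_equal(b$k, b$ell - 1L)

  # mu = 0 collapses to the permuted pure-birth exponential likelihood
  for (lam in c(0.5, 1, 2))
    expect_equal(loglik_crbd(b, lam, 0),
                 loglik_exp(b, lam) + lfactorial(b$ell - 1), tolerance = 1e-10)

  # term-by-term scalar assembly on a 3-tip tree
  toy <- classify_branches(ape::read.tree(text = "((A:1,B:1):1,C:2):0.5;"),
                           include_root_edge = TRUE)
  lam <- 1; mu <- 0.5
  manual <- lfactorial(2) +
    sum(log(g_branch(toy$internal, toy$x, lam, mu)) + log(lam)) +
    sum(log(d_pendant(toy$pendant, lam, mu)))
  expect_equal(loglik_crbd(toy, lam, mu), manual)

  # log(lambda) terms dominate as lambda -> 0
  expect_gt(loglik_crbd(toy, 1e-3, 0.1), loglik_crbd(toy, 1e-6, 0.1))
  expect_error(loglik_crbd(branch_data(internal = 1, pendant = c(1, 1)), 1, 0.5),
               "'x'")
})

test_that("survival conditioning relates the two birth-death likelihoods", {
  toy <- classify_branches(ape::read.tree(text = "((A:1,B:1):1,C:2):0.5;"),
                           include_root_edge = TRUE)
  expect_equal(loglik_nee(toy, 1.3, 0), loglik_crbd(toy, 1.3, 0))
  for (mu in c(0.2, 0.5, 0.9)) {
    expect_gt(loglik_nee(toy, 1, mu), loglik_crbd(toy, 1, mu))
    expect_equal(loglik_nee(toy, 1, mu) - loglik_crbd(toy, 1, mu),
                 -2 * log(1 - extinct_prob(toy$x2, 1, mu)), tolerance = 1e-12)
  }
})

test_that("branch tables round-trip through the TSV reader", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "type\tlength\tx\tt",
               "internal\t1.5\t2.0\t4.0",
               "pendant\t2.0\tNA\t4.0",
               "pendant\t1.0\tNA\t4.0"), p)
  b <- read_branch_table(p)
  expect_equal(b$internal, 1.5)
  expect_equal(sort(b$pendant), c(1, 2))
  expect_equal(b$x, 2)
  expect_equal(b$t, 4)
  expect_equal(b$x2, 3.5)
})
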