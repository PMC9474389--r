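#' Akaike information criterion
#'
#' @param p Number of free parameters.
#' @param logL Maximised log-likelihood.
#' @return `2 * p - 2 * logL`.
#' @examples
#' aic(5, -16727.93)  # 33465.86
#' @export
aic <- function(p, logL) 2 * p - 2 * logL

model_npar <- function(family, n_phases = NA_integer_) {
  switch(family,
    exponential = 1L,
    weibull = 2L,
    crbd = 2L,
    ph_dec = 3L,
    ph_inc = 3L,
    coxian = 2L * as.integer(n_phases) - 1L,
    stop("unknown family: ", family)
  )
}

model_label <- function(family, n_phases = NA_integer_) {
  switch(family,
    exponential = "Exponential",
    weibull = "Weibull",
    crbd = "Constant-rate birth-death",
    ph_dec = "PH_Dec",
    ph_inc = "PH_Inc",
    coxian = paste("General Coxian PH", n_phases)
  )
}

# family-specific transforms between the unconstrained optimiser space and
# natural parameters
par_to_natural <- function(theta, family, n_phases) {
  switch(family,
    exponential = list(lambda = exp(theta[1L])),
    weibull = list(psi = exp(theta[1L]), phi = exp(theta[2L])),
    crbd = list(lambda = exp(theta[1L]), mu = exp(theta[2L])),
    ph_dec = ,
    ph_inc = list(x = stats::plogis(theta[1L]), y = stats::plogis(theta[2L]),
                  z = 2 + exp(theta[3L])),
    coxian = list(lambdas = exp(theta[seq_len(n_phases)]),
                  ps = if (n_phases > 1L)
                    stats::plogis(theta[n_phases + seq_len(n_phases - 1L)])
                  else numeric(0))
  )
}

natural_to_dist <- function(nat, family) {
  switch(family,
    ph_dec = ph_dec(nat$x, nat$y, nat$z),
    ph_inc = ph_inc(nat$x, nat$y, nat$z),
    coxian = coxian_ph(nat$lambdas, nat$ps),
    NULL
  )
}

random_starts <- function(family, n_phases, n_starts, rate_scale) {
  lr <- log(rate_scale)
  one <- function() switch(family,
    exponential = lr + stats::runif(1, -2, 2),
    weibull = c(stats::runif(1, -1.2, 1.2), -lr + stats::runif(1, -2, 2)),
    crbd = {
      a <- lr + stats::runif(1, -1.5, 1.5)
      c(a, a - stats::runif(1, 0.5, 4))
    },
    ph_dec = ,
    ph_inc = c(stats::runif(2, -2.5, 2.5), stats::runif(1, -2, 3)),
    coxian = c(lr + stats::runif(n_phases, -2.5, 2.5),
               stats::runif(n_phases - 1L, -2.5, 2.5))
  )
  lapply(seq_len(n_starts), function(i) one())
}

as_branch_list <- function(data, include_root_edge = FALSE) {
  if (inherits(data, "branch_data")) return(list(data))
  if (is.list(data) && length(data) && all(vapply(data, inherits, logical(1), "branch_data")))
    return(data)
  lapply(as_phylo_list(data), classify_branches, include_root_edge = include_root_edge)
}

#' Fit a waiting-time model to branch-length data by maximum likelihood
#'
#' Maximises the tree(set) log-likelihood of the chosen family over an
#' unconstrained transformed parameter space (log for rates and for
#' `z - 2`, logit for probabilities), using multi-start bounded
#' quasi-Newton optimisation (`optim` with L-BFGS-B) followed by a
#' derivative-free simplex polish (Nelder-Mead) of the best start.
#' Phase-type, exponential and Weibull families use the pure-birth
#' likelihood without the tip-permutation factor; the constant-rate
#' birth-death family uses its survival-free likelihood including the
#' factor (the difference is removed again in [model_table]).
#'
#' @param data A [branch_data] object, a list of them, or trees
#'   (`phylo`/`sim_tree`, possibly in a list) which are classified first.
#' @param family One of `"coxian"`, `"ph_dec"`, `"ph_inc"`,
#'   `"exponential"`, `"weibull"`, `"crbd"`.
#' @param n_phases Number of phases for the general Coxian family.
#' @param n_starts Number of random starting points.
#' @param include_root_edge Passed to [classify_branches] when `data` are
#'   trees (the `crbd` family always uses the root-edge convention).
#' @return An object of class `ph_fit`: `family`, `params` (natural scale),
#'   `dist` (a [coxian_ph] for phase-type families), `logL`, `npar`, `aic`,
#'   `boundary` flags, per-start diagnostics in `starts`, and bookkeeping
#'   (`n_trees`, `k`, `ell`, `sum_lfact`, `tip_counts`).
#' @examples
#' set.seed(1)
#' trees <- simulate_trees(wt_model("exponential", rate = 1), 20, 5)
#' fit <- fit_model(trees, "exponential", n_starts = 5)
#' fit$params$lambda
#' @export
fit_model <- function(data,
                      family = c("coxian", "ph_dec", "ph_inc",
                                 "exponential", "weibull", "crbd"),
                      n_phases = 4L, n_starts = 20L,
                      include_root_edge = FALSE) {
  family <- match.arg(family)
  if (family == "coxian" && !(n_phases >= 1L))
    stop("'n_phases' must be a positive integer")
  bs <- as_branch_list(data, include_root_edge = include_root_edge ||
                         family == "crbd")
  k_tot <- sum(vapply(bs, function(b) b$k, numeric(1)))
  len_tot <- sum(vapply(bs, function(b) sum(b$internal) + sum(b$pendant), numeric(1)))
  rate_scale <- max(k_tot, 1) / len_tot

  negll <- function(theta) {
    nat <- par_to_natural(theta, family, n_phases)
    ll <- switch(family,
      exponential = sum(vapply(bs, loglik_exp, numeric(1), lambda = nat$lambda)),
      weibull = sum(vapply(bs, loglik_weibull, numeric(1),
                           psi = nat$psi, phi = nat$phi)),
      crbd = sum(vapply(bs, loglik_crbd, numeric(1),
                        lambda = nat$lambda, mu = nat$mu)),
      loglik_treeset(bs, natural_to_dist(nat, family))
    )
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  starts <- random_starts(family, n_phases, n_starts, rate_scale)
  runs <- lapply(starts, function(s) {
    tryCatch({
      o <- stats::optim(s, negll, method = "L-BFGS-B",
                        control = list(maxit = 500L, factr = 1e7))
      list(par = o$par, value = o$value, convergence = o$convergence)
    }, error = function(e) list(par = s, value = Inf, convergence = 99L))
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  if (all(!is.finite(vals))) stop("all ", n_starts, " optimisation starts failed")
  best_vals <- which(vals <= min(vals) + 1e-6)
  norms <- vapply(runs[best_vals], function(r) sum(r$par^2), numeric(1))
  best <- runs[[best_vals[which.min(norms)]]]

  if (length(best$par) >= 2L) {
    polish <- tryCatch(
      stats::optim(best$par, negll, method = "Nelder-Mead",
                   control = list(maxit = 2000L, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value)
      best <- list(par = polish$par, value = polish$value,
                   convergence = polish$convergence)
  }

  nat <- par_to_natural(best$par, family, n_phases)
  boundary <- abs(best$par) > 8
  names(boundary) <- paste0("theta", seq_along(best$par))
  ells <- vapply(bs, function(b) b$ell, numeric(1))
  structure(
    list(family = family, n_phases = if (family == "coxian") as.integer(n_phases) else NA_integer_,
         params = nat, dist = natural_to_dist(nat, family),
         logL = -best$value,
         npar = model_npar(family, n_phases),
         aic = aic(model_npar(family, n_phases), -best$value),
         perm_included = family == "crbd",
         boundary = boundary, convergence = best$convergence,
         n_trees = length(bs), k = k_tot, ell = sum(ells),
         tip_counts = as.integer(ells), sum_lfact = sum(lfactorial(ells - 1)),
         n_starts = n_starts,
         starts = data.frame(start = seq_along(vals), neg_loglik = vals,
                             convergence = vapply(runs, `[[`, numeric(1), "convergence"))),
    class = "ph_fit"
  )
}

#' @export
print.ph_fit <- function(x, ...) {
  cat("Maximum-likelihood fit:", model_label(x$family, x$n_phases), "\n")
  cat("  parameters:", paste(names(unlist(x$params)),
                             format(unlist(x$params), digits = 5),
                             sep = " = ", collapse = ", "), "\n")
  cat("  logL:", format(x$logL, digits = 8), " npar:", x$npar,
      " AIC:", format(x$aic, digits = 8), "\n")
  if (any(x$boundary)) cat("  note: parameter(s) at a transform boundary:",
                           paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' Model-comparison table
#'
#' Collects fits of competing families into a table sorted by AIC with the
#' difference from the best model. Because the birth-death likelihood
#' carries the tip-permutation factor that the pure-birth likelihoods omit,
#' `log((ell - 1)!)` (summed over trees) is subtracted from birth-death
#' log-likelihoods before comparison, so all rows are on the same footing.
#'
#' @param fits A list of [fit_model] results on the same data.
#' @return A data frame of class `model_table` with columns `model`,
#'   `n_branches`, `n_parameters`, `logL`, `AIC`, `delta_AIC`, sorted by
#'   AIC (best first, `delta_AIC = 0`).
#' @export
model_table <- function(fits) {
  if (inherits(fits, "ph_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "ph_fit")))
  rows <- lapply(fits, function(f) {
    ll <- if (f$perm_included) f$logL - f$sum_lfact else f$logL
    data.frame(model = model_label(f$family, f$n_phases),
               n_branches = f$k + f$ell,
               n_parameters = f$npar,
               logL = ll,
               AIC = aic(f$npar, ll))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$delta_AIC <- tab$AIC - tab$AIC[1L]
  rownames(tab) <- NULL
  class(tab) <- c("model_table", "data.frame")
  tab
}

fitted_wt_models <- function(fit) {
  switch(fit$family,
    exponential = list(speciation = wt_model("exponential", rate = fit$params$lambda),
                       extinction = NULL),
    weibull = list(speciation = wt_model("weibull", psi = fit$params$psi,
                                         phi = fit$params$phi),
                   extinction = NULL),
    crbd = list(speciation = wt_model("exponential", rate = fit$params$lambda),
                extinction = if (fit$params$mu > 0)
                  wt_model("exponential", rate = fit$params$mu) else NULL),
    list(speciation = wt_model("coxian", dist = fit$dist), extinction = NULL)
  )
}

pooled_log_lengths <- function(trees) {
  len <- unlist(lapply(as_phylo_list(trees), `[[`, "edge.length"))
  keep <- len > 0
  structure(log(len[keep]), n_dropped = sum(!keep))
}

#' Goodness of fit by simulation and the Kolmogorov-Smirnov test
#'
#' Simulates `n_sim` trees from the fitted model (pure birth for the
#' speciation-only families; speciation plus extinction for the birth-death
#' family), matching the tip counts of the source trees (recycled), pools
#' the log branch lengths of the simulated reconstructed trees, and runs a
#' two-sample KS test against the log branch lengths of the source trees.
#' Zero-length branches are dropped before taking logs (counts reported).
#'
#' @param trees Source trees (`phylo`/`sim_tree`, possibly in a list).
#' @param fit A [fit_model] result.
#' @param n_sim Number of trees to simulate from the fitted model.
#' @return A list with `statistic` (KS distance), `p_value`, `n_data`,
#'   `n_sim_branches`, and dropped-branch counts.
#' @export
gof_ks <- function(trees, fit, n_sim = 10L) {
  stopifnot(inherits(fit, "ph_fit"))
  trees <- as_phylo_list(trees)
  emp <- pooled_log_lengths(trees)
  tips <- vapply(trees, ape::Ntip, integer(1))
  mods <- fitted_wt_models(fit)
  sim <- lapply(seq_len(n_sim), function(i) {
    nt <- tips[(i - 1L) %% length(tips) + 1L]
    simulate_tree(mods$speciation, nt, extinction = mods$extinction)$recon
  })
  simlog <- pooled_log_lengths(sim)
  ks <- suppressWarnings(stats::ks.test(emp, simlog))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       n_data = length(emp), n_sim_branches = length(simlog),
       n_dropped_data = attr(emp, "n_dropped"),
       n_dropped_sim = attr(simlog, "n_dropped"))
}

#' Hazard-rate profile of a fitted model
#'
#' Evaluates the instantaneous speciation rate of the fitted waiting-time
#' distribution on a time grid: constant `lambda` for exponential and
#' birth-death fits, `(psi/phi) (t/phi)^(psi-1)` for Weibull, and the
#' phase-type hazard `alpha e^{Qt} q / (alpha e^{Qt} 1)` for the Coxian
#' families. With `scale_by_tree_height = TRUE` the grid is interpreted in
#' units of tree height.
#'
#' @param fit A [fit_model] result.
#' @param t_grid Time grid (non-negative, increasing).
#' @param scale_by_tree_height Interpret `t_grid` as fractions of
#'   `tree_height`.
#' @param tree_height Tree height used when scaling.
#' @return A data frame with columns `time` (as supplied) and `hazard`.
#' @export
hazard_profile <- function(fit, t_grid, scale_by_tree_height = FALSE,
                           tree_height = NULL) {
  stopifnot(inherits(fit, "ph_fit"))
  tt <- as.numeric(t_grid)
  if (any(tt < 0)) stop("'t_grid' must be non-negative")
  te <- if (scale_by_tree_height) {
    if (is.null(tree_height)) stop("'tree_height' needed when scaling")
    tt * tree_height
  } else tt
  h <- switch(fit$family,
    exponential = rep(fit$params$lambda, length(te)),
    crbd = rep(fit$params$lambda, length(te)),
    weibull = (fit$params$psi / fit$params$phi) *
      (te / fit$params$phi)^(fit$params$psi - 1),
    ph_hazard(fit$dist, te)
  )
  data.frame(time = tt, hazard = h)
}
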