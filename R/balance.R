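#' Harvest subtree splits from one or more trees
#'
#' For every internal node whose subtree has at least four tips, records the
#' pair `(n, i)`: the subtree tip count and the tip count of the
#' first-listed child. Subtrees of size 2 or 3 admit only one division of
#' the tips and carry no information about balance, so they are skipped.
#' Records are pooled across trees.
#'
#' @param trees A `phylo`, `sim_tree`, or list of either (rooted, binary).
#' @return A `split_set`: a data frame with columns `n` and `i` and an
#'   attribute `n_trees`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' extract_splits(tr)  # one record: n = 4, i = 2
#' @export
extract_splits <- function(trees) {
  trees <- as_phylo_list(trees)
  recs <- lapply(trees, function(tree) {
    if (!ape::is.rooted(tree) || !ape::is.binary.phylo(tree))
      stop("trees must be rooted and binary")
    tree <- ape::reorder.phylo(tree, "postorder")
    ntip <- ape::Ntip(tree)
    ndesc <- c(rep(1L, ntip), integer(tree$Nnode))
    first <- integer(ntip + tree$Nnode)  # tip count of first-listed child
    for (r in seq_len(nrow(tree$edge))) {
      a <- tree$edge[r, 1L]; b <- tree$edge[r, 2L]
      if (first[a] == 0L) first[a] <- ndesc[b]
      ndesc[a] <- ndesc[a] + ndesc[b]
    }
    nodes <- ntip + seq_len(tree$Nnode)
    keep <- ndesc[nodes] >= 4L
    data.frame(n = ndesc[nodes][keep], i = first[nodes][keep])
  })
  out <- do.call(rbind, recs)
  # postorder lists children in reverse cladewise order; i <-> n - i symmetry
  # of the split distribution makes the choice immaterial
  structure(out, n_trees = length(trees), class = c("split_set", "data.frame"))
}

#' Split probabilities under the beta-splitting model
#'
#' `log_qn_exact` evaluates, in log space via `lgamma`, the probability that
#' a subtree with `n` tips puts `i` of them on the left under the
#' beta-splitting model:
#' `q_n(i, beta) = Gamma(beta+i+1) Gamma(beta+n-i+1) /
#' (a_n(beta) Gamma(i+1) Gamma(n-i+1))`, with `a_n(beta)` normalising over
#' `i = 1, ..., n-1`. `log_qn_approx` uses the large-`n` surrogate
#' `(i/n)^beta (1-i/n)^beta`, again normalised. At `beta = 0` both are the
#' uniform distribution on `1:(n-1)`.
#'
#' @param n Subtree tip count (>= 4).
#' @param i Left-child tip count(s), each in `1:(n-1)`.
#' @param beta Balance parameter; `> -2` for the exact form.
#' @return Log-probabilities, one per element of `i`.
#' @export
log_qn_exact <- function(n, i, beta) {
  if (beta <= -2) stop("'beta' must be > -2 for the exact split probabilities")
  if (any(i < 1) || any(i > n - 1)) stop("'i' must lie in 1:(n-1)")
  num <- function(j) lgamma(beta + j + 1) + lgamma(beta + n - j + 1) -
    lgamma(j + 1) - lgamma(n - j + 1)
  all_i <- seq_len(n - 1)
  log_a <- log_sum_exp(num(all_i))
  num(i) - log_a
}

#' @rdname log_qn_exact
#' @export
log_qn_approx <- function(n, i, beta) {
  if (any(i < 1) || any(i > n - 1)) stop("'i' must lie in 1:(n-1)")
  num <- function(j) beta * (log(j / n) + log(1 - j / n))
  all_i <- seq_len(n - 1)
  log_a <- log_sum_exp(num(all_i))
  num(i) - log_a
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Pooled log-likelihood of a split set at a given beta. Splits are grouped
# by subtree size so each normalising constant is computed once; the (n, i)
# count table is built once per split set and cached on the optimiser side.
split_counts <- function(splits) {
  agg <- stats::aggregate(list(count = rep(1L, nrow(splits))),
                          by = list(n = splits$n, i = splits$i), FUN = sum)
  split(agg[c("i", "count")], agg$n)
}

beta_loglik_counts <- function(counts, beta, use_approx_above = 200L) {
  ll <- 0
  for (nn_chr in names(counts)) {
    nn <- as.integer(nn_chr)
    grp <- counts[[nn_chr]]
    lq <- if (nn > use_approx_above) log_qn_approx(nn, grp$i, beta)
          else log_qn_exact(nn, grp$i, beta)
    ll <- ll + sum(grp$count * lq)
  }
  ll
}

beta_loglik <- function(splits, beta, use_approx_above = 200L) {
  beta_loglik_counts(split_counts(splits), beta, use_approx_above)
}

BETA_LOWER <- -2 + 1e-6
BETA_UPPER <- 10

#' Maximum-likelihood estimate of the balance parameter beta
#'
#' Maximises the pooled log-likelihood of the observed splits over
#' `beta` in `[-2 + 1e-6, 10]` by bounded scalar optimisation. Subtrees
#' larger than `use_approx_above` tips use the approximate split
#' probabilities ([log_qn_approx]); all others the exact log-gamma form.
#' Optima at the search boundary are flagged in the `boundary` field.
#'
#' @param splits A `split_set` from [extract_splits].
#' @param use_approx_above Subtree size above which the approximate form is
#'   used (the exact form is numerically safe well beyond this in log space;
#'   the switch-over mainly saves time on very large subtrees).
#' @return An object of class `beta_estimate` with `beta_hat`, `loglik`,
#'   `n_splits`, `boundary`, and (after [beta_ci]) `se`, `lower`, `upper`.
#' @export
beta_mle <- function(splits, use_approx_above = 200L) {
  if (is.null(splits) || nrow(splits) == 0L) stop("empty split set")
  counts <- split_counts(splits)
  f <- function(b) beta_loglik_counts(counts, b, use_approx_above)
  opt <- stats::optimize(f, interval = c(BETA_LOWER, BETA_UPPER), maximum = TRUE,
                         tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(BETA_LOWER, f(BETA_LOWER)),
                c(BETA_UPPER, f(BETA_UPPER)))
  best <- cand[which.max(cand[, 2L]), ]
  boundary <- best[1L] <= BETA_LOWER || best[1L] >= BETA_UPPER
  structure(
    list(beta_hat = best[1L], loglik = best[2L], n_splits = nrow(splits),
         boundary = boundary, se = NA_real_, lower = NA_real_, upper = NA_real_,
         use_approx_above = use_approx_above),
    class = "beta_estimate"
  )
}

#' Profile 95% confidence interval for the beta estimate
#'
#' The standard error is `1 / sqrt(I(beta_hat))` with the observed Fisher
#' information `I` taken as the negative central second difference of the
#' log-likelihood at the optimum. Each bound is then located on a grid of
#' 500 equidistant points between `beta_hat - 5 SE` and `beta_hat` (lower)
#' and between `beta_hat` and `beta_hat + 5 SE` (upper), at the point whose
#' log-likelihood is closest to the maximum minus half the 0.95
#' chi-square(1) quantile (about 1.9207). Bounds are clipped to the search
#' range; a flat likelihood yields the full range with a warning.
#'
#' @param splits The `split_set` the estimate was computed from.
#' @param est A `beta_estimate` from [beta_mle].
#' @return The estimate updated with `se`, `lower` and `upper`.
#' @export
beta_ci <- function(splits, est) {
  stopifnot(inherits(est, "beta_estimate"))
  counts <- split_counts(splits)
  f <- function(b) beta_loglik_counts(counts, b, est$use_approx_above)
  b0 <- est$beta_hat
  h <- 1e-3 * max(1, abs(b0))
  info <- -(f(min(b0 + h, BETA_UPPER)) - 2 * f(b0) + f(max(b0 - h, BETA_LOWER))) / h^2
  if (!is.finite(info) || info <= 0) {
    warning("non-positive curvature at the optimum; reporting the full search range")
    est$se <- NA_real_
    est$lower <- BETA_LOWER
    est$upper <- BETA_UPPER
    return(est)
  }
  est$se <- 1 / sqrt(info)
  cut <- est$loglik - stats::qchisq(0.95, df = 1) / 2
  locate <- function(from, to) {
    grid <- seq(from, to, length.out = 500L)
    grid <- pmin(pmax(grid, BETA_LOWER), BETA_UPPER)
    ll <- vapply(grid, f, numeric(1))
    grid[which.min(abs(ll - cut))]
  }
  est$lower <- locate(b0 - 5 * est$se, b0)
  est$upper <- locate(b0, b0 + 5 * est$se)
  est
}

#' @export
print.beta_estimate <- function(x, ...) {
  cat("beta estimate:", format(x$beta_hat, digits = 5),
      if (x$boundary) "(boundary)" else "", "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " splits:", x$n_splits, "\n")
  if (is.finite(x$se))
    cat("  SE:", format(x$se, digits = 4), "  95% CI: [",
        format(x$lower, digits = 5), ",", format(x$upper, digits = 5), "]\n")
  invisible(x)
}

#' The gamma statistic of node-time spacing
#'
#' With internode intervals `g_k` (the duration during which the
#' reconstructed tree has exactly `k` lineages, `k = 2, ..., n`) and
#' `T = sum_k k g_k`, the statistic is
#' `gamma = ((1/(n-2)) sum_{i=2}^{n-1} sum_{k=2}^{i} k g_k - T/2) /
#' (T sqrt(1/(12(n-2))))`.
#' Under a pure-birth process it has zero mean and approaches a standard
#' normal; negative values indicate that splits concentrate near the root.
#' Scaling all branch lengths by a positive constant leaves it unchanged.
#'
#' @param tree An ultrametric `phylo` (or `sim_tree`) with at least 3 tips.
#' @param tol Relative ultrametricity tolerance.
#' @return The gamma statistic (finite scalar).
#' @export
gamma_statistic <- function(tree, tol = 1e-8) {
  tree <- as_phylo_tree(tree)
  n <- ape::Ntip(tree)
  if (n < 3L) stop("need at least 3 tips")
  if (!is_ultrametric(tree, tol)) stop("tree is not ultrametric within tolerance")
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(n)])
  node_times <- sort(depths[n + seq_len(tree$Nnode)])  # root first, at 0
  g <- diff(c(node_times, height))  # g[k-1] = interval with k lineages
  kk <- 2:n
  T_total <- sum(kk * g)
  cum <- cumsum(kk * g)  # cum[i-1] = sum_{k=2}^{i} k g_k
  num <- sum(cum[seq_len(n - 2L)]) / (n - 2L) - T_total / 2
  num / (T_total * sqrt(1 / (12 * (n - 2L))))
}
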