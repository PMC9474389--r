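SURVIVAL_FLOOR <- 1e-300

#' Log-likelihood of a reconstructed tree under pure-birth phase-type speciation
#'
#' Each internal branch contributes the phase-type density at its length
#' (a speciation event ends it) and each pendant branch the survival
#' probability (no event is observed before the present):
#' `sum_i log(alpha e^{Q b_i} q) + sum_j log(alpha e^{Q btilde_j} 1)`.
#' With `with_permutations = TRUE` the combinatorial factor
#' `log((ell - 1)!)` for the distinguishable tip orderings is added.
#' Any branch whose density or survival falls below the numeric floor makes
#' the log-likelihood `-Inf` (with the offending counts attached as the
#' `"diagnostics"` attribute), never `NaN`.
#'
#' @param b A [branch_data] object.
#' @param d A [coxian_ph] distribution.
#' @param with_permutations Add `log((ell - 1)!)`.
#' @return Scalar log-likelihood.
#' @export
loglik_ph <- function(b, d, with_permutations = FALSE) {
  stopifnot(inherits(b, "branch_data"), inherits(d, "coxian_ph"))
  ll <- ph_tree_loglik_cpp(d$Q, d$q, matrix(d$alpha, nrow = 1),
                           b$internal, b$pendant, SURVIVAL_FLOOR)
  if (!is.finite(ll)) {
    phi_i <- ph_phi(d, b$internal)$dens
    phi_p <- ph_phi(d, b$pendant)$surv
    attr(ll, "diagnostics") <- list(
      n_internal_floored = sum(!(phi_i > SURVIVAL_FLOOR)),
      n_pendant_floored = sum(!(phi_p > SURVIVAL_FLOOR))
    )
  }
  if (with_permutations) ll <- ll + lfactorial(b$ell - 1)
  ll
}

#' Log-likelihood of a set of trees
#'
#' Trees are independent, so the treeset log-likelihood is the sum of the
#' per-tree values (the product of the per-tree likelihoods).
#'
#' @param bs A list of [branch_data] objects (or a single one).
#' @param d A [coxian_ph] distribution.
#' @param with_permutations Passed through to [loglik_ph].
#' @return Scalar log-likelihood.
#' @export
loglik_treeset <- function(bs, d, with_permutations = FALSE) {
  if (inherits(bs, "branch_data")) bs <- list(bs)
  sum(vapply(bs, function(b) as.numeric(loglik_ph(b, d, with_permutations)),
             numeric(1)))
}

#' Log-likelihoods under exponential and Weibull speciation waiting times
#'
#' Counterparts of [loglik_ph] for one-parameter exponential and
#' two-parameter Weibull waiting times: internal branches contribute the
#' density at their length, pendant branches the survival probability. For
#' the exponential this is `k log(lambda) - lambda * (sum b + sum btilde)`;
#' for the Weibull with shape `psi` and scale `phi` the density term is
#' `(psi/phi) (b/phi)^(psi-1) exp(-(b/phi)^psi)` and the survival term
#' `exp(-(btilde/phi)^psi)`. Weibull with `psi = 1` reduces to the
#' exponential with `lambda = 1/phi`.
#'
#' @param b A [branch_data] object.
#' @param lambda Exponential rate (> 0).
#' @return Scalar log-likelihood.
#' @export
loglik_exp <- function(b, lambda) {
  stopifnot(inherits(b, "branch_data"))
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be > 0")
  b$k * log(lambda) - lambda * (sum(b$internal) + sum(b$pendant))
}

#' @rdname loglik_exp
#' @param psi Weibull shape (> 0).
#' @param phi Weibull scale (> 0, time units).
#' @export
loglik_weibull <- function(b, psi, phi) {
  stopifnot(inherits(b, "branch_data"))
  if (!is.finite(psi) || psi <= 0 || !is.finite(phi) || phi <= 0)
    stop("'psi' and 'phi' must be > 0")
  dens <- log(psi / phi) + (psi - 1) * log(b$internal / phi) - (b$internal / phi)^psi
  surv <- -(b$pendant / phi)^psi
  sum(dens) + sum(surv)
}

#' Extinction probability under the constant-rate birth-death process
#'
#' Probability that a lineage born at time zero is extinct by time `z` under
#' constant speciation rate `lambda` and extinction rate `mu`:
#' `E(z) = (mu - mu e^{(mu-lambda) z}) / (lambda - mu e^{(mu-lambda) z})`.
#' At `mu = 0` this is 0; at `lambda = mu` the limit `lambda z /
#' (1 + lambda z)` is used.
#'
#' @param z Non-negative time(s).
#' @param lambda Speciation rate (> 0).
#' @param mu Extinction rate (>= 0).
#' @return Probabilities in `[0, 1)`.
#' @export
extinct_prob <- function(z, lambda, mu) {
  check_crbd(lambda, mu)
  if (any(z < 0)) stop("'z' must be non-negative")
  if (mu == 0) return(rep(0, length(z)))
  if (crbd_degenerate(lambda, mu)) return(lambda * z / (1 + lambda * z))
  e <- exp((mu - lambda) * z)
  (mu - mu * e) / (lambda - mu * e)
}

check_crbd <- function(lambda, mu) {
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be > 0")
  if (!is.finite(mu) || mu < 0) stop("'mu' must be >= 0")
  invisible(TRUE)
}

crbd_degenerate <- function(lambda, mu) abs(lambda - mu) < 1e-8 * lambda

#' Branch observation probabilities under the constant-rate birth-death process
#'
#' `g_branch` is the probability density contribution of a reconstructed
#' internal branch of length `b` whose end lies `x` time units before the
#' present:
#' `G_x(b) = ((lambda - mu e^{(mu-lambda) x}) /
#' (lambda - mu e^{(mu-lambda)(b+x)}))^2 e^{(mu-lambda) b}`.
#' `d_pendant` is the probability of observing a pendant branch of length
#' `z` with no surviving side lineages:
#' `D(z) = (((lambda - mu) e^{mu z}) / (lambda - mu e^{(mu-lambda) z}))^2
#' e^{-(lambda+mu) z}`.
#' Both equal 1 at length 0 and collapse to `exp(-lambda * length)` when
#' `mu = 0`; at `lambda = mu` their analytic limits are used.
#'
#' @param b,z Non-negative branch length(s).
#' @param x Elapsed time(s) from the end of the internal branch to the
#'   present.
#' @param lambda Speciation rate (> 0).
#' @param mu Extinction rate (>= 0).
#' @return Probability (density) values.
#' @export
g_branch <- function(b, x, lambda, mu) {
  check_crbd(lambda, mu)
  if (any(b < 0) || any(x < 0)) stop("'b' and 'x' must be non-negative")
  if (mu == 0) return(exp(-lambda * b))
  if (crbd_degenerate(lambda, mu))
    return(((1 + lambda * x) / (1 + lambda * (b + x)))^2)
  r <- mu - lambda
  ((lambda - mu * exp(r * x)) / (lambda - mu * exp(r * (b + x))))^2 * exp(r * b)
}

#' @rdname g_branch
#' @export
d_pendant <- function(z, lambda, mu) {
  check_crbd(lambda, mu)
  if (any(z < 0)) stop("'z' must be non-negative")
  if (mu == 0) return(exp(-lambda * z))
  if (crbd_degenerate(lambda, mu)) return(1 / (1 + lambda * z)^2)
  r <- mu - lambda
  (((lambda - mu) * exp(mu * z)) / (lambda - mu * exp(r * z)))^2 *
    exp(-(lambda + mu) * z)
}

#' Log-likelihood of a reconstructed tree under the constant-rate
#' birth-death process
#'
#' `loglik_crbd` assembles
#' `log((ell-1)!) + sum_i [log G_{x_i}(b_i) + log(lambda)] +
#' sum_j log D(btilde_j)`,
#' which requires the elapsed times `x_i` and uses the root-edge convention
#' (`k = ell - 1` internal branches). `loglik_nee` conditions on the
#' survival of both lineages descending from the root, adding
#' `-2 log(1 - E(x2))` where `x2` is the height of the root node above the
#' present; with `mu = 0` the two coincide.
#'
#' @param b A [branch_data] object carrying `x` (and `x2` for
#'   `loglik_nee`).
#' @param lambda Speciation rate (> 0).
#' @param mu Extinction rate (>= 0).
#' @return Scalar log-likelihood.
#' @export
loglik_crbd <- function(b, lambda, mu) {
  stopifnot(inherits(b, "branch_data"))
  check_crbd(lambda, mu)
  if (is.null(b$x)) stop("branch data lack the elapsed-to-present times 'x'")
  g <- g_branch(b$internal, b$x, lambda, mu)
  d <- d_pendant(b$pendant, lambda, mu)
  if (any(!(g > SURVIVAL_FLOOR)) || any(!(d > SURVIVAL_FLOOR))) return(-Inf)
  lfactorial(b$ell - 1) + sum(log(g) + log(lambda)) + sum(log(d))
}

#' @rdname loglik_crbd
#' @export
loglik_nee <- function(b, lambda, mu) {
  stopifnot(inherits(b, "branch_data"))
  if (!is.finite(b$x2)) stop("branch data lack the root-node height 'x2'")
  loglik_crbd(b, lambda, mu) - 2 * log(1 - extinct_prob(b$x2, lambda, mu))
}

#' Read a branch-length table
#'
#' Reads a TSV with columns `type` (`internal` or `pendant`), `length`, and
#' optionally `x` and `t`, as an alternative to [classify_branches] for
#' branch data from external sources. Lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return A [branch_data] object.
#' @export
read_branch_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("type", "length") %in% names(tab)))
    stop("branch table needs 'type' and 'length' columns")
  if (!all(tab$type %in% c("internal", "pendant")))
    stop("'type' must be 'internal' or 'pendant'")
  int <- tab$type == "internal"
  x <- if ("x" %in% names(tab)) tab$x[int] else NULL
  t_age <- if ("t" %in% names(tab)) tab$t[1] else NA_real_
  x2 <- if ("x" %in% names(tab) && any(int)) max(tab$x[int] + tab$length[int]) else NA_real_
  branch_data(internal = tab$length[int], pendant = tab$length[!int],
              x = x, t = t_age, x2 = x2)
}
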