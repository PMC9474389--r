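# shared fixtures built in code

# toy branch data: one internal branch of length 1, two pendants of length 1
toy_branches <- function() {
  branch_data(internal = 1, pendant = c(1, 1), x = 1, t = 2, x2 = 2)
}

# random valid (x, y, z) triples for the ph_dec / ph_inc families
random_xyz <- function(n) {
  data.frame(x = runif(n, 0.02, 1), y = runif(n, 0.02, 0.98),
             z = 2 + rexp(n, 1 / 5))
}

# ultrametric 3-tip tree with internode intervals g2 = g3 = 1
three_tip_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# minimal ph_fit carrying only what model_table needs
stub_fit <- function(family, npar, logL, ell = 50L, n_phases = NA_integer_,
                     perm = FALSE) {
  structure(list(family = family, n_phases = n_phases, params = list(),
                 dist = NULL, logL = logL, npar = npar, aic = aic(npar, logL),
                 perm_included = perm, boundary = logical(0),
                 convergence = 0L, n_trees = 1L, k = ell - 1L, ell = ell,
                 tip_counts = ell, sum_lfact = lfactorial(ell - 1),
                 n_starts = 0L, starts = NULL),
            class = "ph_fit")
}

# write a newick string to a temp file and return the path
textConnection_path <- function(txt) {
  p <- tempfile(fileext = ".nwk")
  writeLines(txt, p)
  p
}

# classic RK4 integrator, used as an independent ODE oracle
rk4 <- function(f, y0, times) {
  y <- numeric(length(times)); y[1] <- y0
  for (i in seq_len(length(times) - 1L)) {
    h <- times[i + 1L] - times[i]; t <- times[i]; yi <- y[i]
    k1 <- f(t, yi); k2 <- f(t + h / 2, yi + h / 2 * k1)
    k3 <- f(t + h / 2, yi + h / 2 * k2); k4 <- f(t + h, yi + h * k3)
    y[i + 1L] <- yi + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}
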