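#' Specify a waiting-time model for speciation or extinction
#'
#' Bundles a distribution family and its parameters into a model object the
#' simulator can draw waiting times from.
#'
#' @param family One of `"exponential"` (parameter `rate`), `"weibull"`
#'   (parameters `psi` = shape, `phi` = scale), `"coxian"` (either a
#'   [coxian_ph] object via `dist`, or `lambdas`/`ps`), `"ph_dec"` or
#'   `"ph_inc"` (parameters `x`, `y`, `z`).
#' @param ... Family parameters, see above.
#' @return An object of class `wt_model` with elements `family`, `params`
#'   and, for phase-type families, `dist`.
#' @examples
#' wt_model("exponential", rate = 1)
#' wt_model("ph_dec", x = 0.1, y = 0.93, z = 10)
#' @export
wt_model <- function(family = c("exponential", "weibull", "coxian", "ph_dec", "ph_inc"),
                     ...) {
  family <- match.arg(family)
  p <- list(...)
  m <- switch(family,
    exponential = {
      rate <- p$rate %||% p[[1]]
      stopifnot(is.finite(rate), rate > 0)
      list(family = family, params = list(rate = rate))
    },
    weibull = {
      psi <- p$psi %||% p$shape
      phi <- p$phi %||% p$scale
      stopifnot(is.finite(psi), psi > 0, is.finite(phi), phi > 0)
      list(family = family, params = list(psi = psi, phi = phi))
    },
    coxian = {
      d <- if (!is.null(p$dist)) p$dist else coxian_ph(p$lambdas, p$ps %||% numeric(0))
      stopifnot(inherits(d, "coxian_ph"))
      list(family = family, params = list(lambdas = -diag(d$Q),
                                          ps = ph_continuation(d)),
           dist = d)
    },
    ph_dec = {
      d <- ph_dec(p$x, p$y, p$z)
      list(family = family, params = as.list(d$params), dist = d)
    },
    ph_inc = {
      d <- ph_inc(p$x, p$y, p$z)
      list(family = family, params = as.list(d$params), dist = d)
    }
  )
  structure(m, class = "wt_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ph_continuation <- function(d) {
  if (d$n == 1L) return(numeric(0))
  lam <- -diag(d$Q)
  d$Q[cbind(seq_len(d$n - 1L), seq_len(d$n - 1L) + 1L)] / lam[-d$n]
}

as_wt_model <- function(m) {
  if (inherits(m, "wt_model")) return(m)
  if (inherits(m, "coxian_ph")) return(wt_model("coxian", dist = m))
  stop("expected a 'wt_model' or 'coxian_ph' object")
}

wt_sampler <- function(m) {
  m <- as_wt_model(m)
  switch(m$family,
    exponential = function(k) stats::rexp(k, rate = m$params$rate),
    weibull = function(k) stats::rweibull(k, shape = m$params$psi, scale = m$params$phi),
    function(k) ph_sample(m$dist, k)
  )
}

#' Simulate a species tree forward in time
#'
#' Grows a binary tree from a single origin lineage. Each lineage carries a
#' pending speciation time drawn from `speciation` and, if `extinction` is
#' given, a pending extinction time; whichever is earlier fires. Under
#' symmetric speciation both daughters are new lineages of age 0 with fresh
#' draws; under asymmetric speciation the parent persists (keeping its
#' pending extinction time and drawing a fresh waiting time to its next
#' speciation) while one new daughter of age 0 draws both afresh. The
#' simulation stops when the number of simultaneously extant lineages first
#' reaches `n_tips`; the present is then set at the epoch of the next
#' scheduled event, so every pendant branch has strictly positive length.
#' A tree in which all lineages die is discarded and the simulation
#' restarts (up to `max_retries` times, with the retry count recorded).
#'
#' @param speciation A [wt_model] (or [coxian_ph]) for waiting times to
#'   speciation.
#' @param n_tips Target number of extant tips (>= 2).
#' @param extinction Optional [wt_model] for waiting times to extinction;
#'   `NULL` for a pure-birth process.
#' @param mode `"symmetric"` or `"asymmetric"` speciation.
#' @param max_retries Retry budget when the whole tree goes extinct.
#' @return An object of class `sim_tree` with components `phylo` (the
#'   original tree including extinct lineages, with the origin branch as
#'   `root.edge`), `extant` (logical per tip of `phylo`), `recon` (the
#'   reconstructed, ultrametric tree of extant tips only), `events` (the
#'   per-lineage event log), `age` (time from origin to present), `mode`,
#'   and `retries`.
#' @examples
#' set.seed(1)
#' tr <- simulate_tree(wt_model("exponential", rate = 1), n_tips = 10)
#' ape::Ntip(tr$recon)  # 10
#' @export
simulate_tree <- function(speciation, n_tips, extinction = NULL,
                          mode = c("symmetric", "asymmetric"),
                          max_retries = 1000L) {
  mode <- match.arg(mode)
  n_tips <- as.integer(n_tips)
  if (n_tips < 2L) stop("'n_tips' must be at least 2")
  speciation <- as_wt_model(speciation)
  if (!is.null(extinction)) extinction <- as_wt_model(extinction)
  draw_sp <- wt_sampler(speciation)
  draw_ex <- if (is.null(extinction)) function(k) rep(Inf, k) else wt_sampler(extinction)

  retries <- 0L
  repeat {
    seg <- sim_once(draw_sp, draw_ex, n_tips, mode)
    if (!is.null(seg)) break
    retries <- retries + 1L
    if (retries > max_retries)
      stop("whole-tree extinction in every attempt (", retries, " retries)")
  }

  orig <- segments_to_phylo(seg, reconstructed = FALSE)
  recon <- segments_to_phylo(seg, reconstructed = TRUE)
  structure(
    list(phylo = orig$phylo, extant = orig$extant, recon = recon$phylo,
         events = as.data.frame(seg[c("parent", "birth", "end", "status")]),
         age = seg$stop_time, mode = mode,
         speciation = speciation, extinction = extinction,
         retries = retries),
    class = "sim_tree"
  )
}

# One forward pass; returns NULL if the tree dies out.
# Segment status codes: 1 = split, 2 = extinct, 3 = extant at the present.
sim_once <- function(draw_sp, draw_ex, n_tips, mode) {
  cap <- 4L * n_tips + 8L
  parent <- integer(cap); birth <- numeric(cap); endt <- numeric(cap)
  status <- integer(cap)
  nseg <- 1L
  parent[1L] <- 0L; birth[1L] <- 0

  grow <- function() {
    cap2 <- 2L * length(parent)
    length(parent) <<- cap2; length(birth) <<- cap2
    length(endt) <<- cap2; length(status) <<- cap2
    parent[is.na(parent)] <<- 0L
  }

  active <- 1L
  asp <- draw_sp(1L)
  aex <- draw_ex(1L)

  repeat {
    k <- length(active)
    if (k == 0L) return(NULL)
    if (k == n_tips) {
      stop_time <- min(asp, aex)
      endt[active] <- stop_time
      status[active] <- 3L
      break
    }
    ev <- pmin(asp, aex)
    j <- which.min(ev)
    te <- ev[j]
    id <- active[j]
    if (nseg + 2L > length(parent)) grow()
    if (asp[j] <= aex[j]) {
      status[id] <- 1L; endt[id] <- te
      c1 <- nseg + 1L; c2 <- nseg + 2L; nseg <- nseg + 2L
      parent[c(c1, c2)] <- id; birth[c(c1, c2)] <- te
      if (mode == "symmetric") {
        nsp <- te + draw_sp(2L); nex <- te + draw_ex(2L)
      } else {
        # c1 continues the parent: extinction clock unchanged, fresh
        # speciation waiting time; c2 is the newborn daughter
        nsp <- c(te + draw_sp(1L), te + draw_sp(1L))
        nex <- c(aex[j], te + draw_ex(1L))
      }
      active[j] <- c1; asp[j] <- nsp[1L]; aex[j] <- nex[1L]
      active <- c(active, c2); asp <- c(asp, nsp[2L]); aex <- c(aex, nex[2L])
    } else {
      status[id] <- 2L; endt[id] <- te
      active <- active[-j]; asp <- asp[-j]; aex <- aex[-j]
    }
  }

  list(parent = parent[seq_len(nseg)], birth = birth[seq_len(nseg)],
       end = endt[seq_len(nseg)], status = status[seq_len(nseg)],
       stop_time = stop_time)
}

# Build an ape phylo from the segment log. reconstructed = TRUE prunes
# lineages with no extant descendants and suppresses unary nodes, summing
# branch lengths; the path from the origin to the (reconstructed) root node
# is stored as root.edge.
segments_to_phylo <- function(seg, reconstructed) {
  n <- length(seg$parent)
  if (reconstructed) {
    cnt <- as.integer(seg$status == 3L)
    for (i in n:1) if (seg$parent[i] > 0L) cnt[seg$parent[i]] <- cnt[seg$parent[i]] + cnt[i]
    child_of <- split(seq_len(n), factor(seg$parent, levels = 0:n))
    is_kept_split <- vapply(seq_len(n), function(s) {
      if (seg$status[s] != 1L) return(FALSE)
      kids <- child_of[[s + 1L]]
      sum(cnt[kids] > 0L) == 2L
    }, logical(1))
    is_tip <- seg$status == 3L
  } else {
    is_kept_split <- seg$status == 1L
    is_tip <- seg$status %in% c(2L, 3L)
  }

  tips <- which(is_tip)
  splits <- which(is_kept_split)
  ntip <- length(tips)
  if (ntip < 2L) stop("fewer than 2 extant tips; cannot build a tree")
  stopifnot(length(splits) == ntip - 1L)

  node_id <- integer(n)
  node_id[tips] <- seq_len(ntip)
  # root (oldest kept split) must get number ntip + 1 for ape
  splits <- splits[order(seg$birth[splits])]
  node_id[splits] <- ntip + seq_along(splits)

  kept <- c(tips, splits)
  edge <- matrix(0L, nrow = length(kept) - 1L, ncol = 2L)
  elen <- numeric(length(kept) - 1L)
  root_edge <- NA_real_
  r <- 0L
  for (e in kept) {
    len <- seg$end[e] - seg$birth[e]
    a <- seg$parent[e]
    while (a > 0L && !is_kept_split[a]) {  # unary in the reconstructed view
      len <- len + seg$end[a] - seg$birth[a]
      a <- seg$parent[a]
    }
    if (a == 0L) {
      root_edge <- len  # e is the root split; len spans origin -> root node
    } else {
      r <- r + 1L
      edge[r, ] <- c(node_id[a], node_id[e])
      elen[r] <- len
    }
  }
  stopifnot(r == nrow(edge))

  phy <- structure(
    list(edge = edge, edge.length = elen, tip.label = paste0("t", seq_len(ntip)),
         Nnode = ntip - 1L),
    class = "phylo", order = NULL
  )
  if (is.finite(root_edge) && root_edge > 0) phy$root.edge <- root_edge
  phy <- ape::reorder.phylo(phy, "cladewise")
  list(phylo = phy, extant = seg$status[tips] == 3L)
}

#' @export
print.sim_tree <- function(x, ...) {
  cat("Simulated species tree (", x$mode, " speciation)\n", sep = "")
  cat("  extant tips:", sum(x$extant), " extinct tips:", sum(!x$extant), "\n")
  cat("  age:", format(x$age, digits = 6), " retries:", x$retries, "\n")
  invisible(x)
}

#' Simulate a set of species trees
#'
#' @inheritParams simulate_tree
#' @param n_trees Number of independent trees.
#' @return A list of [simulate_tree] results.
#' @export
simulate_trees <- function(speciation, n_tips, n_trees, extinction = NULL,
                           mode = c("symmetric", "asymmetric"),
                           max_retries = 1000L) {
  mode <- match.arg(mode)
  lapply(seq_len(n_trees), function(i)
    simulate_tree(speciation, n_tips, extinction, mode, max_retries))
}

#' Extract the reconstructed tree of extant lineages
#'
#' Returns the tree containing only lineages ancestral to extant tips, with
#' extinct subtrees pruned and unary nodes suppressed (their branch lengths
#' summed). Root-to-tip distances of surviving tips are preserved, so the
#' result is ultrametric.
#'
#' @param x A `sim_tree` object.
#' @return An `ape::phylo` tree (with `root.edge` holding the path from the
#'   origin to the root node).
#' @export
reconstructed <- function(x) {
  stopifnot(inherits(x, "sim_tree"))
  x$recon
}

as_phylo_tree <- function(x) {
  if (inherits(x, "sim_tree")) return(x$recon)
  if (inherits(x, "phylo")) return(x)
  stop("expected a 'phylo' or 'sim_tree' object")
}

as_phylo_list <- function(trees) {
  if (inherits(trees, c("phylo", "sim_tree"))) trees <- list(trees)
  lapply(trees, as_phylo_tree)
}

#' Check whether a tree is ultrametric
#'
#' @param tree An `ape::phylo` tree.
#' @param tol Relative tolerance on tip depths.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-9) {
  d <- tip_depths(tree)
  diff(range(d)) <= tol * max(d)
}

tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_len(ape::Ntip(tree))]
}

#' Classify the branches of a reconstructed tree
#'
#' Splits the edges of a rooted binary tree into pendant branches (ending in
#' a tip) and internal branches, recording for each internal branch the
#' elapsed time `x` from its end to the present and the tree age `t`. With
#' `include_root_edge = TRUE` a stored root edge is counted as an internal
#' branch, so that the number of internal branches is one less than the
#' number of tips.
#'
#' @param tree An `ape::phylo` tree or a `sim_tree` (its reconstructed view
#'   is used).
#' @param include_root_edge Count the root edge (if present) as internal.
#' @return An object of class `branch_data`: a list with `internal` and
#'   `pendant` branch lengths, `x` (aligned with `internal`), tree age `t`,
#'   `x2` (height of the root node above the present, used by the
#'   survival-conditioned birth-death likelihood), and counts `k`, `ell`.
#' @export
classify_branches <- function(tree, include_root_edge = FALSE) {
  tree <- as_phylo_tree(tree)
  if (!ape::is.rooted(tree) || !ape::is.binary.phylo(tree))
    stop("tree must be rooted and strictly binary")
  ntip <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(ntip)])
  root_edge <- tree$root.edge %||% 0
  child <- tree$edge[, 2L]
  is_pendant <- child <= ntip
  internal <- tree$edge.length[!is_pendant]
  x <- height - depths[child[!is_pendant]]
  pendant <- tree$edge.length[is_pendant]
  if (include_root_edge && root_edge > 0) {
    internal <- c(root_edge, internal)
    x <- c(height, x)
  }
  branch_data(internal = internal, pendant = pendant, x = x,
              t = height + root_edge, x2 = height)
}

#' Assemble branch-length data
#'
#' Low-level constructor for the container consumed by the likelihood and
#' fitting functions; [classify_branches] builds it from a tree, and
#' [read_branch_table] from a TSV file.
#'
#' @param internal Internal branch lengths.
#' @param pendant Pendant branch lengths.
#' @param x Elapsed time from the end of each internal branch to the
#'   present (same length as `internal`); may be `NULL` when only the
#'   pure-birth likelihoods are needed.
#' @param t Tree age (time from the start of the root branch to the present).
#' @param x2 Height of the root node above the present.
#' @return A `branch_data` object.
#' @export
branch_data <- function(internal, pendant, x = NULL, t = NA_real_, x2 = NA_real_) {
  internal <- as.numeric(internal); pendant <- as.numeric(pendant)
  if (any(internal < 0) || any(pendant < 0)) stop("branch lengths must be >= 0")
  if (!is.null(x) && length(x) != length(internal))
    stop("'x' must align with 'internal'")
  structure(
    list(internal = internal, pendant = pendant, x = x, t = t, x2 = x2,
         k = length(internal), ell = length(pendant)),
    class = "branch_data"
  )
}

#' @export
print.branch_data <- function(x, ...) {
  cat("Branch data: k =", x$k, "internal, ell =", x$ell, "pendant branches\n")
  if (is.finite(x$t)) cat("  tree age t =", format(x$t, digits = 6), "\n")
  invisible(x)
}

#' Write and read trees in Newick format
#'
#' Thin wrappers around `ape::write.tree` / `ape::read.tree`. A multi-tree
#' file holds one Newick string per line; a stored root edge is serialised
#' as the root length field.
#'
#' @param trees A `phylo`, `sim_tree`, or list of either (reconstructed
#'   views are written for `sim_tree` input).
#' @param path File path.
#' @return `read_newick` returns a list of `phylo` trees.
#' @export
write_newick <- function(trees, path) {
  trees <- as_phylo_list(trees)
  txt <- vapply(trees, ape::write.tree, character(1), digits = 15)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) stop("malformed Newick in '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
  if (is.null(trees)) stop("malformed Newick in '", path, "'")
  if (inherits(trees, "phylo")) trees <- list(trees)
  unclass(trees)
}
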