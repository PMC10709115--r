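# Felsenstein pruning: one topology pass is precomputed per tree, then applied
# to any number of datasets at once (tips x m matrix). The same kernel serves
# the observed data, the profiled-ML likelihood, and every bootstrap replicate,
# so no statistic can differ between code paths.

# Branch lengths below this are floored before the PIC division to avoid 0/0
# on degenerate unit trees (e.g. OU with very large alpha).
.bl_floor <- 1e-12

# Static topology arrays for a rooted binary tree.
build_topology <- function(tree) {
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    abort("tree has polytomies or an unrooted basal trifurcation; run resolve_polytomies() first")
  }
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  n_total <- n_tip + n_node
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  edge_of_child <- rep(NA_integer_, n_total)
  edge_of_child[child] <- seq_along(child)
  root <- setdiff(parent, child)[1]
  # parents appear before children in cladewise edge order -> topological depths
  cw <- ape::reorder.phylo(tree, "cladewise")$edge
  topo_depth <- integer(n_total)
  for (e in seq_len(nrow(cw))) topo_depth[cw[e, 2]] <- topo_depth[cw[e, 1]] + 1L
  internal <- (n_tip + 1L):n_total
  nodes <- internal[order(topo_depth[internal], decreasing = TRUE)]
  preorder_edges <- order(topo_depth[child])
  c1 <- integer(n_node)
  c2 <- integer(n_node)
  for (k in seq_along(nodes)) {
    ch <- child[parent == nodes[k]]
    c1[k] <- ch[1]
    c2[k] <- ch[2]
  }
  list(
    n_tip = n_tip, n_node = n_node, n_total = n_total, root = root,
    nodes = nodes, c1 = c1, c2 = c2, edge_of_child = edge_of_child,
    preorder_edges = preorder_edges
  )
}

# Data-independent part of the pruning recursion: extended child variances,
# ancestral-state weights, and the log-determinant of the implied covariance.
build_schedule <- function(topo, elen) {
  if (all(elen <= 0)) abort("singular covariance: all branch lengths are zero")
  elen <- pmax(elen, .bl_floor)
  n <- topo$n_node
  ext <- numeric(topo$n_total)
  va <- numeric(n); vb <- numeric(n); vsum <- numeric(n)
  for (k in seq_len(n)) {
    a <- topo$c1[k]; b <- topo$c2[k]
    va[k] <- elen[topo$edge_of_child[a]] + ext[a]
    vb[k] <- elen[topo$edge_of_child[b]] + ext[b]
    vsum[k] <- va[k] + vb[k]
    ext[topo$nodes[k]] <- va[k] * vb[k] / vsum[k]
  }
  list(
    topo = topo, va = va, vb = vb, vsum = vsum,
    wa = vb / vsum, wb = va / vsum,
    ext_root = ext[topo$root],
    logdet = sum(log(vsum)) + log(ext[topo$root])
  )
}

# Apply the pruning recursion to a tips x m matrix of datasets.
# Returns (n_tip - 1) x m matrices of standardized contrasts and ancestral
# estimates, plus the root (GLS) estimate per dataset.
pics_kernel <- function(sched, X) {
  topo <- sched$topo
  X <- as.matrix(X)
  m <- ncol(X)
  val <- matrix(0, topo$n_total, m)
  val[seq_len(topo$n_tip), ] <- X
  pic <- matrix(0, topo$n_node, m)
  anc <- matrix(0, topo$n_node, m)
  inv_sd <- 1 / sqrt(sched$vsum)
  for (k in seq_len(topo$n_node)) {
    a <- val[topo$c1[k], ]
    b <- val[topo$c2[k], ]
    pic[k, ] <- (a - b) * inv_sd[k]
    est <- sched$wa[k] * a + sched$wb[k] * b
    anc[k, ] <- est
    val[topo$nodes[k], ] <- est
  }
  list(pic = pic, anc = anc, root = val[topo$root, ])
}

# Profiled (full-ML) BM(sigma = 1) log-likelihood on a tree with branch
# lengths `elen`, from a pruning pass. With z0 fixed instead of profiled, the
# root deviation adds a quadratic term.
pruning_loglik <- function(topo, elen, x, z0 = NULL) {
  sched <- build_schedule(topo, elen)
  kr <- pics_kernel(sched, matrix(x, ncol = 1))
  n <- topo$n_tip
  ll <- -n / 2 * log(2 * pi) - sched$logdet / 2 - sum(kr$pic^2) / 2
  if (!is.null(z0)) ll <- ll - (kr$root - z0)^2 / (2 * sched$ext_root)
  ll
}

#' Phylogenetic independent contrasts on a unit tree
#'
#' Runs the pruning recursion of Felsenstein's contrasts: at each internal
#' node with child values `x_a`, `x_b` carrying extended variances `v_a`,
#' `v_b`, the standardized contrast is `(x_a - x_b) / sqrt(v_a + v_b)`, the
#' ancestral estimate is the inverse-variance weighted average, and the
#' node's own branch is extended by `v_a v_b / (v_a + v_b)`. On a unit tree
#' whose generating model matches the fitted one, the contrasts are i.i.d.
#' standard normal.
#'
#' @param utree A `unit_tree` (or any `phylo`; lengths are used as-is).
#' @param traits Trait tibble (`species`, `value`, ...) covering every tip.
#'   The `se` column is ignored here: measurement variance is already part of
#'   a unit tree's terminal branches.
#' @return A tibble with one row per internal node: `node` (ape node id),
#'   `pic`, `v_exp` (expected contrast variance, sum of extended child
#'   variances), `anc_state`, and `height` (node depth from the root of
#'   `utree`).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tv <- trait_vector(c("A", "B", "C"), c(1, 3, 2))
#' compute_pics(tr, tv)
#' @export
compute_pics <- function(utree, traits) {
  validate_phylogeny(utree)
  if ("se" %in% names(traits) && !inherits(utree, "unit_tree") &&
      any(traits$se > 0)) {
    warn("`traits$se` is ignored by compute_pics(); fold it into the tree via rescale_to_unit_tree()")
  }
  al <- align_traits(utree, dplyr::mutate(traits, se = 0))
  topo <- build_topology(utree)
  sched <- build_schedule(topo, utree$edge.length)
  kr <- pics_kernel(sched, matrix(al$value, ncol = 1))
  depth <- node_depths(utree)
  tibble::tibble(
    node = topo$nodes,
    pic = kr$pic[, 1],
    v_exp = sched$vsum,
    anc_state = kr$anc[, 1],
    height = depth[topo$nodes]
  )
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' The ratio of the observed mean squared deviation from the phylogenetically
#' corrected mean (`MSE0`) to the GLS mean squared error (`MSE`), scaled by
#' its expectation under Brownian motion,
#' `(tr(C) - n / sum(C^-1)) / (n - 1)` with `C` the phylogenetic
#' variance-covariance matrix. `K = 1` is the BM expectation; lower values
#' indicate less phylogenetic signal than BM predicts.
#'
#' @param tree A `phylo` object (at least 4 tips).
#' @param traits Trait tibble (`species`, `value`) covering every tip;
#'   constant traits are an error (the ratio is undefined).
#' @return A single number.
#' @export
blomberg_k <- function(tree, traits) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  if (n < 4L) abort("Blomberg's K needs at least 4 tips")
  if (!"se" %in% names(traits)) traits$se <- 0
  al <- align_traits(tree, traits)
  x <- al$value
  if (var(x) == 0) abort("Blomberg's K is undefined for a constant trait")
  C <- phylo_vcv(tree)
  Cinv <- solve(C)
  one <- rep(1, n)
  a_hat <- as.numeric((one %*% Cinv %*% x) / (one %*% Cinv %*% one))
  dev <- x - a_hat
  mse0 <- sum(dev^2) / (n - 1)
  mse <- as.numeric(dev %*% Cinv %*% dev) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  (mse0 / mse) / expected
}
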