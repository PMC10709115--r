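# Generator for trees and expression datasets with the statistical structure
# the analysis assumes: traits evolved under BM/OU/EB (plus multi-rate and
# shifted-optimum variants that violate the single-regime models), observed
# through per-species replicates with Gaussian noise on the log scale.

#' Simulate a pure-birth ultrametric tree
#'
#' A Yule (pure-birth, rate 1) tree rescaled to exact height `height`.
#' Ultrametric and bifurcating by construction; topology is deterministic
#' given `seed`.
#'
#' @param n_tips Number of tips (at least 2).
#' @param height Tree height in time units (default 1).
#' @param seed Integer seed.
#' @return A `phylo` object with tips `t1 ... tn`.
#' @export
simulate_tree <- function(n_tips, height = 1, seed = 1L) {
  if (n_tips < 2L) abort("`n_tips` must be at least 2")
  if (height <= 0) abort("`height` must be positive")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tree$edge.length <- tree$edge.length * (height / tree_height(tree))
  tree
}

# Tip values for m independent genes under one generating model.
# `clade_tips` marks a subtree (including its stem edge) on which either the
# rate is multiplied by `rate_factor` (BM-2rate) or the OU optimum is moved
# by `theta_shift` (OU-shift).
simulate_traits_matrix <- function(tree, model, sigsq, alpha = NULL, r = NULL,
                                   z0 = 0, m = 1L, clade_tips = NULL,
                                   rate_factor = 1, theta_shift = 0) {
  topo <- build_topology(tree)
  n_edge <- nrow(tree$edge)
  depth <- node_depths(tree)
  TT <- max(depth[seq_len(topo$n_tip)])
  in_clade <- rep(FALSE, n_edge)
  if (!is.null(clade_tips) && length(clade_tips) > 0L) {
    node <- ape::getMRCA(tree, clade_tips)
    desc <- clade_descendants(tree, node)
    in_clade <- tree$edge[, 2] %in% c(node, desc)
  }
  edge_sigsq <- sigsq * ifelse(in_clade, rate_factor, 1)
  t1 <- depth[tree$edge[, 1]]
  t2 <- depth[tree$edge[, 2]]
  val <- matrix(0, topo$n_total, m)
  val[topo$root, ] <- z0
  if (model %in% c("BM", "EB")) {
    ev <- vapply(seq_len(n_edge), function(e) {
      edge_model_variance(model, t1[e], t2[e], TT, edge_sigsq[e], r = r)
    }, numeric(1))
    inc <- matrix(rnorm(n_edge * m, sd = sqrt(pmax(ev, 0))), nrow = n_edge)
    for (e in topo$preorder_edges) {
      val[tree$edge[e, 2], ] <- val[tree$edge[e, 1], ] + inc[e, ]
    }
  } else if (model == "OU") {
    theta_edge <- z0 + ifelse(in_clade, theta_shift, 0)
    len <- tree$edge.length
    for (e in topo$preorder_edges) {
      p <- val[tree$edge[e, 1], ]
      th <- theta_edge[e]
      if (alpha == 0) {
        mu <- p
        sdv <- sqrt(edge_sigsq[e] * len[e])
      } else {
        decay <- exp(-alpha * len[e])
        mu <- th + (p - th) * decay
        sdv <- sqrt(edge_sigsq[e] / (2 * alpha) * (1 - decay^2))
      }
      val[tree$edge[e, 2], ] <- mu + rnorm(m, sd = sdv)
    }
  } else {
    abort(paste0("unknown generating model: ", model))
  }
  out <- val[seq_len(topo$n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate trait values on a phylogeny
#'
#' Recursive root-to-tip simulation: under BM a child value is the parent
#' plus `N(0, sigsq * t)`; under OU it decays toward the optimum,
#' `theta + (parent - theta) e^(-alpha t)` plus stationary-matched noise
#' `N(0, sigsq / (2 alpha) (1 - e^(-2 alpha t)))`; EB is BM on branches
#' carrying the exponentially decaying rate `sigsq * e^(-r t)`.
#'
#' @param tree A `phylo` object (ultrametric for OU/EB).
#' @param params A [model_params()] object.
#' @param seed Integer seed.
#' @return A trait tibble (`species`, `value`, `se = 0`).
#' @export
simulate_traits <- function(tree, params, seed = 1L) {
  validate_phylogeny(tree)
  if (!inherits(params, "model_params")) abort("`params` must be a model_params object")
  if (params$model %in% c("OU", "EB") && !is_ultrametric(tree)) {
    abort(paste0(params$model, " simulation requires an ultrametric tree"))
  }
  x <- with_seed(seed, simulate_traits_matrix(
    tree, params$model, params$sigsq, alpha = params$alpha, r = params$r,
    z0 = params$z0, m = 1L
  ))
  trait_vector(tree$tip.label, x[, 1], se = 0)
}

clade_descendants <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  if (length(kids) == 0L) return(integer(0))
  c(kids, unlist(lapply(kids, clade_descendants, tree = tree)))
}

# Deterministic choice of the "marked" clade for the misspecification
# variants: the internal (non-root) node whose tip count is closest to a
# third of the tree, ties to the smaller node id.
pick_marked_clade <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  internal <- setdiff(unique(tree$edge[, 1]), root)
  counts <- vapply(internal, function(nd) {
    sum(clade_descendants(tree, nd) <= n_tip)
  }, numeric(1))
  target <- n_tip / 3
  node <- internal[order(abs(counts - target), internal)][1]
  tree$tip.label[intersect(clade_descendants(tree, node), seq_len(n_tip))]
}

#' Configuration for a synthetic expression study
#'
#' @param n_tips Number of species (>= 4).
#' @param height Tree height in time units.
#' @param n_genes Number of genes.
#' @param model Generating model per gene, recycled over genes: `"BM"`,
#'   `"OU"`, `"EB"`, `"BM-2rate"` (rate multiplied on a marked clade) or
#'   `"OU-shift"` (optimum moved on a marked clade).
#' @param sigsq,alpha,r,z0 Generating parameters (see [model_params()]).
#' @param rate_factor Rate multiplier for `"BM-2rate"` (default 8).
#' @param theta_shift Optimum displacement for `"OU-shift"` (default 2).
#' @param n_replicates Replicate samples per species.
#' @param noise_sd Replicate noise sd on the log scale (>= 0).
#' @param seed Master seed; per-gene seeds are derived from gene ids.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_tips = 20L, height = 1, n_genes = 200L,
                              model = "BM", sigsq = 1, alpha = 1, r = 1,
                              z0 = 0, rate_factor = 8, theta_shift = 2,
                              n_replicates = 3L, noise_sd = 0.1, seed = 1L) {
  if (n_tips < 4L) abort("`n_tips` must be at least 4")
  if (n_genes < 1L) abort("`n_genes` must be at least 1")
  if (sigsq <= 0) abort("`sigsq` must be > 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (n_replicates < 1L) abort("`n_replicates` must be at least 1")
  ok <- c("BM", "OU", "EB", "BM-2rate", "OU-shift")
  if (!all(model %in% ok)) {
    abort(paste0("generating models must be among: ", paste(ok, collapse = ", ")))
  }
  structure(
    list(n_tips = as.integer(n_tips), height = height,
         n_genes = as.integer(n_genes), model = model, sigsq = sigsq,
         alpha = alpha, r = r, z0 = z0, rate_factor = rate_factor,
         theta_shift = theta_shift, n_replicates = as.integer(n_replicates),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a full synthetic expression study
#'
#' Generates one pure-birth tree and, per gene, trait values under its
#' generating model plus `n_replicates` log-scale replicate samples per
#' species with Gaussian noise. The output mirrors the pipeline's inputs: a
#' wide log-expression tibble, a sample map, and a truth table recording each
#' gene's generating model and parameters.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `tree` (`phylo`), `expression` (tibble, `gene_id` +
#'   one column per sample), `samples` (tibble `sample_id`, `species`,
#'   `tissue`), `truth` (tibble, one row per gene).
#' @export
simulate_dataset <- function(cfg) {
  if (!inherits(cfg, "simulation_config")) abort("`cfg` must be a simulation_config")
  tree <- simulate_tree(cfg$n_tips, cfg$height, seed = derive_seed(cfg$seed, "tree"))
  species <- tree$tip.label
  models <- rep_len(cfg$model, cfg$n_genes)
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  marked <- if (any(models %in% c("BM-2rate", "OU-shift"))) pick_marked_clade(tree) else character(0)
  sample_ids <- as.vector(t(outer(species, seq_len(cfg$n_replicates),
                                  function(s, r) paste0(s, "_r", r))))
  samples <- tibble::tibble(
    sample_id = sample_ids,
    species = rep(species, each = cfg$n_replicates),
    tissue = NA_character_
  )
  rows <- matrix(NA_real_, cfg$n_genes, length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_len(cfg$n_genes)) {
    gmodel <- models[i]
    base <- sub("-.*$", "", gmodel)
    vals <- with_seed(derive_seed(cfg$seed, gene_ids[i]), {
      x <- simulate_traits_matrix(
        tree, base, cfg$sigsq,
        alpha = if (base == "OU") cfg$alpha else NULL,
        r = if (base == "EB") cfg$r else NULL,
        z0 = cfg$z0, m = 1L,
        clade_tips = if (gmodel %in% c("BM-2rate", "OU-shift")) marked else NULL,
        rate_factor = if (gmodel == "BM-2rate") cfg$rate_factor else 1,
        theta_shift = if (gmodel == "OU-shift") cfg$theta_shift else 0
      )[, 1]
      reps <- rep(x, each = cfg$n_replicates) +
        rnorm(length(x) * cfg$n_replicates, sd = cfg$noise_sd)
      names(reps) <- as.vector(vapply(species, function(s) {
        paste0(s, "_r", seq_len(cfg$n_replicates))
      }, character(cfg$n_replicates)))
      reps
    })
    rows[i, names(vals)] <- vals
  }
  expression <- tibble::as_tibble(cbind(
    tibble::tibble(gene_id = gene_ids),
    tibble::as_tibble(rows)
  ))
  attr(expression, "normalization") <- "log"
  truth <- tibble::tibble(
    gene_id = gene_ids, model = models, sigsq = cfg$sigsq,
    alpha = ifelse(models == "OU" | models == "OU-shift", cfg$alpha, NA_real_),
    r = ifelse(models == "EB", cfg$r, NA_real_),
    z0 = cfg$z0,
    rate_factor = ifelse(models == "BM-2rate", cfg$rate_factor, NA_real_),
    theta_shift = ifelse(models == "OU-shift", cfg$theta_shift, NA_real_),
    marked_clade = ifelse(models %in% c("BM-2rate", "OU-shift"),
                          paste(marked, collapse = ";"), NA_character_)
  )
  list(tree = tree, expression = expression, samples = samples, truth = truth)
}
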