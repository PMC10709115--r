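#' Construct a set of trait-model parameters
#'
#' Parameters of the three candidate models of continuous trait evolution:
#' Brownian motion (`BM`: rate `sigsq`), single-optimum Ornstein-Uhlenbeck
#' (`OU`: rate `sigsq`, pull `alpha` toward the optimum `theta`), and early
#' burst (`EB`: initial rate `sigsq` decaying as `sigsq * exp(-r * t)` with
#' time `t` from the root). `z0` is the trait value at the root. For the OU
#' model the optimum is constrained to the root state (`theta = z0`): on an
#' ultrametric tree with tip data only the two are not separately
#' identifiable, matching the standard single-regime fit.
#'
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param sigsq Evolutionary rate (BM/OU) or initial rate (EB); > 0.
#' @param alpha OU pull strength, >= 0 (OU only).
#' @param r EB rate-decay parameter, >= 0 (EB only).
#' @param z0 Root trait value; for OU also the optimum `theta`.
#' @param theta OU optimum; if given must equal `z0` (see above).
#' @return A `model_params` object (a named list).
#' @export
model_params <- function(model = c("BM", "OU", "EB"), sigsq, alpha = NULL,
                         r = NULL, z0 = 0, theta = NULL) {
  model <- match.arg(model)
  if (!is_scalar_number(sigsq) || sigsq <= 0) abort("`sigsq` must be > 0")
  if (!is_scalar_number(z0)) abort("`z0` must be a finite number")
  if (model == "OU") {
    if (is.null(alpha)) abort("OU requires `alpha`")
    if (!is_scalar_number(alpha) || alpha < 0) abort("`alpha` must be >= 0")
    if (!is.null(theta) && !isTRUE(all.equal(theta, z0))) {
      abort("single-optimum OU constrains `theta` to equal `z0`")
    }
    theta <- z0
  } else if (!is.null(alpha)) {
    abort("`alpha` applies only to the OU model")
  }
  if (model == "EB") {
    if (is.null(r)) abort("EB requires `r`")
    if (!is_scalar_number(r) || r < 0) abort("`r` must be >= 0")
  } else if (!is.null(r)) {
    abort("`r` applies only to the EB model")
  }
  structure(
    list(model = model, sigsq = sigsq, alpha = alpha, theta = theta,
         r = r, z0 = z0),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  vals <- c(sigsq = x$sigsq, alpha = x$alpha, r = x$r, z0 = x$z0)
  cat("<model_params> ", x$model, ": ",
      paste(names(vals), signif(unlist(vals), 5), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Model-implied variance accumulated along each edge. Edges span depths
# [t1, t2] measured from the root of the ORIGINAL tree of height TT:
#   BM : sigsq * (t2 - t1)
#   OU : sigsq/(2 alpha) * (exp(-2 alpha (TT - t2)) - exp(-2 alpha (TT - t1)))
#   EB : sigsq * (exp(-r t1) - exp(-r t2)) / r        (r -> 0 gives BM)
# OU and EB reduce to BM exactly at alpha = 0 / r = 0.
edge_model_variance <- function(model, t1, t2, TT, sigsq, alpha = NULL, r = NULL) {
  switch(model,
    BM = sigsq * (t2 - t1),
    OU = {
      if (alpha == 0) {
        sigsq * (t2 - t1)
      } else {
        sigsq / (2 * alpha) * (exp(-2 * alpha * (TT - t2)) - exp(-2 * alpha * (TT - t1)))
      }
    },
    EB = {
      if (r == 0) {
        sigsq * (t2 - t1)
      } else {
        sigsq * (exp(-r * t1) - exp(-r * t2)) / r
      }
    },
    abort(paste0("unknown model: ", model))
  )
}

#' Rescale a phylogeny into a unit tree under fitted model parameters
#'
#' Replaces each branch length by the variance the model accumulates along
#' it, then adds each tip's squared standard error to its terminal branch.
#' If the model (with those parameters) generated the data, the tip values on
#' the returned tree are distributed as Brownian motion with unit rate, so
#' the phylogenetic independent contrasts are i.i.d. N(0, 1) — the basis of
#' all adequacy statistics.
#'
#' Depths are measured from the root of the original tree; OU and EB require
#' an ultrametric tree (the transforms are defined relative to its height).
#' Measurement variance is added after rescaling because it lives on the data
#' scale, not the evolutionary-time scale.
#'
#' @param tree A `phylo` object.
#' @param params A [model_params()] object.
#' @param se Per-tip standard errors: a single number, a vector named by tip
#'   label, or an unnamed vector in tip order. Default 0.
#' @return A `unit_tree` object (a `phylo` with rescaled branch lengths and
#'   attributes `params` and `se`).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ut <- rescale_to_unit_tree(tr, model_params("BM", sigsq = 3))
#' ut$edge.length
#' @export
rescale_to_unit_tree <- function(tree, params, se = 0) {
  validate_phylogeny(tree)
  if (!inherits(params, "model_params")) abort("`params` must be a model_params object")
  if (params$model %in% c("OU", "EB") && !is_ultrametric(tree)) {
    abort(paste0(params$model, " rescaling requires an ultrametric tree"))
  }
  n_tip <- length(tree$tip.label)
  se <- resolve_se(se, tree$tip.label)
  depth <- node_depths(tree)
  TT <- max(depth[seq_len(n_tip)])
  t1 <- depth[tree$edge[, 1]]
  t2 <- depth[tree$edge[, 2]]
  new_len <- edge_model_variance(params$model, t1, t2, TT,
                                 sigsq = params$sigsq,
                                 alpha = params$alpha, r = params$r)
  # clamp tiny negatives from floating cancellation in the OU/EB exponentials
  new_len[new_len < 0 & new_len > -1e-12] <- 0
  if (any(new_len < 0)) abort("negative rescaled branch length; invalid parameters")
  out <- tree
  out$edge.length <- new_len
  tip_edge <- match(seq_len(n_tip), tree$edge[, 2])
  out$edge.length[tip_edge] <- out$edge.length[tip_edge] + se^2
  class(out) <- c("unit_tree", "phylo")
  attr(out, "params") <- params
  attr(out, "se") <- se
  out
}

resolve_se <- function(se, tips) {
  if (length(se) == 1L) se <- rep(se, length(tips))
  if (!is.null(names(se))) {
    missing <- setdiff(tips, names(se))
    if (length(missing) > 0L) {
      abort(paste0("no `se` for tip(s): ", paste(missing, collapse = ", ")))
    }
    se <- se[tips]
  }
  if (length(se) != length(tips)) abort("`se` length must match number of tips")
  if (any(!is.finite(se)) || any(se < 0)) abort("`se` must be finite and >= 0")
  unname(se)
}

#' @export
print.unit_tree <- function(x, ...) {
  p <- attr(x, "params")
  cat("<unit_tree> ", length(x$tip.label), " tips, rescaled under ",
      if (is.null(p)) "unknown model" else p$model,
      "; total depth range [",
      signif(min(node_depths(x)[seq_along(x$tip.label)]), 5), ", ",
      signif(max(node_depths(x)[seq_along(x$tip.label)]), 5), "]\n", sep = "")
  invisible(x)
}
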