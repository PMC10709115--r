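#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion with unit rate, `C[i, j]` is the depth (from the
#' root) of the most recent common ancestor of tips `i` and `j`, and
#' `C[i, i]` is the depth of tip `i` — the shared evolutionary history that
#' makes related species covary. Built directly from MRCA depths; inside the
#' package it serves as the brute-force route to the likelihood against which
#' the pruning algorithm is checked.
#'
#' @param tree A `phylo` object.
#' @return A symmetric species-by-species matrix with tip labels as dimnames.
#' @examples
#' phylo_vcv(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_vcv <- function(tree) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  depth <- node_depths(tree)
  M <- ape::mrca(tree)
  C <- matrix(depth[M], n, n, dimnames = list(tree$tip.label, tree$tip.label))
  diag(C) <- depth[seq_len(n)]
  C
}

#' Log-likelihood of trait data under a trait model
#'
#' Gaussian log-likelihood of per-species values under BM, OU or EB with root
#' state `params$z0`, each tip receiving its squared standard error as fixed
#' additive variance. Computed by rescaling the tree to its unit tree and
#' running the contrasts-based BM likelihood — algebraically identical to the
#' multivariate-normal density with the model covariance plus `diag(se^2)`.
#'
#' @param tree A `phylo` object (ultrametric for OU/EB).
#' @param traits Trait tibble (`species`, `value`, `se`).
#' @param params A [model_params()] object (with `z0`).
#' @return The log-likelihood (single number).
#' @export
model_loglik <- function(tree, traits, params) {
  validate_phylogeny(tree)
  tree <- resolve_polytomies(tree)
  al <- align_traits(tree, traits)
  ut <- rescale_to_unit_tree(tree, params, se = al$se)
  topo <- build_topology(ut)
  pruning_loglik(topo, ut$edge.length, al$value, z0 = params$z0)
}

# Parameter bounds scaled to tree height so the transforms
# stay numerically sane.
model_bounds <- function(model, TT) {
  switch(model,
    BM = list(lower = log(1e-8), upper = log(1e4)),
    OU = list(lower = c(log(1e-8), log(1e-8 / TT)), upper = c(log(1e4), log(50 / TT))),
    EB = list(lower = c(log(1e-8), 0), upper = c(log(1e4), log(1e5) / TT))
  )
}

#' Fit a trait model by maximum likelihood
#'
#' Maximises the [model_loglik()] of one model over its parameters, with the
#' root state profiled out analytically (its maximising value is the GLS mean
#' delivered by the pruning recursion). BM reduces to a closed form when all
#' standard errors are zero and a one-dimensional bounded search otherwise;
#' OU and EB use bounded quasi-Newton searches on log-scale parameters from
#' one deterministic plus `restarts - 1` seeded random starting points.
#'
#' @param tree A `phylo` object (ultrametric for OU/EB); polytomies are
#'   resolved to zero-length bifurcations internally.
#' @param traits Trait tibble (`species`, `value`, `se`). Tips without data
#'   must be pruned beforehand (see [prune_tips()]).
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param restarts Number of optimizer starts for OU/EB (default 3).
#' @param seed Integer seed making the random starts reproducible.
#' @return A `model_fit` object: `params`, `lnL`, `k` (parameter count,
#'   including the root state: BM 2, OU 3, EB 3), `aic = 2k - 2 lnL`,
#'   `n_tips`, `convergence`, `boundary`, `restarts`.
#' @examples
#' tr <- parse_newick("(A:1,B:1);")
#' fit <- fit_model(tr, trait_vector(c("A", "B"), c(0, 2)), "BM")
#' glance(fit)
#' @export
fit_model <- function(tree, traits, model = c("BM", "OU", "EB"),
                      restarts = 3L, seed = 1L) {
  model <- match.arg(model)
  validate_phylogeny(tree)
  tree <- resolve_polytomies(tree)
  al <- align_traits(tree, traits)
  n <- length(tree$tip.label)
  if (n < 2L) abort("need at least 2 tips")
  if (model %in% c("OU", "EB") && !is_ultrametric(tree)) {
    abort(paste0(model, " fitting requires an ultrametric tree"))
  }
  depth <- node_depths(tree)
  TT <- max(depth[seq_len(n)])
  if (TT <= 0) abort("singular covariance: tree height is zero")
  topo <- build_topology(tree)
  t1 <- depth[tree$edge[, 1]]
  t2 <- depth[tree$edge[, 2]]
  tip_edge <- match(seq_len(n), tree$edge[, 2])
  se2 <- al$se^2
  bounds <- model_bounds(model, TT)

  # profiled lnL at given natural-scale parameters
  obj_ll <- function(sigsq, alpha = NULL, r = NULL) {
    elen <- edge_model_variance(model, t1, t2, TT, sigsq, alpha, r)
    elen[elen < 0 & elen > -1e-12] <- 0
    elen[tip_edge] <- elen[tip_edge] + se2
    pruning_loglik(topo, elen, al$value)
  }

  boundary <- FALSE
  convergence <- TRUE
  used_restarts <- 0L

  if (model == "BM") {
    if (all(se2 == 0)) {
      # closed form: sigsq_hat = sum(raw_pic^2 / v) / n on the time tree
      sched <- build_schedule(topo, tree$edge.length)
      kr <- pics_kernel(sched, matrix(al$value, ncol = 1))
      s_hat <- sum(kr$pic^2) / n
      s_hat <- min(max(s_hat, 1e-8), 1e4)
      boundary <- s_hat <= 1e-8 || s_hat >= 1e4
      est <- list(sigsq = s_hat)
    } else {
      opt <- optimize(function(ls) -obj_ll(exp(ls)),
                      interval = c(bounds$lower, bounds$upper), tol = 1e-10)
      est <- list(sigsq = exp(opt$minimum))
      boundary <- abs(opt$minimum - bounds$lower) < 1e-6 ||
        abs(opt$minimum - bounds$upper) < 1e-6
    }
  } else {
    neg_ll <- if (model == "OU") {
      function(p) -obj_ll(exp(p[1]), alpha = exp(p[2]))
    } else {
      function(p) -obj_ll(exp(p[1]), r = p[2])
    }
    # deterministic start near the BM rate estimate, mild alpha / r
    bm_sched <- build_schedule(topo, tree$edge.length)
    bm_kr <- pics_kernel(bm_sched, matrix(al$value, ncol = 1))
    s0 <- min(max(sum(bm_kr$pic^2) / n, 1e-6), 1e3)
    start0 <- if (model == "OU") c(log(s0), log(1 / TT)) else c(log(s0), 0.5 / TT)
    starts <- list(start0)
    if (restarts > 1L) {
      rand <- with_seed(seed, {
        lapply(seq_len(restarts - 1L), function(i) {
          stats::runif(2, bounds$lower, bounds$upper)
        })
      })
      starts <- c(starts, rand)
    }
    best <- NULL
    for (st in starts) {
      ans <- tryCatch(
        nlminb(st, neg_ll, lower = bounds$lower, upper = bounds$upper,
               control = list(rel.tol = 1e-10, iter.max = 500)),
        error = function(e) NULL
      )
      used_restarts <- used_restarts + 1L
      if (!is.null(ans) && (is.null(best) || ans$objective < best$objective)) {
        best <- ans
      }
    }
    if (is.null(best)) abort(paste0("all optimizer starts failed for ", model))
    convergence <- best$convergence == 0
    boundary <- any(abs(best$par - bounds$lower) < 1e-6) ||
      any(abs(best$par - bounds$upper) < 1e-6)
    est <- if (model == "OU") {
      list(sigsq = exp(best$par[1]), alpha = exp(best$par[2]))
    } else {
      list(sigsq = exp(best$par[1]), r = best$par[2])
    }
  }

  # recover profiled root state and the maximised lnL at the estimate
  elen <- edge_model_variance(model, t1, t2, TT, est$sigsq,
                              alpha = est$alpha, r = est$r)
  elen[elen < 0 & elen > -1e-12] <- 0
  elen[tip_edge] <- elen[tip_edge] + se2
  sched <- build_schedule(topo, pmax(elen, .bl_floor))
  kr <- pics_kernel(sched, matrix(al$value, ncol = 1))
  z0 <- kr$root
  lnL <- -n / 2 * log(2 * pi) - sched$logdet / 2 - sum(kr$pic^2) / 2
  params <- model_params(model, sigsq = est$sigsq, alpha = est$alpha,
                         r = est$r, z0 = z0)
  k <- if (model == "BM") 2L else 3L
  structure(
    list(
      model = model, params = params, lnL = lnL, k = k,
      aic = 2 * k - 2 * lnL, n_tips = n,
      convergence = convergence, boundary = boundary,
      restarts = used_restarts,
      data_hash = trait_fingerprint(tree$tip.label, al$value, al$se)
    ),
    class = "model_fit"
  )
}

trait_fingerprint <- function(species, value, se) {
  stable_hash(paste(species, signif(value, 12), signif(se, 12), collapse = "|"))
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", x$model, ": lnL = ", signif(x$lnL, 6),
      ", AIC = ", signif(x$aic, 6), ", n = ", x$n_tips,
      if (x$boundary) " (at parameter boundary)" else "", "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Compare fitted models by AIC
#'
#' Computes per-model AIC differences and Akaike weights
#' (`exp(-dAIC/2)`, normalised) and names the best-supported model. Ties are
#' broken toward fewer parameters, then by the fixed order BM, EB, OU.
#'
#' @param fits A list of `model_fit` objects for the same data (at least 2).
#' @return A `model_comparison` object; `tidy()` returns the comparison
#'   table, `glance()` a one-row summary.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "model_fit")) fits <- list(fits)
  if (length(fits) < 2L) abort("need fits for at least 2 models to compare")
  if (!all(vapply(fits, inherits, logical(1), "model_fit"))) {
    abort("`fits` must be a list of model_fit objects")
  }
  hashes <- vapply(fits, function(f) f$data_hash, numeric(1))
  if (length(unique(hashes)) > 1L) abort("fits were made on different data")
  models <- vapply(fits, function(f) f$model, character(1))
  if (anyDuplicated(models)) abort("duplicate model fits supplied")
  tab <- tibble::tibble(
    model = unname(models),
    k = unname(vapply(fits, function(f) f$k, integer(1))),
    lnL = unname(vapply(fits, function(f) f$lnL, numeric(1))),
    AIC = unname(vapply(fits, function(f) f$aic, numeric(1)))
  )
  tab$dAIC <- tab$AIC - min(tab$AIC)
  w <- exp(-tab$dAIC / 2)
  tab$weight <- w / sum(w)
  ord <- order(tab$AIC, tab$k, match(tab$model, c("BM", "EB", "OU")))
  best <- tab$model[ord[1]]
  tab <- tab[order(match(tab$model, c("BM", "OU", "EB"))), ]
  names(fits) <- models
  structure(list(table = tab, fits = fits, best = best),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> best:", x$best, "\n")
  print(x$table)
  invisible(x)
}
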