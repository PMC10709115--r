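# The five adequacy statistics, the parametric-bootstrap null, and the
# two-tailed p-values. All statistics consume the contrasts produced by the
# shared pruning kernel, for observed and simulated data alike.

adequacy_stat_names <- c("c.var", "d.cdf", "s.asr", "s.hgt", "s.var")

#' Coefficient of variation of the absolute contrasts
#'
#' `sd(|pic|) / mean(|pic|)` (sample sd, `n - 1` denominator). Sensitive to
#' rate heterogeneity across the tree that the fitted model did not capture.
#' `NA` when all contrasts are zero.
#'
#' @param pic Numeric vector of standardized contrasts.
#' @return A single number or `NA`.
#' @export
stat_cvar <- function(pic) {
  a <- abs(pic)
  m <- mean(a)
  if (m == 0) return(NA_real_)
  sd(a) / m
}

#' Kolmogorov-Smirnov D of the contrasts against N(0, 1)
#'
#' Two-sided sup distance between the empirical CDF of the signed contrasts
#' and the standard normal CDF; detects departures from normality such as
#' occasional bursts of change.
#'
#' @param pic Numeric vector of standardized contrasts.
#' @return A single number in `[0, 1]`.
#' @export
stat_dcdf <- function(pic) {
  n <- length(pic)
  p <- pnorm(sort(pic))
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
}

#' Ordinary least-squares slope, guarding degenerate predictors
#'
#' The shared kernel of the three slope statistics: `s.asr` regresses `|pic|`
#' on the node's ancestral-state estimate, `s.hgt` on node height (the node
#' height test), `s.var` on the expected contrast variance. Returns `NA` when
#' the predictor is (numerically) constant — the mechanism by which `s.hgt`
#' goes `NA` on unit trees where a large OU pull leaves almost no variance in
#' node heights.
#'
#' @param x Predictor values.
#' @param y Response values (same length).
#' @return The OLS slope of `y` on `x`, or `NA`.
#' @export
stat_slope <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length")
  mx <- mean(x)
  vx <- sum((x - mx)^2)
  if (vx < 1e-12 * max(1, mx^2) * length(x)) return(NA_real_)
  sum((x - mx) * (y - mean(y))) / vx
}

# All five statistics from a matrix of contrasts ((n-1) x m), the matching
# ancestral-state matrix, and the per-node expected variances / heights.
# Vectorised across the m datasets; returns an m x 5 matrix.
adequacy_stats_matrix <- function(pic, anc, v_exp, height) {
  pic <- as.matrix(pic); anc <- as.matrix(anc)
  m <- ncol(pic)
  a <- abs(pic)
  nn <- nrow(pic)
  # c.var
  mean_a <- colMeans(a)
  sd_a <- sqrt(colSums(sweep(a, 2, mean_a)^2) / (nn - 1))
  cvar <- ifelse(mean_a == 0, NA_real_, sd_a / mean_a)
  # d.cdf
  dcdf <- vapply(seq_len(m), function(j) stat_dcdf(pic[, j]), numeric(1))
  # slope helpers
  slope_fixed_x <- function(x, Y) {
    mx <- mean(x)
    dx <- x - mx
    vx <- sum(dx^2)
    if (vx < 1e-12 * max(1, mx^2) * length(x)) return(rep(NA_real_, ncol(Y)))
    as.numeric(crossprod(dx, sweep(Y, 2, colMeans(Y)))) / vx
  }
  sasr <- vapply(seq_len(m), function(j) stat_slope(anc[, j], a[, j]), numeric(1))
  shgt <- slope_fixed_x(height, a)
  svar <- slope_fixed_x(v_exp, a)
  out <- cbind(c.var = cvar, d.cdf = dcdf, s.asr = sasr,
               s.hgt = shgt, s.var = svar)
  rownames(out) <- NULL
  out
}

#' The five adequacy statistics of a contrast set
#'
#' @param cs A contrast tibble from [compute_pics()].
#' @return A named numeric vector `c.var`, `d.cdf`, `s.asr`, `s.hgt`,
#'   `s.var` (entries may be `NA`, see the individual statistics).
#' @export
adequacy_stats <- function(cs) {
  if (nrow(cs) < 3L) abort("need at least 3 contrasts")
  adequacy_stats_matrix(matrix(cs$pic, ncol = 1), matrix(cs$anc_state, ncol = 1),
                        cs$v_exp, cs$height)[1, ]
}

# tips x m matrix of BM(sigma = 1, root = 0) tip values on `tree`: each tip
# is the sum of independent N(0, branch length) increments along its path.
simulate_bm_matrix <- function(tree, m, sigsq = 1, z0 = 0) {
  topo <- build_topology(tree)
  inc <- matrix(rnorm(nrow(tree$edge) * m, sd = sqrt(pmax(sigsq * tree$edge.length, 0))),
                nrow = nrow(tree$edge))
  val <- matrix(0, topo$n_total, m)
  val[topo$root, ] <- z0
  for (e in topo$preorder_edges) {
    val[tree$edge[e, 2], ] <- val[tree$edge[e, 1], ] + inc[e, ]
  }
  val[seq_len(topo$n_tip), , drop = FALSE]
}

#' Parametric-bootstrap null distributions of the adequacy statistics
#'
#' Simulates `n_sim` datasets as unit-rate Brownian motion from root state 0
#' on the unit tree (tip measurement error is already baked into the terminal
#' branches), reduces each to the five statistics through the same contrast
#' kernel used for the observed data, and returns the draws.
#'
#' @param utree A `unit_tree` (any bifurcating `phylo` works).
#' @param n_sim Number of simulations (at least 100).
#' @param seed Integer seed; draws are deterministic given it.
#' @return An `n_sim` x 5 matrix with columns `c.var`, `d.cdf`, `s.asr`,
#'   `s.hgt`, `s.var` (entries may be `NA`).
#' @export
simulate_null <- function(utree, n_sim = 1000L, seed = 1L) {
  validate_phylogeny(utree)
  if (n_sim < 100L) abort("`n_sim` must be at least 100")
  topo <- build_topology(utree)
  sched <- build_schedule(topo, utree$edge.length)
  depth <- node_depths(utree)
  with_seed(seed, {
    X <- simulate_bm_matrix(utree, n_sim)
    kr <- pics_kernel(sched, X)
    adequacy_stats_matrix(kr$pic, kr$anc, sched$vsum, depth[topo$nodes])
  })
}

#' Two-tailed bootstrap p-values for the adequacy statistics
#'
#' For each statistic, the p-value places the observed value in the null
#' draws: with `n` valid (non-`NA`) draws,
#' `p = 2 * min(1 + #(null <= obs), 1 + #(null >= obs)) / (n + 1)`, capped at
#' 1. The add-one convention keeps p strictly positive; an observed value in
#' either tail yields a small p (the model "performs poorly"). An observed
#' `NA` propagates to a `NA` p-value.
#'
#' @param observed Named numeric vector of the five observed statistics.
#' @param null Matrix of null draws from [simulate_null()].
#' @return A named numeric vector of p-values (entries in `(0, 1]` or `NA`).
#' @export
adequacy_pvalues <- function(observed, null) {
  missing_stats <- setdiff(adequacy_stat_names, names(observed))
  if (length(missing_stats) > 0L) {
    abort(paste0("observed statistics missing: ", paste(missing_stats, collapse = ", ")))
  }
  p <- setNames(rep(NA_real_, 5L), adequacy_stat_names)
  for (s in adequacy_stat_names) {
    obs <- observed[[s]]
    if (is.na(obs)) next
    draws <- null[, s]
    draws <- draws[!is.na(draws)]
    n_valid <- length(draws)
    if (n_valid == 0L) {
      warn(paste0("all null draws NA for ", s, "; p-value set to NA"))
      next
    }
    lo <- 1L + sum(draws <= obs)
    hi <- 1L + sum(draws >= obs)
    p[[s]] <- min(1, 2 * min(lo, hi) / (n_valid + 1))
  }
  p
}

#' Assess absolute adequacy of a fitted model
#'
#' Computes the five observed statistics of the contrasts on the unit tree
#' and their two-tailed p-values against a parametric-bootstrap null. The
#' model is called adequate when every non-`NA` p-value is at least `alpha`;
#' statistics that are `NA` on the observed data are excluded from the
#' verdict.
#'
#' @param utree A `unit_tree` from [rescale_to_unit_tree()].
#' @param traits Trait tibble covering the tips (`se` already folded into the
#'   unit tree).
#' @param n_sim Number of bootstrap simulations (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param alpha Significance cutoff for the adequacy verdict (default 0.05).
#' @return An `adequacy_result`: `observed`, `p`, `null` (the draws),
#'   `adequate`, `n_sim`, `seed`. `tidy()` gives a statistic-by-statistic
#'   tibble; `autoplot()` shows observed values against the null.
#' @export
assess_adequacy <- function(utree, traits, n_sim = 1000L, seed = 1L,
                            alpha = 0.05) {
  cs <- compute_pics(utree, traits)
  observed <- adequacy_stats(cs)
  null <- simulate_null(utree, n_sim = n_sim, seed = seed)
  p <- adequacy_pvalues(observed, null)
  adequate <- if (all(is.na(p))) NA else all(p[!is.na(p)] >= alpha)
  structure(
    list(observed = observed, p = p, null = null, adequate = adequate,
         n_sim = as.integer(n_sim), seed = as.integer(seed), alpha = alpha),
    class = "adequacy_result"
  )
}

#' @export
print.adequacy_result <- function(x, ...) {
  cat("<adequacy_result> n_sim =", x$n_sim, "\n")
  print(tibble::tibble(
    statistic = adequacy_stat_names,
    observed = unname(x$observed[adequacy_stat_names]),
    p = unname(x$p[adequacy_stat_names])
  ))
  cat("adequate (all non-NA p >=", x$alpha, "):", x$adequate, "\n")
  invisible(x)
}
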