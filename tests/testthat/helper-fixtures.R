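# Shared fixtures, built in code.

tree3 <- function() parse_newick("((A:1,B:1):1,C:2);")
tree2 <- function() parse_newick("(A:1,B:1);")
tree4 <- function() parse_newick("((A:1,B:1):1,(C:1.5,D:0.5):0.6);")

# Brute-force Gaussian log-density of tip values under a trait model:
# model covariance from the rescaled tree read off as a vcv matrix, plus
# diag(se^2), evaluated with dense linear algebra. Independent of the
# pruning code path.
brute_force_loglik <- function(tree, traits, params) {
  ut <- rescale_to_unit_tree(tree, params, se = 0)
  C <- phylo_vcv(ut)
  idx <- match(rownames(C), traits$species)
  x <- traits$value[idx]
  C <- C + diag(traits$se[idx]^2, nrow(C))
  n <- length(x)
  mu <- rep(params$z0, n)
  as.numeric(
    -n / 2 * log(2 * pi) - 0.5 * determinant(C)$modulus -
      0.5 * t(x - mu) %*% solve(C, x - mu)
  )
}

random_params <- function(model) {
  switch(model,
    BM = model_params("BM", runif(1, 0.1, 3), z0 = rnorm(1)),
    OU = model_params("OU", runif(1, 0.1, 3), alpha = runif(1, 0.01, 3), z0 = rnorm(1)),
    EB = model_params("EB", runif(1, 0.1, 3), r = runif(1, 0, 2), z0 = rnorm(1))
  )
}

small_dataset <- function(n_genes = 4, seed = 7) {
  simulate_dataset(simulation_config(
    n_tips = 8, n_genes = n_genes, model = "BM", sigsq = 1,
    n_replicates = 3, noise_sd = 0.1, seed = seed
  ))
}
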