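test_that("phylo_vcv is the shared-history covariance", {
  expect_equal(phylo_vcv(tree3()),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  star <- resolve_polytomies(parse_newick("(A:1,B:1,C:1);"))
  C <- phylo_vcv(star)
  expect_equal(unname(diag(C)), rep(1, 3))
  expect_equal(max(abs(C[upper.tri(C)])), 0)
  expect_equal(unname(phylo_vcv(tree2())), diag(2))
  # agrees with ape's independent construction on a random tree
  tr <- simulate_tree(12, 1.7, seed = 21)
  expect_equal(phylo_vcv(tr), ape::vcv.phylo(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-12)
})

test_that("model_loglik matches the closed-form bivariate density", {
  tv <- trait_vector(c("A", "B"), c(0, 2))
  ll <- model_loglik(tree2(), tv, model_params("BM", 1, z0 = 1))
  expect_equal(ll, -log(2 * pi) - 1, tolerance = 1e-10)
})

test_that("OU and EB log-likelihoods reduce to BM in the alpha->0 / r->0 limits", {
  tv <- trait_vector(c("A", "B"), c(0, 2))
  ll_bm <- model_loglik(tree2(), tv, model_params("BM", 1, z0 = 1))
  expect_equal(model_loglik(tree2(), tv, model_params("OU", 1, alpha = 1e-12, z0 = 1)),
               ll_bm, tolerance = 1e-6)
  expect_equal(model_loglik(tree2(), tv, model_params("EB", 1, r = 1e-12, z0 = 1)),
               ll_bm, tolerance = 1e-6)
  # and on a larger fixture at alpha/r = 1e-9
  tr <- simulate_tree(15, 1, seed = 2)
  tv2 <- simulate_traits(tr, model_params("BM", 2), seed = 3)
  ll_bm2 <- model_loglik(tr, tv2, model_params("BM", 2, z0 = 0.3))
  expect_lt(abs(model_loglik(tr, tv2, model_params("OU", 2, alpha = 1e-9, z0 = 0.3)) - ll_bm2), 1e-5)
  expect_lt(abs(model_loglik(tr, tv2, model_params("EB", 2, r = 1e-9, z0 = 0.3)) - ll_bm2), 1e-5)
})

test_that("pruning likelihood equals the brute-force Gaussian density", {
  withr::with_seed(101, {
    for (i in 1:150) {
      n <- sample(3:8, 1)
      tr <- simulate_tree(n, height = runif(1, 0.5, 2), seed = i)
      params <- random_params(sample(c("BM", "OU", "EB"), 1))
      tv <- simulate_traits(tr, params, seed = i + 1000)
      tv$se <- runif(n, 0, 0.5)
      expect_equal(model_loglik(tr, tv, params), brute_force_loglik(tr, tv, params),
                   tolerance = 1e-8)
    }
  })
})

test_that("non-ultrametric trees are rejected for OU and EB", {
  tr <- parse_newick("((A:1,B:2):1,C:2);")
  tv <- trait_vector(c("A", "B", "C"), c(0, 1, 2))
  expect_error(model_loglik(tr, tv, model_params("OU", 1, alpha = 1, z0 = 0)), "ultrametric")
  expect_error(fit_model(tr, tv, "EB"), "ultrametric")
  expect_silent(invisible(model_loglik(tr, tv, model_params("BM", 1, z0 = 0))))
})

test_that("BM maximum likelihood has its closed form on two tips", {
  fit <- fit_model(tree2(), trait_vector(c("A", "B"), c(0, 2)), "BM")
  expect_equal(fit$params$sigsq, 1, tolerance = 1e-8)
  expect_equal(fit$params$z0, 1, tolerance = 1e-10)
  expect_equal(fit$k, 2L)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$lnL)
})

test_that("constant traits drive sigma^2 to the lower bound, flagged", {
  tr <- simulate_tree(6, 1, seed = 1)
  fit <- fit_model(tr, trait_vector(tr$tip.label, rep(3, 6)), "BM")
  expect_equal(fit$params$sigsq, 1e-8)
  expect_true(fit$boundary)
})

test_that("adding measurement error never increases the fitted BM rate", {
  withr::with_seed(77, {
    ratios <- replicate(25, {
      tr <- simulate_tree(15, 1, seed = sample.int(1e6, 1))
      tv <- simulate_traits(tr, model_params("BM", 2), seed = sample.int(1e6, 1))
      s0 <- fit_model(tr, tv, "BM")$params$sigsq
      tv$se <- 0.5
      s1 <- fit_model(tr, tv, "BM")$params$sigsq
      s1 / s0
    })
    expect_lte(median(ratios), 1)
  })
})

test_that("compare_models computes Akaike weights and breaks ties as specified", {
  tr <- simulate_tree(10, 1, seed = 4)
  tv <- simulate_traits(tr, model_params("BM", 1), seed = 5)
  f_bm <- fit_model(tr, tv, "BM")
  f_ou <- fit_model(tr, tv, "OU")
  f_eb <- fit_model(tr, tv, "EB")
  cmp <- compare_models(list(f_bm, f_ou, f_eb))
  tab <- tidy(cmp)
  expect_equal(sum(tab$weight), 1)
  expect_equal(tab$dAIC[tab$model == cmp$best], 0)
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$lnL)
  # hand-checked weights for AIC {10, 12}
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  # tie toward fewer parameters: equal AIC picks BM over OU
  f_ou_tie <- f_ou
  f_ou_tie$aic <- f_bm$aic
  expect_equal(compare_models(list(f_bm, f_ou_tie))$best, "BM")
  expect_error(compare_models(list(f_bm)), "at least 2")
})

test_that("fits on different data cannot be compared", {
  tr <- simulate_tree(8, 1, seed = 6)
  tv1 <- simulate_traits(tr, model_params("BM", 1), seed = 7)
  tv2 <- simulate_traits(tr, model_params("BM", 1), seed = 8)
  expect_error(compare_models(list(fit_model(tr, tv1, "BM"), fit_model(tr, tv2, "OU"))),
               "different data")
})

test_that("fit_model recovers generating parameters", {
  tr <- simulate_tree(200, 1, seed = 31)
  s_ratio <- sapply(1:40, function(i) {
    fit_model(tr, simulate_traits(tr, model_params("BM", 2), seed = i), "BM")$params$sigsq / 2
  })
  expect_gt(median(s_ratio), 0.9)
  expect_lt(median(s_ratio), 1.1)
  a_ratio <- sapply(1:15, function(i) {
    fit_model(tr, simulate_traits(tr, model_params("OU", 1, alpha = 2), seed = i),
              "OU", seed = i)$params$alpha / 2
  })
  expect_gt(median(a_ratio), 0.5)
  expect_lt(median(a_ratio), 2.0)
})
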