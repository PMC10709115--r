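test_that("the five statistics follow their defining formulas", {
  expect_equal(stat_cvar(c(1, 1, 1)), 0)
  expect_equal(stat_cvar(c(1, -3)), sqrt(2) / 2)
  expect_true(is.na(stat_cvar(c(0, 0, 0))))

  expect_equal(stat_dcdf(0), 0.5)
  q <- qnorm((1:19) / 20)
  expect_lte(stat_dcdf(q), 0.05 + 1 / 19)
  expect_equal(stat_dcdf(c(10, 11, 12)), 1, tolerance = 1e-6)
  # agrees with the stock KS statistic
  withr::with_seed(3, {
    x <- rnorm(40)
    expect_equal(stat_dcdf(x),
                 unname(suppressWarnings(stats::ks.test(x, "pnorm")$statistic)),
                 tolerance = 1e-12)
  })

  expect_equal(stat_slope(c(0, 1), c(1, 2)), 1)
  expect_equal(stat_slope(c(1, 2, 3), c(2, 4, 6)), 2)
  expect_true(is.na(stat_slope(c(2, 2, 2), c(1, 2, 3))))
  expect_error(stat_slope(1:3, 1:4), "length")
})

test_that("two-tailed bootstrap p-values follow the add-one convention", {
  null <- matrix(rep(1:999, 5), ncol = 5,
                 dimnames = list(NULL, c("c.var", "d.cdf", "s.asr", "s.hgt", "s.var")))
  obs_names <- colnames(null)
  # observed at the null median -> p capped at 1
  obs <- setNames(rep(500, 5), obs_names)
  expect_equal(unname(adequacy_pvalues(obs, null)), rep(1, 5))
  # observed above all 999 draws -> p = 2 * 1 / 1000
  obs_hi <- setNames(rep(2000, 5), obs_names)
  expect_equal(unname(adequacy_pvalues(obs_hi, null)), rep(0.002, 5))
  # observed NA propagates
  obs_na <- setNames(c(NA, 500, 500, NA, 500), obs_names)
  p <- adequacy_pvalues(obs_na, null)
  expect_true(is.na(p[["c.var"]]) && is.na(p[["s.hgt"]]))
  expect_equal(unname(p[c("d.cdf", "s.asr", "s.var")]), rep(1, 3))
  # all-NA null with a non-NA observed warns and yields NA
  null_na <- null
  null_na[, "s.var"] <- NA_real_
  expect_warning(p2 <- adequacy_pvalues(obs, null_na), "s.var")
  expect_true(is.na(p2[["s.var"]]))
})

test_that("simulate_null is seed-deterministic and self-consistent across seeds", {
  tr <- simulate_tree(15, 1, seed = 2)
  ut <- rescale_to_unit_tree(tr, model_params("BM", 1), se = 0)
  a <- simulate_null(ut, n_sim = 300, seed = 5)
  b <- simulate_null(ut, n_sim = 300, seed = 5)
  expect_identical(a, b)
  c2 <- simulate_null(ut, n_sim = 1000, seed = 6)
  d2 <- simulate_null(ut, n_sim = 1000, seed = 7)
  # c.var null means agree within 3 Monte-Carlo standard errors
  se_mc <- sqrt(var(c2[, "c.var"]) / 1000 + var(d2[, "c.var"]) / 1000)
  expect_lt(abs(mean(c2[, "c.var"]) - mean(d2[, "c.var"])), 3.5 * se_mc)
  expect_error(simulate_null(ut, n_sim = 50), "at least 100")
})

test_that("a huge OU pull degenerates node heights and s.hgt goes NA", {
  tr <- simulate_tree(12, 1, seed = 9)
  ut <- rescale_to_unit_tree(tr, model_params("OU", 1, alpha = 400), se = 0)
  null <- simulate_null(ut, n_sim = 200, seed = 1)
  expect_gte(mean(is.na(null[, "s.hgt"])), 0.99)
  tv <- simulate_traits(tr, model_params("BM", 1), seed = 10)
  res <- assess_adequacy(ut, tv, n_sim = 200, seed = 3)
  expect_true(is.na(res$observed[["s.hgt"]]))
  expect_true(is.na(res$p[["s.hgt"]]))
  # the NA statistic is excluded from the verdict rather than failing it
  expect_false(is.na(res$adequate))
})

test_that("assess_adequacy is deterministic and tidies cleanly", {
  tr <- simulate_tree(10, 1, seed = 4)
  tv <- simulate_traits(tr, model_params("BM", 1), seed = 5)
  fit <- fit_model(tr, tv, "BM")
  ut <- rescale_to_unit_tree(tr, fit$params, se = 0)
  r1 <- assess_adequacy(ut, tv, n_sim = 200, seed = 11)
  r2 <- assess_adequacy(ut, tv, n_sim = 200, seed = 11)
  expect_identical(r1, r2)
  td <- tidy(r1)
  expect_equal(nrow(td), 5)
  expect_true(all(td$p_value > 0 & td$p_value <= 1, na.rm = TRUE))
  expect_s3_class(glance(r1), "tbl_df")
  expect_s3_class(autoplot(r1), "ggplot")
})

test_that("null statistics use the same kernel as observed statistics", {
  # feeding a null draw's own data through the observed path reproduces it
  tr <- simulate_tree(8, 1, seed = 6)
  ut <- rescale_to_unit_tree(tr, model_params("BM", 1), se = 0)
  stats_direct <- withr::with_seed(42, {
    x <- adexpr:::simulate_bm_matrix(ut, 1)
    tv <- trait_vector(ut$tip.label, x[, 1])
    adequacy_stats(compute_pics(ut, tv))
  })
  null1 <- withr::with_seed(42, {
    x <- adexpr:::simulate_bm_matrix(ut, 1)
    topo <- adexpr:::build_topology(ut)
    sched <- adexpr:::build_schedule(topo, ut$edge.length)
    kr <- adexpr:::pics_kernel(sched, x)
    adexpr:::adequacy_stats_matrix(kr$pic, kr$anc, sched$vsum,
                                   node_depths(ut)[topo$nodes])[1, ]
  })
  expect_equal(stats_direct, null1, tolerance = 1e-12)
})
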