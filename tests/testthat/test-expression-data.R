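counts2 <- function() tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 3))

test_that("CPM, RPKM and TPM follow their defining arithmetic", {
  cpm <- normalize_counts(counts2(), "CPM")
  expect_equal(cpm$s1, c(250000, 750000))

  m <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10, 10))
  len <- c(g1 = 1000, g2 = 2000)
  tpm <- normalize_counts(m, "TPM", gene_lengths = len)
  expect_equal(tpm$s1, c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-9)
  rpkm <- normalize_counts(m, "RPKM", gene_lengths = len)
  expect_equal(rpkm$s1, c(10 / (20 * 1000) * 1e9, 250000))
})

test_that("TPM columns sum to 1e6 for arbitrary counts", {
  withr::with_seed(5, {
    m <- tibble::tibble(
      gene_id = paste0("g", 1:40),
      a = rpois(40, 50), b = rpois(40, 500), c = rpois(40, 5)
    )
    len <- setNames(sample(200:5000, 40), m$gene_id)
    tpm <- normalize_counts(m, "TPM", gene_lengths = len)
    expect_equal(colSums(tpm[, c("a", "b", "c")]), c(a = 1e6, b = 1e6, c = 1e6),
                 tolerance = 1e-6)
  })
})

test_that("normalization failure modes name the offending sample or gene", {
  bad <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 3), s2 = c(0, 0))
  expect_error(normalize_counts(bad, "CPM"), "s2")
  m <- counts2()
  expect_error(normalize_counts(m, "RPKM", gene_lengths = c(g1 = 100)), "g2")
  expect_error(normalize_counts(m, "TPM"), "gene_lengths")
})

test_that("log_transform is log2(x + offset) and guards zeros", {
  m <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(3, 0))
  lt <- log_transform(m)
  expect_equal(lt$s1, c(2, 0))
  expect_error(log_transform(m, offset = 0), "offset")
  # base and offset are configurable
  lt10 <- log_transform(tibble::tibble(gene_id = "g", s1 = 99), offset = 1, base = 10)
  expect_equal(lt10$s1, 2)
  expect_error(log_transform(tibble::tibble(gene_id = "g", s1 = -1)), "negative")
})

test_that("summarize_replicates returns species means with standard errors", {
  m <- tibble::tibble(gene_id = "g1",
                      x1 = 1, x2 = 2, x3 = 3, y1 = 5, z1 = NA_real_)
  samples <- tibble::tibble(
    sample_id = c("x1", "x2", "x3", "y1", "z1"),
    species = c("X", "X", "X", "Y", "Z"),
    tissue = NA_character_
  )
  tv <- summarize_replicates(m, samples, "g1")
  expect_equal(tv$value[tv$species == "X"], 2)
  expect_equal(tv$se[tv$species == "X"], 1 / sqrt(3))
  expect_equal(tv$se[tv$species == "Y"], 0)
  # all-missing species omitted; unknown gene errors
  expect_false("Z" %in% tv$species)
  expect_error(summarize_replicates(m, samples, "nope"), "nope")
})

test_that("normalize/log/summarize is invariant to sample column order", {
  withr::with_seed(9, {
    m <- tibble::tibble(gene_id = paste0("g", 1:10))
    for (s in paste0("s", 1:6)) m[[s]] <- rpois(10, 100)
    samples <- tibble::tibble(sample_id = paste0("s", 1:6),
                              species = rep(c("X", "Y", "Z"), each = 2),
                              tissue = NA_character_)
    shuffled <- m[, c("gene_id", sample(paste0("s", 1:6)))]
    f <- function(mm) summarize_replicates(log_transform(normalize_counts(mm, "CPM")),
                                           samples, "g3")
    expect_equal(f(shuffled), f(m), ignore_attr = TRUE)
  })
})

test_that("expression and sample-map files round-trip through the readers", {
  ds <- small_dataset(n_genes = 3)
  ef <- tempfile(fileext = ".tsv"); sf <- tempfile(fileext = ".tsv")
  write.table(as.data.frame(ds$expression), ef, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(ds$samples), sf, sep = "\t", quote = FALSE, row.names = FALSE)
  # log-scale tables may hold negatives; raw readers reject them
  expect_error(read_expression(ef), "negative")
  back <- read_expression(ef, log_scale = TRUE)
  expect_equal(back$gene_id, ds$expression$gene_id)
  expect_equal(as.matrix(back[, -1]), as.matrix(ds$expression[, -1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  smap <- read_sample_map(sf)
  expect_equal(smap$species, ds$samples$species)
})

test_that("equal gene lengths make CPM and RPKM log values perfectly correlated", {
  withr::with_seed(13, {
    m <- tibble::tibble(gene_id = paste0("g", 1:30))
    for (s in paste0("s", 1:5)) m[[s]] <- rpois(30, 200) + 1
    len <- setNames(rep(1000, 30), m$gene_id)
    lc <- log_transform(normalize_counts(m, "CPM"))
    lr <- log_transform(normalize_counts(m, "RPKM", gene_lengths = len))
    for (g in c("g1", "g7")) {
      a <- as.numeric(lc[lc$gene_id == g, -1])
      b <- as.numeric(lr[lr$gene_id == g, -1])
      expect_gt(cor(a, b), 0.99)
    }
  })
})
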