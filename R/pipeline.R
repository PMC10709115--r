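# Per-gene analysis and study-level orchestration. Each gene is analysed
# independently: prune the tree to the species with data, fit BM/OU/EB,
# pick the AIC-best model, rescale to its unit tree, and bootstrap the five
# adequacy statistics. No multiple-testing correction is applied across
# genes: each gene tests the single hypothesis that its own fitted model
# generated its data.

gene_result_na <- function(gene_id, tissue, n_tips, skip_reason) {
  tibble::tibble(
    gene_id = gene_id, tissue = tissue %||% NA_character_,
    n_tips = n_tips, skip_reason = skip_reason,
    best_model = NA_character_,
    dAIC_BM = NA_real_, dAIC_OU = NA_real_, dAIC_EB = NA_real_,
    w_BM = NA_real_, w_OU = NA_real_, w_EB = NA_real_,
    sigsq = NA_real_, alpha = NA_real_, r = NA_real_, z0 = NA_real_,
    p_cvar = NA_real_, p_dcdf = NA_real_, p_sasr = NA_real_,
    p_shgt = NA_real_, p_svar = NA_real_, adequate = NA
  )
}

#' Analyse one gene: relative fit then absolute adequacy
#'
#' Prunes the tree to the species with data, fits BM, OU and EB, compares
#' them by AIC, rescales the tree under the best model, and computes the
#' five adequacy statistics with parametric-bootstrap p-values. Genes with
#' fewer than `min_tips` species or zero trait variance are skipped with a
#' recorded reason rather than dropped.
#'
#' @param tree A `phylo` object (the species tree or this gene's own tree).
#' @param traits Trait tibble (`species`, `value`, `se`); species absent
#'   from the tree are an error, tips absent from the traits are pruned.
#' @param gene_id,tissue Identifiers carried into the result row.
#' @param n_sim Bootstrap simulations per gene (default 1000).
#' @param seed Integer seed for this gene's fits and bootstrap.
#' @param min_tips Minimum species required (default 4; below this OU/EB are
#'   effectively unidentifiable).
#' @param alpha_level Cutoff for the adequacy verdict (default 0.05).
#' @return A one-row tibble (`gene_id`, `tissue`, `n_tips`, `skip_reason`,
#'   `best_model`, per-model `dAIC_*`/`w_*`, fitted `sigsq`/`alpha`/`r`/`z0`,
#'   `p_*` per statistic, `adequate`).
#' @export
run_gene <- function(tree, traits, gene_id = NA_character_, tissue = NULL,
                     n_sim = 1000L, seed = 1L, min_tips = 4L,
                     alpha_level = 0.05) {
  validate_traits(traits)
  traits <- dplyr::filter(traits, .data$species %in% tree$tip.label)
  n <- nrow(traits)
  if (n < min_tips) {
    return(gene_result_na(gene_id, tissue, n, "too_few_tips"))
  }
  if (var(traits$value) == 0) {
    return(gene_result_na(gene_id, tissue, n, "zero_variance"))
  }
  gtree <- if (n < length(tree$tip.label)) prune_tips(tree, traits$species) else tree
  gtree <- resolve_polytomies(gtree, seed = seed)
  fits <- list()
  for (mdl in c("BM", "OU", "EB")) {
    f <- tryCatch(
      fit_model(gtree, traits, mdl, seed = derive_seed(seed, mdl)),
      error = function(e) NULL
    )
    if (!is.null(f)) fits[[mdl]] <- f
  }
  if (length(fits) == 0L) {
    return(gene_result_na(gene_id, tissue, n, "fit_failure"))
  }
  if (length(fits) == 1L) {
    return(gene_result_na(gene_id, tissue, n, "fit_failure"))
  }
  cmp <- compare_models(fits)
  best <- cmp$fits[[cmp$best]]
  al <- align_traits(gtree, traits)
  ut <- rescale_to_unit_tree(gtree, best$params, se = al$se)
  adq <- assess_adequacy(ut, traits, n_sim = n_sim,
                         seed = derive_seed(seed, "null"),
                         alpha = alpha_level)
  tab <- cmp$table
  get_stat <- function(mdl, col) {
    v <- tab[[col]][tab$model == mdl]
    if (length(v) == 0L) NA_real_ else v
  }
  tibble::tibble(
    gene_id = gene_id, tissue = tissue %||% NA_character_,
    n_tips = n, skip_reason = NA_character_,
    best_model = cmp$best,
    dAIC_BM = get_stat("BM", "dAIC"), dAIC_OU = get_stat("OU", "dAIC"),
    dAIC_EB = get_stat("EB", "dAIC"),
    w_BM = get_stat("BM", "weight"), w_OU = get_stat("OU", "weight"),
    w_EB = get_stat("EB", "weight"),
    sigsq = best$params$sigsq,
    alpha = best$params$alpha %||% NA_real_,
    r = best$params$r %||% NA_real_,
    z0 = best$params$z0,
    p_cvar = adq$p[["c.var"]], p_dcdf = adq$p[["d.cdf"]],
    p_sasr = adq$p[["s.asr"]], p_shgt = adq$p[["s.hgt"]],
    p_svar = adq$p[["s.var"]],
    adequate = adq$adequate
  )
}

#' Run the full study: every gene (x tissue) against the phylogeny
#'
#' @param expression Wide log-scale expression tibble (`gene_id` + one
#'   column per sample).
#' @param samples Sample map tibble (`sample_id`, `species`, `tissue`).
#' @param tree Species tree (`phylo`), or ignored for a gene when
#'   `gene_trees` provides one.
#' @param gene_trees Optional named list of `phylo` objects, one per gene
#'   id; every gene id must resolve when given.
#' @param tissues Optional character vector of tissues to analyse (default:
#'   each distinct tissue in `samples`, or tissue-less if none).
#' @param n_sim,min_tips,alpha_level Per-gene settings (see [run_gene()]).
#' @param seed Master seed; per-gene seeds are derived from
#'   `gene_id x tissue` by a stable hash, so results do not depend on gene
#'   order.
#' @return A `study_result` list: `genes` (one row per gene x tissue, sorted
#'   by `gene_id`, `tissue`), `summary` (see [summarize_study()]), and
#'   `config` (echo of the run settings).
#' @export
run_study <- function(expression, samples, tree, gene_trees = NULL,
                      tissues = NULL, n_sim = 1000L, seed = 1L,
                      min_tips = 4L, alpha_level = 0.05) {
  if (nrow(expression) == 0L) abort("empty gene table")
  validate_sample_map(samples)
  unmapped <- setdiff(sample_cols(expression), samples$sample_id)
  if (length(unmapped) > 0L) {
    abort(paste0("samples not in the sample map: ", paste(unmapped, collapse = ", ")))
  }
  gene_ids <- sort(unique(expression$gene_id))
  if (!is.null(gene_trees)) {
    missing_trees <- setdiff(gene_ids, names(gene_trees))
    if (length(missing_trees) > 0L) {
      abort(paste0("no gene tree for: ", paste(missing_trees, collapse = ", ")))
    }
  }
  if (is.null(tissues)) {
    tissues <- sort(unique(samples$tissue), na.last = TRUE)
    if (length(tissues) == 0L) tissues <- NA_character_
  }
  grid <- tidyr::expand_grid(gene_id = gene_ids, tissue = tissues)
  rows <- purrr::pmap(grid, function(gene_id, tissue) {
    tis <- if (is.na(tissue)) NULL else tissue
    traits <- summarize_replicates(expression, samples, gene_id, tissue = tis)
    gtree <- if (is.null(gene_trees)) tree else gene_trees[[gene_id]]
    run_gene(gtree, traits, gene_id = gene_id, tissue = tis,
             n_sim = n_sim, seed = derive_seed(seed, paste(gene_id, tissue)),
             min_tips = min_tips, alpha_level = alpha_level)
  })
  genes <- dplyr::arrange(dplyr::bind_rows(rows), .data$gene_id, .data$tissue)
  structure(
    list(
      genes = genes,
      summary = summarize_study(genes, alpha_level = alpha_level),
      config = list(n_sim = n_sim, seed = seed, min_tips = min_tips,
                    alpha_level = alpha_level,
                    gene_trees = !is.null(gene_trees))
    ),
    class = "study_result"
  )
}

#' Study-level summary of per-gene results
#'
#' Recomputes, from the per-gene table alone: the proportion of analysed
#' genes best fit by each model, the proportion adequate, the per-statistic
#' inadequacy proportion at `alpha_level` (among non-`NA` p-values), and the
#' count of `NA` `s.hgt` values.
#'
#' @param genes Per-gene tibble from [run_study()]/[run_gene()].
#' @param alpha_level Significance cutoff (default 0.05).
#' @return A one-row tibble.
#' @export
summarize_study <- function(genes, alpha_level = 0.05) {
  done <- dplyr::filter(genes, is.na(.data$skip_reason))
  n_done <- nrow(done)
  prop_best <- function(mdl) {
    if (n_done == 0L) NA_real_ else mean(done$best_model == mdl)
  }
  inadequacy <- function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0L) NA_real_ else mean(p < alpha_level)
  }
  tibble::tibble(
    n_genes = nrow(genes),
    n_analyzed = n_done,
    n_skipped = nrow(genes) - n_done,
    prop_best_BM = prop_best("BM"),
    prop_best_OU = prop_best("OU"),
    prop_best_EB = prop_best("EB"),
    prop_adequate = if (n_done == 0L) NA_real_ else mean(done$adequate[!is.na(done$adequate)]),
    inadeq_cvar = inadequacy(done$p_cvar),
    inadeq_dcdf = inadequacy(done$p_dcdf),
    inadeq_sasr = inadequacy(done$p_sasr),
    inadeq_shgt = inadequacy(done$p_shgt),
    inadeq_svar = inadequacy(done$p_svar),
    n_shgt_na = sum(is.na(done$p_shgt))
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>", nrow(x$genes), "gene x tissue rows\n")
  print(x$summary)
  invisible(x)
}

#' Write study results as TSV tables plus run metadata
#'
#' Writes `genes.tsv`, `summary.tsv` and `run_metadata.yaml` into `dir`.
#' Output bytes are deterministic given the same inputs and master seed.
#'
#' @param result A `study_result` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(result, dir) {
  if (!inherits(result, "study_result")) abort("`result` must be a study_result")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_plain <- function(df, path) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 10))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  write_tsv_plain(result$genes, file.path(dir, "genes.tsv"))
  write_tsv_plain(result$summary, file.path(dir, "summary.tsv"))
  meta <- c(result$config,
            list(package = "adexpr",
                 version = as.character(utils::packageVersion("adexpr"))))
  yaml::write_yaml(meta, file.path(dir, "run_metadata.yaml"))
  invisible(dir)
}
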