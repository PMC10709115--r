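#' Read an expression table
#'
#' Expects a TSV with gene ids in the first column and one column per sample.
#' Empty cells and `NA` are missing data; negative values are rejected unless
#' the table holds already log-transformed values.
#'
#' @param path Path to the TSV file.
#' @param log_scale Set `TRUE` when the file holds log-transformed values
#'   (negatives allowed; the `"normalization"` attribute is set to `"log"`).
#' @return A tibble with column `gene_id` followed by one numeric column per
#'   sample.
#' @export
read_expression <- function(path, log_scale = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "gene_id"
  df <- tibble::as_tibble(df)
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id)) {
    abort(paste0(
      "duplicate gene ids: ",
      paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", ")
    ))
  }
  check_expression_values(df, allow_negative = log_scale)
  if (log_scale) attr(df, "normalization") <- "log"
  df
}

#' Read a sample-to-species map
#'
#' @param path Path to a TSV with columns `sample_id`, `species` and
#'   optionally `tissue`.
#' @return A tibble with those columns (`tissue` filled with `NA` if absent).
#' @export
read_sample_map <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("sample_id", "species") %in% names(df))) {
    abort("sample map needs columns 'sample_id' and 'species'")
  }
  if (!"tissue" %in% names(df)) df$tissue <- NA_character_
  validate_sample_map(df)
  df[, c("sample_id", "species", "tissue")]
}

validate_sample_map <- function(samples) {
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup) > 0L) {
    abort(paste0("samples mapped more than once: ", paste(dup, collapse = ", ")))
  }
  invisible(samples)
}

#' Read a gene-length table
#'
#' @param path Path to a TSV with columns `gene_id` and `length_bp`.
#' @return A named numeric vector of lengths in bases.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(df))) {
    abort("gene length table needs columns 'gene_id' and 'length_bp'")
  }
  setNames(as.numeric(df$length_bp), as.character(df$gene_id))
}

check_expression_values <- function(m, allow_negative = FALSE) {
  vals <- as.matrix(m[, setdiff(names(m), "gene_id"), drop = FALSE])
  if (!allow_negative && any(vals < 0, na.rm = TRUE)) {
    abort("negative expression values are not allowed before log transformation")
  }
  invisible(m)
}

sample_cols <- function(m) setdiff(names(m), "gene_id")

#' Normalize raw counts to CPM, RPKM or TPM
#'
#' Per sample `s` with library size `N_s` and gene `g` of length `L_g` bases:
#' CPM is `count / N_s * 1e6`; RPKM is `count / (N_s * L_g) * 1e9`; TPM first
#' forms the length rate `count / L_g`, then scales each sample so the column
#' sums to `1e6`.
#'
#' @param counts Wide tibble of raw counts (`gene_id` + one column per sample).
#' @param method One of `"CPM"`, `"RPKM"`, `"TPM"`.
#' @param gene_lengths Named numeric vector of gene lengths in bases (required
#'   for RPKM and TPM).
#' @return A tibble of the same shape with normalized values; the
#'   normalization is recorded in the `"normalization"` attribute.
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 3))
#' normalize_counts(counts, method = "CPM")
#' @export
normalize_counts <- function(counts, method = c("CPM", "RPKM", "TPM"),
                             gene_lengths = NULL) {
  method <- match.arg(method)
  check_expression_values(counts)
  cols <- sample_cols(counts)
  vals <- as.matrix(counts[, cols, drop = FALSE])
  if (anyNA(vals)) abort("raw counts must not contain missing values")
  libsize <- colSums(vals)
  zero <- cols[libsize <= 0]
  if (length(zero) > 0L) {
    abort(paste0("zero library size for sample(s): ", paste(zero, collapse = ", ")))
  }
  if (method %in% c("RPKM", "TPM")) {
    if (is.null(gene_lengths)) abort(paste0(method, " requires `gene_lengths`"))
    len <- gene_lengths[counts$gene_id]
    missing_len <- counts$gene_id[is.na(len) | len <= 0]
    if (length(missing_len) > 0L) {
      abort(paste0(
        "missing or non-positive length for gene(s): ",
        paste(missing_len, collapse = ", ")
      ))
    }
  }
  out <- switch(method,
    CPM = sweep(vals, 2, libsize, "/") * 1e6,
    RPKM = sweep(vals / len, 2, libsize, "/") * 1e9,
    TPM = {
      rate <- vals / len
      sweep(rate, 2, colSums(rate), "/") * 1e6
    }
  )
  res <- counts
  res[, cols] <- tibble::as_tibble(out)
  attr(res, "normalization") <- method
  res
}

#' Log-transform an expression table
#'
#' Applies `log(x + offset)` in the given base, the standard variance-taming
#' transform before fitting Gaussian trait models. Defaults to `log2(x + 1)`.
#'
#' @param m Wide expression tibble (`gene_id` + sample columns), values >= 0.
#' @param offset Pseudo-count added before the log; must be positive when any
#'   value is zero.
#' @param base Logarithm base (default 2).
#' @return The transformed tibble, `"normalization"` attribute set to `"log"`.
#' @export
log_transform <- function(m, offset = 1, base = 2) {
  check_expression_values(m)
  cols <- sample_cols(m)
  vals <- as.matrix(m[, cols, drop = FALSE])
  if (offset <= 0 && any(vals == 0, na.rm = TRUE)) {
    abort("zero values require a positive `offset`")
  }
  if (offset < 0) abort("`offset` must be non-negative")
  res <- m
  res[, cols] <- tibble::as_tibble(log(vals + offset, base = base))
  attr(res, "normalization") <- "log"
  res
}

#' Collapse replicate samples to per-species means and standard errors
#'
#' For one gene (and optionally one tissue) the log-expression values of a
#' species' replicates are averaged; the standard error of that mean
#' (`sd / sqrt(n)`, sample sd with `n - 1` denominator) becomes the species'
#' measurement error, entering the trait models as a fixed additive variance.
#' A species with a single replicate gets `se = 0`; samples with missing
#' values for the gene are dropped, and species with no data are omitted (they
#' are pruned from the tree downstream).
#'
#' @param m Log-scale expression tibble (`gene_id` + sample columns).
#' @param samples Sample map tibble (`sample_id`, `species`, optional
#'   `tissue`).
#' @param gene Gene id to extract.
#' @param tissue Optional tissue label; only samples of that tissue are used.
#' @return A trait tibble with columns `species`, `value`, `se`, `n` and
#'   attributes `gene_id` and `tissue`.
#' @export
summarize_replicates <- function(m, samples, gene, tissue = NULL) {
  validate_sample_map(samples)
  if (!gene %in% m$gene_id) abort(paste0("gene id not found: ", gene))
  if (!is.null(tissue)) {
    samples <- dplyr::filter(samples, .data$tissue == !!tissue)
    if (nrow(samples) == 0L) abort(paste0("no samples for tissue: ", tissue))
  }
  present <- intersect(samples$sample_id, sample_cols(m))
  samples <- dplyr::filter(samples, .data$sample_id %in% present)
  row <- m[m$gene_id == gene, present, drop = FALSE]
  long <- tibble::tibble(
    sample_id = present,
    value = as.numeric(row[1, present])
  )
  out <- long |>
    dplyr::inner_join(samples, by = "sample_id") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      se = if (dplyr::n() > 1L) sd(.data$value) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      value = mean(.data$value),
      .groups = "drop"
    ) |>
    dplyr::select("species", "value", "se", "n") |>
    dplyr::arrange(.data$species)
  attr(out, "gene_id") <- gene
  attr(out, "tissue") <- tissue %||% NA_character_
  out
}

#' Construct a trait tibble directly
#'
#' Convenience constructor for the per-species trait table consumed by
#' [fit_model()] and friends: one mean (log-scale) value and one standard
#' error per species.
#'
#' @param species Character vector of species names (must be unique).
#' @param value Numeric trait values (mean log expression).
#' @param se Numeric standard errors (recycled; default 0).
#' @return A tibble with columns `species`, `value`, `se`.
#' @export
trait_vector <- function(species, value, se = 0) {
  if (anyDuplicated(species)) abort("duplicate species in trait vector")
  if (length(value) != length(species)) abort("`value` and `species` lengths differ")
  se <- rep_len(se, length(species))
  if (any(!is.finite(se)) || any(se < 0)) abort("`se` must be finite and >= 0")
  tibble::tibble(species = as.character(species), value = as.numeric(value), se = se)
}

validate_traits <- function(traits) {
  if (!all(c("species", "value", "se") %in% names(traits))) {
    abort("traits need columns 'species', 'value', 'se'")
  }
  if (anyDuplicated(traits$species)) abort("duplicate species in traits")
  if (any(!is.finite(traits$value))) abort("trait values must be finite")
  if (any(!is.finite(traits$se)) || any(traits$se < 0)) {
    abort("`se` must be finite and >= 0")
  }
  invisible(traits)
}

# Align a trait tibble with a tree's tips; errors if they do not match 1:1.
align_traits <- function(tree, traits) {
  validate_traits(traits)
  missing <- setdiff(tree$tip.label, traits$species)
  if (length(missing) > 0L) {
    abort(paste0("no trait value for tip(s): ", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(traits$species, tree$tip.label)
  if (length(extra) > 0L) {
    abort(paste0("trait species not in tree: ", paste(extra, collapse = ", ")))
  }
  idx <- match(tree$tip.label, traits$species)
  list(value = traits$value[idx], se = traits$se[idx])
}
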