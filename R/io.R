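#' Convert beta-values to M-values
#'
#' Methylation beta-values (proportions in \[0, 1\]) are mapped to the
#' logit2 scale, `M = log2(beta / (1 - beta))`, on which methylation
#' levels are approximately Gaussian and amenable to linear modeling.
#' Values are clamped to `[epsilon, 1 - epsilon]` first so that fully
#' methylated or unmethylated probes do not produce infinite M-values.
#'
#' @param beta Numeric vector or matrix of beta-values in \[0, 1\].
#' @param epsilon Clamping bound in (0, 0.5); default `1e-6`.
#' @return Object of the same shape as `beta` on the M-value scale.
#' @seealso [m_to_beta()] for the inverse transform.
#' @examples
#' beta_to_m(c(0.1, 0.5, 0.8))
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(beta)) {
    stop("`beta` must be numeric", call. = FALSE)
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      !is.finite(epsilon) || epsilon <= 0 || epsilon >= 0.5) {
    stop("`epsilon` must be a single number in (0, 0.5)", call. = FALSE)
  }
  if (anyNA(beta) || any(!is.finite(beta))) {
    stop("`beta` contains non-finite values", call. = FALSE)
  }
  if (any(beta < 0) || any(beta > 1)) {
    bad <- which(beta < 0 | beta > 1)[1L]
    stop("`beta` values must lie in [0, 1]; offending value ", beta[bad],
         " at position ", bad, call. = FALSE)
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  dimnames(out) <- dimnames(beta)
  out
}

#' Convert M-values back to beta-values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`.
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Beta-values in (0, 1).
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stop("`m` must be numeric", call. = FALSE)
  out <- 1 / (1 + 2^(-m))
  dimnames(out) <- dimnames(m)
  out
}

#' Read a CpG-by-sample M-value matrix
#'
#' Reads a tab-delimited file whose first column holds CpG identifiers
#' and whose header row holds sample identifiers, and validates it as a
#' finite numeric matrix with unique row and column names. When the file
#' stores beta-values, set `transform_beta = TRUE` to convert each cell
#' with [beta_to_m()].
#'
#' @param path Path to the tab-delimited file.
#' @param transform_beta Logical; treat cells as beta-values and
#'   logit2-transform them.
#' @param epsilon Clamping bound passed to [beta_to_m()].
#' @return A numeric matrix (CpGs in rows, samples in columns).
#' @export
read_mvalue_matrix <- function(path, transform_beta = FALSE, epsilon = 1e-6) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L),
                          data.table = FALSE, showProgress = FALSE)
  if (ncol(dt) < 2L) {
    stop("matrix file must have a CpG id column plus >= 1 sample column",
         call. = FALSE)
  }
  cpg_ids <- dt[[1L]]
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(dt[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric values in sample column '", colnames(dt)[bad + 1L],
         "'", call. = FALSE)
  }
  rownames(vals) <- cpg_ids
  validate_mvalues(vals)
  if (transform_beta) vals <- beta_to_m(vals, epsilon)
  vals
}

#' Validate an M-value matrix
#'
#' @param m Numeric matrix with CpG rownames and sample colnames.
#' @return `m`, invisibly, after validation.
#' @keywords internal
#' @export
validate_mvalues <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("M-values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("M-value matrix needs CpG rownames and sample colnames",
         call. = FALSE)
  }
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup)) {
    stop("duplicated CpG id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup)) {
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop("non-finite value at CpG '", rownames(m)[idx[1L]], "', sample '",
         colnames(m)[idx[2L]], "' (missing cells are not supported; ",
         "impute upstream)", call. = FALSE)
  }
  invisible(m)
}

#' Read a CpG-to-region map
#'
#' Two input styles are supported. (1) A two-column tab-delimited table
#' `cpg_id<TAB>region_id` assigning each CpG to its co-methylated
#' region, preserving file order within regions. (2) A BED file of
#' region intervals (0-based half-open, name in column 4 when present)
#' plus a CpG position manifest (`cpg_id`, `chrom`, `position`); a CpG
#' joins a region when the chromosome matches and
#' `start <= position < end`. Manifest positions default to 0-based; a
#' first line `#position_base=1` in the manifest (or
#' `manifest_base = 1`) declares 1-based positions.
#'
#' @param path Path to the two-column map or to the BED file.
#' @param manifest Optional path to the CpG position manifest; its
#'   presence selects the BED interpretation of `path`.
#' @param manifest_base Coordinate convention of manifest positions, 0
#'   (default) or 1; overridden by a `#position_base=` header line.
#' @return A `data.frame` with columns `cpg_id` and `region_id`
#'   (character), one row per mapped CpG, region-grouped in first-seen
#'   region order. Empty regions are dropped with a message.
#' @export
read_region_map <- function(path, manifest = NULL, manifest_base = 0L) {
  if (is.null(manifest)) {
    dt <- data.table::fread(path, sep = "\t", header = FALSE,
                            colClasses = "character",
                            data.table = FALSE, showProgress = FALSE)
    # tolerate a header line naming the columns
    if (nrow(dt) && identical(tolower(dt[1L, 1L]), "cpg_id")) {
      dt <- dt[-1L, , drop = FALSE]
    }
    if (ncol(dt) < 2L) {
      stop("region map must have columns cpg_id, region_id", call. = FALSE)
    }
    map <- data.frame(cpg_id = dt[[1L]], region_id = dt[[2L]],
                      stringsAsFactors = FALSE)
  } else {
    map <- .region_map_from_bed(path, manifest, manifest_base)
  }
  validate_region_map(map)
}

.region_map_from_bed <- function(bed_path, manifest_path, manifest_base) {
  regions <- rtracklayer::import(bed_path, format = "BED")
  if (length(regions) == 0L) stop("BED file contains no regions", call. = FALSE)
  rname <- regions$name
  if (is.null(rname) || anyNA(rname)) {
    rname <- paste0("region_", seq_along(regions))
  }
  first <- readLines(manifest_path, n = 1L)
  if (grepl("^#\\s*position_base\\s*=", first)) {
    manifest_base <- as.integer(sub("^#\\s*position_base\\s*=\\s*", "", first))
  }
  if (!manifest_base %in% c(0L, 1L)) {
    stop("manifest position base must be 0 or 1", call. = FALSE)
  }
  man <- data.table::fread(manifest_path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  need <- c("cpg_id", "chrom", "position")
  if (!all(need %in% colnames(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pos1 <- as.integer(man$position) + (1L - as.integer(manifest_base))
  cpgs <- GenomicRanges::GRanges(man$chrom,
                                 IRanges::IRanges(start = pos1, width = 1L))
  hits <- GenomicRanges::findOverlaps(cpgs, regions)
  multi <- S4Vectors::queryHits(hits)[duplicated(S4Vectors::queryHits(hits))]
  if (length(multi)) {
    stop("CpG '", man$cpg_id[multi[1L]], "' overlaps more than one region",
         call. = FALSE)
  }
  n_empty <- length(regions) - length(unique(S4Vectors::subjectHits(hits)))
  if (n_empty > 0L) {
    message(n_empty, " region(s) contained no manifest CpGs and were dropped")
  }
  ord <- order(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  data.frame(cpg_id = man$cpg_id[S4Vectors::queryHits(hits)][ord],
             region_id = rname[S4Vectors::subjectHits(hits)][ord],
             stringsAsFactors = FALSE)
}

#' Validate a CpG-to-region map
#'
#' @param map `data.frame` with character columns `cpg_id`, `region_id`.
#' @return The map, region-grouped in first-seen region order.
#' @keywords internal
#' @export
validate_region_map <- function(map) {
  if (!is.data.frame(map) || !all(c("cpg_id", "region_id") %in% colnames(map))) {
    stop("region map needs columns cpg_id and region_id", call. = FALSE)
  }
  map$cpg_id <- as.character(map$cpg_id)
  map$region_id <- as.character(map$region_id)
  dup <- map$cpg_id[duplicated(map$cpg_id)]
  if (length(dup)) {
    stop("CpG mapped to more than one region: ",
         paste(unique(dup)[seq_len(min(3L, length(unique(dup))))],
               collapse = ", "), call. = FALSE)
  }
  # group rows by region in first-seen order, CpG order preserved within
  rid <- factor(map$region_id, levels = unique(map$region_id))
  out <- map[order(rid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a sample design
#'
#' Bundles a phenotype vector and optional covariates for a set of
#' samples. The phenotype `G` may be binary (0/1), discrete, or
#' continuous; an intercept column is always prepended to the covariate
#' matrix, which must be full rank.
#'
#' @param phenotype Numeric phenotype vector with >= 2 distinct values.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param covariates Optional numeric matrix/data.frame of adjustment
#'   covariates (one row per sample), without an intercept column.
#' @return An object of class `sample_design`: a list with elements
#'   `sample_ids`, `phenotype`, `covariates` (matrix with leading
#'   intercept column) and `covariate_names`.
#' @export
sample_design <- function(phenotype, sample_ids, covariates = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id(s) in design", call. = FALSE)
  }
  phenotype <- as.numeric(phenotype)
  if (length(phenotype) != length(sample_ids)) {
    stop("phenotype length must match sample_ids", call. = FALSE)
  }
  if (anyNA(phenotype)) stop("phenotype contains NA", call. = FALSE)
  if (length(unique(phenotype)) < 2L) {
    stop("phenotype has one level; at least two distinct values required",
         call. = FALSE)
  }
  n <- length(sample_ids)
  if (is.null(covariates)) {
    X <- matrix(1, n, 1L, dimnames = list(sample_ids, "(Intercept)"))
    cov_names <- character(0)
  } else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) {
      stop("covariates must have one row per sample", call. = FALSE)
    }
    if (anyNA(covariates)) stop("covariates contain NA", call. = FALSE)
    cov_names <- colnames(covariates)
    if (is.null(cov_names)) cov_names <- paste0("x", seq_len(ncol(covariates)))
    X <- cbind(1, covariates)
    dimnames(X) <- list(sample_ids, c("(Intercept)", cov_names))
  }
  if (qr(X)$rank < ncol(X)) {
    stop("covariate matrix is rank deficient after intercept prepend",
         call. = FALSE)
  }
  structure(list(sample_ids = sample_ids,
                 phenotype = phenotype,
                 covariates = X,
                 covariate_names = cov_names),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat("sample_design:", length(x$sample_ids), "samples,",
      length(x$covariate_names), "covariate(s)\n")
  cat("phenotype levels:",
      paste(utils::head(sort(unique(x$phenotype)), 5L), collapse = ", "),
      if (length(unique(x$phenotype)) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Read a sample design table
#'
#' Reads a tab-delimited table with one row per sample, a sample id in
#' the first column (or a `sample_id` column), a phenotype column and
#' optional covariate columns. When `mvalues` is supplied the design is
#' aligned to the matrix column order; samples missing from either side
#' are dropped with a warning, and fewer than 3 common samples is an
#' error.
#'
#' @param path Path to the tab-delimited design table.
#' @param phenotype_col Name of the phenotype column.
#' @param covariate_cols Character vector of covariate column names.
#' @param mvalues Optional M-value matrix to align against.
#' @return A `sample_design`.
#' @export
read_sample_design <- function(path, phenotype_col,
                               covariate_cols = character(0),
                               mvalues = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  id_col <- if ("sample_id" %in% colnames(dt)) "sample_id" else colnames(dt)[1L]
  if (!phenotype_col %in% colnames(dt)) {
    stop("phenotype column '", phenotype_col, "' not found", call. = FALSE)
  }
  missing_cov <- setdiff(covariate_cols, colnames(dt))
  if (length(missing_cov)) {
    stop("covariate column(s) not found: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  covs <- if (length(covariate_cols)) {
    as.matrix(dt[, covariate_cols, drop = FALSE])
  } else NULL
  d <- sample_design(phenotype = dt[[phenotype_col]],
                     sample_ids = as.character(dt[[id_col]]),
                     covariates = covs)
  if (!is.null(mvalues)) d <- align_design(d, mvalues)
  d
}

#' Align a sample design to an M-value matrix
#'
#' Restricts and reorders the design to the matrix column order. Dropped
#' samples (on either side) are reported with a warning.
#'
#' @param design A `sample_design`.
#' @param mvalues M-value matrix whose columns define the target order.
#' @return A list with elements `design` (aligned `sample_design`) and
#'   `mvalues` (matrix restricted to the common samples).
#' @export
align_design <- function(design, mvalues) {
  common <- intersect(colnames(mvalues), design$sample_ids)
  if (length(common) < 3L) {
    stop("fewer than 3 samples shared between matrix and design",
         call. = FALSE)
  }
  dropped <- c(setdiff(colnames(mvalues), common),
               setdiff(design$sample_ids, common))
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " sample(s) absent from matrix or design: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "", call. = FALSE)
  }
  idx <- match(common, design$sample_ids)
  covs <- design$covariates[idx, -1L, drop = FALSE]
  d <- sample_design(phenotype = design$phenotype[idx],
                     sample_ids = common,
                     covariates = if (ncol(covs)) covs else NULL)
  list(design = d, mvalues = mvalues[, common, drop = FALSE])
}

# Fixed column order of the on-disk results dialect.
.results_columns <- c("region_id", "n_cpgs", "delta_hat", "se_delta",
                      "kappa_hat", "se_kappa", "sigma_b2", "p_mean",
                      "p_var", "p_joint", "fdr_mean", "fdr_var",
                      "fdr_joint", "call", "converged", "n_iter")

#' Write a results table
#'
#' Writes the per-region results in a stable tab-delimited dialect with
#' fixed column order (`region_id, n_cpgs, delta_hat, se_delta,
#' kappa_hat, se_kappa, sigma_b2, p_mean, p_var, p_joint, fdr_mean,
#' fdr_var, fdr_joint, call, converged, n_iter`). Floats are rendered
#' with 12 significant digits so a read/write round trip is lossless
#' well below 1e-9.
#'
#' @param results Results `data.frame` as returned by [methdys()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(results, path) {
  miss <- setdiff(.results_columns, colnames(results))
  if (length(miss)) {
    stop("results table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- results[, .results_columns, drop = FALSE]
  num <- vapply(out, is.double, logical(1))
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.12g", out[[j]]))
  }
  out$converged <- tolower(as.character(out$converged))
  con <- file(path, open = "wb")  # force LF endings on every platform
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Path to the tab-delimited results file.
#' @return Results `data.frame` with the fixed column set.
#' @export
read_results <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE,
                          na.strings = "NA")
  miss <- setdiff(.results_columns, colnames(dt))
  if (length(miss)) {
    stop("not a results file; missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dt$converged <- dt$converged %in% c("true", "TRUE", "True")
  dt
}
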