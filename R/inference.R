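#' Wald test against zero
#'
#' `W = (estimate / se)^2` referred to a chi-squared distribution with
#' one degree of freedom (two-sided by construction).
#'
#' @param estimate Point estimate.
#' @param se Standard error (> 0).
#' @return List with `W` and `p`; both `NA` when `se` is non-positive
#'   or either input is non-finite.
#' @export
wald_test <- function(estimate, se) {
  bad <- !is.finite(estimate) | !is.finite(se) | se <= 0
  W <- ifelse(bad, NA_real_, (estimate / se)^2)
  p <- ifelse(bad, NA_real_, stats::pchisq(W, df = 1, lower.tail = FALSE))
  list(W = W, p = p)
}

#' Cauchy combination of two p-values
#'
#' Combines the mean-model and variance-model p-values into a joint
#' test via the Cauchy combination test:
#' `T = (tan((1/2 - p_M) pi) + tan((1/2 - p_V) pi)) / 2` and
#' `p_joint = 1/2 - arctan(T)/pi`. The combination is valid under
#' arbitrary dependence of the two inputs. Inputs are clamped to
#' `[epsilon, 1 - epsilon]`; below `1e-10` the tangent is evaluated by
#' the stable expansion `tan((1/2 - p) pi) ~ 1/(p pi)` to avoid
#' cancellation.
#'
#' @param p_mean,p_var P-values in \[0, 1\] (vectorized).
#' @param epsilon Clamping bound; default `1e-15`.
#' @return List with `T` (combination statistic) and `p_joint`.
#' @export
cauchy_combine <- function(p_mean, p_var, epsilon = 1e-15) {
  stopifnot(length(p_mean) == length(p_var))
  tan_term <- function(p) {
    p <- pmin(pmax(p, epsilon), 1 - epsilon)
    ifelse(p < 1e-10, 1 / (p * pi), tan((0.5 - p) * pi))
  }
  bad <- !is.finite(p_mean) | !is.finite(p_var)
  Tstat <- rep(NA_real_, length(p_mean))
  ok <- !bad
  Tstat[ok] <- (tan_term(p_mean[ok]) + tan_term(p_var[ok])) / 2
  p_joint <- rep(NA_real_, length(p_mean))
  big <- ok & Tstat > 1e10
  # arctan tail expansion for huge T: 1/2 - atan(T)/pi ~ 1/(pi T)
  p_joint[big] <- 1 / (pi * Tstat[big])
  reg <- ok & !big
  p_joint[reg] <- 0.5 - atan(Tstat[reg]) / pi
  p_joint <- pmin(pmax(p_joint, 0), 1)
  list(T = Tstat, p_joint = p_joint)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment. `NA` p-values are excluded from the family
#' size and returned as `NA`.
#'
#' @param pvec Numeric vector of p-values in \[0, 1\] (may contain NA).
#' @return Adjusted q-values, same length and order as `pvec`.
#' @export
bh_adjust <- function(pvec) {
  out <- rep(NA_real_, length(pvec))
  ok <- !is.na(pvec)
  if (any(pvec[ok] < 0 | pvec[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out[ok] <- stats::p.adjust(pvec[ok], method = "BH")
  out
}

#' Classify regions into DMR / VMR / DVMR calls
#'
#' Adds independent boolean flags `is_dmr` (`fdr_mean < alpha`),
#' `is_vmr` (`fdr_var < alpha`), `is_dvmr` (`fdr_joint < alpha`) and a
#' single exclusive `call` column with precedence DVMR > DMR > VMR
#' (`"none"` otherwise; `NA` when all three q-values are missing).
#'
#' @param results Data frame with `fdr_mean`, `fdr_var`, `fdr_joint`.
#' @param alpha Significance threshold; default 0.05.
#' @return `results` with `is_dmr`, `is_vmr`, `is_dvmr`, `call` added.
#' @export
classify_regions <- function(results, alpha = 0.05) {
  stopifnot(all(c("fdr_mean", "fdr_var", "fdr_joint") %in% colnames(results)))
  lt <- function(x) !is.na(x) & x < alpha
  results$is_dmr <- lt(results$fdr_mean)
  results$is_vmr <- lt(results$fdr_var)
  results$is_dvmr <- lt(results$fdr_joint)
  call <- ifelse(results$is_dvmr, "DVMR",
          ifelse(results$is_dmr, "DMR",
          ifelse(results$is_vmr, "VMR", "none")))
  all_na <- is.na(results$fdr_mean) & is.na(results$fdr_var) &
    is.na(results$fdr_joint)
  call[all_na] <- NA_character_
  results$call <- call
  results
}

#' Region-based detection of methylation dysregulation
#'
#' End-to-end analysis: every region is fit with the Gaussian HGLM
#' ([fit_region()]), the phenotype effects on the mean (`delta`) and
#' log-variance (`kappa`) are Wald-tested, the two p-values are
#' combined with the Cauchy combination test, each of the three
#' p-value families is BH-adjusted across regions, and regions are
#' classified as DMR / VMR / DVMR at level `alpha`.
#'
#' @param mvalues Numeric M-value matrix (CpGs x samples) with row and
#'   column names; see [read_mvalue_matrix()].
#' @param regions Region map `data.frame` (`cpg_id`, `region_id`); see
#'   [read_region_map()].
#' @param design A `sample_design`; aligned to `mvalues` internally.
#' @param alpha Significance threshold for calls; default 0.05.
#' @param control A [methdys_control()] list.
#' @param threads Number of worker processes for region fitting
#'   (forked; results are collected in region order, so output is
#'   identical to a serial run).
#' @return A results `data.frame` with one row per region: identifiers
#'   and size, `delta_hat`, `se_delta`, `kappa_hat`, `se_kappa`,
#'   `sigma_b2`, Wald statistics, raw and BH-adjusted p-values for the
#'   mean / variance / joint tests, boolean flags, the exclusive
#'   `call`, and convergence information.
#' @examples
#' sim <- simulate_study(scenario_config(n_regions = 20, N = 30,
#'                                       scenario = "DMR", seed = 1))
#' res <- methdys(sim$mvalues, sim$regions, sim$design)
#' head(res[, c("region_id", "delta_hat", "p_mean", "call")])
#' @export
methdys <- function(mvalues, regions, design, alpha = 0.05,
                    control = methdys_control(), threads = 1L) {
  validate_mvalues(mvalues)
  regions <- validate_region_map(regions)
  al <- align_design(design, mvalues)
  design <- al$design
  mvalues <- al$mvalues

  row_idx <- match(regions$cpg_id, rownames(mvalues))
  keep <- !is.na(row_idx)
  regions <- regions[keep, , drop = FALSE]
  row_idx <- row_idx[keep]
  if (!nrow(regions)) stop("no region CpGs found in the matrix", call. = FALSE)
  region_ids <- unique(regions$region_id)
  rfac <- factor(regions$region_id, levels = region_ids)
  idx_sets <- split(row_idx, rfac)
  cpg_sets <- split(regions$cpg_id, rfac)

  Xs <- cbind(design$covariates, phenotype = design$phenotype)
  fit_one <- function(k) {
    rd <- .region_design_from_block(
      mvalues[idx_sets[[k]], , drop = FALSE], Xs,
      cpg_sets[[k]], design$sample_ids)
    fit_region(rd, control)
  }
  ks <- seq_along(region_ids)
  fits <- if (threads > 1L) {
    parallel::mclapply(ks, fit_one, mc.cores = threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(ks, fit_one)
  }

  n_nonconv <- sum(!vapply(fits, `[[`, logical(1), "converged"))
  if (n_nonconv > 0L) {
    warning(n_nonconv, " of ", length(fits),
            " regions did not converge (flagged in the results table)",
            call. = FALSE)
  }

  wm <- wald_test(vapply(fits, `[[`, numeric(1), "delta_hat"),
                  vapply(fits, `[[`, numeric(1), "se_delta"))
  wv <- wald_test(vapply(fits, `[[`, numeric(1), "kappa_hat"),
                  vapply(fits, `[[`, numeric(1), "se_kappa"))
  cc <- cauchy_combine(wm$p, wv$p)

  res <- data.frame(
    region_id = region_ids,
    n_cpgs = vapply(fits, `[[`, integer(1), "n_cpgs"),
    delta_hat = vapply(fits, `[[`, numeric(1), "delta_hat"),
    se_delta = vapply(fits, `[[`, numeric(1), "se_delta"),
    kappa_hat = vapply(fits, `[[`, numeric(1), "kappa_hat"),
    se_kappa = vapply(fits, `[[`, numeric(1), "se_kappa"),
    sigma_b2 = vapply(fits, `[[`, numeric(1), "sigma_b2"),
    W_mean = wm$W, W_var = wv$W, T_cauchy = cc$T,
    p_mean = wm$p, p_var = wv$p, p_joint = cc$p_joint,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    n_iter = vapply(fits, `[[`, integer(1), "n_iter"),
    stringsAsFactors = FALSE
  )
  res$fdr_mean <- bh_adjust(res$p_mean)
  res$fdr_var <- bh_adjust(res$p_var)
  res$fdr_joint <- bh_adjust(res$p_joint)
  res <- classify_regions(res, alpha)
  rownames(res) <- NULL
  res
}
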