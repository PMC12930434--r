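# Deterministic per-region seed derived from (master seed, region index),
# kept below 2^31 so it is a valid R seed. A fixed LCG-style mix keeps
# region k's stream identical regardless of how many regions are drawn.
.derive_seed <- function(seed, k) {
  m <- 2147483629  # prime below 2^31; all products stay below 2^53
  s <- as.numeric(seed) %% m
  kk <- as.numeric(k) %% m
  as.integer((s * 69069 + kk * 3580621 + 12345) %% m)
}

#' Scenario configuration for the simulation engine
#'
#' Captures one simulation scenario: regions of contiguous CpGs drawn
#' per sample from a multivariate normal with compound-symmetry
#' correlation, a group mean shift on signal regions (DMR / DVMR
#' scenarios) and a group-2 residual variance inflation (VMR / DVMR
#' scenarios). Defaults follow the benchmark design this package is
#' calibrated against: 10% true signals, mean effect 0.7 M-value
#' units, 2.5-fold variance inflation, a 30/70 group split,
#' within-region correlation 0.5, unit baseline SD, and region sizes
#' uniform on 3..10 CpGs.
#'
#' @param scenario One of `"null"`, `"DMR"`, `"VMR"`, `"DVMR"`.
#' @param n_regions Number of regions.
#' @param prop_signal Fraction of true-signal regions (ignored for
#'   `"null"`, where it is 0).
#' @param N Number of samples.
#' @param mean_effect Group mean shift (M-value units) on signal
#'   regions in DMR/DVMR scenarios.
#' @param var_fold Group-2 variance multiplier (>= 1) on signal
#'   regions in VMR/DVMR scenarios.
#' @param group_props Length-2 proportions `(group 1, group 2)`
#'   summing to 1; group 2 (phenotype `G = 1`) carries the effects.
#' @param n_cpgs_range Integer range (min, max) of CpGs per region.
#' @param rho Compound-symmetry correlation in `[0, 1)`.
#' @param base_sd Baseline residual SD of group 1.
#' @param mu0 Baseline mean M-value.
#' @param seed Master seed; every draw is a pure function of it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("null", "DMR", "VMR", "DVMR"),
                            n_regions = 10000L, prop_signal = 0.1,
                            N = 100L, mean_effect = 0.7, var_fold = 2.5,
                            group_props = c(0.3, 0.7),
                            n_cpgs_range = c(3L, 10L),
                            rho = 0.5, base_sd = 1, mu0 = 0,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_regions >= 1, prop_signal >= 0, prop_signal <= 1,
            N >= 4, rho >= 0, rho < 1, base_sd > 0, var_fold >= 1,
            length(group_props) == 2L, all(group_props > 0),
            abs(sum(group_props) - 1) < 1e-8,
            length(n_cpgs_range) == 2L,
            n_cpgs_range[1] >= 1, n_cpgs_range[2] >= n_cpgs_range[1])
  if (scenario == "null") prop_signal <- 0
  structure(list(scenario = scenario, n_regions = as.integer(n_regions),
                 prop_signal = prop_signal, N = as.integer(N),
                 mean_effect = mean_effect, var_fold = var_fold,
                 group_props = group_props,
                 n_cpgs_range = as.integer(n_cpgs_range),
                 rho = rho, base_sd = base_sd, mu0 = mu0,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate one region
#'
#' Each sample's CpG vector is drawn independently from
#' `MVN(mu_g, sigma_g^2 * [(1 - rho) I + rho J])` with
#' `mu_g = mu0 + mean_effect * g` (constant across CpGs) and
#' `sigma_g^2 = base_sd^2 * var_fold^g`, where `g` is the sample's
#' group label (0/1). The compound-symmetry draw uses the exact
#' factorization `y = mu + sigma_g (sqrt(rho) u + sqrt(1-rho) z)` with
#' `u` a shared standard normal per sample and `z` i.i.d. per CpG.
#'
#' @param n_cpgs Number of CpGs in the region.
#' @param N Number of samples.
#' @param group_labels 0/1 vector of length `N`.
#' @param rho Compound-symmetry correlation in `[0, 1)`.
#' @param base_sd Group-1 residual SD.
#' @param mean_effect Mean shift added to group 2.
#' @param var_fold Group-2 variance multiplier.
#' @param mu0 Baseline mean.
#' @param seed Optional seed set before drawing (the caller may also
#'   manage the RNG state itself).
#' @return `n_cpgs x N` numeric matrix of M-values.
#' @export
simulate_region <- function(n_cpgs, N, group_labels, rho, base_sd,
                            mean_effect = 0, var_fold = 1, mu0 = 0,
                            seed = NULL) {
  stopifnot(length(group_labels) == N, all(group_labels %in% c(0, 1)),
            rho >= 0, rho < 1, var_fold >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- as.numeric(group_labels)
  sigma_g <- base_sd * sqrt(var_fold^g)            # per-sample SD
  mu_g <- mu0 + mean_effect * g
  u <- stats::rnorm(N)                             # shared component
  z <- matrix(stats::rnorm(n_cpgs * N), n_cpgs, N) # CpG-specific
  shared <- sqrt(rho) * u
  y <- sweep(z * sqrt(1 - rho), 2L, shared, "+")
  y <- sweep(y, 2L, sigma_g, "*")
  sweep(y, 2L, mu_g, "+")
}

#' Simulate a region-structured methylation study
#'
#' Generates a full synthetic dataset with known ground truth: a
#' CpG-by-sample M-value matrix, a region map, a sample design, and a
#' per-region truth table. Group sizes are `floor(N * pi_1)` and the
#' remainder; the group assignment is shuffled once under the master
#' seed. Exactly `round(n_regions * prop_signal)` regions carry the
#' scenario's effects (mean shift for DMR/DVMR, variance inflation for
#' VMR/DVMR); each region is drawn from its own deterministic stream
#' derived from `(seed, region index)`, so region `k` is identical no
#' matter how many regions are generated.
#'
#' @param cfg A [scenario_config()].
#' @return A list of class `sim_dataset` with elements `mvalues`,
#'   `regions`, `design`, `truth`
#'   (`region_id`, `is_signal`, `scenario`, `true_delta`,
#'   `true_log_varfold`) and the generating `config`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  N <- cfg$N
  n1 <- floor(N * cfg$group_props[1])
  n2 <- N - n1
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples", call. = FALSE)

  set.seed(.derive_seed(cfg$seed, 0L))
  G <- sample(rep(c(0, 1), c(n1, n2)))
  n_signal <- round(cfg$n_regions * cfg$prop_signal)
  signal_idx <- if (n_signal > 0) {
    sort(sample.int(cfg$n_regions, n_signal))
  } else integer(0)
  is_signal <- seq_len(cfg$n_regions) %in% signal_idx

  use_delta <- cfg$scenario %in% c("DMR", "DVMR")
  use_var <- cfg$scenario %in% c("VMR", "DVMR")

  region_ids <- sprintf("R%05d", seq_len(cfg$n_regions))
  blocks <- vector("list", cfg$n_regions)
  sizes <- integer(cfg$n_regions)
  for (k in seq_len(cfg$n_regions)) {
    set.seed(.derive_seed(cfg$seed, k))
    n_r <- if (cfg$n_cpgs_range[1] == cfg$n_cpgs_range[2]) {
      cfg$n_cpgs_range[1]
    } else {
      sample(seq(cfg$n_cpgs_range[1], cfg$n_cpgs_range[2]), 1L)
    }
    sizes[k] <- n_r
    blocks[[k]] <- simulate_region(
      n_cpgs = n_r, N = N, group_labels = G,
      rho = cfg$rho, base_sd = cfg$base_sd,
      mean_effect = if (is_signal[k] && use_delta) cfg$mean_effect else 0,
      var_fold = if (is_signal[k] && use_var) cfg$var_fold else 1,
      mu0 = cfg$mu0)
  }
  mvalues <- do.call(rbind, blocks)
  cpg_ids <- unlist(lapply(seq_len(cfg$n_regions), function(k) {
    paste0(region_ids[k], "_cg", seq_len(sizes[k]))
  }), use.names = FALSE)
  sample_ids <- sprintf("S%04d", seq_len(N))
  dimnames(mvalues) <- list(cpg_ids, sample_ids)

  regions <- data.frame(cpg_id = cpg_ids,
                        region_id = rep(region_ids, sizes),
                        stringsAsFactors = FALSE)
  design <- sample_design(phenotype = G, sample_ids = sample_ids)
  truth <- data.frame(
    region_id = region_ids,
    is_signal = is_signal,
    scenario = cfg$scenario,
    true_delta = ifelse(is_signal & use_delta, cfg$mean_effect, 0),
    true_log_varfold = ifelse(is_signal & use_var, log(cfg$var_fold), 0),
    stringsAsFactors = FALSE
  )
  structure(list(mvalues = mvalues, regions = regions, design = design,
                 truth = truth, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", nrow(x$mvalues), "CpGs in",
      nrow(x$truth), "regions x", ncol(x$mvalues), "samples;",
      sum(x$truth$is_signal), x$config$scenario, "signal region(s)\n")
  invisible(x)
}

#' Permute phenotype labels
#'
#' Uniform random permutation of the phenotype vector of a
#' `sample_design`, leaving covariates untouched. Used to build null
#' datasets with no phenotype-methylation association.
#'
#' @param design A `sample_design`.
#' @param seed Seed for the permutation.
#' @return A `sample_design` with permuted phenotype.
#' @export
permute_labels <- function(design, seed) {
  stopifnot(inherits(design, "sample_design"))
  set.seed(seed)
  perm <- sample.int(length(design$phenotype))
  covs <- design$covariates[, -1L, drop = FALSE]
  sample_design(phenotype = design$phenotype[perm],
                sample_ids = design$sample_ids,
                covariates = if (ncol(covs)) covs else NULL)
}

#' Write a simulated dataset as TSV files
#'
#' Writes `<prefix>_mvalues.tsv`, `<prefix>_regions.tsv`,
#' `<prefix>_design.tsv`, `<prefix>_truth.tsv` in the dialects read by
#' [read_mvalue_matrix()], [read_region_map()] and
#' [read_sample_design()].
#'
#' @param sim A `sim_dataset`.
#' @param prefix Output path prefix.
#' @return Character vector of the four paths, invisibly.
#' @export
write_sim_dataset <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_dataset"))
  paths <- paste0(prefix, c("_mvalues.tsv", "_regions.tsv",
                            "_design.tsv", "_truth.tsv"))
  mv <- data.frame(cpg_id = rownames(sim$mvalues), sim$mvalues,
                   check.names = FALSE)
  data.table::fwrite(mv, paths[1], sep = "\t")
  data.table::fwrite(sim$regions, paths[2], sep = "\t",
                     col.names = FALSE)
  des <- data.frame(sample_id = sim$design$sample_ids,
                    phenotype = sim$design$phenotype)
  covs <- sim$design$covariates[, -1L, drop = FALSE]
  if (ncol(covs)) des <- cbind(des, covs)
  data.table::fwrite(des, paths[3], sep = "\t")
  data.table::fwrite(sim$truth, paths[4], sep = "\t")
  invisible(paths)
}
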