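#' Control parameters for the region-level HGLM fitter
#'
#' @param tol Relative convergence tolerance on the outer alternating
#'   updates (absolute tolerance `1e-8` near zero). Default `1e-6`.
#' @param max_iter Outer iteration cap. Default 100.
#' @param inner_max_iter Iteration cap for the inner dispersion GLM.
#'   Default 50.
#' @param leverage_correction Use leverage-adjusted squared residuals
#'   `d = e^2/(1-q)` with prior weights `(1-q)/2` in the dispersion
#'   model (reduces the downward bias of plug-in residual variances).
#'   `FALSE` uses `d = e^2` with weight `1/2`, the joint maximum
#'   h-likelihood variant. Default `TRUE`.
#' @param eta_clamp Bound on the variance-model linear predictor
#'   `log sigma^2`; values are clamped to `[-eta_clamp, eta_clamp]` to
#'   prevent weight overflow. Default 30.
#' @param sigma_b2_pin Either `NULL` (estimate the random-intercept
#'   variance) or a fixed non-negative value to pin it at. Single-CpG
#'   regions are always pinned at 0 (one observation per subject makes
#'   the intercept unidentifiable).
#' @param on_nonconverged `"report"` keeps the last iterate (flagged
#'   `converged = FALSE`); `"na"` replaces estimates with `NA`.
#' @param track_h Record the h-likelihood after every outer iteration
#'   in the fit's `h_trace` element. Default `FALSE`.
#' @return A list of class `methdys_control`.
#' @export
methdys_control <- function(tol = 1e-6, max_iter = 100L,
                            inner_max_iter = 50L,
                            leverage_correction = TRUE,
                            eta_clamp = 30,
                            sigma_b2_pin = NULL,
                            on_nonconverged = c("report", "na"),
                            track_h = FALSE) {
  stopifnot(tol > 0, max_iter >= 1, inner_max_iter >= 1, eta_clamp > 0)
  if (!is.null(sigma_b2_pin)) stopifnot(sigma_b2_pin >= 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 inner_max_iter = as.integer(inner_max_iter),
                 leverage_correction = isTRUE(leverage_correction),
                 eta_clamp = eta_clamp,
                 sigma_b2_pin = sigma_b2_pin,
                 on_nonconverged = match.arg(on_nonconverged),
                 track_h = isTRUE(track_h)),
            class = "methdys_control")
}

#' Stack one region into model form
#'
#' Builds the stacked response and design matrices for one region:
#' CpG-level M-values become repeated measurements within each sample,
#' ordered sample-major (all CpGs of sample 1, then sample 2, ...).
#' The fixed-effect design is `intercept + covariates + phenotype`
#' (phenotype last); the variance-model design is identical, with the
#' per-sample rows replicated across that sample's CpGs.
#'
#' @param cpg_ids Character vector of the region's CpG ids, in region
#'   order.
#' @param mvalues M-value matrix (CpGs x samples).
#' @param design A `sample_design` aligned to `mvalues` columns.
#' @return A list (`region_design`) with `Y`, `X_mean`, `X_var`,
#'   `sample_index` (subject of each observation), `n_cpgs`, `N`,
#'   `delta_col`, `kappa_col` (phenotype column index in each design).
#' @export
build_region_design <- function(cpg_ids, mvalues, design) {
  cpg_ids <- as.character(cpg_ids)
  missing_cpg <- setdiff(cpg_ids, rownames(mvalues))
  if (length(missing_cpg) == length(cpg_ids)) {
    stop("region has no usable CpGs in the matrix", call. = FALSE)
  }
  cpg_ids <- cpg_ids[cpg_ids %in% rownames(mvalues)]
  if (!identical(colnames(mvalues), design$sample_ids)) {
    stop("design is not aligned to the matrix columns; see align_design()",
         call. = FALSE)
  }
  block <- mvalues[cpg_ids, , drop = FALSE]       # n_r x N
  Xs <- cbind(design$covariates, phenotype = design$phenotype)
  .region_design_from_block(block, Xs, cpg_ids, design$sample_ids)
}

# internal constructor working from the n_r x N value block and the
# per-sample design; caches the per-sample sufficient statistics used
# by the collapsed fitter
.region_design_from_block <- function(block, Xs, cpg_ids, sample_ids) {
  n_r <- nrow(block)
  N <- ncol(block)
  Y <- as.vector(block)                           # sample-major stack
  sample_index <- rep(seq_len(N), each = n_r)
  X <- Xs[sample_index, , drop = FALSE]
  rownames(X) <- NULL
  structure(list(Y = Y, X_mean = X, X_var = X,
                 sample_index = sample_index,
                 n_cpgs = n_r, N = N,
                 cpg_ids = cpg_ids, sample_ids = sample_ids,
                 delta_col = ncol(X), kappa_col = ncol(X),
                 Xs = Xs, Xvs = Xs,
                 sy = .colSums(block, n_r, N),
                 sy2 = .colSums(block^2, n_r, N)),
            class = "region_design")
}

#' Solve the weighted mean model with a subject random intercept
#'
#' Solves the joint penalized weighted least-squares system (Henderson
#' mixed-model equations) for the Gaussian HGLM mean model at fixed
#' observation precisions and random-intercept variance: fixed effects
#' and random intercepts maximize the h-likelihood in `(beta, b)` with
#' the variance parameters held fixed. Exploits the diagonal structure
#' of the subject block via the Schur complement, so cost is linear in
#' the number of observations.
#'
#' @param rd A `region_design`.
#' @param weights Per-observation precisions `1/sigma^2_ij` (> 0).
#' @param sigma_b2 Random-intercept variance (>= 0); 0 pins all `b` to
#'   zero and reduces to weighted least squares.
#' @return A list with `coef` (fixed effects), `b` (subject
#'   intercepts), `cov_fixed` (fixed-effect covariance block),
#'   `leverage` (per-observation augmented-hat diagonals),
#'   `subject_leverage` (random-effect leverages), `mu` (fitted means),
#'   or `NULL` when the system is singular.
#' @export
solve_mean_model <- function(rd, weights, sigma_b2) {
  X <- rd$X_mean
  Y <- rd$Y
  g <- rd$sample_index
  n <- length(Y)
  p <- ncol(X)
  if (length(weights) == 1L) weights <- rep(weights, n)
  if (any(weights <= 0) || any(!is.finite(weights))) {
    stop("weights must be strictly positive and finite", call. = FALSE)
  }
  if (sigma_b2 < 0) stop("sigma_b2 must be >= 0", call. = FALSE)
  wX <- X * weights
  XtWX <- crossprod(X, wX)
  XtWy <- crossprod(wX, Y)

  if (sigma_b2 == 0) {
    S_inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(S_inv)) return(NULL)
    beta <- drop(S_inv %*% XtWy)
    q <- weights * rowSums((X %*% S_inv) * X)
    mu <- drop(X %*% beta)
    return(list(coef = stats::setNames(beta, colnames(X)),
                b = numeric(rd$N), cov_fixed = S_inv,
                leverage = q, subject_leverage = rep(0, rd$N), mu = mu))
  }

  D <- unname(drop(rowsum(weights, g))) + 1 / sigma_b2  # N, diagonal block
  A <- t(rowsum(wX, g))                                  # p x N = X'WZ
  Zty <- unname(drop(rowsum(weights * Y, g)))            # N
  AD <- sweep(A, 2L, D, "/")                             # A D^{-1}
  S <- XtWX - tcrossprod(AD, A)                          # Schur complement
  S_inv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(S_inv)) return(NULL)
  beta <- drop(S_inv %*% (XtWy - AD %*% Zty))
  b <- (Zty - unname(drop(crossprod(A, beta)))) / D

  # blocks of the inverse augmented coefficient matrix
  M <- -S_inv %*% AD                                     # beta-b block, p x N
  dbb <- 1 / D + colSums(AD * (S_inv %*% AD))            # diag of b-b block
  qx <- rowSums((X %*% S_inv) * X)
  qxb <- rowSums(X * t(M)[g, , drop = FALSE])
  q <- weights * (qx + 2 * qxb + dbb[g])
  mu <- drop(X %*% beta) + b[g]
  list(coef = stats::setNames(beta, colnames(X)), b = b,
       cov_fixed = S_inv, leverage = q,
       subject_leverage = dbb / sigma_b2, mu = mu)
}

#' Fit the log-linear dispersion model
#'
#' Updates the variance model by a gamma-type GLM with log link:
#' squared (optionally leverage-standardized) residuals from the mean
#' model are the response, consistent with `e^2 ~ sigma^2 * chi^2_1`,
#' so the score equation at the optimum is
#' `sum w_i (d_i / sigma^2_i - 1) x_i = 0`.
#'
#' @param rd A `region_design` (supplies the variance design `X_var`).
#' @param residuals Residuals `y - mu` from the current mean fit.
#' @param leverages Per-observation leverages in `[0, 1)`.
#' @param use_leverage_correction If `TRUE`, response
#'   `d = e^2/(1-q)` with prior weight `(1-q)/2`; if `FALSE`, `d = e^2`
#'   with weight `1/2`.
#' @param gamma_init Optional warm-start coefficients.
#' @param max_iter,tol Inner IRLS controls.
#' @param eta_clamp Clamp for the linear predictor.
#' @return List with `gamma` (coefficients, phenotype effect last),
#'   `cov` (coefficient covariance from the GLM information matrix),
#'   `eta` (clamped linear predictor), `converged`, `n_iter`,
#'   `n_clamped` (observations hitting the clamp at the solution).
#' @export
solve_variance_model <- function(rd, residuals, leverages = NULL,
                                 use_leverage_correction = TRUE,
                                 gamma_init = NULL,
                                 max_iter = 50L, tol = 1e-10,
                                 eta_clamp = 30) {
  Xv <- rd$X_var
  e2 <- residuals^2
  if (all(e2 < 1e-300)) {
    stop("all residuals are zero; degenerate region", call. = FALSE)
  }
  if (use_leverage_correction) {
    if (is.null(leverages)) {
      stop("leverages required when use_leverage_correction = TRUE",
           call. = FALSE)
    }
    lv <- pmin(pmax(leverages, 0), 1 - 1e-8)
    d <- e2 / (1 - lv)
    pw <- (1 - lv) / 2
  } else {
    d <- e2
    pw <- rep(0.5, length(e2))
  }
  if (is.null(gamma_init)) {
    d0 <- pmax(d, 1e-8 * mean(d))
    gamma <- stats::lm.wfit(Xv, log(d0), pw)$coefficients
  } else {
    gamma <- gamma_init
  }
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- pmin(pmax(drop(Xv %*% gamma), -eta_clamp), eta_clamp)
    mu <- exp(eta)
    z <- eta + d / mu - 1            # IRLS working response, log link
    gamma_new <- stats::lm.wfit(Xv, z, pw)$coefficients
    delta <- max(abs(gamma_new - gamma) / pmax(abs(gamma), 1))
    gamma <- gamma_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  eta <- pmin(pmax(drop(Xv %*% gamma), -eta_clamp), eta_clamp)
  info <- crossprod(Xv, Xv * pw)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  list(gamma = stats::setNames(drop(gamma), colnames(Xv)), cov = cov,
       eta = eta, converged = converged, n_iter = iter,
       n_clamped = sum(abs(drop(Xv %*% gamma)) > eta_clamp))
}

#' REML-type update of the random-intercept variance
#'
#' Adjusted-profile update `sigma_b^2 = sum(b^2) / sum(1 - q_i)` with
#' `q_i` the random-effect leverages (diagonal of the subject block of
#' the inverse augmented system divided by the current variance). In
#' the Gaussian homoscedastic special case this fixed point is exactly
#' the REML estimate.
#'
#' @param b_hat Subject random-intercept predictions.
#' @param subject_leverages Random-effect leverages in `[0, 1)`.
#' @return Updated non-negative variance; 0 when `sum(b^2) < 1e-12`.
#' @export
update_sigma_b2 <- function(b_hat, subject_leverages) {
  if (length(b_hat) < 2L) {
    stop("need at least 2 subjects to update sigma_b2", call. = FALSE)
  }
  num <- sum(b_hat^2)
  if (num < 1e-12) return(0)
  den <- sum(1 - pmin(pmax(subject_leverages, 0), 1 - 1e-12))
  max(num / den, 0)
}

#' h-likelihood of a fitted region
#'
#' Joint log-likelihood of the data and the random intercepts:
#' `sum_ij [-log(2 pi sigma^2_ij)/2 - e^2_ij/(2 sigma^2_ij)] +
#'  sum_i  [-log(2 pi sigma_b^2)/2 - b_i^2/(2 sigma_b^2)]`.
#' When `sigma_b2 = 0` the random-effect term is defined as 0 and all
#' `b` must be zero.
#'
#' @param residuals Observation residuals `y - mu`.
#' @param eta Variance-model linear predictor `log sigma^2` per
#'   observation.
#' @param b Subject random intercepts.
#' @param sigma_b2 Random-intercept variance.
#' @return The h-likelihood value (scalar).
#' @export
h_likelihood <- function(residuals, eta, b, sigma_b2) {
  sig2 <- exp(eta)
  if (any(sig2 <= 0) || any(!is.finite(sig2))) {
    stop("non-positive or non-finite variance in h-likelihood",
         call. = FALSE)
  }
  h <- sum(-0.5 * log(2 * pi * sig2) - residuals^2 / (2 * sig2))
  if (sigma_b2 > 0) {
    h <- h + sum(-0.5 * log(2 * pi * sigma_b2) - b^2 / (2 * sigma_b2))
  } else if (any(b != 0)) {
    stop("sigma_b2 = 0 requires all random intercepts to be zero",
         call. = FALSE)
  }
  h
}

# convergence criterion: |change| < tol*|old| + 1e-8, expressed as a
# single ratio (the additive 0.01 makes the absolute floor tol/100)
.param_change <- function(new, old, tol) {
  max(abs(new - old) / (abs(old) + 1e-2))
}

#' Fit the HGLM for one region
#'
#' Alternates (i) the weighted mixed-model solve of the mean model at
#' precisions `exp(-eta)`, (ii) the log-link dispersion GLM on squared
#' standardized residuals, and (iii) the REML-type random-intercept
#' variance update, until the maximum relative parameter change drops
#' below `control$tol` or the iteration cap is reached.
#'
#' @param rd A `region_design` from [build_region_design()].
#' @param control A [methdys_control()] list.
#' @return An object of class `region_fit`: list with elements
#'   `beta_hat`, `delta_hat`, `gamma_hat`, `kappa_hat`, `b_hat`,
#'   `sigma_b2`, `se_delta`, `se_kappa`, `cov_fixed`, `cov_var`,
#'   `mu_hat`, `eta_hat`, `residuals`, `h_lik`, `converged`, `n_iter`,
#'   `n_cpgs`, `N`, `estimable`, and (if tracked) `h_trace`.
#' @export
fit_region <- function(rd, control = methdys_control()) {
  tryCatch({
    # covariates are constant within a sample for designs built by
    # build_region_design, which admits a collapsed per-sample solve;
    # the generic stacked path handles anything else
    fast <- .fit_region_fast(rd, control)
    if (is.null(fast)) .fit_region_impl(rd, control) else fast
  }, error = function(e) .failed_fit(rd, conditionMessage(e)))
}

.failed_fit <- function(rd, msg) {
  p <- ncol(rd$X_mean)
  pv <- ncol(rd$X_var)
  structure(list(beta_hat = rep(NA_real_, p), delta_hat = NA_real_,
                 gamma_hat = rep(NA_real_, pv), kappa_hat = NA_real_,
                 b_hat = rep(NA_real_, rd$N), sigma_b2 = NA_real_,
                 se_delta = NA_real_, se_kappa = NA_real_,
                 cov_fixed = NULL, cov_var = NULL,
                 mu_hat = NULL, eta_hat = NULL, residuals = NULL,
                 h_lik = NA_real_, converged = FALSE, n_iter = 0L,
                 n_cpgs = rd$n_cpgs, N = rd$N,
                 estimable = FALSE, message = msg),
            class = "region_fit")
}

.fit_region_impl <- function(rd, control) {
  X <- rd$X_mean
  Xv <- rd$X_var
  Y <- rd$Y
  g <- rd$sample_index
  n <- length(Y)
  n_r <- rd$n_cpgs
  N <- rd$N

  pin <- control$sigma_b2_pin
  if (n_r == 1L && is.null(pin)) pin <- 0  # unidentifiable with 1 obs/subject

  # --- initialization: OLS mean, log squared residual regression,
  #     method-of-moments subject variance
  ols <- stats::lm.fit(X, Y)
  if (ols$rank < ncol(X)) stop("mean design is rank deficient", call. = FALSE)
  beta <- ols$coefficients
  e <- Y - drop(X %*% beta)
  s2 <- mean(e^2)
  if (s2 < 1e-300) stop("all residuals are zero; degenerate region",
                        call. = FALSE)
  gamma <- stats::lm.fit(Xv, log(pmax(e^2, 1e-8 * s2)))$coefficients
  if (anyNA(gamma)) stop("variance design is rank deficient", call. = FALSE)
  if (is.null(pin)) {
    m_i <- drop(rowsum(e, g)) / n_r
    sigma_b2 <- max(stats::var(m_i) - s2 / n_r, 0.05 * s2)
  } else {
    sigma_b2 <- pin
  }
  eta <- pmin(pmax(drop(Xv %*% gamma), -control$eta_clamp), control$eta_clamp)

  converged <- FALSE
  iter <- 0L
  h_trace <- if (control$track_h) numeric(0) else NULL
  mean_fit <- NULL
  var_fit <- NULL
  n_clamped <- 0L
  repeat {
    iter <- iter + 1L
    theta_old <- c(beta, gamma, sigma_b2)

    w <- exp(-eta)
    mean_fit <- solve_mean_model(rd, w, sigma_b2)
    if (is.null(mean_fit)) stop("singular mean-model system", call. = FALSE)
    beta <- mean_fit$coef
    e <- Y - mean_fit$mu

    var_fit <- solve_variance_model(
      rd, e, leverages = mean_fit$leverage,
      use_leverage_correction = control$leverage_correction,
      gamma_init = gamma, max_iter = control$inner_max_iter,
      eta_clamp = control$eta_clamp)
    gamma <- var_fit$gamma
    eta <- var_fit$eta
    n_clamped <- var_fit$n_clamped

    if (is.null(pin)) {
      if (sigma_b2 > 0) {
        sigma_b2 <- update_sigma_b2(mean_fit$b, mean_fit$subject_leverage)
      } # sigma_b2 == 0 is absorbing: b is pinned at zero
    }

    if (control$track_h) {
      h_trace <- c(h_trace,
                   h_likelihood(e, eta, mean_fit$b,
                                if (all(mean_fit$b == 0)) 0 else sigma_b2))
    }

    if (.param_change(c(beta, gamma, sigma_b2), theta_old,
                      control$tol) < control$tol) {
      converged <- TRUE
      break
    }
    if (iter >= control$max_iter) break
  }

  # refresh the mean solve at the final variance estimates so that the
  # reported covariance/leverages correspond to the reported weights
  w <- exp(-eta)
  mean_fit <- solve_mean_model(rd, w, sigma_b2)
  if (is.null(mean_fit)) stop("singular mean-model system", call. = FALSE)
  beta <- mean_fit$coef
  e <- Y - mean_fit$mu

  dcol <- rd$delta_col
  kcol <- rd$kappa_col
  delta_hat <- if (!is.na(dcol)) unname(beta[dcol]) else NA_real_
  kappa_hat <- if (!is.na(kcol)) unname(gamma[kcol]) else NA_real_
  se_delta <- if (!is.na(dcol)) sqrt(mean_fit$cov_fixed[dcol, dcol]) else NA_real_
  se_kappa <- if (!is.na(kcol) && !is.null(var_fit$cov)) {
    sqrt(var_fit$cov[kcol, kcol])
  } else NA_real_

  b_for_h <- mean_fit$b
  sb_for_h <- if (all(b_for_h == 0)) 0 else sigma_b2
  h <- h_likelihood(e, eta, b_for_h, sb_for_h)

  if (!converged && control$on_nonconverged == "na") {
    beta[] <- NA_real_; gamma[] <- NA_real_
    delta_hat <- kappa_hat <- se_delta <- se_kappa <- NA_real_
  }

  structure(list(beta_hat = beta, delta_hat = delta_hat,
                 gamma_hat = gamma, kappa_hat = kappa_hat,
                 b_hat = mean_fit$b, sigma_b2 = sigma_b2,
                 se_delta = se_delta, se_kappa = se_kappa,
                 cov_fixed = mean_fit$cov_fixed, cov_var = var_fit$cov,
                 mu_hat = mean_fit$mu, eta_hat = eta, residuals = e,
                 h_lik = h, converged = converged, n_iter = iter,
                 n_cpgs = n_r, N = N, n_clamped = n_clamped,
                 estimable = TRUE, message = NULL,
                 h_trace = h_trace),
            class = "region_fit")
}

#' @export
print.region_fit <- function(x, ...) {
  cat("region_fit:", x$n_cpgs, "CpGs x", x$N, "samples\n")
  if (!x$estimable) {
    cat("  non-estimable:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  delta = %.4g (se %.3g), kappa = %.4g (se %.3g)\n",
              x$delta_hat, x$se_delta, x$kappa_hat, x$se_kappa))
  cat(sprintf("  sigma_b2 = %.4g, h = %.6g, %s in %d iterations\n",
              x$sigma_b2, x$h_lik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
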