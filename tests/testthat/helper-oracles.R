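# Shared fixtures and independent oracles for the test suite.

# small simulated region packaged with its design
make_region_fixture <- function(n_r = 3, N = 10, seed = 1, rho = 0.3,
                                mean_effect = 0.5, var_fold = 1.5,
                                covariate = FALSE) {
  G <- rep(c(0, 1), c(floor(N / 2), ceiling(N / 2)))
  m <- simulate_region(n_r, N, G, rho = rho, base_sd = 1,
                       mean_effect = mean_effect, var_fold = var_fold,
                       seed = seed)
  rownames(m) <- paste0("cg", seq_len(n_r))
  colnames(m) <- paste0("S", seq_len(N))
  covar <- if (covariate) {
    set.seed(seed + 5000)
    matrix(rnorm(N), ncol = 1, dimnames = list(NULL, "age"))
  } else NULL
  design <- sample_design(G, colnames(m), covariates = covar)
  list(m = m, design = design,
       rd = build_region_design(rownames(m), m, design))
}

# brute-force maximizer of the joint log-likelihood of data and random
# intercepts over (beta, gamma, b) at fixed sigma_b2, with analytic
# gradients; independent of the alternating-update fitter
oracle_hglm <- function(rd, sigma_b2) {
  X <- rd$X_mean; Xv <- rd$X_var; Y <- rd$Y; g <- rd$sample_index
  p <- ncol(X); pv <- ncol(Xv); N <- rd$N
  pin0 <- sigma_b2 == 0
  nb <- if (pin0) 0L else N
  negh <- function(th) {
    beta <- th[1:p]; gamma <- th[(p + 1):(p + pv)]
    b <- if (pin0) numeric(N) else th[(p + pv + 1):(p + pv + N)]
    e <- Y - drop(X %*% beta) - b[g]
    eta <- drop(Xv %*% gamma)
    h <- sum(-0.5 * log(2 * pi) - 0.5 * eta - e^2 / (2 * exp(eta)))
    if (!pin0) h <- h + sum(-0.5 * log(2 * pi * sigma_b2) -
                              b^2 / (2 * sigma_b2))
    -h
  }
  grad <- function(th) {
    beta <- th[1:p]; gamma <- th[(p + 1):(p + pv)]
    b <- if (pin0) numeric(N) else th[(p + pv + 1):(p + pv + N)]
    e <- Y - drop(X %*% beta) - b[g]
    w <- exp(-drop(Xv %*% gamma))
    out <- c(-drop(crossprod(X, w * e)),
             -drop(crossprod(Xv, 0.5 * (e^2 * w - 1))))
    if (!pin0) out <- c(out, -(drop(rowsum(w * e, g)) - b / sigma_b2))
    out
  }
  init <- c(stats::lm.fit(X, Y)$coefficients, rep(0, pv), rep(0, nb))
  o <- stats::optim(init, negh, grad, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-14))
  list(beta = unname(o$par[1:p]),
       gamma = unname(o$par[(p + 1):(p + pv)]),
       h = -o$value)
}

# literal step-up definition of Benjamini-Hochberg
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- vapply(seq_len(m),
               function(i) min(1, min(ps[i:m] * m / (i:m))),
               numeric(1))
  out <- numeric(m)
  out[ord] <- qs
  out
}

# all positive-negative pairs count with half credit for ties
auroc_bruteforce <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (s in pos) tot <- tot + sum(s > neg) + 0.5 * sum(s == neg)
  tot / (length(pos) * length(neg))
}
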