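#' Confusion counts for region calls
#'
#' @param calls Logical vector of per-region calls.
#' @param truth Logical vector of per-region ground truth.
#' @return List of class `confusion_counts` with `TP`, `FP`, `TN`,
#'   `FN` and `n_dropped` (pairwise-NA regions excluded).
#' @export
confusion <- function(calls, truth) {
  if (length(calls) != length(truth)) {
    stop("calls and truth must have the same length", call. = FALSE)
  }
  keep <- !is.na(calls) & !is.na(truth)
  calls <- as.logical(calls[keep])
  truth <- as.logical(truth[keep])
  structure(list(TP = sum(calls & truth), FP = sum(calls & !truth),
                 TN = sum(!calls & !truth), FN = sum(!calls & truth),
                 n_dropped = sum(!keep)),
            class = "confusion_counts")
}

#' Empirical FDR and power from confusion counts
#'
#' `fdr = FP / max(1, TP + FP)` (an empty discovery set scores 0) and
#' `power = TP / max(1, TP + FN)`.
#'
#' @param cc A `confusion_counts` list.
#' @return List with `fdr` and `power`.
#' @export
fdr_power <- function(cc) {
  list(fdr = cc$FP / max(1, cc$TP + cc$FP),
       power = cc$TP / max(1, cc$TP + cc$FN))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as
#' 0 when any marginal is zero.
#'
#' @param cc A `confusion_counts` list.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(cc) {
  tp <- as.numeric(cc$TP); fp <- as.numeric(cc$FP)
  tn <- as.numeric(cc$TN); fn <- as.numeric(cc$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Rank-based AUROC
#'
#' Mann-Whitney estimate of the probability that a signal region
#' outranks a null region, with ties contributing 1/2. Scores must be
#' oriented so that larger means more signal-like (e.g. `1 - p`).
#'
#' @param scores Numeric ranking scores per region.
#' @param truth Logical ground truth per region.
#' @return AUROC in \[0, 1\]; `NA` when truth has a single class.
#' @export
auroc <- function(scores, truth) {
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]
  truth <- as.logical(truth[keep])
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical type-I error
#'
#' Fraction of non-NA raw p-values below `alpha`; intended for
#' all-null analyses.
#'
#' @param pvec Raw p-values from a null analysis.
#' @param alpha Nominal level; default 0.05.
#' @return Rejection fraction, or `NA` for empty input.
#' @export
type1_error <- function(pvec, alpha = 0.05) {
  pvec <- pvec[!is.na(pvec)]
  if (!length(pvec)) return(NA_real_)
  mean(pvec < alpha)
}

#' Score a results table against simulation truth
#'
#' Evaluates the scenario-relevant call family against the truth
#' table: DMR scenarios use `is_dmr` and `p_mean`, VMR scenarios
#' `is_vmr` and `p_var`, DVMR scenarios `is_dvmr` and `p_joint`.
#' AUROC ranks regions by `1 - p` of the relevant family. For a null
#' truth table the raw-p type-I error of all three families is
#' reported instead of power metrics.
#'
#' @param results Results `data.frame` from [methdys()].
#' @param truth Truth `data.frame` from [simulate_study()].
#' @param scenario One of `"DMR"`, `"VMR"`, `"DVMR"`, `"null"`;
#'   defaults to the scenario recorded in `truth`.
#' @param alpha Level for the type-I error (null scenario only).
#' @return One-row `data.frame` of metrics.
#' @export
evaluate_calls <- function(results, truth, scenario = NULL, alpha = 0.05) {
  stopifnot(all(c("region_id", "is_signal") %in% colnames(truth)))
  if (is.null(scenario)) scenario <- truth$scenario[1L]
  m <- match(truth$region_id, results$region_id)
  if (anyNA(m)) stop("truth contains regions absent from results",
                     call. = FALSE)
  res <- results[m, , drop = FALSE]
  if (scenario == "null") {
    return(data.frame(
      type1_mean = type1_error(res$p_mean, alpha),
      type1_var = type1_error(res$p_var, alpha),
      type1_joint = type1_error(res$p_joint, alpha)))
  }
  fam <- switch(scenario,
                DMR = list(call = res$is_dmr, p = res$p_mean),
                VMR = list(call = res$is_vmr, p = res$p_var),
                DVMR = list(call = res$is_dvmr, p = res$p_joint),
                stop("unknown scenario '", scenario, "'", call. = FALSE))
  cc <- confusion(fam$call, truth$is_signal)
  fp <- fdr_power(cc)
  data.frame(scenario = scenario, TP = cc$TP, FP = cc$FP, TN = cc$TN,
             FN = cc$FN, fdr = fp$fdr, power = fp$power, mcc = mcc(cc),
             auroc = auroc(1 - fam$p, truth$is_signal),
             stringsAsFactors = FALSE)
}
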