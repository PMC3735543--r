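# Performance evaluation: ROC/AUC, operating-threshold reports,
# cross-validated AUC, the dataset-comparison statistics and output
# histograms.

#' RocCurve: an ROC curve with its AUC
#'
#' @slot thresholds descending threshold sequence (with infinite endpoints).
#' @slot tpr,fpr true/false positive rates along the curve, from (0,0) to
#'   (1,1).
#' @slot auc area under the curve by trapezoidal integration.
#' @seealso [rocAndAuc()]
#' @export
setClass("RocCurve", representation(thresholds = "numeric", tpr = "numeric",
                                    fpr = "numeric", auc = "numeric"))

setValidity("RocCurve", function(object) {
  if (is.unsorted(rev(object@thresholds))) return("thresholds must descend")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    return("tpr/fpr must be non-decreasing along the curve")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0,1]")
  TRUE
})

#' @export
setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d points, AUC = %.4f\n",
              length(object@thresholds), object@auc))
})

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (equal scores grouped at one
#' step) and integrates the curve by the trapezoidal rule; computed via
#' \pkg{pROC} with a fixed direction (higher score = more positive).
#'
#' @param scores predicted likelihoods.
#' @param labels 0/1 class labels (1 = positive).
#' @return a [RocCurve-class].
#' @examples
#' rocAndAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' @export
rocAndAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2)
    stop("both classes must be present to compute an ROC curve")
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  ord <- order(r$thresholds, decreasing = TRUE)
  new("RocCurve", thresholds = r$thresholds[ord],
      tpr = r$sensitivities[ord], fpr = 1 - r$specificities[ord],
      auc = as.numeric(r$auc))
}

#' ThresholdReport: operating characteristics at one cutoff
#'
#' Classification counts and rates when calling an insertion positive at
#' `score >= tau` (ties count as positive).  Sensitivity equals the TPR and
#' specificity equals 1 - FPR; all rates are percentages.
#'
#' @param scores predicted likelihoods.
#' @param labels 0/1 class labels.
#' @param tau cutoff in `[0, 1]`.
#' @return list with `tau`, counts `tp`/`fp`/`tn`/`fn` and percentage rates
#'   `tpr`, `fpr`, `sensitivity`, `specificity`.
#' @examples
#' thresholdReport(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
#' @export
thresholdReport <- function(scores, labels, tau) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)),
            tau >= 0, tau <= 1)
  call <- scores >= tau
  tp <- sum(call & labels == 1); fn <- sum(!call & labels == 1)
  fp <- sum(call & labels == 0); tn <- sum(!call & labels == 0)
  tpr <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) 100 * fp / (fp + tn) else NA_real_
  list(tau = tau, tp = tp, fp = fp, tn = tn, fn = fn,
       tpr = tpr, fpr = fpr, sensitivity = tpr, specificity = 100 - fpr)
}

#' Cross-validated performance of the ensemble
#'
#' For each cross-validation split, the outputs of that split's reinitialized
#' members are consolidated on its held-out test cases and an ROC analysis is
#' run; the mean and sample standard deviation of the per-split AUCs are
#' reported (30 AUCs at the default 10 permutations x 3 folds).
#'
#' @param ensemble a trained [ErvEnsemble-class].
#' @param x n x 4 encoded inputs in plan index order.
#' @param target length-n 0/1 targets.
#' @return list with `meanAuc`, `sdAuc` and the per-split `aucs`.
#' @export
cvPerformance <- function(ensemble, x, target) {
  x <- asInputMatrix(x)
  plan <- ensemble@plan
  stopifnot(nrow(x) == plan@nPos + plan@nNeg, length(target) == nrow(x))
  aucs <- rep(NA_real_, length(plan@splits))
  for (s in seq_along(plan@splits)) {
    test <- plan@splits[[s]]$test
    if (length(unique(target[test])) < 2) {
      warning("split ", s, ": held-out set has a single class; AUC skipped")
      next
    }
    scores <- consolidate(splitMembers(ensemble, s), x[test, , drop = FALSE])
    aucs[s] <- rocAndAuc(scores, target[test])@auc
  }
  ok <- aucs[!is.na(aucs)]
  list(meanAuc = mean(ok), sdAuc = sd(ok), aucs = aucs)
}

#' Equality-of-proportions test for a 2 x 2 table
#'
#' Two-sided chi-square test of equal success proportions with Yates
#' continuity correction (a thin wrapper around [stats::prop.test()]).  A
#' degenerate table whose successes or failures are all zero overall is
#' reported as `p = 1` with `degenerate = TRUE`.
#'
#' @param k1,n1 successes and size of group 1.
#' @param k2,n2 successes and size of group 2.
#' @return list with `statistic` (chi-square), `p.value`, `estimate` (the two
#'   proportions) and `degenerate`.
#' @examples
#' propEqualityTest(4, 11, 5, 123)  # p ~ 0.0005
#' @export
propEqualityTest <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  est <- c(k1 / n1, k2 / n2)
  if (k1 + k2 == 0 || k1 + k2 == n1 + n2) {
    return(list(statistic = 0, p.value = 1, estimate = est,
                degenerate = TRUE))
  }
  pt <- suppressWarnings(prop.test(c(k1, k2), c(n1, n2), correct = TRUE))
  list(statistic = unname(pt$statistic), p.value = pt$p.value,
       estimate = est, degenerate = FALSE)
}

#' Two-sample Student's t test
#'
#' Classic pooled-variance two-sided t test (wrapper around
#' [stats::t.test()] with `var.equal = TRUE`).  Degenerate zero-variance
#' inputs are reported as `p = 1` (equal means) or `p = 0` (unequal means)
#' with `degenerate = TRUE`.
#'
#' @param a,b numeric samples, each of size at least 2.
#' @return list with `statistic` (t), `p.value` and `degenerate`.
#' @export
twoSampleT <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    return(list(statistic = if (mean(a) == mean(b)) 0 else Inf,
                p.value = if (mean(a) == mean(b)) 1 else 0,
                degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       degenerate = FALSE)
}

#' Default log-spaced histogram edges
#'
#' Bin edges used for the output-distribution histograms; log-like spacing
#' increases resolution at the low end of predicted likelihoods.
#' @return numeric vector of edges covering `[0, 1]`.
#' @export
logHistogramEdges <- function() {
  c(0, 1e-4, 1e-3, 1e-2, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1)
}

#' Histogram of predicted outputs
#'
#' Bins predicted likelihoods into `[edge_i, edge_{i+1})` intervals (the last
#' bin closed on the right) and reports the percentage of scores per bin;
#' percentages sum to 100.
#'
#' @param scores predicted likelihoods in `[0, 1]`.
#' @param edges strictly increasing bin edges covering `[0, 1]`
#'   (default [logHistogramEdges()]).
#' @return data.frame with `lower`, `upper`, `count` and `percent`.
#' @export
outputHistogram <- function(scores, edges = logHistogramEdges()) {
  stopifnot(length(scores) > 0)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (is.unsorted(edges, strictly = TRUE) || edges[1] != 0 ||
      edges[length(edges)] != 1)
    stop("edges must increase strictly from 0 to 1")
  bin <- findInterval(scores, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  data.frame(lower = edges[-length(edges)], upper = edges[-1],
             count = counts, percent = 100 * counts / length(scores))
}
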