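# ROC analysis and diagnostic metrics. AUC uses the Mann-Whitney
# normalization with half credit for ties; binary radiologic signs are
# summarized from 2x2 contingency counts with AUC = (sens + spec) / 2,
# which is exactly the trapezoidal area of the single-point ROC curve of
# a binary predictor.

#' Diagnostic metrics from a 2x2 contingency table
#'
#' For a binary radiologic sign against the binary reference status:
#' counts are sign-positive/status-positive (`tp`),
#' sign-negative/status-positive (`fn`), sign-positive/status-negative
#' (`fp`) and sign-negative/status-negative (`tn`). Rates with a zero
#' denominator are returned as `NA` (flagged undefined), never as 0.
#'
#' @param tp,fn,fp,tn non-negative integer counts, total `> 0`.
#' @return Named list: `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   `ppv`, `npv`, `youdenJ`.
#' @examples
#' # satellite sign: 14/56 STAS+ and 6/160 STAS- carry the sign
#' unlist(metricsFromCounts(tp = 14, fn = 42, fp = 6, tn = 154))
#' @export
metricsFromCounts <- function(tp, fn, fp, tn) {
  counts <- c(tp, fn, fp, tn)
  if (any(counts < 0) || sum(counts) == 0 || any(counts != round(counts)))
    stop("counts must be non-negative integers with a positive total")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, fp + tn)
  auc <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  list(auc = auc, sensitivity = sens, specificity = spec,
       accuracy = rate(tp + tn, sum(counts)),
       ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn),
       youdenJ = if (!is.na(auc)) sens + spec - 1 else NA_real_)
}

#' ROC curve and AUC from continuous scores
#'
#' Positive cases are expected to score higher. The AUC equals the
#' normalized Mann-Whitney U statistic (ties counted half); the curve
#' contains one operating point per distinct threshold (classify
#' positive when `score >= t`), plus the trivial endpoints.
#'
#' @param scores numeric vector.
#' @param labels `"positive"`/`"negative"` per case; both present.
#' @return list with `auc` and `curve` (data frame: `threshold`,
#'   `sensitivity`, `specificity`).
#' @export
rocCurveAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == "positive"
  if (!any(pos) || all(pos))
    stop("both classes must be present for a ROC curve")
  r <- rank(scores) # midranks: ties get half credit
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  auc <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[pos] >= t), 0),
    specificity = vapply(thr, function(t) mean(scores[!pos] < t), 0))
  list(auc = auc, curve = curve)
}

#' Youden-optimal operating point
#'
#' Scans every candidate threshold of the ROC curve and returns the one
#' maximizing `J = sensitivity + specificity - 1`; ties break toward
#' higher sensitivity, then lower threshold.
#'
#' @inheritParams rocCurveAuc
#' @return list: `threshold`, `sensitivity`, `specificity`, `youdenJ`,
#'   `accuracy`, `ppv`, `npv`, `auc`.
#' @export
youdenThreshold <- function(scores, labels) {
  roc <- rocCurveAuc(scores, labels)
  cv <- roc$curve
  J <- cv$sensitivity + cv$specificity - 1
  ord <- order(-J, -cv$sensitivity, cv$threshold)
  best <- ord[1]
  t <- cv$threshold[best]
  pos <- labels == "positive"
  predPos <- scores >= t
  mets <- metricsFromCounts(sum(predPos & pos), sum(!predPos & pos),
                            sum(predPos & !pos), sum(!predPos & !pos))
  list(threshold = t, sensitivity = cv$sensitivity[best],
       specificity = cv$specificity[best], youdenJ = J[best],
       accuracy = mets$accuracy, ppv = mets$ppv, npv = mets$npv,
       auc = roc$auc)
}

#' Bootstrap confidence interval for the AUC
#'
#' Stratified case resampling (within class) with percentile 2.5/97.5
#' bounds over `nBoot` replicates; deterministic given the seed.
#'
#' @inheritParams rocCurveAuc
#' @param nBoot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return list: `ciLow`, `ciHigh`, `auc` (point estimate), `nBoot`.
#' @export
bootstrapCi <- function(scores, labels, nBoot = 1000L, seed = 1L,
                        level = 0.95) {
  pos <- which(labels == "positive")
  neg <- which(labels == "negative")
  stopifnot(length(pos) > 0, length(neg) > 0)
  point <- rocCurveAuc(scores, labels)$auc
  aucs <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      rocCurveAuc(scores[idx], labels[idx])$auc
    }, 0)
  })
  q <- quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(ciLow = q[1], ciHigh = q[2], auc = point, nBoot = nBoot)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors over the same cases using the
#' DeLong placement-value covariance, returning the z statistic and the
#' two-sided p value. Identical scores give `z = 0`, `p = 1`.
#'
#' @param scoresA,scoresB paired score vectors (same cases, same order).
#' @inheritParams rocCurveAuc
#' @return list: `aucA`, `aucB`, `z`, `p`.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels))
    stop("scoresA, scoresB and labels must have equal length")
  pos <- labels == "positive"
  stopifnot(any(pos), any(!pos))
  m <- sum(pos)
  n <- sum(!pos)
  placements <- function(s) {
    x <- s[pos]
    y <- s[!pos]
    # V10[i] = P(X_i > Y) + 0.5 P(X_i = Y); V01[j] analogous
    v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n, 0)
    v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m, 0)
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  pa <- placements(scoresA)
  pb <- placements(scoresB)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  varDiff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  z <- if (varDiff > 0) (pa$auc - pb$auc) / sqrt(varDiff) else 0
  list(aucA = pa$auc, aucB = pb$auc, z = z,
       p = 2 * pnorm(-abs(z)))
}
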