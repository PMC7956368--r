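#' Classification accuracy (percent)
#'
#' `100 * (number correct) / n`.
#'
#' @param predicted,truth Equal-length class vectors.
#' @return Accuracy in percent.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) abort("Lengths differ.")
  if (length(truth) == 0) abort("Empty inputs.")
  100 * mean(as.character(predicted) == as.character(truth))
}

# Binary AUC of score s against logical positives, ties counted 1/2
# (rank / Mann-Whitney formulation).
binary_auc <- function(s, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(s, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-all multiclass AUC
#'
#' Mean over classes of the binary area under the ROC curve of the class's
#' score column against the indicator `truth == class`, ties counted half.
#' In the two-class case this equals the Mann-Whitney U statistic normalized
#' by `n1 * n0`. Classes absent from `truth` are skipped with a warning.
#'
#' @param scores A `score_matrix` tibble (or numeric matrix with class
#'   columns).
#' @param truth Class vector aligned with the score rows.
#' @return List of class `eval_auc`: `auc` (macro average) and
#'   `per_class` (named vector).
#' @export
auc_ova <- function(scores, truth) {
  m <- if (is.matrix(scores)) scores else score_values(scores)
  if (nrow(m) != length(truth)) abort("`truth` must align with score rows.")
  classes <- colnames(m)
  if (length(classes) < 2) abort("Need >= 2 class columns.")
  per <- vapply(classes, function(cl) {
    pos <- as.character(truth) == cl
    if (!any(pos)) {
      warn(sprintf("Class '%s' absent from truth; skipped.", cl))
      return(NA_real_)
    }
    binary_auc(m[, cl], pos)
  }, numeric(1))
  structure(list(auc = mean(per, na.rm = TRUE), per_class = per),
            class = "eval_auc")
}

#' Wilcoxon signed-rank comparison of two paired accuracy vectors
#'
#' Two-sided signed-rank test on the per-fold (or per-dataset) differences
#' `a - b`; zero differences are dropped per the standard convention
#' (`zero_method = "wilcox"`) or kept in the ranking with the Pratt variant.
#' An all-zero difference vector is flagged degenerate.
#'
#' @param acc_a,acc_b Equal-length numeric vectors of paired performance
#'   values.
#' @param zero_method `"wilcox"` (drop zeros, default) or `"pratt"`.
#' @return Tibble with `statistic` (V, from the positive ranks of `a - b`),
#'   `p_value`, `n_effective` and `degenerate`.
#' @export
wilcoxon_compare <- function(acc_a, acc_b, zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (length(acc_a) != length(acc_b)) abort("Lengths differ.")
  d <- acc_a - acc_b
  if (all(d == 0)) {
    warn("All paired differences are zero; no evidence of a difference.")
    return(tibble(statistic = NA_real_, p_value = NA_real_,
                  n_effective = 0L, degenerate = TRUE))
  }
  if (zero_method == "wilcox") {
    dd <- d[d != 0]
    wt <- suppressWarnings(stats::wilcox.test(dd, alternative = "two.sided"))
    tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
           n_effective = length(dd), degenerate = FALSE)
  } else {
    # Pratt: rank |d| including zeros, then drop zero ranks from the sums
    r <- rank(abs(d), ties.method = "average")
    keep <- d != 0
    v <- sum(r[keep & d > 0])
    # normal approximation with zero adjustment
    nz <- sum(keep)
    n <- length(d)
    mu <- (n * (n + 1) / 2 - sum(r[!keep])) / 2
    sigma2 <- sum(r[keep]^2) / 4
    z <- (v - mu) / sqrt(sigma2)
    tibble(statistic = v, p_value = 2 * stats::pnorm(-abs(z)),
           n_effective = nz, degenerate = FALSE)
  }
}

#' Evaluate a score matrix against true labels
#'
#' @param scores A `score_matrix` tibble.
#' @param truth Class vector aligned with the rows.
#' @return An `eval_report`: tibble with `accuracy` (percent), `auc`
#'   (one-vs-all average), `n`; per-class AUCs in attribute `per_class_auc`.
#' @export
evaluate_scores <- function(scores, truth) {
  acc <- accuracy(scores$.pred, truth)
  a <- auc_ova(scores, truth)
  structure(tibble(accuracy = acc, auc = a$auc, n = length(truth)),
            per_class_auc = a$per_class,
            class = c("eval_report", class(tibble())))
}
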