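# Paired differential expression on log2(CPM + 1) with BH adjustment and the
# printed filter thresholds (|FC| >= 2, p < 0.05, FDR < 0.001 for the
# tumor/normal circRNA contrast; |FC| >= 1.5, p < 0.05 for knockdown DEGs).

#' Log2 fold change of mean CPM between two sample groups
#'
#' `log2((mean_cpm_A + c) / (mean_cpm_B + c))` with pseudocount `c`.
#'
#' @param cpm CPM matrix (features x samples), e.g. from [cpm_normalize()].
#' @param group_a,group_b disjoint, non-empty character vectors of sample ids;
#'   A is the numerator (tumor or knockdown).
#' @param feature feature id (or vector of ids).
#' @param pseudocount stabilizing constant `c`, default 1 CPM.
#' @return log2 fold change(s).
#' @export
log2fc <- function(cpm, group_a, group_b, feature, pseudocount = 1) {
  if (!length(group_a) || !length(group_b)) stop("empty sample group")
  if (length(intersect(group_a, group_b))) stop("sample groups overlap")
  if (!all(feature %in% rownames(cpm)))
    stop("unknown feature: ", setdiff(feature, rownames(cpm))[1])
  a <- rowMeans(cpm[feature, group_a, drop = FALSE])
  b <- rowMeans(cpm[feature, group_b, drop = FALSE])
  unname(log2((a + pseudocount) / (b + pseudocount)))
}

#' Paired two-sided t-test on per-subject log2(CPM+1) differences
#'
#' For each subject the difference `log2(cpm_A + 1) - log2(cpm_B + 1)` is
#' formed and a two-sided one-sample t-test against zero is applied. If the
#' differences have zero variance: all-zero differences give p = 1; otherwise
#' the variance is floored at `var_floor` so a consistent nonzero shift is
#' still detected.
#'
#' @param diffs numeric vector of per-pair differences (length >= 3).
#' @param var_floor variance floor for degenerate inputs, default 1e-8.
#' @return two-sided p-value.
#' @export
paired_t_pvalue <- function(diffs, var_floor = 1e-8) {
  n <- length(diffs)
  if (n < 3L) stop("paired test needs at least 3 complete pairs")
  if (stats::var(diffs) == 0) {
    if (all(diffs == 0)) return(1)
    tstat <- mean(diffs) / sqrt(var_floor / n)
  } else {
    tstat <- mean(diffs) / (stats::sd(diffs) / sqrt(n))
  }
  2 * stats::pt(-abs(tstat), df = n - 1L)
}

#' @rdname paired_t_pvalue
#' @param cpm CPM matrix.
#' @param pairs pairing data.frame from [pairing_index()]: column 2 holds the
#'   numerator-condition sample ids, column 3 the denominator's.
#' @param feature feature id.
#' @export
paired_test <- function(cpm, pairs, feature, var_floor = 1e-8) {
  if (!feature %in% rownames(cpm)) stop("unknown feature: ", feature)
  d <- log2(cpm[feature, pairs[[2]]] + 1) - log2(cpm[feature, pairs[[3]]] + 1)
  paired_t_pvalue(as.numeric(d), var_floor = var_floor)
}

#' Welch's two-sided t-test on log2(CPM+1) (unpaired contrasts)
#' @param cpm CPM matrix.
#' @param group_a,group_b sample id vectors (>= 2 each).
#' @param feature feature id.
#' @param var_floor variance floor applied when both groups are degenerate.
#' @return two-sided p-value.
#' @export
welch_test <- function(cpm, group_a, group_b, feature, var_floor = 1e-8) {
  x <- log2(cpm[feature, group_a] + 1)
  y <- log2(cpm[feature, group_b] + 1)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx + vy == 0) {
    if (mean(x) == mean(y)) return(1)
    vx <- vy <- var_floor
  }
  se2 <- vx / length(x) + vy / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                 vy^2 / (length(y)^2 * (length(y) - 1)))
  2 * stats::pt(-abs(tstat), df = df)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order, each `>=` its raw p.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Full differential-expression table for a paired contrast
#'
#' Features with zero counts in every sample are dropped before testing (with
#' a message). CPM normalization, per-feature log2 fold change (group A over
#' group B), paired t p-values and BH adjustment are computed.
#'
#' @param em an [expr_matrix()].
#' @param conditions length-2: numerator condition first (e.g.
#'   `c("tumor", "normal")`).
#' @param pseudocount pseudocount for fold changes (CPM units).
#' @return data.frame: `feature_id`, `log2fc`, `p`, `padj`, `direction`.
#' @export
de_paired <- function(em, conditions = c("tumor", "normal"), pseudocount = 1) {
  allzero <- rowSums(em$counts) == 0
  if (any(allzero)) {
    message("dropping ", sum(allzero), " feature(s) with all-zero counts")
    em$counts <- em$counts[!allzero, , drop = FALSE]
  }
  cpm <- cpm_normalize(em)
  pairs <- pairing_index(em, conditions)
  ga <- pairs[[2]]; gb <- pairs[[3]]
  la <- log2(cpm[, ga, drop = FALSE] + 1)
  lb <- log2(cpm[, gb, drop = FALSE] + 1)
  d <- la - lb
  p <- apply(d, 1, paired_t_pvalue)
  lfc <- log2fc(cpm, ga, gb, rownames(cpm), pseudocount = pseudocount)
  data.frame(feature_id = rownames(cpm), log2fc = lfc, p = p,
             padj = bh_adjust(p),
             direction = ifelse(lfc > 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential-expression table for an unpaired (knockdown) contrast
#'
#' Welch's t on log2(CPM+1), knockdown over control fold change.
#'
#' @param em an [expr_matrix()] with conditions `knockdown`/`control` (or as
#'   given).
#' @param conditions length-2: numerator condition first.
#' @inheritParams de_paired
#' @return data.frame as in [de_paired()].
#' @export
de_unpaired <- function(em, conditions = c("knockdown", "control"),
                        pseudocount = 1) {
  allzero <- rowSums(em$counts) == 0
  if (any(allzero)) {
    message("dropping ", sum(allzero), " feature(s) with all-zero counts")
    em$counts <- em$counts[!allzero, , drop = FALSE]
  }
  cpm <- cpm_normalize(em)
  ga <- em$samples$sample_id[em$samples$condition == conditions[1]]
  gb <- em$samples$sample_id[em$samples$condition == conditions[2]]
  if (length(ga) < 2L || length(gb) < 2L)
    stop("each condition needs at least 2 samples")
  p <- vapply(rownames(cpm), function(f) welch_test(cpm, ga, gb, f),
              numeric(1))
  lfc <- log2fc(cpm, ga, gb, rownames(cpm), pseudocount = pseudocount)
  data.frame(feature_id = rownames(cpm), log2fc = lfc, p = unname(p),
             padj = bh_adjust(unname(p)),
             direction = ifelse(lfc > 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed circRNAs (tumor vs normal filter)
#'
#' Keeps features with `|fold change| >= fc` (default 2, i.e.
#' `|log2fc| >= 1`), `p < p_max` and `padj < padj_max`.
#'
#' @param results data.frame with `log2fc`, `p`, `padj` (from [de_paired()]).
#' @param fc fold-change threshold, default 2.
#' @param p_max raw p-value threshold, default 0.05.
#' @param padj_max FDR threshold, default 0.001.
#' @return the subset of rows passing all three filters.
#' @export
call_dec <- function(results, fc = 2, p_max = 0.05, padj_max = 0.001) {
  keep <- abs(results$log2fc) >= log2(fc) &
    results$p < p_max & results$padj < padj_max
  results[keep, , drop = FALSE]
}

#' Call knockdown DEGs
#'
#' Keeps features with `|fold change| >= fc` (default 1.5) and `p < p_max`
#' (default 0.05); no FDR filter, matching the printed knockdown criterion.
#'
#' @inheritParams call_dec
#' @export
call_kd_degs <- function(results, fc = 1.5, p_max = 0.05) {
  keep <- abs(results$log2fc) >= log2(fc) & results$p < p_max
  results[keep, , drop = FALSE]
}
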