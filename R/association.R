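# Nonparametric association of repertoire features with clinical
# covariates: Spearman correlation, Mann-Whitney U, Fisher's exact test and
# Benjamini-Hochberg correction. The tests delegate to base R's stats
# implementations, whose conventions match what is required here: exact
# enumeration for small samples without ties, tie-corrected continuity-
# corrected normal / t approximations otherwise, and the minimum-likelihood
# two-sided convention for Fisher's test.

assoc_result <- function(statistic_name, estimate, p_value, n,
                         flag = NA_character_) {
  data.frame(statistic_name = statistic_name, estimate = estimate,
             p_value = p_value, n = paste(n, collapse = "/"),
             flag = flag, stringsAsFactors = FALSE)
}

#' Spearman rank correlation test
#'
#' Two-sided Spearman test with tie-averaged ranks; the p-value is exact
#' (permutation distribution) for `n <= 9` without ties and uses the
#' t-distributed statistic `rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#' Pairs with missing values are dropped.
#'
#' @param x,y Numeric vectors of equal length (`n >= 3` after NA removal).
#' @return One-row data frame: `statistic_name`, `estimate` (rho),
#'   `p_value`, `n`, `flag`.
#' @export
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(assoc_result("spearman_rho", NA_real_, NA_real_, n,
                        flag = "constant_input"))
  exact <- n <= 9L && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact,
                                  alternative = "two.sided"))
  assoc_result("spearman_rho", unname(ct$estimate), ct$p.value, n)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test; exact enumeration when the smaller group has at
#' most 8 observations and there are no ties, otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param group_a,group_b Numeric vectors (both non-empty).
#' @return One-row data frame with the U statistic and p-value.
#' @export
mann_whitney_test <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  exact <- min(length(group_a), length(group_b)) <= 8L &&
    !anyDuplicated(c(group_a, group_b))
  wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = exact,
                                     correct = TRUE))
  assoc_result("mann_whitney_U", unname(wt$statistic), wt$p.value,
               c(length(group_a), length(group_b)))
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional maximum-likelihood odds ratio and two-sided p-value under
#' the minimum-likelihood convention (sum of hypergeometric probabilities
#' no larger than that of the observed table). A degenerate margin gives
#' p = 1 with a flag.
#'
#' @param tab 2x2 matrix of non-negative counts, or a length-4 vector
#'   `(a, b, c, d)` filled by row.
#' @return One-row data frame with the odds ratio and p-value.
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), nrow = 2, byrow = TRUE)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(assoc_result("fisher_or", NA_real_, 1, sum(tab),
                        flag = "degenerate_margin"))
  ft <- fisher.test(tab, alternative = "two.sided")
  assoc_result("fisher_or", unname(ft$estimate), ft$p.value, sum(tab))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, capped at 1; invariant to input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  p.adjust(p_values, method = "BH")
}

#' Correlate repertoire features with a clinical covariate
#'
#' Runs a Spearman test of each feature column against the covariate within
#' a group stratum and applies Benjamini-Hochberg correction across the
#' feature family. For age analyses in the PV group, the `k_oldest` oldest
#' PV subjects older than the oldest healthy control are excluded first
#' (there are no age-matched controls for them).
#'
#' @param features Data frame with `subject_id` and numeric feature columns.
#' @param subjects Subject metadata (see [read_subjects()]).
#' @param covariate One of `"age"`, `"pasi"`, `"duration_years"`,
#'   `"cmv_igg"`.
#' @param group Group stratum (`"PV"`, `"HC"`, or `NULL` for all).
#' @param k_oldest How many unmatched oldest PV subjects to drop in age
#'   analyses (default 4).
#' @return Data frame: one row per feature with rho, `p_value`,
#'   `p_adjusted` and `n`; strata with fewer than 3 subjects are skipped
#'   with a message.
#' @export
correlate_features <- function(features, subjects,
                               covariate = c("age", "pasi",
                                             "duration_years", "cmv_igg"),
                               group = "PV", k_oldest = 4L) {
  covariate <- match.arg(covariate)
  df <- merge(features, subjects, by = "subject_id")
  if (!is.null(group)) df <- df[df$group %in% group, , drop = FALSE]
  if (covariate == "age" && !is.null(group) && "PV" %in% group) {
    hc_max <- suppressWarnings(max(subjects$age[subjects$group == "HC"]))
    older <- df$subject_id[df$group == "PV" & df$age > hc_max]
    if (length(older) && k_oldest > 0L) {
      drop_ids <- df$subject_id[order(-df$age)]
      drop_ids <- intersect(drop_ids, older)[seq_len(min(k_oldest,
                                                         length(older)))]
      df <- df[!df$subject_id %in% drop_ids, , drop = FALSE]
    }
  }
  feat_cols <- setdiff(names(features), "subject_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  rows <- lapply(feat_cols, function(fc) {
    ok <- stats::complete.cases(df[[covariate]], df[[fc]])
    if (sum(ok) < 3L) {
      message("skipping feature '", fc, "': fewer than 3 complete pairs")
      return(NULL)
    }
    r <- spearman_test(df[[covariate]][ok], df[[fc]][ok])
    data.frame(feature = fc, covariate = covariate,
               n = sum(ok), rho = r$estimate, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adjusted <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}
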