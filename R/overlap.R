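# Cross-sample overlap: clonotype keys, public/private classification,
# pairwise Jaccard similarity and paired blood-skin sharing.

#' Build clonotype keys
#'
#' Deterministic keys `v_gene|j_gene|cdr3` on the amino-acid (default) or
#' nucleotide basis. Keys carry V and J context so identical CDR3s on
#' different segments are not conflated.
#'
#' @param x A [rep_sample()] or clonotype data frame.
#' @param basis `"aa"` or `"nt"`.
#' @return Character vector of keys (one per clonotype row).
#' @export
build_key <- function(x, basis = c("aa", "nt")) {
  basis <- match.arg(basis)
  cl <- if (inherits(x, "rep_sample")) x$clonotypes else as.data.frame(x)
  cdr3 <- if (basis == "aa") cl$cdr3_aa else cl$cdr3_nt
  paste(cl$v_gene, cl$j_gene, cdr3, sep = "|")
}

sample_keys <- function(sample, basis, segment = NULL) {
  cl <- sample$clonotypes
  if (!is.null(segment)) cl <- cl[cl$v_gene %in% segment, , drop = FALSE]
  unique(build_key(cl, basis))
}

#' Public/private clonotype classification
#'
#' A key is public when observed in at least two distinct subjects (paired
#' samples of one person never make a clonotype public). The public
#' fraction is the share of public keys among all distinct keys in the
#' stratum.
#'
#' @param cohort A `rep_cohort`.
#' @param basis `"aa"` or `"nt"`.
#' @param tissue,chain Optional stratum filters.
#' @return List: `table` (key, `n_subjects`, `n_pv`, `n_hc`, `public`,
#'   per-subject presence counts) and `public_fraction` (`NA` with a
#'   warning when fewer than two subjects are present).
#' @export
sharing_counts <- function(cohort, basis = c("aa", "nt"), tissue = NULL,
                           chain = NULL) {
  basis <- match.arg(basis)
  samples <- filter_samples(cohort$samples, tissue, chain)
  subj <- vapply(samples, `[[`, character(1), "subject_id")
  key_by_subj <- lapply(split(samples, subj), function(ss)
    unique(unlist(lapply(ss, sample_keys, basis = basis), use.names = FALSE)))
  all_keys <- sort(unique(unlist(key_by_subj, use.names = FALSE)))
  counts <- setNames(integer(length(all_keys)), all_keys)
  pv_counts <- hc_counts <- counts
  grp <- setNames(cohort$subjects$group, cohort$subjects$subject_id)
  for (sid in names(key_by_subj)) {
    k <- key_by_subj[[sid]]
    counts[k] <- counts[k] + 1L
    if (identical(grp[[sid]], "PV")) pv_counts[k] <- pv_counts[k] + 1L
    if (identical(grp[[sid]], "HC")) hc_counts[k] <- hc_counts[k] + 1L
  }
  tab <- data.frame(key = all_keys, n_subjects = as.integer(counts),
                    n_pv = as.integer(pv_counts),
                    n_hc = as.integer(hc_counts),
                    public = counts >= 2L,
                    stringsAsFactors = FALSE, row.names = NULL)
  n_subjects <- length(key_by_subj)
  pf <- if (n_subjects < 2L) {
    warning("public fraction undefined with fewer than 2 subjects")
    NA_real_
  } else if (nrow(tab) == 0L) NA_real_ else mean(tab$public)
  list(table = tab, public_fraction = pf, n_subjects = n_subjects)
}

#' Pairwise Jaccard similarity matrix
#'
#' `JI(A, B) = |keys(A) intersect keys(B)| / |keys(A) union keys(B)|` over
#' clonotype key sets (frequency-blind). The diagonal is 1; a sample with
#' no keys gets JI 0 against every other sample.
#'
#' @param x A `rep_cohort` or list of [rep_sample()] objects.
#' @param basis `"aa"` or `"nt"`.
#' @param segment Optional V segment(s) to restrict the key sets to.
#' @return Symmetric matrix with sample ids as dimnames.
#' @export
jaccard_matrix <- function(x, basis = c("aa", "nt"), segment = NULL) {
  basis <- match.arg(basis)
  samples <- if (inherits(x, "rep_cohort")) x$samples else x
  if (length(samples) < 2L) stop("need at least 2 samples")
  keysets <- lapply(samples, sample_keys, basis = basis, segment = segment)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  n <- length(samples)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    u <- length(union(keysets[[i]], keysets[[j]]))
    m[i, j] <- m[j, i] <- if (u == 0L) 0 else
      length(intersect(keysets[[i]], keysets[[j]])) / u
  }
  empty <- ids[lengths(keysets) == 0L]
  if (length(empty)) attr(m, "empty_samples") <- empty
  m
}

#' Paired blood-skin clonotype sharing
#'
#' Keys present in both compartments of one subject, with their blood and
#' skin frequencies and the arithmetic mean cross-compartment frequency.
#'
#' @param blood,skin Two [rep_sample()] objects from the same subject and
#'   chain.
#' @param basis `"aa"` or `"nt"`.
#' @return Data frame: `key`, `blood_freq`, `skin_freq`, `mean_freq`.
#' @export
paired_overlap <- function(blood, skin, basis = c("aa", "nt")) {
  basis <- match.arg(basis)
  if (!identical(blood$chain, skin$chain))
    stop("chain mismatch: ", blood$chain, " vs ", skin$chain)
  if (!identical(blood$subject_id, skin$subject_id))
    stop("samples belong to different subjects")
  key_freq <- function(s) {
    k <- build_key(s, basis)
    vapply(split(s$clonotypes$freq, k), sum, numeric(1))
  }
  fb <- key_freq(blood)
  fs <- key_freq(skin)
  shared <- sort(intersect(names(fb), names(fs)))
  data.frame(key = shared,
             blood_freq = unname(fb[shared]),
             skin_freq = unname(fs[shared]),
             mean_freq = unname((fb[shared] + fs[shared]) / 2),
             stringsAsFactors = FALSE)
}
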