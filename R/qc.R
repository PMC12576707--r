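# Library-level QC and clonotype-level filtering / error-correction.
# Processing order for a passing library: functional filter -> segment
# restriction -> error-correction merging.

#' QC thresholds
#'
#' Library acceptance and clonotype-filtering parameters. Defaults separate
#' the kept and excluded libraries reported for the cohort this pipeline
#' models: libraries with fewer than `min_reads` reads (excluded example:
#' 26 reads against a median around one million), at most `min_clonotypes`
#' clonotypes, or more than `max_offtarget_fraction` TRA/TRB reads fail.
#' Merging parameters (`merge_max_mismatch`, `merge_max_ratio`) follow common
#' repertoire error-correction practice; the allowed V sets retain the
#' functional TRGV2/3/4/5/8/9 and TRDV1-8 segments.
#'
#' @param min_reads Minimum library read count.
#' @param min_clonotypes Libraries with clonotype count `<=` this fail.
#' @param max_offtarget_fraction Maximal tolerated TRA/TRB read fraction.
#' @param merge_max_mismatch Maximal Hamming distance for error merging.
#' @param merge_max_ratio Maximal child/parent count ratio for merging.
#' @param allowed_trgv,allowed_trdv Retained V segments per chain.
#' @param excluded_segments Additional V segments to drop.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_reads = 1000L, min_clonotypes = 10L,
                          max_offtarget_fraction = 0.5,
                          merge_max_mismatch = 1L, merge_max_ratio = 0.1,
                          allowed_trgv = c("TRGV2", "TRGV3", "TRGV4",
                                           "TRGV5", "TRGV8", "TRGV9"),
                          allowed_trdv = paste0("TRDV", 1:8),
                          excluded_segments = character()) {
  stopifnot(merge_max_ratio > 0, merge_max_ratio < 1,
            merge_max_mismatch >= 0,
            length(allowed_trgv) > 0, length(allowed_trdv) > 0)
  structure(list(min_reads = as.integer(min_reads),
                 min_clonotypes = as.integer(min_clonotypes),
                 max_offtarget_fraction = max_offtarget_fraction,
                 merge_max_mismatch = as.integer(merge_max_mismatch),
                 merge_max_ratio = merge_max_ratio,
                 allowed_trgv = allowed_trgv, allowed_trdv = allowed_trdv,
                 excluded_segments = excluded_segments),
            class = "qc_thresholds")
}

#' Library-level acceptance check
#'
#' A library fails if any rule trips: total reads below `min_reads`,
#' clonotype count at or below `min_clonotypes`, or off-target (TRA/TRB)
#' read fraction above `max_offtarget_fraction`. All tripped reasons are
#' listed.
#'
#' @param sample A [rep_sample()].
#' @param thresholds A [qc_thresholds()].
#' @return One-row data frame: `sample_id`, `verdict`, `reasons`
#'   (comma-separated), `total_reads`, `n_clonotypes`, `offtarget_fraction`.
#' @export
assess_library <- function(sample, thresholds = qc_thresholds()) {
  reasons <- character()
  if (sample$total_reads < thresholds$min_reads)
    reasons <- c(reasons, "low_depth")
  if (nrow(sample$clonotypes) <= thresholds$min_clonotypes)
    reasons <- c(reasons, "few_clonotypes")
  denom <- sample$total_reads + sample$off_target_reads
  offt <- if (denom > 0) sample$off_target_reads / denom else 0
  if (offt > thresholds$max_offtarget_fraction)
    reasons <- c(reasons, "offtarget_excess")
  data.frame(sample_id = sample$sample_id,
             verdict = if (length(reasons)) "fail" else "pass",
             reasons = paste(reasons, collapse = ","),
             total_reads = sample$total_reads,
             n_clonotypes = nrow(sample$clonotypes),
             offtarget_fraction = offt,
             stringsAsFactors = FALSE)
}

#' Remove non-functional clonotypes
#'
#' Drops out-of-frame clonotypes and those whose CDR3 carries a stop codon
#' or frameshift marker; frequencies are renormalised. When the stored
#' `functional` flag is missing it is derived from the frame rule.
#'
#' @param sample A [rep_sample()].
#' @return The filtered sample.
#' @export
filter_nonfunctional <- function(sample) {
  cl <- sample$clonotypes
  fun <- cl$functional
  fun[is.na(fun)] <- derive_functional(cl$cdr3_nt[is.na(fun)],
                                       cl$cdr3_aa[is.na(fun)])
  if (nrow(cl) && !any(fun)) {
    warning("all clonotypes non-functional in ", sample$sample_id,
            "; returning empty repertoire")
    return(set_clonotypes(sample, cl[0L, , drop = FALSE]))
  }
  set_clonotypes(sample, cl[fun, , drop = FALSE])
}

#' Restrict a repertoire to functional V segments
#'
#' Keeps only clonotypes using the allowed TRGV (TRG) or TRDV (TRD)
#' segments; pseudogenes (e.g. TRGV10), TRAV-incorporating hybrids and any
#' explicitly excluded segments are dropped and frequencies renormalised.
#'
#' @inheritParams assess_library
#' @return The filtered sample.
#' @export
restrict_segments <- function(sample, thresholds = qc_thresholds()) {
  cl <- sample$clonotypes
  allowed <- if (sample$chain == "TRG") thresholds$allowed_trgv
             else thresholds$allowed_trdv
  keep <- cl$v_gene %in% allowed &
    !grepl("TRAV", cl$v_gene, fixed = TRUE) &
    !cl$v_gene %in% thresholds$excluded_segments
  set_clonotypes(sample, cl[keep, , drop = FALSE])
}

# Hamming-distance-1 pair detection among equal-length strings, compiled
# (see src/hamming_pairs.cpp). Returns a 2-column matrix of index pairs.
find_hamming1_pairs <- function(seqs, L) {
  .hamming1_pairs(seqs)
}

#' Merge likely sequencing-error clonotypes
#'
#' Absorbs low-abundance clonotypes into similar high-abundance ones: a
#' child merges into the highest-count eligible parent sharing `v_gene`,
#' `j_gene` and CDR3 nt length, at Hamming distance at most
#' `merge_max_mismatch` (0 disables merging; only 0/1 are supported), with
#' `child_count / parent_count <= merge_max_ratio`. Children are scanned in
#' ascending count order (ties broken lexicographically by CDR3 nt) and the
#' scan is repeated until no further merge applies, which makes the
#' operation idempotent. Total reads are conserved exactly.
#'
#' @inheritParams assess_library
#' @return The merged sample.
#' @export
merge_error_clonotypes <- function(sample, thresholds = qc_thresholds()) {
  if (thresholds$merge_max_mismatch > 1L)
    stop("merge_max_mismatch > 1 is not supported")
  cl <- sample$clonotypes
  if (nrow(cl) < 2L || thresholds$merge_max_mismatch == 0L) return(sample)
  grp <- paste(cl$v_gene, cl$j_gene, nchar(cl$cdr3_nt), sep = "\r")
  counts <- cl$count
  alive <- rep(TRUE, nrow(cl))
  for (ii in split(seq_len(nrow(cl)), grp)) {
    if (length(ii) < 2L) next
    L <- nchar(cl$cdr3_nt[ii[1L]])
    pairs <- find_hamming1_pairs(cl$cdr3_nt[ii], L)
    if (nrow(pairs) == 0L) next
    # neighbour lists (global indices), only members with a neighbour scan
    nb <- split(ii[c(pairs[, 2L], pairs[, 1L])],
                ii[c(pairs[, 1L], pairs[, 2L])])
    touch <- as.integer(names(nb))
    nbi <- integer(nrow(cl))
    nbi[touch] <- seq_along(nb)
    repeat {
      merged_any <- FALSE
      live <- touch[alive[touch]]
      if (length(live) < 2L) break
      for (child in live[order(counts[live], cl$cdr3_nt[live])]) {
        if (!alive[child]) next
        cand <- nb[[nbi[child]]]
        cand <- cand[alive[cand]]
        cand <- cand[counts[child] / counts[cand] <=
                       thresholds$merge_max_ratio]
        if (!length(cand)) next
        if (length(cand) == 1L) parent <- cand
        else {
          best <- cand[counts[cand] == max(counts[cand])]
          parent <- if (length(best) == 1L) best
                    else best[order(cl$cdr3_nt[best])][1L]
        }
        counts[parent] <- counts[parent] + counts[child]
        alive[child] <- FALSE
        merged_any <- TRUE
      }
      if (!merged_any) break
    }
  }
  out <- cl[alive, , drop = FALSE]
  out$count <- counts[alive]
  set_clonotypes(sample, out)
}

#' Run full QC over a cohort
#'
#' Applies library assessment and, for passing libraries, the clonotype
#' pipeline (functional filter, segment restriction, error merging) in that
#' order. Failing libraries are excluded from the returned cohort.
#'
#' @param cohort A `rep_cohort` from [attach_metadata()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `cohort` (filtered) and `report` (one row per input
#'   library: verdict, reasons, reads/clonotypes before and after,
#'   `reads_retained_fraction`).
#' @export
qc_cohort <- function(cohort, thresholds = qc_thresholds()) {
  reports <- vector("list", length(cohort$samples))
  kept <- list()
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    a <- assess_library(s, thresholds)
    rb <- s$total_reads
    cb <- nrow(s$clonotypes)
    if (a$verdict == "pass") {
      s2 <- merge_error_clonotypes(
        restrict_segments(filter_nonfunctional(s), thresholds), thresholds)
      kept[[s2$sample_id]] <- s2
      ra <- s2$total_reads
      ca <- nrow(s2$clonotypes)
    } else {
      ra <- NA_integer_
      ca <- NA_integer_
    }
    reports[[i]] <- data.frame(
      sample_id = s$sample_id, verdict = a$verdict, reasons = a$reasons,
      reads_before = rb, reads_after = ra,
      clonotypes_before = cb, clonotypes_after = ca,
      reads_retained_fraction = if (is.na(ra)) NA_real_ else ra / rb,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, reports)
  cohort$samples <- kept
  list(cohort = cohort, report = report)
}
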