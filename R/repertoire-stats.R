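# Segment usage, V-J pairing, CDR3 spectratypes, junctional inserts and
# nucleotide-to-amino-acid convergence.

usage_weights <- function(cl, weighting) {
  if (weighting == "reads") cl$freq else rep(1 / nrow(cl), nrow(cl))
}

#' Gene segment usage of a repertoire
#'
#' Fraction of the repertoire attributed to each V segment, J segment or
#' V-J pair, weighted either by reads (clone frequencies summed per
#' segment) or by clonotypes (each unique clonotype counts once).
#'
#' @param sample A [rep_sample()].
#' @param level `"V"`, `"J"` or `"VJ"`.
#' @param weighting `"reads"` or `"clonotypes"`.
#' @return Named numeric vector of fractions summing to 1 (empty for an
#'   empty repertoire), sorted decreasingly.
#' @export
segment_usage <- function(sample, level = c("V", "J", "VJ"),
                          weighting = c("reads", "clonotypes")) {
  level <- match.arg(level)
  weighting <- match.arg(weighting)
  cl <- sample$clonotypes
  if (nrow(cl) == 0L) return(setNames(numeric(0), character(0)))
  key <- switch(level, V = cl$v_gene, J = cl$j_gene,
                VJ = paste(cl$v_gene, cl$j_gene, sep = "-"))
  w <- usage_weights(cl, weighting)
  out <- vapply(split(w, key), sum, numeric(1))
  sort(out / sum(out), decreasing = TRUE)
}

#' Pooled V-J pairing profile across samples
#'
#' Per-sample V-J usage profiles averaged with equal sample weight (each
#' sample contributes 1/n regardless of depth).
#'
#' @param samples List of [rep_sample()] objects sharing one chain.
#' @param weighting `"reads"` or `"clonotypes"`.
#' @return Named numeric vector over V-J pairs, summing to 1.
#' @export
vj_pairing_matrix <- function(samples, weighting = c("reads", "clonotypes")) {
  weighting <- match.arg(weighting)
  stopifnot(length(samples) >= 1L)
  chains <- unique(vapply(samples, `[[`, character(1), "chain"))
  if (length(chains) > 1L)
    stop("samples mix chains: ", paste(chains, collapse = ", "))
  profiles <- lapply(samples, segment_usage, level = "VJ",
                     weighting = weighting)
  keys <- sort(unique(unlist(lapply(profiles, names))))
  pooled <- setNames(numeric(length(keys)), keys)
  for (p in profiles) pooled[names(p)] <- pooled[names(p)] + p
  sort(pooled / length(samples), decreasing = TRUE)
}

#' CDR3 length spectratype
#'
#' Histogram of CDR3 lengths in amino acids or nucleotides, weighted by
#' reads or clonotypes.
#'
#' @inheritParams segment_usage
#' @param unit `"aa"` or `"nt"`.
#' @return Named numeric vector keyed by integer length, summing to 1.
#' @export
spectratype <- function(sample, unit = c("aa", "nt"),
                        weighting = c("reads", "clonotypes")) {
  unit <- match.arg(unit)
  weighting <- match.arg(weighting)
  cl <- sample$clonotypes
  if (nrow(cl) == 0L) return(setNames(numeric(0), character(0)))
  len <- nchar(if (unit == "aa") cl$cdr3_aa else cl$cdr3_nt)
  w <- usage_weights(cl, weighting)
  out <- vapply(split(w, len), sum, numeric(1))
  out <- out / sum(out)
  out[order(as.integer(names(out)))]
}

#' Mean CDR3 length
#'
#' @inheritParams spectratype
#' @return Weighted mean CDR3 length (reads weighting by default).
#' @export
mean_cdr3_length <- function(sample, unit = c("aa", "nt"),
                             weighting = c("reads", "clonotypes")) {
  unit <- match.arg(unit)
  weighting <- match.arg(weighting)
  cl <- sample$clonotypes
  if (nrow(cl) == 0L) stop("mean CDR3 length undefined for empty repertoire")
  len <- nchar(if (unit == "aa") cl$cdr3_aa else cl$cdr3_nt)
  w <- usage_weights(cl, weighting)
  sum(len * w) / sum(w)
}

#' Junctional (NDN) insert sizes
#'
#' Non-templated insert lengths from 0-based junction coordinates. With a D
#' segment: `vd_insert = max(0, d_start - v_end)` and
#' `dj_insert = max(0, j_start - d_end)`; without D the single V-J insert is
#' `max(0, j_start - v_end)`. Negative gaps (exonucleolytic overlap) clamp
#' to 0. Rows whose required coordinates are undefined (-1) yield `NA` and
#' are excluded from aggregates.
#'
#' @param clonotypes A clonotype data frame or a [rep_sample()].
#' @return Data frame with `vd_insert`, `dj_insert`, `total_insert`.
#' @export
junction_inserts <- function(clonotypes) {
  cl <- if (inherits(clonotypes, "rep_sample")) clonotypes$clonotypes
        else as.data.frame(clonotypes)
  n <- nrow(cl)
  vd <- dj <- tot <- rep(NA_real_, n)
  has_d <- !is.na(cl$d_gene) & cl$d_start >= 0 & cl$d_end >= 0
  ok_d <- has_d & cl$v_end >= 0 & cl$j_start >= 0
  vd[ok_d] <- pmax(0, cl$d_start[ok_d] - cl$v_end[ok_d])
  dj[ok_d] <- pmax(0, cl$j_start[ok_d] - cl$d_end[ok_d])
  tot[ok_d] <- vd[ok_d] + dj[ok_d]
  ok_nd <- !has_d & cl$v_end >= 0 & cl$j_start >= 0
  tot[ok_nd] <- pmax(0, cl$j_start[ok_nd] - cl$v_end[ok_nd])
  data.frame(vd_insert = vd, dj_insert = dj, total_insert = tot)
}

#' TCR convergence ratio
#'
#' Number of distinct nucleotide-level clonotypes (`v_gene`, `cdr3_nt`,
#' `j_gene`) divided by the number of distinct amino-acid groups (`v_gene`,
#' `cdr3_aa`, `j_gene`). Always at least 1; equals 1 when no two nucleotide
#' variants encode the same CDR3 within a V-J context.
#'
#' @param sample A [rep_sample()].
#' @return Numeric scalar `>= 1` (`NA` for an empty repertoire).
#' @export
convergence_ratio <- function(sample) {
  cl <- sample$clonotypes
  if (nrow(cl) == 0L) return(NA_real_)
  n_nt <- length(unique(paste(cl$v_gene, cl$cdr3_nt, cl$j_gene, sep = "\r")))
  n_aa <- length(unique(paste(cl$v_gene, cl$cdr3_aa, cl$j_gene, sep = "\r")))
  n_nt / n_aa
}
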