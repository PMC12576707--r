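#' @importFrom stats cor.test fisher.test p.adjust rbeta rbinom
#'   rlnorm rmultinom rnorm rpois runif setNames wilcox.test
#' @importFrom utils read.delim write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib gdrepertoire, .registration = TRUE
NULL

# Genetic code tables, derived once from the standard code shipped with
# Biostrings. .AA_CODON_MAT / .AA_NCODONS support vectorised reverse
# translation with uniformly drawn synonymous codons.
.GC <- Biostrings::GENETIC_CODE
.AA_CODONS <- split(names(.GC), unname(.GC))
.AA_LETTERS <- setdiff(names(.AA_CODONS), "*")
.AA_NCODONS <- vapply(.AA_CODONS, length, integer(1))
.AA_CODON_MAT <- local({
  m <- matrix(NA_character_, nrow = length(.AA_CODONS),
              ncol = max(.AA_NCODONS), dimnames = list(names(.AA_CODONS), NULL))
  for (a in names(.AA_CODONS)) m[a, seq_along(.AA_CODONS[[a]])] <- .AA_CODONS[[a]]
  m
})

.SENSE_CODONS <- names(.GC)[.GC != "*"]
.SENSE_AA <- unname(.GC[.SENSE_CODONS])

.CLONOTYPE_COLS <- c("count", "freq", "cdr3_nt", "cdr3_aa", "v_gene", "d_gene",
                     "j_gene", "v_end", "d_start", "d_end", "j_start",
                     "functional")

#' Translate CDR3 nucleotide strings
#'
#' Codon-wise translation under the standard genetic code. Sequences whose
#' length is not a multiple of 3 translate to `NA`; stop codons appear as
#' `"*"`.
#'
#' @param nt Character vector of DNA strings over `A`, `C`, `G`, `T`.
#' @return Character vector of amino-acid strings.
#' @export
translate_cdr3 <- function(nt) {
  out <- rep(NA_character_, length(nt))
  n <- nchar(nt)
  ok <- !is.na(nt) & n > 0L & n %% 3L == 0L
  for (L in unique(n[ok])) {
    sel <- which(ok & n == L)
    starts <- seq(1L, L - 2L, 3L)
    cod <- matrix(.GC[vapply(starts, function(p)
      substr(nt[sel], p, p + 2L), character(length(sel)))],
      nrow = length(sel))
    bad <- rowSums(is.na(cod)) > 0L
    aa <- do.call(paste0, asplit(cod, 2L))
    aa[bad] <- NA_character_
    out[sel] <- aa
  }
  out
}

# Reverse-translate amino-acid strings into DNA, drawing synonymous codons
# either uniformly at random (canonical = FALSE) or always the first codon
# of each residue (canonical = TRUE, a fixed "germline-like" realisation).
reverse_translate <- function(aa, canonical = FALSE) {
  if (length(aa) == 0L) return(character(0))
  chars <- strsplit(aa, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  idx <- match(flat, rownames(.AA_CODON_MAT))
  if (anyNA(idx)) stop("non-standard amino-acid letter in CDR3: ",
                       paste(unique(flat[is.na(idx)]), collapse = ", "))
  pick <- if (canonical) rep(1L, length(idx)) else
    1L + floor(runif(length(idx)) * .AA_NCODONS[idx])
  codons <- .AA_CODON_MAT[cbind(idx, pick)]
  grp <- rep.int(seq_along(aa), lens)
  out <- character(length(aa))
  for (L in unique(lens)) {
    sel <- lens == L
    m <- matrix(codons[grp %in% which(sel)], ncol = L, byrow = TRUE)
    out[sel] <- do.call(paste0, asplit(m, 2L))
  }
  out
}

# Functionality rule used whenever an explicit flag is absent: in-frame
# (length divisible by 3) and no stop/frameshift marker in the aa string.
derive_functional <- function(cdr3_nt, cdr3_aa) {
  nchar(cdr3_nt) %% 3L == 0L & !grepl("[*_]", cdr3_aa)
}

#' Build a validated clonotype table
#'
#' Coerces a data frame to the canonical clonotype layout (one row per
#' rearrangement: count, frequency, CDR3 nt/aa, V/D/J calls, 0-based junction
#' coordinates, functionality flag). Frequencies are always recomputed from
#' counts; a stored frequency column is advisory only. Junction coordinates
#' use -1 for "undefined".
#'
#' @param df Data frame with at least `count`, `cdr3_nt`, `cdr3_aa`,
#'   `v_gene`, `j_gene`. Missing `d_gene` / coordinates / `functional`
#'   columns are filled with `NA`, -1 and the derived frame rule.
#' @return A `data.frame` with the canonical columns.
#' @export
clonotype_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("count", "cdr3_nt", "cdr3_aa", "v_gene", "j_gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clonotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"d_gene" %in% names(df)) df$d_gene <- NA_character_
  for (cc in c("v_end", "d_start", "d_end", "j_start"))
    if (!cc %in% names(df)) df[[cc]] <- -1L
  df$count <- as.integer(df$count)
  if (nrow(df) && any(is.na(df$count) | df$count < 1L))
    stop("clonotype counts must be integers >= 1")
  for (cc in c("cdr3_nt", "cdr3_aa", "v_gene", "d_gene", "j_gene"))
    df[[cc]] <- as.character(df[[cc]])
  for (cc in c("v_end", "d_start", "d_end", "j_start")) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    v[is.na(v)] <- -1L
    df[[cc]] <- v
  }
  if (!"functional" %in% names(df) || all(is.na(df$functional)))
    df$functional <- derive_functional(df$cdr3_nt, df$cdr3_aa)
  df$functional <- as.logical(df$functional)
  tot <- sum(df$count)
  df$freq <- if (tot > 0) df$count / tot else numeric(nrow(df))
  bad <- with(df, v_end >= 0 & d_start >= 0 & d_start < v_end |
                d_start >= 0 & d_end >= 0 & d_end < d_start |
                d_end >= 0 & j_start >= 0 & j_start < d_end |
                j_start >= 0 & j_start > nchar(cdr3_nt))
  if (nrow(df) && any(bad, na.rm = TRUE))
    stop("junction coordinates out of order in ", sum(bad), " row(s)")
  df[, .CLONOTYPE_COLS]
}

#' Construct a repertoire sample
#'
#' One sequencing library of a single chain (TRG or TRD) from one tissue of
#' one subject. Clonotype identities (`v_gene`, `cdr3_nt`, `j_gene`) must be
#' unique within the sample; duplicate identities are aggregated by summing
#' counts.
#'
#' @param sample_id,subject_id Identifiers.
#' @param tissue `"blood"` or `"skin"`.
#' @param chain `"TRG"` or `"TRD"`.
#' @param clonotypes Data frame accepted by [clonotype_table()].
#' @param off_target_reads Reads mapping to TRA/TRB in the same library
#'   (used only by library QC).
#' @param validate Run full field validation/coercion (internal callers
#'   constructing already-canonical tables may skip it).
#' @return An object of class `rep_sample`.
#' @export
rep_sample <- function(sample_id, subject_id, tissue, chain, clonotypes,
                       off_target_reads = 0L, validate = TRUE) {
  tissue <- match.arg(tissue, c("blood", "skin"))
  chain <- match.arg(chain, c("TRG", "TRD"))
  cl <- if (validate) clonotype_table(clonotypes) else clonotypes
  key <- paste(cl$v_gene, cl$cdr3_nt, cl$j_gene, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(cl$count, key, reorder = FALSE)
    first <- !duplicated(key)
    cl <- cl[first, , drop = FALSE]
    cl$count <- as.integer(agg[match(key[first], rownames(agg)), 1L])
  }
  tot <- sum(cl$count)
  cl$freq <- if (tot > 0) cl$count / tot else numeric(nrow(cl))
  rownames(cl) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 subject_id = as.character(subject_id),
                 tissue = tissue, chain = chain,
                 clonotypes = cl,
                 total_reads = sum(cl$count),
                 off_target_reads = as.integer(off_target_reads)),
            class = "rep_sample")
}

# Replace the clonotype table of a sample, recomputing frequencies/totals.
set_clonotypes <- function(sample, cl) {
  cl <- as.data.frame(cl, stringsAsFactors = FALSE)
  tot <- sum(cl$count)
  cl$freq <- if (tot > 0) cl$count / tot else numeric(nrow(cl))
  rownames(cl) <- NULL
  sample$clonotypes <- cl
  sample$total_reads <- as.integer(tot)
  sample
}

#' @export
print.rep_sample <- function(x, ...) {
  cat(sprintf("<rep_sample> %s  subject %s  %s %s\n", x$sample_id,
              x$subject_id, x$tissue, x$chain))
  cat(sprintf("  %d clonotypes, %d reads (%d off-target)\n",
              nrow(x$clonotypes), x$total_reads, x$off_target_reads))
  invisible(x)
}

#' @export
print.rep_cohort <- function(x, ...) {
  cat(sprintf("<rep_cohort> %d samples from %d subjects\n",
              length(x$samples), nrow(x$subjects)))
  invisible(x)
}

# Subset the samples of a cohort by tissue/chain (NULL = keep all).
filter_samples <- function(samples, tissue = NULL, chain = NULL) {
  keep <- vapply(samples, function(s) {
    (is.null(tissue) || s$tissue %in% tissue) &&
      (is.null(chain) || s$chain %in% chain)
  }, logical(1))
  samples[keep]
}
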