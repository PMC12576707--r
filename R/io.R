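# Readers and writers for clonotype tables (AIRR Rearrangement TSV and the
# legacy 11-column dialect) plus subject metadata.

# Segment-level normalisation of a gene call: first call of a multi-call
# field, allele suffix ("*01") stripped. "."/"" map to NA.
normalize_gene_call <- function(x) {
  x <- as.character(x)
  x <- sub(",.*$", "", x)
  x <- sub("\\*.*$", "", x)
  x <- trimws(x)
  x[x %in% c("", ".", "NA")] <- NA_character_
  x
}

.AIRR_REQUIRED <- c("duplicate_count", "junction", "junction_aa",
                    "v_call", "d_call", "j_call")
.LEGACY_COLS <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j",
                  "VEnd", "DStart", "DEnd", "JStart")

#' Read a clonotype table in AIRR Rearrangement format
#'
#' Parses an AIRR TSV (columns `duplicate_count`, `junction`, `junction_aa`,
#' `v_call`, `d_call`, `j_call`, optionally `productive` and junction-relative
#' `v_sequence_end`/`d_sequence_start`/`d_sequence_end`/`j_sequence_start`).
#' Gene calls are normalised to segment level and frequencies are recomputed
#' from counts.
#'
#' @param path TSV file path.
#' @param sample_meta List with `sample_id`, `subject_id`, `tissue`, `chain`
#'   and optionally `off_target_reads`.
#' @return A [rep_sample()].
#' @export
parse_airr <- function(path, sample_meta) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("", "NA"))
  miss <- setdiff(.AIRR_REQUIRED, names(df))
  if (length(miss))
    stop("AIRR schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("empty repertoire: no rearrangements in ", path)
  cl <- data.frame(count = as.integer(df$duplicate_count),
                   cdr3_nt = as.character(df$junction),
                   cdr3_aa = as.character(df$junction_aa),
                   v_gene = normalize_gene_call(df$v_call),
                   d_gene = normalize_gene_call(df$d_call),
                   j_gene = normalize_gene_call(df$j_call),
                   stringsAsFactors = FALSE)
  coord_map <- c(v_end = "v_sequence_end", d_start = "d_sequence_start",
                 d_end = "d_sequence_end", j_start = "j_sequence_start")
  for (k in names(coord_map)) {
    src <- coord_map[[k]]
    cl[[k]] <- if (src %in% names(df)) {
      v <- suppressWarnings(as.integer(df[[src]]))
      v[is.na(v)] <- -1L
      v
    } else -1L
  }
  if ("productive" %in% names(df)) {
    p <- toupper(as.character(df$productive))
    cl$functional <- p %in% c("T", "TRUE")
  }
  build_sample(cl, sample_meta)
}

#' Read a clonotype table in the legacy 11-column dialect
#'
#' Tab-delimited table with header
#' `count freq cdr3nt cdr3aa v d j VEnd DStart DEnd JStart`; `.` encodes an
#' absent D call and -1 an undefined junction coordinate. A stored frequency
#' column disagreeing with `count / total` by more than 1e-6 triggers a
#' warning and is recomputed.
#'
#' @inheritParams parse_airr
#' @return A [rep_sample()].
#' @export
parse_legacy_table <- function(path, sample_meta) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  miss <- setdiff(.LEGACY_COLS, names(df))
  if (length(miss))
    stop("legacy clonotype table ", path, " lacks column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("empty repertoire: no clonotypes in ", path)
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(cnt) | cnt != round(cnt))
  if (length(bad))
    stop("non-integer count in ", path, " at data row ", bad[1L])
  cl <- data.frame(count = as.integer(cnt),
                   cdr3_nt = df$cdr3nt, cdr3_aa = df$cdr3aa,
                   v_gene = normalize_gene_call(df$v),
                   d_gene = normalize_gene_call(df$d),
                   j_gene = normalize_gene_call(df$j),
                   v_end = as.integer(df$VEnd),
                   d_start = as.integer(df$DStart),
                   d_end = as.integer(df$DEnd),
                   j_start = as.integer(df$JStart),
                   stringsAsFactors = FALSE)
  stored <- suppressWarnings(as.numeric(df$freq))
  recomputed <- cl$count / sum(cl$count)
  if (any(is.na(stored)) || any(abs(stored - recomputed) > 1e-6))
    warning("stored frequencies in ", path,
            " disagree with counts; recomputed")
  build_sample(cl, sample_meta)
}

build_sample <- function(cl, sample_meta) {
  m <- as.list(sample_meta)
  for (k in c("sample_id", "subject_id", "tissue", "chain"))
    if (is.null(m[[k]])) stop("sample_meta lacks '", k, "'")
  rep_sample(m$sample_id, m$subject_id, m$tissue, m$chain, cl,
             off_target_reads = if (is.null(m$off_target_reads)) 0L
                                else m$off_target_reads)
}

#' Write a clonotype table
#'
#' Serialises a sample so that re-reading with the matching parser
#' reproduces every field. The `airr` dialect writes -1 coordinates as empty
#' cells; the `legacy` dialect preserves -1 literally.
#'
#' @param sample A [rep_sample()].
#' @param path Output TSV path.
#' @param dialect `"airr"` or `"legacy"`.
#' @export
write_clonotype_table <- function(sample, path, dialect = c("airr", "legacy")) {
  dialect <- match.arg(dialect)
  cl <- sample$clonotypes
  if (dialect == "airr") {
    coords <- lapply(cl[c("v_end", "d_start", "d_end", "j_start")],
                     function(v) ifelse(v < 0L, NA_integer_, v))
    out <- data.frame(sequence_id = sprintf("%s_%06d", sample$sample_id,
                                            seq_len(max(nrow(cl), 0L))),
                      duplicate_count = cl$count,
                      junction = cl$cdr3_nt, junction_aa = cl$cdr3_aa,
                      v_call = cl$v_gene,
                      d_call = ifelse(is.na(cl$d_gene), "", cl$d_gene),
                      j_call = cl$j_gene,
                      productive = ifelse(cl$functional, "T", "F"),
                      v_sequence_end = coords$v_end,
                      d_sequence_start = coords$d_start,
                      d_sequence_end = coords$d_end,
                      j_sequence_start = coords$j_start,
                      stringsAsFactors = FALSE)
    if (nrow(cl) == 0L) out <- out[0L, , drop = FALSE]
  } else {
    out <- data.frame(count = cl$count, freq = cl$freq,
                      cdr3nt = cl$cdr3_nt, cdr3aa = cl$cdr3_aa,
                      v = cl$v_gene,
                      d = ifelse(is.na(cl$d_gene), ".", cl$d_gene),
                      j = cl$j_gene,
                      VEnd = cl$v_end, DStart = cl$d_start,
                      DEnd = cl$d_end, JStart = cl$j_start,
                      stringsAsFactors = FALSE)
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write clonotype table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a subject metadata table
#'
#' TSV with columns `subject_id`, `group` (PV/HC), `age`, `sex`, `pasi`,
#' `duration_years`, `cmv_igg`, `cmv_status`. PV subjects may lack PASI
#' (kept with a warning); healthy controls carrying a PASI score have it
#' cleared with a warning.
#'
#' @param path TSV path.
#' @return Data frame of subject records.
#' @export
read_subjects <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  need <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("subject table lacks column(s) ",
                         paste(miss, collapse = ", "))
  for (cc in c("pasi", "duration_years", "cmv_igg"))
    if (!cc %in% names(df)) df[[cc]] <- NA_real_
  if (!"cmv_status" %in% names(df)) df$cmv_status <- "unknown"
  validate_subjects(df)
}

validate_subjects <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("integrity error: duplicate subject_id in metadata: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  if (!all(df$group %in% c("PV", "HC")))
    stop("group must be PV or HC")
  hc_pasi <- df$group == "HC" & !is.na(df$pasi)
  if (any(hc_pasi)) {
    warning("PASI recorded for HC subject(s) ",
            paste(df$subject_id[hc_pasi], collapse = ", "), "; cleared")
    df$pasi[hc_pasi] <- NA_real_
  }
  pv_nopasi <- df$group == "PV" & is.na(df$pasi)
  if (any(pv_nopasi))
    warning("PV subject(s) without PASI kept: ",
            paste(df$subject_id[pv_nopasi], collapse = ", "))
  df
}

#' Bind repertoire samples to subject metadata
#'
#' @param samples List of [rep_sample()] objects.
#' @param subjects Subject data frame (see [read_subjects()]).
#' @return An object of class `rep_cohort`: `$samples` (named list) and
#'   `$subjects`.
#' @export
attach_metadata <- function(samples, subjects) {
  subjects <- validate_subjects(subjects)
  sids <- vapply(samples, `[[`, character(1), "subject_id")
  unknown <- setdiff(unique(sids), subjects$subject_id)
  if (length(unknown))
    stop("sample(s) reference unknown subject id(s): ",
         paste(unknown, collapse = ", "))
  names(samples) <- vapply(samples, `[[`, character(1), "sample_id")
  structure(list(samples = samples, subjects = subjects),
            class = "rep_cohort")
}
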