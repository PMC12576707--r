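# File-based orchestration: simulate (or ingest) -> qc -> repertoire stats
# -> diversity -> overlap -> association, with a manifest and a markdown
# report. Stages communicate via TSV so each is independently re-runnable.

write_stage_tsv <- function(df, dir, file) {
  path <- file.path(dir, file)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

#' Run the full repertoire analysis pipeline
#'
#' Either simulates a cohort from a [sim_config()] or ingests a directory
#' of AIRR clonotype tables (`*_airr.tsv` named `<subject>_<tissue>_<chain>`,
#' plus `subjects.tsv`), then runs QC, repertoire statistics, diversity,
#' overlap and covariate association, writing one TSV per stage plus a
#' manifest with file checksums. Reruns with the same seed produce
#' identical artifacts.
#'
#' @param input A [sim_config()] or a directory path.
#' @param out_dir Output directory (created if needed).
#' @param thresholds A [qc_thresholds()].
#' @param basis Clonotype key basis for overlap analyses.
#' @param top_n Top-clonotype count for cumulative frequency summaries.
#' @param covariates Covariates tested against diversity features (PV
#'   blood stratum).
#' @param seed Overrides the simulation seed when `input` is a config.
#' @return Invisibly, a list with `manifest` (file, stage, checksum),
#'   `qc_report` and the output directory.
#' @export
run_pipeline <- function(input = sim_config(), out_dir,
                         thresholds = qc_thresholds(), basis = "aa",
                         top_n = 10L,
                         covariates = c("pasi", "age"), seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(file, stage)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(file), stage = stage,
      checksum = unname(tools::md5sum(file)), stringsAsFactors = FALSE)

  # stage 1: cohort acquisition
  if (inherits(input, "sim_config")) {
    if (!is.null(seed)) input$seed <- as.integer(seed)
    sim <- generate_cohort(input)
    cohort <- sim$cohort
    for (s in cohort$samples) {
      f <- file.path(out_dir, paste0(s$sample_id, "_airr.tsv"))
      write_clonotype_table(s, f, dialect = "airr")
      note(f, "simulate")
    }
    note(write_stage_tsv(cohort$subjects, out_dir, "subjects.tsv"),
         "simulate")
    note(write_stage_tsv(sim$truth, out_dir, "truth.tsv"), "simulate")
  } else {
    files <- list.files(input, pattern = "_airr\\.tsv$", full.names = TRUE)
    if (!length(files)) stop("no *_airr.tsv clonotype tables in ", input)
    subjects <- read_subjects(file.path(input, "subjects.tsv"))
    samples <- lapply(files, function(f) {
      parts <- strsplit(sub("_airr\\.tsv$", "", basename(f)), "_")[[1L]]
      if (length(parts) < 3L)
        stop("cannot parse sample descriptor from file name: ", basename(f))
      parse_airr(f, list(sample_id = sub("_airr\\.tsv$", "", basename(f)),
                         subject_id = parts[1L], tissue = parts[2L],
                         chain = parts[3L]))
    })
    cohort <- attach_metadata(samples, subjects)
  }

  # stage 2: QC
  qc <- qc_cohort(cohort, thresholds)
  note(write_stage_tsv(qc$report, out_dir, "qc_report.tsv"), "qc")
  cohort <- qc$cohort
  if (!length(cohort$samples)) {
    warning("all libraries failed QC; pipeline stopped after QC")
    return(invisible(list(manifest = do.call(rbind, manifest),
                          qc_report = qc$report, out_dir = out_dir)))
  }

  # stage 3: repertoire statistics
  stats_rows <- lapply(cohort$samples, function(s) {
    u <- segment_usage(s, "V")
    data.frame(sample_id = s$sample_id, tissue = s$tissue, chain = s$chain,
               segment = names(u), usage = as.numeric(u),
               stringsAsFactors = FALSE)
  })
  note(write_stage_tsv(do.call(rbind, stats_rows), out_dir, "usage_V.tsv"),
       "stats")
  spec_rows <- lapply(cohort$samples, function(s) {
    sp <- spectratype(s, "aa")
    data.frame(sample_id = s$sample_id, length_aa = as.integer(names(sp)),
               fraction = as.numeric(sp), stringsAsFactors = FALSE)
  })
  note(write_stage_tsv(do.call(rbind, spec_rows), out_dir,
                       "spectratype_aa.tsv"), "stats")
  conv_rows <- lapply(cohort$samples, function(s)
    data.frame(sample_id = s$sample_id, tissue = s$tissue, chain = s$chain,
               convergence_ratio = convergence_ratio(s),
               mean_cdr3_aa = mean_cdr3_length(s, "aa"),
               stringsAsFactors = FALSE))
  note(write_stage_tsv(do.call(rbind, conv_rows), out_dir,
                       "convergence.tsv"), "stats")

  # stage 4: diversity
  div_rows <- lapply(cohort$samples, function(s) {
    d <- diversity_profile(s, per_segment = FALSE)
    d$tissue <- s$tissue
    d$chain <- s$chain
    d$subject_id <- s$subject_id
    d$top_n_cumfreq <- top_n_cumulative(s, top_n)
    d
  })
  diversity_tab <- do.call(rbind, div_rows)
  note(write_stage_tsv(diversity_tab, out_dir, "diversity.tsv"),
       "diversity")

  # stage 5: overlap
  overlap_rows <- list()
  for (ti in unique(vapply(cohort$samples, `[[`, character(1), "tissue")))
    for (ch in unique(vapply(cohort$samples, `[[`, character(1), "chain"))) {
      ss <- filter_samples(cohort$samples, ti, ch)
      if (length(ss) < 2L) next
      sc <- suppressWarnings(sharing_counts(cohort, basis = basis,
                                            tissue = ti, chain = ch))
      overlap_rows[[paste(ti, ch)]] <- data.frame(
        tissue = ti, chain = ch, n_subjects = sc$n_subjects,
        n_keys = nrow(sc$table),
        public_fraction = sc$public_fraction, stringsAsFactors = FALSE)
    }
  if (length(overlap_rows))
    note(write_stage_tsv(do.call(rbind, overlap_rows), out_dir,
                         "overlap_summary.tsv"), "overlap")

  # stage 6: association (diversity features vs covariates, PV blood)
  assoc_rows <- list()
  for (ch in unique(diversity_tab$chain)) {
    feat <- diversity_tab[diversity_tab$tissue == "blood" &
                            diversity_tab$chain == ch,
                          c("subject_id", "s_obs", "d50", "shannon",
                            "inv_simpson", "top_n_cumfreq")]
    for (cv in covariates) {
      a <- correlate_features(feat, cohort$subjects, covariate = cv,
                              group = "PV")
      if (is.null(a)) next
      a$chain <- ch
      assoc_rows[[paste(ch, cv)]] <- a
    }
  }
  if (length(assoc_rows))
    note(write_stage_tsv(do.call(rbind, assoc_rows), out_dir, "assoc.tsv"),
         "associate")

  manifest <- do.call(rbind, manifest)
  note2 <- write_stage_tsv(manifest, out_dir, "manifest.tsv")
  write_report(manifest, file.path(out_dir, "report.md"), out_dir)
  invisible(list(manifest = manifest, qc_report = qc$report,
                 out_dir = out_dir))
}

#' Render a human-readable pipeline report
#'
#' Markdown summary with one section per pipeline stage; stages without
#' artifacts are marked unavailable.
#'
#' @param manifest Manifest data frame (`file`, `stage`, `checksum`).
#' @param path Output markdown path.
#' @param out_dir Directory holding the stage TSVs.
#' @return Invisibly, the report path.
#' @export
write_report <- function(manifest, path, out_dir = dirname(path)) {
  stages <- c("simulate", "qc", "stats", "diversity", "overlap",
              "associate")
  lines <- c("# Repertoire pipeline report", "")
  if (is.null(manifest) || nrow(manifest) == 0L) {
    warning("empty manifest; writing stub report")
    lines <- c(lines, "No artifacts were produced.")
  } else {
    for (st in stages) {
      lines <- c(lines, paste0("## ", st), "")
      files <- manifest$file[manifest$stage == st]
      if (!length(files)) {
        lines <- c(lines, "_unavailable_", "")
        next
      }
      lines <- c(lines, paste0("- `", files, "`"), "")
      summary_file <- switch(st, qc = "qc_report.tsv",
                             overlap = "overlap_summary.tsv",
                             associate = "assoc.tsv", NULL)
      if (!is.null(summary_file) &&
          file.exists(file.path(out_dir, summary_file))) {
        tab <- read.delim(file.path(out_dir, summary_file))
        lines <- c(lines, paste0("Rows: ", nrow(tab)), "")
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
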