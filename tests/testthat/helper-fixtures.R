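# In-code fixtures: hand-built toy samples and random valid repertoires.

toy_clonotypes <- function(counts, v = NULL, j = NULL, aa = NULL, nt = NULL) {
  n <- length(counts)
  if (is.null(aa)) {
    aa <- replicate(n, paste0("C", paste(sample(c("A", "G", "L", "W", "E",
                                                  "V", "K", "I"), 10,
                                                replace = TRUE),
                                         collapse = ""), "F"))
  }
  if (is.null(nt)) nt <- gdrepertoire:::reverse_translate(aa)
  data.frame(count = counts, cdr3_nt = nt, cdr3_aa = aa,
             v_gene = if (is.null(v)) rep("TRGV9", n) else v,
             j_gene = if (is.null(j)) rep("TRGJP", n) else j,
             stringsAsFactors = FALSE)
}

toy_sample <- function(counts, v = NULL, j = NULL, aa = NULL, nt = NULL,
                       sample_id = "S1", subject_id = "P1",
                       tissue = "blood", chain = "TRG",
                       off_target_reads = 0L) {
  rep_sample(sample_id, subject_id, tissue, chain,
             toy_clonotypes(counts, v, j, aa, nt),
             off_target_reads = off_target_reads)
}

# random valid repertoire of at most n_max clones (unique nt identities)
random_sample <- function(n_max = 20L, sample_id = "R1", subject_id = "P1",
                          chain = "TRG", tissue = "blood") {
  n <- sample(2:n_max, 1L)
  len <- sample(4:8, n, replace = TRUE)
  aa <- vapply(len, function(L)
    paste0("C", paste(sample(LETTERS[c(1, 4, 5, 7, 9, 11, 12, 22)], L,
                             replace = TRUE), collapse = ""), "F"),
    character(1))
  nt <- gdrepertoire:::reverse_translate(aa)
  keep <- !duplicated(nt)
  vs <- if (chain == "TRG") c("TRGV9", "TRGV4", "TRGV2")
        else c("TRDV1", "TRDV2", "TRDV3")
  js <- if (chain == "TRG") c("TRGJP", "TRGJ2") else c("TRDJ1", "TRDJ3")
  toy_sample(sample(1:50, sum(keep), replace = TRUE),
             v = sample(vs, sum(keep), replace = TRUE),
             j = sample(js, sum(keep), replace = TRUE),
             aa = aa[keep], nt = nt[keep],
             sample_id = sample_id, subject_id = subject_id,
             tissue = tissue, chain = chain)
}

small_sim <- function(seed = 1L, ...) {
  sim_config(n_pv = 4L, n_hc = 3L, n_skin_pv = 2L, n_skin_hc = 1L,
             seed = seed, ...)
}
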