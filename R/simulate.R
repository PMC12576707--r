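# Synthetic blood/skin TRG/TRD repertoire cohorts with known ground truth:
# dominant canonical rearrangements, per-segment CDR3 length mixtures
# (including bimodal segments), heavy-tailed clone sizes, shared public
# clonotype pools, synonymous-variant convergence, sequencing-error
# children and clinical covariate effects on repertoire richness.

normalize_priors <- function(w) {
  stopifnot(all(w > 0))
  w / sum(w)
}

default_usage_priors <- function() {
  blood_trg <- c("TRGV9-TRGJP" = 0.55, "TRGV9-TRGJ2" = 0.10)
  for (v in c("TRGV2", "TRGV3", "TRGV4", "TRGV5", "TRGV8"))
    blood_trg[paste0(v, "-", c("TRGJ2", "TRGJP1", "TRGJP2", "TRGJ1"))] <-
      c(0.030, 0.015, 0.015, 0.010)
  blood_trd <- c("TRDV2-TRDJ1" = 0.60, "TRDV2-TRDJ3" = 0.08,
                 "TRDV2-TRDJ2" = 0.02, "TRDV1-TRDJ1" = 0.15,
                 "TRDV1-TRDJ2" = 0.03, "TRDV1-TRDJ3" = 0.02,
                 "TRDV3-TRDJ1" = 0.06, "TRDV3-TRDJ2" = 0.02)
  blood_trd[paste0("TRDV", 4:8, "-TRDJ1")] <- 0.004
  skin_trg <- numeric(0)
  for (v in c("TRGV2", "TRGV3", "TRGV4", "TRGV5", "TRGV8", "TRGV9"))
    skin_trg[paste0(v, "-", c("TRGJ2", "TRGJP2", "TRGJP1", "TRGJP"))] <-
      c(0.090, 0.030, 0.025, 0.020)
  skin_trd <- c("TRDV1-TRDJ1" = 0.35, "TRDV1-TRDJ2" = 0.05,
                "TRDV2-TRDJ1" = 0.30, "TRDV2-TRDJ2" = 0.05,
                "TRDV2-TRDJ3" = 0.05, "TRDV3-TRDJ1" = 0.15,
                "TRDV3-TRDJ2" = 0.05)
  list(blood = list(TRG = normalize_priors(blood_trg),
                    TRD = normalize_priors(blood_trd)),
       skin = list(TRG = normalize_priors(skin_trg),
                   TRD = normalize_priors(skin_trd)))
}

default_length_models <- function() {
  short <- list(means = 13, sds = 1.3, weights = 1)
  list(TRGV9 = list(means = 15, sds = 1.6, weights = 1),
       TRGV2 = short, TRGV3 = short, TRGV4 = short, TRGV5 = short,
       TRGV8 = short,
       TRDV1 = list(means = c(13, 17), sds = c(1, 1),
                    weights = c(0.55, 0.45)),
       TRDV2 = list(means = 16, sds = 1.5, weights = 1),
       TRDV3 = list(means = c(12, 16), sds = c(1, 1),
                    weights = c(0.5, 0.5)),
       .default = list(means = 14, sds = 1.5, weights = 1))
}

default_public_pool <- function() {
  data.frame(
    v_gene = c(rep("TRGV9", 5), rep("TRGV4", 3), "TRGV2",
               "TRDV2", "TRDV2"),
    j_gene = c(rep("TRGJP", 5), rep("TRGJ2", 3), "TRGJ2",
               "TRDJ1", "TRDJ1"),
    cdr3_aa = c("CALWEVQELGKKIKVF", "CALWEVRELGKKIKVF", "CALWEVLELGKKIKVF",
                "CALWEVKELGKKIKVF", "CALWEVHELGKKIKVF",
                "CATWDGPYYKKLF", "CATWDRPNYYKKLF", "CATWDGGYYKKLF",
                "CATWDSTGWFKIF",
                "CACDVLGDPYTDKLIF", "CACDRLGDTDKLIF"),
    base_freq = c(0.030, 0.015, 0.010, 0.008, 0.006,
                  0.010, 0.008, 0.006, 0.006,
                  0.020, 0.010),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' All knobs of the synthetic cohort generator. Defaults emulate the
#' repertoire structure of a psoriasis-vs-control gamma-delta TCR cohort:
#' canonical TRGV9-TRGJP / TRDV2-TRDJ1 dominance in blood with near-uniform
#' TRGJ2-skewed skin usage, per-segment CDR3 length mixtures (bimodal
#' TRDV1/TRDV3), Zipf-like clone sizes, a germline-like public clonotype
#' pool, synonymous-variant convergence, 1-mismatch singleton error
#' children, and negative severity (PASI) and age effects on log blood
#' richness in patients.
#'
#' @param n_pv,n_hc Patient / control subject counts.
#' @param n_skin_pv,n_skin_hc How many subjects (the first of each group)
#'   also contribute skin libraries.
#' @param tissues,chains Compartments and chains to simulate.
#' @param depth_blood,depth_skin Reads per library.
#' @param richness_base Expected distinct blood clonotypes per library.
#' @param richness_skin_factor Skin richness as a fraction of blood.
#' @param sigma_log_richness Subject-level lognormal richness noise (sd).
#' @param clone_size_alpha Power-law exponent of clone sizes (`> 1`).
#' @param usage_priors Per tissue/chain named V-J pair probabilities.
#' @param cdr3_length_models Per V segment discrete-Gaussian mixtures on
#'   amino-acid CDR3 length (`means`, `sds`, `weights`; `.default` used for
#'   unlisted segments).
#' @param beta_pasi,beta_age Effects of standardised PASI / age on log
#'   blood richness (patients only).
#' @param public_pool Data frame `v_gene`, `j_gene`, `cdr3_aa`, `base_freq`
#'   of germline-like public clonotypes.
#' @param share_prob,skin_share_prob Probability a public-pool clonotype is
#'   placed in a given subject's blood / (if sampled) skin.
#' @param convergence_rate Probability an expanded clonotype carries a
#'   synonymous nucleotide variant.
#' @param error_rate Fraction of reads emitted as 1-mismatch singleton
#'   error children.
#' @param nonfunctional_rate Probability a clonotype is an out-of-frame
#'   passenger rearrangement (down-weighted in expression, as
#'   nonsense-mediated decay suppresses out-of-frame transcripts).
#' @param pseudogene_rate Probability a clonotype uses a pseudogene or
#'   TRAV-hybrid segment.
#' @param offtarget_shape Beta shape parameters for the TRA/TRB off-target
#'   read fraction.
#' @param seed Integer seed; identical configurations and seeds give
#'   identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pv = 20L, n_hc = 15L, n_skin_pv = 10L,
                       n_skin_hc = 5L,
                       tissues = c("blood", "skin"),
                       chains = c("TRG", "TRD"),
                       depth_blood = 20000L, depth_skin = 2000L,
                       richness_base = 900, richness_skin_factor = 0.08,
                       sigma_log_richness = 0.25,
                       clone_size_alpha = 2.5,
                       usage_priors = default_usage_priors(),
                       cdr3_length_models = default_length_models(),
                       beta_pasi = -0.5, beta_age = -0.5,
                       public_pool = default_public_pool(),
                       share_prob = 0.5, skin_share_prob = 0.4,
                       convergence_rate = 0.15, error_rate = 0.01,
                       nonfunctional_rate = 0.015, pseudogene_rate = 0.005,
                       offtarget_shape = c(2, 14),
                       seed = 1L) {
  stopifnot(clone_size_alpha > 1, n_pv >= 0, n_hc >= 0)
  tissues <- match.arg(tissues, c("blood", "skin"), several.ok = TRUE)
  chains <- match.arg(chains, c("TRG", "TRD"), several.ok = TRUE)
  rates <- c(share_prob, skin_share_prob, convergence_rate, error_rate,
             nonfunctional_rate, pseudogene_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  for (ti in tissues) for (ch in chains) {
    pr <- usage_priors[[ti]][[ch]]
    if (is.null(pr) || any(pr <= 0) || abs(sum(pr) - 1) > 1e-6)
      stop("invalid usage priors for ", ti, " ", ch)
  }
  structure(list(n_pv = as.integer(n_pv), n_hc = as.integer(n_hc),
                 n_skin_pv = as.integer(n_skin_pv),
                 n_skin_hc = as.integer(n_skin_hc),
                 tissues = tissues, chains = chains,
                 depth_blood = as.integer(depth_blood),
                 depth_skin = as.integer(depth_skin),
                 richness_base = richness_base,
                 richness_skin_factor = richness_skin_factor,
                 sigma_log_richness = sigma_log_richness,
                 clone_size_alpha = clone_size_alpha,
                 usage_priors = usage_priors,
                 cdr3_length_models = cdr3_length_models,
                 beta_pasi = beta_pasi, beta_age = beta_age,
                 public_pool = public_pool,
                 share_prob = share_prob, skin_share_prob = skin_share_prob,
                 convergence_rate = convergence_rate,
                 error_rate = error_rate,
                 nonfunctional_rate = nonfunctional_rate,
                 pseudogene_rate = pseudogene_rate,
                 offtarget_shape = offtarget_shape,
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_subjects <- function(config) {
  n <- config$n_pv + config$n_hc
  group <- c(rep("PV", config$n_pv), rep("HC", config$n_hc))
  id <- sprintf("%s%02d", group, c(seq_len(config$n_pv),
                                   seq_len(config$n_hc)))
  age <- ifelse(group == "PV",
                pmin(pmax(round(rnorm(n, 44, 12)), 18), 75),
                pmin(pmax(round(rnorm(n, 38, 10)), 18), 65))
  sex <- ifelse(runif(n) < 0.75, "M", "F")
  pasi <- ifelse(group == "PV", round(rlnorm(n, log(16), 0.6), 1), NA_real_)
  duration <- ifelse(group == "PV", round(rlnorm(n, log(9), 0.7), 1),
                     NA_real_)
  neg <- runif(n) < ifelse(group == "PV", 0.21, 0.05)
  cmv_igg <- ifelse(neg, round(runif(n, 0, 5), 1),
                    round(rlnorm(n, log(100), 0.5), 1))
  data.frame(subject_id = id, group = group, age = age, sex = sex,
             pasi = pasi, duration_years = duration, cmv_igg = cmv_igg,
             cmv_status = ifelse(neg, "neg", "pos"),
             stringsAsFactors = FALSE)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

draw_mixture_lengths <- function(n, model) {
  comp <- sample.int(length(model$weights), n, replace = TRUE,
                     prob = model$weights)
  pmin(pmax(round(rnorm(n, model$means[comp], model$sds[comp])), 8L), 22L)
}

#' Generate one CDR3 (batch)
#'
#' Draws anchored CDR3 amino-acid strings (`C...F`), a consistent random
#' codon realisation, and junction coordinates compatible with a simulated
#' V-end / D / J-start split (so junctional inserts are well defined).
#'
#' @param v_gene,j_gene Segment labels (recycled).
#' @param length_aa Target amino-acid lengths (`>= 5`).
#' @param chain `"TRG"` (no D segment) or `"TRD"`.
#' @return Data frame with `cdr3_aa`, `cdr3_nt`, `d_gene` and junction
#'   coordinates.
#' @export
sample_cdr3 <- function(v_gene, j_gene, length_aa, chain = c("TRG", "TRD")) {
  chain <- match.arg(chain)
  n <- length(length_aa)
  stopifnot(all(length_aa >= 5L))
  aa <- nt <- character(n)
  for (L in unique(length_aa)) {
    sel <- which(length_aa == L)
    m <- length(sel)
    mid <- L - 2L
    # draw sense codons directly: one pass yields consistent nt and aa
    ci <- sample.int(length(.SENSE_CODONS), m * mid, replace = TRUE)
    cod_cols <- lapply(seq_len(mid), function(j)
      .SENSE_CODONS[ci[(j - 1L) * m + seq_len(m)]])
    aa_cols <- lapply(seq_len(mid), function(j)
      .SENSE_AA[ci[(j - 1L) * m + seq_len(m)]])
    nt[sel] <- paste0(sample(c("TGT", "TGC"), m, replace = TRUE),
                      do.call(paste0, cod_cols),
                      sample(c("TTT", "TTC"), m, replace = TRUE))
    aa[sel] <- paste0("C", do.call(paste0, aa_cols), "F")
  }
  L_nt <- 3L * length_aa
  v_end <- pmax(3L, pmin(round(L_nt * 0.35) +
                           sample(-2:2, n, replace = TRUE), L_nt))
  if (chain == "TRD") {
    d_start <- pmin(v_end + rpois(n, 3), L_nt)
    d_end <- pmin(d_start + sample(4:8, n, replace = TRUE), L_nt)
    j_start <- pmin(d_end + rpois(n, 3), L_nt)
    d_gene <- sample(c("TRDD3", "TRDD2"), n, replace = TRUE,
                     prob = c(0.8, 0.2))
  } else {
    d_start <- d_end <- rep(-1L, n)
    j_start <- pmin(v_end + rpois(n, 4), L_nt)
    d_gene <- NA_character_
  }
  data.frame(cdr3_aa = aa, cdr3_nt = nt, d_gene = d_gene,
             v_end = as.integer(v_end), d_start = as.integer(d_start),
             d_end = as.integer(d_end), j_start = as.integer(j_start),
             stringsAsFactors = FALSE)
}

mutate_one_base <- function(nt) {
  bases <- c("A", "C", "G", "T")
  n <- length(nt)
  L <- nchar(nt)
  p <- 1L + floor(runif(n) * L)
  old <- substr(nt, p, p)
  new <- bases[(match(old, bases) - 1L +
                  sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
  paste0(substr(nt, 1L, p - 1L), new, substring(nt, p + 1L))
}

#' Simulate one repertoire library
#'
#' Draws clonotype identities from the tissue/chain usage priors and the
#' per-segment CDR3 length mixtures, assigns Zipf-like clone sizes by
#' multinomial sampling at the library depth, then adds synonymous
#' convergence variants, out-of-frame and pseudogene rearrangements and
#' 1-mismatch singleton error children. Reads moved into variants or error
#' children are taken from their parents, so the library depth is exact.
#'
#' @param subject One-row subject data frame.
#' @param tissue,chain Library compartment and chain.
#' @param config A [sim_config()].
#' @param target_richness Expected distinct clonotypes before sampling.
#' @return A [rep_sample()] with an extra `truth_keys` element (nt-basis
#'   keys of the true clonotypes, before error injection).
#' @export
sample_repertoire <- function(subject, tissue, chain, config,
                              target_richness) {
  S <- max(10L, round(target_richness))
  depth <- if (tissue == "blood") config$depth_blood else config$depth_skin
  priors <- config$usage_priors[[tissue]][[chain]]
  pair <- names(priors)[sample.int(length(priors), S, replace = TRUE,
                                   prob = priors)]
  vj <- do.call(rbind, strsplit(pair, "-", fixed = TRUE))
  v_gene <- vj[, 1L]
  j_gene <- vj[, 2L]
  len <- integer(S)
  models <- config$cdr3_length_models
  for (v in unique(v_gene)) {
    m <- if (!is.null(models[[v]])) models[[v]] else models$.default
    sel <- v_gene == v
    len[sel] <- draw_mixture_lengths(sum(sel), m)
  }
  cd <- sample_cdr3(v_gene, j_gene, len, chain)
  cdr3_nt <- cd$cdr3_nt
  cdr3_aa <- cd$cdr3_aa
  d_gene <- cd$d_gene
  v_end <- cd$v_end; d_start <- cd$d_start
  d_end <- cd$d_end; j_start <- cd$j_start
  n <- length(cdr3_nt)
  functional <- rep(TRUE, n)
  # pseudogene / TRAV-hybrid passenger rearrangements
  pseudo <- runif(n) < config$pseudogene_rate
  if (any(pseudo)) {
    pool <- if (chain == "TRG") c("TRGV10", "TRGV11")
            else c("TRAV14/DV4", "TRAV29/DV5")
    v_gene[pseudo] <- sample(pool, sum(pseudo), replace = TRUE)
  }
  # out-of-frame rearrangements (frameshifted nt, "_" marker in aa)
  oof <- runif(n) < config$nonfunctional_rate
  if (any(oof)) {
    newlen <- nchar(cdr3_nt[oof]) - 1L
    cdr3_nt[oof] <- substr(cdr3_nt[oof], 1L, newlen)
    cdr3_aa[oof] <- paste0(cdr3_aa[oof], "_")
    functional[oof] <- FALSE
    # keep junction coordinates inside the truncated string
    v_end[oof] <- pmin(v_end[oof], newlen)
    d_start[oof] <- pmin(d_start[oof], newlen)
    d_end[oof] <- pmin(d_end[oof], newlen)
    j_start[oof] <- pmin(j_start[oof], newlen)
  }
  # Zipf-like clone sizes; out-of-frame transcripts are NMD-suppressed and
  # pseudogene transcripts lowly expressed, hence down-weighted
  kmax <- 1000L
  w <- as.numeric(sample.int(kmax, n, replace = TRUE,
                             prob = seq_len(kmax)^(-config$clone_size_alpha)))
  w[oof] <- w[oof] * 0.1
  w[pseudo] <- w[pseudo] * 0.3
  count <- as.integer(rmultinom(1L, depth, w))
  keep <- which(count > 0L)
  for (nm in c("v_gene", "j_gene", "d_gene", "cdr3_nt", "cdr3_aa", "v_end",
               "d_start", "d_end", "j_start", "functional", "count"))
    assign(nm, get(nm)[keep])
  # synonymous convergence variants carved out of expanded clones
  cand <- which(functional & count >= 2L)
  conv <- cand[runif(length(cand)) < config$convergence_rate]
  if (length(conv)) {
    var_nt <- reverse_translate(cdr3_aa[conv])
    ok <- var_nt != cdr3_nt[conv]
    conv <- conv[ok]
    var_nt <- var_nt[ok]
    if (length(conv)) {
      var_cnt <- pmax(1L, rbinom(length(conv), count[conv] - 1L, 0.3))
      count[conv] <- count[conv] - var_cnt
      for (nm in c("v_gene", "j_gene", "d_gene", "cdr3_aa", "v_end",
                   "d_start", "d_end", "j_start", "functional"))
        assign(nm, c(get(nm), get(nm)[conv]))
      cdr3_nt <- c(cdr3_nt, var_nt)
      count <- c(count, var_cnt)
    }
  }
  truth_keys <- unique(paste(v_gene, cdr3_nt, j_gene, sep = "|"))
  # 1-mismatch singleton error children, reads taken from their parents
  n_err <- rbinom(1L, sum(count), config$error_rate)
  if (n_err > 0L) {
    elig <- which(count >= 2L)
    if (length(elig)) {
      par_idx <- sample(elig, n_err, replace = TRUE, prob = count[elig])
      tab <- table(par_idx)
      idx <- as.integer(names(tab))
      n_child <- pmin(as.integer(tab), count[idx] - 1L)
      sel <- n_child > 0L
      idx <- idx[sel]
      n_child <- n_child[sel]
      if (length(idx)) {
        rep_idx <- rep.int(idx, n_child)
        child_nt <- mutate_one_base(cdr3_nt[rep_idx])
        child_aa <- cdr3_aa[rep_idx]
        inframe <- nchar(child_nt) %% 3L == 0L
        child_aa[inframe] <- translate_cdr3(child_nt[inframe])
        count[idx] <- count[idx] - n_child
        for (nm in c("v_gene", "j_gene", "d_gene", "v_end", "d_start",
                     "d_end", "j_start"))
          assign(nm, c(get(nm), get(nm)[rep_idx]))
        functional <- c(functional, derive_functional(child_nt, child_aa))
        cdr3_nt <- c(cdr3_nt, child_nt)
        cdr3_aa <- c(cdr3_aa, child_aa)
        count <- c(count, rep.int(1L, length(rep_idx)))
      }
    }
  }
  cl <- structure(list(count = count, freq = numeric(length(count)),
                       cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
                       v_gene = v_gene, d_gene = d_gene, j_gene = j_gene,
                       v_end = v_end, d_start = d_start, d_end = d_end,
                       j_start = j_start, functional = functional),
                  class = "data.frame",
                  row.names = seq_along(count))
  offt <- round(depth * rbeta(1, config$offtarget_shape[1],
                              config$offtarget_shape[2]))
  s <- rep_sample(sprintf("%s_%s_%s", subject$subject_id, tissue, chain),
                  subject$subject_id, tissue, chain, cl,
                  off_target_reads = offt, validate = FALSE)
  s$truth_keys <- truth_keys
  s
}

#' Inject public clonotypes into samples
#'
#' Places each public-pool clonotype into the designated samples at its
#' base frequency, using one fixed ("germline-like") codon realisation so
#' the clonotype is shared at the nucleotide level too.
#'
#' @param samples Named list of [rep_sample()] objects.
#' @param pool Public pool data frame (`v_gene`, `j_gene`, `cdr3_aa`,
#'   `base_freq`).
#' @param design Data frame mapping `pool_row` to `sample_id`.
#' @return The samples with injections applied.
#' @export
inject_public_clonotypes <- function(samples, pool, design) {
  if (nrow(pool) == 0L || nrow(design) == 0L) return(samples)
  by_sample <- split(design$pool_row, design$sample_id)
  for (sid in names(by_sample)) {
    rows <- by_sample[[sid]]
    if (sum(pool$base_freq[rows]) > 1)
      stop("public-pool frequency overflow in sample ", sid)
    s <- samples[[sid]]
    if (is.null(s)) next
    p <- pool[rows, , drop = FALSE]
    nt <- reverse_translate(p$cdr3_aa, canonical = TRUE)
    L <- nchar(nt)
    add <- data.frame(v_gene = p$v_gene, j_gene = p$j_gene,
                      cdr3_aa = p$cdr3_aa, cdr3_nt = nt,
                      d_gene = ifelse(substr(p$v_gene, 1, 4) == "TRDV",
                                      "TRDD3", NA_character_),
                      v_end = pmax(3L, as.integer(round(L * 0.4))),
                      d_start = -1L, d_end = -1L,
                      j_start = as.integer(round(L * 0.6)),
                      functional = TRUE,
                      count = pmax(1L, as.integer(round(
                        p$base_freq * s$total_reads))),
                      stringsAsFactors = FALSE)
    tk <- s$truth_keys
    s <- rep_sample(s$sample_id, s$subject_id, s$tissue, s$chain,
                    rbind(s$clonotypes[, setdiff(.CLONOTYPE_COLS, "freq")],
                          add[, setdiff(.CLONOTYPE_COLS, "freq")]),
                    off_target_reads = s$off_target_reads)
    s$truth_keys <- unique(c(tk, paste(add$v_gene, add$cdr3_nt,
                                       add$j_gene, sep = "|")))
    samples[[sid]] <- s
  }
  samples
}

#' Generate a synthetic cohort
#'
#' Draws subjects with clinical covariates, sets each patient's expected
#' blood richness to
#' `exp(log(richness_base) + beta_pasi * z(PASI) + beta_age * z(age))`
#' (controls receive the base richness; both get lognormal subject noise),
#' simulates every requested library, and injects the public clonotype
#' pool into randomly chosen subjects. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return List of class `gdr_simulation`: `cohort` (a `rep_cohort`),
#'   `truth` (per-library target and realised richness), `public_design`
#'   (which pool clonotype went into which sample) and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  subjects <- draw_subjects(config)
  pv <- subjects$group == "PV"
  log_rich <- rep(log(config$richness_base), nrow(subjects))
  if (any(pv)) {
    log_rich[pv] <- log_rich[pv] +
      config$beta_pasi * zscore(subjects$pasi[pv]) +
      config$beta_age * zscore(subjects$age[pv])
  }
  log_rich <- log_rich + rnorm(nrow(subjects), 0, config$sigma_log_richness)
  richness <- exp(log_rich)
  has_skin <- c(seq_len(config$n_pv) <= config$n_skin_pv,
                seq_len(config$n_hc) <= config$n_skin_hc)
  samples <- list()
  truth <- list()
  for (i in seq_len(nrow(subjects))) {
    for (ti in config$tissues) {
      if (ti == "skin" && !has_skin[i]) next
      for (ch in config$chains) {
        tr <- richness[i] * if (ti == "skin") config$richness_skin_factor
                            else 1
        s <- sample_repertoire(subjects[i, ], ti, ch, config, tr)
        samples[[s$sample_id]] <- s
        truth[[s$sample_id]] <- data.frame(
          sample_id = s$sample_id, subject_id = subjects$subject_id[i],
          tissue = ti, chain = ch, target_richness = tr,
          realized_richness = nrow(s$clonotypes),
          stringsAsFactors = FALSE)
      }
    }
  }
  pool <- config$public_pool
  design <- NULL
  if (!is.null(pool) && nrow(pool)) {
    chain_of <- ifelse(substr(pool$v_gene, 1, 4) == "TRGV", "TRG", "TRD")
    des <- list()
    for (r in seq_len(nrow(pool))) {
      if (!chain_of[r] %in% config$chains) next
      carriers <- subjects$subject_id[runif(nrow(subjects)) <
                                        config$share_prob]
      for (sid in carriers) {
        bl <- sprintf("%s_blood_%s", sid, chain_of[r])
        if (bl %in% names(samples))
          des[[length(des) + 1L]] <- data.frame(pool_row = r,
                                                sample_id = bl)
        sk <- sprintf("%s_skin_%s", sid, chain_of[r])
        if (sk %in% names(samples) && runif(1) < config$skin_share_prob)
          des[[length(des) + 1L]] <- data.frame(pool_row = r,
                                                sample_id = sk)
      }
    }
    if (length(des)) {
      design <- do.call(rbind, des)
      samples <- inject_public_clonotypes(samples, pool, design)
    }
  }
  structure(list(cohort = attach_metadata(samples, subjects),
                 truth = do.call(rbind, truth),
                 public_design = design, config = config),
            class = "gdr_simulation")
}
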