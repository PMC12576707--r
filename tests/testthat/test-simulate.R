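test_that("identical configurations and seeds give identical cohorts", {
  a <- generate_cohort(small_sim(17))
  b <- generate_cohort(small_sim(17))
  expect_identical(a$cohort$subjects, b$cohort$subjects)
  expect_identical(names(a$cohort$samples), names(b$cohort$samples))
  for (id in names(a$cohort$samples))
    expect_identical(a$cohort$samples[[id]]$clonotypes,
                     b$cohort$samples[[id]]$clonotypes)
  expect_false(identical(
    a$cohort$samples[[1]]$clonotypes,
    generate_cohort(small_sim(18))$cohort$samples[[1]]$clonotypes))
})

test_that("simulated CDR3s are anchored, translatable and coordinate-sane", {
  set.seed(41)
  for (chain in c("TRG", "TRD")) {
    cd <- sample_cdr3("X", "Y", sample(9:20, 200, replace = TRUE), chain)
    expect_true(all(substr(cd$cdr3_aa, 1, 1) == "C"))
    expect_true(all(substring(cd$cdr3_aa, nchar(cd$cdr3_aa)) == "F"))
    expect_identical(translate_cdr3(cd$cdr3_nt), cd$cdr3_aa)
    L <- nchar(cd$cdr3_nt)
    if (chain == "TRD") {
      expect_true(all(cd$v_end <= cd$d_start))
      expect_true(all(cd$d_start <= cd$d_end))
      expect_true(all(cd$d_end <= cd$j_start))
    } else {
      expect_true(all(cd$v_end <= cd$j_start))
    }
    expect_true(all(cd$j_start <= L))
  }
})

test_that("blood repertoires show canonical dominance and length profile", {
  sim <- generate_cohort(sim_config(n_pv = 5, n_hc = 5, n_skin_pv = 0,
                                    n_skin_hc = 0, tissues = "blood",
                                    seed = 42))
  trg <- gdrepertoire:::filter_samples(sim$cohort$samples, "blood", "TRG")
  canon <- vapply(trg, function(s)
    sum(segment_usage(s, "VJ")[["TRGV9-TRGJP"]]), numeric(1))
  expect_gt(mean(canon), 0.5)
  mass_13_17 <- vapply(trg, function(s) {
    sp <- spectratype(s, "aa")
    sum(sp[names(sp) %in% 13:17])
  }, numeric(1))
  expect_gte(mean(mass_13_17), 0.6)
  trd <- gdrepertoire:::filter_samples(sim$cohort$samples, "blood", "TRD")
  canon_d <- vapply(trd, function(s)
    sum(segment_usage(s, "VJ")[["TRDV2-TRDJ1"]]), numeric(1))
  expect_gt(mean(canon_d), 0.4)
})

test_that("TRDV1 CDR3 lengths are bimodal in the generated repertoires", {
  sim <- generate_cohort(sim_config(n_pv = 5, n_hc = 5, n_skin_pv = 0,
                                    n_skin_hc = 0, tissues = "blood",
                                    chains = "TRD", seed = 43))
  pooled <- numeric(0)
  for (s in sim$cohort$samples) {
    cl <- s$clonotypes
    pooled <- c(pooled, nchar(cl$cdr3_aa[cl$v_gene == "TRDV1" &
                                           cl$functional]))
  }
  lo <- mean(pooled <= 14)
  hi <- mean(pooled >= 16)
  expect_gt(lo, 0.25)
  expect_gt(hi, 0.25)
  expect_lt(mean(pooled == 15), 0.2)  # antimode between the two modes
})

test_that("convergence ratio rises with the synonymous-variant rate", {
  means <- vapply(c(0.05, 0.15, 0.3), function(rate) {
    sim <- generate_cohort(sim_config(n_pv = 4, n_hc = 0, n_skin_pv = 0,
                                      n_skin_hc = 0, tissues = "blood",
                                      chains = "TRG",
                                      convergence_rate = rate,
                                      error_rate = 0, seed = 44))
    mean(vapply(sim$cohort$samples, convergence_ratio, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("error merging recovers the true clonotype identities", {
  for (seed in 1:3) {
    sim <- generate_cohort(small_sim(seed))
    for (s in sim$cohort$samples[c(1, 3, 5)]) {
      m <- merge_error_clonotypes(s)
      obs <- paste(m$clonotypes$v_gene, m$clonotypes$cdr3_nt,
                   m$clonotypes$j_gene, sep = "|")
      expect_gte(mean(s$truth_keys %in% obs), 0.95)
    }
  }
})

test_that("public-pool injection respects design and frequency bounds", {
  cfg <- small_sim(45, public_pool = default_public_pool()[0, ])
  sim <- generate_cohort(cfg)
  pool <- data.frame(v_gene = "TRGV9", j_gene = "TRGJP",
                     cdr3_aa = "CALWEVQELGKKIKVF", base_freq = 0.02,
                     stringsAsFactors = FALSE)
  out <- inject_public_clonotypes(sim$cohort$samples, pool,
                                  data.frame(pool_row = 1L,
                                             sample_id = "PV01_blood_TRG"))
  s <- out[["PV01_blood_TRG"]]
  k <- build_key(s, "aa")
  expect_true("TRGV9|TRGJP|CALWEVQELGKKIKVF" %in% k)
  i <- which(k == "TRGV9|TRGJP|CALWEVQELGKKIKVF")
  expect_lt(abs(s$clonotypes$freq[i] - 0.02), 0.005)
  # empty pool leaves samples untouched
  expect_identical(inject_public_clonotypes(sim$cohort$samples, pool[0, ],
                                            data.frame()),
                   sim$cohort$samples)
  # frequency overflow rejected
  big <- pool
  big$base_freq <- 1.2
  expect_error(inject_public_clonotypes(sim$cohort$samples, big,
                                        data.frame(pool_row = 1L,
                                                   sample_id =
                                                     "PV01_blood_TRG")),
               "overflow")
})

test_that("richness covariate effects carry the configured sign", {
  cfg <- sim_config(n_pv = 25, n_hc = 0, n_skin_pv = 0, n_skin_hc = 0,
                    tissues = "blood", chains = "TRG", beta_pasi = -0.8,
                    beta_age = 0, sigma_log_richness = 0.1, seed = 46)
  sim <- generate_cohort(cfg)
  tr <- sim$truth
  sub <- sim$cohort$subjects
  r <- spearman_test(sub$pasi[match(tr$subject_id, sub$subject_id)],
                     tr$realized_richness)
  expect_lt(r$estimate, 0)
  expect_lt(r$p_value, 0.05)
})
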