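make_cohort <- function(samples) {
  sids <- unique(vapply(samples, `[[`, character(1), "subject_id"))
  subjects <- data.frame(subject_id = sids,
                         group = rep(c("PV", "HC"),
                                     length.out = length(sids)),
                         age = seq(30, by = 2,
                                   length.out = length(sids)),
                         sex = "M", pasi = NA_real_,
                         duration_years = NA_real_, cmv_igg = NA_real_,
                         cmv_status = "unknown", stringsAsFactors = FALSE)
  subjects$pasi[subjects$group == "PV"] <- 10
  attach_metadata(samples, subjects)
}

test_that("clonotype keys are deterministic triples on either basis", {
  s <- toy_sample(c(2, 1), aa = c("CALWEVQELGKKIKVF", "CALWEVQELGKKIKVF"),
                  nt = c("TGTGCACTTTGGGAAGTTCAAGAACTTGGCAAGAAAATAAAAGTTTTT",
                         "TGCGCACTTTGGGAAGTTCAAGAACTTGGCAAGAAAATAAAAGTTTTT"))
  k_aa <- build_key(s, "aa")
  k_nt <- build_key(s, "nt")
  expect_equal(k_aa[1], "TRGV9|TRGJP|CALWEVQELGKKIKVF")
  expect_equal(k_aa[1], k_aa[2])   # synonymous variants collapse
  expect_false(k_nt[1] == k_nt[2]) # but stay distinct at nt level
})

test_that("publicity requires presence in two distinct subjects", {
  s1 <- toy_sample(c(5, 5), aa = c("CAAF", "CDDF"),
                   nt = c("TGTGCTGCTTTT", "TGTGATGATTTT"),
                   sample_id = "A", subject_id = "P1")
  s2 <- toy_sample(c(5, 5), aa = c("CAAF", "CEEF"),
                   nt = c("TGTGCTGCTTTT", "TGTGAGGAGTTT"),
                   sample_id = "B", subject_id = "P2")
  s3 <- toy_sample(5, aa = "CGGF", nt = "TGTGGTGGTTTT",
                   sample_id = "C", subject_id = "P3")
  sc <- sharing_counts(make_cohort(list(s1, s2, s3)), "aa")
  expect_equal(sum(sc$table$public), 1L)
  expect_equal(sc$table$key[sc$table$public], "TRGV9|TRGJP|CAAF")
  expect_equal(sc$public_fraction, 0.25)  # 1 public of 4 distinct keys

  all_same <- lapply(1:3, function(i)
    toy_sample(c(1, 1, 1, 1, 1),
               aa = c("CAF", "CDF", "CEF", "CGF", "CHF"),
               nt = c("TGTGCTTTT", "TGTGATTTT", "TGTGAGTTT",
                      "TGTGGTTTT", "TGTCATTTT"),
               sample_id = paste0("S", i), subject_id = paste0("P", i)))
  expect_equal(sharing_counts(make_cohort(all_same), "aa")$public_fraction,
               1)
  expect_warning(sharing_counts(make_cohort(list(s1)), "aa"),
                 "fewer than 2 subjects")
})

test_that("Jaccard matrix matches set arithmetic and is symmetric", {
  a <- toy_sample(c(1, 1, 1), aa = c("CAF", "CDF", "CEF"),
                  nt = c("TGTGCTTTT", "TGTGATTTT", "TGTGAGTTT"),
                  sample_id = "A")
  b <- toy_sample(c(9, 9, 9), aa = c("CDF", "CEF", "CGF"),
                  nt = c("TGTGATTTT", "TGTGAGTTT", "TGTGGTTTT"),
                  sample_id = "B", subject_id = "P2")
  d <- toy_sample(1, aa = "CHF", nt = "TGTCATTTT", sample_id = "D",
                  subject_id = "P3")
  m <- jaccard_matrix(list(a, b, d), "aa")
  expect_equal(m["A", "B"], 0.5)
  expect_equal(m["A", "D"], 0)
  expect_equal(diag(m), c(A = 1, B = 1, D = 1))
  expect_equal(m, t(m))
  # frequency-blind: scaling counts changes nothing
  b2 <- toy_sample(c(90, 9, 900), aa = c("CDF", "CEF", "CGF"),
                   nt = c("TGTGATTTT", "TGTGAGTTT", "TGTGGTTTT"),
                   sample_id = "B", subject_id = "P2")
  expect_equal(jaccard_matrix(list(a, b2), "aa")["A", "B"], 0.5)
})

test_that("Jaccard equals brute-force enumeration on random cohorts", {
  set.seed(21)
  for (i in 1:20) {
    ss <- lapply(1:4, function(k)
      random_sample(12L, sample_id = paste0("S", k),
                    subject_id = paste0("P", k)))
    m <- jaccard_matrix(ss, "aa")
    for (x in 1:3) for (y in (x + 1):4)
      expect_equal(m[x, y],
                   oracle_jaccard(build_key(ss[[x]], "aa"),
                                  build_key(ss[[y]], "aa")),
                   tolerance = 1e-12)
  }
})

test_that("paired blood-skin overlap reports per-compartment frequencies", {
  blood <- toy_sample(c(5, 5), aa = c("CXAF", "CYYF"),
                      nt = c("TGTNNNGCTTTT", "TGTTATTATTTT"),
                      sample_id = "B", subject_id = "P1")
  blood$clonotypes$cdr3_nt <- c("TGTAAAGCTTTT", "TGTTATTATTTT")
  blood <- gdrepertoire:::set_clonotypes(blood, blood$clonotypes)
  skin <- toy_sample(10, aa = "CYYF", nt = "TGTTATTATTTT",
                     sample_id = "S", subject_id = "P1", tissue = "skin")
  po <- paired_overlap(blood, skin, "aa")
  expect_equal(nrow(po), 1L)
  expect_equal(po$blood_freq, 0.5)
  expect_equal(po$skin_freq, 1)
  expect_equal(po$mean_freq, 0.75)

  disjoint <- toy_sample(3, aa = "CZZF", nt = "TGTTCTTCTTTT",
                         sample_id = "S2", subject_id = "P1",
                         tissue = "skin")
  expect_equal(nrow(paired_overlap(blood, disjoint, "aa")), 0L)

  trd <- toy_sample(3, v = "TRDV2", j = "TRDJ1", chain = "TRD",
                    subject_id = "P1", tissue = "skin")
  expect_error(paired_overlap(blood, trd, "aa"), "chain mismatch")
  expect_equal(paired_overlap(
    toy_sample(c(2, 8), aa = c("CAF", "CDF"),
               nt = c("TGTGCTTTT", "TGTGATTTT"), subject_id = "P1"),
    toy_sample(c(4, 6), aa = c("CAF", "CEF"),
               nt = c("TGTGCTTTT", "TGTGAGTTT"), subject_id = "P1",
               tissue = "skin"), "aa")$mean_freq,
    (0.2 + 0.4) / 2)
})

test_that("aa-basis publicity is at least nt-basis publicity here", {
  sim <- generate_cohort(small_sim(3))
  for (ch in c("TRG", "TRD")) {
    aa <- suppressWarnings(sharing_counts(sim$cohort, "aa",
                                          tissue = "blood", chain = ch))
    nt <- suppressWarnings(sharing_counts(sim$cohort, "nt",
                                          tissue = "blood", chain = ch))
    expect_gte(aa$public_fraction, nt$public_fraction)
  }
})
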