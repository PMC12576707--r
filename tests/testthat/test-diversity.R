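test_that("within-segment renormalisation makes each segment sum to one", {
  s <- toy_sample(c(60, 20, 20), v = c("TRGV9", "TRGV9", "TRGV4"))
  subs <- normalize_within_segment(s)
  expect_setequal(names(subs), c("TRGV9", "TRGV4"))
  expect_equal(subs$TRGV9$freq, c(0.75, 0.25))
  expect_equal(subs$TRGV4$freq, 1)
  one <- toy_sample(7, v = "TRGV8")
  expect_equal(normalize_within_segment(one)$TRGV8$freq, 1)
})

test_that("abundance spectra tally the frequency of frequencies", {
  sp <- abundance_spectrum(c(1, 1, 1, 1, 2, 2, 5, 5, 5, 10))
  expect_equal(sp$f, c(`1` = 4L, `2` = 2L, `5` = 3L, `10` = 1L))
  expect_equal(sp$s_obs, 10L)
  expect_equal(sp$n_reads, 33L)
  expect_equal(abundance_spectrum(c(1, 1, 1))$f, c(`1` = 3L))
  expect_equal(abundance_spectrum(7)$f, c(`7` = 1L))
  expect_error(abundance_spectrum(c(1, 0)), ">= 1")
})

test_that("diversity indices match their closed forms on worked examples", {
  expect_equal(shannon_index(rep(0.1, 10)), log(10), tolerance = 1e-12)
  expect_equal(shannon_index(1), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.039721,
               tolerance = 1e-6)
  expect_equal(inverse_simpson(rep(0.1, 10)), 10, tolerance = 1e-12)
  expect_equal(inverse_simpson(c(0.9, 0.1)), 1 / 0.82, tolerance = 1e-12)
  expect_equal(inverse_simpson(1), 1)

  expect_equal(chao1(abundance_spectrum(c(1, 1, 1, 1, 2, 2, 5, 5, 5, 10))),
               14)
  expect_equal(chao1(abundance_spectrum(c(3, 4, 5))), 3)
  expect_equal(chao1(abundance_spectrum(c(1, 1, 1, 3, 4))), 8)

  expect_equal(efron_thisted(abundance_spectrum(
    c(1, 1, 1, 1, 2, 2, 3))), 7 + (4 - 2 + 1))
  expect_equal(efron_thisted(abundance_spectrum(c(2, 2, 3))), 3)
  expect_equal(efron_thisted(abundance_spectrum(c(1, 1))), 4)

  expect_equal(d50(rep(0.1, 10)), 0.5)
  expect_equal(d50(c(0.6, 0.3, 0.1)), 1 / 3)
  expect_equal(d50(1), 1)
})

test_that("shannon and inverse Simpson agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(5)
  for (i in 1:20) {
    counts <- sample(1:40, sample(2:20, 1), replace = TRUE)
    p <- counts / sum(counts)
    expect_equal(shannon_index(p), unname(vegan::diversity(counts)),
                 tolerance = 1e-10)
    expect_equal(inverse_simpson(p),
                 unname(vegan::diversity(counts, "invsimpson")),
                 tolerance = 1e-10)
  }
})

test_that("frequency compartments partition the repertoire", {
  p <- c(0.93, 0.04, 0.004, rep(0.0004, 65))
  cp <- compartment_profile(p)
  expect_equal(cp$bin, c("small", "medium", "large", "hyperexpanded"))
  expect_equal(cp$clonotype_fraction, c(65, 1, 1, 1) / 68)
  expect_equal(cp$space_fraction, c(0.026, 0.004, 0.04, 0.93),
               tolerance = 1e-9)

  single <- compartment_profile(1)
  expect_equal(single$space_fraction[single$bin == "hyperexpanded"], 1)
  # clone exactly at the 0.05% boundary is small (inclusive upper edge)
  b <- compartment_profile(c(0.0005, 0.9995))
  expect_equal(b$clonotype_fraction[b$bin == "small"], 0.5)
})

test_that("top-n cumulative frequencies respect stratification", {
  s <- toy_sample(c(5, 3, 2))
  expect_equal(top_n_cumulative(s, 10), 1)
  expect_equal(top_n_cumulative(s, 2), 0.8)
  st <- toy_sample(c(4, 1, 3, 2), v = c("TRGV9", "TRGV9", "TRGV4", "TRGV4"))
  expect_equal(top_n_cumulative(st, 1, stratify_by_segment = TRUE),
               c(TRGV4 = 0.3, TRGV9 = 0.4))
})

test_that("diversity invariants hold on random repertoires", {
  set.seed(99)
  for (i in 1:30) {
    counts <- sample(1:60, sample(2:20, 1), replace = TRUE)
    p <- counts / sum(counts)
    sp <- abundance_spectrum(counts)
    # Hill ordering and estimator lower bounds
    expect_lte(inverse_simpson(p), exp(shannon_index(p)) + 1e-9)
    expect_lte(exp(shannon_index(p)), sp$s_obs + 1e-9)
    expect_gte(chao1(sp), sp$s_obs)
    expect_gte(efron_thisted(sp), sp$s_obs)
    # D50 is scale-free
    expect_equal(d50(p), d50(7 * counts / sum(7 * counts)))
    # compartments partition
    cp <- compartment_profile(p)
    expect_equal(sum(cp$clonotype_fraction), 1, tolerance = 1e-9)
    expect_equal(sum(cp$space_fraction), 1, tolerance = 1e-9)
  }
})

test_that("per-segment diversity profiles cover each observed segment", {
  s <- toy_sample(c(30, 20, 10, 5), v = c("TRGV9", "TRGV9", "TRGV4",
                                          "TRGV8"))
  d <- diversity_profile(s, per_segment = TRUE)
  expect_setequal(d$stratum, c("all", "TRGV9", "TRGV4", "TRGV8"))
  expect_equal(d$s_obs[d$stratum == "all"], 4L)
  expect_equal(d$d50[d$stratum == "TRGV4"], 1)
})

test_that("rarefaction reduces reads to the target and richness monotonely", {
  set.seed(61)
  s <- toy_sample(sample(1:30, 15, replace = TRUE))
  d <- downsample_reads(s, 20)
  expect_equal(d$total_reads, 20L)
  expect_lte(nrow(d$clonotypes), nrow(s$clonotypes))
  expect_true(all(d$clonotypes$cdr3_nt %in% s$clonotypes$cdr3_nt))
  # no-op at or above the library depth
  expect_identical(downsample_reads(s, s$total_reads + 5), s)
  prof <- diversity_profile(s, downsample = 20)
  expect_lte(prof$s_obs, 20L)
  expect_gte(prof$s_obs, 1L)
})
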