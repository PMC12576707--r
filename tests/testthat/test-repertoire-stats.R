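test_that("segment usage sums clone mass or counts per segment", {
  s <- toy_sample(c(60, 20, 20), v = c("TRGV9", "TRGV9", "TRGV4"))
  expect_equal(segment_usage(s, "V", "reads"),
               c(TRGV9 = 0.8, TRGV4 = 0.2))
  expect_equal(segment_usage(s, "V", "clonotypes"),
               c(TRGV9 = 2 / 3, TRGV4 = 1 / 3))
  one <- toy_sample(10, v = "TRGV8")
  expect_equal(segment_usage(one, "V"), c(TRGV8 = 1))
})

test_that("pooled V-J pairing averages samples with equal weight", {
  a <- toy_sample(c(5, 5), v = "TRGV9", j = "TRGJP")
  b <- toy_sample(c(100, 100), v = "TRGV4", j = "TRGJ2", sample_id = "S2")
  pooled <- vj_pairing_matrix(list(a, b))
  expect_equal(pooled[order(names(pooled))],
               c("TRGV4-TRGJ2" = 0.5, "TRGV9-TRGJP" = 0.5))
  expect_equal(vj_pairing_matrix(list(a, a)),
               segment_usage(a, "VJ"))
  cc <- toy_sample(c(3, 1), v = c("TRGV9", "TRGV4"),
                   j = c("TRGJP", "TRGJ2"), sample_id = "S3")
  pooled3 <- vj_pairing_matrix(list(a, b, cc))
  expect_equal(pooled3[["TRGV9-TRGJP"]], (1 + 0 + 0.75) / 3)
  expect_equal(pooled3[["TRGV4-TRGJ2"]], (0 + 1 + 0.25) / 3)
  trd <- toy_sample(5, v = "TRDV2", j = "TRDJ1", chain = "TRD")
  expect_error(vj_pairing_matrix(list(a, trd)), "chain")
})

test_that("spectratypes histogram CDR3 lengths under both weightings", {
  s <- toy_sample(c(7, 3), aa = c("CALWEVQELGKKIKF", "CALWEVQELGKKF"))
  expect_equal(spectratype(s, "aa", "reads"),
               c(`13` = 0.3, `15` = 0.7))
  expect_equal(nchar("CALWEVQELGKKIKVF"), 16L)
  expect_equal(names(spectratype(toy_sample(5, aa = "CALWEVQELGKKIKVF"),
                                 "nt")), "48")
  eq <- toy_sample(c(4, 4), aa = c("CALWEVQELGKKIKF", "CALWEVQELGKKF"))
  expect_equal(spectratype(eq, "aa", "reads"),
               spectratype(eq, "aa", "clonotypes"))
})

test_that("mean CDR3 length is the weighted mean", {
  s <- toy_sample(c(5, 5), nt = c(strrep("TGA", 16), strrep("TGA", 17)),
                  aa = c(strrep("A", 48 / 3), strrep("A", 51 / 3)))
  expect_equal(mean_cdr3_length(s, "nt"), 49.5)
  s2 <- toy_sample(c(9, 1), nt = c(strrep("A", 45), strrep("A", 51)),
                   aa = c(strrep("G", 15), strrep("G", 17)))
  expect_equal(mean_cdr3_length(s2, "nt"), 45.6)
  expect_equal(mean_cdr3_length(toy_sample(3, aa = strrep("W", 17)), "aa"),
               17)
  expect_error(mean_cdr3_length(
    gdrepertoire:::set_clonotypes(s, s$clonotypes[0, ]), "aa"), "empty")
})

test_that("junctional inserts follow the clamped coordinate arithmetic", {
  cl <- data.frame(count = rep(1L, 4),
                   cdr3_nt = rep(strrep("A", 30), 4),
                   cdr3_aa = rep(strrep("K", 10), 4),
                   v_gene = "TRDV2",
                   d_gene = c("TRDD3", NA, NA, "TRDD3"),
                   j_gene = "TRDJ1",
                   v_end = c(10L, 10L, 12L, -1L),
                   d_start = c(13L, -1L, -1L, 10L),
                   d_end = c(20L, -1L, -1L, 20L),
                   j_start = c(24L, 10L, 10L, 24L),
                   stringsAsFactors = FALSE)
  cl$d_start[3] <- -1L  # V-J only, overlap case uses v_end > j_start
  cl$j_start[3] <- 10L
  cl$v_end[3] <- 12L
  ji <- junction_inserts(cl)
  expect_equal(ji$vd_insert[1], 3)
  expect_equal(ji$dj_insert[1], 4)
  expect_equal(ji$total_insert[1], 7)
  expect_equal(ji$total_insert[2], 0)     # abutting V-J
  expect_equal(ji$total_insert[3], 0)     # negative gap clamps to 0
  expect_true(is.na(ji$total_insert[4]))  # undefined v_end
})

test_that("convergence ratio counts nt variants per aa group", {
  set.seed(11)
  aa <- "CALWEVQELGKKIKVF"
  nts <- unique(replicate(20, gdrepertoire:::reverse_translate(aa)))[1:3]
  s <- toy_sample(c(5, 3, 2), aa = rep(aa, 3), nt = nts)
  s$clonotypes$cdr3_aa <- c(aa, aa, "CALWEVQELGKKIKYF")
  s <- gdrepertoire:::set_clonotypes(s, s$clonotypes)
  expect_equal(convergence_ratio(s), 1.5)

  inj <- toy_sample(c(1, 1), aa = c("CAF", "CDF"),
                    nt = c("TGTGCTTTC", "TGTGATTTC"))
  expect_equal(convergence_ratio(inj), 1)

  syn <- toy_sample(rep(1, 4), aa = rep(aa, 4),
                    nt = unique(replicate(50,
                      gdrepertoire:::reverse_translate(aa)))[1:4])
  expect_equal(convergence_ratio(syn), 4)
})

test_that("profiles normalise to one and empty inputs stay empty", {
  set.seed(7)
  for (i in 1:10) {
    s <- random_sample(15L)
    expect_equal(sum(segment_usage(s, "VJ")), 1, tolerance = 1e-9)
    expect_equal(sum(spectratype(s, "aa")), 1, tolerance = 1e-9)
    expect_gte(convergence_ratio(s), 1)
  }
  empty <- gdrepertoire:::set_clonotypes(toy_sample(3),
                                         toy_clonotypes(3)[0, ])
  expect_length(segment_usage(empty, "V"), 0L)
  expect_length(spectratype(empty, "aa"), 0L)
})
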