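# Diversity and clonality metrics: abundance spectra, richness estimators
# (Chao1, Efron-Thisted), Shannon / inverse Simpson, D50, frequency
# compartments and segment-stratified summaries.

#' Renormalise clonotype frequencies within each V segment
#'
#' Splits a repertoire by V segment and rescales frequencies so each
#' sub-repertoire sums to 1, making per-segment diversity independent of
#' the segment's overall share of the repertoire.
#'
#' @param sample A [rep_sample()].
#' @return Named list of clonotype data frames, one per observed V segment.
#' @export
normalize_within_segment <- function(sample) {
  cl <- sample$clonotypes
  if (nrow(cl) == 0L) return(list())
  lapply(split(cl, cl$v_gene), function(d) {
    d$freq <- d$count / sum(d$count)
    rownames(d) <- NULL
    d
  })
}

#' Frequency-of-frequencies spectrum
#'
#' Tallies how many clonotypes were observed exactly `k` times (`f_k`), the
#' input to the nonparametric richness estimators.
#'
#' @param counts Integer vector of clonotype read counts (all `>= 1`), or a
#'   [rep_sample()].
#' @return List of class `abundance_spectrum`: `f` (named vector, names are
#'   `k`), `s_obs`, `n_reads`.
#' @export
abundance_spectrum <- function(counts) {
  if (inherits(counts, "rep_sample")) counts <- counts$clonotypes$count
  counts <- as.integer(counts)
  if (length(counts) && any(counts < 1L)) stop("counts must be >= 1")
  tab <- table(counts)
  structure(list(f = setNames(as.integer(tab), names(tab)),
                 s_obs = length(counts), n_reads = sum(counts)),
            class = "abundance_spectrum")
}

check_freqs <- function(freqs) {
  if (length(freqs) == 0L) stop("empty frequency vector")
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  freqs
}

#' Shannon-Wiener diversity index
#'
#' `-sum(p * log(p))` with `0 * log(0)` taken as 0. Natural log (nats) by
#' default; the base is configurable.
#'
#' @param freqs Clonotype frequencies summing to 1.
#' @param base Logarithm base (default `exp(1)`).
#' @return Non-negative scalar.
#' @export
shannon_index <- function(freqs, base = exp(1)) {
  p <- check_freqs(freqs)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Inverse Simpson index
#'
#' `1 / sum(p^2)`; ranges from 1 (monoclonal) to the clonotype count
#' (uniform).
#'
#' @inheritParams shannon_index
#' @return Scalar `>= 1`.
#' @export
inverse_simpson <- function(freqs) {
  p <- check_freqs(freqs)
  1 / sum(p^2)
}

#' Chao1 richness estimator
#'
#' `S_obs + f1^2 / (2 f2)` when doubletons exist, and the bias-corrected
#' form `S_obs + f1 (f1 - 1) / 2` when `f2 = 0`.
#'
#' @param spectrum An [abundance_spectrum()] (or counts coercible to one).
#' @return Estimated richness `>= S_obs`.
#' @export
chao1 <- function(spectrum) {
  if (!inherits(spectrum, "abundance_spectrum"))
    spectrum <- abundance_spectrum(spectrum)
  f <- spectrum$f
  f1 <- if ("1" %in% names(f)) as.numeric(f[["1"]]) else 0
  f2 <- if ("2" %in% names(f)) as.numeric(f[["2"]]) else 0
  if (f2 > 0) spectrum$s_obs + f1^2 / (2 * f2)
  else spectrum$s_obs + f1 * (f1 - 1) / 2
}

#' Efron-Thisted unseen-species estimator
#'
#' Adds to the observed richness the truncated alternating series
#' `sum_k (-1)^(k+1) f_k`, `k = 1 .. min(max observed count, max_terms)`.
#' When the series does not decay (`|f_K| > |f_1|`) the Euler
#' transformation of the alternating series is applied for numerical
#' stability. The correction is floored at 0 so the estimate never falls
#' below `S_obs`.
#'
#' @inheritParams chao1
#' @param max_terms Truncation order of the series (default 20).
#' @return Estimated richness `>= S_obs`.
#' @export
efron_thisted <- function(spectrum, max_terms = 20L) {
  if (!inherits(spectrum, "abundance_spectrum"))
    spectrum <- abundance_spectrum(spectrum)
  stopifnot(max_terms >= 1L)
  if (spectrum$s_obs == 0L) return(0)
  kmax <- max(as.integer(names(spectrum$f)))
  K <- min(kmax, as.integer(max_terms))
  fk <- numeric(K)
  present <- as.integer(names(spectrum$f))
  sel <- present <= K
  fk[present[sel]] <- as.numeric(spectrum$f[sel])
  if (K > 1L && abs(fk[K]) > abs(fk[1L])) {
    # Euler transform of sum_{j>=0} (-1)^j a_j with a_j = f_{j+1}
    a <- fk
    delta <- 0
    for (n in seq_len(K) - 1L) {
      delta <- delta + (-1)^n * a[1L] / 2^(n + 1L)
      a <- diff(a)
    }
  } else {
    delta <- sum((-1)^(seq_len(K) + 1L) * fk)
  }
  spectrum$s_obs + max(0, delta)
}

#' D50 clonality index
#'
#' Fraction of clonotypes (ranked by decreasing abundance, ties kept in
#' input order) needed to accumulate 50% of the reads. Small values
#' indicate oligoclonal repertoires; a uniform repertoire of `S` clones
#' gives `ceiling(S/2) / S`.
#'
#' @param freqs Clonotype frequencies summing to 1.
#' @return Fraction in `(0, 1]`.
#' @export
d50 <- function(freqs) {
  p <- check_freqs(freqs)
  p <- sort(p, decreasing = TRUE, method = "radix")
  k <- which(cumsum(p) >= 0.5 - 1e-12)[1L]
  k / length(p)
}

.COMPARTMENT_BINS <- c("small", "medium", "large", "hyperexpanded")

# Frequency partition of (0, 1]: small (0, 0.05%], medium (0.05%, 0.5%],
# large (0.5%, 5%], hyperexpanded (5%, 100%].
compartment_of <- function(freqs) {
  cut(freqs, breaks = c(0, 0.0005, 0.005, 0.05, 1),
      labels = .COMPARTMENT_BINS, include.lowest = FALSE, right = TRUE)
}

#' Frequency-compartment profile
#'
#' Assigns every clonotype to one of four frequency bins --
#' small (at most 0.05%), medium (0.05-0.5%], large (0.5-5%] and
#' hyperexpanded (above 5%) -- and reports both the fraction of clonotypes
#' and the fraction of repertoire space (summed read frequency) per bin.
#'
#' @param x A [rep_sample()], a clonotype data frame, or a frequency vector.
#' @return Data frame with `bin`, `clonotype_fraction`, `space_fraction`.
#' @export
compartment_profile <- function(x) {
  freqs <- if (inherits(x, "rep_sample")) x$clonotypes$freq
           else if (is.data.frame(x)) x$freq else x
  p <- check_freqs(freqs)
  bin <- compartment_of(p)
  data.frame(bin = .COMPARTMENT_BINS,
             clonotype_fraction = as.numeric(table(bin) / length(p)),
             space_fraction = as.numeric(vapply(
               split(p, bin), sum, numeric(1))),
             stringsAsFactors = FALSE)
}

#' Cumulative frequency of the top n clonotypes
#'
#' Unstratified: the summed frequency of the `n` most abundant clonotypes
#' (the whole repertoire when fewer exist). Stratified: per V segment, the
#' summed whole-sample frequency of that segment's own top `n` clonotypes,
#' independent of their overall ranking.
#'
#' @param sample A [rep_sample()].
#' @param n Number of top clonotypes.
#' @param stratify_by_segment Stratify by V segment?
#' @return A fraction, or a named vector of fractions per segment.
#' @export
top_n_cumulative <- function(sample, n = 10L, stratify_by_segment = FALSE) {
  stopifnot(n >= 1L)
  cl <- sample$clonotypes
  top_sum <- function(p) sum(sort(p, decreasing = TRUE)[seq_len(min(n, length(p)))])
  if (!stratify_by_segment) return(top_sum(cl$freq))
  vapply(split(cl$freq, cl$v_gene), top_sum, numeric(1))
}

#' Downsample clonotype counts to a fixed read depth
#'
#' Rarefaction without replacement: draws `n` reads from the observed
#' reads and retabulates clonotype counts (clonotypes falling to zero are
#' dropped). Uses the session RNG; seed it for reproducibility.
#'
#' @param sample A [rep_sample()].
#' @param n Target read count (no-op when `n >= total_reads`).
#' @return The downsampled sample.
#' @export
downsample_reads <- function(sample, n) {
  stopifnot(n >= 1)
  cl <- sample$clonotypes
  if (n >= sample$total_reads) return(sample)
  reads <- rep.int(seq_len(nrow(cl)), cl$count)
  cnt <- tabulate(sample(reads, n), nbins = nrow(cl))
  cl <- cl[cnt > 0L, , drop = FALSE]
  cl$count <- cnt[cnt > 0L]
  set_clonotypes(sample, cl)
}

#' Full diversity profile of a sample
#'
#' Computes observed richness, D50, Chao1, Efron-Thisted, Shannon and
#' inverse Simpson for the whole repertoire and, optionally, for each
#' within-segment renormalised sub-repertoire.
#'
#' @param sample A [rep_sample()].
#' @param per_segment Also compute per-V-segment rows?
#' @param base Logarithm base for Shannon.
#' @param downsample Optional read depth to rarefy to before computing
#'   (off by default; diversity is otherwise computed on the full
#'   library, so cross-tissue comparisons inherit depth differences).
#' @return Data frame with one row per stratum.
#' @export
diversity_profile <- function(sample, per_segment = FALSE, base = exp(1),
                              downsample = NULL) {
  if (!is.null(downsample)) sample <- downsample_reads(sample, downsample)
  one <- function(stratum, cl) {
    sp <- abundance_spectrum(cl$count)
    data.frame(sample_id = sample$sample_id, stratum = stratum,
               s_obs = sp$s_obs, d50 = d50(cl$freq),
               chao1 = chao1(sp), efron_thisted = efron_thisted(sp),
               shannon = shannon_index(cl$freq, base = base),
               inv_simpson = inverse_simpson(cl$freq),
               stringsAsFactors = FALSE)
  }
  out <- list(one("all", sample$clonotypes))
  if (per_segment) {
    subs <- normalize_within_segment(sample)
    out <- c(out, lapply(names(subs), function(v) one(v, subs[[v]])))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
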