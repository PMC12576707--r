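# Independent brute-force oracles: direct loops over definitions, kept
# deliberately naive and separate from the package implementations.

oracle_shannon <- function(p) {
  s <- 0
  for (x in p) if (x > 0) s <- s - x * log(x)
  s
}

oracle_inv_simpson <- function(p) {
  s <- 0
  for (x in p) s <- s + x * x
  1 / s
}

oracle_chao1 <- function(counts) {
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  S <- length(counts)
  if (f2 > 0) S + f1^2 / (2 * f2) else S + f1 * (f1 - 1) / 2
}

# Efron-Thisted via explicit binomial-weight Euler transform (independent
# of the iterated-difference implementation)
oracle_efron_thisted <- function(counts, max_terms = 20L) {
  K <- min(max(counts), max_terms)
  fk <- vapply(seq_len(K), function(k) sum(counts == k), numeric(1))
  if (K > 1 && abs(fk[K]) > abs(fk[1])) {
    delta <- 0
    for (n in 0:(K - 1)) {
      dn <- 0
      for (i in 0:n)
        dn <- dn + (-1)^(n - i) * choose(n, i) * fk[i + 1]
      delta <- delta + (-1)^n * dn / 2^(n + 1)
    }
  } else {
    delta <- 0
    for (k in seq_len(K)) delta <- delta + (-1)^(k + 1) * fk[k]
  }
  length(counts) + max(0, delta)
}

oracle_d50 <- function(p) {
  p <- sort(p, decreasing = TRUE)
  acc <- 0
  for (k in seq_along(p)) {
    acc <- acc + p[k]
    if (acc >= 0.5 - 1e-12) return(k / length(p))
  }
  1
}

oracle_compartments <- function(p) {
  bins <- c(small = 0, medium = 0, large = 0, hyperexpanded = 0)
  space <- bins
  for (x in p) {
    b <- if (x <= 0.0005) "small" else if (x <= 0.005) "medium"
         else if (x <= 0.05) "large" else "hyperexpanded"
    bins[b] <- bins[b] + 1
    space[b] <- space[b] + x
  }
  list(clonotype_fraction = bins / length(p), space_fraction = space)
}

oracle_convergence <- function(cl) {
  nt_keys <- character(0)
  aa_keys <- character(0)
  for (i in seq_len(nrow(cl))) {
    nt_keys <- union(nt_keys, paste(cl$v_gene[i], cl$cdr3_nt[i],
                                    cl$j_gene[i]))
    aa_keys <- union(aa_keys, paste(cl$v_gene[i], cl$cdr3_aa[i],
                                    cl$j_gene[i]))
  }
  length(nt_keys) / length(aa_keys)
}

oracle_jaccard <- function(keys_a, keys_b) {
  keys_a <- unique(keys_a)
  keys_b <- unique(keys_b)
  inter <- 0
  for (k in keys_a) if (k %in% keys_b) inter <- inter + 1
  u <- length(keys_a) + length(keys_b) - inter
  if (u == 0) 0 else inter / u
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], all_perms(v[-i])))
  out
}

oracle_spearman_p <- function(x, y) {
  r_obs <- cor(rank(x), rank(y))
  P <- all_perms(seq_along(y))
  ry <- rank(y)
  rhos <- apply(P, 1L, function(p) cor(rank(x), ry[p]))
  mean(abs(rhos) >= abs(r_obs) - 1e-12)
}

oracle_mw_p <- function(a, b) {
  nA <- length(a)
  v <- c(a, b)
  r <- rank(v)
  cmb <- combn(length(v), nA)
  Us <- apply(cmb, 2L, function(idx) sum(r[idx]) - nA * (nA + 1) / 2)
  u <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  min(1, 2 * min(mean(Us <= u), mean(Us >= u)))
}

oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_
  n <- b + d
  k <- a + b
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
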