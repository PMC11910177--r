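# Independent brute-force oracles used to validate the encoder, plus small
# fixture builders. Oracles are deliberately written as plain loops over
# the definitions, sharing no code with the package implementation.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

moment_pairs <- cbind(a = c(0, 0, 1, 1, 0, 2, 1, 2, 0, 3),
                      b = c(0, 1, 0, 1, 2, 0, 2, 1, 3, 0))

brute_raw_moments <- function(m) {
  K <- nrow(m)
  out <- numeric(10)
  for (i in 1:10) {
    a <- moment_pairs[i, "a"]; b <- moment_pairs[i, "b"]
    s <- 0
    for (p in 1:K) for (q in 1:K) s <- s + p^a * q^b * m[p, q]
    out[i] <- s
  }
  out
}

brute_central_moments <- function(m) {
  K <- nrow(m)
  d00 <- sum(m)
  xb <- if (d00 == 0) 0 else sum(row(m) * m) / d00
  yb <- if (d00 == 0) 0 else sum(col(m) * m) / d00
  out <- numeric(10)
  for (i in 1:10) {
    a <- moment_pairs[i, "a"]; b <- moment_pairs[i, "b"]
    s <- 0
    for (g in 1:K) for (h in 1:K) {
      s <- s + (g - xb)^a * (h - yb)^b * m[g, h]
    }
    out[i] <- s
  }
  out
}

# Orthonormal polynomial basis on x = 0..K-1 by classical Gram-Schmidt on
# the monomials, with positive leading coefficients (matching the
# convention of the recurrence construction).
gs_hahn_basis <- function(K, max_order = 3) {
  x <- 0:(K - 1)
  V <- sapply(0:max_order, function(n) x^n)
  Q <- matrix(0, K, max_order + 1)
  for (j in seq_len(max_order + 1)) {
    v <- V[, j]
    if (j > 1) for (i in 1:(j - 1)) {
      v <- v - sum(v * Q[, i]) * Q[, i]
    }
    Q[, j] <- v / sqrt(sum(v^2))
  }
  Q
}

brute_hahn_moments <- function(m) {
  K <- nrow(m)
  P <- gs_hahn_basis(K, 3)
  out <- numeric(10)
  for (i in 1:10) {
    p <- moment_pairs[i, "a"]; q <- moment_pairs[i, "b"]
    s <- 0
    for (gi in 1:K) for (gj in 1:K) {
      s <- s + P[gi, p + 1] * P[gj, q + 1] * m[gi, gj]
    }
    out[i] <- s
  }
  out
}

brute_kmers <- function(seq, k) {
  n <- nchar(seq)
  vapply(1:(n - k + 1), function(i) substr(seq, i, i + k - 1), "")
}

all_kmers_oracle <- function(k) {
  sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1,
             function(r) paste(rev(r), collapse = "")))
}

brute_prim <- function(seq, k) {
  toks <- brute_kmers(seq, k)
  types <- all_kmers_oracle(k)
  d <- length(types)
  M <- matrix(0, d, d, dimnames = list(types, types))
  for (i in types) {
    fp <- which(toks == i)[1]
    if (is.na(fp)) next
    for (j in types) {
      occ <- which(toks == j)
      if (length(occ) == 0) next
      s <- 0
      for (p in occ) s <- s + (p - fp)
      M[i, j] <- s
    }
  }
  M
}

brute_freq <- function(seq, k) {
  toks <- brute_kmers(seq, k)
  vapply(all_kmers_oracle(k), function(t) sum(toks == t), 0)
}

brute_aapiv <- function(seq, k) {
  toks <- brute_kmers(seq, k)
  vapply(all_kmers_oracle(k), function(t) sum(which(toks == t)), 0)
}

str_reverse <- function(s) {
  paste(rev(strsplit(s, "")[[1]]), collapse = "")
}

# Independent pairwise identity estimate (shared overlapping 5-mers over
# the 5-mer count of the shorter sequence), used to cross-check clustering.
brute_identity <- function(a, b, k = 5) {
  ta <- table(brute_kmers(a, k))
  tb <- table(brute_kmers(b, k))
  shared <- intersect(names(ta), names(tb))
  if (length(shared) == 0) return(0)
  sum(pmin(ta[shared], tb[shared])) / min(sum(ta), sum(tb))
}

# Linearly separable labeled feature table: gaussian noise with a class
# shift on a block of coordinates. Large shift => memorisable and
# generalisable by any of the tree ensembles.
make_sep_table <- function(n_per_class = 20, shift = 6, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  m <- matrix(rnorm(n * 522), n, 522)
  labels <- rep(c(1L, 0L), each = n_per_class)
  m[labels == 1L, 1:10] <- m[labels == 1L, 1:10] + shift
  feature_table(m, ids = sprintf("s%03d", 1:n), labels = labels)
}

make_noise_table <- function(n_per_class = 20, seed = 1) {
  make_sep_table(n_per_class, shift = 0, seed = seed)
}

quiet <- function(expr) suppressMessages(expr)
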