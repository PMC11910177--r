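# 522-coefficient feature encoding of a DNA sequence: raw/central/Hahn
# moments of nine matrix views of the sequence (2D sequence matrix forward
# and reversed, PRIM and RPRIM at k = 1,2,3, dinucleotide frequency
# matrix), plus k-mer frequency, AAPIV and RAAPIV vectors at k = 1,2,3.

N_FEATURES <- 522L
FEATURE_LAYOUT_TAG <- "moments522/v1"

# The ten (a, b) moment index pairs with a + b <= 3, in layout order.
MOMENT_ORDERS <- cbind(
  a = c(0L, 0L, 1L, 1L, 0L, 2L, 1L, 2L, 0L, 3L),
  b = c(0L, 1L, 0L, 1L, 2L, 0L, 2L, 1L, 3L, 0L))

# All k-mers over {A,C,G,T} in lexicographic order (A < C < G < T).
all_kmers <- function(k) {
  out <- DNA_BASES
  if (k > 1L) for (i in 2:k) {
    out <- as.vector(t(outer(out, DNA_BASES, paste0)))
  }
  out
}

reverse_seq <- function(seq) {
  paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Encode a DNA sequence as integer codes
#'
#' Maps A, C, G, T to 1, 2, 3, 4 (in that order). The codes are nonzero on
#' purpose: 0 is reserved for the padding cells of the square sequence
#' matrix, so padding is distinguishable from every base.
#'
#' @param seq A single sequence string over `{A,C,G,T}`.
#' @return Integer vector of codes, same length as the sequence.
#' @export
#' @examples
#' encode_numeric("ACGT")   # 1 2 3 4
encode_numeric <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  codes <- match(chars, DNA_BASES)
  if (anyNA(codes)) {
    stop("invalid residue '", chars[which(is.na(codes))[1L]],
         "' at position ", which(is.na(codes))[1L], call. = FALSE)
  }
  codes
}

#' Reshape a coded sequence into a square matrix
#'
#' Row-major fill of a K x K matrix with K = ceiling(sqrt(n)); the
#' K^2 - n trailing cells are zero padding. The two-dimensional form is
#' what the Hahn moment machinery operates on.
#'
#' @param codes Integer vector of nucleotide codes (from
#'   [encode_numeric()]).
#' @return K x K integer matrix with attribute `source_length`.
#' @export
reshape_square <- function(codes) {
  n <- length(codes)
  if (n < 1L) stop("empty sequence cannot be reshaped", call. = FALSE)
  K <- ceiling(sqrt(n))
  m <- matrix(c(codes, rep(0L, K * K - n)), nrow = K, byrow = TRUE)
  attr(m, "source_length") <- n
  m
}

#' Raw geometric moments of a matrix
#'
#' Computes the ten raw moments `D_ab = sum_p sum_q p^a q^b m[p,q]` over
#' 1-based row (p) and column (q) indices for all orders a + b <= 3,
#' together with the centroid `(D10/D00, D01/D00)` (defined as (0, 0) when
#' `D00 == 0`).
#'
#' @param m Square numeric matrix.
#' @return List with `values` (named length-10 vector, names `D00` ...)
#'   and `centroid` (length-2 numeric).
#' @export
raw_moments <- function(m) {
  m <- check_square(m)
  K <- nrow(m)
  idx <- seq_len(K)
  vals <- apply(MOMENT_ORDERS, 1L, function(ab) {
    sum(outer(idx^ab[1L], idx^ab[2L]) * m)
  })
  names(vals) <- sprintf("D%d%d", MOMENT_ORDERS[, "a"], MOMENT_ORDERS[, "b"])
  d00 <- vals[["D00"]]
  centroid <- if (d00 == 0) c(0, 0) else
    c(vals[["D10"]], vals[["D01"]]) / d00
  list(values = vals, centroid = centroid)
}

#' Central moments of a matrix about its centroid
#'
#' `V_ab = sum_g sum_h (g - x)^a (h - y)^b m[g,h]` with 1-based indices
#' and centroid `(x, y)` computed from the same matrix (see
#' [raw_moments()]). By construction `V10` and `V01` vanish up to floating
#' tolerance.
#'
#' @param m Square numeric matrix.
#' @param centroid Length-2 numeric, the centroid of `m`.
#' @return Named length-10 vector (`V00` ...).
#' @export
central_moments <- function(m, centroid) {
  m <- check_square(m)
  K <- nrow(m)
  dg <- seq_len(K) - centroid[1L]
  dh <- seq_len(K) - centroid[2L]
  vals <- apply(MOMENT_ORDERS, 1L, function(ab) {
    sum(outer(dg^ab[1L], dh^ab[2L]) * m)
  })
  names(vals) <- sprintf("V%d%d", MOMENT_ORDERS[, "a"], MOMENT_ORDERS[, "b"])
  vals
}

check_square <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  m
}

# Basis matrices are pure functions of (K, max_order); cache them because
# encoding a dataset reuses a handful of K values thousands of times.
.hahn_cache <- new.env(parent = emptyenv())

#' Orthonormal discrete Hahn polynomial basis
#'
#' Values of the order-0..`max_order` Hahn polynomials (family parameters
#' a = b = 0, where the family coincides with the discrete Chebyshev/Gram
#' polynomials) on the integer grid x = 0..K-1, computed by the standard
#' three-term recurrence with per-order numerical normalisation so that
#' `sum_x h_m(x) h_n(x) = [m == n]` to 1e-10.
#'
#' @param K Grid size; must exceed `max_order` so the requested orders are
#'   linearly independent. The full order-3 block needs K >= 4, i.e.
#'   sequences of length >= 10.
#' @param max_order Highest polynomial order (default 3).
#' @return K x (max_order + 1) matrix; column n + 1 holds order n.
#' @export
hahn_basis <- function(K, max_order = 3L) {
  K <- as.integer(K); max_order <- as.integer(max_order)
  if (K < max_order + 1L) {
    stop("Hahn basis needs K >= ", max_order + 1L, " (got K = ", K,
         "); for the order-3 moment block this means a sequence of ",
         "length >= 10", call. = FALSE)
  }
  key <- paste0(K, ":", max_order)
  cached <- .hahn_cache[[key]]
  if (!is.null(cached)) return(cached)
  x <- 0:(K - 1L)
  H <- matrix(0, K, max_order + 1L)
  t2 <- rep(1, K)
  H[, 1L] <- t2 / sqrt(sum(t2^2))
  if (max_order >= 1L) {
    t1 <- 2 * x - K + 1
    H[, 2L] <- t1 / sqrt(sum(t1^2))
    if (max_order >= 2L) for (n in 2:max_order) {
      # the 1/n factor keeps magnitudes manageable at the orders used
      # (<= 3 in the encoder, <= K-1 <= 63 for the full transform)
      tn <- ((2 * n - 1) * (2 * x - K + 1) * t1 -
               (n - 1) * (K^2 - (n - 1)^2) * t2) / n
      H[, n + 1L] <- tn / sqrt(sum(tn^2))
      t2 <- t1
      t1 <- tn
    }
  }
  .hahn_cache[[key]] <- H
  H
}

#' Hahn moments of a matrix
#'
#' Projects a K x K matrix onto the orthonormal Hahn basis:
#' `H_pq = sum_i sum_j h_p(i) h_q(j) m[i,j]` for the ten order pairs with
#' p + q <= 3 (indices i, j on 0..K-1). Because the basis is orthonormal
#' and complete, retaining all K^2 orders makes the transform exactly
#' invertible; the ten kept here are a fixed-size summary.
#'
#' @param m Square numeric matrix with K >= 4.
#' @return Named length-10 vector (`H00` ...).
#' @export
hahn_moments <- function(m) {
  m <- check_square(m)
  P <- hahn_basis(nrow(m), 3L)
  Hfull <- crossprod(P, m %*% P)      # 4 x 4: all orders p, q <= 3
  vals <- Hfull[cbind(MOMENT_ORDERS[, "a"] + 1L, MOMENT_ORDERS[, "b"] + 1L)]
  names(vals) <- sprintf("H%d%d", MOMENT_ORDERS[, "a"], MOMENT_ORDERS[, "b"])
  vals
}

# 30 moments of one matrix: 10 raw, 10 central, 10 Hahn.
moment_block <- function(m) {
  rm <- raw_moments(m)
  c(rm$values, central_moments(m, rm$centroid), hahn_moments(m))
}

# Positions (1-based starts) of every k-mer type of a sequence, as a list
# indexed by the 4^k lexicographic k-mer types.
kmer_positions <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) {
    stop("sequence of length ", n, " is shorter than k = ", k,
         call. = FALSE)
  }
  tokens <- substring(seq, 1:(n - k + 1L), k:n)
  split(seq_along(tokens), factor(tokens, levels = all_kmers(k)))
}

#' Position relative incidence matrix (PRIM)
#'
#' A 4^k x 4^k accumulator of where each k-mer type occurs relative to the
#' first occurrence of every other type: for ordered type pair (i, j),
#' `cell(i, j) = sum over occurrences p of j of (p - firstpos(i))`, with
#' 1-based overlapping k-mer start positions, and 0 when either type is
#' absent. The rule is order-sensitive (the matrix is not symmetric in
#' general) and cells can be negative when j occurs before i first does.
#'
#' @param seq Sequence string of length >= k.
#' @param k k-mer order, 1, 2 or 3.
#' @return 4^k x 4^k numeric matrix with k-mers (lexicographic, A<C<G<T)
#'   as dimnames.
#' @export
prim <- function(seq, k) {
  stopifnot(k %in% 1:3)
  pos <- kmer_positions(seq, k)
  firstpos <- vapply(pos, function(p) if (length(p)) p[1L] else NA_real_, 0)
  counts <- lengths(pos)
  sumpos <- vapply(pos, sum, 0)
  d <- length(pos)
  # cell(i, j) = sumpos[j] - counts[j] * firstpos[i] when both present
  M <- matrix(sumpos, d, d, byrow = TRUE) - outer(firstpos, counts)
  M[is.na(M)] <- 0
  dimnames(M) <- list(names(pos), names(pos))
  M
}

#' Reverse position relative incidence matrix (RPRIM)
#'
#' The PRIM of the string-reversed sequence (strict reversal, no
#' complementation).
#'
#' @inheritParams prim
#' @return 4^k x 4^k numeric matrix.
#' @export
rprim <- function(seq, k) {
  prim(reverse_seq(seq), k)
}

#' Dinucleotide frequency matrix
#'
#' 4 x 4 matrix counting adjacent base pairs: `cell(i, j)` is the number
#' of positions where base i is immediately followed by base j; cells sum
#' to n - 1.
#'
#' @param seq Sequence string of length >= 2.
#' @return 4 x 4 numeric matrix with bases as dimnames.
#' @export
dinucleotide_frequency_matrix <- function(seq) {
  n <- nchar(seq)
  if (n < 2L) stop("sequence must have length >= 2", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- table(factor(chars[-n], levels = DNA_BASES),
             factor(chars[-1L], levels = DNA_BASES))
  unclass(matrix(as.numeric(m), 4L, 4L, dimnames = dimnames(m)))
}

#' k-mer frequency vector
#'
#' Counts of the 4^k overlapping k-mers in lexicographic order; counts sum
#' to n - k + 1.
#'
#' @inheritParams prim
#' @return Named numeric vector of length 4^k.
#' @export
frequency_vector <- function(seq, k) {
  stopifnot(k %in% 1:3)
  as.numeric_named(lengths(kmer_positions(seq, k)))
}

#' Accumulative absolute position incidence vector (AAPIV)
#'
#' For each of the 4^k k-mer types, the sum of the 1-based start positions
#' of all its (overlapping) occurrences; 0 for absent types. Summed over
#' types this equals (n-k+1)(n-k+2)/2, every position being counted once.
#'
#' @inheritParams prim
#' @return Named numeric vector of length 4^k.
#' @export
aapiv <- function(seq, k) {
  stopifnot(k %in% 1:3)
  as.numeric_named(vapply(kmer_positions(seq, k), sum, 0))
}

#' Reverse AAPIV
#'
#' The AAPIV of the string-reversed sequence.
#'
#' @inheritParams prim
#' @return Named numeric vector of length 4^k.
#' @export
raapiv <- function(seq, k) {
  aapiv(reverse_seq(seq), k)
}

as.numeric_named <- function(x) {
  out <- as.numeric(x)
  names(out) <- names(x)
  out
}

#' Build the 522-coefficient feature vector of one sequence
#'
#' Fixed layout (tagged `moments522/v1`): 30-value moment blocks (10 raw +
#' 10 central + 10 Hahn) for nine matrices -- the forward square sequence
#' matrix, the reversed-sequence square matrix, PRIM at k = 1, 2, 3, RPRIM
#' at k = 1, 2, 3 and the dinucleotide frequency matrix (270 values) --
#' followed by frequency vectors at k = 1, 2, 3 (84), AAPIV at k = 1, 2, 3
#' (84) and RAAPIV at k = 1, 2, 3 (84): 522 coefficients in total.
#'
#' @param seq Sequence string over `{A,C,G,T}`, length >= 10 (so the
#'   square matrix side is >= 4, as the order-3 Hahn block requires).
#' @return Named numeric vector of length 522 with attribute
#'   `layout_tag`.
#' @seealso [feature_layout()] for the index-by-index description.
#' @export
build_feature_vector <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 10L) {
    stop("sequence must have length >= 10 (square side >= 4 is needed ",
         "for the order-3 Hahn moments); got ", nchar(seq), call. = FALSE)
  }
  rev <- reverse_seq(seq)
  mats <- c(
    list(seqmat_fwd = reshape_square(encode_numeric(seq)),
         seqmat_rev = reshape_square(encode_numeric(rev))),
    stats::setNames(lapply(1:3, prim, seq = seq),
                    paste0("prim_k", 1:3)),
    stats::setNames(lapply(1:3, rprim, seq = seq),
                    paste0("rprim_k", 1:3)),
    list(dinuc_freq = dinucleotide_frequency_matrix(seq)))
  moments <- unlist(lapply(mats, moment_block), use.names = FALSE)
  vecs <- c(unlist(lapply(1:3, frequency_vector, seq = seq), use.names = FALSE),
            unlist(lapply(1:3, aapiv, seq = seq), use.names = FALSE),
            unlist(lapply(1:3, raapiv, seq = seq), use.names = FALSE))
  out <- c(moments, vecs)
  stopifnot(length(out) == N_FEATURES, all(is.finite(out)))
  names(out) <- feature_names()
  attr(out, "layout_tag") <- FEATURE_LAYOUT_TAG
  out
}

feature_names <- function() {
  sprintf("f%03d", seq_len(N_FEATURES))
}

#' Reference table of the 522-feature layout
#'
#' @return Data frame with columns `index`, `name`, `block` and
#'   `description`, one row per coefficient.
#' @export
feature_layout <- function() {
  mat_names <- c("forward sequence matrix", "reversed sequence matrix",
                 "PRIM k=1", "PRIM k=2", "PRIM k=3",
                 "RPRIM k=1", "RPRIM k=2", "RPRIM k=3",
                 "dinucleotide frequency matrix")
  fam <- c("raw", "central", "Hahn")
  ords <- sprintf("%d%d", MOMENT_ORDERS[, "a"], MOMENT_ORDERS[, "b"])
  blocks <- character(0); descr <- character(0)
  for (mn in mat_names) for (f in fam) {
    blocks <- c(blocks, rep(paste0("moments: ", mn), 10L))
    descr <- c(descr, paste0(f, " moment ", ords, " of ", mn))
  }
  for (kind in c("frequency vector", "AAPIV", "RAAPIV")) for (k in 1:3) {
    km <- all_kmers(k)
    blocks <- c(blocks, rep(paste0(kind, " k=", k), length(km)))
    descr <- c(descr, paste0(kind, " k=", k, ": ", km))
  }
  data.frame(index = seq_len(N_FEATURES), name = feature_names(),
             block = blocks, description = descr,
             stringsAsFactors = FALSE)
}

#' Encode every sequence of a labeled dataset into a feature table
#'
#' @param dataset A `labeled_dataset` (see [assemble_dataset()]) or a
#'   named character vector of sequences (yielding an unlabeled table).
#' @return A [feature_table()].
#' @export
encode_dataset <- function(dataset) {
  if (inherits(dataset, "labeled_dataset")) {
    seqs <- dataset$sequences
    labels <- dataset$labels
  } else {
    stopifnot(is.character(dataset))
    seqs <- dataset
    labels <- NULL
  }
  mat <- t(vapply(seqs, build_feature_vector, numeric(N_FEATURES)))
  feature_table(mat, ids = names(seqs), labels = labels)
}
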