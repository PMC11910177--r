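# The 522-coefficient encoder: numeric coding, square reshaping, the
# three moment families, PRIM/RPRIM, frequency/AAPIV/RAAPIV vectors and
# the assembled feature vector.

test_that("numeric coding maps A,C,G,T to 1..4 and rejects others", {
  expect_identical(encode_numeric("ACGT"), 1:4)
  expect_identical(encode_numeric("AAAA"), rep(1L, 4))
  expect_identical(encode_numeric("TGCA"), 4:1)
  expect_error(encode_numeric("ACNT"), "position 3")
})

test_that("square reshaping pads row-major to side ceiling(sqrt(n))", {
  expect_identical(unclass(reshape_square(1:4))[, ],
                   matrix(c(1L, 2L, 3L, 4L), 2, byrow = TRUE)[, ])
  m <- reshape_square(c(1L, 2L, 3L, 4L, 1L))
  expect_identical(dim(m), c(3L, 3L))
  expect_identical(m[2, ], c(4L, 1L, 0L))
  expect_identical(m[3, ], c(0L, 0L, 0L))
  m300 <- reshape_square(encode_numeric(rand_seq(300)))
  expect_identical(dim(m300), c(18L, 18L))
  expect_identical(sum(m300 == 0L), 24L)
  expect_error(reshape_square(integer(0)), "empty")
})

test_that("raw and central moments match the brute-force double loops", {
  m <- matrix(c(1, 3, 2, 4), 2)     # [[1,2],[3,4]]
  rm_ <- raw_moments(m)
  expect_equal(rm_$values[["D00"]], 10)
  expect_equal(rm_$values[["D10"]], 17)
  expect_equal(rm_$values[["D01"]], 16)
  set.seed(4)
  for (K in c(2, 5, 9)) {
    r <- matrix(rnorm(K * K), K)
    rr <- raw_moments(r)
    expect_equal(unname(rr$values), brute_raw_moments(r), tolerance = 1e-12)
    expect_equal(unname(central_moments(r, rr$centroid)),
                 brute_central_moments(r), tolerance = 1e-9)
  }
  expect_error(raw_moments(matrix(0, 2, 3)), "square")
})

test_that("moment edge cases: zero matrix, single cell, constant matrix", {
  z <- matrix(0, 3, 3)
  rz <- raw_moments(z)
  expect_true(all(rz$values == 0))
  expect_identical(rz$centroid, c(0, 0))
  expect_true(all(central_moments(z, rz$centroid) == 0))
  r1 <- raw_moments(matrix(7, 1, 1))
  expect_true(all(r1$values == 7))
  cc <- matrix(2.5, 2, 2)
  vc <- central_moments(cc, raw_moments(cc)$centroid)
  expect_identical(vc[["V10"]], 0)
  expect_identical(vc[["V01"]], 0)
  expect_equal(vc[["V00"]], 10)
  v <- central_moments(matrix(c(1, 3, 2, 4), 2),
                       raw_moments(matrix(c(1, 3, 2, 4), 2))$centroid)
  expect_lt(abs(v[["V10"]]), 1e-9)
  expect_lt(abs(v[["V01"]]), 1e-9)
})

test_that("Hahn basis is orthonormal and matches Gram-Schmidt", {
  for (K in c(4, 5, 8, 12)) {
    P <- hahn_basis(K, 3)
    expect_lt(max(abs(crossprod(P) - diag(4))), 1e-10)
    expect_equal(P[, 1], rep(1 / sqrt(K), K))
    G <- gs_hahn_basis(K, 3)
    expect_equal(P, G, tolerance = 1e-9)
  }
  # order-1 polynomial is the centered linear ramp
  p1 <- hahn_basis(5, 3)[, 2]
  ramp <- (0:4) - 2
  expect_equal(p1, ramp / sqrt(sum(ramp^2)), tolerance = 1e-12)
  expect_error(hahn_basis(3, 3), "length >= 10")
})

test_that("Hahn moments: zero matrix, constant-basis identity, oracle", {
  expect_true(all(hahn_moments(matrix(0, 4, 4)) == 0))
  set.seed(8)
  m <- matrix(rnorm(16), 4)
  hm <- hahn_moments(m)
  expect_equal(hm[["H00"]], sum(m) / 4, tolerance = 1e-12)
  expect_equal(unname(hm), brute_hahn_moments(m), tolerance = 1e-9)
})

test_that("full-order Hahn transform reconstructs the matrix", {
  set.seed(12)
  for (K in c(4, 7, 12)) {
    m <- matrix(rnorm(K * K), K)
    P <- hahn_basis(K, K - 1)
    H <- crossprod(P, m %*% P)
    expect_lt(max(abs(P %*% H %*% t(P) - m)), 1e-6)
  }
})

test_that("PRIM follows the first-occurrence accumulation rule", {
  M <- prim("AACG", 1)
  expect_equal(M["A", "A"], 1)   # (1-1)+(2-1)
  expect_equal(M["A", "C"], 2)   # 3-1
  expect_equal(M["A", "G"], 3)   # 4-1
  expect_equal(M["C", "G"], 1)   # 4-3
  expect_true(all(M["T", ] == 0))
  expect_true(all(M[, "T"] == 0))

  M3 <- prim("ACGT", 3)
  expect_identical(dim(M3), c(64L, 64L))
  expect_equal(M3["ACG", "CGT"], 1)   # 2-1
  expect_equal(M3["CGT", "ACG"], -1)
  expect_equal(M3["ACG", "ACG"], 0)
  expect_equal(sum(M3 != 0), 2)       # only the two cross pairs move
  expect_error(prim("AC", 3), "shorter")
})

test_that("PRIM agrees with the brute-force oracle on random sequences", {
  set.seed(13)
  for (rep in 1:5) {
    s <- rand_seq(sample(20:120, 1))
    for (k in 1:3) {
      expect_identical(prim(s, k), brute_prim(s, k))
    }
  }
})

test_that("RPRIM is the PRIM of the reversed string", {
  expect_identical(rprim("ACGCA", 1), prim("ACGCA", 1))  # palindrome
  expect_identical(rprim("AACG", 1), prim("GCAA", 1))
  expect_identical(rprim("ACGT", 2), prim("TGCA", 2))
  set.seed(14)
  s <- rand_seq(60)
  expect_identical(rprim(s, 3), prim(str_reverse(s), 3))
})

test_that("dinucleotide matrix counts adjacent pairs and conserves n-1", {
  m <- dinucleotide_frequency_matrix("AAAA")
  expect_equal(m["A", "A"], 3)
  expect_equal(sum(m), 3)
  m2 <- dinucleotide_frequency_matrix("ACGT")
  expect_equal(m2["A", "C"], 1)
  expect_equal(m2["C", "G"], 1)
  expect_equal(m2["G", "T"], 1)
  expect_equal(sum(m2), 3)
  set.seed(15)
  s <- rand_seq(100)
  expect_equal(sum(dinucleotide_frequency_matrix(s)), 99)
  expect_error(dinucleotide_frequency_matrix("A"), "length >= 2")
})

test_that("frequency, AAPIV and RAAPIV match definitions and conserve", {
  expect_equal(unname(frequency_vector("AACGT", 1)), c(2, 1, 1, 1))
  fv2 <- frequency_vector("AAAA", 2)
  expect_equal(fv2[["AA"]], 3)
  expect_equal(sum(fv2), 3)
  expect_equal(unname(aapiv("ACGT", 1)), c(1, 2, 3, 4))
  expect_equal(unname(aapiv("AACA", 1)), c(7, 3, 0, 0))
  expect_equal(unname(raapiv("ACGT", 1)), c(4, 3, 2, 1))
  expect_equal(unname(raapiv("AACA", 1)), c(8, 2, 0, 0))
  expect_identical(raapiv("ACGCA", 1), aapiv("ACGCA", 1))  # palindrome

  set.seed(16)
  for (rep in 1:5) {
    n <- sample(10:150, 1)
    s <- rand_seq(n)
    for (k in 1:3) {
      expect_equal(sum(frequency_vector(s, k)), n - k + 1)
      expect_equal(sum(aapiv(s, k)), (n - k + 1) * (n - k + 2) / 2)
      expect_equal(unname(frequency_vector(s, k)), unname(brute_freq(s, k)))
      expect_equal(unname(aapiv(s, k)), unname(brute_aapiv(s, k)))
      expect_equal(unname(raapiv(s, k)),
                   unname(brute_aapiv(str_reverse(s), k)))
    }
  }
})

test_that("feature vectors have 522 finite entries regardless of length", {
  set.seed(17)
  for (n in c(10, 57, 300)) {
    fv <- build_feature_vector(rand_seq(n))
    expect_length(fv, 522L)
    expect_true(all(is.finite(fv)))
    expect_identical(attr(fv, "layout_tag"), "moments522/v1")
  }
  expect_error(build_feature_vector("ACGTACGTA"), "length >= 10")
})

test_that("encoding is deterministic and reversal swaps paired blocks", {
  set.seed(18)
  s <- rand_seq(80)
  expect_identical(build_feature_vector(s), build_feature_vector(s))

  r <- str_reverse(s)
  vf <- unname(build_feature_vector(s))
  vr <- unname(build_feature_vector(r))
  blk <- function(v, i) v[(30 * (i - 1) + 1):(30 * i)]
  # forward/reversed sequence-matrix blocks swap
  expect_equal(blk(vf, 1), blk(vr, 2))
  expect_equal(blk(vf, 2), blk(vr, 1))
  # PRIM blocks of one are the RPRIM blocks of the other (k = 1..3)
  for (k in 1:3) {
    expect_equal(blk(vf, 2 + k), blk(vr, 5 + k))
    expect_equal(blk(vf, 5 + k), blk(vr, 2 + k))
  }
  # mononucleotide composition is reversal-invariant
  expect_equal(vf[271:274], vr[271:274])
  # AAPIV and RAAPIV blocks swap (k = 1..3 -> 84 values each)
  expect_equal(vf[355:438], vr[439:522])
  expect_equal(vf[439:522], vr[355:438])
})

test_that("the layout reference table is complete and consistent", {
  lay <- feature_layout()
  expect_identical(nrow(lay), 522L)
  expect_identical(lay$name, sprintf("f%03d", 1:522))
  expect_identical(sum(grepl("^moments", lay$block)), 270L)
  expect_identical(sum(grepl("AAPIV", lay$block)), 168L)
})
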