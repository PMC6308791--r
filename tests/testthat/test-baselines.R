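test_that("binarization follows the two-state >= rule", {
  expect_identical(rbpBinarize(c(3, 1, 4, 1, 5)), c(0L, 1L, 0L, 1L))
  expect_identical(rbpBinarize(1:5), rep(1L, 4))   # strictly increasing
  expect_identical(rbpBinarize(rep(2, 4)), rep(1L, 3))  # equality counts up
  expect_identical(rbpBinarize(5:1), rep(0L, 4))
  expect_error(rbpBinarize(3), "length >= 2")
})

test_that("word profiles count overlapping m-bit windows with ranked frequencies", {
  # binarization of (3,1,4,1,5) is (0,1,0,1); m=2 words are 1,2,1
  pr <- rbpProfile(c(3, 1, 4, 1, 5), m = 2)
  expect_identical(pr$words, c(1L, 2L))
  expect_equal(pr$p, c(2 / 3, 1 / 3))
  expect_identical(pr$rank, c(1L, 2L))
  expect_equal(sum(pr$p), 1)

  # all-equal words: single word, p = 1, rank 1
  prc <- rbpProfile(1:10, m = 3)
  expect_identical(length(prc$words), 1L)
  expect_equal(prc$p, 1)
  expect_identical(prc$rank, 1L)

  # word values always below 2^m; word count is n - m
  set.seed(2)
  x <- rnorm(60)
  pr4 <- rbpProfile(x, m = 4)
  expect_true(all(pr4$words >= 0L & pr4$words < 16L))
  expect_error(rbpProfile(1:3, m = 4), "length >= m")
})

test_that("profile dissimilarity matches the definitional formula and stays in [0,1]", {
  mkProfile <- function(words, p, rank, m = 2L)
    structure(list(m = m, words = as.integer(words), p = p,
                   rank = as.integer(rank)), class = "RbpProfile")
  S1 <- mkProfile(c(0, 1, 2), c(0.5, 0.3, 0.2), c(1, 2, 3))
  S2 <- mkProfile(c(0, 1, 2), c(0.2, 0.5, 0.3), c(3, 1, 2))
  # direct formula over the shared support
  pp <- S1$p * S2$p
  oracle <- sum(abs(S1$rank - S2$rank) * pp) / sum(pp) / (2^2 - 1)
  expect_equal(rbpDistance(S1, S2), oracle, tolerance = 1e-12)

  expect_identical(rbpDistance(S1, S1), 0)  # identical profiles

  # disjoint supports -> maximal dissimilarity with warning
  S3 <- mkProfile(3, 1, 1)
  expect_warning(d <- rbpDistance(S1, S3), "disjoint")
  expect_identical(d, 1)

  expect_error(rbpDistance(S1, mkProfile(0, 1, 1, m = 3L)), "word length")

  # bounded on random profile pairs
  set.seed(31)
  for (rep in 1:100) {
    x <- rnorm(sample(30:80, 1)); y <- rnorm(sample(30:80, 1))
    d <- rbpDistance(rbpProfile(x, 3), rbpProfile(y, 3))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("fiducial detection recovers the generator's wave landmarks", {
  p <- drawIndividualParams(3)
  rate <- 250
  r <- simulateIndividual(p, durationS = 4, rate = rate, noiseSd = 0, seed = 1)
  beats <- detectFiducials(ecg(r), rate, filter = FALSE)
  expect_gt(nrow(beats), 1L)
  expect_true(all(beats$P < beats$Q & beats$Q < beats$R &
                  beats$R < beats$S & beats$S < beats$T))

  # R peaks sit on the known beat grid (bump centers at k / heartRate)
  period <- 1 / p@heartRateHz
  rTimes <- (beats$R - 1) / rate
  offs <- abs(((rTimes + period / 2) %% period) - period / 2)
  expect_true(all(offs <= 1 / rate + 1e-9))

  # two concatenated beats give (at least) two fiducial sets
  two <- simulateIndividual(p, durationS = 2 * period + 0.5, rate = rate,
                            noiseSd = 0, seed = 1)
  b2 <- detectFiducials(ecg(two), rate, filter = FALSE)
  expect_gte(nrow(b2), 2L)

  # flat line -> no beats
  expect_warning(b0 <- detectFiducials(rep(0, 1000), rate), "no R peaks")
  expect_identical(nrow(b0), 0L)
})

test_that("waveform feature vectors have 19 defined components", {
  p <- drawIndividualParams(3)
  r <- simulateIndividual(p, 6, 250, noiseSd = 0, seed = 2)
  beats <- detectFiducials(ecg(r), 250, filter = FALSE)
  f <- waveformFeatures(beats, 250)
  expect_length(f, 19L)
  expect_true(all(f[paste0("dur", c("QS", "PR", "QR", "ST", "QT"))] >= 0))
  expect_gte(f["areaQRS"], 0)

  # amplitude features are absolute differences by definition
  b1 <- beats[1, ]
  expect_equal(unname(waveformFeatures(b1, 250)["ampPQ"]),
               abs(b1$ampP - b1$ampQ))

  # colinear Q,R,S -> zero triangle area
  colin <- data.frame(P = 1L, Q = 5L, R = 7L, S = 9L, T = 15L,
                      ampP = 0.1, ampQ = 0, ampR = 1, ampS = 2, ampT = 0.2)
  expect_equal(unname(waveformFeatures(colin, 100)["areaQRS"]), 0)

  # degenerate beats are skipped with a warning
  degen <- rbind(beats[1, ], within(beats[1, ], S <- R))
  expect_warning(fd <- waveformFeatures(degen, 250), "degenerate")
  expect_length(fd, 19L)
  expect_error(waveformFeatures(beats[0, ], 250), "at least one beat")
})

test_that("the Daubechies pyramid annihilates constants and conserves energy", {
  w <- dwtDaub4(rep(3.7, 64), level = 3)
  expect_length(w$approx, 8L)
  for (d in w$details) expect_equal(max(abs(d)), 0, tolerance = 1e-12)
  expect_equal(w$approx, rep(3.7 * 2^(3 / 2), 8))  # sqrt(2) gain per level

  set.seed(6)
  x <- rnorm(128)
  w <- dwtDaub4(x, level = 4)
  energy <- sum(w$approx^2) + sum(unlist(w$details)^2)
  expect_equal(energy, sum(x^2), tolerance = 1e-9)  # orthonormal filter bank
  expect_error(dwtDaub4(rnorm(100), 3), "divisible")
})

test_that("the wavelet pipeline keeps its segmentation arithmetic", {
  # structural constants of the beat segmentation
  expect_identical(85L + 156L + 43L, 284L)
  expect_identical(85L + 43L, 128L)

  p <- drawIndividualParams(8)
  r <- simulateIndividual(p, 10, 250, noiseSd = 0.01, seed = 3)
  wv <- waveletVector(ecg(r), 250, level = 3)
  expect_identical(wv$blockLength, 16L)           # 128 / 2^3
  expect_identical(ncol(wv$groups), 4L * 16L)     # 4 blocks per group
  expect_length(wv$vector, 64L)

  # too few cycles rejected
  short <- simulateIndividual(p, 1.2, 250, noiseSd = 0, seed = 3)
  expect_error(waveletVector(ecg(short), 250), "R peaks")
})

test_that("the sparse-Euclidean baseline matches an element-wise loop", {
  A <- cooEncode(reducedFromMatrix(matrix(c(0L, 1L, 2L, 0L), 2, 2), 3))
  B <- cooEncode(reducedFromMatrix(matrix(c(2L, 1L, 0L, 0L), 2, 2), 3))
  expect_identical(baselineSparseDistance(A, A), 0)
  # differ in one cell by 2 -> squared distance 4
  C <- cooEncode(reducedFromMatrix(matrix(c(2L, 1L, 2L, 0L), 2, 2), 3))
  expect_identical(baselineSparseDistance(A, C), 4)

  set.seed(14)
  m1 <- matrix(sample(0:2, 25, TRUE), 5, 5)
  m2 <- matrix(sample(0:2, 25, TRUE), 5, 5)
  loop <- 0
  for (i in 1:5) for (j in 1:5) loop <- loop + (m1[i, j] - m2[i, j])^2
  s1 <- cooEncode(reducedFromMatrix(m1, 3))
  s2 <- cooEncode(reducedFromMatrix(m2, 3))
  expect_identical(baselineSparseDistance(s1, s2), loop)
  expect_equal(baselineSparseDistance(s1, s2, sqrt = TRUE), sqrt(loop))
  expect_error(
    baselineSparseDistance(s1, cooEncode(reducedFromMatrix(matrix(0L, 3, 3)))),
    "shape mismatch")
})

test_that("PCA projections agree with the covariance eigen-decomposition", {
  # data on one axis: first component captures all variance
  X1 <- outer(c(1, 2, 3, 5), c(2, -1, 3, 0.5))
  f1 <- pcaFeatures(X1, k = 1)
  expect_equal(f1$eigenvalues[1] / sum(f1$eigenvalues), 1, tolerance = 1e-10)

  # reconstruction error is non-increasing in k
  set.seed(9)
  X <- matrix(rnorm(8 * 30), 8, 30)
  Xc <- X - rowMeans(X)
  errs <- vapply(1:6, function(k) {
    f <- pcaFeatures(X, k)
    sum((Xc - t(f$P) %*% f$Y)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))

  # hand 4x4 matrix: directions match eigen() on C_X = (1/n) X X^T
  set.seed(4)
  H <- matrix(rnorm(16), 4, 4)
  f <- pcaFeatures(H, k = 4)
  Hc <- H - rowMeans(H)
  eo <- eigen(Hc %*% t(Hc) / ncol(H), symmetric = TRUE)
  expect_equal(f$eigenvalues, eo$values, tolerance = 1e-9)
  for (k in 1:3)  # up to sign
    expect_equal(abs(sum(f$P[k, ] * eo$vectors[, k])), 1, tolerance = 1e-8)

  expect_error(pcaFeatures(H, k = 5), "between 1 and")
})
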