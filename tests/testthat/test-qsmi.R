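test_that("counting matrix conserves the sample count and counts duplicates", {
  # single pair -> exactly one cell set
  r1 <- makeRecord(ecg = 0.5, spo2 = 97)
  # both channels are constant, so the binner warns once per channel
  expect_warning(expect_warning(M1 <- mapToMatrix(r1, n = 8), "constant"),
                 "constant")
  expect_identical(sum(M1@counts), 1L)
  expect_identical(sum(M1@counts == 1L), 1L)

  # k identical pairs land in one cell
  rk <- makeRecord(ecg = rep(0.3, 7), spo2 = rep(96, 7))
  expect_warning(expect_warning(Mk <- mapToMatrix(rk, n = 8), "constant"),
                 "constant")
  expect_identical(max(Mk@counts), 7L)
  expect_identical(sum(Mk@counts), 7L)

  # conservation on a random 500-pair record
  set.seed(42)
  r <- makeRecord(ecg = rnorm(500), spo2 = runif(500, 90, 99))
  M <- mapToMatrix(r, n = 32)
  expect_identical(sum(M@counts), 500L)
  expect_true(all(M@counts >= 0))
})

test_that("quantize-reduce applies thresholds per non-overlapping window", {
  # hand case: n=4, m=2, 3 levels with a=0, c=2; window sums 0,1,3,5
  counts <- matrix(0L, 4, 4)
  counts[1, 1] <- 0L           # top-left window sum 0
  counts[1, 3] <- 1L           # top-right window sum 1
  counts[3, 1] <- 2L; counts[4, 2] <- 1L  # bottom-left sum 3
  counts[3, 3] <- 5L           # bottom-right sum 5
  M <- new("CountMatrix", counts = counts, nMapped = sum(counts))
  RM <- quantizeReduce(M, quantizationSpec(nLevels = 3, maskSize = 2,
                                           a = 0, c = 2))
  expect_identical(RM@levels, matrix(c(0L, 2L, 1L, 2L), 2, 2))

  # m = 1 with thresholds 0,1,2 caps each cell at 3 (4-level)
  set.seed(1)
  cnt <- matrix(rpois(36, 2), 6, 6)
  M6 <- new("CountMatrix", counts = cnt, nMapped = sum(cnt))
  RM6 <- quantizeReduce(M6, quantizationSpec(nLevels = 4, maskSize = 1,
                                             a = 0, c = 1, d = 2))
  expect_identical(RM6@levels, matrix(as.integer(pmin(cnt, 3L)), 6, 6))

  # all-zero matrix stays all zero for a >= 0
  Z <- new("CountMatrix", counts = matrix(0L, 4, 4), nMapped = 0L)
  expect_true(all(quantizeReduce(Z, quantizationSpec())@levels == 0L))
})

test_that("quantize-reduce agrees with the naive double-loop tiling oracle", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(2:16, 1)
    m <- sample(1:4, 1)
    counts <- matrix(rpois(n * n, 1.2), n, n)
    thr <- sort(sample(0:6, 3))
    spec <- quantizationSpec(nLevels = sample(3:4, 1), maskSize = m,
                             a = thr[1], c = thr[2], d = thr[3])
    M <- new("CountMatrix", counts = counts, nMapped = sum(counts))
    expect_identical(quantizeReduce(M, spec)@levels,
                     naiveQuantizeReduce(counts, spec))
  }
})

test_that("raising any quantization threshold never increases a level", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    counts <- matrix(rpois(n * n, 2), n, n)
    M <- new("CountMatrix", counts = counts, nMapped = sum(counts))
    a <- sample(0:3, 1); c <- a + sample(0:3, 1); d <- c + sample(0:3, 1)
    base <- quantizeReduce(M, quantizationSpec(4, 2, a, c, d))@levels
    up <- list(c(a + 1, max(c, a + 1), max(d, a + 1)),
               c(a, c + 1, max(d, c + 1)), c(a, c, d + 1))
    for (t in up) {
      bumped <- quantizeReduce(M, quantizationSpec(4, 2, t[1], t[2], t[3]))@levels
      expect_true(all(bumped <= base))
    }
  }
})

test_that("COO encoding reproduces the worked 5x5 listing in column-major order", {
  RM <- reducedFromMatrix(table1Matrix(), nLevels = 3)
  SM <- cooEncode(RM)
  expect_identical(SM@row,   c(2L, 1L, 2L, 3L, 1L, 2L, 1L, 2L))
  expect_identical(SM@col,   c(2L, 3L, 3L, 3L, 4L, 4L, 5L, 5L))
  expect_identical(SM@value, c(1L, 2L, 2L, 2L, 2L, 2L, 1L, 1L))
  expect_identical(cooDecode(SM)@levels, table1Matrix())

  # zero matrix -> empty triple list; empty set decodes to zero matrix
  Z <- cooEncode(reducedFromMatrix(matrix(0L, 5, 5)))
  expect_length(Z@value, 0L)
  expect_true(all(cooDecode(Z)@levels == 0L))

  # identity pattern
  I3 <- cooEncode(reducedFromMatrix(diag(3) * 1L))
  expect_identical(I3@value, c(1L, 1L, 1L))
  expect_identical(I3@row, I3@col)
})

test_that("COO round-trip is the identity on random reduced matrices", {
  set.seed(11)
  for (rep in 1:100) {
    q <- sample(1:10, 1)
    lv <- matrix(sample(0:2, q * q, replace = TRUE), q, q)
    RM <- reducedFromMatrix(lv, nLevels = 3)
    expect_identical(cooDecode(cooEncode(RM))@levels, lv)
  }
  # out-of-shape coordinate rejected at decode
  bad <- new("SparseCOO", row = 1L, col = 1L, value = 1L,
             nrow = 2L, ncol = 2L, nLevels = 3L)
  bad@col <- 5L
  expect_error(cooDecode(bad), "shape")
})

test_that("the COO text format round-trips bit-exactly", {
  RM <- reducedFromMatrix(table1Matrix(), nLevels = 3)
  SM <- cooEncode(RM)
  f <- withr::local_tempfile(fileext = ".coo")
  writeCOO(SM, f)
  back <- readCOO(f)
  expect_identical(back@row, SM@row)
  expect_identical(back@col, SM@col)
  expect_identical(back@value, SM@value)
  expect_identical(c(back@nrow, back@ncol, back@nLevels),
                   c(SM@nrow, SM@ncol, SM@nLevels))
  # and the file content is stable under rewrite
  f2 <- withr::local_tempfile(fileext = ".coo")
  writeCOO(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("correlation similarity matches its definitional formula", {
  A <- reducedFromMatrix(matrix(c(0L, 1L, 2L, 0L), 2, 2), 3)
  B <- reducedFromMatrix(matrix(c(2L, 0L, 1L, 1L), 2, 2), 3)
  sA <- cooEncode(A); sB <- cooEncode(B)

  # definitional oracle: covariance over the product of standard deviations
  x <- as.vector(A@levels); y <- as.vector(B@levels)
  oracle <- mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
  expect_equal(qsmiSimilarity(sA, sB), oracle, tolerance = 1e-12)

  # self-correlation and perfect anti-correlation
  expect_equal(qsmiSimilarity(sA, sA), 1)
  Anti <- reducedFromMatrix(2L - A@levels, 3)
  expect_equal(qsmiSimilarity(sA, cooEncode(Anti)), -1)

  # zero variance -> 0 with warning
  flat <- cooEncode(reducedFromMatrix(matrix(1L, 2, 2), 3))
  expect_warning(v <- qsmiSimilarity(flat, sA), "zero-variance")
  expect_identical(v, 0)

  # shape mismatch
  C <- cooEncode(reducedFromMatrix(matrix(0:3, 2, 2) * 0L + diag(2), 3))
  D <- cooEncode(reducedFromMatrix(matrix(0L, 3, 3), 3))
  expect_error(qsmiSimilarity(C, D), "shape mismatch")
})

test_that("enrollment yields one template per training record, deterministically", {
  co <- simulateCohort(nIndividuals = 18, sessionsPerIndividual = 2,
                       durationS = 2, rate = 100, seed = 21)
  train <- Filter(function(r) sessionId(r) == "s1", co)
  enr <- enrollQsmi(train)
  expect_length(enr$templates, 18L)
  expect_identical(
    sort(unique(vapply(enr$templates, `[[`, "", "individualId"))),
    sort(vapply(train, individualId, "")))
  expect_gt(nrow(enr$trainScores), 0L)

  enr2 <- enrollQsmi(train)
  expect_identical(enr$templates[[3]]$coo@value, enr2$templates[[3]]$coo@value)

  # single individual: one template, no between-class scores
  one <- enrollQsmi(train[1])
  expect_length(one$templates, 1L)
  expect_identical(nrow(one$trainScores), 0L)

  expect_error(enrollQsmi(list()), "empty cohort")
})

test_that("reduced matrices from short synthetic records are sparse", {
  # the high-sparsity premise, asserted on generated data
  set.seed(13)
  for (s in 1:5) {
    p <- drawIndividualParams(s)
    r <- simulateIndividual(p, durationS = 5, rate = 100, seed = s + 100)
    M <- mapToMatrix(r, n = 32)
    RM <- quantizeReduce(M, quantizationSpec())
    expect_lt(mean(RM@levels != 0), 0.5)
  }
})
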