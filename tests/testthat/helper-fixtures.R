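# Shared fixtures: all built in code, nothing read from disk.

# The worked-example reduced matrix (5 x 5, three levels plus value 2 cells).
table1Matrix <- function() {
  m <- matrix(0L, 5, 5)
  m[1, ] <- c(0L, 0L, 2L, 2L, 1L)
  m[2, ] <- c(0L, 1L, 2L, 2L, 1L)
  m[3, ] <- c(0L, 0L, 2L, 0L, 0L)
  m
}

reducedFromMatrix <- function(m, nLevels = max(m) + 1L) {
  new("ReducedMatrix", levels = m, nLevels = as.integer(max(nLevels, 2L)))
}

# Hand-built paired record.
makeRecord <- function(ecg, spo2 = NULL, id = "indX", session = "s1",
                       rate = 100) {
  if (is.null(spo2)) spo2 <- rep(97, length(ecg))
  new("BiosignalRecord", individualId = id, sessionId = session,
      ecg = as.numeric(ecg), spo2 = as.numeric(spo2), samplingRate = rate)
}

# Sparse element sequence straight from coordinates (duplicates merged by
# summing occupancies, then lexicographically sorted).
makeElements <- function(coords, values, u) {
  key <- apply(coords, 1, paste, collapse = ",")
  first <- !duplicated(key)
  values <- as.vector(rowsum(as.numeric(values),
                             factor(key, levels = key[first])))
  coords <- coords[first, , drop = FALSE]
  o <- do.call(order, split(coords, col(coords)))
  new("SparseElementSequence",
      coords = matrix(as.integer(coords[o, , drop = FALSE]), nrow = nrow(coords)),
      values = as.integer(values[o]), u = as.integer(u))
}

# Independent naive window-sum quantizer: double loop over tiles.
naiveQuantizeReduce <- function(counts, spec) {
  m <- spec@maskSize
  n <- nrow(counts)
  q <- ceiling(n / m)
  out <- matrix(0L, q, q)
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      rows <- ((i - 1) * m + 1):min(i * m, n)
      cols <- ((j - 1) * m + 1):min(j * m, n)
      s <- sum(counts[rows, cols]) + sum(spec@bias)
      lev <- if (s <= spec@a) 0L
        else if (s <= spec@c) 1L
        else if (spec@nLevels == 3L) 2L
        else if (s <= spec@d) 2L
        else 3L
      out[i, j] <- lev
    }
  }
  out
}

# Exhaustive minimum over all monotone alignments (no dynamic programming):
# recursively enumerates every warping path from (1,1) to (n,m).
bruteForceDtw <- function(A, B) {
  cost <- function(i, j) sum((A[i, ] - B[j, ])^2)
  rec <- function(i, j) {
    c0 <- cost(i, j)
    if (i == nrow(A) && j == nrow(B)) return(c0)
    cands <- c()
    if (i < nrow(A)) cands <- c(cands, rec(i + 1, j))
    if (j < nrow(B)) cands <- c(cands, rec(i, j + 1))
    if (i < nrow(A) && j < nrow(B)) cands <- c(cands, rec(i + 1, j + 1))
    c0 + min(cands)
  }
  rec(1, 1)
}

# Small deterministic score set builder.
makeScores <- function(genuineScores, impostorScores) {
  scoreSet(probe = c(rep("a", length(genuineScores)),
                     rep("a", length(impostorScores))),
           template = c(rep("a", length(genuineScores)),
                        rep("b", length(impostorScores))),
           score = c(genuineScores, impostorScores))
}
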