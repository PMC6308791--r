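# Reference algorithms the hybrid methods are compared against: reduced
# binary patterns (RBP), fiducial waveform features, a wavelet pipeline,
# the sparse-Euclidean baseline, and PCA feature projection. All plug into
# the evaluation harness through the common fit/score contract
# (see biometricMethod()).

## ---- reduced binary patterns ------------------------------------------------

#' Binarize a series by successive differences
#'
#' `y_i = 1` when `x_{i+1} >= x_i` (equality counts as an increase),
#' 0 otherwise; output length is `length(x) - 1`.
#'
#' @param x numeric series of length >= 2.
#' @return integer 0/1 vector.
#' @examples
#' rbpBinarize(c(3, 1, 4, 1, 5))  # 0 1 0 1
#' @export
rbpBinarize <- function(x) {
  if (length(x) < 2L) stop("series must have length >= 2")
  as.integer(diff(x) >= 0)
}

#' Word frequency and rank profile of a binarized series
#'
#' The binary sequence is scanned with overlapping m-bit windows (stride
#' 1, first bit most significant), giving `length(x) - m` words with
#' decimal values in 0 .. 2^m - 1. Relative frequencies and ranks by
#' descending frequency (ties broken by ascending word value) are
#' computed over the observed words.
#'
#' @param x numeric series of length >= m + 1.
#' @param m word length in bits (default 4).
#' @return a list of class `RbpProfile`: `m`, `words` (observed word
#'   values), `p` (relative frequencies, summing to 1), `rank`.
#' @export
rbpProfile <- function(x, m = 4L) {
  m <- as.integer(m)
  if (length(x) < m + 1L) stop("series must have length >= m + 1")
  y <- rbpBinarize(x)
  win <- embed(y, m)              # row k = (y[k+m-1], ..., y[k])
  d <- as.vector(win %*% 2^(0:(m - 1)))  # first bit most significant
  tab <- table(d)
  words <- as.integer(names(tab))
  p <- as.vector(tab) / length(d)
  rk <- integer(length(words))
  rk[order(-p, words)] <- seq_along(words)
  structure(list(m = m, words = words, p = p, rank = rk),
            class = "RbpProfile")
}

#' @export
print.RbpProfile <- function(x, ...) {
  cat(sprintf("RbpProfile: m = %d, %d observed words of %d possible\n",
              x$m, length(x$words), 2^x$m))
  invisible(x)
}

#' Rank/frequency-weighted dissimilarity between two RBP profiles
#'
#' D_m = (1 / (2^m - 1)) * sum(|R1 - R2| p1 p2) / sum(p1 p2), summed over
#' words observed in both profiles. The 1/(2^m - 1) factor bounds the
#' value to \[0, 1\]. Profiles with disjoint supports get the maximal
#' dissimilarity 1 (with a warning).
#'
#' @param S1,S2 `RbpProfile` objects with the same word length m.
#' @return a number in \[0, 1\]; 0 for identical profiles.
#' @export
rbpDistance <- function(S1, S2) {
  stopifnot(inherits(S1, "RbpProfile"), inherits(S2, "RbpProfile"))
  if (S1$m != S2$m) stop("profiles use different word lengths")
  shared <- intersect(S1$words, S2$words)
  if (!length(shared)) {
    warning("disjoint word supports; returning maximal dissimilarity 1")
    return(1)
  }
  i1 <- match(shared, S1$words); i2 <- match(shared, S2$words)
  pp <- S1$p[i1] * S2$p[i2]
  sum(abs(S1$rank[i1] - S2$rank[i2]) * pp) / sum(pp) / (2^S1$m - 1)
}

## ---- fiducial waveform features ---------------------------------------------

localExtreme <- function(x, lo, hi, what = c("max", "min")) {
  what <- match.arg(what)
  lo <- max(1L, lo); hi <- min(length(x), hi)
  if (lo > hi) return(NA_integer_)
  seg <- x[lo:hi]
  lo - 1L + if (what == "max") which.max(seg) else which.min(seg)
}

#' Band-pass filter an ECG series
#'
#' Zero-phase Butterworth band-pass (default 0.5-40 Hz, order 2 each
#' way), the conventional pre-processing for fiducial-point extraction.
#'
#' @param x numeric ECG series.
#' @param rate sampling rate (Hz); must exceed twice the upper edge.
#' @param band length-2 pass band in Hz.
#' @return filtered series of the same length.
#' @export
bandpassEcg <- function(x, rate, band = c(0.5, 40)) {
  w <- band / (rate / 2)
  if (w[2] >= 1) w[2] <- 0.99
  bf <- signal::butter(2, w, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect P, Q, R, S, T fiducial points per beat
#'
#' R peaks are local maxima above an adaptive threshold (a fraction of
#' the signal's upper amplitude range) separated by a refractory period;
#' Q and S are the nearest local minima left/right of each R within a
#' rate-scaled window; P and T are the largest local maxima in the pre-Q
#' and post-S search windows. Beats whose five indices are not strictly
#' ordered P < Q < R < S < T, or that touch the series edges, are
#' dropped.
#'
#' @param x numeric ECG series.
#' @param rate sampling rate in Hz.
#' @param filter band-pass the signal first (default TRUE).
#' @param thresholdFrac R-peak threshold as a fraction of the maximum
#'   amplitude (default 0.5).
#' @return data.frame with one row per detected beat and columns
#'   `P, Q, R, S, T` (sample indices) and `ampP .. ampT` (amplitudes in
#'   the analyzed signal); zero rows (with a warning) if no R peak is
#'   found.
#' @export
detectFiducials <- function(x, rate, filter = TRUE, thresholdFrac = 0.5) {
  if (length(x) < rate) {
    warning("series shorter than one second; no beats detected")
    return(emptyBeats())
  }
  sig <- if (filter) bandpassEcg(x, rate) else as.numeric(x)
  thr <- thresholdFrac * max(sig)
  n <- length(sig)
  isPeak <- c(FALSE, sig[2:(n - 1)] > sig[1:(n - 2)] &
                     sig[2:(n - 1)] >= sig[3:n], FALSE)
  cand <- which(isPeak & sig > thr & sig > 0)
  if (!length(cand)) {
    warning("no R peaks found above the adaptive threshold")
    return(emptyBeats())
  }
  # enforce a 0.4 s refractory period, keeping the taller peak
  refr <- round(0.4 * rate)
  keep <- cand[1]
  for (k in cand[-1]) {
    if (k - keep[length(keep)] < refr) {
      if (sig[k] > sig[keep[length(keep)]]) keep[length(keep)] <- k
    } else keep <- c(keep, k)
  }
  qsWin <- max(2L, round(0.08 * rate))
  pWin  <- round(0.30 * rate)
  tWin  <- round(0.45 * rate)
  beats <- lapply(keep, function(r) {
    q <- localExtreme(sig, r - qsWin, r - 1L, "min")
    s <- localExtreme(sig, r + 1L, r + qsWin, "min")
    if (is.na(q) || is.na(s)) return(NULL)
    p <- localExtreme(sig, r - pWin, q - 1L, "max")
    t <- localExtreme(sig, s + 1L, r + tWin, "max")
    if (is.na(p) || is.na(t)) return(NULL)
    if (!(p < q && q < r && r < s && s < t)) return(NULL)
    data.frame(P = p, Q = q, R = r, S = s, T = t,
               ampP = sig[p], ampQ = sig[q], ampR = sig[r],
               ampS = sig[s], ampT = sig[t])
  })
  beats <- do.call(rbind, beats)
  if (is.null(beats)) {
    warning("no complete P-Q-R-S-T beat detected")
    return(emptyBeats())
  }
  beats
}

emptyBeats <- function() {
  data.frame(P = integer(), Q = integer(), R = integer(), S = integer(),
             T = integer(), ampP = numeric(), ampQ = numeric(),
             ampR = numeric(), ampS = numeric(), ampT = numeric())
}

#' 19-component fiducial feature vector, averaged over beats
#'
#' From each beat's P, Q, R, S, T indices and amplitudes: 10 amplitude
#' differences (PQ, RQ, TQ, RT, PS, RP, TS, RS, PT, QS, each
#' `|amp(X) - amp(Y)|`), 5 durations in seconds (QS, PR, QR, ST, QT,
#' each `(idx(Y) - idx(X)) / rate`), 3 slopes (RS, ST, QR, amplitude
#' change over time), and the area of the Q-R-S triangle in the
#' (time, amplitude) plane. Degenerate beats with coincident fiducials
#' are skipped with a warning.
#'
#' @param beats data.frame from [detectFiducials()] with >= 1 row.
#' @param rate sampling rate in Hz.
#' @return named numeric vector of exactly 19 features, averaged over
#'   the usable beats.
#' @export
waveformFeatures <- function(beats, rate) {
  if (nrow(beats) < 1L) stop("at least one beat is required")
  ok <- apply(beats[, c("P", "Q", "R", "S", "T")], 1,
              function(b) !anyDuplicated(b))
  if (!all(ok)) warning(sum(!ok), " degenerate beat(s) skipped")
  beats <- beats[ok, , drop = FALSE]
  if (nrow(beats) < 1L) stop("no usable beat after skipping degenerate ones")
  one <- function(b) {
    a <- c(P = b$ampP, Q = b$ampQ, R = b$ampR, S = b$ampS, T = b$ampT)
    i <- c(P = b$P, Q = b$Q, R = b$R, S = b$S, T = b$T)
    ampPairs <- c("PQ", "RQ", "TQ", "RT", "PS", "RP", "TS", "RS", "PT", "QS")
    amps <- vapply(ampPairs, function(pr)
      abs(a[substr(pr, 1, 1)] - a[substr(pr, 2, 2)]), numeric(1))
    durPairs <- c("QS", "PR", "QR", "ST", "QT")
    durs <- vapply(durPairs, function(pr)
      (i[substr(pr, 2, 2)] - i[substr(pr, 1, 1)]) / rate, numeric(1))
    slpPairs <- c("RS", "ST", "QR")
    slps <- vapply(slpPairs, function(pr) {
      x1 <- substr(pr, 1, 1); x2 <- substr(pr, 2, 2)
      (a[x2] - a[x1]) / ((i[x2] - i[x1]) / rate)
    }, numeric(1))
    # QRS triangle in the (time, amplitude) plane
    tx <- i[c("Q", "R", "S")] / rate; ty <- a[c("Q", "R", "S")]
    area <- abs((tx[2] - tx[1]) * (ty[3] - ty[1]) -
                (tx[3] - tx[1]) * (ty[2] - ty[1])) / 2
    c(stats::setNames(amps, paste0("amp", ampPairs)),
      stats::setNames(durs, paste0("dur", durPairs)),
      stats::setNames(slps, paste0("slope", slpPairs)),
      areaQRS = unname(area))
  }
  fs <- t(vapply(seq_len(nrow(beats)), function(k) one(beats[k, ]),
                 numeric(19)))
  colMeans(fs)
}

## ---- wavelet pipeline -------------------------------------------------------

# Daubechies 4-tap analysis filters (2 vanishing moments), periodized.
daub4 <- local({
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)
  list(h = h, g = g)
})

# One periodized analysis step: x (even length) -> list(approx, detail).
dwtStep <- function(x) {
  n <- length(x)
  idx <- outer(seq(0, n - 2, by = 2), 0:3, `+`) %% n + 1
  xw <- matrix(x[idx], ncol = 4)
  list(a = as.vector(xw %*% daub4$h), d = as.vector(xw %*% daub4$g))
}

#' Periodized Daubechies-4 discrete wavelet transform
#'
#' Mallat pyramid on a dyadic-length series: `level` analysis steps, each
#' halving the approximation. For a constant input all detail
#' coefficients are exactly zero.
#'
#' @param x numeric series whose length is divisible by 2^level.
#' @param level number of analysis steps.
#' @return list with `approx` (length `length(x) / 2^level`) and
#'   `details` (list of detail blocks, finest first).
#' @export
dwtDaub4 <- function(x, level = 3L) {
  level <- as.integer(level)
  if (length(x) %% 2^level != 0)
    stop("series length must be divisible by 2^level")
  details <- vector("list", level)
  a <- as.numeric(x)
  for (l in seq_len(level)) {
    st <- dwtStep(a)
    a <- st$a
    details[[l]] <- st$d
  }
  list(approx = a, details = details)
}

#' Wavelet feature vectors from an ECG series
#'
#' Classic beat-synchronous wavelet features: R peaks are detected, each
#' R-R cycle is resampled to 284 points and split 85 / 156 / 43; the
#' first 85 and last 43 points form a 128-point segment framing the QRS
#' complex. Segments are taken in groups of four; each segment's
#' level-`level` approximation coefficients form one block, and the four
#' blocks concatenate into one group vector of length
#' `4 * 128 / 2^level`.
#'
#' @param x numeric ECG series with at least 5 R peaks (4 full cycles).
#' @param rate sampling rate in Hz.
#' @param level DWT depth (default 3, giving 16-coefficient blocks).
#' @return a list of class `WaveletVector`: `groups` (matrix, one group
#'   vector per row), `vector` (mean over groups, used for matching),
#'   `blockLength`, `level`.
#' @export
waveletVector <- function(x, rate, level = 3L) {
  beats <- detectFiducials(x, rate)
  rpeaks <- beats$R
  if (length(rpeaks) < 5L)
    stop("at least 5 R peaks (4 full R-R cycles) are required")
  segs <- lapply(seq_len(length(rpeaks) - 1L), function(k) {
    cyc <- x[rpeaks[k]:(rpeaks[k + 1] - 1L)]
    res <- stats::approx(seq_along(cyc), cyc, n = 284L)$y
    c(res[1:85], res[242:284])  # 85 + 43 = 128 points around the QRS
  })
  nGroups <- length(segs) %/% 4L
  if (nGroups < 1L) stop("at least 4 full R-R cycles are required")
  blockLength <- as.integer(128 %/% 2^as.integer(level))
  groups <- t(vapply(seq_len(nGroups), function(g) {
    unlist(lapply(segs[(4 * g - 3):(4 * g)], function(s)
      dwtDaub4(s, level)$approx))
  }, numeric(4L * blockLength)))
  structure(list(groups = groups, vector = colMeans(groups),
                 blockLength = blockLength, level = as.integer(level)),
            class = "WaveletVector")
}

#' @export
print.WaveletVector <- function(x, ...) {
  cat(sprintf("WaveletVector: %d group(s), 4 blocks x %d coefficients (level %d)\n",
              nrow(x$groups), x$blockLength, x$level))
  invisible(x)
}

## ---- two-dimensional baselines ----------------------------------------------

#' Sparse-Euclidean baseline distance between two encoded matrices
#'
#' The element-wise sum of squared differences over the dense grid,
#' `b = sum_ij ((SM1)_ij - (SM2)_ij)^2` (the printed squared form);
#' `sqrt = TRUE` returns the proper Euclidean norm instead.
#'
#' @param SM1,SM2 [SparseCOO-class] objects of equal shape.
#' @param sqrt take the square root of the sum (default FALSE).
#' @return a non-negative number.
#' @export
baselineSparseDistance <- function(SM1, SM2, sqrt = FALSE) {
  stopifnot(is(SM1, "SparseCOO"), is(SM2, "SparseCOO"))
  if (SM1@nrow != SM2@nrow || SM1@ncol != SM2@ncol)
    stop("shape mismatch: ", SM1@nrow, "x", SM1@ncol, " vs ",
         SM2@nrow, "x", SM2@ncol)
  b <- sum((cooDecode(SM1)@levels - cooDecode(SM2)@levels)^2)
  if (sqrt) base::sqrt(b) else b
}

#' PCA feature extraction by eigen-decomposition of the sample covariance
#'
#' Rows of `X` are centered (each row's mean subtracted); the covariance
#' `C = X Xt / n` (n = number of columns) is eigen-decomposed, the top-k
#' eigenvectors (rows of the projection `P`) extract the principal
#' components `Y = P X`. The implementation uses the SVD of the centered
#' matrix for numerical stability. `project()` maps a new row vector to
#' its k coordinates on the principal axes in column space.
#'
#' @param X numeric matrix (rows are the stacked samples/variables the
#'   decomposition is taken over).
#' @param k number of components, `1 <= k <= min(dim(X))` (default 5).
#' @return list of class `PcaFeatures`: `Y` (k x ncol component matrix),
#'   `P` (k x nrow projection), `eigenvalues` (all, descending), `basis`
#'   (ncol x k orthonormal axes in column space), `project(z)` closure.
#' @export
pcaFeatures <- function(X, k = 5L) {
  X <- as.matrix(X)
  k <- as.integer(k)
  if (k < 1L || k > min(dim(X)))
    stop("k must be between 1 and min(dim(X)) = ", min(dim(X)))
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)
  ev <- sv$d^2 / ncol(X)
  P <- t(sv$u[, seq_len(k), drop = FALSE])
  basis <- sv$v[, seq_len(k), drop = FALSE]
  structure(list(
    Y = P %*% Xc,
    P = P,
    eigenvalues = ev,
    basis = basis,
    project = function(z) as.vector(t(basis) %*% (z - mean(z)))
  ), class = "PcaFeatures")
}

#' @export
print.PcaFeatures <- function(x, ...) {
  k <- nrow(x$Y)
  tot <- sum(x$eigenvalues)
  cat(sprintf("PcaFeatures: %d component(s), %.1f%% of variance\n",
              k, 100 * sum(x$eigenvalues[seq_len(k)]) / max(tot, .Machine$double.eps)))
  invisible(x)
}
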