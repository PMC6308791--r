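# FA/FR evaluation harness: trial score sets, rate computation at a
# threshold, threshold sweeping for the minimum of (FA + FR)/2, accuracy
# Acc = 1 - (FA + FR)/2, per-individual FA, and the quantization-interval
# comparison experiment.

#' Build a trial score set
#'
#' One row per (probe session, template) trial. A trial is genuine when
#' probe and template belong to the same individual.
#'
#' @param probe,template character vectors of individual labels.
#' @param score numeric trial scores.
#' @return data.frame of class `ScoreSet` with columns `probe`,
#'   `template`, `score`, `genuine`.
#' @export
scoreSet <- function(probe, template, score) {
  stopifnot(length(probe) == length(template),
            length(probe) == length(score))
  structure(data.frame(probe = as.character(probe),
                       template = as.character(template),
                       score = as.numeric(score),
                       genuine = as.character(probe) == as.character(template),
                       stringsAsFactors = FALSE),
            class = c("ScoreSet", "data.frame"))
}

checkScoreSet <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("probe", "template", "score", "genuine") %in% names(scores)))
  if (!any(scores$genuine) || !any(!scores$genuine))
    stop("rate computation needs at least one genuine and one impostor trial")
  invisible(scores)
}

#' False-acceptance and false-rejection rates at a threshold
#'
#' With distance polarity a trial is accepted when `score <= delta`;
#' with similarity polarity when `score >= delta`. FA is the fraction of
#' impostor trials accepted, FR the fraction of genuine trials rejected.
#'
#' @param scores a [scoreSet()] with >= 1 genuine and >= 1 impostor
#'   trial.
#' @param delta decision threshold.
#' @param polarity `"distance"` (default) or `"similarity"`.
#' @return named numeric `c(FA = , FR = )`.
#' @export
computeRates <- function(scores, delta, polarity = c("distance", "similarity")) {
  polarity <- match.arg(polarity)
  checkScoreSet(scores)
  acc <- if (polarity == "distance") scores$score <= delta
         else scores$score >= delta
  c(FA = mean(acc[!scores$genuine]),
    FR = mean(!acc[scores$genuine]))
}

#' Identification accuracy from FA and FR
#'
#' `Acc = 1 - (FA + FR) / 2`.
#'
#' @param FA,FR rates in \[0, 1\].
#' @return accuracy in \[0, 1\].
#' @examples
#' accuracy(0.1373, 0)  # 0.93135
#' @export
accuracy <- function(FA, FR) {
  if (any(c(FA, FR) < 0) || any(c(FA, FR) > 1))
    stop("FA and FR must lie in [0, 1]")
  1 - (FA + FR) / 2
}

#' Per-individual false-acceptance rates
#'
#' FA restricted to the impostor trials against each template
#' individual. Individuals with no impostor trials are excluded with a
#' warning. The trial-weighted mean of the per-individual rates equals
#' the global FA.
#'
#' @inheritParams computeRates
#' @return named numeric vector, one FA per template individual.
#' @export
perIndividualFA <- function(scores, delta,
                            polarity = c("distance", "similarity")) {
  polarity <- match.arg(polarity)
  checkScoreSet(scores)
  imp <- scores[!scores$genuine, ]
  ids <- unique(scores$template)
  miss <- setdiff(ids, unique(imp$template))
  if (length(miss))
    warning("no impostor trials against: ", paste(miss, collapse = ", "))
  acc <- if (polarity == "distance") imp$score <= delta
         else imp$score >= delta
  vapply(split(acc, imp$template), mean, numeric(1))
}

#' Sweep a threshold grid for the minimum of (FA + FR) / 2
#'
#' Evaluates every grid threshold and returns the one minimizing the
#' half-sum (ties broken by the smallest threshold), with the full
#' evaluation at that threshold. The default grid, 0.001 to 0.030 in
#' steps of 0.001, suits correlation-derived distances near zero; pass a
#' data-adaptive grid (e.g. [scoreGrid()]) for scores on other scales.
#'
#' @inheritParams computeRates
#' @param grid ordered numeric vector of candidate thresholds.
#' @return an [EvalResult-class] at the chosen threshold.
#' @export
sweepThreshold <- function(scores, grid = seq(0.001, 0.030, by = 0.001),
                           polarity = c("distance", "similarity")) {
  polarity <- match.arg(polarity)
  if (!length(grid)) stop("threshold grid must be non-empty")
  checkScoreSet(scores)
  grid <- sort(grid)
  half <- vapply(grid, function(d) {
    r <- computeRates(scores, d, polarity)
    (r["FA"] + r["FR"]) / 2
  }, numeric(1))
  best <- grid[which.min(half)]  # which.min takes the first = smallest delta
  r <- computeRates(scores, best, polarity)
  new("EvalResult",
      FA = unname(r["FA"]), FR = unname(r["FR"]),
      halfSum = unname((r["FA"] + r["FR"]) / 2),
      acc = unname(accuracy(r["FA"], r["FR"])),
      delta = best,
      perIndividualFA = suppressWarnings(
        perIndividualFA(scores, best, polarity)))
}

#' Data-adaptive threshold grid
#'
#' Midpoints between consecutive distinct scores, plus a point below and
#' above the observed range: sweeping this grid realizes every
#' achievable (FA, FR) operating point of the score set.
#'
#' @param scores a [scoreSet()].
#' @return sorted numeric vector of candidate thresholds.
#' @export
scoreGrid <- function(scores) {
  s <- sort(unique(scores$score))
  if (length(s) == 1) return(s)
  eps <- min(diff(s)) / 2
  c(s[1] - eps, s[-length(s)] + diff(s) / 2, s[length(s)] + eps)
}

## ---- method harness ----------------------------------------------------------

#' The common fit/score contract for all identification methods
#'
#' Every method is a list with fields `name`, `polarity` ("distance" or
#' "similarity" -- all built-in methods score distances so one sweep
#' convention serves them all), `fit(trainRecords)` returning an
#' enrollment state, and `score(state, probe)` returning a data.frame
#' with `templateIndividual` and `score` for the probe against every
#' template. `biometricMethod(name, ...)` builds the built-in methods:
#'
#' * `"qsmi"`: counting matrix + quantization + COO + correlation
#'   (scored as distance 1 - correlation); parameters `n`, `spec`.
#' * `"mdi"`: multi-lead reduction + sparse elements + DTW; parameters
#'   `spec` ([reductionSpec()]), `useValue`.
#' * `"rbp"`: reduced binary pattern profile distance; parameter `m`.
#' * `"waveform"`: Euclidean distance between 19-component fiducial
#'   feature vectors.
#' * `"wavelet"`: Euclidean distance between wavelet vectors; parameter
#'   `level`.
#' * `"baseline2d"`: sparse-Euclidean distance between the (unquantized
#'   reduced, `m = 1`) encoded matrices; parameter `n`.
#' * `"pca"`: Euclidean distance between top-`k` PCA projections of the
#'   concatenated (ECG, SpO2) session vectors; parameter `k`.
#'
#' @param algorithm method name (see above).
#' @param ... method parameters overriding the defaults.
#' @return a method object usable with [evaluateMethod()].
#' @export
biometricMethod <- function(algorithm = c("qsmi", "mdi", "rbp", "waveform",
                                          "wavelet", "baseline2d", "pca"),
                            ...) {
  name <- match.arg(algorithm)
  prm <- list(...)
  take <- function(key, default) if (!is.null(prm[[key]])) prm[[key]] else default
  switch(name,
    qsmi = {
      n <- take("n", 32L); spec <- take("spec", quantizationSpec())
      list(name = "qsmi", polarity = "distance",
           fit = function(train) enrollQsmi(train, n = n, spec = spec),
           score = function(state, probe) {
             s <- scoreQsmi(probe, state)
             s$score <- 1 - s$score  # correlation -> distance
             s
           })
    },
    mdi = {
      spec <- take("spec", reductionSpec()); useValue <- take("useValue", FALSE)
      list(name = "mdi", polarity = "distance",
           fit = function(train) enrollMdi(train, spec = spec),
           score = function(state, probe) {
             d <- mdiIdentify(probe, state, threshold = Inf,
                              useValue = useValue)$distances
             data.frame(templateIndividual = names(d), score = unname(d))
           })
    },
    rbp = {
      m <- take("m", 4L)
      list(name = "rbp", polarity = "distance",
           fit = function(train) lapply(train, function(r)
             list(individualId = individualId(r),
                  profile = rbpProfile(ecg(r), m = m))),
           score = function(state, probe) {
             pp <- rbpProfile(ecg(probe), m = m)
             do.call(rbind, lapply(state, function(tp)
               data.frame(templateIndividual = tp$individualId,
                          score = rbpDistance(pp, tp$profile))))
           })
    },
    waveform = {
      list(name = "waveform", polarity = "distance",
           fit = function(train) lapply(train, function(r)
             list(individualId = individualId(r),
                  features = waveformFeatures(
                    detectFiducials(ecg(r), samplingRate(r)),
                    samplingRate(r)))),
           score = function(state, probe) {
             pf <- waveformFeatures(
               detectFiducials(ecg(probe), samplingRate(probe)),
               samplingRate(probe))
             do.call(rbind, lapply(state, function(tp)
               data.frame(templateIndividual = tp$individualId,
                          score = sqrt(sum((pf - tp$features)^2)))))
           })
    },
    wavelet = {
      level <- take("level", 3L)
      list(name = "wavelet", polarity = "distance",
           fit = function(train) lapply(train, function(r)
             list(individualId = individualId(r),
                  wv = waveletVector(ecg(r), samplingRate(r), level)$vector)),
           score = function(state, probe) {
             pv <- waveletVector(ecg(probe), samplingRate(probe), level)$vector
             do.call(rbind, lapply(state, function(tp)
               data.frame(templateIndividual = tp$individualId,
                          score = sqrt(sum((pv - tp$wv)^2)))))
           })
    },
    baseline2d = {
      n <- take("n", 32L)
      idSpec <- quantizationSpec(nLevels = 4L, maskSize = 1L,
                                 a = 0, c = 1, d = 2)
      list(name = "baseline2d", polarity = "distance",
           fit = function(train) lapply(train, function(r) {
             er <- range(ecg(r)); sr <- range(spo2(r))
             list(individualId = individualId(r), ecgRange = er,
                  spo2Range = sr,
                  coo = cooEncode(quantizeReduce(
                    mapToMatrix(r, n, er, sr), idSpec)))
           }),
           score = function(state, probe) {
             do.call(rbind, lapply(state, function(tp) {
               pc <- cooEncode(quantizeReduce(
                 mapToMatrix(probe, n, tp$ecgRange, tp$spo2Range), idSpec))
               data.frame(templateIndividual = tp$individualId,
                          score = baselineSparseDistance(pc, tp$coo))
             }))
           })
    },
    pca = {
      k <- take("k", 5L)
      list(name = "pca", polarity = "distance",
           fit = function(train) {
             vecs <- lapply(train, function(r) c(ecg(r), spo2(r)))
             len <- min(lengths(vecs))
             X <- do.call(rbind, lapply(vecs, function(v) v[seq_len(len)]))
             fit <- pcaFeatures(X, k = min(k, min(dim(X))))
             list(fit = fit, len = len,
                  templates = lapply(seq_along(train), function(i)
                    list(individualId = individualId(train[[i]]),
                         features = fit$project(vecs[[i]][seq_len(len)]))))
           },
           score = function(state, probe) {
             pv <- c(ecg(probe), spo2(probe))[seq_len(state$len)]
             pf <- state$fit$project(pv)
             do.call(rbind, lapply(state$templates, function(tp)
               data.frame(templateIndividual = tp$individualId,
                          score = sqrt(sum((pf - tp$features)^2)))))
           })
    }
  )
}

splitCohort <- function(cohort, trainSession = "s1") {
  isTrain <- vapply(cohort, function(r) sessionId(r) == trainSession,
                    logical(1))
  if (!any(isTrain) || all(isTrain))
    stop("cohort must contain the training session '", trainSession,
         "' and at least one other session")
  list(train = cohort[isTrain], test = cohort[!isTrain])
}

#' Run a method end-to-end on a cohort: enroll, score all trials, sweep
#'
#' The cohort is split into the training session (templates) and the
#' remaining sessions (probes); every probe is scored against every
#' template (all-vs-all), and the decision threshold minimizing
#' (FA + FR)/2 is chosen on the resulting score set.
#'
#' @param cohort list of records (all sessions of all individuals).
#' @param method a [biometricMethod()].
#' @param trainSession session label used for enrollment (default "s1").
#' @param grid threshold grid; `NULL` (default) uses the data-adaptive
#'   [scoreGrid()].
#' @return list with `scores` (the [scoreSet()]), `result` (the
#'   [EvalResult-class]) and `method` name.
#' @export
evaluateMethod <- function(cohort, method, trainSession = "s1", grid = NULL) {
  sp <- splitCohort(cohort, trainSession)
  state <- method$fit(sp$train)
  trials <- do.call(rbind, lapply(sp$test, function(pr) {
    s <- method$score(state, pr)
    data.frame(probe = individualId(pr),
               template = s$templateIndividual, score = s$score,
               stringsAsFactors = FALSE)
  }))
  scores <- scoreSet(trials$probe, trials$template, trials$score)
  if (is.null(grid)) grid <- scoreGrid(scores)
  list(scores = scores,
       result = sweepThreshold(scores, grid, polarity = method$polarity),
       method = method$name)
}

#' Compare quantization specifications on one cohort split
#'
#' Runs the full QSMI enroll/score/sweep pipeline once per specification
#' on the same cohort and returns one row per spec, enabling
#' quantization-interval comparisons.
#'
#' @param cohort list of [BiosignalRecord-class] objects.
#' @param specs list of [QuantizationSpec-class] objects (>= 1).
#' @param n counting-matrix side.
#' @param trainSession,grid passed to [evaluateMethod()].
#' @return data.frame with columns `label`, `nLevels`, `maskSize`, `FA`,
#'   `FR`, `halfSum`, `acc`, `delta`.
#' @export
compareQuantization <- function(cohort, specs, n = 32L,
                                trainSession = "s1", grid = NULL) {
  if (!length(specs)) stop("at least one quantization spec is required")
  if (is(specs, "QuantizationSpec")) specs <- list(specs)
  rows <- lapply(seq_along(specs), function(k) {
    sp <- specs[[k]]
    ev <- evaluateMethod(cohort, biometricMethod("qsmi", n = n, spec = sp),
                         trainSession = trainSession, grid = grid)$result
    data.frame(label = sprintf("levels%d_m%d", sp@nLevels, sp@maskSize),
               nLevels = sp@nLevels, maskSize = sp@maskSize,
               FA = ev@FA, FR = ev@FR, halfSum = ev@halfSum,
               acc = ev@acc, delta = ev@delta)
  })
  do.call(rbind, rows)
}
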