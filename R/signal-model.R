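# Synthetic biosignal cohort generator and plain-text record I/O.
#
# The generator emulates what the identification algorithms assume about
# real recordings: per-individual quasi-periodic ECG morphology (stable
# within, distinct across individuals), a slowly drifting SpO2 series in a
# physiological band, session-to-session noise, and multi-lead versions
# sharing morphology up to per-lead gains.

# Deterministic sub-seed derivation: cohorts stay stable when the number of
# individuals or sessions changes, and all derived seeds remain 32-bit.
deriveSeed <- function(seed, i = 0L, j = 0L) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + i * 7919 + j * 104729) %% 2147483647)
}

#' Draw one synthetic individual's generative parameters
#'
#' Samples per-wave (P, Q, R, S, T) amplitudes, widths and center offsets
#' around textbook adult values, a heart rate, an SpO2 baseline, and
#' per-lead gains, all from continuous priors so two draws differ almost
#' surely.
#'
#' @param seed integer seed for this draw.
#' @param nLeads number of per-lead scale factors to draw (default 12,
#'   enough for any supported lead count).
#' @return an [IndividualParams-class] object.
#' @examples
#' p <- drawIndividualParams(1)
#' p
#' @export
drawIndividualParams <- function(seed, nLeads = 12L) {
  set.seed(deriveSeed(seed))
  base <- data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    amp    = c(0.13, -0.14, 1.00, -0.22, 0.32),
    width  = c(0.035, 0.012, 0.014, 0.013, 0.055),
    center = c(-0.20, -0.035, 0.00, 0.035, 0.28),
    stringsAsFactors = FALSE
  )
  base$amp    <- base$amp * exp(stats::rnorm(5, 0, 0.15))
  base$width  <- base$width * exp(stats::rnorm(5, 0, 0.10))
  jit <- stats::rnorm(5, 0, 0.008); jit[3] <- 0  # R peak anchors the beat
  base$center <- base$center + jit
  new("IndividualParams",
    morphology  = base,
    heartRateHz = stats::runif(1, 0.9, 1.5),
    spo2Mean    = stats::runif(1, 94, 99),
    spo2Sd      = 0.10,
    leadScales  = stats::runif(nLeads, 0.6, 1.4)
  )
}

# Sum-of-Gaussian-bumps ECG waveform on a time grid, beats at k / heartRate.
ecgWaveform <- function(t, params) {
  period <- 1 / params@heartRateHz
  off <- ((t + period / 2) %% period) - period / 2  # offset to nearest beat
  m <- params@morphology
  x <- numeric(length(t))
  for (w in seq_len(nrow(m)))
    x <- x + m$amp[w] * exp(-((off - m$center[w])^2) / (2 * m$width[w]^2))
  x
}

#' Simulate one paired ECG/SpO2 session
#'
#' ECG is a quasi-periodic sum of five Gaussian bumps (P, Q, R, S, T) per
#' cardiac cycle plus white noise; SpO2 is the individual's baseline plus
#' a slow Gaussian random walk clipped to the physiological band
#' \[85, 100\]. Output is a pure function of the arguments, including the
#' seed.
#'
#' @param params an [IndividualParams-class] object.
#' @param durationS session duration in seconds, > 0.
#' @param rate sampling rate in samples/second, > 0.
#' @param noiseSd standard deviation of the additive ECG noise
#'   (amplitude units; the R wave has nominal amplitude ~1).
#' @param seed integer seed.
#' @param individualId,sessionId labels stored on the record.
#' @return a [BiosignalRecord-class] of `floor(durationS * rate)` paired
#'   samples.
#' @examples
#' p <- drawIndividualParams(1)
#' r <- simulateIndividual(p, durationS = 10, rate = 100, seed = 7)
#' length(r)
#' @export
simulateIndividual <- function(params, durationS, rate, noiseSd = 0.05,
                               seed = 1L, individualId = "ind1",
                               sessionId = "s1") {
  if (!is(params, "IndividualParams")) stop("params must be IndividualParams")
  if (durationS <= 0 || rate <= 0)
    stop("durationS and rate must be positive")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  n <- floor(durationS * rate)
  if (n < 1) stop("durationS * rate must be at least 1 sample")
  set.seed(deriveSeed(seed))
  t <- (seq_len(n) - 1) / rate
  ecg <- ecgWaveform(t, params) + stats::rnorm(n, 0, noiseSd)
  walk <- cumsum(stats::rnorm(n, 0, params@spo2Sd / sqrt(rate)))
  spo2 <- pmin(100, pmax(85, params@spo2Mean + walk))
  new("BiosignalRecord",
      individualId = as.character(individualId),
      sessionId = as.character(sessionId),
      ecg = ecg, spo2 = spo2, samplingRate = rate)
}

#' Simulate a labeled cohort of paired-signal sessions
#'
#' Each individual gets one parameter draw reused across its sessions;
#' every session adds fresh noise and SpO2 drift. Sub-seeds are derived
#' arithmetically from the master seed, so individual k's data do not
#' change when the cohort is enlarged. The default emulates a small
#' enrollment study: 18 individuals with one training and one test
#' session each.
#'
#' @param nIndividuals number of individuals, >= 2.
#' @param sessionsPerIndividual sessions per individual, >= 2 (one to
#'   enroll, at least one to test).
#' @param durationS,rate session length (s) and sampling rate (Hz).
#' @param noiseSd ECG noise standard deviation per session.
#' @param seed master integer seed.
#' @return a list of [BiosignalRecord-class] objects, individuals labeled
#'   `ind01`, `ind02`, ... and sessions `s1`, `s2`, ...
#' @examples
#' cohort <- simulateCohort(nIndividuals = 3, seed = 1)
#' length(cohort)
#' @export
simulateCohort <- function(nIndividuals = 18L, sessionsPerIndividual = 2L,
                           durationS = 30, rate = 100, noiseSd = 0.05,
                           seed = 1L) {
  if (nIndividuals < 2L)
    stop("nIndividuals must be >= 2")
  if (sessionsPerIndividual < 2L)
    stop("sessionsPerIndividual must be >= 2 (train + test)")
  out <- vector("list", nIndividuals * sessionsPerIndividual)
  k <- 0L
  for (i in seq_len(nIndividuals)) {
    p <- drawIndividualParams(deriveSeed(seed, i))
    for (s in seq_len(sessionsPerIndividual)) {
      k <- k + 1L
      out[[k]] <- simulateIndividual(
        p, durationS, rate, noiseSd, seed = deriveSeed(seed, i, s),
        individualId = sprintf("ind%02d", i), sessionId = sprintf("s%d", s))
    }
  }
  out
}

#' Simulate one multi-lead ECG session
#'
#' Lead j is `leadScales[j]` times the individual's base morphology plus
#' independent noise; all leads share the time base.
#'
#' @param params an [IndividualParams-class] object.
#' @param nLeads number of leads J, between 2 and 12.
#' @param durationS,rate,noiseSd,seed as in [simulateIndividual()].
#' @param individualId,sessionId labels stored on the record.
#' @return a [MultiLeadRecord-class].
#' @examples
#' p <- drawIndividualParams(1)
#' ml <- simulateMultilead(p, nLeads = 5, durationS = 5, rate = 100, seed = 3)
#' dim(leads(ml))
#' @export
simulateMultilead <- function(params, nLeads = 5L, durationS = 30, rate = 100,
                              noiseSd = 0.05, seed = 1L,
                              individualId = "ind1", sessionId = "s1") {
  if (nLeads < 2L || nLeads > 12L)
    stop("nLeads must be between 2 and 12")
  if (durationS <= 0 || rate <= 0)
    stop("durationS and rate must be positive")
  n <- floor(durationS * rate)
  if (n < 1) stop("durationS * rate must be at least 1 sample")
  set.seed(deriveSeed(seed))
  t <- (seq_len(n) - 1) / rate
  base <- ecgWaveform(t, params)
  L <- matrix(0, nrow = n, ncol = nLeads)
  for (j in seq_len(nLeads))
    L[, j] <- params@leadScales[j] * base + stats::rnorm(n, 0, noiseSd)
  colnames(L) <- sprintf("lead%d", seq_len(nLeads))
  new("MultiLeadRecord",
      individualId = as.character(individualId),
      sessionId = as.character(sessionId),
      leads = L, samplingRate = rate)
}

#' Simulate a multi-lead cohort
#'
#' Multi-lead analogue of [simulateCohort()]: one parameter draw per
#' individual, fresh noise per session.
#'
#' @inheritParams simulateCohort
#' @param nLeads number of leads per record (2..12).
#' @return a list of [MultiLeadRecord-class] objects.
#' @export
simulateMultileadCohort <- function(nIndividuals = 10L,
                                    sessionsPerIndividual = 2L,
                                    nLeads = 5L, durationS = 10, rate = 100,
                                    noiseSd = 0.05, seed = 1L) {
  if (nIndividuals < 2L) stop("nIndividuals must be >= 2")
  if (sessionsPerIndividual < 2L)
    stop("sessionsPerIndividual must be >= 2 (train + test)")
  out <- vector("list", nIndividuals * sessionsPerIndividual)
  k <- 0L
  for (i in seq_len(nIndividuals)) {
    p <- drawIndividualParams(deriveSeed(seed, i))
    for (s in seq_len(sessionsPerIndividual)) {
      k <- k + 1L
      out[[k]] <- simulateMultilead(
        p, nLeads, durationS, rate, noiseSd, seed = deriveSeed(seed, i, s),
        individualId = sprintf("ind%02d", i), sessionId = sprintf("s%d", s))
    }
  }
  out
}

## ---- plain-text record I/O -------------------------------------------------

recordChannels <- function(x) {
  if (is(x, "BiosignalRecord")) {
    list(ecg = x@ecg, spo2 = x@spo2)
  } else {
    cols <- lapply(seq_len(ncol(x@leads)), function(j) x@leads[, j])
    names(cols) <- sprintf("lead%d", seq_len(ncol(x@leads)))
    cols
  }
}

#' Write records to a long-format CSV
#'
#' One row per sample per channel with columns `individual_id`,
#' `session_id`, `channel`, `index`, `value`. The sampling rate is stored
#' as a one-row `sampling_rate` pseudo-channel per session so the file
#' round-trips through [readRecords()].
#'
#' @param records list of [BiosignalRecord-class] and/or
#'   [MultiLeadRecord-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readRecords()]
#' @export
writeRecords <- function(records, path) {
  if (is(records, "BiosignalRecord") || is(records, "MultiLeadRecord"))
    records <- list(records)
  rows <- lapply(records, function(r) {
    ch <- recordChannels(r)
    dat <- do.call(rbind, lapply(names(ch), function(nm) {
      data.frame(individual_id = individualId(r), session_id = sessionId(r),
                 channel = nm, index = seq_along(ch[[nm]]),
                 value = ch[[nm]], stringsAsFactors = FALSE)
    }))
    rbind(dat,
          data.frame(individual_id = individualId(r),
                     session_id = sessionId(r),
                     channel = "sampling_rate", index = 1L,
                     value = samplingRate(r), stringsAsFactors = FALSE))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

knownChannels <- c("ecg", "spo2", sprintf("lead%d", 1:12), "sampling_rate")

#' Read records from CSV or a WFDB-style text layout
#'
#' `format = "csv"` expects the long format written by [writeRecords()]
#' (columns `individual_id`, `session_id`, `channel`, `index`, `value`).
#' Sessions with both `ecg` and `spo2` channels become
#' [BiosignalRecord-class] objects; sessions with `lead1..leadJ` channels
#' become [MultiLeadRecord-class] objects.
#'
#' `format = "wfdb"` reads a minimal WFDB-like record: `<path>.hea` with a
#' header line `record_name n_sig sampling_rate n_samples` and
#' `<path>.dat` holding a whitespace-separated n_samples x n_sig text
#' matrix; the result is a one-element list with a
#' [MultiLeadRecord-class].
#'
#' @param path file path (for `"wfdb"`, the record path without
#'   extension).
#' @param format `"csv"` or `"wfdb"`.
#' @return a list of records; an empty CSV yields an empty list.
#' @export
readRecords <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "wfdb") return(readWfdbLike(path))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e)))
  if (nrow(df) == 0) return(list())
  need <- c("individual_id", "session_id", "channel", "index", "value")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  bad <- !df$channel %in% knownChannels
  if (any(bad))
    stop("unknown channel name(s) at data line(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), ": ",
         paste(unique(df$channel[bad]), collapse = ", "))
  if (anyNA(df$value) || anyNA(df$index))
    stop("malformed rows (non-numeric index/value) at data line(s) ",
         paste(utils::head(which(is.na(df$value) | is.na(df$index)), 5),
               collapse = ", "))
  key <- paste(df$individual_id, df$session_id, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(s) {
    chans <- split(s, s$channel)
    series <- lapply(chans, function(d) d$value[order(d$index)])
    rate <- if ("sampling_rate" %in% names(series))
      series$sampling_rate[1] else 100
    series$sampling_rate <- NULL
    iid <- s$individual_id[1]; sid <- s$session_id[1]
    if (all(c("ecg", "spo2") %in% names(series))) {
      new("BiosignalRecord", individualId = iid, sessionId = sid,
          ecg = series$ecg, spo2 = series$spo2, samplingRate = rate)
    } else if (all(grepl("^lead", names(series)))) {
      ord <- order(as.integer(sub("^lead", "", names(series))))
      lens <- lengths(series)
      if (length(unique(lens)) != 1)
        stop("leads of session '", sid, "' have unequal lengths")
      new("MultiLeadRecord", individualId = iid, sessionId = sid,
          leads = do.call(cbind, series[ord]), samplingRate = rate)
    } else {
      stop("session '", sid, "' of individual '", iid,
           "' has an incomplete channel set: ",
           paste(names(series), collapse = ", "))
    }
  }) |> unname()
}

readWfdbLike <- function(path) {
  hea <- paste0(path, ".hea")
  dat <- paste0(path, ".dat")
  if (!file.exists(hea)) stop("header not found: ", hea)
  if (!file.exists(dat)) stop("signal file not found: ", dat)
  hdr <- strsplit(trimws(readLines(hea, n = 1L)), "\\s+")[[1]]
  if (length(hdr) < 4) stop("malformed header line in ", hea)
  nsig <- as.integer(hdr[2]); fs <- as.numeric(hdr[3]); nsamp <- as.integer(hdr[4])
  m <- as.matrix(utils::read.table(dat))
  if (ncol(m) != nsig || nrow(m) != nsamp)
    stop("signal matrix in ", dat, " does not match header (",
         nsamp, " x ", nsig, " expected)")
  colnames(m) <- sprintf("lead%d", seq_len(nsig))
  list(new("MultiLeadRecord", individualId = hdr[1], sessionId = "s1",
           leads = m, samplingRate = fs))
}
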