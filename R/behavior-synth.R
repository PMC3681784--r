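#' Default probe-stimulus catalog
#'
#' Probe stimuli used when none are supplied: a 20 kHz tone (the diagnostic
#' frequency for high-frequency noise-induced tinnitus) and broad-band noise
#' (BBN, the hearing control), each at five presentation levels spanning the
#' 30-90 dB SPL testing range.
#'
#' @param toneKhz tone frequency in kHz.
#' @param levels presentation levels in dB SPL.
#' @return data.frame with columns `kind`, `freq_khz`, `level_db`.
#' @export
#' @examples
#' defaultProbeCatalog()
defaultProbeCatalog <- function(toneKhz = 20, levels = c(30, 45, 60, 75, 90)) {
  stopifnot(all(levels >= 30), all(levels <= 90))
  rbind(
    data.frame(kind = "tone", freq_khz = toneKhz, level_db = levels),
    data.frame(kind = "BBN", freq_khz = NA_real_, level_db = levels)
  )
}

## Uniform draw of k mutually non-adjacent integers from lo..hi.
## Bijection: sorted k-subsets of {1..m-k+1} <-> non-adjacent k-subsets of
## {1..m} via x_i = z_(i) + (i - 1).
.sampleNonAdjacent <- function(k, lo, hi) {
  m <- hi - lo + 1L
  if (k == 0L) return(integer(0))
  if (m - k + 1L < k)
    stop("infeasible placement: cannot fit ", k,
         " non-adjacent probe minutes into minutes ", lo, "..", hi)
  z <- sort(sample.int(m - k + 1L, k))
  lo - 1L + z + seq_len(k) - 1L
}

#' Build a daily test-session schedule
#'
#' Draws one session schedule: `nProbes` whole, non-contiguous 1-min probe
#' periods placed uniformly at random among the interior minutes (neither the
#' first nor the last minute of the session), of which exactly `nSpeakerOff`
#' are speaker-off; the remaining probes are drawn with replacement from
#' `probeCatalog`. All other minutes are background broad-band noise.
#'
#' @param sessionMinutes session duration in minutes.
#' @param nProbes number of probe periods.
#' @param nSpeakerOff number of probes that are speaker-off periods.
#' @param probeCatalog data.frame of candidate probe stimuli
#'   (see [defaultProbeCatalog()]).
#' @param backgroundLevel ambient BBN level, dB SPL.
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @return A [Protocol-class] object carrying the realized schedule.
#' @export
#' @examples
#' p <- buildProtocol(seed = 1)
#' table(schedule(p)$kind)
buildProtocol <- function(sessionMinutes = 60, nProbes = 10, nSpeakerOff = 2,
                          probeCatalog = defaultProbeCatalog(),
                          backgroundLevel = 60, seed = 1L) {
  sessionMinutes <- as.integer(sessionMinutes)
  nProbes <- as.integer(nProbes)
  nSpeakerOff <- as.integer(nSpeakerOff)
  stopifnot(sessionMinutes >= 1L, nProbes >= 0L,
            nSpeakerOff >= 0L, nSpeakerOff <= nProbes)
  if (nProbes > 0L && sessionMinutes < 3L)
    stop("infeasible placement: probes occupy interior minutes only")
  if (nProbes > nSpeakerOff && nrow(probeCatalog) == 0L)
    stop("probeCatalog is empty but sound probes were requested")

  minuteKind <- rep("background", sessionMinutes)
  minuteStim <- rep("BBN", sessionMinutes)
  minuteFreq <- rep(NA_real_, sessionMinutes)
  minuteLevel <- rep(backgroundLevel, sessionMinutes)

  withr::with_seed(seed, {
    if (nProbes > 0L) {
      ## 0-based interior minutes 1..(sessionMinutes - 2)
      slots <- .sampleNonAdjacent(nProbes, 1L, sessionMinutes - 2L) + 1L
      offIdx <- if (nSpeakerOff > 0L) sample(slots, nSpeakerOff) else integer(0)
      sndIdx <- setdiff(slots, offIdx)
      minuteKind[offIdx] <- "speaker_off"
      minuteStim[offIdx] <- "speaker_off"
      minuteLevel[offIdx] <- NA_real_
      if (length(sndIdx)) {
        rows <- sample.int(nrow(probeCatalog), length(sndIdx), replace = TRUE)
        minuteKind[sndIdx] <- "probe"
        minuteStim[sndIdx] <- probeCatalog$kind[rows]
        minuteFreq[sndIdx] <- probeCatalog$freq_khz[rows]
        minuteLevel[sndIdx] <- probeCatalog$level_db[rows]
      }
    }
  })

  ## merge consecutive background minutes into single periods
  grp <- cumsum(c(TRUE, minuteKind[-1] != "background" |
                        minuteKind[-sessionMinutes] != "background"))
  starts <- tapply(seq_len(sessionMinutes) - 1L, grp, min)
  ends <- tapply(seq_len(sessionMinutes) - 1L, grp, max)
  first <- !duplicated(grp)
  sched <- data.frame(
    period_index = seq_along(starts),
    start_sec = as.numeric(starts) * 60,
    end_sec = (as.numeric(ends) + 1) * 60,
    kind = minuteKind[first],
    stimulus = minuteStim[first],
    freq_khz = minuteFreq[first],
    level_db = minuteLevel[first],
    stringsAsFactors = FALSE
  )

  new("Protocol",
      sessionMinutes = sessionMinutes, nProbes = nProbes,
      nSpeakerOff = nSpeakerOff, probeCatalog = probeCatalog,
      backgroundLevel = backgroundLevel, schedule = sched,
      seed = as.integer(seed))
}

#' Construct an animal state
#'
#' @param animalId character identifier.
#' @param exposed logical noise-exposure status.
#' @param tau latent tinnitus severity in \[0, 1\]; must be 0 when unexposed.
#' @param tinnitusPitch pitch of the tinnitus percept, kHz.
#' @param lambdaBg mean lever presses/min under background noise.
#' @param cOff trained suppression depth in \[0, 1\].
#' @return An [AnimalState-class] object.
#' @export
#' @examples
#' animalState("E01", exposed = TRUE, tau = 0.8)
animalState <- function(animalId, exposed = FALSE, tau = 0,
                        tinnitusPitch = 20, lambdaBg = 15, cOff = 0.85) {
  new("AnimalState", animalId = as.character(animalId),
      exposed = isTRUE(exposed), tau = tau, tinnitusPitch = tinnitusPitch,
      lambdaBg = lambdaBg, cOff = cOff)
}

#' Similarity-kernel parameters
#'
#' Parameters of the perceived-similarity kernel used by the session
#' simulator. The silence channel is a decreasing logistic in level (a loud
#' stimulus cannot resemble silence); the tinnitus channel is a Gaussian
#' kernel in log2 frequency centred on the tinnitus pitch, times a
#' decreasing-logistic level admission window (the percept is faint, so very
#' loud tones resemble it less). The tinnitus window is shallower and
#' right-shifted relative to the silence channel, so at the tinnitus pitch
#' the tinnitus channel dominates at every testing level; broad-band noise
#' gets only the kernel floor.
#'
#' @param silL50 level (dB SPL) of half-similarity to silence.
#' @param silSlope dB per logit of the silence channel.
#' @param tinL50 level (dB SPL) of half-similarity to the tinnitus percept.
#' @param tinSlope dB per logit of the tinnitus admission window.
#' @param widthOct Gaussian kernel width (octaves, SD) around the pitch.
#' @param floor minimum tinnitus-channel similarity for any sound stimulus.
#' @return named list of parameters.
#' @export
similarityParams <- function(silL50 = 40, silSlope = 5,
                             tinL50 = 80, tinSlope = 10,
                             widthOct = 0.5, floor = 0.05) {
  stopifnot(silSlope > 0, tinSlope > 0, widthOct > 0, floor >= 0, floor <= 1)
  list(silL50 = silL50, silSlope = silSlope, tinL50 = tinL50,
       tinSlope = tinSlope, widthOct = widthOct, floor = floor)
}

#' Perceived similarity of a probe stimulus to the punished percept
#'
#' During speaker-off periods lever pressing is punished, so suppression
#' tracks how much a probe resembles whatever the animal experiences during
#' speaker-off: silence for a healthy animal, the tinnitus percept for a
#' tinnitus animal. The kernel mixes the two channels by the latent severity
#' `tau`: \eqn{S = (1 - \tau) S_{sil}(L) + \tau S_{tin}(f, L)}. Speaker-off
#' itself always has S = 1 (whatever is experienced during speaker-off is,
#' by definition, the punished percept).
#'
#' @param kind "speaker_off", "tone" or "BBN" (vectorized).
#' @param freqKhz tone frequency in kHz (NA for BBN / speaker-off).
#' @param levelDb presentation level in dB SPL (NA for speaker-off).
#' @param animal an [AnimalState-class] object.
#' @param params kernel parameters, see [similarityParams()].
#' @return numeric similarity values in \[0, 1\].
#' @export
#' @examples
#' a <- animalState("E01", exposed = TRUE, tau = 0.8)
#' perceivedSimilarity("tone", 20, 70, a) > perceivedSimilarity("tone", 10, 70, a)
perceivedSimilarity <- function(kind, freqKhz = NA_real_, levelDb = NA_real_,
                                animal, params = similarityParams()) {
  stopifnot(is(animal, "AnimalState"))
  n <- max(length(kind), length(freqKhz), length(levelDb))
  kind <- rep_len(kind, n)
  freqKhz <- rep_len(freqKhz, n)
  levelDb <- rep_len(levelDb, n)
  if (!all(kind %in% c("speaker_off", "tone", "BBN")))
    stop("stimulus kind must be speaker_off, tone or BBN")

  sSil <- stats::plogis((params$silL50 - levelDb) / params$silSlope)
  window <- stats::plogis((params$tinL50 - levelDb) / params$tinSlope)
  octDist <- log2(freqKhz / animal@tinnitusPitch)
  gauss <- exp(-octDist^2 / (2 * params$widthOct^2))
  sTin <- pmax(params$floor, gauss * window)
  sTin[kind == "BBN"] <- params$floor

  s <- (1 - animal@tau) * sSil + animal@tau * sTin
  s[kind == "speaker_off"] <- 1
  pmin(pmax(s, 0), 1)
}

## Expand a period schedule into one row per 1-min epoch.
.minuteTable <- function(sched) {
  mins <- sum(sched$end_sec - sched$start_sec) / 60
  minute <- seq_len(mins) - 1L
  idx <- findInterval(minute * 60, sched$start_sec)
  data.frame(minute = minute,
             kind = sched$kind[idx],
             stimulus = sched$stimulus[idx],
             freq_khz = sched$freq_khz[idx],
             level_db = sched$level_db[idx],
             stringsAsFactors = FALSE)
}

#' Simulate one conditioned-suppression session
#'
#' Per-minute press counts are Poisson with rate
#' \eqn{\lambda = \lambda_{bg} (1 - c_{off} S)}, where S is the perceived
#' similarity of that minute's stimulus to the punished percept (S = 0 during
#' background noise) and press times are uniform within the minute. The
#' result is byte-identical for identical inputs and seed.
#'
#' @param animal an [AnimalState-class] object.
#' @param protocol a [Protocol-class] object (realized schedule).
#' @param seed integer seed.
#' @param session session index stored on the log.
#' @param params similarity-kernel parameters, see [similarityParams()].
#' @return A [SessionLog-class] object.
#' @export
#' @examples
#' log <- simulateSession(animalState("U01"), buildProtocol(seed = 1), seed = 2)
#' length(pressTimes(log))
simulateSession <- function(animal, protocol, seed, session = 1L,
                            params = similarityParams()) {
  stopifnot(is(animal, "AnimalState"), is(protocol, "Protocol"))
  mt <- .minuteTable(protocol@schedule)
  s <- numeric(nrow(mt))
  nb <- mt$kind != "background"
  if (any(nb))
    s[nb] <- perceivedSimilarity(mt$stimulus[nb], mt$freq_khz[nb],
                                 mt$level_db[nb], animal, params)
  lambda <- animal@lambdaBg * (1 - animal@cOff * s)

  times <- withr::with_seed(seed, {
    counts <- stats::rpois(length(lambda), lambda)
    unlist(lapply(seq_along(counts), function(i) {
      if (counts[i] == 0L) return(numeric(0))
      sort(stats::runif(counts[i], min = (i - 1) * 60, max = i * 60))
    }), use.names = FALSE)
  })
  if (is.null(times)) times <- numeric(0)

  new("SessionLog", animalId = animal@animalId,
      session = as.integer(session), pressTimes = times,
      schedule = protocol@schedule, seed = as.integer(seed))
}

#' Build a session log from prescribed per-minute counts
#'
#' Deterministic helper for constructing sessions with exactly known epoch
#' counts (QC boundary scans, worked examples, tests): presses are evenly
#' spaced within each minute.
#'
#' @param counts non-negative integer vector, one entry per minute.
#' @param schedule optional period schedule; defaults to all-background
#'   minutes matching `length(counts)`.
#' @param animalId,session identifiers stored on the log.
#' @return A [SessionLog-class] object.
#' @export
#' @examples
#' log <- sessionLogFromCounts(c(10, 10, 0))
#' epochCounts(log)$count
sessionLogFromCounts <- function(counts, schedule = NULL,
                                 animalId = "synthetic", session = 1L) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (is.null(schedule)) {
    schedule <- data.frame(period_index = 1L, start_sec = 0,
                           end_sec = 60 * length(counts),
                           kind = "background", stimulus = "BBN",
                           freq_khz = NA_real_, level_db = 60,
                           stringsAsFactors = FALSE)
  }
  if (sum(schedule$end_sec - schedule$start_sec) / 60 != length(counts))
    stop("counts length must match the schedule duration in minutes")
  times <- unlist(lapply(seq_along(counts), function(i) {
    k <- counts[i]
    if (k == 0) return(numeric(0))
    (i - 1) * 60 + (seq_len(k) - 0.5) * (60 / k)
  }), use.names = FALSE)
  if (is.null(times)) times <- numeric(0)
  new("SessionLog", animalId = as.character(animalId),
      session = as.integer(session), pressTimes = times,
      schedule = schedule, seed = NA_integer_)
}

#' Simulate a cohort of animals over repeated sessions
#'
#' Unexposed animals have tau = 0; exposed animals draw tau from a Beta
#' distribution (or a degenerate point mass). Each animal's background press
#' rate is drawn from a log-normal so that session quality-control filters
#' have non-trivial action. Every animal receives `nSessions` sessions, each
#' with a freshly drawn probe schedule, under sub-seeds derived from `seed`.
#'
#' @param nExposed,nUnexposed group sizes.
#' @param tauDist either a length-2 numeric (Beta shape1, shape2) or a single
#'   value in \[0, 1\] for a degenerate severity distribution.
#' @param nSessions sessions per animal (0 is allowed: animals are still
#'   enumerated, with empty session lists).
#' @param seed master integer seed; all randomness flows from it.
#' @param lambdaMedian median background press rate (presses/min).
#' @param lambdaSdlog log-scale SD of the background press rate.
#' @param cOff trained suppression depth.
#' @param tinnitusPitch tinnitus pitch, kHz.
#' @param protocolArgs list of arguments forwarded to [buildProtocol()].
#' @param params similarity-kernel parameters.
#' @return list with `animals` (data.frame: animal_id, exposed, tau,
#'   lambda_bg, c_off, tinnitus_pitch) and `sessions` (named list, one list
#'   of [SessionLog-class] per animal).
#' @export
#' @examples
#' coh <- simulateCohort(nExposed = 2, nUnexposed = 1, nSessions = 1, seed = 1)
#' nrow(coh$animals)
simulateCohort <- function(nExposed = 24, nUnexposed = 16,
                           tauDist = c(2, 1), nSessions = 10, seed = 1L,
                           lambdaMedian = 15, lambdaSdlog = 0.5,
                           cOff = 0.85, tinnitusPitch = 20,
                           protocolArgs = list(),
                           params = similarityParams()) {
  stopifnot(nExposed >= 0, nUnexposed >= 0, nExposed + nUnexposed > 0,
            nSessions >= 0)
  n <- nExposed + nUnexposed
  ids <- c(sprintf("E%02d", seq_len(nExposed)),
           sprintf("U%02d", seq_len(nUnexposed)))
  exposed <- rep(c(TRUE, FALSE), c(nExposed, nUnexposed))

  draws <- withr::with_seed(seed, {
    tau <- if (length(tauDist) == 1L) rep(tauDist, nExposed)
           else stats::rbeta(nExposed, tauDist[1], tauDist[2])
    list(tau = c(tau, rep(0, nUnexposed)),
         lambda = stats::rlnorm(n, log(lambdaMedian), lambdaSdlog),
         protoSeeds = matrix(if (nSessions > 0)
           sample.int(.Machine$integer.max, n * nSessions) else integer(0),
           nrow = n, ncol = nSessions),
         sessSeeds = matrix(if (nSessions > 0)
           sample.int(.Machine$integer.max, n * nSessions) else integer(0),
           nrow = n, ncol = nSessions))
  })

  animals <- data.frame(animal_id = ids, exposed = exposed,
                        tau = draws$tau, lambda_bg = draws$lambda,
                        c_off = cOff, tinnitus_pitch = tinnitusPitch,
                        stringsAsFactors = FALSE)
  sessions <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    st <- animalState(ids[i], exposed = exposed[i], tau = draws$tau[i],
                      tinnitusPitch = tinnitusPitch,
                      lambdaBg = draws$lambda[i], cOff = cOff)
    sessions[[i]] <- lapply(seq_len(nSessions), function(j) {
      proto <- do.call(buildProtocol,
                       c(protocolArgs, list(seed = draws$protoSeeds[i, j])))
      simulateSession(st, proto, seed = draws$sessSeeds[i, j],
                      session = j, params = params)
    })
  }
  list(animals = animals, sessions = sessions)
}
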