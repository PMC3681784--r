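#' @import methods
NULL

## Schedules are data.frames with one row per period, half-open [start, end)
## in seconds, tiling the session. Kinds: "background", "speaker_off", "probe".
.SCHEDULE_COLS <- c("period_index", "start_sec", "end_sec", "kind",
                    "stimulus", "freq_khz", "level_db")

.validSchedule <- function(sched) {
  msgs <- character(0)
  if (!is.data.frame(sched) || !all(.SCHEDULE_COLS %in% names(sched)))
    return(sprintf("schedule must contain columns: %s",
                   paste(.SCHEDULE_COLS, collapse = ", ")))
  if (nrow(sched) == 0L) return("schedule has no periods")
  o <- order(sched$start_sec)
  s <- sched[o, , drop = FALSE]
  if (s$start_sec[1] != 0)
    msgs <- c(msgs, "schedule must start at 0 s")
  if (any(s$end_sec <= s$start_sec))
    msgs <- c(msgs, "periods must have positive duration")
  if (nrow(s) > 1L && any(abs(s$start_sec[-1] - s$end_sec[-nrow(s)]) > 1e-9))
    msgs <- c(msgs, "periods must tile the session without gaps or overlap")
  if (!all(s$kind %in% c("background", "speaker_off", "probe")))
    msgs <- c(msgs, "period kind must be background, speaker_off or probe")
  if (length(msgs)) msgs else TRUE
}

#' Protocol: a realized daily test-session schedule
#'
#' A `Protocol` holds the design parameters of one daily conditioned-
#' suppression test session (duration, number of embedded probe periods, how
#' many of them are speaker-off, the catalog of probe stimuli, the ambient
#' background level) together with one realized schedule: an ordered set of
#' half-open periods \eqn{[start, end)} in seconds that tile the session.
#'
#' @slot sessionMinutes integer, session duration in minutes (default 60).
#' @slot nProbes integer, number of 1-min probe periods (default 10).
#' @slot nSpeakerOff integer, how many probes are speaker-off (default 2).
#' @slot probeCatalog data.frame with columns `kind` ("tone" or "BBN"),
#'   `freq_khz` (NA for BBN) and `level_db` (dB SPL in \[30, 90\]).
#' @slot backgroundLevel numeric, ambient broad-band noise level in dB SPL.
#' @slot schedule data.frame of periods (columns `period_index`, `start_sec`,
#'   `end_sec`, `kind`, `stimulus`, `freq_khz`, `level_db`).
#' @slot seed integer seed the schedule was drawn with.
#'
#' @seealso [buildProtocol()]
#' @exportClass Protocol
setClass("Protocol",
  representation(
    sessionMinutes = "integer",
    nProbes = "integer",
    nSpeakerOff = "integer",
    probeCatalog = "data.frame",
    backgroundLevel = "numeric",
    schedule = "data.frame",
    seed = "integer"
  )
)

setValidity("Protocol", function(object) {
  msgs <- character(0)
  if (object@sessionMinutes < 1L)
    msgs <- c(msgs, "sessionMinutes must be >= 1")
  if (object@nSpeakerOff > object@nProbes)
    msgs <- c(msgs, "nSpeakerOff must not exceed nProbes")
  if (object@nProbes > object@sessionMinutes)
    msgs <- c(msgs, "nProbes must not exceed sessionMinutes")
  sv <- .validSchedule(object@schedule)
  if (!isTRUE(sv)) msgs <- c(msgs, sv)
  else {
    sched <- object@schedule
    if (sum(sched$kind != "background") != object@nProbes)
      msgs <- c(msgs, "schedule must contain exactly nProbes probe periods")
    if (sum(sched$kind == "speaker_off") != object@nSpeakerOff)
      msgs <- c(msgs, "schedule must contain exactly nSpeakerOff speaker-off periods")
  }
  if (length(msgs)) msgs else TRUE
})

#' AnimalState: latent state of one simulated subject
#'
#' Simulation-only description of one animal: whether it was noise-exposed,
#' its latent tinnitus severity `tau` (0 = none, 1 = maximal; unobservable in
#' a real experiment and used here only to generate behavior and to validate
#' parameter recovery), the pitch of the tinnitus percept, its mean lever-press
#' rate under background noise, and the depth of trained suppression.
#'
#' @slot animalId character identifier.
#' @slot exposed logical, noise-exposure status.
#' @slot tau numeric in \[0, 1\], latent tinnitus severity.
#' @slot tinnitusPitch numeric, kHz, pitch of the tinnitus percept.
#' @slot lambdaBg numeric > 0, mean presses/min under background noise.
#' @slot cOff numeric in \[0, 1\], trained suppression depth: the fractional
#'   rate reduction during a period perceived as identical to speaker-off.
#'
#' @seealso [animalState()], [simulateSession()]
#' @exportClass AnimalState
setClass("AnimalState",
  representation(
    animalId = "character",
    exposed = "logical",
    tau = "numeric",
    tinnitusPitch = "numeric",
    lambdaBg = "numeric",
    cOff = "numeric"
  )
)

setValidity("AnimalState", function(object) {
  msgs <- character(0)
  if (object@tau < 0 || object@tau > 1)
    msgs <- c(msgs, "tau must lie in [0, 1]")
  if (!object@exposed && object@tau != 0)
    msgs <- c(msgs, "unexposed animals must have tau = 0")
  if (object@lambdaBg <= 0)
    msgs <- c(msgs, "lambdaBg must be > 0")
  if (object@cOff < 0 || object@cOff > 1)
    msgs <- c(msgs, "cOff must lie in [0, 1]")
  if (object@tinnitusPitch <= 0)
    msgs <- c(msgs, "tinnitusPitch must be > 0 kHz")
  if (length(msgs)) msgs else TRUE
})

#' SessionLog: timestamped lever presses for one session
#'
#' All press times are seconds from session start, ascending, within
#' \eqn{[0, end)}; the schedule is carried along so the log is self-describing.
#'
#' @slot animalId character identifier.
#' @slot session integer session index.
#' @slot pressTimes numeric vector of press times (s), ascending.
#' @slot schedule data.frame of periods (see [Protocol-class]).
#' @slot seed integer seed the session was simulated with (NA for real or
#'   hand-built logs).
#'
#' @seealso [simulateSession()], [epochCounts()], [sessionLogFromCounts()]
#' @exportClass SessionLog
setClass("SessionLog",
  representation(
    animalId = "character",
    session = "integer",
    pressTimes = "numeric",
    schedule = "data.frame",
    seed = "integer"
  )
)

setValidity("SessionLog", function(object) {
  msgs <- character(0)
  sv <- .validSchedule(object@schedule)
  if (!isTRUE(sv)) msgs <- c(msgs, sv)
  else {
    dur <- max(object@schedule$end_sec)
    pt <- object@pressTimes
    if (length(pt)) {
      if (is.unsorted(pt)) msgs <- c(msgs, "pressTimes must be ascending")
      if (any(pt < 0) || any(pt >= dur))
        msgs <- c(msgs, "pressTimes must lie within [0, session end)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' QCReport: session inclusion decision
#'
#' Conjoint inclusion criteria for one session: a minimum total lever-press
#' count and a minimum mean suppression ratio over background (BBN) minutes.
#' Boundary values pass (criteria are inclusive).
#'
#' @slot totalPresses integer, total lever presses in the session.
#' @slot meanBackgroundR numeric, mean of defined R over uncontaminated
#'   background minutes (NA if no such minute exists).
#' @slot passed logical.
#' @slot failureReasons character vector, empty when passed.
#' @slot thresholds numeric, the (minPresses, minBackgroundR) pair applied.
#'
#' @seealso [sessionQC()]
#' @exportClass QCReport
setClass("QCReport",
  representation(
    totalPresses = "integer",
    meanBackgroundR = "numeric",
    passed = "logical",
    failureReasons = "character",
    thresholds = "numeric"
  )
)

#' Micrograph: a single-channel intensity raster with an AOI mask
#'
#' Intensities are stored as a numeric matrix (rows = y, columns = x,
#' 0-based pixel coordinates in the API, 1-based internally as usual in R);
#' the area-of-interest mask is a logical matrix of the same shape.
#' `pixelArea` calibrates one pixel to physical area.
#'
#' @slot image numeric matrix of intensities.
#' @slot aoi logical matrix, TRUE inside the area of interest.
#' @slot pixelArea numeric > 0, physical area per pixel (e.g. um^2).
#' @slot animalId character.
#' @slot region character, anatomical region (e.g. "DCN", "vPFL/FL").
#' @slot side character, "ipsilateral" or "contralateral".
#' @slot id character, unique micrograph identifier.
#'
#' @seealso [synthMicrograph()], [thresholdImage()], [particleAnalysis()]
#' @exportClass Micrograph
setClass("Micrograph",
  representation(
    image = "matrix",
    aoi = "matrix",
    pixelArea = "numeric",
    animalId = "character",
    region = "character",
    side = "character",
    id = "character"
  )
)

setValidity("Micrograph", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@image), dim(object@aoi)))
    msgs <- c(msgs, "image and AOI mask must have identical dimensions")
  if (!is.logical(object@aoi))
    msgs <- c(msgs, "AOI mask must be logical")
  else if (!any(object@aoi))
    msgs <- c(msgs, "AOI must be non-empty")
  if (object@pixelArea <= 0)
    msgs <- c(msgs, "pixelArea must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' ParticleStats: immunoreactive-particle summary for one AOI
#'
#' @slot nParticles integer, discrete particles surviving the filters.
#' @slot stainedArea numeric, physical stained area (pixel count x pixelArea).
#' @slot aoiArea numeric, physical AOI area.
#' @slot percentArea numeric, 100 * stainedArea / aoiArea.
#' @slot thresholdUsed numeric, the intensity threshold applied.
#'
#' @seealso [particleAnalysis()]
#' @exportClass ParticleStats
setClass("ParticleStats",
  representation(
    nParticles = "integer",
    stainedArea = "numeric",
    aoiArea = "numeric",
    percentArea = "numeric",
    thresholdUsed = "numeric"
  )
)

setValidity("ParticleStats", function(object) {
  msgs <- character(0)
  if (object@nParticles < 0L) msgs <- c(msgs, "nParticles must be >= 0")
  if (object@percentArea < 0 || object@percentArea > 100)
    msgs <- c(msgs, "percentArea must lie in [0, 100]")
  if (length(msgs)) msgs else TRUE
})
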