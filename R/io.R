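.SESSION_COLS <- c("animal_id", "session", "t_sec")

.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Write a session log to CSV
#'
#' Two files: the press log (`animal_id`, `session`, `t_sec`) and a
#' companion schedule CSV (`period_index`, `start_sec`, `end_sec`, `kind`,
#' `stimulus`, `freq_khz`, `level_db`). Numeric fields are written at full
#' precision so a write/read round trip reproduces the log exactly.
#'
#' @param log a [SessionLog-class] object.
#' @param path destination for the press log CSV.
#' @param schedulePath destination for the schedule CSV; defaults to
#'   `path` with a `_schedule.csv` suffix.
#' @return `path`, invisibly.
#' @export
writeSessionCsv <- function(log, path,
                            schedulePath = sub("\\.csv$", "_schedule.csv", path)) {
  stopifnot(is(log, "SessionLog"))
  presses <- data.frame(animal_id = rep(log@animalId, length(log@pressTimes)),
                        session = rep(log@session, length(log@pressTimes)),
                        t_sec = .fmtNum(log@pressTimes),
                        stringsAsFactors = FALSE)
  utils::write.csv(presses, path, row.names = FALSE, quote = FALSE, na = "NA")
  s <- log@schedule
  sched <- data.frame(period_index = s$period_index,
                      start_sec = .fmtNum(s$start_sec),
                      end_sec = .fmtNum(s$end_sec),
                      kind = s$kind, stimulus = s$stimulus,
                      freq_khz = .fmtNum(s$freq_khz),
                      level_db = .fmtNum(s$level_db),
                      stringsAsFactors = FALSE)
  utils::write.csv(sched, schedulePath, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}

.checkCols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema violation in ", path, ": missing columns ",
         paste(miss, collapse = ", "))
}

#' Read a session log from CSV
#'
#' Inverse of [writeSessionCsv()]. Both LF and CRLF line endings are
#' accepted; schema violations are reported with line numbers (header is
#' line 1).
#'
#' @param path press log CSV path.
#' @param schedulePath companion schedule CSV path.
#' @return A [SessionLog-class] object.
#' @export
readSessionCsv <- function(path,
                           schedulePath = sub("\\.csv$", "_schedule.csv", path)) {
  if (!file.exists(path)) stop("press log file not found: ", path)
  if (!file.exists(schedulePath))
    stop("missing schedule file: ", schedulePath)
  presses <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkCols(presses, .SESSION_COLS, path)
  bad <- which(is.na(suppressWarnings(as.numeric(presses$t_sec))))
  if (length(bad))
    stop("schema violation in ", path, ": non-numeric t_sec at line(s) ",
         paste(bad + 1L, collapse = ", "))
  sched <- utils::read.csv(schedulePath, stringsAsFactors = FALSE,
                           colClasses = c(freq_khz = "numeric",
                                          level_db = "numeric"))
  .checkCols(sched, .SCHEDULE_COLS, schedulePath)
  animalId <- if (nrow(presses)) presses$animal_id[1] else "NA"
  session <- if (nrow(presses)) as.integer(presses$session[1]) else 1L
  new("SessionLog", animalId = animalId, session = session,
      pressTimes = as.numeric(presses$t_sec), schedule = sched,
      seed = NA_integer_)
}

#' Default run configuration
#'
#' All tunables of [runPipeline()] with their defaults: the session
#' protocol, cohort sizes matching the canonical design (24 exposed, 16
#' unexposed), QC thresholds (200 presses, mean background R 0.4), the
#' subgroup design (16 prominent + 8 weak), and the synthetic IHC contrast.
#'
#' @return nested list of configuration values.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    protocol = list(sessionMinutes = 60, nProbes = 10, nSpeakerOff = 2,
                    backgroundLevel = 60),
    cohort = list(nExposed = 24, nUnexposed = 16, nSessions = 10,
                  tauDist = c(2, 1), lambdaMedian = 15, lambdaSdlog = 0.5,
                  cOff = 0.85, tinnitusPitch = 20),
    qc = list(minPresses = 200, minBackgroundR = 0.4),
    classify = list(nProminent = 16, nWeak = 8),
    ihc = list(enabled = TRUE, nExposed = 4, nUnexposed = 3,
               fractionExposed = 0.08, fractionUnexposed = 0.04,
               method = "otsu", minSize = 4)
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Values omitted from the file keep their [defaultRunConfig()] defaults.
#' Thresholds are validated against their documented ranges.
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- .mergeConfig(defaultRunConfig(), yaml::read_yaml(path))
  validateRunConfig(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg nested configuration list.
#' @return `cfg`, invisibly; errors on out-of-range values.
#' @export
validateRunConfig <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), cfg$seed == round(cfg$seed))
  if (cfg$qc$minPresses < 0)
    stop("qc$minPresses must be >= 0")
  if (cfg$qc$minBackgroundR < 0 || cfg$qc$minBackgroundR > 1)
    stop("qc$minBackgroundR must lie in [0, 1]")
  with(cfg$protocol, {
    if (nSpeakerOff > nProbes || nProbes > sessionMinutes)
      stop("protocol requires nSpeakerOff <= nProbes <= sessionMinutes")
  })
  if (cfg$ihc$fractionExposed < 0 || cfg$ihc$fractionExposed > 1 ||
      cfg$ihc$fractionUnexposed < 0 || cfg$ihc$fractionUnexposed > 1)
    stop("ihc stained fractions must lie in [0, 1]")
  invisible(cfg)
}
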