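#' Per-minute press counts aligned to the schedule
#'
#' Bins press times into half-open 1-min epochs \eqn{[60k, 60(k+1))} and
#' carries each minute's period kind and stimulus from the schedule.
#'
#' @param log a [SessionLog-class] object.
#' @return data.frame with one row per minute: `minute` (0-based), `count`,
#'   `kind`, `stimulus`, `freq_khz`, `level_db`. Counts sum to the total
#'   number of presses.
#' @export
#' @examples
#' log <- sessionLogFromCounts(c(2, 1))
#' epochCounts(log)
epochCounts <- function(log) {
  stopifnot(is(log, "SessionLog"))
  sched <- log@schedule
  dur <- max(sched$end_sec)
  pt <- log@pressTimes
  if (length(pt) && (any(pt < 0) || any(pt >= dur)))
    stop("press times outside session bounds [0, ", dur, ")")
  mt <- .minuteTable(sched)
  mt$count <- as.integer(tabulate(floor(pt / 60) + 1L, nbins = nrow(mt)))
  mt[, c("minute", "count", "kind", "stimulus", "freq_khz", "level_db")]
}

#' The suppression ratio R = B / (A + B)
#'
#' A is the lever-press count of the preceding 1-min segment, B that of the
#' current segment. R is 0.5 when pressing is unchanged, 0 when the current
#' minute has no presses, and 1 when the preceding minute had none. When
#' A + B = 0 the ratio is undefined and returned as NA; undefined epochs are
#' excluded from all downstream means.
#'
#' @param A,B non-negative press counts (vectorized).
#' @return numeric R in \[0, 1\], NA where A + B = 0.
#' @export
#' @examples
#' suppressionRatio(7, 7)   # 0.5
#' suppressionRatio(9, 0)   # 0
#' suppressionRatio(0, 4)   # 1
suppressionRatio <- function(A, B) {
  if (any(A < 0, na.rm = TRUE) || any(B < 0, na.rm = TRUE))
    stop("press counts must be non-negative")
  tot <- A + B
  r <- ifelse(tot > 0, B / tot, NA_real_)
  as.numeric(r)
}

#' Running suppression ratio over a session
#'
#' Applies R = B/(A+B) to successive 1-min epochs: the value at minute k uses
#' A = count(k-1) and B = count(k). Minute 0 has no preceding segment and is
#' undefined (NA).
#'
#' @param counts either the data.frame returned by [epochCounts()] or a bare
#'   numeric vector of per-minute counts (at least 2 minutes).
#' @return data.frame (the epoch series): `minute`, `count`, `prev_count`,
#'   `R`, plus `kind`/`stimulus`/`freq_khz`/`level_db` when available.
#' @export
#' @examples
#' runningR(c(10, 10, 0))$R   # NA 0.5 0
runningR <- function(counts) {
  if (is.data.frame(counts)) {
    df <- counts
    cnt <- df$count
  } else {
    cnt <- as.numeric(counts)
    df <- data.frame(minute = seq_along(cnt) - 1L, count = cnt)
  }
  if (length(cnt) < 2L)
    stop("need at least 2 minutes to compute a running suppression ratio")
  prev <- c(NA_real_, cnt[-length(cnt)])
  df$prev_count <- prev
  df$R <- c(NA_real_, suppressionRatio(prev[-1], cnt[-1]))
  df
}

## Background minutes eligible for the QC mean: background kind, defined R,
## not the minute immediately after a probe/speaker-off (A contaminated).
.qcBackgroundIdx <- function(series) {
  afterProbe <- c(FALSE, series$kind[-nrow(series)] != "background")
  which(series$kind == "background" & !afterProbe & !is.na(series$R))
}

#' Session inclusion quality control
#'
#' A session enters analysis only if (a) it contains at least `minPresses`
#' total lever presses and (b) the mean suppression ratio over background
#' (BBN) minutes is at least `minBackgroundR`. Both criteria are inclusive at
#' the boundary and applied conjointly. The background mean uses defined-R
#' background minutes only, excluding the minute immediately following a
#' probe (whose A count is contaminated by the probe response).
#'
#' @param log a [SessionLog-class] object.
#' @param series the epoch series from [runningR()]; computed from `log`
#'   when omitted.
#' @param minPresses minimum total press count (default 200).
#' @param minBackgroundR minimum mean background R (default 0.4).
#' @return A [QCReport-class] object.
#' @export
#' @examples
#' qcPassed(sessionQC(sessionLogFromCounts(rep(5, 60))))
sessionQC <- function(log, series = NULL,
                      minPresses = 200, minBackgroundR = 0.4) {
  stopifnot(is(log, "SessionLog"))
  if (is.null(series)) series <- runningR(epochCounts(log))
  total <- length(log@pressTimes)
  idx <- .qcBackgroundIdx(series)
  reasons <- character(0)
  if (total < minPresses)
    reasons <- c(reasons,
                 sprintf("press-count: %d total presses < %g", total, minPresses))
  if (length(idx) == 0L) {
    meanBg <- NA_real_
    reasons <- c(reasons, "background-R: no defined background-R minute")
  } else {
    meanBg <- mean(series$R[idx])
    if (meanBg < minBackgroundR)
      reasons <- c(reasons,
                   sprintf("background-R: mean background R %.3f < %g",
                           meanBg, minBackgroundR))
  }
  new("QCReport", totalPresses = as.integer(total),
      meanBackgroundR = meanBg, passed = length(reasons) == 0L,
      failureReasons = reasons,
      thresholds = c(minPresses = minPresses,
                     minBackgroundR = minBackgroundR))
}

#' Suppression ratios of the probe minutes
#'
#' Extracts one row per probe period (tone/BBN probes and speaker-off
#' periods) with a defined suppression ratio; A is the count of the
#' preceding (background) minute. Undefined rows are dropped; their number
#' is recorded in the `n_undefined` attribute.
#'
#' @param series the epoch series from [runningR()] (must carry period kinds).
#' @return data.frame with columns `minute`, `stimulus`, `freq_khz`,
#'   `level_db`, `A`, `B`, `R`; attribute `n_undefined` counts dropped rows.
#' @export
probeR <- function(series) {
  if (is.null(series$kind))
    stop("epoch series must carry period kinds; epoch a SessionLog first")
  probe <- series[series$kind %in% c("probe", "speaker_off"), , drop = FALSE]
  undef <- is.na(probe$R)
  out <- probe[!undef, c("minute", "stimulus", "freq_khz", "level_db",
                         "prev_count", "count", "R")]
  names(out)[names(out) == "prev_count"] <- "A"
  names(out)[names(out) == "count"] <- "B"
  rownames(out) <- NULL
  attr(out, "n_undefined") <- sum(undef)
  out
}

#' Score a cohort: epoch, QC-filter and pool probe ratios
#'
#' Runs [epochCounts()], [runningR()], [sessionQC()] and [probeR()] over
#' every session of a simulated or loaded cohort and pools probe rows from
#' QC-passing sessions.
#'
#' @param cohort list with `animals` and `sessions` as returned by
#'   [simulateCohort()].
#' @param minPresses,minBackgroundR QC thresholds, see [sessionQC()].
#' @return list with `probes` (pooled data.frame: animal_id, session,
#'   stimulus, freq_khz, level_db, A, B, R from passing sessions only) and
#'   `qc` (data.frame: animal_id, session, total_presses,
#'   mean_background_r, passed, reasons).
#' @export
scoreCohort <- function(cohort, minPresses = 200, minBackgroundR = 0.4) {
  qcRows <- list(); probeRows <- list()
  for (id in names(cohort$sessions)) {
    for (log in cohort$sessions[[id]]) {
      series <- runningR(epochCounts(log))
      qc <- sessionQC(log, series, minPresses, minBackgroundR)
      qcRows[[length(qcRows) + 1L]] <- data.frame(
        animal_id = id, session = log@session,
        total_presses = qc@totalPresses,
        mean_background_r = qc@meanBackgroundR,
        passed = qc@passed,
        reasons = paste(qc@failureReasons, collapse = "; "),
        stringsAsFactors = FALSE)
      if (qc@passed) {
        pr <- probeR(series)
        if (nrow(pr)) {
          pr$animal_id <- id
          pr$session <- log@session
          probeRows[[length(probeRows) + 1L]] <- pr
        }
      }
    }
  }
  qcTab <- if (length(qcRows)) do.call(rbind, qcRows) else
    data.frame(animal_id = character(0), session = integer(0),
               total_presses = integer(0), mean_background_r = numeric(0),
               passed = logical(0), reasons = character(0))
  probeTab <- if (length(probeRows)) do.call(rbind, probeRows) else
    data.frame(minute = integer(0), stimulus = character(0),
               freq_khz = numeric(0), level_db = numeric(0),
               A = numeric(0), B = numeric(0), R = numeric(0),
               animal_id = character(0), session = integer(0))
  rownames(probeTab) <- NULL
  list(probes = probeTab, qc = qcTab)
}
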