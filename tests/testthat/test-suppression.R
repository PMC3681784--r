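mkLog <- function(times, minutes = 2) {
  new("SessionLog", animalId = "a", session = 1L, pressTimes = times,
      schedule = data.frame(period_index = 1L, start_sec = 0,
                            end_sec = 60 * minutes, kind = "background",
                            stimulus = "BBN", freq_khz = NA_real_,
                            level_db = 60, stringsAsFactors = FALSE),
      seed = NA_integer_)
}

test_that("epoching uses half-open minute bins and conserves presses", {
  ec <- epochCounts(mkLog(c(10, 59.9, 60.0)))
  expect_equal(ec$count, c(2L, 1L))
  expect_equal(epochCounts(mkLog(numeric(0)))$count, c(0L, 0L))
  # the class itself refuses out-of-bounds presses at construction ...
  expect_error(mkLog(c(10, 120)), "within \\[0, session end\\)")
  # ... and epoching re-checks in case a log was mutated past validity
  tampered <- mkLog(c(10, 50))
  slot(tampered, "pressTimes", check = FALSE) <- c(10, 120)
  expect_error(epochCounts(tampered), "outside session bounds")

  set.seed(4)
  times <- sort(runif(500, 0, 3600))
  log <- mkLog(times, minutes = 60)
  expect_equal(sum(epochCounts(log)$count), 500L)
  expect_equal(nrow(epochCounts(log)), 60L)
})

test_that("the suppression ratio reproduces its boundary behaviors", {
  expect_equal(suppressionRatio(7, 7), 0.5)
  expect_equal(suppressionRatio(9, 0), 0)
  expect_equal(suppressionRatio(0, 4), 1)
  expect_true(is.na(suppressionRatio(0, 0)))
  expect_error(suppressionRatio(-1, 3), "non-negative")
})

test_that("R is bounded, antisymmetric and monotone in the current count", {
  set.seed(7)
  A <- rpois(500, 8); B <- rpois(500, 8)
  r <- suppressionRatio(A, B)
  def <- !is.na(r)
  expect_true(all(r[def] >= 0 & r[def] <= 1))
  expect_equal(r[def] + suppressionRatio(B, A)[def], rep(1, sum(def)))
  # strictly increasing in B at fixed A > 0
  expect_true(all(diff(suppressionRatio(5, 0:20)) > 0))
})

test_that("the running ratio matches direct per-pair evaluation", {
  expect_equal(runningR(c(10, 10, 0))$R, c(NA, 0.5, 0))
  expect_equal(runningR(c(0, 5, 5, 0))$R, c(NA, 1, 0.5, 0))
  expect_equal(runningR(rep(7, 10))$R, c(NA, rep(0.5, 9)))
  expect_error(runningR(5), "at least 2 minutes")

  set.seed(11)
  for (i in 1:1000) {
    cnt <- rpois(60, sample(c(0.5, 2, 10), 1))
    got <- runningR(cnt)$R
    want <- c(NA_real_, vapply(2:60, function(k) {
      tot <- cnt[k - 1] + cnt[k]
      if (tot == 0) NA_real_ else cnt[k] / tot
    }, numeric(1)))
    expect_identical(got, want)
  }
})

test_that("session QC applies both criteria conjointly with inclusive boundaries", {
  # exactly 200 presses, mean background R exactly 0.40 -> pass
  atBoundary <- sessionWithMeanBgR(200, 0.40)
  qc <- sessionQC(atBoundary)
  expect_true(qcPassed(qc))
  expect_equal(qc@totalPresses, 200L)
  expect_equal(qc@meanBackgroundR, 0.40)

  # 199 presses with healthy background behavior -> fail on press count only
  fewPresses <- sessionWithTotal(199)
  qc2 <- sessionQC(fewPresses)
  expect_false(qcPassed(qc2))
  expect_match(qc2@failureReasons, "press-count", all = FALSE)
  expect_false(any(grepl("background-R", qc2@failureReasons)))

  # 400 presses but sluggish background (mean R 0.39) -> fail on background R
  sluggish <- sessionWithMeanBgR(400, 0.39)
  qc3 <- sessionQC(sluggish)
  expect_false(qcPassed(qc3))
  expect_match(qc3@failureReasons, "background-R", all = FALSE)
  expect_equal(qc3@meanBackgroundR, 0.39)

  # no defined background minute -> explicit failure reason
  silent <- sessionLogFromCounts(rep(0, 60))
  expect_match(sessionQC(silent)@failureReasons, "no defined", all = FALSE)
})

test_that("QC ignores probe minutes and the contaminated minute after them", {
  p <- buildProtocol(seed = 5)
  a <- animalState("E07", exposed = TRUE, tau = 0.9)
  series <- runningR(epochCounts(simulateSession(a, p, seed = 5)))
  idx <- tinnscreen:::.qcBackgroundIdx(series)
  expect_true(all(series$kind[idx] == "background"))
  expect_true(all(series$kind[idx - 1] == "background"))
  expect_false(0 %in% series$minute[idx])
})

test_that("the QC decision is invariant to press-time jitter within minutes", {
  set.seed(13)
  counts <- rpois(60, 4)
  base <- sessionLogFromCounts(counts)
  qcBase <- sessionQC(base)
  for (i in 1:10) {
    t0 <- pressTimes(base)
    jit <- (t0 %/% 60) * 60 + runif(length(t0), 0, 60)
    log <- new("SessionLog", animalId = "a", session = 1L,
               pressTimes = sort(jit), schedule = schedule(base),
               seed = NA_integer_)
    qc <- sessionQC(log)
    expect_equal(qcPassed(qc), qcPassed(qcBase))
    expect_equal(qc@meanBackgroundR, qcBase@meanBackgroundR)
  }
})

test_that("probe extraction returns one defined row per probe period", {
  p <- buildProtocol(seed = 8)
  a <- animalState("U03", lambdaBg = 25)
  series <- runningR(epochCounts(simulateSession(a, p, seed = 8)))
  pr <- probeR(series)
  expect_equal(nrow(pr) + attr(pr, "n_undefined"), 10L)
  expect_true(all(pr$R >= 0 & pr$R <= 1))
  expect_equal(pr$R, suppressionRatio(pr$A, pr$B))

  # probes preceded by a silent minute, with presses during the probe -> R = 1
  counts <- rep(0L, 60)
  probeMin <- c(10, 20, 30)
  counts[probeMin + 1] <- 5L
  kinds <- rep("background", 60); kinds[probeMin + 1] <- "probe"
  sched <- data.frame(period_index = seq_len(60), start_sec = (0:59) * 60,
                      end_sec = (1:60) * 60, kind = kinds,
                      stimulus = ifelse(kinds == "probe", "tone", "BBN"),
                      freq_khz = ifelse(kinds == "probe", 20, NA),
                      level_db = 60, stringsAsFactors = FALSE)
  log <- sessionLogFromCounts(counts, schedule = sched)
  pr2 <- probeR(runningR(epochCounts(log)))
  expect_equal(pr2$R, rep(1, 3))
  # probe minute with A = B
  counts2 <- rep(4L, 60)
  log2 <- sessionLogFromCounts(counts2, schedule = sched)
  expect_equal(probeR(runningR(epochCounts(log2)))$R, rep(0.5, 3))
})
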