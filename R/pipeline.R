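.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

## Per-animal x level mean R for one stimulus, keeping only levels observed
## for every animal (the mixed ANOVA needs a complete design).
.animalLevelMeans <- function(probes, stimulus) {
  sel <- probes[probes$stimulus == stimulus & !is.na(probes$level_db), ,
                drop = FALSE]
  if (nrow(sel) == 0L) return(NULL)
  key <- interaction(sel$animal_id, sel$level_db, drop = TRUE)
  agg <- do.call(rbind, lapply(split(sel, key), function(d)
    data.frame(animal_id = d$animal_id[1], level_db = d$level_db[1],
               mean_r = mean(d$R), stringsAsFactors = FALSE)))
  nAnimals <- length(unique(agg$animal_id))
  full <- names(which(table(agg$level_db) == nAnimals))
  agg <- agg[agg$level_db %in% as.numeric(full), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Plot group discrimination functions
#'
#' @param pooled the `group` table from [discriminationFunction()].
#' @param title plot title.
#' @return a ggplot object: mean R (+/- SEM) against presentation level,
#'   with the speaker-off point leftmost.
#' @export
plotDiscrimination <- function(pooled, title = "Discrimination function") {
  d <- pooled
  d$x <- ifelse(is.na(d$level_db), "OFF", as.character(d$level_db))
  lv <- c("OFF", sort(unique(d$level_db[!is.na(d$level_db)])))
  d$x <- factor(d$x, levels = as.character(lv))
  ggplot2::ggplot(d, ggplot2::aes(x = x, y = mean_r,
                                  group = group, colour = group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_r - sem_r,
                                        ymax = mean_r + sem_r),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Presentation level (dB SPL)",
                  y = "Suppression ratio (R)", title = title) +
    ggplot2::theme_classic()
}

#' Run the full analysis pipeline
#'
#' Simulate -> score -> QC -> discrimination functions -> subgroup
#' classification (when the exposed group meets the 16 + 8 design) -> mixed
#' ANOVA group comparison, plus the synthetic-IHC quantification and
#' t-tests. When `outDir` is given, per-stage CSV tables, a JSON summary, a
#' seed/config manifest and a discrimination-function plot (PDF) are
#' written; re-running with the same configuration reproduces the CSVs
#' byte-identically.
#'
#' If no session passes QC the summary (with 0 analyzable sessions) is
#' still written, and inference aborts with a clear message.
#'
#' @param config nested configuration list, see [defaultRunConfig()] /
#'   [readRunConfig()].
#' @param outDir optional output directory (created if needed).
#' @return the summary list, invisibly: sections `psychophysics`
#'   (session counts, ANOVA table, subgroup sizes, group means) and `ihc`
#'   (per-group percent-area means and the t-test).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL) {
  validateRunConfig(config)
  seed <- as.integer(config$seed)
  stageSeeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 4))

  cohort <- .stage("simulate", do.call(simulateCohort,
    c(config$cohort, list(seed = stageSeeds[1],
                          protocolArgs = config$protocol))))
  scores <- .stage("score", scoreCohort(cohort,
    minPresses = config$qc$minPresses,
    minBackgroundR = config$qc$minBackgroundR))

  nPass <- sum(scores$qc$passed)
  summary <- list(
    seed = seed,
    psychophysics = list(
      n_animals = nrow(cohort$animals),
      n_sessions = nrow(scores$qc),
      n_analyzable_sessions = nPass,
      n_excluded_sessions = nrow(scores$qc) - nPass
    )
  )

  writeOutputs <- function() {
    if (is.null(outDir)) return(invisible(NULL))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores$qc, file.path(outDir, "qc.csv"),
                     row.names = FALSE)
    utils::write.csv(scores$probes, file.path(outDir, "probes.csv"),
                     row.names = FALSE)
    yaml::write_yaml(config, file.path(outDir, "config.yaml"))
    manifest <- list(seed = seed, stage_seeds = stageSeeds,
                     config_md5 = unname(tools::md5sum(
                       file.path(outDir, "config.yaml"))),
                     package_version =
                       as.character(utils::packageVersion("tinnscreen")))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    invisible(NULL)
  }

  if (nPass == 0L) {
    summary$psychophysics$note <-
      "no session passed QC; inference aborted"
    writeOutputs()
    stop("[stage qc] 0 analyzable sessions: every session failed the ",
         "inclusion criteria; inference aborted")
  }

  groups <- stats::setNames(
    ifelse(cohort$animals$exposed, "exposed", "unexposed"),
    cohort$animals$animal_id)
  haveAnimals <- unique(scores$probes$animal_id)

  disc <- .stage("discrimination", {
    out <- list()
    for (stim in intersect(c("tone", "BBN"), unique(scores$probes$stimulus)))
      out[[stim]] <- discriminationFunction(scores$probes, stim,
                                            groups = groups[haveAnimals])
    out
  })
  summary$psychophysics$group_means <-
    lapply(disc, function(d) d$group)

  classifyTab <- NULL
  exposedIds <- cohort$animals$animal_id[cohort$animals$exposed]
  need <- config$classify$nProminent + config$classify$nWeak
  if (sum(exposedIds %in% haveAnimals) >= need) {
    classifyTab <- .stage("classify", {
      m <- meanProbeR(scores$probes[scores$probes$animal_id %in% exposedIds, ],
                      freqKhz = config$cohort$tinnitusPitch)
      classifySubgroups(m, seed = stageSeeds[2],
                        nProminent = config$classify$nProminent,
                        nWeak = config$classify$nWeak)
    })
    summary$psychophysics$subgroups <-
      as.list(table(classifyTab$group))
  } else {
    summary$psychophysics$subgroups <- sprintf(
      "skipped: %d exposed animals with data, design needs %d",
      sum(exposedIds %in% haveAnimals), need)
  }

  anova <- .stage("inference", {
    alm <- .animalLevelMeans(scores$probes, "tone")
    if (is.null(alm) || length(unique(alm$level_db)) < 2L) NULL else {
      alm$group <- groups[alm$animal_id]
      groupCompare(alm)
    }
  })
  summary$psychophysics$anova_tone <- anova

  if (isTRUE(config$ihc$enabled)) {
    ihc <- .stage("quantify-ihc", {
      syn <- synthIhcCohort(nExposed = config$ihc$nExposed,
                            nUnexposed = config$ihc$nUnexposed,
                            fractionExposed = config$ihc$fractionExposed,
                            fractionUnexposed = config$ihc$fractionUnexposed,
                            seed = stageSeeds[3])
      q <- quantifyCohort(syn$micrographs, method = config$ihc$method,
                          minSize = config$ihc$minSize)
      exposed <- q$animals$percent_area[grepl("^E", q$animals$animal_id)]
      unexposed <- q$animals$percent_area[grepl("^U", q$animals$animal_id)]
      list(table = q, ttest = ihcGroupTTest(exposed, unexposed))
    })
    summary$ihc <- list(
      percent_area = ihc$table$animals,
      t = ihc$ttest$t, df = ihc$ttest$df, p = ihc$ttest$p,
      mean_exposed = ihc$ttest$mean_exposed,
      mean_unexposed = ihc$ttest$mean_unexposed)
  }

  writeOutputs()
  if (!is.null(outDir)) {
    for (stim in names(disc))
      utils::write.csv(disc[[stim]]$group,
                       file.path(outDir, sprintf("discrimination_%s.csv", stim)),
                       row.names = FALSE)
    if (!is.null(classifyTab))
      utils::write.csv(classifyTab, file.path(outDir, "subgroups.csv"),
                       row.names = FALSE)
    if (isTRUE(config$ihc$enabled))
      utils::write.csv(summary$ihc$percent_area,
                       file.path(outDir, "ihc.csv"), row.names = FALSE)
    if ("tone" %in% names(disc)) {
      grDevices::pdf(file.path(outDir, "discrimination.pdf"), 6, 4)
      print(plotDiscrimination(disc$tone$group,
                               "20 kHz tone discrimination"))
      grDevices::dev.off()
    }
  }
  invisible(summary)
}
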