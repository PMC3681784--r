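#' Psychophysical discrimination function
#'
#' Mean suppression ratio (with dispersion) per presentation level for one
#' probe stimulus, with the speaker-off point reported alongside (level NA,
#' ordered first). Pooling gives every animal equal weight: per-animal means
#' by level are computed first, then averaged; the SEM is across animals.
#'
#' @param probes pooled probe table (QC-passing sessions only), as returned
#'   in `scoreCohort()$probes`: must contain `animal_id`, `stimulus`,
#'   `level_db`, `R`.
#' @param stimulus "tone" or "BBN"; rows of this stimulus plus all
#'   speaker-off rows are used.
#' @param groups optional named character vector mapping animal_id to a group
#'   label; when supplied the pooled table is computed per group.
#' @return list with `animal` (animal_id, stimulus, level_db, mean_r, n) and
#'   `group` (group, stimulus, level_db, mean_r, sem_r — NA when only one
#'   animal contributes — and n_animals). Levels ascend; speaker-off first.
#' @export
discriminationFunction <- function(probes, stimulus, groups = NULL) {
  if (!stimulus %in% probes$stimulus)
    stop("stimulus '", stimulus, "' absent from the probe table")
  sel <- probes[probes$stimulus %in% c(stimulus, "speaker_off"), , drop = FALSE]
  sel$stimulus[sel$stimulus == "speaker_off"] <- "speaker_off"

  ## paste keys, not interaction(): the speaker-off level is NA and
  ## interaction() would silently drop those rows in split()
  key <- paste(sel$animal_id, sel$stimulus,
               ifelse(is.na(sel$level_db), "off", sel$level_db))
  agg <- do.call(rbind, lapply(split(sel, key), function(d) {
    data.frame(animal_id = d$animal_id[1], stimulus = d$stimulus[1],
               level_db = d$level_db[1], mean_r = mean(d$R), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  ## speaker-off (level NA) sorts first; order() would otherwise push NA last
  lvKey <- function(x) ifelse(is.na(x), -Inf, x)
  agg <- agg[order(agg$animal_id, lvKey(agg$level_db)), ]
  rownames(agg) <- NULL

  grp <- if (is.null(groups)) rep("all", nrow(agg)) else {
    miss <- setdiff(unique(agg$animal_id), names(groups))
    if (length(miss))
      stop("no group label for animals: ", paste(miss, collapse = ", "))
    unname(groups[agg$animal_id])
  }
  agg$group <- grp
  gkey <- paste(agg$group, agg$stimulus,
                ifelse(is.na(agg$level_db), "off", agg$level_db))
  pooled <- do.call(rbind, lapply(split(agg, gkey), function(d) {
    data.frame(group = d$group[1], stimulus = d$stimulus[1],
               level_db = d$level_db[1], mean_r = mean(d$mean_r),
               sem_r = if (nrow(d) > 1)
                 stats::sd(d$mean_r) / sqrt(nrow(d)) else NA_real_,
               n_animals = nrow(d), stringsAsFactors = FALSE)
  }))
  pooled <- pooled[order(pooled$group, lvKey(pooled$level_db)), ]
  rownames(pooled) <- NULL
  agg$group <- NULL
  list(animal = agg, group = pooled)
}

#' Mean 20 kHz probe suppression ratio per animal
#'
#' The ranking statistic for subgroup classification: each animal's mean R
#' over tone-probe minutes at the diagnostic frequency, across all
#' QC-passing sessions (equal weight per probe minute).
#'
#' @param probes pooled probe table (see [discriminationFunction()]).
#' @param freqKhz diagnostic frequency (default 20 kHz).
#' @return data.frame: `animal_id`, `mean_r`, `n` probe minutes.
#' @export
meanProbeR <- function(probes, freqKhz = 20) {
  sel <- probes[probes$stimulus == "tone" &
                !is.na(probes$freq_khz) & probes$freq_khz == freqKhz, ,
                drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no tone probes at ", freqKhz, " kHz in the probe table")
  out <- do.call(rbind, lapply(split(sel, sel$animal_id), function(d) {
    data.frame(animal_id = d$animal_id[1], mean_r = mean(d$R), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classify exposed animals into tinnitus subgroups
#'
#' Implements the prominent/weak classification and treatment assignment:
#' exposed animals are ranked ascending by their mean suppression ratio
#' during 20 kHz probe periods; the 16 with the lowest means are designated
#' prominent tinnitus and randomly halved (seeded) into antagonist and
#' no-drug subgroups of 8; the remaining 8 (highest ratios) are weak
#' tinnitus and receive the agonist. Ties are broken by animal_id order
#' (stable ranking).
#'
#' @param exposedMeans data.frame with `animal_id` and `mean_r` (one row per
#'   exposed animal), e.g. from [meanProbeR()].
#' @param seed integer seed for the random 8/8 split.
#' @param nProminent,nWeak design counts (defaults 16 and 8).
#' @return data.frame: `animal_id`, `mean_r`, `rank` (1 = lowest ratio),
#'   `tinnitus` ("prominent"/"weak"), `group` (one of
#'   exposed_prominent_antagonist, exposed_prominent_no_drug,
#'   exposed_weak_agonist), ordered by rank.
#' @export
#' @examples
#' m <- data.frame(animal_id = sprintf("E%02d", 1:24), mean_r = (1:24) / 30)
#' table(classifySubgroups(m, seed = 1)$tinnitus)
classifySubgroups <- function(exposedMeans, seed = 1L,
                              nProminent = 16L, nWeak = 8L) {
  need <- nProminent + nWeak
  if (nrow(exposedMeans) < need)
    stop("subgroup design needs ", need, " exposed animals (",
         nProminent, " prominent + ", nWeak, " weak); got ",
         nrow(exposedMeans))
  if (anyDuplicated(exposedMeans$animal_id))
    stop("duplicate animal_id in exposedMeans")
  ## stable sort: ties resolved by animal_id order
  o <- order(exposedMeans$mean_r, exposedMeans$animal_id)
  out <- exposedMeans[o, c("animal_id", "mean_r"), drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tinnitus <- ifelse(out$rank <= nProminent, "prominent", "weak")
  out$group <- "exposed_weak_agonist"
  antag <- withr::with_seed(seed,
    sample(out$animal_id[out$tinnitus == "prominent"], nProminent %/% 2L))
  out$group[out$tinnitus == "prominent"] <-
    ifelse(out$animal_id[out$tinnitus == "prominent"] %in% antag,
           "exposed_prominent_antagonist", "exposed_prominent_no_drug")
  rownames(out) <- NULL
  out
}

#' Mixed-design ANOVA group comparison
#'
#' Classical two-way mixed (repeated-measures) ANOVA on per-animal,
#' per-level mean suppression ratios: group is the between-subjects factor,
#' presentation level the within-subjects factor. Speaker-off rows are
#' excluded before fitting (as the analysis convention requires). The
#' between-stratum F tests the group main effect against subjects-within-
#' groups; level and group x level are tested against the within error.
#' No sphericity correction is applied; this is recorded in the output.
#'
#' @param data long data.frame with columns `animal_id`, `group`, `level_db`
#'   and `mean_r` (one row per animal x level). Rows with NA `level_db`
#'   (speaker-off) are dropped.
#' @return data.frame with rows `group`, `level`, `group:level`: columns
#'   `effect`, `df1`, `df2`, `F`, `p`; attribute `sphericity_correction`
#'   is "none".
#' @export
groupCompare <- function(data) {
  data <- data[!is.na(data$level_db), , drop = FALSE]
  if (length(unique(data$group)) < 2L)
    stop("need at least 2 groups")
  if (length(unique(data$level_db)) < 2L)
    stop("need at least 2 presentation levels")
  tab <- table(data$group, data$level_db)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)
    stop("empty group x level cells: ",
         paste(sprintf("%s x %s dB", rownames(tab)[empty[, 1]],
                       colnames(tab)[empty[, 2]]), collapse = ", "))
  }
  d <- data.frame(
    r = data$mean_r,
    group = factor(data$group),
    level = factor(data$level_db),
    animal = factor(data$animal_id)
  )
  fit <- stats::aov(r ~ group * level + Error(animal), data = d)
  sm <- summary(fit)
  btw <- sm[["Error: animal"]][[1]]
  wth <- sm[["Error: Within"]][[1]]
  pick <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    resid <- grep("Residuals", rownames(tab))
    c(df1 = tab[i, "Df"], df2 = tab[resid, "Df"],
      F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  res <- rbind(pick(btw, "group"), pick(wth, "level"),
               pick(wth, "group:level"))
  out <- data.frame(effect = c("group", "level", "group:level"),
                    df1 = res[, "df1"], df2 = res[, "df2"],
                    F = res[, "F"], p = res[, "p"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sphericity_correction") <- "none"
  out
}

#' Uncorrected independent t-test on percent-area immunoreactivity
#'
#' Two-sample equal-variance t-test (uncorrected for multiple comparisons),
#' two-sided, as used to compare exposed and unexposed percent-area values
#' region by region. When both groups have zero variance: equal means give
#' t = 0, p = 1; unequal means give t = +/-Inf, p = 0.
#'
#' @param exposedValues,unexposedValues numeric vectors (n >= 2 each).
#' @return list: `t`, `df`, `p`, `mean_exposed`, `mean_unexposed`. The
#'   statistic's sign follows `exposedValues - unexposedValues`.
#' @export
#' @examples
#' ihcGroupTTest(c(1, 2, 3), c(4, 5, 6))$t   # -3.674
ihcGroupTTest <- function(exposedValues, unexposedValues) {
  stopifnot(length(exposedValues) >= 2L, length(unexposedValues) >= 2L)
  df <- length(exposedValues) + length(unexposedValues) - 2L
  if (stats::sd(exposedValues) == 0 && stats::sd(unexposedValues) == 0) {
    diff <- mean(exposedValues) - mean(unexposedValues)
    return(list(t = if (diff == 0) 0 else sign(diff) * Inf,
                df = df, p = if (diff == 0) 1 else 0,
                mean_exposed = mean(exposedValues),
                mean_unexposed = mean(unexposedValues)))
  }
  ht <- stats::t.test(exposedValues, unexposedValues, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       mean_exposed = mean(exposedValues),
       mean_unexposed = mean(unexposedValues))
}
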