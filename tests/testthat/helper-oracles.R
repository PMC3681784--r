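# Independent brute-force oracles used to validate the package's own
# implementations. They share no code with the functions they check.

# Flood-fill connected components, 8-connectivity, stack-based.
floodFillLabels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextLab <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nextLab <- nextLab + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nextLab
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nextLab
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Column-major first-appearance labels are label-permutation canonical form;
# both implementations use it, but canonicalize anyway for safety.
canonLabels <- function(lab) {
  v <- lab[lab != 0L]
  lab[lab != 0L] <- match(v, unique(v))
  lab
}

# Two-way mixed (split-plot) ANOVA by explicit sums of squares on a
# balanced design: a groups x s subjects/group x l levels.
mixedAnovaSS <- function(d) {
  r <- d$mean_r
  grand <- mean(r)
  a <- length(unique(d$group))
  l <- length(unique(d$level_db))
  s <- length(unique(d$animal_id)) / a
  subjMeans <- tapply(r, d$animal_id, mean)
  groupMeans <- tapply(r, d$group, mean)
  levelMeans <- tapply(r, d$level_db, mean)
  cellMeans <- tapply(r, list(d$group, d$level_db), mean)
  ssTotal <- sum((r - grand)^2)
  ssBetweenSubj <- l * sum((subjMeans - grand)^2)
  ssGroup <- s * l * sum((groupMeans - grand)^2)
  ssSubjWithin <- ssBetweenSubj - ssGroup
  ssLevel <- a * s * sum((levelMeans - grand)^2)
  ssCells <- s * sum((sweep(sweep(cellMeans, 1, groupMeans), 2,
                            levelMeans) + grand)^2)
  ssError <- ssTotal - ssBetweenSubj - ssLevel - ssCells
  dfGroup <- a - 1; dfSubj <- a * (s - 1)
  dfLevel <- l - 1; dfInter <- (a - 1) * (l - 1)
  dfError <- a * (s - 1) * (l - 1)
  list(
    F_group = (ssGroup / dfGroup) / (ssSubjWithin / dfSubj),
    F_level = (ssLevel / dfLevel) / (ssError / dfError),
    F_inter = (ssCells / dfInter) / (ssError / dfError),
    df = c(group = dfGroup, subj = dfSubj, level = dfLevel,
           inter = dfInter, error = dfError)
  )
}

# Exhaustive Otsu: try every midpoint between consecutive distinct values,
# maximize between-class variance.
otsuExhaustive <- function(v) {
  u <- sort(unique(v))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf; bestT <- cand[1]
  for (t in cand) {
    lo <- v[v < t]; hi <- v[v >= t]
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; bestT <- t }
  }
  bestT
}

# A session whose background epochs have an exactly prescribed mean R:
# counts [a, b, 0, 0, ...] give defined ratios {b/(a+b), 0} and hence mean
# b / (2 (a+b)); all later 0/0 epochs are undefined and excluded.
sessionWithMeanBgR <- function(total, meanR, minutes = 60) {
  b <- round(2 * meanR * total)
  stopifnot(b == 2 * meanR * total, b <= total)
  sessionLogFromCounts(c(total - b, b, rep(0, minutes - 2)))
}

# A session with an exact press total and near-0.5 background mean R.
sessionWithTotal <- function(total, minutes = 60) {
  base <- total %/% minutes
  counts <- rep(base, minutes) + rep(c(1, 0), c(total %% minutes,
                                                minutes - total %% minutes))
  sessionLogFromCounts(counts)
}
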