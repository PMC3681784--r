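mkProbes <- function(animals, levels = c(30, 60, 90), r) {
  # one tone row per animal x level with prescribed R
  do.call(rbind, lapply(seq_along(animals), function(i)
    data.frame(animal_id = animals[i], stimulus = "tone", freq_khz = 20,
               level_db = levels, A = 10, B = 10, R = r[[i]],
               stringsAsFactors = FALSE)))
}

test_that("discrimination functions pool animals with equal weight", {
  # single animal, one probe per level: function equals those R values
  one <- mkProbes("A1", r = list(c(0.1, 0.5, 0.6)))
  d1 <- discriminationFunction(one, "tone")
  expect_equal(d1$group$mean_r, c(0.1, 0.5, 0.6))
  expect_true(all(is.na(d1$group$sem_r)))
  expect_equal(d1$group$n_animals, rep(1L, 3))

  # per-level means 0.2 and 0.4 -> group mean 0.3 at each level
  two <- mkProbes(c("A1", "A2"), r = list(rep(0.2, 3), rep(0.4, 3)))
  d2 <- discriminationFunction(two, "tone")
  expect_equal(d2$group$mean_r, rep(0.3, 3))
  expect_equal(d2$group$sem_r, rep(sd(c(0.2, 0.4)) / sqrt(2), 3))

  expect_error(discriminationFunction(two, "BBN"), "absent")

  # speaker-off rows are carried as the leading point
  withOff <- rbind(two, data.frame(animal_id = c("A1", "A2"),
                                   stimulus = "speaker_off", freq_khz = NA,
                                   level_db = NA, A = 10, B = 1,
                                   R = c(0.05, 0.15)))
  d3 <- discriminationFunction(withOff, "tone")
  expect_equal(d3$group$stimulus[1], "speaker_off")
  expect_equal(d3$group$mean_r[1], 0.1)
})

test_that("a severe-tinnitus group's 20 kHz function sits below the control group", {
  tinny <- simulateCohort(nExposed = 6, nUnexposed = 0, tauDist = 0.8,
                          nSessions = 12, seed = 31)
  ctrl <- simulateCohort(nExposed = 0, nUnexposed = 6, nSessions = 12,
                         seed = 32)
  pt <- scoreCohort(tinny)$probes
  pc <- scoreCohort(ctrl)$probes
  dt <- discriminationFunction(pt, "tone")$group
  dc <- discriminationFunction(pc, "tone")$group
  for (lv in c(45, 60, 75, 90)) {
    expect_lt(dt$mean_r[!is.na(dt$level_db) & dt$level_db == lv],
              dc$mean_r[!is.na(dc$level_db) & dc$level_db == lv])
  }
  # BBN does not separate the groups anywhere near as far
  bt <- discriminationFunction(pt, "BBN")$group
  bc <- discriminationFunction(pc, "BBN")$group
  gap20 <- mean(dc$mean_r[!is.na(dc$level_db)] - dt$mean_r[!is.na(dt$level_db)])
  gapBBN <- mean(bc$mean_r[!is.na(bc$level_db)] - bt$mean_r[!is.na(bt$level_db)])
  expect_lt(gapBBN, gap20 / 2)
})

test_that("subgroup classification follows the lowest-16-of-24 rule", {
  m <- data.frame(animal_id = sprintf("E%02d", 1:24),
                  mean_r = (24:1) / 30)   # E24 has the lowest ratio
  cl <- classifySubgroups(m, seed = 7)
  expect_equal(sum(cl$tinnitus == "prominent"), 16L)
  expect_equal(sum(cl$tinnitus == "weak"), 8L)
  expect_equal(as.integer(table(cl$group)[c("exposed_prominent_antagonist",
                                            "exposed_prominent_no_drug",
                                            "exposed_weak_agonist")]),
               c(8L, 8L, 8L))
  # the 16 lowest means are prominent
  expect_setequal(cl$animal_id[cl$tinnitus == "prominent"],
                  m$animal_id[order(m$mean_r)][1:16])
  # permuting the input order leaves the membership unchanged
  cl2 <- classifySubgroups(m[sample(24), ], seed = 7)
  expect_equal(cl2[order(cl2$animal_id), ], cl[order(cl$animal_id), ],
               ignore_attr = TRUE)
  # all-equal means: assignment still 16/8, resolved by animal_id order
  tied <- data.frame(animal_id = sprintf("E%02d", 1:24), mean_r = 0.3)
  clT <- classifySubgroups(tied, seed = 7)
  expect_equal(clT$animal_id[clT$tinnitus == "prominent"],
               sprintf("E%02d", 1:16))
  expect_error(classifySubgroups(m[1:20, ], seed = 1), "24 exposed")
})

test_that("identical groups give a null group effect", {
  d <- data.frame(animal_id = rep(sprintf("a%d", 1:8), each = 3),
                  group = rep(c("g1", "g2"), each = 12),
                  level_db = rep(c(30, 60, 90), 8),
                  mean_r = rep(c(0.2, 0.4, 0.6, 0.3, 0.5, 0.7,
                                 0.25, 0.45, 0.65, 0.35, 0.55, 0.75), 2))
  res <- groupCompare(d)
  g <- res[res$effect == "group", ]
  expect_lt(g$F, 1e-20)
  expect_gt(g$p, 0.999)
})

test_that("the mixed ANOVA matches the sums-of-squares oracle", {
  # 2 groups x 2 subjects x 2 levels toy with hand-computable cells
  toy <- data.frame(animal_id = rep(c("a1", "a2", "b1", "b2"), each = 2),
                    group = rep(c("g1", "g2"), each = 4),
                    level_db = rep(c(30, 60), 4),
                    mean_r = c(0.2, 0.6, 0.3, 0.75, 0.5, 0.8, 0.6, 0.92))
  res <- groupCompare(toy)
  want <- mixedAnovaSS(toy)
  expect_equal(res$F[res$effect == "group"], want$F_group, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "group:level"], want$F_inter,
               tolerance = 1e-10)
  expect_equal(res$df1, unname(want$df[c("group", "level", "inter")]))
  expect_equal(res$df2, unname(want$df[c("subj", "error", "error")]))

  # all balanced designs up to 3 groups x 4 levels x 5 subjects
  set.seed(17)
  for (a in 2:3) for (l in 2:4) for (s in 2:5) {
    d <- expand.grid(subj = seq_len(s), group = paste0("g", seq_len(a)),
                     level_db = seq_len(l) * 10)
    d$animal_id <- paste0(d$group, d$subj)
    d$mean_r <- runif(nrow(d))
    res <- groupCompare(d)
    want <- mixedAnovaSS(d)
    expect_equal(res$F, unname(c(want$F_group, want$F_level, want$F_inter)),
                 tolerance = 1e-10)
  }

  # unbalanced empty cells are refused with their names
  bad <- toy[!(toy$group == "g1" & toy$level_db == 30), ]
  expect_error(groupCompare(bad), "empty group x level cells")
  expect_error(groupCompare(toy[toy$group == "g1", ]), "2 groups")
})

test_that("the IHC t-test matches the closed form and its invariances", {
  expect_equal(ihcGroupTTest(c(1, 2, 3), c(4, 5, 6))$t, -3 / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(ihcGroupTTest(c(1, 2, 3), c(4, 5, 6))$df, 4)
  expect_equal(ihcGroupTTest(c(2, 4, 9), c(2, 4, 9))$t, 0)
  # location invariance
  r1 <- ihcGroupTTest(c(1.2, 3.4, 2.2, 5), c(4, 5, 6))
  r2 <- ihcGroupTTest(c(1.2, 3.4, 2.2, 5) + 17, c(4, 5, 6) + 17)
  expect_equal(r1$t, r2$t)
  expect_equal(r1$p, r2$p)
  # zero variance in both groups, equal means -> p = 1 convention
  z <- ihcGroupTTest(c(2, 2), c(2, 2))
  expect_equal(z$t, 0); expect_equal(z$p, 1)
})

test_that("latent severity is recovered as a negative rank correlation", {
  coh <- simulateCohort(nExposed = 24, nUnexposed = 0, nSessions = 10,
                        seed = 41)
  sc <- scoreCohort(coh)
  m <- meanProbeR(sc$probes, freqKhz = 20)
  tau <- coh$animals$tau[match(m$animal_id, coh$animals$animal_id)]
  rho <- cor(tau, m$mean_r, method = "spearman")
  expect_lt(rho, -0.5)
})
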