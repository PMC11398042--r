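test_that("Shapiro-Wilk wrapper enforces its domain and detects non-normality", {
  set.seed(101)
  normal <- rnorm(40)
  expect_gt(shapiro_wilk(normal)$p, 0.05)
  bimodal <- c(rnorm(20, -8, 0.3), rnorm(20, 8, 0.3))
  expect_lt(shapiro_wilk(bimodal)$p, 0.05)
  expect_error(shapiro_wilk(rep(1.5, 10)), "identical")
  expect_error(shapiro_wilk(rnorm(2)), "3 <= n <= 50")
  expect_error(shapiro_wilk(rnorm(51)), "3 <= n <= 50")
})

test_that("Holm-Sidak adjustment follows the step-down formula", {
  # smallest of m = 3 raw ps {0.01, 0.2, 0.3}: 1 - (1 - 0.01)^3
  adj <- holm_sidak(c(0.01, 0.2, 0.3))
  expect_equal(adj[1], 1 - (1 - 0.01)^3)
  expect_equal(adj[2], max(1 - (1 - 0.2)^2, adj[1]))
  # monotone in raw-p order and never below raw p
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    a <- holm_sidak(p)
    expect_true(all(a >= p - 1e-12))
    expect_true(all(a <= 1))
    ord <- order(p)
    expect_true(all(diff(a[ord]) >= -1e-12))
  }
})

test_that("repeated-measures ANOVA matches its algebraic identities", {
  set.seed(21)
  m_id <- matrix(rnorm(9), 9, 4)          # identical columns
  res <- rm_anova_holm_sidak(m_id)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # two conditions: F is the squared paired-t statistic
  m2 <- cbind(rnorm(9, 10), rnorm(9, 12))
  res2 <- rm_anova_holm_sidak(m2)
  t2 <- t.test(m2[, 1] - m2[, 2])$statistic^2
  expect_equal(res2$statistic, unname(t2), tolerance = 1e-9)

  # general case against the aov() Error-stratum fit
  m5 <- matrix(rnorm(45, mean = rep(c(0, 1, 2, 1, 0), each = 9)), 9, 5)
  res5 <- rm_anova_holm_sidak(m5)
  df <- data.frame(y = as.vector(m5),
                   cond = factor(rep(1:5, each = 9)),
                   subj = factor(rep(1:9, 5)))
  fit <- summary(stats::aov(y ~ cond + Error(subj), data = df))
  ftab <- fit[["Error: Within"]][[1]]
  expect_equal(res5$statistic, ftab["cond", "F value"], tolerance = 1e-9)
  expect_equal(res5$p, ftab["cond", "Pr(>F)"], tolerance = 1e-9)
  expect_equal(nrow(res5$posthoc), choose(5, 2))
  expect_true(all(res5$posthoc$adj_p >= res5$posthoc$raw_p - 1e-12))

  m5[3, 2] <- NA
  expect_error(rm_anova_holm_sidak(m5), "missing cells")
})

test_that("the Friedman statistic matches closed forms and the vetted routine", {
  # all subjects rank the conditions identically: chi2 = 2n for k = 3
  m <- t(replicate(9, c(1, 5, 9)))
  expect_equal(friedman_statistic(m), 18)
  expect_equal(friedman_statistic(matrix(3, 6, 4)), 0)

  set.seed(33)
  for (i in 1:10) {
    mm <- matrix(rnorm(9 * 5), 9, 5)   # continuous: no ties
    expect_equal(friedman_statistic(mm),
                 unname(stats::friedman.test(mm)$statistic),
                 tolerance = 1e-9)
  }
})

test_that("exact Friedman p equals the full within-row permutation law", {
  set.seed(55)
  m <- matrix(rnorm(12), 4, 3)
  res <- friedman_dunn(m, p_method = "exact")

  # independent enumeration over all (3!)^4 rank arrangements
  perms <- matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1),
                  ncol = 3, byrow = TRUE)
  grid <- expand.grid(1:6, 1:6, 1:6, 1:6)
  stat_of <- function(ranks) {
    rj <- colSums(ranks)
    12 / (4 * 3 * 4) * sum(rj^2) - 3 * 4 * 4
  }
  stats_all <- apply(grid, 1, function(g) stat_of(perms[unlist(g), ]))
  expect_equal(length(stats_all), 6^4)
  p_oracle <- mean(stats_all >= res$statistic - 1e-9)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
})

test_that("Dunn's comparisons use rank-sum z with Bonferroni correction", {
  set.seed(66)
  m <- matrix(rnorm(27, mean = rep(c(0, 2, 5), each = 9)), 9, 3)
  res <- friedman_dunn(m)
  ranks <- t(apply(m, 1, rank))
  rbar <- colMeans(ranks)
  z13 <- abs(rbar[1] - rbar[3]) / sqrt(3 * 4 / (6 * 9))
  row <- res$posthoc[res$posthoc$group1 == "C1" & res$posthoc$group2 == "C3", ]
  expect_equal(row$z, unname(z13), tolerance = 1e-9)
  expect_equal(row$adj_p, min(1, 2 * pnorm(-z13) * 3), tolerance = 1e-9)
  expect_error(friedman_dunn(m[, 1:2]), "at least 3")
})

test_that("setting summaries aggregate limbs and catch identifier mismatches", {
  results <- data.frame(
    limb = rep(1:3, each = 10), setting = "50 kV; 1.2 mAs", kv = 50, mas = 1.2,
    step = rep(1:10, 3), count = 100, white_count = 1000,
    percent = rep(c(30, 20, 10), each = 10) + rep(1:10, 3),
    artifact_pixels = 0, fraction = 0, flagged = FALSE, severity = "none"
  )
  summaries <- list("50 kV; 1.2 mAs" = reference_ranges("50 kV; 1.2 mAs"))
  sm <- summarize_settings(results, summaries)
  expect_equal(nrow(sm), 10)
  expect_equal(sm$n_artifact_occurrences, rep(0, 10))
  expect_equal(sm$mean_percent, 20 + 1:10)
  expect_equal(sm$sd_percent, rep(sd(c(30, 20, 10)), 10))
  expect_equal(sm$min_hu[1], 880.6)
  expect_error(summarize_settings(results, list()), "no calibration summary")
})

test_that("setting recommendation prefers low artifact-free coverage", {
  # published coverage plus the observed artifact pattern: artifacts at
  # 60 kV; 12 mAs and the two high-kV presets, none at 50 and 60 kV; 1.2 mAs
  ref <- reference_ranges()
  artifacts <- c("50 kV; 1.2 mAs" = 0, "60 kV; 1.2 mAs" = 0,
                 "60 kV; 12 mAs" = 5, "70 kV; 1.2 mAs" = 10,
                 "80 kV; 1.2 mAs" = 10)
  summary <- do.call(rbind, lapply(names(artifacts), function(s) {
    sub <- ref[ref$setting == s, ]
    mins <- sub$mean[sub$bound == "Min"][order(sub$step[sub$bound == "Min"])]
    maxs <- sub$mean[sub$bound == "Max"][order(sub$step[sub$bound == "Max"])]
    data.frame(setting = s, kv = sub$kv[1], mas = sub$mas[1], step = 1:10,
               min_hu = mins, max_hu = maxs, mean_percent = 10,
               sd_percent = 1, n = 9,
               n_artifact_occurrences = c(artifacts[s], rep(0, 9)))
  }))
  best <- recommend_setting(summary)
  expect_equal(best$kv, 60)
  expect_equal(best$mas, 1.2)
  expect_false(attr(best, "warning"))

  # a single artifact-free setting wins outright
  one_clean <- summary
  one_clean$n_artifact_occurrences[one_clean$setting == "60 kV; 1.2 mAs" &
                                     one_clean$step == 1] <- 3
  expect_equal(recommend_setting(one_clean)$kv, 50)

  # all clean with equal lows: the wider total coverage wins
  flat <- summary[summary$setting %in% c("50 kV; 1.2 mAs", "60 kV; 1.2 mAs"), ]
  flat$n_artifact_occurrences <- 0
  flat$min_hu[flat$step == 1] <- 500
  wide <- recommend_setting(flat)
  span <- tapply(flat$max_hu, flat$setting, max) - 500
  expect_equal(wide$label, names(which.max(span)))

  # every setting affected: least-affected wins, with a warning flag
  dirty <- summary
  dirty$n_artifact_occurrences[dirty$step == 1] <-
    c(9, 1, 5, 10, 10)[match(dirty$setting[dirty$step == 1],
                             names(artifacts))]
  expect_warning(worst_case <- recommend_setting(dirty), "artifacts")
  expect_equal(worst_case$kv, 60)
  expect_equal(worst_case$mas, 1.2)
  expect_true(attr(worst_case, "warning"))
})
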