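test_that("performance rates follow their confusion-matrix definitions", {
  y <- c(1, 1, 1, -1, -1, -1)
  p <- c(1, 1, -1, -1, -1, 1)
  s <- summarize_performance(y, p)
  expect_equal(s$sensitivity, 2 / 3)
  expect_equal(s$specificity, 2 / 3)
  expect_equal(s$balanced_accuracy, 2 / 3)
  expect_equal(s$ppv, 2 / 3)
  expect_equal(s$npv, 2 / 3)

  perfect <- summarize_performance(y, y)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)

  all_pos <- summarize_performance(y, rep(1, 6))
  expect_equal(all_pos$specificity, 0)
  expect_true(is.na(all_pos$npv))
  expect_equal(all_pos$undefined, "npv")

  expect_error(summarize_performance(numeric(0), numeric(0)), "empty")
  expect_error(summarize_performance(y, p[-1]), "mismatch")
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  set.seed(14)
  for (i in 1:50) {
    y <- sample(c(-1, 1), 30, replace = TRUE)
    p <- sample(c(-1, 1), 30, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- summarize_performance(y, p)
    expect_equal(s$balanced_accuracy, (s$sensitivity + s$specificity) / 2)
  }
})

test_that("the study's printed sensitivity/specificity triples satisfy the identity", {
  printed <- rbind(c(67.3, 61.2, 64.3),
                   c(60.0, 58.3, 59.1),
                   c(41.9, 51.8, 46.8))
  for (i in 1:3) {
    acc <- (printed[i, 1] + printed[i, 2]) / 2
    expect_lte(abs(acc - printed[i, 3]), 0.05)
  }
})

test_that("ROC endpoints and AUC behave on canonical score patterns", {
  y <- c(rep(1, 4), rep(-1, 6))
  sep <- roc_points(c(4, 3.5, 3, 2.5, 2, 1, 0.5, 0, -1, -2), y)
  expect_equal(sep$auc, 1)
  anti <- roc_points(c(-4, -3.5, -3, -2.5, 2, 1, 0.5, 0, 1.5, 2.5), y)
  expect_equal(anti$auc, 0) # every negative outscores every positive
  tied <- roc_points(rep(0.3, 10), y)
  expect_equal(tied$auc, 0.5) # single diagonal segment
  expect_equal(tied$fpr, c(0, 1))
  expect_error(roc_points(1:4, rep(1, 4)), "both classes")
})

test_that("trapezoidal AUC equals the tie-adjusted rank statistic", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
    scores <- round(rnorm(n), sample(0:2, 1)) # rounding forces ties
    auc <- roc_points(scores, y)$auc
    pos <- scores[y > 0]
    neg <- scores[y < 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(cmp), tolerance = 1e-12)
  }
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  y <- sample(c(-1, 1), 40, replace = TRUE)
  s <- rnorm(40) + y * 0.8
  expect_equal(roc_points(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("vertical ROC averaging anchors endpoints and averages AUCs", {
  y <- c(rep(1, 5), rep(-1, 5))
  set.seed(21)
  rocs <- lapply(1:10, function(i) roc_points(rnorm(10) + y, y))
  avg <- mean_roc(rocs)
  expect_length(avg$fpr_grid, 101)
  expect_equal(avg$mean_tpr[1], 0)
  expect_equal(avg$mean_tpr[101], 1)
  expect_true(all(diff(avg$mean_tpr) >= -1e-12))
  expect_equal(avg$mean_auc, mean(vapply(rocs, `[[`, numeric(1), "auc")))
  expect_true(all(avg$lower <= avg$mean_tpr + 1e-12 &
                  avg$mean_tpr <= avg$upper + 1e-12))

  # identical curves: zero-width band, curve reproduced at grid points
  same <- mean_roc(rep(rocs[1], 5))
  expect_equal(same$lower[2:100], same$upper[2:100])
  expect_equal(same$mean_auc, rocs[[1]]$auc)

  pct <- mean_roc(rocs, band = "percentile")
  expect_true(all(pct$lower <= pct$upper))
})

test_that("trend t-tests report direction, significance and flags", {
  coh <- tiny_cohort(d = 6, planted = c(2, 3), effect = 2, seed = 12,
                     rho = 0)
  tt <- trend_ttest(coh$table, coh$labels)
  expect_equal(nrow(tt), 6)
  # planted directions alternate +, - (non-improver minus improver)
  expect_equal(tt$sign[2], "+")
  expect_equal(tt$sign[3], "-")
  expect_lt(tt$p[2], 0.05)

  # pooled t matches the closed-form pooled statistic
  j <- 2
  xi <- coh$table$values[coh$labels$improver, j]
  xn <- coh$table$values[!coh$labels$improver, j]
  sp2 <- ((length(xi) - 1) * var(xi) + (length(xn) - 1) * var(xn)) /
    (length(xi) + length(xn) - 2)
  t_manual <- (mean(xn) - mean(xi)) /
    sqrt(sp2 * (1 / length(xi) + 1 / length(xn)))
  expect_equal(tt$t[j], t_manual)

  # Welch variant differs in general
  tw <- trend_ttest(coh$table, coh$labels, features = j, welch = TRUE)
  expect_false(identical(tw$t, tt$t[j]))

  # identical constant groups: t = 0, no direction
  coh2 <- coh
  coh2$table$values[, 1] <- 5
  tt2 <- trend_ttest(coh2$table, coh2$labels, features = 1)
  expect_equal(tt2$t, 0)
  expect_equal(tt2$sign, "none")

  # distinct constants: flagged undefined
  coh2$table$values[coh2$labels$improver, 1] <- 6
  tt3 <- trend_ttest(coh2$table, coh2$labels, features = 1)
  expect_true(is.na(tt3$t))
  expect_equal(tt3$sign, "-") # improvers sit at the higher constant
})

test_that("planted effects are detected with high power at study size", {
  sig <- 0
  for (s in 1:50) {
    coh <- tiny_cohort(d = 4, planted = 1, effect = 2, seed = 200 + s,
                       rho = 0)
    tt <- trend_ttest(coh$table, coh$labels, features = 1)
    sig <- sig + (tt$p < 0.05)
  }
  expect_gte(sig / 50, 0.9)
})

test_that("the chromosome-length sweep aggregates per-length results", {
  coh <- tiny_cohort(d = 8, planted = 2, effect = 2.5, seed = 17)
  sw <- chromosome_sweep(coh$table, coh$labels, "lsld", lengths = c(1, 2),
                         ga_config = ga_config(generations = 5,
                                               population_size = 10),
                         repeats = 3, k = 5, seed = 23)
  expect_equal(nrow(sw$summary), 2)
  expect_equal(sw$summary$length, c(1, 2))
  expect_length(sw$frequency, 2)
  # with L = 1 the single informative feature must carry the signal
  f1 <- sw$frequency$L1
  expect_equal(f1$feature[1], 2)
  expect_equal(sum(f1$count), 1 * 3 * 5)
  expect_error(chromosome_sweep(coh$table, coh$labels, "lsld",
                                lengths = 1:20), "exceeds")
})
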