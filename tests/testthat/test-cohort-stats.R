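test_that("group assignment follows the clinical rules", {
  expect_identical(assignGroup("none", NA, NA), "healthy")
  expect_identical(assignGroup("2", 0, 0, FALSE), "NC")
  expect_identical(assignGroup("2", 3, 3, FALSE), "LN")
  expect_identical(assignGroup("1", 9, 9, FALSE), "HN")
  # HN precedence when both disjunctions hold (NDS high, NSS low)
  expect_identical(assignGroup("2", 9, 2, FALSE), "HN")
  expect_identical(assignGroup("2", 2, 9, FALSE), "HN")
  expect_identical(assignGroup("2", 4, 6, TRUE), "NA_")
  expect_error(assignGroup("2", NA, 3), "scores")
  expect_error(assignGroup("2", 12, 3), "0-10")
  expect_identical(neuroStratum(c("LN", "HN", "NA_", "NC", "healthy")),
                   c("NnA", "NnA", "NA", NA, NA))
})

test_that("star annotation is exact at the thresholds", {
  expect_identical(pStars(0.05), "ns")
  expect_identical(pStars(0.049999), "*")
  expect_identical(pStars(0.01), "*")
  expect_identical(pStars(0.009999), "**")
  expect_identical(pStars(0.001), "**")
  expect_identical(pStars(0.0009999), "***")
})

test_that("identical samples compare as indistinguishable", {
  r <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 1)
  expect_identical(r$stars, "ns")
  rc <- compareGroups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(rc$p, 1)
  expect_error(compareGroups(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("Mann-Whitney p equals exhaustive enumeration up to 8v8", {
  # the spec worked example: fully separated 3v3 gives the smallest
  # attainable two-sided exact p, 2/20
  expect_equal(mannWhitneyTest(c(1, 2, 3), c(10, 11, 12))$p, 0.1)
  set.seed(31)
  for (n1 in c(3, 5, 8)) for (n2 in c(3, 6, 8)) {
    a <- rnorm(n1); b <- rnorm(n2, 0.8)
    expect_equal(mannWhitneyTest(a, b)$p, oracleMannWhitneyP(a, b),
                 tolerance = 1e-12,
                 label = sprintf("MW p (n1=%d, n2=%d)", n1, n2))
  }
})

test_that("the normality gate picks the right test", {
  set.seed(7)
  a <- rnorm(30); b <- rnorm(30, 1)
  expect_identical(compareGroups(a, b)$test, "unpaired t")
  al <- exp(rnorm(30, 0, 1.5)); bl <- exp(rnorm(30, 1, 1.5))
  expect_identical(compareGroups(al, bl)$test, "Mann-Whitney U")
})

test_that("Spearman correlations hit the exact extremes and null behaviour", {
  x <- 1:20
  tab <- data.frame(age = x, duration_y = -x, hba1c = x^2,
                    bmi = rep(1, 20), tbv_pct = x, svn = 20:1)
  r <- spearmanCorrelations(tab)
  expect_equal(r$rho[r$x == "age" & r$y == "tbv_pct"], 1)
  expect_equal(r$rho[r$x == "age" & r$y == "svn"], -1)
  expect_equal(r$rho[r$x == "duration_y" & r$y == "tbv_pct"], -1)
  # monotone transform leaves rank correlation at 1
  expect_equal(r$rho[r$x == "hba1c" & r$y == "tbv_pct"], 1)
  # constant column reported as missing
  expect_true(all(is.na(r$rho[r$x == "bmi"])))
  expect_error(spearmanCorrelations(tab[1:3, ]), ">= 5")
})

test_that("Spearman null rejections are calibrated", {
  set.seed(17)
  rej <- replicate(200, {
    tab <- data.frame(age = rnorm(100), duration_y = rnorm(100),
                      hba1c = rnorm(100), bmi = rnorm(100),
                      tbv_pct = rnorm(100), svn = rnorm(100))
    r <- spearmanCorrelations(tab)
    r$p[1] < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("logistic regression recovers slopes and flags degeneracies", {
  set.seed(23)
  n <- 400
  x <- rnorm(n)
  covs <- data.frame(age = rnorm(n), duration_y = rnorm(n),
                     hba1c = rnorm(n), bmi = rnorm(n))
  y <- rbinom(n, 1, plogis(1.0 * x))
  tab <- cbind(data.frame(svn = x), covs)
  fit <- adjustedLogistic(tab, y, "svn")
  est <- fit$estimate[fit$term == "svn"]
  expect_lt(abs(est - 1.0), 0.3)
  # constant covariate dropped with a warning
  tab2 <- tab; tab2$bmi <- 0
  expect_warning(f2 <- adjustedLogistic(tab2, y, "svn"), "constant")
  expect_false("bmi" %in% f2$term)
  # perfect separation is reported, not silently diverged
  sep <- data.frame(svn = c(rnorm(50, -5), rnorm(50, 5)),
                    age = rnorm(100), duration_y = rnorm(100),
                    hba1c = rnorm(100), bmi = rnorm(100))
  ysep <- rep(c(0, 1), each = 50)
  expect_warning(fs <- adjustedLogistic(sep, ysep, "svn"), "separation")
  expect_true(attr(fs, "separation"))
  expect_error(adjustedLogistic(tab, rep(1, n), "svn"), "binary")
})

test_that("threshold ROC matches its identities and edge cases", {
  # perfect separation
  r <- thresholdROC(c(1, 2, 3, 10, 11, 12), c(TRUE, TRUE, TRUE, FALSE,
                                              FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_error(thresholdROC(1:4, rep(TRUE, 4)), "both classes")
  # rank identity equals trapezoidal integration, with and without ties
  set.seed(13)
  for (rep in 1:10) {
    v <- c(rnorm(30, 3), rnorm(40, 5))
    if (rep > 5) v <- round(v)          # force ties
    lab <- rep(c(TRUE, FALSE), c(30, 40))
    expect_equal(thresholdROC(v, lab)$auc, trapezoidAUC(v, lab),
                 tolerance = 1e-12)
  }
  # shuffled labels give chance-level AUC
  set.seed(19)
  v <- rnorm(200)
  lab <- sample(rep(c(TRUE, FALSE), 100))
  expect_lt(abs(thresholdROC(v, lab)$auc - 0.5), 0.08)
})

test_that("threshold ROC agrees with an independent implementation", {
  set.seed(29)
  v <- c(rnorm(48, 9.78, 3.41), rnorm(95, 3.45, 2.62))
  lab <- rep(c(FALSE, TRUE), c(48, 95))
  ours <- thresholdROC(v, lab)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = v, direction = ">"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("group summaries report mean and SD per group", {
  tab <- data.frame(group = c("a", "a", "b"),
                    svn = c(1, 3, 5), lvn = c(2, 2, 2), tvn = c(3, 5, 7),
                    tbv_pct = c(1, 1, 1), ep_thickness_um = c(90, 110, 100),
                    ep_density = c(1, 1, 1))
  s <- summarizeGroups(tab)
  expect_equal(s$svn_mean[s$group == "a"], 2)
  expect_equal(s$svn_sd[s$group == "a"], sd(c(1, 3)))
  # single subject: SD reported as 0 by convention
  expect_equal(s$svn_sd[s$group == "b"], 0)
  expect_equal(s$lvn_sd[s$group == "a"], 0)    # two equal values
})

test_that("generator defaults round-trip to the specified group moments", {
  tab <- makeCohort(cohortSpec(sizes = c(healthy = 2000, NC = 2000),
                               seed = 41))
  s <- summarizeGroups(tab)
  for (g in c("healthy", "NC")) {
    prm <- rsomskin:::defaultGroupParams()$bio[[g]]
    for (b in c("svn", "tbv_pct", "ep_thickness_um")) {
      se <- prm[[b]][2] / sqrt(2000)
      expect_lt(abs(s[[paste0(b, "_mean")]][s$group == g] - prm[[b]][1]),
                3 * se)
    }
  }
})
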