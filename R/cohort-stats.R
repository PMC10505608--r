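# Cohort statistics: group assignment, normality-gated two-sample tests
# with star annotation, Spearman correlations, covariate-adjusted
# logistic regression, the threshold-classifier ROC, and group summaries.

#' Assign a subject to a study group
#'
#' Grouping rules of the study: healthy if no diabetes; among diabetic
#' subjects without atherosclerosis, NC when both neuropathy scores are
#' zero, HN when NDS > 5 or NSS > 5, otherwise LN when 1 <= NDS <= 5 or
#' 1 <= NSS <= 5 (HN takes precedence when both disjunctions hold);
#' diabetic subjects with neuropathy and the atherosclerosis flag form
#' the `NA_` group. The neuropathy-without-atherosclerosis stratum
#' (`NnA`) is the union of LN and HN; see [neuroStratum()].
#'
#' @param dmType `"1"`, `"2"` or `"none"`.
#' @param nds,nss neuropathy scores (0-10); required for diabetic
#'   subjects.
#' @param ascvd logical atherosclerosis/PAD flag.
#' @return Group label: `"healthy"`, `"NC"`, `"LN"`, `"HN"` or `"NA_"`.
#' @export
assignGroup <- function(dmType, nds, nss, ascvd = FALSE) {
  if (length(dmType) > 1L) {
    return(mapply(assignGroup, dmType, nds, nss, ascvd, USE.NAMES = FALSE))
  }
  if (dmType == "none") return("healthy")
  if (is.na(nds) || is.na(nss))
    stop("neuropathy scores are required for diabetic subjects")
  if (nds < 0 || nds > 10 || nss < 0 || nss > 10)
    stop("neuropathy scores must lie in 0-10")
  neuro <- nds >= 1 || nss >= 1
  if (isTRUE(ascvd)) {
    if (neuro) return("NA_")
    stop("diabetic subject with atherosclerosis but no neuropathy does not fit the study grouping")
  }
  if (!neuro) return("NC")
  if (nds > 5 || nss > 5) return("HN")
  "LN"
}

#' Atherosclerosis stratum of a neuropathic subject
#'
#' Among subjects with diabetic neuropathy: `"NA"` when the
#' atherosclerosis flag is set, `"NnA"` otherwise; `NA` (missing) for
#' non-neuropathic subjects.
#'
#' @param group group label from [assignGroup()] (vectorized).
#' @return `"NnA"`, `"NA"`, or `NA_character_`.
#' @export
neuroStratum <- function(group) {
  ifelse(group %in% c("LN", "HN"), "NnA",
         ifelse(group == "NA_", "NA", NA_character_))
}

#' Star annotation for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `"ns"`
#' otherwise (boundaries exclusive: p = 0.05 earns no star).
#'
#' @param p p-value.
#' @return Character annotation.
#' @export
pStars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution when `n1 * n2 <= exactLimit` and the pooled
#' sample is tie-free; otherwise the normal approximation with
#' tie/continuity correction.
#'
#' @param a,b numeric samples.
#' @param exactLimit largest `n1 * n2` for the exact distribution.
#' @return List `statistic` (U for the first sample) and `p` (two-sided).
#' @export
mannWhitneyTest <- function(a, b, exactLimit = 64) {
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) * length(b) <= exactLimit && !ties
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                           correct = TRUE))
  list(statistic = unname(w$statistic), p = w$p.value)
}

#' Normality-gated two-sample comparison
#'
#' Shapiro-Wilk normality is assessed on both groups at alpha = 0.05;
#' when neither rejects, an unpaired two-sided t test is used, otherwise
#' a two-sided Mann-Whitney U test (exact when `n1 * n2 <= 64` and no
#' ties, normal approximation with continuity correction otherwise).
#' Identical constant samples return p = 1.
#'
#' @param a,b numeric samples (each n >= 3).
#' @param exactLimit largest `n1 * n2` for which the exact Mann-Whitney
#'   distribution is used.
#' @return List `test, statistic, p, stars, n, means, sds`.
#' @export
compareGroups <- function(a, b, exactLimit = 64) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  res <- list(n = c(length(a), length(b)),
              means = c(mean(a), mean(b)),
              sds = c(stats::sd(a), stats::sd(b)))
  if (stats::sd(c(a, b)) == 0) {
    res$test <- "degenerate"; res$statistic <- NA_real_; res$p <- 1
    res$stars <- pStars(1)
    return(res)
  }
  normalOk <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value > 0.05
  }
  if (normalOk(a) && normalOk(b)) {
    t <- stats::t.test(a, b)
    res$test <- "unpaired t"
    res$statistic <- unname(t$statistic)
    res$p <- t$p.value
  } else {
    w <- mannWhitneyTest(a, b, exactLimit = exactLimit)
    res$test <- "Mann-Whitney U"
    res$statistic <- w$statistic
    res$p <- w$p
  }
  res$stars <- pStars(res$p)
  res
}

#' Spearman correlations of covariates with vascular biomarkers
#'
#' Tie-corrected rank correlation with two-sided p, for every
#' (covariate, biomarker) pair. Constant columns yield missing rho.
#'
#' @param table subject table (schema of [makeCohort()]).
#' @param xCols covariate columns.
#' @param yCols biomarker columns.
#' @return data.frame `x, y, rho, p, n`.
#' @export
spearmanCorrelations <- function(table,
                                 xCols = c("age", "duration_y", "hba1c",
                                           "bmi"),
                                 yCols = c("tbv_pct", "svn")) {
  out <- list()
  for (x in xCols) for (y in yCols) {
    xv <- table[[x]]; yv <- table[[y]]
    ok <- is.finite(xv) & is.finite(yv)
    n <- sum(ok)
    if (n < 5) stop("need >= 5 paired observations for ", x, " vs ", y)
    if (stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0) {
      rho <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::cor.test(xv[ok], yv[ok],
                                             method = "spearman",
                                             exact = FALSE))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    out[[length(out) + 1L]] <- data.frame(x = x, y = y, rho = rho, p = p,
                                          n = n)
  }
  do.call(rbind, out)
}

#' Covariate-adjusted logistic regression of group on a biomarker
#'
#' Maximum-likelihood logistic fit of a binary outcome on a biomarker
#' with covariate adjustment; reports per-term estimates, standard
#' errors and Wald p-values. Perfect separation is detected and reported
#' explicitly; constant covariates are dropped with a warning.
#'
#' @param table subject table.
#' @param outcome logical/0-1 vector, or the name of a column.
#' @param biomarker biomarker column name.
#' @param covariates covariate column names.
#' @return data.frame `term, estimate, se, z, p`, with attribute
#'   `"separation"`.
#' @export
adjustedLogistic <- function(table, outcome, biomarker,
                             covariates = c("age", "duration_y", "hba1c",
                                            "bmi")) {
  y <- if (is.character(outcome) && length(outcome) == 1L)
    table[[outcome]] else outcome
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) stop("outcome must be binary with both classes")
  keep <- covariates[vapply(covariates, function(cv)
    stats::sd(table[[cv]], na.rm = TRUE) > 0, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped))
    warning("dropping constant covariate(s): ",
            paste(dropped, collapse = ", "))
  df <- table[, c(biomarker, keep), drop = FALSE]
  df$.y <- y
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fml <- stats::as.formula(paste(".y ~", paste(c(biomarker, keep),
                                               collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = df))
  mu <- stats::fitted(fit)
  separation <- !fit$converged || all(mu > 0.999 | mu < 0.001)
  if (separation)
    warning("perfect or quasi-perfect separation detected; ",
            "Wald statistics are unreliable")
  cf <- summary(fit)$coefficients
  out <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                    z = cf[, 3], p = cf[, 4], row.names = NULL)
  attr(out, "separation") <- separation
  out
}

#' Threshold classifier and ROC of a single biomarker
#'
#' AUC via the rank (Mann-Whitney) identity
#' `AUC = U / (n1 * n2)` with midranks handling ties; the decision rule
#' predicts "diabetic" below the threshold (the direction of the
#' diabetes effect on vascular biomarkers), and the reported threshold
#' maximizes accuracy over all cut midpoints.
#'
#' @param values biomarker values.
#' @param isDiabetic logical labels (TRUE = diabetic).
#' @return List `auc, best_threshold, accuracy, sensitivity, specificity`.
#' @export
thresholdROC <- function(values, isDiabetic) {
  isDiabetic <- as.logical(isDiabetic)
  ok <- is.finite(values) & !is.na(isDiabetic)
  values <- values[ok]; isDiabetic <- isDiabetic[ok]
  n1 <- sum(isDiabetic); n0 <- sum(!isDiabetic)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(values)                     # midranks correct for ties
  # probability a healthy value exceeds a diabetic one
  auc <- (sum(r[!isDiabetic]) - n0 * (n0 + 1) / 2) / (n0 * n1)
  cuts <- sort(unique(values))
  cand <- c(cuts[1] - 1, (utils::head(cuts, -1) + utils::tail(cuts, -1)) / 2,
            cuts[length(cuts)] + 1)
  best <- NULL
  for (th in cand) {
    pred <- values < th                 # below threshold -> diabetic
    acc <- mean(pred == isDiabetic)
    if (is.null(best) || acc > best$accuracy + 1e-12) {
      best <- list(
        best_threshold = th,
        accuracy = acc,
        sensitivity = sum(pred & isDiabetic) / n1,
        specificity = sum(!pred & !isDiabetic) / n0
      )
    }
  }
  c(list(auc = auc), best)
}

#' Trapezoidal ROC integration
#'
#' Independent AUC computation by integrating the empirical ROC curve
#' (sensitivity vs. 1 - specificity over all thresholds) with the
#' trapezoidal rule; used to cross-check the rank identity.
#'
#' @inheritParams thresholdROC
#' @return AUC value.
#' @export
trapezoidAUC <- function(values, isDiabetic) {
  isDiabetic <- as.logical(isDiabetic)
  cuts <- c(-Inf, sort(unique(values)), Inf)
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    pred <- values < cuts[i]
    sens[i] <- sum(pred & isDiabetic) / sum(isDiabetic)
    spec[i] <- sum(!pred & !isDiabetic) / sum(!isDiabetic)
  }
  fpr <- 1 - spec
  o <- order(fpr, sens)
  sum(diff(fpr[o]) * (utils::head(sens[o], -1) + utils::tail(sens[o], -1)) / 2)
}

#' Per-group mean and SD summary
#'
#' Mean +/- SD of each numeric column per group (SD is reported as 0 for
#' single-subject groups).
#'
#' @param table subject table with a `group` column.
#' @param cols columns to summarize (default: the six biomarkers).
#' @return data.frame with one row per group and `<col>_mean`,
#'   `<col>_sd` and `n` columns.
#' @export
summarizeGroups <- function(table, cols = biomarkerCols) {
  groups <- unique(table$group)
  out <- data.frame(group = groups)
  out$n <- vapply(groups, function(g) sum(table$group == g), numeric(1))
  for (cl in cols) {
    out[[paste0(cl, "_mean")]] <- vapply(groups, function(g)
      mean(table[[cl]][table$group == g]), numeric(1))
    out[[paste0(cl, "_sd")]] <- vapply(groups, function(g) {
      v <- table[[cl]][table$group == g]
      if (length(v) < 2) 0 else stats::sd(v)
    }, numeric(1))
  }
  out
}
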