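# Synthetic cohort generator: draws per-subject biomarker rows from
# per-group normal distributions whose defaults are the published group
# statistics of the clinical study (healthy n = 48 and pooled diabetic
# n = 95 for the two-group analyses; NC/LN/HN/NA subgroups for the
# severity and atherosclerosis analyses).

biomarkerCols <- c("svn", "lvn", "tvn", "tbv_pct", "ep_thickness_um",
                   "ep_density")

cohortColumns <- c("subject_id", "group", "age", "sex", "bmi", "dm_type",
                   "duration_y", "nds", "nss", "hba1c", "ascvd",
                   biomarkerCols)

defaultGroupParams <- function() {
  # biomarker (mean, sd) per group. healthy and pooled "diabetic" values
  # are the printed cohort statistics; NC/LN/HN/NA subgroup values are
  # generator defaults chosen to be consistent with the printed pooled
  # statistics and the reported significance structure across severity
  # groups (see the methods vignette).
  bio <- list(
    healthy  = list(svn = c(9.78, 3.41), lvn = c(20.34, 8.32),
                    tvn = c(30.12, 9.87), tbv_pct = c(4.21, 1.10),
                    ep_thickness_um = c(105.27, 17.04),
                    ep_density = c(1.00, 0.22)),
    diabetic = list(svn = c(3.45, 2.62), lvn = c(13.39, 11.30),
                    tvn = c(16.87, 9.30), tbv_pct = c(1.58, 0.90),
                    ep_thickness_um = c(81.03, 23.06),
                    ep_density = c(0.78, 0.25)),
    NC = list(svn = c(5.5, 2.6), lvn = c(14.5, 11.0), tvn = c(20.0, 9.0),
              tbv_pct = c(2.10, 0.90), ep_thickness_um = c(112.8, 16.0),
              ep_density = c(0.82, 0.22)),
    LN = list(svn = c(2.8, 1.2), lvn = c(13.0, 10.0), tvn = c(17.0, 8.0),
              tbv_pct = c(1.40, 0.60), ep_thickness_um = c(95.0, 16.0),
              ep_density = c(0.80, 0.24)),
    HN = list(svn = c(0.6, 0.5), lvn = c(11.5, 10.0), tvn = c(8.0, 5.0),
              tbv_pct = c(0.50, 0.30), ep_thickness_um = c(80.0, 18.0),
              ep_density = c(0.65, 0.22)),
    NA_ = list(svn = c(0.5, 0.5), lvn = c(7.0, 6.0), tvn = c(7.0, 5.0),
               tbv_pct = c(0.25, 0.20), ep_thickness_um = c(82.0, 20.0),
               ep_density = c(0.70, 0.25))
  )
  # covariates: age, duration, BMI, HbA1c as (mean, sd); sex/type as
  # male and type-1 proportions; neuropathy score ranges per group rule.
  cov <- list(
    healthy  = list(age = c(64, 13), duration = c(0, 0), bmi = c(26, 7),
                    hba1c = c(5.4, 0.4), maleProp = 27 / 48,
                    type1Prop = NA, scores = "zero", ascvd = FALSE),
    diabetic = list(age = c(68, 12), duration = c(20, 16), bmi = c(27, 8),
                    hba1c = c(7.1, 1.1), maleProp = 42 / 98,
                    type1Prop = 21 / 95, scores = "any", ascvd = FALSE),
    NC = list(age = c(63, 19), duration = c(12, 11), bmi = c(27, 6),
              hba1c = c(7.1, 1.6), maleProp = 24 / 43,
              type1Prop = 7 / 43, scores = "zero", ascvd = FALSE),
    LN = list(age = c(70, 10), duration = c(27, 17), bmi = c(30, 8),
              hba1c = c(7.2, 0.7), maleProp = 9 / 27,
              type1Prop = 11 / 25, scores = "low", ascvd = FALSE),
    HN = list(age = c(70, 10), duration = c(27, 17), bmi = c(30, 8),
              hba1c = c(7.2, 0.7), maleProp = 9 / 27,
              type1Prop = 11 / 25, scores = "high", ascvd = FALSE),
    NA_ = list(age = c(76, 7), duration = c(23, 16), bmi = c(28, 4),
               hba1c = c(6.9, 0.9), maleProp = 6 / 25,
               type1Prop = 3 / 25, scores = "neuro", ascvd = TRUE)
  )
  list(bio = bio, cov = cov)
}

#' Specify a synthetic biomarker cohort
#'
#' Per-group sample sizes and per-biomarker normal (mean, SD) parameters.
#' Defaults reproduce the published cohort: healthy (n = 48) and pooled
#' diabetic (n = 95) groups carry the printed means/SDs of all six
#' biomarkers (e.g. small-vessel number 9.78 +/- 3.41 healthy vs.
#' 3.45 +/- 2.62 diabetic); severity subgroups NC (n = 45), LN (n = 13),
#' HN (n = 12) and the neuropathy-with-atherosclerosis group `NA_`
#' (n = 25) use defaults consistent with the reported group structure.
#'
#' @param sizes named integer vector of group sizes; names from
#'   `c("healthy", "diabetic", "NC", "LN", "HN", "NA_")`.
#' @param params optional override of the default parameter list (same
#'   shape as the internal defaults; partial overrides are merged).
#' @param clipAtZero clip negative biomarker draws to zero (off by
#'   default; draws are untruncated normals).
#' @param seed integer seed.
#' @return A validated `CohortSpec` list.
#' @export
cohortSpec <- function(sizes = c(healthy = 48, NC = 45, LN = 13, HN = 12,
                                 NA_ = 25),
                       params = NULL, clipAtZero = FALSE, seed = 1L) {
  defaults <- defaultGroupParams()
  if (!is.null(params)) defaults <- utils::modifyList(defaults, params)
  if (is.null(names(sizes)) || any(!names(sizes) %in% names(defaults$bio)))
    stop("unknown group name in 'sizes'; allowed: ",
         paste(names(defaults$bio), collapse = ", "))
  if (any(sizes <= 0)) stop("group sizes must be > 0")
  structure(list(sizes = sizes, params = defaults,
                 clipAtZero = clipAtZero, seed = as.integer(seed)),
            class = "CohortSpec")
}

drawScores <- function(kind, n) {
  switch(kind,
    zero = list(nds = rep(0L, n), nss = rep(0L, n)),
    low = list(nds = pmin(pmax(round(stats::rnorm(n, 3, 1.2)), 1L), 5L),
               nss = pmin(pmax(round(stats::rnorm(n, 3, 1.2)), 1L), 5L)),
    high = list(nds = pmin(pmax(round(stats::rnorm(n, 7.5, 1.2)), 6L), 10L),
                nss = pmin(pmax(round(stats::rnorm(n, 7.5, 1.2)), 6L), 10L)),
    neuro = list(nds = pmin(pmax(round(stats::rnorm(n, 6, 3)), 1L), 10L),
                 nss = pmin(pmax(round(stats::rnorm(n, 7, 2)), 1L), 10L)),
    any = list(nds = pmin(pmax(round(stats::rnorm(n, 4, 4)), 0L), 10L),
               nss = pmin(pmax(round(stats::rnorm(n, 4, 4)), 0L), 10L))
  )
}

#' Generate a synthetic subject table
#'
#' One row per subject with group label, covariates and the six
#' biomarkers drawn from that group's normal distributions. Draws are
#' untruncated unless `spec$clipAtZero` is set (then biomarkers are
#' clipped at zero). Neuropathy scores are drawn consistently with the
#' group definitions (NC: both scores 0; LN: scores in 1-5; HN: a score
#' above 5; `NA_`: neuropathic scores with the atherosclerosis flag set).
#'
#' @param spec a [cohortSpec()].
#' @return A data.frame with columns `subject_id, group, age, sex, bmi,
#'   dm_type, duration_y, nds, nss, hba1c, ascvd, svn, lvn, tvn, tbv_pct,
#'   ep_thickness_um, ep_density`.
#' @export
makeCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  rows <- list()
  sid <- 0L
  for (g in names(spec$sizes)) {
    n <- spec$sizes[[g]]
    bio <- spec$params$bio[[g]]
    cov <- spec$params$cov[[g]]
    sc <- drawScores(cov$scores, n)
    df <- data.frame(
      subject_id = sprintf("S%04d", sid + seq_len(n)),
      group = g,
      age = round(stats::rnorm(n, cov$age[1], cov$age[2])),
      sex = ifelse(stats::runif(n) < cov$maleProp, "male", "female"),
      bmi = round(stats::rnorm(n, cov$bmi[1], cov$bmi[2]), 1),
      dm_type = if (is.na(cov$type1Prop)) "none" else
        ifelse(stats::runif(n) < cov$type1Prop, "1", "2"),
      duration_y = if (cov$duration[2] == 0) rep(0, n) else
        pmax(round(stats::rnorm(n, cov$duration[1], cov$duration[2])), 0),
      nds = sc$nds, nss = sc$nss,
      hba1c = round(stats::rnorm(n, cov$hba1c[1], cov$hba1c[2]), 1),
      ascvd = cov$ascvd,
      stringsAsFactors = FALSE
    )
    for (b in biomarkerCols) {
      v <- stats::rnorm(n, bio[[b]][1], bio[[b]][2])
      if (spec$clipAtZero) v <- pmax(v, 0)
      df[[b]] <- v
    }
    rows[[g]] <- df
    sid <- sid + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, cohortColumns]
}

#' Write / read a cohort table as CSV
#'
#' @param table a cohort data.frame (schema of [makeCohort()]).
#' @param path CSV path.
#' @return `path` invisibly (write); the table (read).
#' @export
writeCohortCsv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
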