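# Pipeline drivers: per-subject biomarker extraction from a band pair,
# and cohort-level statistics over a subject table.

#' Default pipeline configuration
#'
#' All tunable thresholds of the pipeline with their default values;
#' `overrides` is a nested list merged on top.
#'
#' @param overrides nested list of overrides (unknown keys rejected).
#' @return Nested configuration list.
#' @export
rsomConfig <- function(overrides = NULL) {
  cfg <- list(
    surface = list(threshold_fraction = 0.5, smooth_voxels = 5,
                   median_window = 3),
    flatten = list(reference_depth_um = NULL),
    layers = list(n_stacks = 4L, jump_limit = 1L, eps = 1e-5,
                  min_separation_voxels = 2L, smooth_window = 11L),
    dermis = list(depth_um = 1500, guard_voxels = 2L),
    vessels = list(scales_um = c(15, 30, 45, 60, 90),
                   n_orientations = 12L, cutoff_um = 40,
                   min_skeleton_px = 5L, tbv_threshold_fraction = 0.2,
                   mask_threshold = NULL, count_unbranched = FALSE)
  )
  if (!is.null(overrides)) {
    checkKeys <- function(ov, ref, path = "") {
      for (k in names(ov)) {
        if (!k %in% names(ref))
          stop("unknown config key: ", path, k)
        if (is.list(ov[[k]]) && is.list(ref[[k]]))
          checkKeys(ov[[k]], ref[[k]], paste0(path, k, "."))
      }
    }
    checkKeys(overrides, cfg)
    cfg <- utils::modifyList(cfg, overrides)
  }
  cfg
}

#' Extract the six biomarkers from one subject's band pair
#'
#' Runs the full per-subject pipeline: surface detection and flattening
#' (both bands, shifts from the low band), epidermis segmentation on the
#' low band, epidermal thickness and signal density, dermis slab,
#' per-band coronal MIPs and vessel networks, junction-classified vessel
#' counts (small from the high band, large from the low band, total as
#' their sum) and total blood volume on the combined
#' (low + weight x high) volume.
#'
#' @param pair a [BandPair-class].
#' @param config configuration from [rsomConfig()].
#' @param outDir optional directory for artifacts (boundary CSV, segment
#'   tables, biomarker row CSV).
#' @param subjectId identifier used in artifact names and error messages.
#' @return List with `biomarkers` (named numeric vector `svn, lvn, tvn,
#'   tbv_pct, ep_thickness_um, ep_density`), `boundaries`, `slab`,
#'   `networks` (per band) and `diameterHistograms`.
#' @export
runSubject <- function(pair, config = rsomConfig(), outDir = NULL,
                       subjectId = "subject") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage '%s' failed: %s", subjectId, name,
                   conditionMessage(e)), call. = FALSE))
  }
  flat <- stage("flatten", flattenPair(
    pair, on = "low",
    thresholdFraction = config$surface$threshold_fraction,
    smoothVoxels = config$surface$smooth_voxels,
    medianWindow = config$surface$median_window))
  bnd <- stage("layers", segmentLayers(
    flat@low, nStacks = config$layers$n_stacks,
    jumpLimit = config$layers$jump_limit, eps = config$layers$eps,
    minSeparation = config$layers$min_separation_voxels,
    smoothWindow = config$layers$smooth_window))
  thick <- stage("biomarkers", epThickness(bnd))
  dens <- stage("biomarkers", epSignalDensity(flat@low, bnd))
  slab <- stage("dermis", dermisMask(
    bnd, flat@low, depthUm = config$dermis$depth_um,
    guardVoxels = config$dermis$guard_voxels))
  sp <- voxelSpacing(pair)[2]
  nets <- list()
  for (b in c("low", "high")) {
    grid <- if (b == "low") flat@low else flat@high
    mip <- stage("vessels", dermisMIP(grid, slab))
    nets[[b]] <- stage("vessels", vesselNetwork(
      mip, spacingUm = sp, band = b,
      scalesUm = config$vessels$scales_um,
      nOrientations = config$vessels$n_orientations,
      threshold = config$vessels$mask_threshold,
      minSkeletonPx = config$vessels$min_skeleton_px))
  }
  cutoff <- config$vessels$cutoff_um
  unb <- config$vessels$count_unbranched
  cHigh <- countVessels(nets$high, cutoffUm = cutoff, countUnbranched = unb)
  cLow <- countVessels(nets$low, cutoffUm = cutoff, countUnbranched = unb)
  svn <- cHigh[["svn"]]; lvn <- cLow[["lvn"]]
  combined <- VolumeGrid(
    flat@low@values + pair@weight * flat@high@values,
    spacing = voxelSpacing(pair), band = "full")
  tbv <- stage("tbv", totalBloodVolume(
    combined, slab,
    thresholdFraction = config$vessels$tbv_threshold_fraction))
  biomarkers <- c(svn = svn, lvn = lvn, tvn = svn + lvn, tbv_pct = tbv,
                  ep_thickness_um = thick, ep_density = dens)
  hists <- lapply(nets, function(n) diameterHistogram(n@segments))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeBoundariesCsv(bnd, file.path(outDir,
                                      paste0(subjectId, "_boundaries.csv")))
    for (b in names(nets)) {
      segs <- nets[[b]]@segments
      segs$band <- rep(b, nrow(segs))
      utils::write.csv(segs, file.path(
        outDir, sprintf("%s_segments_%s.csv", subjectId, b)),
        row.names = FALSE)
    }
    utils::write.csv(
      data.frame(subject_id = subjectId, t(biomarkers)),
      file.path(outDir, paste0(subjectId, "_biomarkers.csv")),
      row.names = FALSE)
  }
  list(biomarkers = biomarkers, boundaries = bnd, slab = slab,
       networks = nets, diameterHistograms = hists)
}

#' Run the cohort-level statistical analysis
#'
#' Produces the group contrasts of the study over a subject table: the
#' healthy-vs-diabetic comparison of all six biomarkers, the severity
#' ladder (healthy / NC / LN / HN, atherosclerosis-free), the
#' NnA-vs-NA atherosclerosis contrast, Spearman correlations of
#' covariates with TBV and SVN, covariate-adjusted logistic regressions,
#' and the small-vessel-number threshold-classifier ROC. Groups with
#' fewer than 3 subjects are excluded with a warning.
#'
#' @param table subject table (schema of [makeCohort()]).
#' @param outDir optional results directory (`comparisons.csv`,
#'   `correlations.csv`, `logistic.csv`, `roc.json`, `summary.csv`).
#' @return List `comparisons` (data.frame), `correlations`, `logistic`,
#'   `roc`, `summary`.
#' @export
runCohort <- function(table, outDir = NULL) {
  if (!nrow(table)) stop("empty subject table")
  needed <- setdiff(c("group", biomarkerCols), names(table))
  if (length(needed))
    stop("subject table lacks columns: ", paste(needed, collapse = ", "))
  isDiab <- table$group != "healthy"
  pairs <- list(
    c("healthy", "diabetic"),
    c("healthy", "NC"), c("NC", "LN"), c("LN", "HN"),
    c("NnA", "NA"))
  sel <- function(lbl) {
    switch(lbl,
      diabetic = which(isDiab),
      NnA = which(table$group %in% c("LN", "HN")),
      `NA` = which(table$group == "NA_"),
      which(table$group == lbl))
  }
  comp <- list()
  for (p in pairs) {
    ia <- sel(p[1]); ib <- sel(p[2])
    if (length(ia) < 3 || length(ib) < 3) {
      warning("skipping contrast ", p[1], " vs ", p[2],
              ": a group has n < 3")
      next
    }
    for (b in biomarkerCols) {
      r <- compareGroups(table[[b]][ia], table[[b]][ib])
      comp[[length(comp) + 1L]] <- data.frame(
        group_a = p[1], group_b = p[2], biomarker = b, test = r$test,
        statistic = r$statistic, p = r$p, stars = r$stars,
        n_a = r$n[1], n_b = r$n[2],
        mean_a = r$means[1], sd_a = r$sds[1],
        mean_b = r$means[2], sd_b = r$sds[2])
    }
  }
  comparisons <- do.call(rbind, comp)
  correlations <- spearmanCorrelations(table)
  logistic <- list(
    svn = adjustedLogistic(table, isDiab, "svn"),
    tbv_pct = adjustedLogistic(table, isDiab, "tbv_pct"))
  roc <- thresholdROC(table$svn, isDiab)
  summary <- summarizeGroups(table)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(comparisons, file.path(outDir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(outDir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, lapply(names(logistic), function(nm) {
      x <- logistic[[nm]]; x$biomarker <- nm; x
    })), file.path(outDir, "logistic.csv"), row.names = FALSE)
    jsonlite::write_json(roc, file.path(outDir, "roc.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(summary, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
  }
  list(comparisons = comparisons, correlations = correlations,
       logistic = logistic, roc = roc, summary = summary)
}
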