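#' Configure a full trajectory analysis run
#'
#' One global seed deterministically derives the stage seeds (cohort
#' simulation and Monte-Carlo null), so a run is reproducible end to end
#' and stages can be re-run in isolation.
#'
#' @param cohort a \code{\link{cohortConfig}} (the phantom to simulate),
#'   or NULL when \code{cohortData} supplies real maps.
#' @param cohortData optional pre-built \linkS4class{GMCohort}.
#' @param cluster a \code{\link{clusterParams}}.
#' @param terms covariates of interest for the voxelwise model.
#' @param nuisance nuisance covariates.
#' @param maskThreshold mean-GM threshold for the analysis mask.
#' @param roiNuisance nuisance covariates for per-ROI trend fits
#'   (default none; the per-ROI line is a single-predictor fit).
#' @param crossoverWindow plausibility window for crossover points.
#' @param seed global integer seed.
#' @param outDir optional directory; when set, \code{runFullAnalysis}
#'   writes the report bundle there.
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(cohort = cohortConfig(),
                      cohortData = NULL,
                      cluster = clusterParams(),
                      terms = c("abstinence_weeks", "years_use"),
                      nuisance = "age",
                      maskThreshold = 0.05,
                      roiNuisance = character(0),
                      crossoverWindow = c(0, Inf),
                      seed = 1L,
                      outDir = NULL) {
  seed <- as.integer(seed)
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "CohortConfig"))
    cohort$seed <- seed + 1L
  } else if (is.null(cohortData)) {
    stop("either a cohort config or cohortData is required")
  }
  stopifnot(inherits(cluster, "ClusterParams"))
  cluster$seed <- seed + 2L
  structure(list(cohort = cohort, cohortData = cohortData,
                 cluster = cluster, terms = terms, nuisance = nuisance,
                 maskThreshold = maskThreshold,
                 roiNuisance = roiNuisance,
                 crossoverWindow = crossoverWindow,
                 seed = seed, outDir = outDir),
            class = "RunConfig")
}

#' Run the full grey-matter trajectory analysis
#'
#' Stages, in order: simulate (or accept) the cohort; build the analysis
#' mask; fit the voxelwise Huber model on the CD group; threshold at the
#' two-tailed critical t; calibrate the cluster-extent threshold by
#' Monte-Carlo simulation; extract surviving clusters per term and
#' polarity; per cluster, extract ROI means, fit the robust trend,
#' compute the crossover against the control mean, the Welch test beyond
#' the crossover, and the cross-term independence check. Any stage
#' failure aborts with an error naming the stage.
#'
#' @param config a \code{\link{runConfig}}.
#' @return list of class \code{"vbmAnalysis"}: \code{config},
#'   \code{cohort}, \code{mask}, \code{statMaps}, \code{tCrit},
#'   \code{nullDist}, \code{extent}, \code{clusterTables} (per term),
#'   \code{clusters} (combined data.frame), \code{crossovers}
#'   (data.frame with trend, crossover, Welch and cross-term columns).
#' @export
runFullAnalysis <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("simulate", {
    if (!is.null(config$cohortData)) config$cohortData
    else simulateCohort(config$cohort)
  })
  design <- stage("design",
    buildDesign(cohort, terms = config$terms, nuisance = config$nuisance))
  mask <- stage("mask", makeAnalysisMask(cohort, config$maskThreshold))
  statMaps <- stage("fit", fitVoxelwise(cohort, design, mask))
  clp <- config$cluster
  clp$df <- dfResidual(statMaps)
  tCrit <- criticalT(clp$voxelP, clp$df)
  nullDist <- stage("cluster_null", simulateNullMaxClusters(mask, clp))
  extent <- extentThreshold(nullDist, clp$alphaFWE)
  clusterTables <- list()
  for (term in config$terms)
    clusterTables[[term]] <- stage("cluster_extract",
      extractClusterTable(statMaps, term, tCrit,
                          extent$thresholdVoxels, clp$connectivity))
  allClusters <- do.call(rbind, lapply(clusterTables, clusters))
  rownames(allClusters) <- NULL

  crossRows <- list()
  stage("crossover", for (term in config$terms) {
    ct <- clusterTables[[term]]
    tab <- clusters(ct)
    otherTerms <- setdiff(config$terms, term)
    for (i in seq_len(nrow(tab))) {
      pol <- tab$polarity[i]
      series <- extractROIMeans(cohort, clusterLabels(ct, pol),
                                tab$label[i])
      trend <- fitROITrend(series, term, config$roiNuisance)
      ctrlMean <- mean(series$control$value)
      co <- crossoverPoint(trend, ctrlMean,
                           window = config$crossoverWindow)
      welch <- welchBeyondCrossover(series, co$crossover, term)
      xterm <- if (length(otherTerms))
        crossTermCheck(series, otherTerms[1]) else list(testable = FALSE)
      crossRows[[length(crossRows) + 1L]] <- data.frame(
        term = term, polarity = pol, label = tab$label[i],
        size_voxels = tab$size_voxels[i],
        volume_ul = tab$volume_ul[i],
        slope = co$slope, intercept = co$intercept,
        control_mean = co$controlMean, crossover = co$crossover,
        crossover_valid = co$valid,
        welch_t = if (welch$testable) welch$t else NA_real_,
        welch_df = if (welch$testable) welch$df else NA_real_,
        welch_p = if (welch$testable) welch$p else NA_real_,
        cross_term = if (length(otherTerms)) otherTerms[1] else NA,
        cross_term_p = if (isTRUE(xterm$testable)) xterm$p else NA_real_,
        stringsAsFactors = FALSE)
    }
  })
  crossovers <- if (length(crossRows)) do.call(rbind, crossRows)
    else data.frame()

  result <- structure(list(config = config, cohort = cohort, mask = mask,
                           statMaps = statMaps, tCrit = tCrit,
                           nullDist = nullDist, extent = extent,
                           clusterTables = clusterTables,
                           clusters = allClusters,
                           crossovers = crossovers),
                      class = "vbmAnalysis")
  if (!is.null(config$outDir)) writeReport(result, config$outDir)
  result
}

#' Write the report bundle for an analysis
#'
#' Cluster and crossover tables as TSV, the resolved configuration as
#' JSON (provenance: seed, thresholds, package version), and a
#' human-readable markdown summary mirroring the per-term/polarity
#' cluster layout with crossover summaries. Output is deterministic:
#' regenerating from the same result is byte-identical.
#'
#' @param result a \code{\link{runFullAnalysis}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(result, dir) {
  stopifnot(inherits(result, "vbmAnalysis"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create report directory: ", dir)
  writeTSV <- function(d, f)
    write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  writeTSV(result$clusters, "clusters.tsv")
  writeTSV(result$crossovers, "crossovers.tsv")
  cfg <- result$config
  prov <- list(seed = cfg$seed,
               package_version = as.character(utils::packageVersion("vbmtraj")),
               t_critical = result$tCrit,
               extent_threshold_voxels = result$extent$thresholdVoxels,
               extent_threshold_ul = result$extent$thresholdUL,
               voxel_p = cfg$cluster$voxelP,
               alpha_fwe = cfg$cluster$alphaFWE,
               n_iterations = cfg$cluster$nIterations,
               terms = cfg$terms, nuisance = cfg$nuisance,
               mask_voxels = nVoxels(result$mask),
               df = dfResidual(result$statMaps))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  lines <- c("# Grey-matter trajectory analysis report", "",
             sprintf("- voxelwise |t| threshold: %.4f (p = %g, df = %d)",
                     result$tCrit, cfg$cluster$voxelP,
                     dfResidual(result$statMaps)),
             sprintf("- cluster-extent threshold: %d voxels (%.0f ul) at FWE alpha %.2f",
                     result$extent$thresholdVoxels,
                     result$extent$thresholdUL, cfg$cluster$alphaFWE),
             "")
  if (!nrow(result$clusters)) {
    lines <- c(lines, "No surviving clusters.")
  } else {
    for (term in cfg$terms) for (pol in c("positive", "negative")) {
      sub <- result$crossovers[result$crossovers$term == term &
                               result$crossovers$polarity == pol, ,
                               drop = FALSE]
      if (!nrow(sub)) next
      lines <- c(lines, sprintf("## Term: %s, polarity: %s", term, pol), "")
      for (i in seq_len(nrow(sub)))
        lines <- c(lines, sprintf(
          "- cluster %d: %.0f ul, slope %.3g, crossover %.1f",
          sub$label[i], sub$volume_ul[i], sub$slope[i], sub$crossover[i]))
      ok <- sub$crossover[sub$crossover_valid]
      if (length(ok)) {
        sm <- summarizeCrossovers(ok)
        lines <- c(lines, sprintf(
          "- crossover summary: mean %.1f, sd %s, range %.1f-%.1f (n = %d)",
          sm$mean, ifelse(is.na(sm$sd), "NA", sprintf("%.1f", sm$sd)),
          sm$min, sm$max, sm$n), "")
      } else lines <- c(lines, "")
    }
  }
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
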