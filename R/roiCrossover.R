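#' Per-subject mean grey matter within one cluster
#'
#' @param cohort a \linkS4class{GMCohort} (CD and control subjects).
#' @param labels integer label array (e.g. from
#'   \code{\link{clusterLabels}} or \code{\link{labelClusters}}).
#' @param clusterID label value of the cluster to extract.
#' @return list of class \code{"ROISeries"}: \code{clusterID}, \code{cd}
#'   (data.frame subject/value/age/abstinence_weeks/years_use) and
#'   \code{control} (data.frame subject/value).
#' @export
extractROIMeans <- function(cohort, labels, clusterID = 1L) {
  stopifnot(is(cohort, "GMCohort"))
  if (!all(dim(labels) == cohort@grid@dim))
    stop("labels grid does not match cohort")
  vox <- which(labels == clusterID)
  if (!length(vox)) stop("cluster ", clusterID, " is empty")
  flat <- matrix(cohort@maps, nrow = prod(cohort@grid@dim))
  means <- colMeans(flat[vox, , drop = FALSE])
  cv <- cohort@covariates
  cd <- cv$group == "CD"
  structure(list(
    clusterID = clusterID,
    cd = data.frame(subject = cv$subject[cd], value = means[cd],
                    age = cv$age[cd],
                    abstinence_weeks = cv$abstinence_weeks[cd],
                    years_use = cv$years_use[cd],
                    stringsAsFactors = FALSE),
    control = data.frame(subject = cv$subject[!cd], value = means[!cd],
                         stringsAsFactors = FALSE)),
    class = "ROISeries")
}

#' Robust trend of ROI grey matter against one covariate
#'
#' Huber fit of the CD subjects' ROI means on an intercept, the
#' covariate of interest, and any nuisance covariates. The returned
#' slope and intercept refer to the covariate of interest with the
#' nuisances held at their sample means (the intercept is re-centred
#' accordingly), so the line is directly comparable to the control mean.
#'
#' @param series an \code{\link{extractROIMeans}} result.
#' @param covariate covariate of interest (column of \code{series$cd}).
#' @param nuisance optional nuisance covariate names.
#' @param ... passed to \code{\link{huberFit}}.
#' @return list of class \code{"ROITrend"}: \code{slope},
#'   \code{intercept}, \code{covariate}, \code{fit} (the underlying
#'   \code{huberFit}), \code{n}.
#' @export
fitROITrend <- function(series, covariate = "abstinence_weeks",
                        nuisance = character(0), ...) {
  stopifnot(inherits(series, "ROISeries"))
  cd <- series$cd
  cols <- c(covariate, nuisance)
  for (nm in cols)
    if (!nm %in% names(cd)) stop("unknown covariate: ", nm)
  X <- cbind(1, as.matrix(cd[, cols, drop = FALSE]))
  colnames(X) <- c("(Intercept)", cols)
  if (nrow(X) < ncol(X) + 2)
    stop("need at least p + 2 CD subjects")
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient ROI design (constant covariate?)")
  fit <- huberFit(cd$value, X, ...)
  cf <- fit$coefficients
  intercept <- cf[["(Intercept)"]]
  if (length(nuisance))
    intercept <- intercept +
      sum(cf[nuisance] * colMeans(cd[, nuisance, drop = FALSE]))
  structure(list(slope = unname(cf[[covariate]]), intercept = intercept,
                 covariate = covariate, nuisance = nuisance,
                 fit = fit, n = nrow(X)),
            class = "ROITrend")
}

#' Covariate value where the CD trend meets the control mean
#'
#' Solves \code{intercept + slope * x = controlMean}. The result is
#' flagged invalid (but still reported) when the slope is numerically
#' zero or the crossover falls outside the plausibility window.
#'
#' @param trend a \code{\link{fitROITrend}} result, or a list with
#'   \code{slope} and \code{intercept}.
#' @param controlMean mean control-group ROI value (the dashed line).
#' @param slopeFloor slopes with |slope| below this are degenerate.
#' @param window plausibility window for the crossover, in covariate
#'   units; default non-negative.
#' @return list of class \code{"CrossoverResult"}: \code{slope},
#'   \code{intercept}, \code{controlMean}, \code{crossover},
#'   \code{valid}.
#' @examples
#' crossoverPoint(list(slope = 0.005, intercept = 0.4), 0.5)$crossover
#' # 20 covariate units
#' @export
crossoverPoint <- function(trend, controlMean, slopeFloor = 1e-10,
                           window = c(0, Inf)) {
  slope <- trend$slope
  intercept <- trend$intercept
  if (abs(slope) < slopeFloor) {
    return(structure(list(slope = slope, intercept = intercept,
                          controlMean = controlMean,
                          crossover = NA_real_, valid = FALSE),
                     class = "CrossoverResult"))
  }
  x <- (controlMean - intercept) / slope
  structure(list(slope = slope, intercept = intercept,
                 controlMean = controlMean, crossover = x,
                 valid = x >= window[1] && x <= window[2]),
            class = "CrossoverResult")
}

#' Summarize a set of crossover points
#'
#' @param x numeric vector of crossover values, or a list of
#'   \code{\link{crossoverPoint}} results (invalid ones are dropped).
#' @return list: \code{n}, \code{mean}, \code{sd} (sample, NA when
#'   n < 2), \code{min}, \code{max}.
#' @export
summarizeCrossovers <- function(x) {
  if (is.list(x) && !is.data.frame(x))
    x <- vapply(Filter(function(r) isTRUE(r$valid), x),
                function(r) r$crossover, numeric(1))
  x <- as.numeric(x)
  if (!length(x)) stop("no valid crossover points")
  list(n = length(x), mean = mean(x),
       sd = if (length(x) >= 2) sd(x) else NA_real_,
       min = min(x), max = max(x))
}

#' Welch test of CD subjects beyond the crossover against controls
#'
#' Compares ROI grey matter of CD subjects whose covariate value is
#' strictly greater than the crossover with the control group
#' (two-sample Welch t, Satterthwaite df, two-tailed p).
#'
#' @param series an \code{\link{extractROIMeans}} result.
#' @param crossover covariate value separating "beyond".
#' @param covariate covariate defining the trajectory axis.
#' @return list: \code{testable}, and when testable \code{t}, \code{df},
#'   \code{p}, \code{nBeyond}.
#' @export
welchBeyondCrossover <- function(series, crossover,
                                 covariate = "abstinence_weeks") {
  stopifnot(inherits(series, "ROISeries"))
  beyond <- series$cd$value[series$cd[[covariate]] > crossover]
  ctrl <- series$control$value
  if (length(beyond) < 2 || length(ctrl) < 2)
    return(list(testable = FALSE, nBeyond = length(beyond)))
  if (var(beyond) + var(ctrl) == 0) {
    # degenerate: both groups constant; the difference of means carries
    # all the information
    d <- mean(beyond) - mean(ctrl)
    return(list(testable = TRUE,
                t = if (d == 0) 0 else sign(d) * Inf,
                df = NA_real_, p = if (d == 0) 1 else 0,
                nBeyond = length(beyond)))
  }
  tt <- t.test(beyond, ctrl)
  list(testable = TRUE, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       nBeyond = length(beyond))
}

#' Cross-term independence check
#'
#' For a cluster identified under one regression term, fits the ROI
#' means on the other covariate (age as nuisance by default) and reports
#' whether the cross-term slope is significant at an uncorrected
#' threshold -- a specificity check that use- and abstinence-linked
#' regions are distinct.
#'
#' @param series an \code{\link{extractROIMeans}} result.
#' @param covariateB the other covariate.
#' @param nuisance nuisance covariates (default age).
#' @param alpha uncorrected significance level.
#' @return list: \code{testable}, and when testable \code{slope},
#'   \code{t}, \code{df}, \code{p}, \code{significant}.
#' @export
crossTermCheck <- function(series, covariateB, nuisance = "age",
                           alpha = 0.05) {
  trend <- tryCatch(fitROITrend(series, covariateB, nuisance),
                    error = function(e) NULL)
  if (is.null(trend)) return(list(testable = FALSE))
  fit <- trend$fit
  tv <- fit$tstat[[covariateB]]
  p <- 2 * pt(-abs(tv), fit$df)
  list(testable = TRUE, slope = trend$slope, t = unname(tv),
       df = fit$df, p = unname(p), significant = unname(p < alpha))
}
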