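#' Group summary (mean, SEM, n)
#'
#' Demographic tables usually print mean +/- SEM with group size; these
#' summaries are sufficient for Welch tests without the raw data.
#'
#' @param mean group mean.
#' @param sem standard error of the mean.
#' @param n group size.
#' @return list of class \code{"GroupSummary"}.
#' @export
groupSummary <- function(mean, sem, n) {
  if (sem < 0) stop("sem must be >= 0")
  if (n < 2) stop("n must be >= 2")
  structure(list(mean = mean, sem = sem, n = as.integer(n)),
            class = "GroupSummary")
}

#' Welch t statistic from group summaries
#'
#' \code{t = (mean1 - mean2) / sqrt(sem1^2 + sem2^2)}.
#'
#' @param g1,g2 \code{\link{groupSummary}} objects.
#' @return The t statistic.
#' @examples
#' cd <- groupSummary(37.5, 1.2, 43)
#' ctrl <- groupSummary(38.7, 1.6, 43)
#' welchTFromSummary(cd, ctrl)  # -0.6
#' @export
welchTFromSummary <- function(g1, g2) {
  stopifnot(inherits(g1, "GroupSummary"), inherits(g2, "GroupSummary"))
  denom <- sqrt(g1$sem^2 + g2$sem^2)
  if (denom == 0) stop("both SEMs are zero")
  (g1$mean - g2$mean) / denom
}

#' Satterthwaite degrees of freedom from group summaries
#'
#' \code{df = (sem1^2 + sem2^2)^2 / (sem1^4/(n1-1) + sem2^4/(n2-1))}.
#'
#' @param g1,g2 \code{\link{groupSummary}} objects.
#' @return Effective degrees of freedom.
#' @export
satterthwaiteDF <- function(g1, g2) {
  stopifnot(inherits(g1, "GroupSummary"), inherits(g2, "GroupSummary"))
  a <- g1$sem^2; b <- g2$sem^2
  if (a + b == 0) stop("both SEMs are zero")
  (a + b)^2 / (a^2 / (g1$n - 1) + b^2 / (g2$n - 1))
}

#' Yates-corrected chi-square for a 2x2 table
#'
#' Pearson chi-square with continuity correction (|O - E| reduced by
#' 0.5, floored at 0), 1 df. This reproduces the usual two-proportion
#' comparison for, e.g., a gender-by-group table.
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @return list: \code{statistic}, \code{p}.
#' @examples
#' chisqYates2x2(matrix(c(41, 36, 2, 7), nrow = 2))
#' @export
chisqYates2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be 2x2")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin")
  res <- suppressWarnings(chisq.test(counts, correct = TRUE))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' t statistic for a Pearson correlation
#'
#' \code{t = r * sqrt(n - 2) / sqrt(1 - r^2)} with \code{df = n - 2}.
#'
#' @param r correlation coefficient, |r| < 1.
#' @param n sample size, >= 3.
#' @return list: \code{t}, \code{df}.
#' @export
pearsonRT <- function(r, n) {
  if (abs(r) >= 1) stop("|r| must be < 1")
  if (n < 3) stop("n must be >= 3")
  list(t = r * sqrt(n - 2) / sqrt(1 - r^2), df = n - 2)
}

#' Convert Gaussian sigma to FWHM (and back)
#'
#' \code{FWHM = 2 sqrt(2 ln 2) sigma}, about 2.355 sigma.
#'
#' @param sigma kernel standard deviation (any length unit).
#' @return FWHM in the same unit.
#' @examples
#' sigmaToFWHM(2)  # ~4.7 mm
#' @export
sigmaToFWHM <- function(sigma) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  2 * sqrt(2 * log(2)) * sigma
}

#' @rdname sigmaToFWHM
#' @param fwhm full width at half maximum.
#' @export
fwhmToSigma <- function(fwhm) {
  if (any(fwhm < 0)) stop("fwhm must be >= 0")
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Reference cluster table of the modelled study
#'
#' The published cluster table of the cocaine-abstinence VBM study the
#' package models: term, polarity, anatomical structure, volume,
#' centre of mass (MNI152, LPI sign convention) and trajectory crossover
#' point (weeks for abstinence terms, years for use terms). Shipped as a
#' plain-text fixture for summary reproduction and worked examples; the
#' underlying MRI data were never deposited.
#'
#' @return data.frame, one row per reported cluster.
#' @export
referenceClusters <- function() {
  f <- system.file("extdata", "reference_clusters.tsv",
                   package = "vbmtraj", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE)
}
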