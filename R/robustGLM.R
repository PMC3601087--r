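#' Build the CD-group design matrix
#'
#' Intercept first, then the covariates of interest in the requested
#' order, then nuisance covariates. With the defaults this is
#' [intercept, abstinence_weeks, years_use, age], giving residual
#' df = n - 4 (39 for a 43-subject CD group). Covariates stay in natural
#' units (weeks, years) so downstream crossover estimates are directly
#' interpretable.
#'
#' @param covariates cohort covariate table (or a \linkS4class{GMCohort}).
#' @param terms covariates of interest, in order.
#' @param nuisance nuisance covariates appended after the terms.
#' @param group which group to model (default \code{"CD"}).
#' @return list of class \code{"vbmDesign"}: \code{X} (n x p matrix),
#'   \code{subjects}, \code{terms}, \code{nuisance}, \code{n}, \code{p},
#'   \code{df}.
#' @export
buildDesign <- function(covariates, terms = c("abstinence_weeks", "years_use"),
                        nuisance = "age", group = "CD") {
  if (is(covariates, "GMCohort")) covariates <- covariates@covariates
  rows <- if (is.null(group)) rep(TRUE, nrow(covariates))
          else covariates$group == group
  cv <- covariates[rows, , drop = FALSE]
  cols <- c(terms, nuisance)
  for (nm in cols) {
    if (!nm %in% names(cv)) stop("missing covariate column: ", nm)
    if (any(is.na(cv[[nm]]))) stop("missing values in covariate: ", nm)
  }
  X <- cbind(1, as.matrix(cv[, cols, drop = FALSE]))
  colnames(X) <- c("(Intercept)", cols)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more subjects (", n, ") than columns (", p, ")")
  kap <- kappa(X, exact = TRUE)
  if (qr(X)$rank < p || kap > 1e8)
    stop("design is rank deficient or ill-conditioned (condition number ",
         format(kap, digits = 3), ")")
  structure(list(X = X, subjects = cv$subject, terms = terms,
                 nuisance = nuisance, n = n, p = p, df = n - p),
            class = "vbmDesign")
}

.designMatrix <- function(X) {
  if (inherits(X, "vbmDesign")) X$X else as.matrix(X)
}

#' Huber robust regression by IRLS
#'
#' M-estimation with the Huber loss: observations with residuals within
#' \code{k} robust standard deviations get weight 1, larger residuals
#' are downweighted as \code{k*scale/|r|}. The scale is the median
#' absolute deviation of the current residuals divided by 0.6745,
#' recomputed every iteration and floored so exact-fit responses remain
#' well defined. Standard errors use Huber's small-sample-corrected
#' formula on the unweighted \code{(X'X)^-1}; t statistics carry
#' \code{n - p} degrees of freedom.
#'
#' @param y response vector.
#' @param X design matrix or \code{\link{buildDesign}} result.
#' @param k Huber tuning constant (default 1.345, 95\% Gaussian
#'   efficiency).
#' @param tol convergence tolerance on the relative coefficient change.
#' @param maxIter maximum IRLS iterations; non-convergence is flagged,
#'   not raised.
#' @return list of class \code{"huberFit"}: \code{coefficients},
#'   \code{se}, \code{tstat}, \code{scale}, \code{weights},
#'   \code{iterations}, \code{converged}, \code{df}, \code{residuals}.
#' @examples
#' x <- c(0, 1, 2, 3)
#' y <- c(0, 1, 2, 10)           # one gross outlier
#' f <- huberFit(y, cbind(1, x))
#' f$coefficients[2]             # pulled toward 1, unlike least squares
#' @export
huberFit <- function(y, X, k = 1.345, tol = 1e-8, maxIter = 50L) {
  Xm <- .designMatrix(X)
  if (length(y) != nrow(Xm))
    stop("length(y) (", length(y), ") != rows of X (", nrow(Xm), ")")
  fit <- .huberIrlsCpp(Xm, matrix(as.numeric(y), ncol = 1),
                       k, tol, as.integer(maxIter), 1e-12)
  cf <- drop(fit$beta); names(cf) <- colnames(Xm)
  se <- drop(fit$se); names(se) <- colnames(Xm)
  structure(list(coefficients = cf, se = se, tstat = cf / se,
                 scale = fit$scale[1], weights = drop(fit$weights),
                 iterations = fit$iterations[1],
                 converged = fit$converged[1],
                 df = nrow(Xm) - ncol(Xm),
                 residuals = drop(y - Xm %*% fit$beta)),
            class = "huberFit")
}

#' Voxelwise Huber regression over the analysis mask
#'
#' Fits \code{\link{huberFit}} independently at every in-mask voxel
#' (shared design, one response per voxel) and assembles per-term
#' coefficient and t maps, NaN outside the mask.
#'
#' @param cohort a \linkS4class{GMCohort} (or 4D array via \code{maps}).
#' @param design a \code{\link{buildDesign}} result; its subjects select
#'   and order the maps used.
#' @param mask an \linkS4class{AnalysisMask}.
#' @param k,tol,maxIter IRLS controls, as in \code{\link{huberFit}}.
#' @return A \linkS4class{StatMaps}.
#' @export
fitVoxelwise <- function(cohort, design, mask, k = 1.345, tol = 1e-8,
                         maxIter = 50L) {
  stopifnot(inherits(design, "vbmDesign"), is(mask, "AnalysisMask"))
  if (!.sameGrid(cohort@grid, mask@grid))
    stop("cohort and mask grids disagree")
  sidx <- match(design$subjects, cohort@covariates$subject)
  if (anyNA(sidx))
    stop("design subjects missing from cohort: ",
         paste(design$subjects[is.na(sidx)], collapse = ", "))
  flat <- matrix(cohort@maps, nrow = prod(cohort@grid@dim))
  sel <- which(mask@mask)
  Y <- t(flat[sel, sidx, drop = FALSE])   # subjects x voxels
  fit <- .huberIrlsCpp(design$X, Y, k, tol, as.integer(maxIter), 1e-12)
  dimn <- cohort@grid@dim
  mkmap <- function(v) {
    arr <- array(NaN, dim = dimn)
    arr[sel] <- v
    arr
  }
  terms <- colnames(design$X)
  beta <- tstat <- setNames(vector("list", length(terms)), terms)
  for (j in seq_along(terms)) {
    beta[[j]] <- mkmap(fit$beta[j, ])
    tstat[[j]] <- mkmap(fit$beta[j, ] / fit$se[j, ])
  }
  new("StatMaps", beta = beta, tstat = tstat,
      df = as.integer(design$df), mask = mask,
      info = list(k = k, subjects = design$subjects,
                  nNonConverged = sum(!fit$converged)))
}

#' Split a term's t map by coefficient sign
#'
#' Positive map: t where beta > 0, NaN elsewhere; negative map: t where
#' beta < 0. Voxels with beta exactly 0 appear in neither.
#'
#' @param statMaps a \linkS4class{StatMaps}.
#' @param term design column name.
#' @return list with 3D arrays \code{positive} and \code{negative}.
#' @export
splitBySign <- function(statMaps, term) {
  b <- betaMap(statMaps, term)
  t <- tMap(statMaps, term)
  pos <- t; pos[!(!is.na(b) & b > 0)] <- NaN
  neg <- t; neg[!(!is.na(b) & b < 0)] <- NaN
  list(positive = pos, negative = neg)
}

#' Two-tailed critical t value
#'
#' @param pTwoTailed two-tailed uncorrected voxel p value.
#' @param df degrees of freedom.
#' @return Upper quantile of Student's t at \code{1 - p/2}.
#' @examples
#' criticalT(0.005, 39)  # 2.97, the classic p = 0.005 threshold at df 39
#' @export
criticalT <- function(pTwoTailed, df) {
  if (pTwoTailed <= 0 || pTwoTailed >= 1) stop("p must be in (0,1)")
  if (df < 1) stop("df must be >= 1")
  qt(1 - pTwoTailed / 2, df)
}
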