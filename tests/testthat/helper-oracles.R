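# Independent oracles and tiny fixtures shared across the suite.

# Brute-force flood fill connected components (reference for the
# package's labeling). Stack-based, first-encounter order.
floodLabelsR <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(offs))
  keep <- man > 0 & switch(as.character(connectivity),
                           "6" = man <= 1, "18" = man <= 2,
                           "26" = rep(TRUE, length(man)))
  offs <- offs[keep, , drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- integer(512)
    stack[1] <- start
    top <- 1L
    lab[start] <- nxt
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      ci <- arrayInd(cur, d)
      nb <- sweep(offs, 2, as.integer(ci), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * ((nb[, 2] - 1) + d[2] * (nb[, 3] - 1))
      new <- lin[mask[lin] & lab[lin] == 0L]
      if (length(new)) {
        lab[new] <- nxt
        if (top + length(new) > length(stack))
          stack <- c(stack, integer(length(stack)))
        stack[top + seq_along(new)] <- new
        top <- top + length(new)
      }
    }
  }
  lab
}

# relabel components 1..K in order of first linear-index occurrence so
# two labelings can be compared as partitions
canonicalLabels <- function(lab) {
  pos <- which(lab > 0)
  if (!length(pos)) return(lab)
  m <- integer(max(lab))
  nxt <- 0L
  for (i in pos) {
    o <- lab[i]
    if (m[o] == 0L) { nxt <- nxt + 1L; m[o] <- nxt }
  }
  out <- lab
  out[pos] <- m[lab[pos]]
  out
}

# out[x] = arr[x + s] with zero padding
shiftArray <- function(arr, s) {
  d <- dim(arr)
  out <- array(0, d)
  r <- lapply(1:3, function(a) {
    dst <- max(1, 1 - s[a]):min(d[a], d[a] - s[a])
    list(dst = dst, src = dst + s[a])
  })
  out[r[[1]]$dst, r[[2]]$dst, r[[3]]$dst] <-
    arr[r[[1]]$src, r[[2]]$src, r[[3]]$src]
  out
}

# brute-force dense Gaussian convolution (product kernel, zero padding),
# the reference for the separable smoother
convolveOracle <- function(arr, sigmaVox) {
  rad <- max(1, ceiling(4 * sigmaVox))
  off <- -rad:rad
  k1 <- exp(-0.5 * off^2 / sigmaVox^2)
  k1 <- k1 / sum(k1)
  out <- array(0, dim(arr))
  for (a in seq_along(off))
    for (b in seq_along(off))
      for (cc in seq_along(off))
        out <- out + k1[a] * k1[b] * k1[cc] *
          shiftArray(arr, c(off[a], off[b], off[cc]))
  out
}

# hand-built cohort: explicit maps and covariates, no simulation
tinyCohort <- function(maps, covariates, voxelSize = c(2, 2, 2)) {
  d <- dim(maps)
  grid <- voxelGrid(d[1:3], voxelSize)
  new("GMCohort", maps = maps, covariates = covariates, grid = grid,
      support = array(TRUE, d[1:3]), effectMasks = list())
}

# covariate table with nC controls then nD CD subjects; the default
# covariate patterns are deterministic but mutually non-collinear
tinyCovariates <- function(nC, nD, abstinence = NULL, years = NULL,
                           age = NULL) {
  n <- nC + nD
  if (is.null(age)) age <- 25 + (seq_len(n) * 7) %% 27
  data.frame(
    subject = c(sprintf("c%02d", seq_len(nC)), sprintf("d%02d", seq_len(nD))),
    group = c(rep("control", nC), rep("CD", nD)),
    age = age,
    abstinence_weeks = c(rep(NA_real_, nC),
                         if (is.null(abstinence))
                           1 + (seq_len(nD) * 37) %% 100 else abstinence),
    years_use = c(rep(NA_real_, nC),
                  if (is.null(years))
                    0.5 + ((seq_len(nD) * 11) %% 39) / 2 else years),
    stringsAsFactors = FALSE)
}

# small fast phantom configuration used by several module tests
smallPhantomConfig <- function(nCD = 20, nControl = 20,
                               gridDim = c(20, 24, 20), noiseSD = 0.02,
                               seed = 11, ...) {
  cohortConfig(nCD = nCD, nControl = nControl, gridDim = gridDim,
               noiseSD = noiseSD, seed = seed, ...)
}
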