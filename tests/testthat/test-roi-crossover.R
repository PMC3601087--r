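# a 2x2x2 cohort with hand-set ROI values for arithmetic checks
handCohort <- function(valuesBySubject, cv) {
  maps <- array(0, c(2, 2, 2, length(valuesBySubject)))
  for (s in seq_along(valuesBySubject))
    maps[, , , s] <- valuesBySubject[[s]]
  tinyCohort(maps, cv)
}

test_that("ROI means are unweighted voxel averages per subject", {
  cv <- tinyCovariates(2, 2)
  vols <- list(0.3, 0.7, 0.2, 0.9)
  coh <- handCohort(vols, cv)
  labels <- array(0L, c(2, 2, 2)); labels[1, 1, 1] <- 1L
  s <- extractROIMeans(coh, labels, 1)
  expect_equal(s$cd$value, c(0.2, 0.9))       # constant maps
  expect_equal(s$control$value, c(0.3, 0.7))
  # a 2-voxel cluster averaging {0.4, 0.6}
  maps <- array(0.1, c(2, 2, 2, 4))
  maps[1, 1, 1, ] <- 0.4; maps[2, 1, 1, ] <- 0.6
  coh2 <- tinyCohort(maps, cv)
  lab2 <- array(0L, c(2, 2, 2)); lab2[1:2, 1, 1] <- 1L
  s2 <- extractROIMeans(coh2, lab2, 1)
  expect_equal(s2$cd$value, c(0.5, 0.5))
  expect_error(extractROIMeans(coh2, lab2, 9), "empty")
})

test_that("ROI trends recover noiseless lines and respect nuisances", {
  cv <- tinyCovariates(3, 12)
  cd <- cv$group == "CD"
  vols <- as.list(ifelse(cd, 0.4 + 0.005 * cv$abstinence_weeks, 0.5))
  coh <- handCohort(vols, cv)
  labels <- array(1L, c(2, 2, 2))
  s <- extractROIMeans(coh, labels, 1)
  tr <- fitROITrend(s, "abstinence_weeks")
  expect_equal(tr$slope, 0.005, tolerance = 1e-10)
  expect_equal(tr$intercept, 0.4, tolerance = 1e-10)

  # an orthogonalized nuisance leaves the slope unchanged; bounded
  # noise keeps every weight at 1 so the argument is exact
  set.seed(33)
  n <- 30
  cv2 <- tinyCovariates(0, n, abstinence = runif(n, 1, 100))
  x <- cv2$abstinence_weeks[cv2$group == "CD"]
  z <- rnorm(n)
  z <- residuals(lm(z ~ x))                  # orthogonal to x
  cv2$age[cv2$group == "CD"] <- z
  y <- 0.4 + 0.003 * x + 0.005 * sin(seq_len(n))
  coh2 <- handCohort(as.list(y), cv2)
  s2 <- extractROIMeans(coh2, array(1L, c(2, 2, 2)), 1)
  t0 <- fitROITrend(s2, "abstinence_weeks")
  t1 <- fitROITrend(s2, "abstinence_weeks", nuisance = "age")
  expect_equal(t1$slope, t0$slope, tolerance = 1e-6)

  # slope recovery within 3 se on noisy data
  f <- t0$fit
  expect_lt(abs(t0$slope - 0.003), 3 * f$se[["abstinence_weeks"]])
  expect_error(fitROITrend(s2, "bogus"), "bogus")
})

test_that("crossover solves the line-intersection identity", {
  co <- crossoverPoint(list(slope = 0.005, intercept = 0.4), 0.5)
  expect_equal(co$crossover, 20)
  expect_true(co$valid)
  # identity holds whenever valid
  expect_equal(co$intercept + co$slope * co$crossover, co$controlMean,
               tolerance = 1e-10)
  # zero slope: invalid, not an error
  co0 <- crossoverPoint(list(slope = 0, intercept = 0.4), 0.5)
  expect_false(co0$valid)
  expect_true(is.na(co0$crossover))
  # outside the plausibility window: reported but flagged
  coW <- crossoverPoint(list(slope = -0.005, intercept = 0.4), 0.5)
  expect_equal(coW$crossover, -20)
  expect_false(coW$valid)
})

test_that("crossover is equivariant under covariate rescaling", {
  cv <- tinyCovariates(3, 12)
  cd <- cv$group == "CD"
  y <- ifelse(cd, 0.42 + 0.004 * cv$abstinence_weeks, 0.55)
  coh <- handCohort(as.list(y), cv)
  s <- extractROIMeans(coh, array(1L, c(2, 2, 2)), 1)
  trWeeks <- fitROITrend(s, "abstinence_weeks")
  # re-express the covariate in days
  cvD <- cv; cvD$abstinence_weeks <- cv$abstinence_weeks * 7
  cohD <- handCohort(as.list(y), cvD)
  sD <- extractROIMeans(cohD, array(1L, c(2, 2, 2)), 1)
  trDays <- fitROITrend(sD, "abstinence_weeks")
  expect_equal(trDays$slope, trWeeks$slope / 7, tolerance = 1e-10)
  cW <- crossoverPoint(trWeeks, 0.5)
  cD <- crossoverPoint(trDays, 0.5)
  expect_equal(cD$crossover, cW$crossover * 7, tolerance = 1e-8)
})

test_that("crossover summaries reproduce the reported statistics", {
  pos <- c(29.9, 26.4, 42.3, 32.8, 38.0, 44.9, 37.1, 33.3)
  sm <- summarizeCrossovers(pos)
  expect_equal(sm$mean, 35.6, tolerance = 0.05)
  expect_equal(sm$sd, 6.2, tolerance = 0.05)
  expect_equal(c(sm$min, sm$max), c(26.4, 44.9))
  neg <- summarizeCrossovers(c(27.6, 26.6, 18.5))
  expect_equal(neg$mean, 24.2, tolerance = 0.05)
  expect_equal(neg$sd, 5.0, tolerance = 0.05)
  # single value: sd undefined
  one <- summarizeCrossovers(42)
  expect_equal(one$mean, 42)
  expect_true(is.na(one$sd))
  # lists of results drop invalid entries
  lst <- list(crossoverPoint(list(slope = 0.005, intercept = 0.4), 0.5),
              crossoverPoint(list(slope = 0, intercept = 0.4), 0.5))
  expect_equal(summarizeCrossovers(lst)$n, 1)
  expect_error(summarizeCrossovers(numeric(0)), "no valid")
})

test_that("Welch beyond the crossover behaves like a two-sample test", {
  cv <- tinyCovariates(12, 12)
  y <- rep(0.5, 24)
  coh <- handCohort(as.list(y), cv)
  s <- extractROIMeans(coh, array(1L, c(2, 2, 2)), 1)
  w <- welchBeyondCrossover(s, 0)
  expect_true(w$testable)
  expect_equal(w$t, 0)
  # a clear shift beyond the crossover is detected
  set.seed(55)
  cv2 <- tinyCovariates(15, 30, abstinence = c(runif(15, 1, 30),
                                               runif(15, 50, 100)))
  sdv <- 0.02
  yv <- c(rnorm(15, 0.5, sdv),                       # controls
          rnorm(15, 0.5, sdv),                       # CD before
          rnorm(15, 0.5 + 3 * sdv, sdv))             # CD beyond
  coh2 <- handCohort(as.list(yv), cv2)
  s2 <- extractROIMeans(coh2, array(1L, c(2, 2, 2)), 1)
  w2 <- welchBeyondCrossover(s2, 40)
  expect_true(w2$testable)
  expect_equal(w2$nBeyond, 15)
  expect_lt(w2$p, 0.05)
  expect_gt(w2$t, 0)
  # swapping the roles flips the sign: compare against t.test directly
  tt <- t.test(s2$cd$value[s2$cd$abstinence_weeks > 40], s2$control$value)
  expect_equal(w2$t, unname(tt$statistic), tolerance = 1e-12)
  # too few subjects beyond: not testable
  w3 <- welchBeyondCrossover(s2, 99.9)
  expect_false(w3$testable)
})

test_that("cross-term checks separate disjoint from overlapping effects", {
  effA <- effectSpec(c(7, 8, 10), 5, "abstinence_weeks", 0.002, -0.07)
  effU <- effectSpec(c(14, 17, 10), 5, "years_use", -0.004)
  nonsig <- 0
  for (seed in 1:5) {
    cfg <- smallPhantomConfig(nCD = 30, nControl = 30, noiseSD = 0.02,
                              effects = list(effA, effU), seed = seed)
    coh <- simulateCohort(cfg)
    sphA <- effectMasks(coh)[["abstinence_weeks_1"]]
    s <- extractROIMeans(coh, array(as.integer(sphA), dim(sphA)), 1)
    ck <- crossTermCheck(s, "years_use")
    if (isTRUE(ck$testable) && !ck$significant) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 4)   # specificity: years-of-use not seen in A

  # overlapping effects: the cross-term is detected
  effB <- effectSpec(c(7, 8, 10), 5, "years_use", -0.004)
  cfg2 <- smallPhantomConfig(nCD = 30, nControl = 30, noiseSD = 0.02,
                             effects = list(effA, effB), seed = 77)
  coh2 <- simulateCohort(cfg2)
  sph <- effectMasks(coh2)[["abstinence_weeks_1"]]
  s2 <- extractROIMeans(coh2, array(as.integer(sph), dim(sph)), 1)
  ck2 <- crossTermCheck(s2, "years_use")
  expect_true(ck2$testable)
  expect_true(ck2$significant)
  expect_lt(ck2$slope, 0)

  # constant covariate: handled as not testable
  cv <- tinyCovariates(3, 10, years = rep(5, 10))
  coh3 <- handCohort(as.list(seq(0.4, 0.6, length.out = 13)), cv)
  s3 <- extractROIMeans(coh3, array(1L, c(2, 2, 2)), 1)
  ck3 <- crossTermCheck(s3, "years_use")
  expect_false(ck3$testable)
})
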