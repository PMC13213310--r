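# small helper: a dataset and model with one orthonormal planted
# interference component, used across fit/correct tests
emscFixture <- function() memoFixture("emscFixture", {
  set.seed(21)
  wn <- seq(1000, 1490, by = 10)
  base <- 1 + exp(-(wn - 1200)^2 / (2 * 30^2)) +
    0.6 * exp(-(wn - 1400)^2 / (2 * 20^2))
  Y <- sapply(1:12, function(i) base * runif(1, 0.8, 1.2) + rnorm(50, 0, 0.01))
  rs <- RamanSpectra(wn, Y)
  g <- exp(-(wn - 1100)^2 / (2 * 15^2))
  # orthogonalize the interference against nothing -- just normalize
  g <- g / sqrt(sum(g^2))
  basis <- new("InterferenceBasis", components = matrix(g, 1),
               explainedVarianceRatio = 0.5)
  model <- buildEMSCModel(rs, polyOrder = 4, interference = basis)
  list(rs = rs, model = model, g = g, wn = wn)
})

test_that("PCA interference extraction handles rank-1 and planted spectra", {
  set.seed(5)
  wn <- seq(1000, 1390, by = 10)
  u <- exp(-(wn - 1150)^2 / 800)
  scales <- runif(30, 0.5, 3)
  rank1 <- RamanSpectra(wn, outer(u, scales))
  b1 <- extractInterferenceComponents(rank1)
  expect_equal(nrow(b1@components), 1)
  expect_equal(b1@explainedVarianceRatio, 1, tolerance = 1e-9)
  expect_error(extractInterferenceComponents(rank1, nComponents = 5),
               "rank error")
})

test_that("variance-threshold selection follows the planted eigenspectrum", {
  # two orthonormal directions with variances 9 and 1: ratios 0.9 / 0.1,
  # so a 0.96 threshold needs both components
  set.seed(8)
  wn <- seq(1000, 1990, by = 10)
  Q <- qr.Q(qr(matrix(rnorm(200), 100, 2)))
  n <- 600
  scores <- cbind(rnorm(n, 0, 3), rnorm(n, 0, 1))
  rs <- RamanSpectra(wn, t(scores %*% t(Q)) + 5)
  b <- extractInterferenceComponents(rs, varianceThreshold = 0.96)
  expect_equal(nrow(b@components), 2)
  expect_equal(b@explainedVarianceRatio[1], 0.9, tolerance = 0.03)
  # with a threshold below the first ratio a single component suffices
  b1 <- extractInterferenceComponents(rs, varianceThreshold = 0.85)
  expect_equal(nrow(b1@components), 1)
})

test_that("extracted loadings are pairwise orthonormal", {
  set.seed(9)
  rs <- randomSpectra(n = 25, wn = seq(900, 1300, by = 10), seed = 9)
  b <- extractInterferenceComponents(rs, nComponents = 6)
  G <- b@components %*% t(b@components)
  expect_lt(max(abs(G - diag(6))), 1e-8)
  expect_true(all(diff(b@explainedVarianceRatio) <= 1e-12))
})

test_that("EMSC model takes the dataset mean as reference and rank-checks", {
  wn <- seq(1000, 1190, by = 10)
  one <- 2 + sin(wn / 50)
  same <- RamanSpectra(wn, matrix(one, 20, 5))
  m <- buildEMSCModel(same, interference = NULL)
  expect_equal(m@reference, one)
  # an interference component collinear with the reference is refused
  rcomp <- matrix(one / sqrt(sum(one^2)), 1)
  bad <- new("InterferenceBasis", components = rcomp,
             explainedVarianceRatio = 0.9)
  expect_error(buildEMSCModel(same, interference = bad), "collinearity")
})

test_that("reported condition number matches an independent computation", {
  fx <- emscFixture()
  ev <- sqrt(eigen(crossprod(fx$model@design), symmetric = TRUE,
                   only.values = TRUE)$values)
  expect_equal(fx$model@conditionNumber, max(ev) / min(ev),
               tolerance = 1e-6)
})

test_that("EMSC fits recover coefficients of spectra in the design span", {
  fx <- emscFixture()
  r <- fx$model@reference
  f1 <- fitEMSC(1 + 2 * r, fx$model)
  expect_equal(f1@a, 1, tolerance = 1e-8)
  expect_equal(f1@b, 2, tolerance = 1e-8)
  expect_equal(f1@c, rep(0, 4), tolerance = 1e-8)
  expect_equal(f1@d, 0, tolerance = 1e-8)
  expect_lt(f1@rmse, 1e-10)
  f2 <- fitEMSC(r + 0.5 * fx$g, fx$model)
  expect_equal(f2@b, 1, tolerance = 1e-8)
  expect_equal(f2@d, 0.5, tolerance = 1e-8)
  expect_lt(f2@rmse, 1e-10)
})

test_that("EMSC least squares equals the normal-equations oracle", {
  fx <- emscFixture()
  set.seed(33)
  for (i in 1:5) {
    y <- fx$model@reference + rnorm(50, 0, 0.05)
    f <- fitEMSC(y, fx$model)
    beta <- bruteEMSC(y, fx$model)
    expect_equal(c(f@a, f@c, f@b, f@d), beta, tolerance = 1e-9)
  }
})

test_that("correction inverts the fitted model", {
  fx <- emscFixture()
  r <- fx$model@reference
  s1 <- 1 + 2 * r
  expect_equal(correctSpectrum(s1, fitEMSC(s1, fx$model), fx$model), r,
               tolerance = 1e-10)
  lam <- 2 * (fx$wn - min(fx$wn)) / diff(range(fx$wn)) - 1
  s2 <- r + 0.8 * fx$g + 0.3 * lam^2 - 0.1 * lam
  expect_equal(correctSpectrum(s2, fitEMSC(s2, fx$model), fx$model), r,
               tolerance = 1e-8)
  # a spectrum unrelated to the reference has |b| below the guard
  expect_error(fitEMSC(lam^2, fx$model), "degenerate-fit")
})

test_that("dataset correction maps span-exact spectra onto the reference", {
  fx <- emscFixture()
  r <- fx$model@reference
  lam <- 2 * (fx$wn - min(fx$wn)) / diff(range(fx$wn)) - 1
  S <- cbind(2 * r + 1, 0.5 * r - 2 + 0.3 * lam, r + fx$g + lam^3)
  ds <- RamanSpectra(fx$wn, S)
  out <- correctSpectra(ds, fx$model)
  expect_equal(length(out$quarantine), 0)
  for (j in 1:3)
    expect_equal(unname(intensityMatrix(out$spectra)[, j]), r,
                 tolerance = 1e-8)
  expect_equal(colnames(out$coefficients),
               c("spectrum_id", "a", paste0("c", 1:4), "b", "d1", "rmse"))
  # coefficient table round-trips through CSV
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(out$coefficients, p, row.names = FALSE)
  back <- utils::read.csv(p)
  expect_equal(back$b, out$coefficients$b, tolerance = 1e-12)
})

test_that("correction is idempotent and shrinks carotenoid variance", {
  ch <- generateCohort(smallCohortConfig(seed = 6,
                                         nPatientsPerWeightClass = 2))
  cc <- correctCohort(ch$spectra)
  expect_equal(length(cc$quarantine), 0)
  wn <- wavenumbers(cc$corrected)
  for (b in c(1004, 1155, 1520)) {
    j <- which.min(abs(wn - b))
    expect_lte(var(intensityMatrix(cc$corrected)[j, ]),
               var(intensityMatrix(cc$preprocessed)[j, ]))
  }
  # idempotence: reapplying the fitted correction is a no-op -- residuals of
  # the first least-squares pass are orthogonal to the design, so a second
  # pass fits (a, c, d) = 0 and b = 1 exactly
  again <- correctSpectra(cc$corrected, cc$model)
  rel <- max(abs(intensityMatrix(again$spectra) -
                 intensityMatrix(cc$corrected))) /
    max(abs(intensityMatrix(cc$corrected)))
  expect_lt(rel, 1e-10)
})

test_that("interference-free cohorts keep planted class band ratios", {
  profs <- defaultClassProfiles()
  profs[["CAA"]] <- c(b1655 = 1.08)
  profs[["OW"]] <- c()
  cfg <- smallCohortConfig(seed = 3, nPatientsPerWeightClass = 2,
                           carotenoidSdlog = 0, patientCarotenoidSdlog = 0,
                           classProfiles = profs, noiseSd = 0)
  ch <- generateCohort(cfg)
  cc <- correctCohort(ch$spectra, nComponents = 0)
  cls <- spectrumMeta(cc$corrected)$tissue_class
  Y <- intensityMatrix(cc$corrected)
  j <- which.min(abs(wavenumbers(cc$corrected) - 1655))
  ratio <- mean(Y[j, cls == "CAA"]) / mean(Y[j, cls == "NA"])
  expect_lt(abs(ratio - 1.08) / 1.08, 0.02)
})
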