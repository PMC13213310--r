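test_that("map grid enumerates border-inclusive positions row-major", {
  expect_equal(nrow(buildMapGrid(30, 30, 1)), 961)
  expect_equal(buildMapGrid(0, 0, 1), data.frame(x_um = 0, y_um = 0))
  g <- buildMapGrid(2, 3, 1)
  # exhaustive 3 x 4 lattice, x fastest
  expect_equal(nrow(g), 12)
  expect_equal(g$x_um, rep(0:2, times = 4))
  expect_equal(g$y_um, rep(0:3, each = 3))
  expect_error(buildMapGrid(30, 30, 0), "invalid geometry")
  expect_error(buildMapGrid(30, 30, -1), "invalid geometry")
  expect_error(buildMapGrid(5, 5, 2), "integer multiples")
})

test_that("map grid count equals (w/s+1)(h/s+1) for random geometries", {
  set.seed(11)
  for (i in 1:25) {
    s <- sample(1:4, 1)
    w <- s * sample(0:12, 1)
    h <- s * sample(0:12, 1)
    expect_equal(nrow(buildMapGrid(w, h, s)), (w / s + 1) * (h / s + 1))
  }
})

test_that("region cutting keeps closed-interval channels and metadata", {
  rs <- randomSpectra(wn = seq(800, 1800, by = 10))
  cut <- cutRegion(rs, spectralRegion("fingerprint"))
  expect_equal(wavenumbers(cut), seq(900, 1800, by = 10))
  expect_equal(spectrumMeta(cut), spectrumMeta(rs))
  # covering region is an identity
  full <- cutRegion(rs, spectralRegion("custom", 700, 2000))
  expect_identical(intensityMatrix(full), intensityMatrix(rs))
  # disjoint region
  expect_error(cutRegion(rs, spectralRegion("high_wavenumber")),
               "empty region")
  # idempotence
  expect_identical(intensityMatrix(cutRegion(cut, spectralRegion("fingerprint"))),
                   intensityMatrix(cut))
})

test_that("resampling is exact on identical axes and affine spectra", {
  rs <- randomSpectra(n = 3, wn = seq(1000, 1500, by = 5))
  out <- resampleToCommonAxis(list(rs, rs), wavenumbers(rs))
  expect_equal(ncol(out), 6)
  expect_identical(unname(intensityMatrix(out)[, 1:3]),
                   unname(intensityMatrix(rs)))
  # affine spectra are reproduced exactly at arbitrary interior nodes
  wn <- seq(1000, 1500, by = 7)
  aff <- RamanSpectra(wn, cbind(2 * wn - 5, -0.3 * wn + 100))
  target <- sort(runif(40, min(wn), max(wn)))
  res <- resampleToCommonAxis(list(aff), target)
  expect_equal(unname(intensityMatrix(res)),
               cbind(2 * target - 5, -0.3 * target + 100), tolerance = 1e-12)
  expect_error(resampleToCommonAxis(list(aff), seq(900, 1400, by = 10)),
               "extrapolation")
})

test_that("resampling matches the two-point interpolation formula", {
  set.seed(42)
  wn <- sort(runif(80, 900, 1800))
  y <- cumsum(rnorm(80))
  rs <- RamanSpectra(wn, cbind(y))
  target <- sort(runif(50, min(wn), max(wn)))
  got <- as.numeric(intensityMatrix(resampleToCommonAxis(list(rs), target)))
  oracle <- vapply(target, function(t0) {
    i <- findInterval(t0, wn, rightmost.closed = TRUE)
    if (wn[i] == t0) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (t0 - wn[i]) / (wn[i + 1] - wn[i])
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("mean spectra match the direct summation oracle", {
  rs <- randomSpectra(n = 4, seed = 3)
  same <- RamanSpectra(wavenumbers(rs),
                       matrix(intensityMatrix(rs)[, 1], ncol = 3,
                              nrow = nrow(rs)))
  expect_equal(meanSpectrum(same)$all, unname(intensityMatrix(same)[, 1]))
  two <- RamanSpectra(seq(900, 1000, 10),
                      cbind(rep(0, 11), rep(2, 11)))
  expect_equal(meanSpectrum(two)$all, rep(1, 11))
  # grouped means vs column-sum oracle
  meta <- data.frame(tissue_class = c("NA", "CAA", "NA", "CAA"))
  rsg <- randomSpectra(n = 4, seed = 9, meta = meta)
  ms <- meanSpectrum(rsg, "tissue_class")
  Y <- intensityMatrix(rsg)
  expect_equal(ms[["NA"]], unname(colSums(t(Y[, c(1, 3)])) / 2),
               tolerance = 1e-12)
  expect_equal(ms[["CAA"]], unname(colSums(t(Y[, c(2, 4)])) / 2),
               tolerance = 1e-12)
  expect_error(meanSpectrum(rsg, "nonexistent"), "unknown metadata field")
})

test_that("spectral files round-trip and validate", {
  meta <- data.frame(spectrum_id = paste0("S", 1:5),
                     sample_id = c("NW1_NA", "NW1_NA", "NW1_CAA",
                                   "OW2_NA", "OW2_CAA"),
                     tissue_class = c("NA", "NA", "CAA", "NA", "CAA"),
                     weight_class = c("NW", "NW", "NW", "OW", "OW"),
                     roi_id = "r1", x_um = 0:4, y_um = 0)
  rs <- randomSpectra(n = 5, seed = 5, meta = meta)
  d <- withr::local_tempdir()
  mp <- file.path(d, "spectra.tsv"); mm <- file.path(d, "meta.csv")
  writeRamanSpectra(rs, mp, mm)
  back <- readRamanSpectra(mp, mm)
  expect_equal(intensityMatrix(back), intensityMatrix(rs),
               tolerance = 1e-9)
  expect_identical(spectrumMeta(back)$sample_id, meta$sample_id)
  expect_identical(spectrumMeta(back)$tissue_class, meta$tissue_class)
  # comma dialect is auto-detected
  writeRamanSpectra(rs, file.path(d, "c.csv"), sep = ",")
  expect_equal(intensityMatrix(readRamanSpectra(file.path(d, "c.csv"))),
               intensityMatrix(rs), tolerance = 1e-9)
  # metadata mismatch names the offending column
  writeRamanSpectra(rs, mp, mm)
  meta_bad <- meta[-3, ]
  utils::write.csv(meta_bad, mm, row.names = FALSE)
  expect_error(readRamanSpectra(mp, mm), "S3")
  # descending axis is reversed with a notice
  rev_rs <- rs
  tab <- utils::read.delim(mp, check.names = FALSE)
  utils::write.table(tab[rev(seq_len(nrow(tab))), ], mp, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_message(back2 <- readRamanSpectra(mp), "descending")
  expect_equal(wavenumbers(back2), wavenumbers(rs))
  # non-monotone axis is an error
  tab2 <- utils::read.delim(mp, check.names = FALSE)
  tab2[[1]][3] <- tab2[[1]][2]
  utils::write.table(tab2, mp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readRamanSpectra(mp), "non-monotone")
})

test_that("container validity enforces axis and metadata invariants", {
  expect_error(RamanSpectra(c(1000, 990, 1010), matrix(1, 3, 2)),
               "strictly increasing")
  expect_error(RamanSpectra(c(1000), matrix(1, 1, 2)), "length")
  expect_error(RamanSpectra(c(1000, 1010), matrix(c(1, NA, 1, 1), 2, 2)),
               "finite")
  meta <- data.frame(sample_id = "NW1_NA", roi_id = "r", x_um = 1, y_um = 1)
  expect_error(RamanSpectra(c(1000, 1010), matrix(1, 2, 2),
                            meta[c(1, 1), ]), "duplicate")
  expect_error(RamanSpectra(c(1000, 1010), matrix(1, 2, 1),
                            data.frame(tissue_class = "tumor")),
               "tissue_class")
})

test_that("sample identifiers parse into weight/index/tissue", {
  p <- parseSampleId(c("NW5_CAA", "OW2_NA", "weird"))
  expect_equal(p$weight_class, c("NW", "OW", NA))
  expect_equal(p$patient_index, c(5L, 2L, NA))
  expect_equal(p$tissue_class, c("CAA", "NA", NA))
})
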