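# Shared fixtures. Everything is generated in code; heavier shared objects
# are memoised so several test blocks can reuse one computation.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# a reduced synthetic cohort: 3 + 3 patients, 5 x 5 um maps (16 px) at a
# 4 cm^-1 axis -- the scaled-down study design used throughout the tests
smallCohortConfig <- function(seed = 0, ...) {
  args <- list(axisStep = 4, nPatientsPerWeightClass = 3,
               grid = c(4, 4, 1), seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generatorConfig, args)
}

randomSpectra <- function(n = 6, wn = seq(900, 1800, by = 10), seed = 1,
                          meta = NULL) {
  set.seed(seed)
  RamanSpectra(wn, matrix(rexp(length(wn) * n), ncol = n), meta)
}

# brute-force silhouette: literal double loop over points and clusters
bruteSilhouette <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(coords) - coords[i, ])^2))
    own <- labels == labels[i]
    a <- sum(di[own]) / (sum(own) - 1)   # excludes self (distance 0)
    b <- Inf
    for (lv in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(di[labels == lv]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# direct normal-equations EMSC solve: beta = (X'X)^-1 X' y
bruteEMSC <- function(y, model) {
  X <- model@design
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}
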