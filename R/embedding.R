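#' UMAP configuration
#'
#' @param nNeighbors local neighbourhood size (default 15, the library
#'   default).
#' @param minDist minimum embedding distance (default 0.1).
#' @param nComponents embedding dimension; fixed at 2 (scatterplot contract).
#' @param init embedding initialization; `"spectral"` (spectral decomposition
#'   of the fuzzy graph).
#' @param seeds integer vector of random seeds over which the embedding is
#'   repeated for stability selection (default 42--51).
#' @return a validated list of class `UMAPConfig`.
#' @export
umapConfig <- function(nNeighbors = 15L, minDist = 0.1, nComponents = 2L,
                       init = "spectral", seeds = 42:51) {
  if (nComponents != 2L) stop("nComponents is fixed at 2")
  if (length(seeds) < 1 || anyDuplicated(seeds))
    stop("seeds must be a non-empty set of distinct integers")
  structure(list(nNeighbors = as.integer(nNeighbors), minDist = minDist,
                 nComponents = 2L, init = init, seeds = as.integer(seeds)),
            class = "UMAPConfig")
}

.pythonBin <- function() {
  bin <- Sys.which("python")
  if (bin == "") bin <- Sys.which("python3")
  if (bin == "") stop("python interpreter not found on PATH ",
                      "(required for UMAP embedding)")
  bin
}

.umapScript <- function() {
  p <- system.file("python", "umap_batch.py", package = "adipoRaman")
  if (p == "") stop("umap_batch.py helper script not found")
  p
}

#' Embed a batch of matrices with UMAP over several seeds
#'
#' Runs umap-learn (via the `python` on the PATH) once for a whole batch of
#' input matrices and seeds, which amortizes the interpreter start-up cost.
#' Embeddings are deterministic given the input and seed (fixing the random
#' state forces single-threaded layout optimization).
#'
#' @param mats named list of numeric matrices (rows = observations).
#' @param config a [umapConfig()].
#' @param seeds seeds to run (default `config$seeds`).
#' @return nested list: per matrix, a list (named `seed<value>`) of n x 2
#'   coordinate matrices.
#' @export
umapEmbedBatch <- function(mats, config = umapConfig(),
                           seeds = config$seeds) {
  stopifnot(is.list(mats), length(mats) >= 1)
  if (is.null(names(mats))) names(mats) <- paste0("m", seq_along(mats))
  for (nm in names(mats)) {
    X <- mats[[nm]]
    if (nrow(X) <= config$nNeighbors)
      stop("parameter error: matrix '", nm, "' has ", nrow(X),
           " observations but n_neighbors is ", config$nNeighbors)
    if (!all(is.finite(X))) stop("non-finite values in matrix '", nm, "'")
  }
  dir <- tempfile("umapjob")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  inputs <- lapply(names(mats), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(as.data.frame(mats[[nm]]), p, col.names = FALSE)
    list(id = nm, path = p)
  })
  job <- list(n_neighbors = config$nNeighbors, min_dist = config$minDist,
              n_components = config$nComponents, init = config$init,
              seeds = I(as.integer(seeds)), inputs = inputs, out_dir = dir)
  jobPath <- file.path(dir, "job.json")
  jsonlite::write_json(job, jobPath, auto_unbox = TRUE, digits = NA)
  res <- suppressWarnings(
    system2(.pythonBin(), c(.umapScript(), jobPath),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if ((!is.null(status) && status != 0) || !any(res == "OK"))
    stop("UMAP embedding failed:\n", paste(res, collapse = "\n"))
  out <- lapply(names(mats), function(nm) {
    percd <- lapply(as.integer(seeds), function(sd) {
      f <- file.path(dir, sprintf("%s_seed%d.csv", nm, sd))
      as.matrix(data.table::fread(f, header = FALSE, data.table = FALSE))
    })
    names(percd) <- paste0("seed", as.integer(seeds))
    percd
  })
  names(out) <- names(mats)
  out
}

#' Embed one matrix with UMAP
#'
#' @param x numeric matrix (rows = observations) or [RamanSpectra-class]
#'   (spectra become rows).
#' @param config a [umapConfig()].
#' @param seed single random seed (default the first of `config$seeds`).
#' @return n x 2 coordinate matrix.
#' @export
umapEmbed <- function(x, config = umapConfig(), seed = config$seeds[1]) {
  if (is(x, "RamanSpectra")) x <- t(intensityMatrix(x))
  stopifnot(length(seed) == 1)
  umapEmbedBatch(list(m = x), config, seeds = seed)$m[[1]]
}

.procrustesDisparity <- function(A, B) {
  # symmetric Procrustes statistic: both configurations centered and scaled
  # to unit norm, optimal rotation/reflection/scaling; equals the squared
  # residual sum ("disparity")
  vegan::procrustes(A, B, symmetric = TRUE)$ss
}

#' Select the most stable embedding across seeds
#'
#' For each candidate embedding, computes the mean symmetric Procrustes
#' disparity (optimal translation, rotation, reflection and scaling -- UMAP
#' coordinates carry no absolute orientation or scale) to all sibling
#' embeddings, and retains the minimizer; ties go to the lowest seed.
#'
#' @param embeddings list of n x 2 coordinate matrices (as returned for one
#'   matrix by [umapEmbedBatch()]).
#' @param seeds integer seeds aligned with `embeddings` (default parsed from
#'   names, else `1:k`).
#' @param labels optional class labels; when given, the silhouette score of
#'   the retained embedding is computed and stored.
#' @return an [EmbeddingResult-class].
#' @export
selectStableEmbedding <- function(embeddings, seeds = NULL, labels = NULL) {
  k <- length(embeddings)
  if (k < 2) stop("need at least 2 embeddings")
  n <- unique(vapply(embeddings, nrow, integer(1)))
  if (length(n) != 1) stop("embeddings have mismatched point counts")
  if (is.null(seeds)) {
    nm <- names(embeddings)
    seeds <- if (!is.null(nm) && all(grepl("^seed-?[0-9]+$", nm)))
      as.integer(sub("^seed", "", nm)) else seq_len(k)
  }
  D <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    D[i, j] <- D[j, i] <- .procrustesDisparity(embeddings[[i]],
                                               embeddings[[j]])
  meanDisp <- rowSums(D) / (k - 1)
  # numerically tied candidates resolve to the lowest seed
  tied <- which(meanDisp <= min(meanDisp) + 1e-12 * max(1, min(meanDisp)))
  best <- tied[which.min(seeds[tied])]
  sil <- if (is.null(labels)) NA_real_ else
    silhouetteScore(embeddings[[best]], labels)
  new("EmbeddingResult", coords = unname(embeddings[[best]]),
      seed = as.integer(seeds[best]),
      stabilityDisparity = meanDisp[best], silhouette = sil)
}

setMethod("show", "EmbeddingResult", function(object) {
  cat("EmbeddingResult:", nrow(object@coords), "points, seed", object@seed,
      "\n")
  cat(sprintf("  stability disparity: %.4g\n", object@stabilityDisparity))
  if (!is.na(object@silhouette))
    cat(sprintf("  silhouette: %.3f\n", object@silhouette))
})

#' Mean silhouette score of labelled points
#'
#' For each point, `a` is its mean Euclidean distance to the other members of
#' its own cluster and `b` the smallest mean distance to any other cluster;
#' the silhouette is the mean over points of `(b - a) / max(a, b)`. Every
#' label must have at least 2 members (a singleton cluster leaves `a`
#' undefined).
#'
#' @param coords numeric matrix of coordinates (rows = points).
#' @param labels cluster labels, one per row.
#' @return mean silhouette score in \eqn{[-1, 1]}.
#' @export
silhouetteScore <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2)
    stop("undefined silhouette: need at least 2 distinct labels")
  if (min(table(labels)) < 2)
    stop("undefined silhouette: every label needs at least 2 members")
  D <- as.matrix(stats::dist(coords))
  n <- nrow(D)
  # mean distance of every point to every cluster
  G <- vapply(levels(labels), function(lv)
    rowSums(D[, labels == lv, drop = FALSE]), numeric(n))
  sizes <- as.numeric(table(labels)[levels(labels)])
  own <- match(labels, levels(labels))
  a <- G[cbind(seq_len(n), own)] / (sizes[own] - 1)
  Gm <- sweep(G, 2, sizes, `/`)
  Gm[cbind(seq_len(n), own)] <- Inf
  b <- apply(Gm, 1, min)
  mean((b - a) / pmax(a, b))
}

#' Compare class separability before and after feature selection
#'
#' Runs the embed / stabilize / silhouette chain twice -- on all channels and
#' on the top-`k` discriminant wavenumbers of a [FeatureRanking-class] -- and
#' reports both silhouette scores and their difference. Both matrices are
#' embedded in a single umap-learn invocation.
#'
#' @param x a [RamanSpectra-class] object.
#' @param ranking a [FeatureRanking-class] aligned to `x`'s axis.
#' @param k number of top wavenumbers to select (default 15).
#' @param labels metadata column name (default `"tissue_class"`) or label
#'   vector used for the silhouette.
#' @param config a [umapConfig()].
#' @return list of class `BeforeAfterComparison`: `before` and `after`
#'   ([EmbeddingResult-class]s), `silhouetteBefore`, `silhouetteAfter`,
#'   `delta`, `k`, `selected` (the chosen wavenumbers).
#' @export
compareBeforeAfter <- function(x, ranking, k = 15L,
                               labels = "tissue_class",
                               config = umapConfig()) {
  wn <- wavenumbers(x)
  if (k > length(wn)) stop("k exceeds the number of channels")
  if (is.character(labels) && length(labels) == 1)
    labels <- spectrumMeta(x)[[labels]]
  sel <- selectTopK(ranking, k)
  idx <- match(sel, wn)
  if (anyNA(idx)) stop("ranking wavenumbers not found on the dataset axis")
  Xall <- t(intensityMatrix(x))
  emb <- umapEmbedBatch(list(before = Xall,
                             after = Xall[, idx, drop = FALSE]), config)
  before <- selectStableEmbedding(emb$before, labels = labels)
  after <- selectStableEmbedding(emb$after, labels = labels)
  structure(list(before = before, after = after,
                 silhouetteBefore = before@silhouette,
                 silhouetteAfter = after@silhouette,
                 delta = after@silhouette - before@silhouette,
                 k = as.integer(k), selected = sel),
            class = "BeforeAfterComparison")
}

#' @export
print.BeforeAfterComparison <- function(x, ...) {
  cat(sprintf("silhouette before selection: %.3f (seed %d)\n",
              x$silhouetteBefore, x$before@seed))
  cat(sprintf("silhouette after top-%d selection: %.3f (seed %d)\n",
              x$k, x$silhouetteAfter, x$after@seed))
  cat(sprintf("delta: %+.3f\n", x$delta))
  invisible(x)
}
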