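#' Pipeline configuration
#'
#' Assembles a validated end-to-end configuration: input (a synthetic
#' generator block or file paths), the preprocessing / EMSC / random-forest /
#' UMAP blocks, and the analysis partitions. The partition scheme crosses the
#' cohort strata (`all`, `NW`, `OW`; each comparing `NA` vs `CAA`) with the
#' two spectral regions. One global seed drives the generator; the analysis
#' stages use their conventional fixed seeds (random forest 42, UMAP 42--51)
#' unless overridden in their blocks.
#'
#' @param input either `list(synth = generatorConfig(...))` or
#'   `list(path = ..., metaPath = ...)`.
#' @param preprocess a [preprocessConfig()].
#' @param emsc list with `polyOrder`, `varianceThreshold`, `nComponents`
#'   (optional fixed count), `bMin`.
#' @param rf an [rfConfig()].
#' @param umap a [umapConfig()].
#' @param partitions character vector from
#'   `{all, NW, OW} x {fingerprint, high_wavenumber}` written as
#'   `"<stratum>.<region>"`; default all six.
#' @param seed global seed (propagated to the generator when no explicit
#'   generator seed was set).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(input = list(synth = generatorConfig()),
                           preprocess = preprocessConfig(),
                           emsc = list(polyOrder = 4L,
                                       varianceThreshold = 0.96,
                                       nComponents = NULL, bMin = 1e-6),
                           rf = rfConfig(),
                           umap = umapConfig(),
                           partitions = as.vector(outer(
                             c("all", "NW", "OW"),
                             c("fingerprint", "high_wavenumber"),
                             paste, sep = ".")),
                           seed = 1L) {
  if (length(partitions) < 1)
    stop("validation error: partitions list is empty")
  strata <- sub("\\..*$", "", partitions)
  regions <- sub("^[^.]*\\.", "", partitions)
  if (!all(strata %in% c("all", "NW", "OW")) ||
      !all(regions %in% c("fingerprint", "high_wavenumber")))
    stop("validation error: partitions must be of the form ",
         "<all|NW|OW>.<fingerprint|high_wavenumber>")
  structure(list(input = input, preprocess = preprocess, emsc = emsc,
                 rf = rf, umap = umap, partitions = partitions,
                 seed = as.integer(seed)), class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; top-level blocks `input`/`synth`, `preprocess`,
#'   `emsc`, `rf`, `umap`, `partitions`, `seed` map onto the
#'   [pipelineConfig()] arguments.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synth)) {
    args$input <- list(synth = do.call(generatorConfig, y$synth))
  } else if (!is.null(y$input)) args$input <- y$input
  if (!is.null(y$preprocess)) args$preprocess <- do.call(preprocessConfig,
                                                         y$preprocess)
  if (!is.null(y$emsc)) {
    e <- list(polyOrder = 4L, varianceThreshold = 0.96, nComponents = NULL,
              bMin = 1e-6)
    e[names(y$emsc)] <- y$emsc
    args$emsc <- e
  }
  if (!is.null(y$rf)) args$rf <- do.call(rfConfig, y$rf)
  if (!is.null(y$umap)) args$umap <- do.call(umapConfig, y$umap)
  if (!is.null(y$partitions)) args$partitions <- unlist(y$partitions)
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(pipelineConfig, args)
}

#' Run the full analysis pipeline
#'
#' Executes the correction chain (per-window preprocessing, concatenation,
#' EMSC with PCA interference components; see [correctCohort()]); then, for
#' each configured partition (stratum x spectral region): random-forest
#' ranking of discriminant wavenumbers (with stratified cross-validation)
#' and UMAP embedding with seed-stability selection and silhouette scoring,
#' before and after top-k selection. All artifacts (corrected matrices,
#' coefficient tables, rankings, embeddings, silhouette summary, run
#' manifest) are written under `outDir`.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param verbose print stage progress.
#' @return (invisibly) list with `manifest`, `silhouette` (summary
#'   `data.frame`), `rankings`, `comparisons`.
#' @export
runPipeline <- function(config, outDir, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  warnings_log <- character()
  t0 <- Sys.time()

  say("stage: input")
  if (!is.null(config$input$synth)) {
    gen <- config$input$synth
    if (identical(gen$seed, 1L) && !identical(config$seed, 1L))
      gen$seed <- config$seed
    cohort <- generateCohort(gen)
    rs <- cohort$spectra
    utils::write.csv(cohort$truth, file.path(outDir, "ground_truth.csv"),
                     row.names = FALSE)
  } else {
    rs <- readRamanSpectra(config$input$path, config$input$metaPath)
  }
  writeRamanSpectra(rs, file.path(outDir, "input_spectra.tsv"),
                    file.path(outDir, "input_metadata.csv"))

  regionNames <- unique(sub("^[^.]*\\.", "", config$partitions))
  say("stage: preprocess + EMSC (windows: ",
      paste(regionNames, collapse = ", "), ")")
  ch <- tryCatch(
    correctCohort(rs, windows = as.list(regionNames),
                  preConfig = config$preprocess,
                  polyOrder = config$emsc$polyOrder,
                  nComponents = config$emsc$nComponents,
                  varianceThreshold = config$emsc$varianceThreshold,
                  bMin = config$emsc$bMin),
    error = function(e)
      stop("stage 'preprocess+EMSC' failed: ", conditionMessage(e),
           call. = FALSE))
  if (length(ch$quarantine))
    warnings_log <- c(warnings_log,
                      paste0(length(ch$quarantine),
                             " spectra quarantined by EMSC"))
  utils::write.csv(ch$coefficients,
                   file.path(outDir, "emsc_coefficients.csv"),
                   row.names = FALSE)
  ld <- as.data.frame(t(ch$basis@components))
  colnames(ld) <- paste0("PC", seq_len(ncol(ld)))
  ld <- cbind(wavenumber = wavenumbers(ch$corrected), ld)
  utils::write.csv(ld, file.path(outDir, "interference_loadings.csv"),
                   row.names = FALSE)
  writeRamanSpectra(ch$corrected, file.path(outDir, "corrected_spectra.tsv"))

  rankings <- list()
  parts <- list()
  for (p in config$partitions) {
    stratum <- sub("\\..*$", "", p)
    rn <- sub("^[^.]*\\.", "", p)
    ds <- cutRegion(ch$corrected, rn)
    if (stratum != "all")
      ds <- ds[, spectrumMeta(ds)$weight_class == stratum]
    say("stage: ranking partition ", p)
    fit <- tryCatch(trainRFCV(ds, "tissue_class", config$rf),
                    error = function(e)
                      stop("stage 'rank ", p, "' failed: ",
                           conditionMessage(e), call. = FALSE))
    ranking <- rankWavenumbers(fit)
    rankings[[p]] <- ranking
    utils::write.csv(as.data.frame(ranking),
                     file.path(outDir, paste0("feature_ranking_", p, ".csv")),
                     row.names = FALSE)
    utils::write.csv(fit$cv,
                     file.path(outDir, paste0("cv_metrics_", p, ".csv")),
                     row.names = FALSE)
    parts[[p]] <- list(ds = ds, ranking = ranking)
  }

  # embed all partitions x (before, after) in one umap-learn invocation
  say("stage: UMAP embedding (", length(parts), " partitions x 2 stages)")
  mats <- list(); labs <- list()
  for (p in names(parts)) {
    X <- t(intensityMatrix(parts[[p]]$ds))
    sel <- selectTopK(parts[[p]]$ranking,
                      min(config$rf$topK, ncol(X)))
    idx <- match(sel, wavenumbers(parts[[p]]$ds))
    mats[[paste0(p, ".before")]] <- X
    mats[[paste0(p, ".after")]] <- X[, idx, drop = FALSE]
    labs[[p]] <- spectrumMeta(parts[[p]]$ds)$tissue_class
  }
  emb <- umapEmbedBatch(mats, config$umap)

  silhouette_rows <- list(); comparisons <- list()
  for (p in names(parts)) {
    before <- selectStableEmbedding(emb[[paste0(p, ".before")]],
                                    labels = labs[[p]])
    after <- selectStableEmbedding(emb[[paste0(p, ".after")]],
                                   labels = labs[[p]])
    meta <- spectrumMeta(parts[[p]]$ds)
    for (stage in c("before", "after")) {
      er <- if (stage == "before") before else after
      utils::write.csv(
        data.frame(spectrum_id = meta$spectrum_id,
                   x = er@coords[, 1], y = er@coords[, 2],
                   label = labs[[p]]),
        file.path(outDir, paste0("embedding_", p, "_", stage, ".csv")),
        row.names = FALSE)
    }
    comparisons[[p]] <- list(before = before, after = after)
    silhouette_rows[[p]] <- data.frame(
      partition = p,
      silhouette_before = before@silhouette,
      silhouette_after = after@silhouette,
      delta = after@silhouette - before@silhouette,
      seed_before = before@seed, seed_after = after@seed,
      cv_accuracy = rankings[[p]]@cvAccuracyMean)
  }
  sil <- do.call(rbind, silhouette_rows)
  rownames(sil) <- NULL
  utils::write.csv(sil, file.path(outDir, "silhouette_summary.csv"),
                   row.names = FALSE)

  outFiles <- list.files(outDir, pattern = "\\.(csv|tsv)$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("adipoRaman")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    partitions = config$partitions,
    config = .configSnapshot(config),
    output_hashes = as.list(tools::md5sum(outFiles)),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, silhouette = sil,
                 rankings = rankings, comparisons = comparisons))
}

.configSnapshot <- function(config) {
  strip <- function(x) {
    if (is.function(x)) return("<function>")
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(config)
}

#' Write a markdown report for a completed run
#'
#' Summarizes a [runPipeline()] output directory into a single
#' `report.md`: silhouette table, top-ranked wavenumbers per partition, EMSC
#' diagnostics, and links to every produced artifact. Missing artifacts are
#' listed as absent; regenerating the report is idempotent.
#'
#' @param outDir the pipeline output directory.
#' @return (invisibly) the report path.
#' @export
writeReport <- function(outDir) {
  lines <- c("# Adipocyte Raman pipeline report", "")
  sil_path <- file.path(outDir, "silhouette_summary.csv")
  if (file.exists(sil_path)) {
    sil <- utils::read.csv(sil_path)
    lines <- c(lines, "## Silhouette scores (before vs after feature selection)",
               "",
               "| partition | before | after | delta | CV accuracy |",
               "|---|---|---|---|---|",
               sprintf("| %s | %.3f | %.3f | %+.3f | %.3f |",
                       sil$partition, sil$silhouette_before,
                       sil$silhouette_after, sil$delta, sil$cv_accuracy),
               "")
  } else {
    lines <- c(lines, "Silhouette summary: absent", "")
  }
  rank_files <- list.files(outDir, pattern = "^feature_ranking_.*\\.csv$")
  if (length(rank_files)) {
    lines <- c(lines, "## Top discriminant wavenumbers", "")
    for (f in rank_files) {
      rk <- utils::read.csv(file.path(outDir, f))
      top <- utils::head(rk, 15)
      lines <- c(lines,
                 paste0("- `", f, "`: ",
                        paste(sprintf("%.0f", top$wavenumber), collapse = ", "),
                        " cm^-1"))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "## Top discriminant wavenumbers", "",
               "Ranking panels: absent", "")
  }
  lines <- c(lines, "## Artifacts", "")
  arts <- list.files(outDir, pattern = "\\.(csv|tsv|json|png)$")
  arts <- setdiff(arts, "report.md")
  if (length(arts))
    lines <- c(lines, paste0("- [", arts, "](", arts, ")"))
  else lines <- c(lines, "No artifacts found.")
  path <- file.path(outDir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

#' Scatterplot of an embedding colored by class
#'
#' @param result an [EmbeddingResult-class] (or n x 2 matrix).
#' @param labels class labels (color).
#' @param sample per-point sample ids (shape), optional.
#' @return a `ggplot` object.
#' @export
plotEmbedding <- function(result, labels, sample = NULL) {
  coords <- if (is(result, "EmbeddingResult")) result@coords else as.matrix(result)
  df <- data.frame(UMAP1 = coords[, 1], UMAP2 = coords[, 2],
                   class = as.factor(labels))
  mapping <- ggplot2::aes(x = .data$UMAP1, y = .data$UMAP2,
                          colour = .data$class)
  if (!is.null(sample)) {
    df$sample <- as.factor(sample)
    mapping <- utils::modifyList(mapping,
                                 ggplot2::aes(shape = .data$sample))
  }
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::theme_minimal()
}

#' Overlayed group mean spectra
#'
#' @param x a [RamanSpectra-class] object.
#' @param groupBy metadata column to average within (default
#'   `"tissue_class"`).
#' @return a `ggplot` object.
#' @export
plotMeanSpectra <- function(x, groupBy = "tissue_class") {
  ms <- meanSpectrum(x, groupBy)
  wn <- wavenumbers(x)
  df <- do.call(rbind, lapply(names(ms), function(g)
    data.frame(wavenumber = wn, intensity = ms[[g]], group = g)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber,
                                   y = .data$intensity,
                                   colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "wavenumber (cm-1)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}
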