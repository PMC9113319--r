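# Pipeline plumbing: YAML run configuration, end-to-end decomposition and
# simulation runs with artifact writing and a reproducibility manifest.
# A thin command-line wrapper over these functions ships in
# inst/scripts/omicssvd-cli.R.

.configDefaults <- list(
  K = 2L, alpha = 1, penalty = "lam", lam = 0, degree = NULL,
  degree_grid = NULL, backend = "memory", chunk_rows = 256L,
  cluster = FALSE, k_range = c(2L, 6L), embedding = "none",
  seed = 1L, output_dir = "omicssvd_run",
  n = 150L, p = 350L, latent_rank = 3L, signal_fraction = 0.1,
  n_replicates = 1000L)

#' Read a YAML run configuration
#'
#' Loads the configuration and applies overrides on top (overrides win, so
#' command-line flags can modify a stored config). Unknown keys are
#' rejected; missing keys fall back to package defaults.
#'
#' @param path YAML file, or \code{NULL} to start from defaults only.
#' @param overrides named list applied over the file contents.
#' @return A validated configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .configDefaults
  user <- if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    yaml::read_yaml(path)
  } else list()
  for (src in list(user, overrides)) {
    unknown <- setdiff(names(src), c(names(.configDefaults), "blocks",
                                     "covariates"))
    if (length(unknown))
      stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    cfg[names(src)] <- src
  }
  if (!cfg$penalty %in% c("lam", "degree", "auto"))
    stop("'penalty' must be one of lam, degree, auto")
  if (!cfg$backend %in% c("memory", "chunked"))
    stop("'backend' must be memory or chunked")
  if (!is.null(cfg$signal_fraction) &&
      (cfg$signal_fraction <= 0 || cfg$signal_fraction >= 1))
    stop("'signal_fraction' must lie strictly between 0 and 1")
  cfg
}

.writeManifest <- function(dir, cfg, paths) {
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(config = cfg,
         seed = cfg$seed,
         package = "OmicSSVD",
         package_version = as.character(utils::packageVersion("OmicSSVD")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         artifacts = lapply(stats::setNames(paths, basename(paths)),
                            function(p) unname(tools::md5sum(p)))),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

# run `expr`, removing every artifact it registered if it fails
.withCleanup <- function(expr) {
  written <- character(0)
  register <- function(p) written <<- c(written, p)
  tryCatch(expr(register),
           error = function(e) {
             unlink(written, recursive = TRUE)
             stop(e)
           })
}

#' Run a full decomposition from a configuration
#'
#' Reads the configured omic blocks (and covariates), builds the extended
#' matrix, optionally spills it to the chunked on-disk backend, decomposes
#' it with the configured penalty, optionally clusters and embeds the
#' sample scores, and writes factors, tuning grid, cluster labels, and a
#' manifest (config echo, seed, artifact checksums) to the output
#' directory. On any error, partial outputs of this run are removed before
#' the error propagates.
#'
#' @param config configuration list from \code{\link{readRunConfig}}, with
#'   \code{blocks} = list of \code{list(path =, label =)} entries.
#' @return Invisibly, a list with the fitted \code{SvdFactors}, the
#'   optional \code{ClusterResult}, and the artifact paths.
#' @export
runDecomposition <- function(config) {
  if (is.null(config$blocks) || !length(config$blocks))
    stop("config must name at least one omic block under 'blocks'")
  blocks <- lapply(config$blocks, function(b) {
    if (is.character(b)) b <- list(path = b)
    readOmicBlock(b$path, label = b$label %||% NULL,
                  format = b$format %||% "auto")
  })
  covariates <- if (!is.null(config$covariates))
    readCovariates(config$covariates) else NULL
  em <- buildExtendedMatrix(blocks, covariates)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  .withCleanup(function(register) {
    X <- em
    if (config$backend == "chunked") {
      binPath <- file.path(config$output_dir, "extended.bin")
      X <- writeChunkedMatrix(em, binPath, chunkRows = config$chunk_rows)
      register(c(binPath, paste0(binPath, ".json")))
    }
    penalty <- switch(config$penalty,
      lam = PenaltySpec(alpha = config$alpha, lam = config$lam),
      degree = PenaltySpec(alpha = config$alpha, degree = config$degree),
      auto = "auto")
    fit <- omicSSVD(X, K = config$K, penalty = penalty,
                    alpha = config$alpha,
                    candidateDegrees = config$degree_grid)
    paths <- writeFactors(fit, config$output_dir)
    register(paths)
    clusters <- NULL
    if (isTRUE(config$cluster)) {
      kr <- seq(config$k_range[1], config$k_range[2])
      clusters <- clusterScores(fit, kRange = kr, seed = config$seed)
      coords <- embedScores(fit, method = config$embedding,
                            seed = config$seed)
      cpath <- file.path(config$output_dir, "clusters.tsv")
      writeClusters(clusters, cpath, coords)
      register(cpath)
      paths <- c(paths, cpath)
    }
    manifest <- .writeManifest(config$output_dir, config, paths)
    invisible(list(factors = fit, clusters = clusters,
                   paths = c(paths, manifest)))
  })
}

#' Run the shuffle-decorrelation benchmark from a configuration
#'
#' Delegates to \code{\link{runFeatureBenchmark}}; writes the tidy
#' replicate table, the per-degree curve plot, and a manifest to the output
#' directory. Deterministic given \code{config$seed}.
#'
#' @param config configuration list from \code{\link{readRunConfig}}.
#' @return Invisibly, the \code{\link{BenchmarkResult-class}} and paths.
#' @export
runSimulation <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  .withCleanup(function(register) {
    bench <- runFeatureBenchmark(
      n = config$n, p = config$p, latentRank = config$latent_rank,
      signalFraction = config$signal_fraction,
      nReplicates = config$n_replicates,
      degreeGrid = config$degree_grid, alpha = config$alpha,
      K = config$K, seed = config$seed)
    tpath <- file.path(config$output_dir, "benchmark.tsv")
    writeBenchmark(bench, tpath)
    register(tpath)
    ppath <- file.path(config$output_dir, "benchmark.png")
    plotBenchmark(bench, file = ppath)
    register(ppath)
    manifest <- .writeManifest(config$output_dir, config, c(tpath, ppath))
    invisible(list(benchmark = bench, paths = c(tpath, ppath, manifest)))
  })
}
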