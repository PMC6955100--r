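#' Run the full two-group analysis
#'
#' End-to-end orchestration: read tracings and grouping metadata, compute
#' per-neuron morphometrics and Sholl profiles, compare cohorts per
#' region, and write the report bundle (per-neuron metrics CSV, long
#' Sholl CSV, comparison CSV/JSON, and a JSON run manifest echoing the
#' configuration, package version, seed and any skipped files).
#' Comparisons are run within each region between the two cohorts present
#' there; a region with a single cohort is skipped with a warning.
#'
#' @param inputDir directory of tracing files (one cohort's files may be
#'   mixed with another's; grouping is metadata-driven, never positional).
#' @param outDir output directory, created if absent.
#' @param format \code{"swc"} or \code{"amira"}.
#' @param shollStepUm shell spacing for Sholl profiles (µm).
#' @param shollRanges optional list of \code{c(lo, hi)} radius ranges for
#'   range-wise Sholl tests (µm).
#' @param alpha significance level in (0, 1).
#' @param variant t-test variant, \code{"student"} or \code{"welch"}.
#' @param volumeMode spatial-volume reading, \code{"box"} or
#'   \code{"cube"}; always echoed in outputs.
#' @param convention a \code{\link{namingConvention}} for filename
#'   metadata.
#' @param seed integer seed recorded in the manifest (the analysis itself
#'   is deterministic; the seed feeds any downstream simulation).
#' @return invisibly, a list with \code{metrics}, \code{sholl},
#'   \code{comparisons}, \code{manifest}.
#' @export
runAnalysis <- function(inputDir, outDir, format = c("swc", "amira"),
                        shollStepUm = 30, shollRanges = NULL,
                        alpha = 0.05, variant = c("student", "welch"),
                        volumeMode = c("box", "cube"),
                        convention = namingConvention(), seed = 1L) {
  format <- match.arg(format)
  variant <- match.arg(variant)
  volumeMode <- match.arg(volumeMode)
  stopifnot(alpha > 0, alpha < 1, dir.exists(inputDir))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  trees <- readCohort(inputDir, format = format, convention = convention)
  skipped <- attr(trees, "skipped")
  if (!length(trees))
    stop("fatal input error: no parsable neurons in ", inputDir)

  metrics <- morphometryTable(trees, volumeMode = volumeMode)
  profiles <- lapply(trees, shollProfile, stepUm = shollStepUm)
  shollLong <- shollTable(profiles)

  cohortOf <- vapply(trees, function(t) t@meta@cohort, "")
  regionOf <- vapply(trees, function(t) t@meta@region, "")
  comparisons <- list()
  for (reg in unique(regionOf)) {
    inReg <- regionOf == reg
    cohorts <- sort(unique(cohortOf[inReg]))
    if (length(cohorts) < 2L) {
      warning("region ", reg, " has a single cohort (", cohorts,
              "); comparisons skipped", call. = FALSE)
      next
    }
    if (length(cohorts) > 2L)
      warning("region ", reg, " has ", length(cohorts),
              " cohorts; comparing the first two (",
              paste(cohorts[1:2], collapse = " vs "), ")", call. = FALSE)
    selA <- inReg & cohortOf == cohorts[1L]
    selB <- inReg & cohortOf == cohorts[2L]
    treesA <- trees[selA]; treesB <- trees[selB]
    rows <- lapply(c("length", "terminal_count", "spatial_volume"),
                   function(m) compareMetric(treesA, treesB, metric = m,
                                             variant = variant,
                                             alpha = alpha,
                                             volumeMode = volumeMode))
    sh <- suppressMessages(
      compareSholl(profiles[selA], profiles[selB], mode = "per_shell",
                   variant = variant, alpha = alpha))
    if (!is.null(shollRanges))
      sh <- rbind(sh, suppressMessages(
        compareSholl(profiles[selA], profiles[selB], mode = "range",
                     ranges = shollRanges, variant = variant,
                     alpha = alpha)))
    regRows <- rbind(do.call(rbind, rows), sh)
    regRows <- cbind(region = reg, regRows, stringsAsFactors = FALSE)
    comparisons[[reg]] <- regRows
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
    else NULL
  if (!is.null(comparisons)) rownames(comparisons) <- NULL

  utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(shollLong, file.path(outDir, "sholl.csv"),
                   row.names = FALSE)
  if (!is.null(comparisons))
    comparisonTable(comparisons,
                    csvFile = file.path(outDir, "comparisons.csv"),
                    jsonFile = file.path(outDir, "comparisons.json"))

  manifest <- list(
    package = "neuroarbor",
    version = as.character(utils::packageVersion("neuroarbor")),
    inputDir = inputDir, format = format,
    nNeurons = length(trees), nSkipped = length(skipped),
    skipped = as.list(skipped),
    shollStepUm = shollStepUm, alpha = alpha, variant = variant,
    volumeMode = volumeMode, seed = seed
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metrics = metrics, sholl = shollLong,
                 comparisons = comparisons, manifest = manifest))
}

#' Simulate cohorts to disk
#'
#' Generates each cohort with \code{\link{generateCohort}} and writes all
#' neurons into one directory of SWC files plus a metadata CSV, ready for
#' \code{\link{runAnalysis}}. The generator configuration is echoed into
#' the output directory.
#'
#' @param specs list of \code{\link{cohortSpec}} (or a single one).
#' @param outDir output directory.
#' @param seed master integer seed; cohort \code{i} uses a seed derived
#'   from it by counter.
#' @param convention a \code{\link{namingConvention}}.
#' @return invisibly, the combined metadata data.frame.
#' @export
runSimulation <- function(specs, outDir, seed = 1L,
                          convention = namingConvention()) {
  if (inherits(specs, "cohortSpec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, TRUE, "cohortSpec")))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  trees <- list()
  for (i in seq_along(specs))
    trees <- c(trees, generateCohort(specs[[i]],
                                     seed = .deriveSeed(seed, 1000L + i)))
  md <- writeCohort(trees, outDir, convention = convention)
  cfg <- lapply(specs, function(s)
    c(s[c("label", "nNeurons", "region", "hemisphere", "layer",
          "lengthEffect", "branchProbEffect")], unclass(s$params)))
  jsonlite::write_json(list(seed = seed, cohorts = cfg),
                       file.path(outDir, "simulation-config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(md)
}

#' Read a flat key/value simulation config
#'
#' Parses a plain-text config of \code{key = value} lines describing a
#' two-cohort simulation (used by the command-line wrapper). Recognised
#' keys: \code{label_a}, \code{label_b}, \code{n_neurons}, \code{region},
#' the \code{\link{growthParams}} fields in snake_case
#' (\code{n_stems}, \code{mean_branch_len_um}, \code{branch_len_cv},
#' \code{branch_prob}, \code{max_order}, \code{angle_spread_deg},
#' \code{step_um}), and planted effects for cohort B
#' (\code{length_effect_b}, \code{branch_prob_effect_b}). Unknown keys
#' are a configuration error naming the key.
#'
#' @param file path to the config file.
#' @return list of two \code{\link{cohortSpec}}.
#' @export
readSimulationConfig <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[grepl("\\S", lines) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop("configuration error: malformed line '", lines[bad[1L]], "'")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  known <- c("label_a", "label_b", "n_neurons", "region", "n_stems",
             "mean_branch_len_um", "branch_len_cv", "branch_prob",
             "max_order", "angle_spread_deg", "step_um",
             "length_effect_b", "branch_prob_effect_b")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "))
  get <- function(key, default) {
    if (key %in% keys) vals[match(key, keys)] else default
  }
  num <- function(key, default) as.numeric(get(key, default))
  params <- growthParams(
    nStems = num("n_stems", 3), meanBranchLenUm = num("mean_branch_len_um", 47),
    branchLenCv = num("branch_len_cv", 0.4), branchProb = num("branch_prob", 0.8),
    maxOrder = num("max_order", 3), angleSpreadDeg = num("angle_spread_deg", 35),
    stepUm = num("step_um", 10))
  n <- as.integer(num("n_neurons", 60))
  if (is.na(n) || n < 1L)
    stop("configuration error: field n_neurons must be a positive integer")
  region <- get("region", "PFC")
  list(
    cohortSpec(get("label_a", "AD06"), nNeurons = n, params = params,
               region = region),
    cohortSpec(get("label_b", "AD12"), nNeurons = n, params = params,
               region = region,
               lengthEffect = num("length_effect_b", 1),
               branchProbEffect = num("branch_prob_effect_b", 1))
  )
}
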