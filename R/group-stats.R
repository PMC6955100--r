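#' Group summary: mean and SEM
#'
#' @param values numeric vector of per-neuron (or per-block) values,
#'   length >= 2.
#' @param label group label.
#' @return one-row data.frame: \code{label}, \code{n}, \code{mean},
#'   \code{sem} (sd with the n-1 denominator, divided by sqrt(n)).
#' @examples
#' summarizeGroup(c(1, 2, 3), "A")  # mean 2, sem 0.5774
#' @export
summarizeGroup <- function(values, label = "group") {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("sample-size error: group '", label, "' has n = ", length(values),
         " (need n >= 2 for an SEM)")
  data.frame(label = label, n = length(values), mean = mean(values),
             sem = stats::sd(values) / sqrt(length(values)),
             stringsAsFactors = FALSE)
}

#' Two-sample t-test
#'
#' Two-sided comparison of two independent samples. The default variant is
#' Student's pooled-variance t with \eqn{df = n_1 + n_2 - 2} (the
#' historical default of common statistics software when only "t-test" is
#' specified); Welch's unequal-variance t with Satterthwaite df is
#' selectable. Degenerate zero-variance samples are handled by a limiting
#' convention: both samples constant and equal gives t = 0, p = 1; both
#' constant but unequal gives an infinite t and p = 0.
#'
#' @param xs,ys numeric samples, each n >= 2.
#' @param variant \code{"student"} or \code{"welch"}.
#' @param alpha significance level for the \code{significant} flag.
#' @return one-row data.frame: \code{t}, \code{df}, \code{p},
#'   \code{significant}, \code{variant}.
#' @examples
#' twoSampleT(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
twoSampleT <- function(xs, ys, variant = c("student", "welch"),
                       alpha = 0.05) {
  variant <- match.arg(variant)
  stopifnot(alpha > 0, alpha < 1)
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) < 2L || length(ys) < 2L)
    stop("sample-size error: both samples need n >= 2")
  vx <- stats::var(xs); vy <- stats::var(ys)
  if (vx == 0 && vy == 0) {
    dfOut <- if (variant == "student") length(xs) + length(ys) - 2 else NA_real_
    if (mean(xs) == mean(ys)) {
      tOut <- 0; pOut <- 1
    } else {
      tOut <- sign(mean(xs) - mean(ys)) * Inf; pOut <- 0
    }
    return(data.frame(t = tOut, df = dfOut, p = pOut,
                      significant = pOut < alpha, variant = variant,
                      stringsAsFactors = FALSE))
  }
  ht <- stats::t.test(xs, ys, var.equal = (variant == "student"))
  data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, significant = ht$p.value < alpha,
             variant = variant, stringsAsFactors = FALSE)
}

## Shared assembly of a one-row comparison record.
.compareValues <- function(metric, valuesA, valuesB, labelA, labelB,
                           variant, alpha) {
  sa <- summarizeGroup(valuesA, labelA)
  sb <- summarizeGroup(valuesB, labelB)
  tt <- twoSampleT(valuesA, valuesB, variant = variant, alpha = alpha)
  data.frame(
    metric = metric,
    group_a = sa$label, n_a = sa$n, mean_a = sa$mean, sem_a = sa$sem,
    group_b = sb$label, n_b = sb$n, mean_b = sb$mean, sem_b = sb$sem,
    t = tt$t, df = tt$df, p = tt$p, significant = tt$significant,
    variant = tt$variant, stringsAsFactors = FALSE
  )
}

#' Compare one morphometric between two cohorts
#'
#' Computes the per-neuron metric in each cohort, then mean ± SEM per
#' group and a two-sample t-test. The unit of analysis is the neuron.
#'
#' @param treesA,treesB lists of \code{\linkS4class{NeuronTree}}, the two
#'   cohorts.
#' @param metric one of \code{"length"}, \code{"terminal_count"},
#'   \code{"spatial_volume"}.
#' @param labelA,labelB group labels; default: the cohort label of each
#'   group's first neuron.
#' @param variant,alpha see \code{\link{twoSampleT}}.
#' @param volumeMode see \code{\link{spatialVolume}}; recorded in the
#'   metric name when the metric is the volume.
#' @return one-row comparison data.frame (see \code{\link{comparisonTable}}
#'   columns).
#' @export
compareMetric <- function(treesA, treesB,
                          metric = c("length", "terminal_count",
                                     "spatial_volume"),
                          labelA = NULL, labelB = NULL,
                          variant = c("student", "welch"), alpha = 0.05,
                          volumeMode = c("box", "cube")) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  volumeMode <- match.arg(volumeMode)
  stopifnot(length(treesA) >= 1L, length(treesB) >= 1L)
  metricFun <- switch(metric,
    length = totalDendriticLength,
    terminal_count = function(t) suppressWarnings(terminalCount(t)),
    spatial_volume = function(t) spatialVolume(t, mode = volumeMode))
  va <- vapply(treesA, metricFun, 1.0)
  vb <- vapply(treesB, metricFun, 1.0)
  if (is.null(labelA)) labelA <- treesA[[1L]]@meta@cohort
  if (is.null(labelB)) labelB <- treesB[[1L]]@meta@cohort
  name <- if (metric == "spatial_volume")
    sprintf("spatial_volume[%s]", volumeMode) else metric
  .compareValues(name, va, vb, labelA, labelB, variant, alpha)
}

#' Compare Sholl profiles between two cohorts
#'
#' Profiles are first aligned onto a common shell grid (shorter profiles
#' zero-padded). In \code{per_shell} mode one t-test is run per shell
#' radius; in \code{range} mode each configured radius range is reduced to
#' one per-neuron sum via \code{\link{aggregateRange}} before a single
#' test, which avoids pseudo-replication across shells. No
#' multiple-testing correction is applied by default (each shell or range
#' is reported at the nominal level); Holm adjustment is available via
#' \code{correction}, and a note on the number of comparisons is emitted
#' as a message.
#'
#' @param profilesA,profilesB lists of \code{\linkS4class{ShollProfile}}.
#' @param mode \code{"per_shell"} or \code{"range"}.
#' @param ranges for \code{range} mode: list of numeric \code{c(lo, hi)}
#'   bounds in µm.
#' @param labelA,labelB group labels (defaults from profile metadata).
#' @param variant,alpha see \code{\link{twoSampleT}}.
#' @param correction \code{"none"} (default) or \code{"holm"}.
#' @return data.frame with one comparison row per shell or per range,
#'   metric named \code{sholl_shell@r} or \code{sholl_range@lo-hi}.
#' @export
compareSholl <- function(profilesA, profilesB,
                         mode = c("per_shell", "range"), ranges = NULL,
                         labelA = NULL, labelB = NULL,
                         variant = c("student", "welch"), alpha = 0.05,
                         correction = c("none", "holm")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  correction <- match.arg(correction)
  stopifnot(length(profilesA) >= 2L, length(profilesB) >= 2L)
  if (is.null(labelA)) labelA <- profilesA[[1L]]@meta@cohort
  if (is.null(labelB)) labelB <- profilesB[[1L]]@meta@cohort

  aligned <- alignShollProfiles(c(profilesA, profilesB))
  nA <- length(profilesA)
  countsA <- aligned$counts[seq_len(nA), , drop = FALSE]
  countsB <- aligned$counts[-seq_len(nA), , drop = FALSE]

  if (mode == "per_shell") {
    rows <- lapply(seq_along(aligned$radii), function(i) {
      .compareValues(sprintf("sholl_shell@%g", aligned$radii[i]),
                     countsA[, i], countsB[, i], labelA, labelB,
                     variant, alpha)
    })
  } else {
    if (is.null(ranges) || !length(ranges))
      stop("range mode needs a list of c(lo, hi) ranges")
    step <- profilesA[[1L]]@stepUm
    rows <- lapply(ranges, function(rg) {
      stopifnot(length(rg) == 2L, rg[1L] <= rg[2L])
      lo <- floor(rg[1L] / step) * step
      hi <- ceiling(rg[2L] / step) * step
      if (lo != rg[1L] || hi != rg[2L])
        warning(sprintf("range [%g, %g] snapped outward to [%g, %g]",
                        rg[1L], rg[2L], lo, hi), call. = FALSE)
      sel <- aligned$radii >= lo & aligned$radii <= hi
      .compareValues(sprintf("sholl_range@%g-%g", lo, hi),
                     rowSums(countsA[, sel, drop = FALSE]),
                     rowSums(countsB[, sel, drop = FALSE]),
                     labelA, labelB, variant, alpha)
    })
  }
  out <- do.call(rbind, rows)
  message(sprintf(
    "compareSholl: %d comparisons at nominal alpha = %g (correction: %s)",
    nrow(out), alpha, correction))
  if (correction == "holm") {
    out$p_adjusted <- stats::p.adjust(out$p, method = "holm")
    out$significant <- out$p_adjusted < alpha
  }
  out
}

#' Write a comparison report
#'
#' @param comparisons data.frame of comparison rows (from
#'   \code{\link{compareMetric}} / \code{\link{compareSholl}}, rbind-ed).
#' @param csvFile,jsonFile output paths (either may be NULL).
#' @return the data.frame, invisibly.
#' @export
comparisonTable <- function(comparisons, csvFile = NULL, jsonFile = NULL) {
  if (!is.null(csvFile))
    utils::write.csv(comparisons, csvFile, row.names = FALSE)
  if (!is.null(jsonFile))
    jsonlite::write_json(comparisons, jsonFile, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(comparisons)
}
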