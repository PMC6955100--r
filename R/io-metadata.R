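#' Filename naming convention for specimen metadata
#'
#' Tracing archives encode the grouping of each neuron in the file name:
#' cohort, brain-region abbreviation, hemisphere, layer position and
#' neuron number. The exact separators and casing vary between archives,
#' so the convention is configurable as an ordered token pattern rather
#' than hard-coded. The default expects
#' \code{<cohort>_<region>_<hemisphere>_<layer>_<index>.<ext>}, e.g.
#' \code{"AD06_CA1_L_L1_003.swc"}.
#'
#' @param tokens character vector naming the ordered tokens; a permutation
#'   of \code{c("cohort", "region", "hemisphere", "layer", "index")}.
#' @param sep single-character token separator.
#' @param cohorts,regions controlled vocabularies; tokens outside them are
#'   rejected rather than silently accepted.
#' @param hemispheres accepted hemisphere codes.
#' @return A list of class \code{"namingConvention"}.
#' @export
namingConvention <- function(tokens = c("cohort", "region", "hemisphere",
                                        "layer", "index"),
                             sep = "_",
                             cohorts = c("AD06", "AD12", "WT"),
                             regions = c("PFC", "PMC", "EC", "CA1"),
                             hemispheres = c("L", "R")) {
  stopifnot(setequal(tokens, c("cohort", "region", "hemisphere", "layer",
                               "index")),
            nchar(sep) == 1L)
  structure(list(tokens = tokens, sep = sep, cohorts = cohorts,
                 regions = regions, hemispheres = hemispheres),
            class = "namingConvention")
}

#' Parse specimen metadata from a file name
#'
#' @param filename file name (directories and extension are ignored).
#' @param convention a \code{\link{namingConvention}}.
#' @return A \code{\linkS4class{SpecimenMeta}}.
#' @examples
#' parseSpecimenMetadata("AD06_CA1_L_L1_003.swc")
#' @export
parseSpecimenMetadata <- function(filename,
                                  convention = namingConvention()) {
  stopifnot(inherits(convention, "namingConvention"))
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(filename))
  parts <- strsplit(base, convention$sep, fixed = TRUE)[[1L]]
  expected <- sprintf("<%s>", paste(convention$tokens,
                                    collapse = paste0(">", convention$sep, "<")))
  if (length(parts) != length(convention$tokens))
    stop("metadata error: '", filename, "' does not match the expected ",
         "pattern ", expected)
  names(parts) <- convention$tokens
  if (!parts[["cohort"]] %in% convention$cohorts)
    stop("metadata error: unknown cohort '", parts[["cohort"]],
         "' (expected one of ", paste(convention$cohorts, collapse = ", "), ")")
  if (!parts[["region"]] %in% convention$regions)
    stop("metadata error: unknown region '", parts[["region"]],
         "' (expected one of ", paste(convention$regions, collapse = ", "), ")")
  if (!parts[["hemisphere"]] %in% convention$hemispheres)
    stop("metadata error: unknown hemisphere '", parts[["hemisphere"]], "'")
  idx <- suppressWarnings(as.integer(parts[["index"]]))
  if (is.na(idx))
    stop("metadata error: non-numeric neuron index '", parts[["index"]], "'")
  SpecimenMeta(cohort = parts[["cohort"]], region = parts[["region"]],
               hemisphere = parts[["hemisphere"]], layer = parts[["layer"]],
               neuronIndex = idx)
}

#' Format a file name from specimen metadata
#'
#' Inverse of \code{\link{parseSpecimenMetadata}} under the same
#' convention; used when writing synthetic cohorts to disk.
#'
#' @param meta a \code{\linkS4class{SpecimenMeta}}.
#' @param convention a \code{\link{namingConvention}}.
#' @param ext file extension (without dot).
#' @return character(1) file name.
#' @export
formatSpecimenFilename <- function(meta, convention = namingConvention(),
                                   ext = "swc") {
  vals <- c(cohort = meta@cohort, region = meta@region,
            hemisphere = meta@hemisphere, layer = meta@layer,
            index = sprintf("%03d", meta@neuronIndex))
  paste0(paste(vals[convention$tokens], collapse = convention$sep),
         ".", ext)
}

#' Read / write a cohort metadata table
#'
#' The on-disk companion of a directory of tracing files: one row per
#' neuron with columns cohort, region, hemisphere, layer, index, path.
#'
#' @param metas list of \code{\linkS4class{SpecimenMeta}}.
#' @param paths character vector of file paths, parallel to \code{metas}.
#' @param file CSV path.
#' @return \code{writeCohortMetadata}: the data.frame, invisibly;
#'   \code{readCohortMetadata}: the data.frame.
#' @export
writeCohortMetadata <- function(metas, paths, file) {
  df <- data.frame(
    cohort = vapply(metas, function(m) m@cohort, ""),
    region = vapply(metas, function(m) m@region, ""),
    hemisphere = vapply(metas, function(m) m@hemisphere, ""),
    layer = vapply(metas, function(m) m@layer, ""),
    index = vapply(metas, function(m) m@neuronIndex, 1L),
    path = paths,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' @rdname writeCohortMetadata
#' @export
readCohortMetadata <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("cohort", "region", "hemisphere", "layer", "index", "path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata error: CSV lacks column(s): ", paste(miss, collapse = ", "))
  df
}
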