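#' Construct a polysome profile trace
#'
#' A profile trace is the sampled UV absorbance (A254) of a sucrose gradient
#' as a function of sedimentation depth, in millimetres from the gradient top.
#' It is represented as a tibble with columns `position_mm` and `a254` plus
#' metadata attributes describing the sample.
#'
#' @param position_mm Numeric vector of positions in mm from the gradient top,
#'   strictly increasing, at least 32 points.
#' @param a254 Numeric vector of absorbance values (arbitrary A254 units),
#'   same length as `position_mm`, all finite.
#' @param sample_id Sample identifier string.
#' @param treatment One of `"CHX"`, `"HRN"`, `"HRN+EDTA"`, `"HRN+PMY"`,
#'   `"RNase1"`, `"NMDA"`, `"control"`. `"CHX"` (cycloheximide only) is the
#'   t = 0 reference of a runoff series.
#' @param runoff_time_min Harringtonine runoff time in minutes, `>= 0`. Must be
#'   0 for no-runoff controls (CHX, control, RNase1) and positive for
#'   HRN-family treatments.
#' @param gradient `"standard_18_50"` (18--50 % sucrose) or `"highres_5_25"`
#'   (5--25 %, resolves 80S and disome peaks).
#' @param cell_type Optional cell-type label.
#' @param replicate Replicate index (integer).
#' @param baseline_corrected Logical; has a baseline been subtracted yet?
#'
#' @return A tibble of class `"profile_trace"`.
#' @export
#' @examples
#' x <- seq(0, 60, by = 0.5)
#' tr <- profile_trace(x, 0.1 + dnorm(x, 20, 1), treatment = "CHX")
profile_trace <- function(position_mm, a254,
                          sample_id = "sample",
                          treatment = "CHX",
                          runoff_time_min = 0,
                          gradient = "standard_18_50",
                          cell_type = NA_character_,
                          replicate = 1L,
                          baseline_corrected = FALSE) {
  out <- tibble(position_mm = as.numeric(position_mm), a254 = as.numeric(a254))
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "treatment") <- as.character(treatment)
  attr(out, "runoff_time_min") <- as.numeric(runoff_time_min)
  attr(out, "gradient") <- as.character(gradient)
  attr(out, "cell_type") <- as.character(cell_type)
  attr(out, "replicate") <- as.integer(replicate)
  attr(out, "baseline_corrected") <- isTRUE(baseline_corrected)
  class(out) <- c("profile_trace", class(out))
  validate_profile_trace(out)
}

trace_treatments <- c("CHX", "HRN", "HRN+EDTA", "HRN+PMY", "RNase1", "NMDA",
                      "control")
no_runoff_treatments <- c("CHX", "control", "RNase1")
trace_gradients <- c("standard_18_50", "highres_5_25")

#' Validate a profile trace
#'
#' Checks geometry (strictly increasing positions, at least 32 points),
#' finiteness of the absorbance, treatment/time consistency and, for
#' baseline-corrected traces, non-negativity up to a 1e-9 tolerance.
#'
#' @param trace A `profile_trace`.
#' @return The trace, invisibly validated (returned unchanged).
#' @export
validate_profile_trace <- function(trace) {
  if (!inherits(trace, "profile_trace")) {
    stop_format("not a profile_trace object")
  }
  pos <- trace$position_mm
  ab <- trace$a254
  if (length(pos) < 32L) {
    stop_format(sprintf("trace has %d points; at least 32 required", length(pos)))
  }
  if (anyNA(pos) || any(!is.finite(pos))) stop_format("non-finite position value")
  if (anyNA(ab) || any(!is.finite(ab))) stop_format("non-finite absorbance value")
  if (any(diff(pos) <= 0)) {
    stop_geometry("positions must be strictly increasing (traces are never re-sorted)")
  }
  tre <- trace_treatment(trace)
  if (!tre %in% trace_treatments) {
    stop_format(sprintf("unknown treatment '%s'", tre))
  }
  if (!trace_gradient(trace) %in% trace_gradients) {
    stop_format(sprintf("unknown gradient '%s'", trace_gradient(trace)))
  }
  t_run <- trace_runoff_time(trace)
  if (is.na(t_run) || t_run < 0) stop_format("runoff_time_min must be >= 0")
  if (tre %in% no_runoff_treatments && t_run != 0) {
    stop_format(sprintf("treatment '%s' is a no-runoff control but runoff_time_min = %g",
                        tre, t_run))
  }
  if (grepl("^HRN", tre) && t_run == 0) {
    stop_format(sprintf("treatment '%s' implies runoff but runoff_time_min = 0", tre))
  }
  if (isTRUE(attr(trace, "baseline_corrected")) && min(ab) < -1e-9) {
    stop_format("baseline-corrected trace has absorbance below -1e-9")
  }
  trace
}

trace_meta_keys <- c("sample_id", "treatment", "runoff_time_min", "gradient",
                     "cell_type", "replicate", "baseline_corrected")

trace_sample_id <- function(trace) attr(trace, "sample_id")
trace_treatment <- function(trace) attr(trace, "treatment")
trace_runoff_time <- function(trace) attr(trace, "runoff_time_min")
trace_gradient <- function(trace) attr(trace, "gradient")

#' Metadata of a profile trace as a one-row tibble
#'
#' @param trace A `profile_trace`.
#' @return One-row tibble with the trace's metadata fields.
#' @export
trace_meta <- function(trace) {
  tibble(
    sample_id = trace_sample_id(trace),
    treatment = trace_treatment(trace),
    runoff_time_min = trace_runoff_time(trace),
    gradient = trace_gradient(trace),
    cell_type = attr(trace, "cell_type"),
    replicate = attr(trace, "replicate"),
    baseline_corrected = attr(trace, "baseline_corrected")
  )
}

#' @export
print.profile_trace <- function(x, ...) {
  cat(sprintf("<profile_trace> %s | %s | t = %g min | %s%s\n",
              trace_sample_id(x), trace_treatment(x), trace_runoff_time(x),
              trace_gradient(x),
              if (attr(x, "baseline_corrected")) " | baseline-corrected" else ""))
  cat(sprintf("  %d points, %.2f-%.2f mm, A254 range %.4g-%.4g\n",
              nrow(x), min(x$position_mm), max(x$position_mm),
              min(x$a254), max(x$a254)))
  invisible(x)
}

#' Read a profile trace from a delimited text file
#'
#' The file format is two numeric columns (`position_mm`, `a254`), optionally
#' preceded by `# key: value` metadata header lines and an optional column
#' header line. Metadata keys recognised are `sample_id`, `treatment`,
#' `runoff_time_min`, `gradient`, `cell_type`, `replicate` and
#' `baseline_corrected`; header values override the defaults (and any
#' sample-sheet values supplied via `...`).
#'
#' Files with non-monotone positions are rejected with a geometry error --
#' they are never silently re-sorted.
#'
#' @param path Path to a CSV or TSV trace file.
#' @param dialect `"autodetect"` (default), `"csv"` or `"tsv"`.
#' @param ... Default metadata fields (as in [profile_trace()]) that header
#'   lines may override.
#' @return A validated [profile_trace()].
#' @export
read_trace <- function(path, dialect = c("autodetect", "csv", "tsv"), ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_meta <- startsWith(trimws(lines), "#")
  meta_lines <- lines[is_meta]
  data_lines <- lines[!is_meta]
  if (length(data_lines) == 0L) stop_format("no data rows in trace file")

  sep <- switch(dialect,
    csv = ",", tsv = "\t",
    autodetect = if (grepl("\t", data_lines[[1]])) "\t" else ","
  )

  # optional single header line naming the two columns
  first <- strsplit(data_lines[[1]], sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(trimws(first)))))
  if (has_header) data_lines <- data_lines[-1]
  if (length(data_lines) < 32L) {
    stop_format(sprintf("trace has %d data rows; at least 32 required",
                        length(data_lines)))
  }

  cells <- strsplit(data_lines, sep, fixed = TRUE)
  ncol_ok <- vapply(cells, length, integer(1)) >= 2L
  if (!all(ncol_ok)) {
    stop_format(sprintf("row %d does not have two columns", which(!ncol_ok)[1]))
  }
  pos <- suppressWarnings(as.numeric(trimws(vapply(cells, `[[`, "", 1L))))
  ab <- suppressWarnings(as.numeric(trimws(vapply(cells, `[[`, "", 2L))))
  bad <- which(is.na(pos) | is.na(ab))
  if (length(bad) > 0L) {
    stop_format(sprintf("non-numeric cell in data row %d", bad[1]))
  }

  meta <- list(...)
  for (ml in meta_lines) {
    kv <- sub("^\\s*#\\s*", "", ml)
    if (!grepl(":", kv, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key %in% trace_meta_keys && nzchar(val)) meta[[key]] <- val
  }
  args <- list(position_mm = pos, a254 = ab)
  if (!is.null(meta$sample_id)) args$sample_id <- meta$sample_id
  if (!is.null(meta$treatment)) args$treatment <- meta$treatment
  if (!is.null(meta$runoff_time_min)) args$runoff_time_min <- as.numeric(meta$runoff_time_min)
  if (!is.null(meta$gradient)) args$gradient <- meta$gradient
  if (!is.null(meta$cell_type)) args$cell_type <- meta$cell_type
  if (!is.null(meta$replicate)) args$replicate <- as.integer(as.numeric(meta$replicate))
  if (!is.null(meta$baseline_corrected)) {
    args$baseline_corrected <- as.logical(meta$baseline_corrected)
  }
  do.call(profile_trace, args)
}

#' Write a profile trace to a TSV file
#'
#' Writes `# key: value` metadata header lines followed by a two-column TSV
#' (`position_mm`, `a254`). Values are written with 17 significant digits so
#' that a write/read round trip is lossless to better than 1e-12.
#'
#' @param trace A validated [profile_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_profile_trace(trace)
  meta <- trace_meta(trace)
  hdr <- character(0)
  for (key in trace_meta_keys) {
    val <- meta[[key]]
    if (is.null(val) || length(val) == 0L || is.na(val) || identical(val, "")) next
    hdr <- c(hdr, sprintf("# %s: %s", key, format(val)))
  }
  body <- sprintf("%.17g\t%.17g", trace$position_mm, trace$a254)
  out <- c(hdr, "position_mm\ta254", body)
  ok <- tryCatch({
    writeLines(out, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_riborunoff("io_error", sprintf("cannot write trace to '%s'", path))
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet is a CSV with columns `path`, `sample_id`, `treatment`,
#' `runoff_time_min`, `gradient` and optional `cell_type`, `replicate`.
#' `sample_id` must be unique.
#'
#' @param path CSV file path.
#' @return A tibble with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                  comment.char = "#"))
  needed <- c("path", "sample_id", "treatment", "runoff_time_min", "gradient")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop_format(sprintf("sample sheet lacks columns: %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) stop_design("sample_id values must be unique")
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (!"cell_type" %in% names(df)) df$cell_type <- NA_character_
  df
}
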