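#' Baseline-correct a profile trace
#'
#' Estimates and subtracts the optical baseline of a gradient trace.
#' `linear_endpoints` fits a straight line through the mean of the first and
#' last 2 % of points (adequate for a constant or linearly drifting offset);
#' `rolling_minimum` uses a running minimum over a window, smoothed by a
#' running mean of the same width, for baselines that drift non-linearly.
#' Residual negative values (noise dipping below the estimated baseline) are
#' clipped to zero, so the corrected trace satisfies `min(a254) >= -1e-9`.
#'
#' @param trace A [profile_trace()] that has not been baseline-corrected yet.
#' @param method `"linear_endpoints"` (default) or `"rolling_minimum"`.
#' @param window Window width in mm for `rolling_minimum`; must be positive
#'   and should exceed the widest contiguous peak structure of the trace
#'   (default 25 mm).
#' @return The corrected trace with `baseline_corrected = TRUE`.
#' @export
correct_baseline <- function(trace, method = c("linear_endpoints", "rolling_minimum"),
                             window = 25) {
  method <- match.arg(method)
  validate_profile_trace(trace)
  if (isTRUE(attr(trace, "baseline_corrected"))) {
    stop_idempotence("trace is already baseline-corrected")
  }
  if (!is.numeric(window) || window <= 0) stop_parameter("window must be > 0 mm")
  pos <- trace$position_mm
  ab <- trace$a254
  n <- length(pos)

  if (method == "linear_endpoints") {
    k <- max(2L, ceiling(0.02 * n))
    x1 <- mean(pos[seq_len(k)]); y1 <- mean(ab[seq_len(k)])
    x2 <- mean(pos[(n - k + 1L):n]); y2 <- mean(ab[(n - k + 1L):n])
    slope <- (y2 - y1) / (x2 - x1)
    baseline <- y1 + slope * (pos - x1)
  } else {
    # morphological opening (rolling min, then rolling max) tracks a drifting
    # baseline without the half-window downward bias of a plain rolling
    # minimum, then a rolling mean smooths the corners
    step <- median(diff(pos))
    w <- max(3L, 2L * floor(window / step / 2L) + 1L)  # odd window in samples
    half <- (w - 1L) %/% 2L
    roll <- function(x, fun) {
      padded <- c(rep(x[1], half), x, rep(x[n], half))
      vapply(seq_len(n), function(i) fun(padded[i:(i + w - 1L)]), numeric(1))
    }
    baseline <- roll(roll(roll(ab, min), max), mean)
  }

  corrected <- pmax(ab - baseline, 0)
  out <- trace
  out$a254 <- corrected
  attr(out, "baseline_corrected") <- TRUE
  validate_profile_trace(out)
}

#' Default peak search windows for a gradient type
#'
#' Windows (mm from gradient top) within which the ribosomal-species peaks of
#' the built-in trace geometry are sought. These match the peak layout used by
#' [synthesize_trace()] and are starting points for real traces, where windows
#' should be adjusted to the fractionator at hand.
#'
#' @param gradient `"standard_18_50"` or `"highres_5_25"`.
#' @return Named list of `c(lo, hi)` windows.
#' @export
default_search_windows <- function(gradient = "standard_18_50") {
  switch(gradient,
    standard_18_50 = list(
      "40S" = c(8, 13), "60S" = c(13, 17), "80S" = c(17, 26.5)
    ),
    highres_5_25 = list(
      "40S" = c(4, 9), "60S" = c(9, 14), "80S" = c(14, 24), disome = c(24, 34)
    ),
    stop_parameter(sprintf("unknown gradient '%s'", gradient))
  )
}

#' Detect peaks in a baseline-corrected trace
#'
#' Within each search window the local maximum of greatest prominence is
#' reported; its centre is refined by fitting a parabola through the three
#' points around the sampled maximum. Prominence of a candidate is its height
#' above the higher of the two minima separating it from the window edges.
#'
#' @param trace A baseline-corrected [profile_trace()].
#' @param search_windows Named list mapping a peak label (e.g. `"80S"`,
#'   `"disome"`) to a `c(lo, hi)` window in mm.
#' @param min_prominence Minimum prominence (A254 units) for a peak to count.
#' @param required Labels whose absence is an error; windows for other labels
#'   that contain no qualifying peak are silently dropped (e.g. subunit peaks
#'   are absent without EDTA).
#' @return A tibble of class `"peak_set"` with columns `label`, `center_mm`,
#'   `height`, `window_lo`, `window_hi`, ordered by centre.
#' @export
detect_peaks <- function(trace, search_windows = NULL, min_prominence = 0.01,
                         required = "80S") {
  validate_profile_trace(trace)
  if (!isTRUE(attr(trace, "baseline_corrected"))) {
    stop_parameter("detect_peaks requires a baseline-corrected trace")
  }
  if (is.null(search_windows)) {
    search_windows <- default_search_windows(trace_gradient(trace))
  }
  pos <- trace$position_mm
  ab <- trace$a254
  miss <- setdiff(required, names(search_windows))
  if (length(miss) > 0L) {
    stop_peak(sprintf("no search window for required peak '%s'", miss[1]))
  }
  rows <- imap(search_windows, function(win, label) {
    if (!label %in% required) {
      return(tryCatch(detect_one_peak(trace, win, label, min_prominence),
                      peak_not_found_error = function(e) NULL))
    }
    detect_one_peak(trace, win, label, min_prominence)
  })
  out <- arrange(bind_rows(keep(rows, ~ !is.null(.x))), .data$center_mm)
  class(out) <- c("peak_set", class(out))
  out
}

detect_one_peak <- function(trace, win, label, min_prominence) {
  pos <- trace$position_mm
  ab <- trace$a254
  {
    idx <- which(pos >= win[1] & pos <= win[2])
    if (length(idx) < 3L) {
      stop_peak(sprintf("window for '%s' contains fewer than 3 samples", label))
    }
    y <- ab[idx]
    m <- length(y)
    interior <- 2:(m - 1L)
    is_max <- y[interior] >= y[interior - 1L] & y[interior] > y[interior + 1L]
    cand <- interior[is_max]
    if (length(cand) == 0L) {
      stop_peak(sprintf("no local maximum in window for '%s'", label))
    }
    prom <- vapply(cand, function(i) {
      left_min <- min(y[1:i]); right_min <- min(y[i:m])
      y[i] - max(left_min, right_min)
    }, numeric(1))
    keep <- prom >= min_prominence
    if (!any(keep)) {
      stop_peak(sprintf("no peak above prominence %g in window for '%s'",
                        min_prominence, label))
    }
    best <- cand[keep][which.max(prom[keep])]
    i0 <- idx[best]
    # 3-point parabolic refinement on the (possibly non-uniform) grid
    xs <- pos[(i0 - 1L):(i0 + 1L)]
    ys <- ab[(i0 - 1L):(i0 + 1L)]
    co <- stats::coef(stats::lm(ys ~ xs + I(xs^2)))
    center <- if (is.na(co[3]) || co[3] >= 0) xs[2] else unname(-co[2] / (2 * co[3]))
    if (center < xs[1] || center > xs[3]) center <- xs[2]
    tibble(label = label, center_mm = center, height = ys[2],
           window_lo = win[1], window_hi = win[2])
  }
}

#' Segment a trace into subunit, monosome and polysome regions
#'
#' Implements the fixed monosome-to-polysome offset rule: the polysome region
#' begins a constant distance (default 8.9 mm) downstream of the 80S peak
#' centre. The monosome region spans from the start of the 80S search window
#' to that boundary; everything to the left is the ribosomal-subunit region.
#'
#' @param peaks A `peak_set` containing an `"80S"` peak.
#' @param mono_poly_offset Offset in mm between the 80S peak centre and the
#'   start of the polysome region (default 8.9).
#' @param gradient_end End of the usable gradient in mm; material beyond it
#'   (the pellet) is excluded.
#' @return A list of class `"region_scheme"` with elements `subunit_region`,
#'   `monosome_region`, `polysome_region` (each `c(lo, hi)` mm) and
#'   `mono_poly_offset`.
#' @export
segment_regions <- function(peaks, mono_poly_offset = 8.9, gradient_end = 60) {
  if (!inherits(peaks, "peak_set")) stop_parameter("peaks must be a peak_set")
  if (mono_poly_offset < 0) stop_parameter("mono_poly_offset must be >= 0")
  row <- peaks[peaks$label == "80S", , drop = FALSE]
  if (nrow(row) != 1L) stop_peak("peak set must contain exactly one 80S peak")
  boundary <- row$center_mm + mono_poly_offset
  if (boundary >= gradient_end) {
    stop_segmentation(sprintf(
      "80S centre %.2f + offset %.2f reaches past gradient end %.2f",
      row$center_mm, mono_poly_offset, gradient_end))
  }
  structure(list(
    subunit_region = c(0, row$window_lo),
    monosome_region = c(row$window_lo, boundary),
    polysome_region = c(boundary, gradient_end),
    mono_poly_offset = mono_poly_offset
  ), class = "region_scheme")
}

#' @export
print.region_scheme <- function(x, ...) {
  cat(sprintf(paste0("<region_scheme> subunits [%.1f, %.1f) | monosome ",
                     "[%.1f, %.1f) | polysome [%.1f, %.1f] (offset %.1f mm)\n"),
              x$subunit_region[1], x$subunit_region[2],
              x$monosome_region[1], x$monosome_region[2],
              x$polysome_region[1], x$polysome_region[2], x$mono_poly_offset))
  invisible(x)
}

# trapezoidal AUC of the trace over [lo, hi], with interpolated boundary points
region_auc <- function(pos, ab, lo, hi) {
  if (hi <= lo) return(0)
  inside <- pos > lo & pos < hi
  xs <- pos[inside]
  ys <- ab[inside]
  ylo <- approx(pos, ab, xout = lo, rule = 1)$y
  yhi <- approx(pos, ab, xout = hi, rule = 1)$y
  xs <- c(lo, xs, hi)
  ys <- c(ylo, ys, yhi)
  pracma::trapz(xs, ys)
}

#' Integrate trace regions and compute the polysome-to-monosome ratio
#'
#' Trapezoidal integration of the baseline-corrected absorbance over the
#' subunit, monosome and polysome regions; no smoothing is applied. The
#' polysome AUC approximates the number of polysomal ribosomes, and
#' `pm_ratio = polysome_auc / monosome_auc` is the translation-activity proxy.
#' A zero monosome AUC yields `pm_ratio = NaN` with a warning (never an
#' error), so degenerate simulated inputs do not break batch runs.
#'
#' @param trace A baseline-corrected [profile_trace()] spanning the regions.
#' @param regions A [segment_regions()] result.
#' @param peaks Optional `peak_set`; if given, per-peak areas over each search
#'   window are added as `auc_<label>` columns.
#' @return A one-row tibble (class `"quant_result"`): `sample_id`,
#'   `subunit_auc`, `monosome_auc`, `polysome_auc`, `total_auc`, `pm_ratio`
#'   and optional per-peak areas.
#' @export
integrate_regions <- function(trace, regions, peaks = NULL) {
  validate_profile_trace(trace)
  if (!inherits(regions, "region_scheme")) {
    stop_parameter("regions must be a region_scheme")
  }
  pos <- trace$position_mm
  ab <- trace$a254
  span <- range(pos)
  for (rg in list(regions$monosome_region, regions$polysome_region)) {
    if (rg[1] < span[1] - 1e-9 || rg[2] > span[2] + 1e-9) {
      stop_segmentation(sprintf("region [%.2f, %.2f] outside trace span [%.2f, %.2f]",
                                rg[1], rg[2], span[1], span[2]))
    }
  }
  sub_lo <- max(regions$subunit_region[1], span[1])
  out <- tibble(
    sample_id = trace_sample_id(trace),
    subunit_auc = region_auc(pos, ab, sub_lo, regions$subunit_region[2]),
    monosome_auc = region_auc(pos, ab, regions$monosome_region[1],
                              regions$monosome_region[2]),
    polysome_auc = region_auc(pos, ab, regions$polysome_region[1],
                              regions$polysome_region[2]),
    total_auc = pracma::trapz(pos, ab)
  )
  if (out$monosome_auc > 0) {
    out$pm_ratio <- out$polysome_auc / out$monosome_auc
  } else {
    warn("monosome AUC is zero; pm_ratio reported as NaN")
    out$pm_ratio <- NaN
  }
  if (!is.null(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      out[[paste0("auc_", peaks$label[i])]] <-
        region_auc(pos, ab, peaks$window_lo[i], peaks$window_hi[i])
    }
  }
  class(out) <- c("quant_result", class(out))
  out
}

#' Quantify a profile trace end to end
#'
#' Convenience wrapper: baseline correction, peak detection, region
#' segmentation with the fixed monosome-to-polysome offset, and region
#' integration, returning the per-sample quantification row together with the
#' trace's metadata columns.
#'
#' @param trace A raw (or already corrected) [profile_trace()].
#' @param mono_poly_offset Monosome-to-polysome offset in mm (default 8.9).
#' @param gradient_end End of the usable gradient in mm; defaults to the last
#'   sampled position.
#' @param search_windows Optional peak windows, see [detect_peaks()].
#' @param min_prominence Peak prominence threshold.
#' @param baseline Baseline method, see [correct_baseline()].
#' @return A one-row tibble with metadata and quantification columns.
#' @export
quantify_trace <- function(trace, mono_poly_offset = 8.9, gradient_end = NULL,
                           search_windows = NULL, min_prominence = 0.01,
                           baseline = "linear_endpoints") {
  if (!isTRUE(attr(trace, "baseline_corrected"))) {
    trace <- correct_baseline(trace, method = baseline)
  }
  if (is.null(gradient_end)) gradient_end <- max(trace$position_mm)
  peaks <- detect_peaks(trace, search_windows, min_prominence)
  regions <- segment_regions(peaks, mono_poly_offset, gradient_end)
  quant <- integrate_regions(trace, regions, peaks)
  meta <- trace_meta(trace)
  dplyr::bind_cols(meta, quant[setdiff(names(quant), "sample_id")])
}

#' Quantify a list of traces
#'
#' @param traces List of [profile_trace()] objects.
#' @param ... Passed to [quantify_trace()].
#' @return A tibble with one row per trace.
#' @export
quantify_traces <- function(traces, ...) {
  bind_rows(lapply(traces, quantify_trace, ...))
}

#' Region fold change between two quantified samples
#'
#' Ratio of a region's AUC in a sample to the same region's AUC in the t = 0
#' CHX reference. `fold_change(x, x)` is exactly 1.
#'
#' @param quant_t Quantification row of the sample (from
#'   [integrate_regions()] or [quantify_trace()]).
#' @param quant_ref Quantification row of the t = 0 CHX control.
#' @param region `"polysome"` or `"monosome"`.
#' @return Dimensionless fold change.
#' @export
fold_change <- function(quant_t, quant_ref, region = c("polysome", "monosome")) {
  region <- match.arg(region)
  col <- paste0(region, "_auc")
  a <- quant_t[[col]][1]
  ref <- quant_ref[[col]][1]
  if (is.null(a) || is.null(ref)) stop_parameter(sprintf("missing column %s", col))
  if (ref == 0) stop_division(sprintf("reference %s AUC is zero", region))
  a / ref
}

#' Disome-to-monosome area ratio
#'
#' Ratio of the disome peak area to the 80S peak area on a high-resolution
#' gradient; requires per-peak areas from [integrate_regions()] with a peak
#' set containing both species.
#'
#' @param quant Quantification row with `auc_80S` and `auc_disome` columns.
#' @return Dimensionless disome/80S area ratio.
#' @export
disome_monosome_ratio <- function(quant) {
  for (col in c("auc_80S", "auc_disome")) {
    if (is.null(quant[[col]])) {
      stop_peak(sprintf("quantification lacks %s; was the peak detected?", col))
    }
  }
  if (quant$auc_80S[1] <= 0) stop_division("80S peak area is zero")
  quant$auc_disome[1] / quant$auc_80S[1]
}

#' RNase1 dose for controlled polysome digestion
#'
#' Enzyme units for digesting polysomes to monosomes at the calibrated dosing
#' ratio of 0.19 U per microlitre of lysate per A260 unit.
#'
#' @param a260 Lysate absorbance at 260 nm (A260 units), > 0.
#' @param lysate_volume Lysate volume in microlitres, > 0.
#' @param ratio Dosing ratio in U/(ul * A260); default 0.19.
#' @return RNase1 units.
#' @export
#' @examples
#' rnase_units(1.0, 100) # 19 U
rnase_units <- function(a260, lysate_volume, ratio = 0.19) {
  if (!is.numeric(a260) || a260 <= 0) stop_parameter("a260 must be > 0")
  if (!is.numeric(lysate_volume) || lysate_volume <= 0) {
    stop_parameter("lysate_volume must be > 0")
  }
  ratio * a260 * lysate_volume
}
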