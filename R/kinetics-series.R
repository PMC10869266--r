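#' Build a runoff fold-change series from quantified samples
#'
#' Converts per-sample region AUCs into fold changes relative to the t = 0
#' CHX control of the same replicate, then averages across replicates. Each
#' replicate must contain exactly one t = 0 CHX control; fitting is done on
#' the replicate means (per-replicate values are retained in the
#' `replicate_values` attribute).
#'
#' @param quants Tibble from [quantify_traces()] (or [quantify_trace()] rows
#'   bound together) containing `treatment`, `runoff_time_min`, `replicate`
#'   and the region AUC columns. Alternatively supply a bare quantification
#'   table plus a `sheet` to join metadata by `sample_id`.
#' @param region `"polysome"` or `"monosome"`.
#' @param sheet Optional sample sheet tibble joined by `sample_id`.
#' @return A [runoff_series()] (kind `polysome_decline` or `monosome_rise`).
#' @export
build_series <- function(quants, region = c("polysome", "monosome"),
                         sheet = NULL) {
  region <- match.arg(region)
  col <- paste0(region, "_auc")
  if (!is.null(sheet)) {
    keep <- setdiff(names(sheet), c("path", names(quants)[names(quants) != "sample_id"]))
    quants <- left_join(quants, sheet[, keep, drop = FALSE], by = "sample_id")
  }
  needed <- c("treatment", "runoff_time_min", "replicate", col)
  missing_cols <- setdiff(needed, names(quants))
  if (length(missing_cols) > 0L) {
    stop_design(sprintf("quantification table lacks columns: %s",
                        paste(missing_cols, collapse = ", ")))
  }
  reps <- split(quants, quants$replicate)
  fold_tabs <- imap(reps, function(df, rep_id) {
    ctrl <- df[df$treatment == "CHX" & df$runoff_time_min == 0, , drop = FALSE]
    if (nrow(ctrl) != 1L) {
      stop_design(sprintf("replicate %s needs exactly one t = 0 CHX control (found %d)",
                          rep_id, nrow(ctrl)))
    }
    if (ctrl[[col]] == 0) stop_division(sprintf("replicate %s control %s is zero",
                                                rep_id, col))
    tibble(replicate = rep_id,
           time_min = df$runoff_time_min,
           fold = df[[col]] / ctrl[[col]])
  })
  folds <- bind_rows(fold_tabs)
  times <- sort(unique(folds$time_min))
  if (sum(times > 0) < 2L) {
    stop_design("at least 2 runoff time points (> 0 min) are required")
  }
  wide <- tidyr::pivot_wider(folds, names_from = "replicate",
                             values_from = "fold", values_fn = mean)
  wide <- arrange(wide, .data$time_min)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  runoff_series(
    time_min = wide$time_min,
    value = rowMeans(mat, na.rm = TRUE),
    kind = if (region == "polysome") "polysome_decline" else "monosome_rise",
    replicate_values = mat
  )
}

#' Tabulate fitted kinetics across conditions
#'
#' Descriptive comparison of runoff fits across cell types or treatments:
#' rate constant, plateau, goodness of fit and (optionally) the steady-state
#' translation-activity proxy P/M(0), ranked by rate constant. No inferential
#' statistics are computed.
#'
#' @param fits Named list of `decay_fit` objects, one per condition.
#' @param pm0 Optional named numeric vector of P/M(0) values (names matching
#'   `fits`).
#' @return A tibble with one row per condition, sorted by decreasing `k`.
#' @export
compare_conditions <- function(fits, pm0 = NULL) {
  if (length(fits) == 0L) stop_parameter("no fits supplied")
  if (length(fits) < 2L) {
    warn("only one condition supplied; comparison table has a single row")
  }
  out <- bind_rows(imap(fits, function(f, cond) {
    tibble(condition = cond, k = f$k, plateau = f$plateau,
           r_squared = f$r_squared, n_points = f$n_points)
  }))
  if (!is.null(pm0)) {
    out$pm0 <- unname(pm0[out$condition])
  }
  arrange(out, desc(.data$k))
}
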