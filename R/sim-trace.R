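#' Geometry of synthesised A254 traces
#'
#' Peak layout used when turning a species census into an absorbance trace.
#' n-some peak centres follow a geometrically compressing spacing
#' `mu_n = mu_80S + d1 * (1 - r^(n-1)) / (1 - r)` -- heavier species migrate
#' proportionally less far, as on a real sucrose gradient -- and peak widths
#' grow mildly with n. The standard 18-50 % geometry places the 80S peak at
#' 20 mm with an 11 mm 80S-disome spacing, so the default 8.9 mm
#' monosome-to-polysome offset cleanly separates the disome from the 80S
#' peak; the high-resolution 5-25 % geometry stretches the light region to
#' resolve 80S and disome.
#'
#' @param gradient `"standard_18_50"` or `"highres_5_25"`.
#' @param ... Overrides of individual geometry fields.
#' @return A list of class `"trace_geometry"`.
#' @export
trace_geometry <- function(gradient = "standard_18_50", ...) {
  base <- switch(gradient,
    standard_18_50 = list(
      gradient = gradient,
      mu_40S = 11, mu_60S = 14.5, mu_80S = 20,
      first_spacing = 11, spacing_ratio = 0.6,
      sigma_80S = 0.9, sigma_growth = 0.08,
      sigma_subunit = 0.8,
      baseline = 0.05, baseline_slope = 5e-4,
      step_mm = 0.2, start_mm = 0, gradient_end = 60,
      au_per_unit = 1e-3
    ),
    highres_5_25 = list(
      gradient = gradient,
      mu_40S = 6, mu_60S = 11, mu_80S = 18,
      first_spacing = 12, spacing_ratio = 0.55,
      sigma_80S = 1.0, sigma_growth = 0.08,
      sigma_subunit = 0.9,
      baseline = 0.05, baseline_slope = 5e-4,
      step_mm = 0.2, start_mm = 0, gradient_end = 55,
      au_per_unit = 1e-3
    ),
    stop_parameter(sprintf("unknown gradient '%s'", gradient))
  )
  geom <- modifyList(base, list(...))
  if (geom$spacing_ratio <= 0 || geom$spacing_ratio >= 1) {
    stop_parameter("spacing_ratio must be in (0, 1) so peak centres increase")
  }
  if (geom$first_spacing <= 0) stop_parameter("first_spacing must be > 0")
  class(geom) <- "trace_geometry"
  geom
}

nsome_center <- function(n, geom) {
  geom$mu_80S + geom$first_spacing *
    (1 - geom$spacing_ratio^(n - 1)) / (1 - geom$spacing_ratio)
}

nsome_sigma <- function(n, geom) geom$sigma_80S + geom$sigma_growth * n

# A254 signal weight per particle: RNA content, n ribosomes + 1 mRNA-equivalent
# for an n-some; half a ribosome per free subunit; 1 for a free 80S couple.
species_weight_nsome <- function(n) n + 1

#' Ground-truth RNA-weighted region signal of a census
#'
#' Analytic (Gaussian-integral) signal that [synthesize_trace()] places in
#' each region, before sampling and noise: the oracle the quantification
#' pipeline is checked against.
#'
#' @param counts A [census()] result.
#' @param geom A [trace_geometry()].
#' @param mono_poly_offset Monosome-to-polysome boundary offset in mm.
#' @return Tibble with `monosome_signal`, `polysome_signal`, `pm_ratio`.
#' @export
ground_truth_signal <- function(counts, geom = trace_geometry(),
                                mono_poly_offset = 8.9) {
  boundary <- geom$mu_80S + mono_poly_offset
  species <- bind_rows(
    mutate(counts$nsome, what = "active"),
    mutate(counts$granule_nsome, what = "granule")
  )
  mono_sig <- counts$free_80S * 1  # free 80S sediment at the 80S position, weight 1
  poly_sig <- 0
  if (nrow(species) > 0) {
    for (i in seq_len(nrow(species))) {
      n <- species$n[i]
      w <- species$count[i] * species_weight_nsome(n)
      mu <- nsome_center(n, geom)
      sg <- nsome_sigma(n, geom)
      frac_poly <- pnorm(geom$gradient_end, mu, sg) - pnorm(boundary, mu, sg)
      frac_mono <- pnorm(boundary, mu, sg) -
        pnorm(geom$mu_80S - (boundary - geom$mu_80S), mu, sg)
      poly_sig <- poly_sig + w * frac_poly
      mono_sig <- mono_sig + w * frac_mono
    }
  }
  tibble(monosome_signal = mono_sig * geom$au_per_unit,
         polysome_signal = poly_sig * geom$au_per_unit,
         pm_ratio = if (mono_sig > 0) poly_sig / mono_sig else NaN)
}

#' Synthesise an A254 trace from a species census
#'
#' Each species contributes a Gaussian at its sedimentation position with an
#' amplitude proportional to its RNA content (n ribosomes + 1 mRNA-equivalent
#' per n-some; 0.5 per free subunit; 1 per free 80S). Granule n-somes are
#' placed at the same polysome-region positions as active n-somes of equal n
#' (after detergent treatment granules enter the gradient and sediment with
#' the heavy fractions). A linear baseline and Gaussian noise complete the
#' trace.
#'
#' @param counts A [census()] result.
#' @param geom A [trace_geometry()].
#' @param noise_sd Gaussian noise SD in A254 units.
#' @param seed Optional integer seed for the noise.
#' @param ... Metadata passed to [profile_trace()] (`sample_id`, `treatment`,
#'   `runoff_time_min`, ...).
#' @return A raw (not baseline-corrected) [profile_trace()].
#' @export
synthesize_trace <- function(counts, geom = trace_geometry(), noise_sd = 0.002,
                             seed = NULL, ...) {
  if (!inherits(counts, "species_counts")) {
    stop_parameter("counts must be a species_counts census")
  }
  x <- seq(geom$start_mm, geom$gradient_end, by = geom$step_mm)
  y <- geom$baseline + geom$baseline_slope * x

  add_peak <- function(y, mu, sigma, weight) {
    y + weight * geom$au_per_unit * exp(-0.5 * ((x - mu) / sigma)^2) /
      (sigma * sqrt(2 * pi))
  }
  species <- bind_rows(counts$nsome, counts$granule_nsome)
  if (nrow(species) > 0) {
    agg <- summarise(group_by(species, .data$n), count = sum(.data$count),
                     .groups = "drop")
    for (i in seq_len(nrow(agg))) {
      n <- agg$n[i]
      y <- add_peak(y, nsome_center(n, geom), nsome_sigma(n, geom),
                    agg$count[i] * species_weight_nsome(n))
    }
  }
  if (counts$free_80S > 0) {
    y <- add_peak(y, geom$mu_80S, geom$sigma_80S, counts$free_80S * 1)
  }
  if (counts$subunits > 0) {
    y <- add_peak(y, geom$mu_40S, geom$sigma_subunit, counts$subunits / 2 * 0.5)
    y <- add_peak(y, geom$mu_60S, geom$sigma_subunit, counts$subunits / 2 * 0.5)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(x), 0, noise_sd)
  }
  y <- pmax(y, 0)
  profile_trace(x, y, gradient = geom$gradient, ...)
}

#' Simulate a harringtonine runoff time course
#'
#' Initialises the steady state, applies runoff for each requested time,
#' optionally applies a biochemical treatment to each lysate, and returns
#' both the synthesised traces and the exact ground-truth polysome
#' ribosome-count fold-change series (polysomal ribosomes, active plus
#' granule, relative to t = 0). Fully reproducible under the config seed.
#'
#' @param config A [sim_config()].
#' @param times Runoff times in minutes; must include 0.
#' @param treatment Optional treatment (see [apply_treatment()]) applied to
#'   every lysate after runoff.
#' @param geom A [trace_geometry()].
#' @param ... Extra arguments to [apply_treatment()] (e.g. `units`).
#' @return A list of class `"runoff_simulation"`: `series` (ground-truth
#'   [runoff_series()]), `traces` (list of [profile_trace()]), `counts`
#'   (list of censuses), `config`, `times`.
#' @export
simulate_timecourse <- function(config, times = c(0, 1, 5, 10, 20),
                                treatment = NULL, geom = NULL, ...) {
  if (!0 %in% times) stop_parameter("times must include 0")
  times <- sort(unique(times))
  if (is.null(geom)) geom <- trace_geometry("standard_18_50")
  state0 <- init_steady_state(config)
  counts <- vector("list", length(times))
  traces <- vector("list", length(times))
  poly <- numeric(length(times))
  for (i in seq_along(times)) {
    st <- apply_runoff(state0, times[i], config)
    if (!is.null(treatment)) st <- apply_treatment(st, treatment, config, ...)
    cs <- census(st)
    counts[[i]] <- cs
    poly[i] <- polysome_ribosomes(cs)
    treat_label <- if (times[i] == 0) "CHX" else "HRN"
    traces[[i]] <- synthesize_trace(
      cs, geom = geom, noise_sd = config$noise_sd,
      seed = config$seed + 1000L + i,
      sample_id = sprintf("sim_t%02g", times[i]),
      treatment = treat_label, runoff_time_min = times[i])
  }
  if (poly[1] <= 0) stop_design("no polysomal ribosomes at t = 0; raise loading density")
  out <- list(
    series = runoff_series(times, poly / poly[1], kind = "polysome_decline"),
    traces = traces, counts = counts, config = config, times = times
  )
  class(out) <- "runoff_simulation"
  out
}

#' @export
print.runoff_simulation <- function(x, ...) {
  cat(sprintf("<runoff_simulation> %d time points (%s min) | %d mRNAs | f_inactive = %g\n",
              length(x$times), paste(x$times, collapse = ", "),
              x$config$n_mrnas, x$config$f_inactive))
  invisible(x)
}
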