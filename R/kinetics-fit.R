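#' Construct a runoff time series
#'
#' Fold changes of a gradient region relative to the t = 0 CHX control,
#' sampled at the harringtonine incubation times. By construction the value
#' at t = 0 is 1.
#'
#' @param time_min Times in minutes, strictly increasing, starting at 0.
#' @param value Fold changes (dimensionless, >= 0); `value[1]` must be 1
#'   within 1e-9.
#' @param kind `"polysome_decline"`, `"monosome_rise"` or `"pmy_decline"`.
#' @param replicate_values Optional matrix (time x replicate) of per-replicate
#'   fold changes whose row means equal `value`.
#' @return A tibble of class `"runoff_series"` with columns `time_min`,
#'   `value`.
#' @export
runoff_series <- function(time_min, value,
                          kind = c("polysome_decline", "monosome_rise",
                                   "pmy_decline"),
                          replicate_values = NULL) {
  kind <- match.arg(kind)
  time_min <- as.numeric(time_min)
  value <- as.numeric(value)
  if (length(time_min) != length(value)) stop_format("times/values length mismatch")
  if (time_min[1] != 0) stop_format("series must start at t = 0")
  if (any(diff(time_min) <= 0)) stop_format("times must be strictly increasing")
  if (any(value < 0)) stop_format("fold changes must be >= 0")
  if (abs(value[1] - 1) > 1e-9) {
    stop_format("value at t = 0 must be 1 (fold change relative to CHX control)")
  }
  out <- tibble(time_min = time_min, value = value)
  attr(out, "kind") <- kind
  attr(out, "replicate_values") <- replicate_values
  class(out) <- c("runoff_series", class(out))
  out
}

series_kind <- function(series) attr(series, "kind")

# Profiled least squares for the pinned-intercept decay/rise model.
# For fixed k with E = exp(-k t), the model value is E + P (1 - E) where the
# plateau P is the only linear parameter; its optimum is closed-form and is
# clipped to the admissible interval, so the fit reduces to a 1-D search in k.
profile_sse <- function(k, t, y, p_lo, p_hi) {
  e <- exp(-k * t)
  w <- 1 - e
  denom <- sum(w^2)
  p <- if (denom == 0) p_lo else sum(w * (y - e)) / denom
  p <- min(max(p, p_lo), p_hi)
  list(plateau = p, sse = sum((y - (e + p * w))^2))
}

fit_pinned <- function(t, y, p_lo, p_hi, k_max = 20) {
  grid <- c(0, exp(seq(log(1e-4), log(k_max), length.out = 160)))
  sse <- vapply(grid, function(k) profile_sse(k, t, y, p_lo, p_hi)$sse, numeric(1))
  i <- which.min(sse)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (hi > lo) {
    opt <- optimise(function(k) profile_sse(k, t, y, p_lo, p_hi)$sse,
                    interval = c(lo, hi), tol = 1e-12)
    if (opt$objective <= sse[i]) {
      k <- opt$minimum
    } else {
      k <- grid[i]
    }
  } else {
    k <- grid[i]
  }
  prof <- profile_sse(k, t, y, p_lo, p_hi)
  list(k = k, plateau = prof$plateau, sse = prof$sse)
}

new_decay_fit <- function(k, plateau, amplitude, t, y, fitted, kind,
                          constrained_t0, degenerate = FALSE) {
  resid <- y - fitted
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else NA_real_
  structure(list(
    k = k, plateau = plateau, amplitude = amplitude, r_squared = r2,
    residuals = resid, fitted = fitted,
    data = tibble(time_min = t, value = y),
    n_points = length(t), kind = kind,
    constrained_t0 = constrained_t0, degenerate = degenerate
  ), class = "decay_fit")
}

#' Fit exponential runoff-decay kinetics
#'
#' Least-squares fit of the exponential decay model to a declining fold-change
#' series (polysome signal or puromycin incorporation during harringtonine
#' runoff). The constrained form pins the curve at the t = 0 control value:
#' \deqn{P(t) = C + (1 - C) e^{-k t},}
#' with rate constant `k >= 0` per minute (the ribosome-speed proxy) and
#' plateau `C` in `[0, 1]` (the translationally inactive fraction of the
#' initial polysome signal). The objective is non-convex in `k`, so the fit
#' profiles out the plateau (closed-form for fixed `k`) and minimises over a
#' dense log-spaced `k` grid refined by golden-section search, which the test
#' suite checks against an exhaustive grid-search oracle. With
#' `constrain_t0 = FALSE` a 3-parameter variant `C + A e^{-k t}` is fitted
#' (the intercept is then free).
#'
#' @param series A [runoff_series()] of kind `polysome_decline` or
#'   `pmy_decline`, at least 3 time points.
#' @param constrain_t0 Pin the fitted curve to 1 at t = 0 (default TRUE).
#' @return An object of class `"decay_fit"` with elements `k`, `plateau`,
#'   `amplitude`, `r_squared`, `residuals`, `fitted`, `n_points`,
#'   `constrained_t0` and `degenerate`.
#' @export
#' @examples
#' s <- runoff_series(c(0, 1, 2), c(1, 0.5, 0.25))
#' fit_decay(s)$k # ~ log(2)
fit_decay <- function(series, constrain_t0 = TRUE) {
  if (!inherits(series, "runoff_series")) stop_parameter("series must be a runoff_series")
  kind <- series_kind(series)
  if (!kind %in% c("polysome_decline", "pmy_decline")) {
    stop_parameter("fit_decay expects a declining series; use fit_rise for monosomes")
  }
  t <- series$time_min
  y <- series$value
  if (length(t) < 3L) stop_fit("at least 3 time points required")
  if (sd(y) == 0) {
    return(new_decay_fit(0, y[1], 0, t, y, rep(y[1], length(y)), kind,
                         constrain_t0, degenerate = TRUE))
  }
  if (constrain_t0) {
    res <- fit_pinned(t, y, p_lo = 0, p_hi = 1)
    e <- exp(-res$k * t)
    fitted <- e + res$plateau * (1 - e)
    new_decay_fit(res$k, res$plateau, abs(1 - res$plateau), t, y, fitted,
                  kind, TRUE)
  } else {
    fit_free(t, y, kind, c_lo = 0, c_hi = max(y))
  }
}

# 3-parameter variant: y = C + A exp(-k t), linear in (C, A) for fixed k.
fit_free <- function(t, y, kind, c_lo, c_hi) {
  sse_k <- function(k) {
    e <- exp(-k * t)
    X <- cbind(1, e)
    co <- tryCatch(qr.coef(qr(X), y), error = function(err) c(mean(y), 0))
    C <- min(max(co[1], c_lo), c_hi)
    if (C != co[1]) co[2] <- sum(e * (y - C)) / sum(e^2)
    list(sse = sum((y - (C + co[2] * e))^2), C = C, A = co[2])
  }
  grid <- c(1e-4, exp(seq(log(1e-3), log(20), length.out = 160)))
  sse <- vapply(grid, function(k) sse_k(k)$sse, numeric(1))
  i <- which.min(sse)
  opt <- optimise(function(k) sse_k(k)$sse,
                  interval = c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)]),
                  tol = 1e-12)
  k <- if (opt$objective <= sse[i]) opt$minimum else grid[i]
  best <- sse_k(k)
  e <- exp(-k * t)
  new_decay_fit(k, unname(best$C), unname(best$A), t, y,
                best$C + best$A * e, kind, FALSE)
}

#' Fit the monosome-rise counterpart of the runoff model
#'
#' During runoff the monosome fold change rises as elongating ribosomes are
#' released as 80S; the model is the mirror of the decline:
#' \deqn{M(t) = M_\infty - (M_\infty - 1) e^{-k t},}
#' with `M_inf >= 1` stored in the `plateau` field.
#'
#' @param series A [runoff_series()] of kind `monosome_rise`, >= 3 points.
#' @return A `"decay_fit"` object (see [fit_decay()]).
#' @export
fit_rise <- function(series) {
  if (!inherits(series, "runoff_series")) stop_parameter("series must be a runoff_series")
  if (series_kind(series) != "monosome_rise") {
    stop_parameter("fit_rise expects a monosome_rise series")
  }
  t <- series$time_min
  y <- series$value
  if (length(t) < 3L) stop_fit("at least 3 time points required")
  if (sd(y) == 0) {
    return(new_decay_fit(0, y[1], 0, t, y, rep(y[1], length(y)),
                         "monosome_rise", TRUE, degenerate = TRUE))
  }
  res <- fit_pinned(t, y, p_lo = 1, p_hi = max(10, 10 * max(y)))
  e <- exp(-res$k * t)
  fitted <- e + res$plateau * (1 - e)
  new_decay_fit(res$k, res$plateau, abs(res$plateau - 1), t, y, fitted,
                "monosome_rise", TRUE)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s%s\n", x$kind,
              if (x$degenerate) " (degenerate: constant series)" else ""))
  cat(sprintf("  k = %.4g /min, plateau = %.4g, amplitude = %.4g, R^2 = %s, n = %d\n",
              x$k, x$plateau, x$amplitude,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              x$n_points))
  invisible(x)
}

#' @rdname fit_decay
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(
    term = c("k", "plateau", "amplitude"),
    estimate = c(x$k, x$plateau, x$amplitude)
  )
}

#' @rdname fit_decay
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(k = x$k, plateau = x$plateau, amplitude = x$amplitude,
         r.squared = x$r_squared, nobs = x$n_points,
         kind = x$kind, degenerate = x$degenerate)
}

#' Predicted fold change from a decay fit
#'
#' @param object A `decay_fit`.
#' @param time_min Times (minutes) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Numeric vector of model values.
#' @export
predict.decay_fit <- function(object, time_min = object$data$time_min, ...) {
  e <- exp(-object$k * time_min)
  if (object$constrained_t0) {
    if (object$kind == "monosome_rise") {
      object$plateau - (object$plateau - 1) * e
    } else {
      object$plateau + (1 - object$plateau) * e
    }
  } else {
    object$plateau + object$amplitude * e
  }
}
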