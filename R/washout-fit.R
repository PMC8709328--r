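#' Construct a time-intensity series
#'
#' A time-intensity curve (TIC) is the ROI-averaged, log-compressed echo
#' intensity (dB) of one region of interest recorded over the late vascular
#' phase of a CEUS examination. Two such series are taken per lesion: one
#' outlining the lesion, one in adjacent parenchyma at the same depth.
#'
#' @param times sampling times in seconds, strictly increasing.
#' @param intensities intensities in dB, same length as `times`, finite.
#' @param lesion_id identifier of the lesion the series belongs to.
#' @param roi `"lesion"` or `"parenchyma"`.
#' @return An object of class `tic_series`: a list with elements `times`,
#'   `intensities`, `lesion_id`, `roi`.
#' @export
#' @examples
#' s <- tic_series(120:300, -57 + 10 * exp(-0.02 * (0:180)))
#' fit_washout(s)
tic_series <- function(times, intensities, lesion_id = "lesion",
                       roi = c("lesion", "parenchyma")) {
  roi <- match.arg(roi)
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    stop("'times' and 'intensities' must have the same length")
  if (length(times) == 0L) stop("empty series")
  if (any(!is.finite(times)) || any(!is.finite(intensities)))
    stop("non-finite values in TIC series")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  structure(list(times = times, intensities = intensities,
                 lesion_id = as.character(lesion_id), roi = roi),
            class = "tic_series")
}

#' @export
print.tic_series <- function(x, ...) {
  cat(sprintf("TIC series: lesion '%s', ROI %s, %d samples over %.0f-%.0f s\n",
              x$lesion_id, x$roi, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

## Evaluate the washout model A*exp(-k*tau) + B on a re-zeroed clock.
washout_model <- function(tau, A, B, k) A * exp(-k * tau) + B

## Residual sum of squares of the best (A, B) for a fixed decay rate k:
## the model is linear in (A, B) given k, so they are solved exactly by
## ordinary least squares on the basis exp(-k*tau) (variable projection).
.profile_rss <- function(k, tau, y) {
  g <- exp(-k * tau)
  X <- cbind(1, g)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  list(rss = rss, B = unname(fit$coefficients[1]),
       A = unname(fit$coefficients[2]))
}

#' Fit the exponential washout model to a late-phase TIC
#'
#' Fits `F(t) = A * exp(-k * (t - t0)) + B` to the observed samples by least
#' squares, where `t0` is the start-frame time, `B` is the asymptotic minimum
#' intensity, `A` the difference between the start-frame intercept and `B`,
#' and `k >= 0` the decay rate. A positive `A` describes washout (falling
#' intensity); a negative `A` a rising curve.
#'
#' For any fixed `k` the model is linear in `(A, B)`, which are therefore
#' solved exactly by linear least squares; the fit reduces to a deterministic
#' one-dimensional search for `k` on `[0, 10]` per second (coarse log-spaced
#' grid followed by golden-section refinement, objective tolerance 1e-8).
#' When no exponential improves on the best constant, the flat tie-break
#' `A = 0, k = 0, B = mean(intensity)` is reported, so the fitted MSE never
#' exceeds that of the constant model.
#'
#' Derived quantities are populated on the returned object: the initial
#' gradient `-A*k` (dB/s), the time to peak intensity from the start frame
#' (seconds, first occurrence on ties), the AREA washout statistic (see
#' [compute_area()]) and the mean squared error of the fit.
#'
#' @param x a [tic_series], or times when using the default method.
#' @param intensities intensities in dB (default method only).
#' @param k_max upper bound of the decay-rate search, per second.
#' @param area_mode how AREA is computed, see [compute_area()].
#' @param ... passed between methods.
#' @return An object of class `washout_fit` with components `coefficients`
#'   (named `A`, `B`, `k`), `gradient0`, `ttopk`, `area`, `mse`, `converged`,
#'   `fitted.values`, `residuals`, and the input series. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`, `plot()`
#'   and `simulate()`.
#' @export
#' @examples
#' tt <- 120:300
#' y <- 10 * exp(-0.05 * (tt - 120)) - 57
#' fit <- fit_washout(tic_series(tt, y))
#' coef(fit)
#' fit$area
fit_washout <- function(x, ...) UseMethod("fit_washout")

#' @rdname fit_washout
#' @export
fit_washout.default <- function(x, intensities, ...) {
  fit_washout(tic_series(x, intensities), ...)
}

#' @rdname fit_washout
#' @export
fit_washout.tic_series <- function(x, k_max = 10,
                                   area_mode = c("fitted", "raw"), ...) {
  area_mode <- match.arg(area_mode)
  tau <- x$times - x$times[1]
  y <- x$intensities
  n <- length(y)
  if (n < 4L) stop("washout fit needs at least 4 samples")

  ybar <- mean(y)
  rss_const <- sum((y - ybar)^2)
  best <- list(A = 0, B = ybar, k = 0, rss = rss_const)
  converged <- TRUE

  if (rss_const > 0) {
    res <- tryCatch({
      Tlen <- tau[n]
      ## decay rates from far-slower-than-window to k_max, log-spaced
      kgrid <- 10^seq(log10(1e-3 / Tlen), log10(k_max), length.out = 60L)
      rssg <- vapply(kgrid, function(k) .profile_rss(k, tau, y)$rss,
                     numeric(1))
      i <- which.min(rssg)
      lo <- kgrid[max(i - 1L, 1L)]
      hi <- kgrid[min(i + 1L, length(kgrid))]
      opt <- stats::optimize(function(k) .profile_rss(k, tau, y)$rss,
                             interval = c(lo, hi), tol = 1e-8)
      k <- opt$minimum
      prof <- .profile_rss(k, tau, y)
      list(A = prof$A, B = prof$B, k = k, rss = prof$rss)
    }, error = function(e) NULL)
    if (is.null(res)) {
      converged <- FALSE
    } else if (res$rss < best$rss && is.finite(res$A) && is.finite(res$B)) {
      best <- res
    }
  }

  fitted <- washout_model(tau, best$A, best$B, best$k)
  obj <- structure(list(
    coefficients = c(A = best$A, B = best$B, k = best$k),
    gradient0 = -best$A * best$k,
    ttopk = tau[which.max(y)],
    mse = best$rss / n,
    converged = converged,
    t0 = x$times[1],
    series = x,
    fitted.values = fitted,
    residuals = y - fitted,
    area_mode = area_mode
  ), class = "washout_fit")
  obj$area <- compute_area(obj, mode = area_mode)
  obj
}

#' AREA washout statistic of a fitted TIC
#'
#' AREA is the signed area between the curve and its own start-frame value
#' over the analysis window, divided by the window length so its unit is dB:
#' `AREA = (1/T) * integral(F(t) - F(t_start)) dt`. A falling (washing-out)
#' curve gives a negative AREA; the more pronounced the washout, the more
#' negative the value. For the exponential model the integral has the closed
#' form `A * ((1 - exp(-kT)) / (kT) - 1)`.
#'
#' @param fit a [fit_washout()] result.
#' @param mode `"fitted"` integrates the fitted curve (closed form, default);
#'   `"raw"` integrates the observed samples by the trapezoidal rule.
#' @param normalize divide by the window length `T` (default, unit dB). With
#'   `normalize = FALSE` the raw integral in dB*s is returned.
#' @return AREA in dB (or dB*s when `normalize = FALSE`).
#' @export
#' @examples
#' tt <- 120:300
#' fit <- fit_washout(tic_series(tt, 20 * exp(-0.03 * (tt - 120)) - 60))
#' compute_area(fit)            # negative: washout
compute_area <- function(fit, mode = c("fitted", "raw"), normalize = TRUE) {
  mode <- match.arg(mode)
  tau <- fit$series$times - fit$t0
  Tlen <- tau[length(tau)]
  if (Tlen <= 0) stop("zero-length analysis window")
  if (mode == "fitted") {
    A <- fit$coefficients[["A"]]; k <- fit$coefficients[["k"]]
    kT <- k * Tlen
    area <- if (kT < 1e-12) 0 else A * ((1 - exp(-kT)) / kT - 1)
  } else {
    dev <- fit$series$intensities - fit$series$intensities[1]
    area <- sum(diff(tau) * (dev[-1] + dev[-length(dev)]) / 2) / Tlen
  }
  if (!normalize) area <- area * Tlen
  unname(area)
}

#' Washout flag from the AREA statistic
#'
#' Declares washout (the late-phase hallmark of malignancy) when the lesion's
#' AREA is at or below the operating cutoff. The default cutoff of -19.3 dB
#' places typical malignant lesions (class mean about -25 dB) on the flagged
#' side and typical benign lesions (about -7 dB) on the other; the boundary
#' itself is flagged.
#'
#' @param lesion_area AREA of the lesion ROI, dB.
#' @param cutoff operating cutoff, dB.
#' @return logical, `TRUE` when washout is present.
#' @export
#' @examples
#' washout_flag(-25.08)  # TRUE
#' washout_flag(-7.08)   # FALSE
washout_flag <- function(lesion_area, cutoff = -19.3) {
  stopifnot(is.finite(lesion_area), is.finite(cutoff))
  lesion_area <= cutoff
}

#' Time to peak intensity
#'
#' Time from the start frame to the maximum observed intensity; ties go to
#' the earliest frame, so a monotonically decreasing (pure washout) series
#' peaks at 0 s.
#'
#' @param times sampling times, seconds.
#' @param intensities intensities, dB.
#' @return seconds from the start frame.
#' @export
time_to_peak <- function(times, intensities) {
  if (length(times) == 0L) stop("empty series")
  times[which.max(intensities)] - times[1]
}

#' Do two fitted washout curves cross within a window?
#'
#' A qualitative secondary washout sign: on the late-phase display, the
#' lesion and parenchyma TIC graphs intersecting one another indicates that
#' the lesion is losing contrast relative to its surroundings. The crossing
#' is detected as a sign change of the difference of the two fitted curves
#' over the window, and located by bisection (`uniroot`).
#'
#' @param lesion_fit,parenchyma_fit [fit_washout()] results.
#' @param window numeric length-2 absolute time interval (seconds); defaults
#'   to the overlap of the two fitted windows.
#' @param n_grid number of evaluation points used to bracket a sign change.
#' @return logical; when `TRUE`, the crossing time (s) is attached as
#'   attribute `"crossing_time"`.
#' @export
curves_intersect <- function(lesion_fit, parenchyma_fit, window = NULL,
                             n_grid = 256L) {
  if (is.null(window)) {
    window <- c(max(min(lesion_fit$series$times),
                    min(parenchyma_fit$series$times)),
                min(max(lesion_fit$series$times),
                    max(parenchyma_fit$series$times)))
  }
  if (window[2] <= window[1]) stop("empty comparison window")
  tt <- seq(window[1], window[2], length.out = n_grid)
  d <- predict(lesion_fit, tt) - predict(parenchyma_fit, tt)
  s <- sign(d)
  chg <- which(s[-1] * s[-length(s)] < 0)
  if (length(chg) == 0L) {
    if (any(s == 0) && !all(s == 0)) {       # tangential touch
      out <- TRUE
      attr(out, "crossing_time") <- tt[which(s == 0)[1]]
      return(out)
    }
    return(FALSE)
  }
  i <- chg[1]
  root <- stats::uniroot(function(t) predict(lesion_fit, t) -
                           predict(parenchyma_fit, t),
                         interval = c(tt[i], tt[i + 1]), tol = 1e-8)
  out <- TRUE
  attr(out, "crossing_time") <- root$root
  out
}

#' @export
print.washout_fit <- function(x, digits = 4, ...) {
  cat("Exponential washout fit: F(t) = A*exp(-k*(t - t0)) + B\n")
  cat(sprintf("  lesion '%s', ROI %s, %d samples, window %.0f-%.0f s\n",
              x$series$lesion_id, x$series$roi, length(x$series$times),
              min(x$series$times), max(x$series$times)))
  print(round(x$coefficients, digits))
  cat(sprintf("  AREA %.*f dB  gradient(t0) %.*f dB/s  TtoPk %.*f s  MSE %.*g dB^2\n",
              digits, x$area, digits, x$gradient0, digits, x$ttopk,
              digits, x$mse))
  if (!x$converged) cat("  (optimizer did not converge; best-effort fit)\n")
  invisible(x)
}

#' @export
coef.washout_fit <- function(object, ...) object$coefficients

#' @export
fitted.washout_fit <- function(object, ...) object$fitted.values

#' @export
residuals.washout_fit <- function(object, ...) object$residuals

#' Predict intensity from a washout fit
#'
#' @param object a `washout_fit`.
#' @param times absolute times in seconds (same clock as the input series);
#'   defaults to the observed sampling times.
#' @param ... unused.
#' @return predicted intensities, dB.
#' @export
predict.washout_fit <- function(object, times = object$series$times, ...) {
  washout_model(times - object$t0, object$coefficients[["A"]],
                object$coefficients[["B"]], object$coefficients[["k"]])
}

#' Simulate replicate series from a washout fit
#'
#' Draws `nsim` new TIC series from the fitted curve with i.i.d. Gaussian
#' noise at the residual standard deviation (or a supplied `noise_sd`).
#'
#' @param object a `washout_fit`.
#' @param nsim number of replicate series.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param noise_sd noise standard deviation in dB; defaults to the fit's
#'   residual standard deviation.
#' @param ... unused.
#' @return a data frame with one column per replicate, `nsim` columns.
#' @export
simulate.washout_fit <- function(object, nsim = 1, seed = NULL,
                                 noise_sd = NULL, ...) {
  if (is.null(noise_sd)) noise_sd <- sqrt(object$mse)
  mu <- object$fitted.values
  sims <- with_seed(seed, {
    replicate(nsim, mu + stats::rnorm(length(mu), 0, noise_sd),
              simplify = FALSE)
  })
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.washout_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.washout_fit")
}

#' @export
print.summary.washout_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  dev <- f$series$intensities - mean(f$series$intensities)
  cat(sprintf("  constant-model MSE %.4g dB^2; variance explained %.1f%%\n",
              mean(dev^2),
              if (mean(dev^2) > 0) 100 * (1 - f$mse / mean(dev^2)) else 0))
  cat(sprintf("  washout flag at -19.3 dB: %s\n",
              ifelse(washout_flag(f$area), "present", "absent")))
  invisible(x)
}

#' Plot a washout fit
#'
#' Observed samples with the fitted exponential overlaid.
#'
#' @param x a `washout_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.washout_fit <- function(x, ...) {
  graphics::plot(x$series$times, x$series$intensities,
                 xlab = "time (s)", ylab = "intensity (dB)",
                 main = sprintf("washout fit, %s ROI (AREA %.1f dB)",
                                x$series$roi, x$area), ...)
  tt <- seq(min(x$series$times), max(x$series$times), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "red3", lwd = 2)
  invisible(x)
}
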