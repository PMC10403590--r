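#' Extract an amplitude trend series from a frame sequence
#'
#' For each frame, takes the peak-to-peak amplitude (max minus min) of the
#' samples inside the ROI, optionally followed by moving-average smoothing.
#' Frames may be [channel_data()] records (ROI over elements; peak-to-peak
#' over the ROI traces) or [recon_volume()]s (ROI over voxels).
#'
#' @param frames list of frames.
#' @param roi logical mask or index vector into a frame's element grid or
#'   voxel array.
#' @param frame_rate frames per second (default 10).
#' @param window moving-average window (s); `NULL` for none.
#' @param roi_label label for the returned series.
#' @return A [trend_series()].
#' @export
extract_trend <- function(frames, roi, frame_rate = 10, window = NULL,
                          roi_label = "vein") {
  if (!length(frames)) obs_usage_error("no frames supplied")
  idx <- if (is.logical(roi)) which(roi) else as.integer(roi)
  if (!length(idx)) obs_usage_error("empty ROI")
  ptp <- vapply(frames, function(fr) {
    v <- if (inherits(fr, "channel_data")) {
      nel <- dim(fr$samples)[1] * dim(fr$samples)[2]
      m <- matrix(fr$samples, nrow = nel)
      m[idx, , drop = FALSE]
    } else if (inherits(fr, "recon_volume")) fr$voxels[idx]
    else if (is.array(fr) || is.numeric(fr)) fr[idx]
    else obs_usage_error("frames must be channel_data, recon_volume or arrays")
    max(v) - min(v)
  }, numeric(1))
  if (!is.null(window)) {
    w <- max(1L, round(window * frame_rate))
    ptp <- as.numeric(stats::filter(ptp, rep(1 / w, w), sides = 2))
    # fill the ends left NA by the centred filter
    ptp <- approx(which(!is.na(ptp)), ptp[!is.na(ptp)], xout = seq_along(ptp),
                  rule = 2)$y
  }
  trend_series((seq_along(frames) - 1) / frame_rate, ptp, roi = roi_label)
}

#' Linear oxygen-saturation calibration
#'
#' Least-squares line of optoacoustic amplitude against reference oxygen
#' saturation; the slope is reported in mV per % saturation.
#'
#' @param trend a [trend_series()] of amplitudes (mV).
#' @param so2_reference paired saturation values (%).
#' @return Object of class `so2_calibration`: `$slope` (mV/%), `$intercept`
#'   (mV), `$r_squared`.
#' @export
fit_so2_linear <- function(trend, so2_reference) {
  y <- trend$values
  x <- as.numeric(so2_reference)
  if (length(x) != length(y) || length(x) < 3)
    obs_usage_error("need >= 3 paired amplitude/saturation points")
  if (sd(x) == 0) obs_fit_error("saturation reference has zero variance")
  fit <- lm(y ~ x)
  ss <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = ss$r.squared), class = "so2_calibration")
}

#' @export
print.so2_calibration <- function(x, ...) {
  cat(sprintf("<so2_calibration> slope %.4g mV/%%, intercept %.4g mV, R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Exponential decay fit against a tissue baseline
#'
#' Normalizes the vascular trend by the time-aligned tissue baseline (both
#' scaled to their initial value), then fits `A exp(-k t)` by nonlinear
#' least squares (log-linear initialisation).
#'
#' @param trend vascular [trend_series()].
#' @param baseline tissue [trend_series()]; must overlap `trend` in time.
#' @return Object of class `decay_fit`: `$k` (1/s), `$r_squared`,
#'   `$rms_agreement` (%, 100 x (1 - rms residual / mean level)).
#' @export
fit_decay <- function(trend, baseline) {
  t0 <- max(min(trend$time), min(baseline$time))
  t1 <- min(max(trend$time), max(baseline$time))
  if (t1 <= t0) obs_usage_error("trend and baseline do not overlap in time")
  keep <- trend$time >= t0 & trend$time <= t1
  tt <- trend$time[keep]
  b <- approx(baseline$time, baseline$values, xout = tt)$y
  if (any(b <= 0)) obs_fit_error("baseline contains non-positive values")
  r <- (trend$values[keep] / trend$values[keep][1]) / (b / b[1])
  bad <- mean(r <= 0)
  if (bad > 0.05)
    obs_fit_error(sprintf("%.0f%% of baseline-adjusted values are non-positive", 100 * bad))
  ok <- r > 0
  init <- lm(log(r[ok]) ~ tt[ok])
  k0 <- -unname(coef(init)[2]); a0 <- exp(unname(coef(init)[1]))
  fit <- tryCatch(
    nls(r ~ A * exp(-k * tt), start = list(A = a0, k = k0),
        control = list(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred <- a0 * exp(-k0 * tt); k <- k0
  } else {
    k <- unname(coef(fit)["k"]); pred <- fitted(fit)
  }
  res <- r - pred
  r2 <- 1 - sum(res^2) / sum((r - mean(r))^2)
  rms <- 100 * (1 - sqrt(mean(res^2)) / mean(r))
  structure(list(k = k, r_squared = r2, rms_agreement = rms,
                 ratio = r, time = tt, fitted = pred), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> k = %.4g 1/s, R^2 = %.3f, RMS agreement = %.1f%%\n",
              x$k, x$r_squared, x$rms_agreement))
  invisible(x)
}

#' Venous compliance from amplitude ratios under occlusion pressures
#'
#' Per-interval finite differences dR/dP (% per mmHg) of the venous
#' amplitude ratio against cuff pressure. Points at or below the validity
#' threshold (vessel flattening) are excluded and reported.
#'
#' @param ratios amplitude ratios (%) at the occlusion pressures.
#' @param pressures occlusion pressures (mmHg).
#' @param min_pressure validity threshold (mmHg); only pressures strictly
#'   above it enter the differences (default 40).
#' @return Object of class `compliance_result`: `$dR_dP` per interval
#'   (%/mmHg), `$pressures`, `$ratios`, `$excluded`.
#' @export
compliance <- function(ratios, pressures, min_pressure = 40) {
  if (length(ratios) != length(pressures))
    obs_usage_error("ratios and pressures must pair up")
  valid <- pressures > min_pressure
  excluded <- data.frame(pressure = pressures[!valid], ratio = ratios[!valid])
  p <- pressures[valid]; r <- ratios[valid]
  if (length(p) < 2)
    obs_usage_error("need >= 2 valid points above the pressure threshold")
  o <- order(p)
  p <- p[o]; r <- r[o]
  if (any(diff(p) == 0)) obs_usage_error("degenerate (repeated) pressure values")
  dd <- diff(r) / diff(p)
  names(dd) <- sprintf("%g-%g mmHg", p[-length(p)], p[-1])
  structure(list(dR_dP = dd, pressures = p, ratios = r, excluded = excluded),
            class = "compliance_result")
}

#' @export
print.compliance_result <- function(x, ...) {
  cat("<compliance_result> dR/dP (%/mmHg):\n")
  print(round(x$dR_dP, 4))
  if (nrow(x$excluded))
    cat(sprintf("  %d point(s) excluded below the pressure threshold\n",
                nrow(x$excluded)))
  invisible(x)
}

#' Flow-mediated dilation: diameter change from the peak signal change
#'
#' Converts the relative optoacoustic signal change `p_A` at the
#' post-release peak into a fractional diameter change, `sqrt(1 + p_A) - 1`,
#' under the approximation that signal tracks vascular volume (area).
#'
#' @param p_A relative signal change at the peak (fraction, > -1).
#' @return fractional diameter change.
#' @export
fmd_diameter_change <- function(p_A) {
  if (any(p_A <= -1)) obs_domain_error("p_A must be > -1")
  sqrt(1 + p_A) - 1
}
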