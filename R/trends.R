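#' Time-stamped amplitude trend series
#'
#' Peak-to-peak optoacoustic amplitudes of a region of interest over time —
#' the series all physiological fits operate on.
#'
#' @param time timestamps (s), strictly increasing.
#' @param values amplitudes (mV or a.u.), finite.
#' @param roi ROI label: `"vein"`, `"artery"` or `"tissue"`.
#' @return Object of class `trend_series`.
#' @export
trend_series <- function(time, values, roi = c("vein", "artery", "tissue")) {
  roi <- match.arg(roi)
  if (length(time) != length(values)) obs_usage_error("time/values length mismatch")
  if (any(diff(time) <= 0)) obs_validation_error("timestamps must be strictly increasing")
  if (!all(is.finite(values))) obs_validation_error("trend values must be finite")
  structure(list(time = as.numeric(time), values = as.numeric(values), roi = roi),
            class = "trend_series")
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("<trend_series> roi '%s', %d samples over %.1f s\n",
              x$roi, length(x$time), diff(range(x$time))))
  invisible(x)
}

#' @export
plot.trend_series <- function(x, ...) {
  plot(x$time, x$values, type = "l", xlab = "time (s)",
       ylab = "peak-to-peak amplitude", main = sprintf("ROI: %s", x$roi), ...)
  invisible(x)
}

#' Physiological amplitude protocol specification
#'
#' Defines the synthetic amplitude protocols used to emulate the in-vivo
#' measurement campaigns:
#'
#' * `hypoxia_cycle` — square-wave oxygen cycling, each cycle `cycle_s`
#'   seconds comprising `low_s` seconds of the oxygen-poor state followed by
#'   the normal state. Amplitude follows the linear amplitude-vs-saturation
#'   relation `baseline_mv - slope_mv_per_pct * (so2_normal - so2(t))`;
#'   venous ROIs respond with a `venous_delay` lag on both edges.
#' * `occlusion_vein` / `occlusion_artery` — cuff occlusion/release steps
#'   (rest, occlusion, release, occlusion, release) changing the amplitude
#'   by `delta_pct` during occlusion (veins pool blood: positive; arteries
#'   are starved: negative).
#' * `agent_decay` — exogenous-agent washout: the blood trace is
#'   `A ((1 - f) + f exp(-k t))` times a slow shared tissue drift
#'   `exp(-tissue_k t)`; the tissue trace carries the drift alone.
#'
#' @param type protocol kind.
#' @param ... overrides of the kind-specific defaults listed above
#'   (`cycle_s = 230`, `low_s = 50`, `baseline_mv = 120`,
#'   `slope_mv_per_pct = 0.76`, `so2_normal = 98`, `so2_low = 48`,
#'   `venous_delay = 15`; `rest_s = 60`, `step_s = 40`,
#'   `delta_pct = 23` or `-37`, `baseline = 100`;
#'   `k = 3.6e-4`, `agent_fraction = 1`, `tissue_k = 5.27e-5`,
#'   `amplitude = 100`), plus `noise_sd` (additive Gaussian s.d.).
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(type = c("hypoxia_cycle", "occlusion_vein",
                                   "occlusion_artery", "agent_decay"), ...) {
  kind <- tryCatch(match.arg(type),
                   error = function(e) obs_usage_error(
                     sprintf("unknown protocol kind '%s'", type[1])))
  defaults <- switch(kind,
    hypoxia_cycle = list(cycle_s = 230, low_s = 50, baseline_mv = 120,
                         slope_mv_per_pct = 0.76, so2_normal = 98,
                         so2_low = 48, venous_delay = 15, noise_sd = 0),
    occlusion_vein = list(rest_s = 60, step_s = 40, delta_pct = 23,
                          baseline = 100, noise_sd = 0),
    occlusion_artery = list(rest_s = 60, step_s = 40, delta_pct = -37,
                            baseline = 100, noise_sd = 0),
    agent_decay = list(k = 3.6e-4, agent_fraction = 1, tissue_k = 5.27e-5,
                       amplitude = 100, noise_sd = 0))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    obs_usage_error(sprintf("unknown parameter(s) for '%s': %s", kind,
                            paste(unknown, collapse = ", ")))
  p <- utils::modifyList(defaults, over)
  if (kind == "hypoxia_cycle" && (p$cycle_s <= 0 || p$low_s <= 0 || p$low_s >= p$cycle_s))
    obs_usage_error("need 0 < low_s < cycle_s")
  if (grepl("occlusion", kind) && p$delta_pct <= -100)
    obs_usage_error("delta_pct must be > -100")
  structure(c(list(kind = kind), p), class = "protocol_spec")
}

#' Simulate a physiological amplitude trend series
#'
#' Generates the amplitude trace a given [protocol_spec()] produces for a
#' chosen ROI, plus seeded Gaussian noise. Deterministic for a fixed seed.
#'
#' @param protocol a [protocol_spec()].
#' @param duration record length (s).
#' @param dt sampling interval (s), `0 < dt < duration`.
#' @param roi ROI label for the returned series; for `agent_decay`, the
#'   `"tissue"` ROI returns the drift-only baseline trace, any vascular ROI
#'   the decaying blood trace. For `hypoxia_cycle`, `"vein"` applies the
#'   venous lag.
#' @param seed RNG seed for the noise.
#' @return A [trend_series()].
#' @export
simulate_trend_series <- function(protocol, duration, dt, roi = "artery",
                                  seed = NULL) {
  if (!inherits(protocol, "protocol_spec"))
    obs_usage_error("'protocol' must be a protocol_spec")
  if (!(dt > 0 && duration > dt)) obs_usage_error("need duration > dt > 0")
  t <- seq(0, duration, by = dt)
  p <- protocol
  vals <- switch(p$kind,
    hypoxia_cycle = {
      lag <- if (roi == "vein") p$venous_delay else 0
      phase <- (t - lag) %% p$cycle_s
      so2 <- ifelse(phase >= 0 & phase < p$low_s, p$so2_low, p$so2_normal)
      # before the first cycle reaches a lagged vein, it still sits at baseline
      so2[t < lag] <- p$so2_normal
      p$baseline_mv - p$slope_mv_per_pct * (p$so2_normal - so2)
    },
    occlusion_vein = ,
    occlusion_artery = {
      occ <- (t >= p$rest_s & t < p$rest_s + p$step_s) |
        (t >= p$rest_s + 2 * p$step_s & t < p$rest_s + 3 * p$step_s)
      p$baseline * (1 + occ * p$delta_pct / 100)
    },
    agent_decay = {
      drift <- exp(-p$tissue_k * t)
      if (roi == "tissue") p$amplitude * drift
      else p$amplitude * ((1 - p$agent_fraction) +
                            p$agent_fraction * exp(-p$k * t)) * drift
    })
  if (p$noise_sd > 0)
    vals <- vals + with_seed(seed, rnorm(length(t), sd = p$noise_sd))
  trend_series(t, vals, roi = if (roi %in% c("vein", "artery", "tissue")) roi else "vein")
}
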