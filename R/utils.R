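#' @useDynLib obscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft nextn optimize optim approx lm coef nls sd
#'   mvfft rnorm runif resid fitted predict
NULL

# classed conditions so callers can distinguish contract violations
obs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "obscope_error")))
}

obs_format_error     <- function(msg) obs_error(msg, "obscope_format_error")
obs_geometry_error   <- function(msg) obs_error(msg, "obscope_geometry_error")
obs_usage_error      <- function(msg) obs_error(msg, "obscope_usage_error")
obs_validation_error <- function(msg) obs_error(msg, "obscope_validation_error")
obs_domain_error     <- function(msg) obs_error(msg, "obscope_domain_error")
obs_fit_error        <- function(msg) obs_error(msg, "obscope_fit_error")
obs_measure_error    <- function(msg) obs_error(msg, "obscope_measure_error")
obs_config_error     <- function(msg) obs_error(msg, "obscope_config_error")

# evaluate expr with a temporarily seeded RNG, restoring global state after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# sound speed m/s -> mm/us
mm_per_us <- function(c_m_per_s) c_m_per_s / 1000

# DFT sample frequencies in cycles per unit, fft bin order
fft_freq <- function(n, d = 1) {
  half <- floor((n - 1) / 2)
  c(0:half, -(n - half - 1):-1) / (n * d)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    obs_usage_error(sprintf("'%s' must be a single positive finite number", name))
}
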