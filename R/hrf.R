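#' Canonical double-gamma HRF parameter set
#'
#' Parameters of the canonical hemodynamic response function modeled as the
#' difference of two gamma densities: a positive response peaking around 5 s
#' and a delayed undershoot, the latter scaled down by
#' `peak_undershoot_ratio`.  The defaults are the widely used canonical
#' values (peak delay 6 s, undershoot delay 16 s, unit dispersions, ratio 6,
#' 32 s of support).
#'
#' @param peak_delay Delay of the response peak gamma, seconds.
#' @param undershoot_delay Delay of the undershoot gamma, seconds.
#' @param peak_dispersion Dispersion (scale) of the response gamma, seconds.
#' @param undershoot_dispersion Dispersion of the undershoot gamma, seconds.
#' @param peak_undershoot_ratio Ratio of peak to undershoot amplitude
#'   (dimensionless, > 0); the undershoot gamma is divided by this value.
#' @param kernel_length Total support of the sampled kernel, seconds.
#' @return An object of class `hrf_params` (a named list).
#' @examples
#' p <- hrf_params()
#' h <- canonical_hrf(p, tr = 2.5)
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       peak_undershoot_ratio = 6, kernel_length = 32) {
  p <- list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
            peak_dispersion = peak_dispersion,
            undershoot_dispersion = undershoot_dispersion,
            peak_undershoot_ratio = peak_undershoot_ratio,
            kernel_length = kernel_length)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0,
                 logical(1L))))
    stop("all HRF parameters must be single positive finite numbers")
  class(p) <- "hrf_params"
  p
}

# unnormalized continuous double-gamma; gamma shape = delay / dispersion
hrf_fun <- function(t, params) {
  stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                scale = params$peak_dispersion) -
    stats::dgamma(t, shape = params$undershoot_delay / params$undershoot_dispersion,
                  scale = params$undershoot_dispersion) /
      params$peak_undershoot_ratio
}

# analytic peak height, so that sampled kernels at different tr agree at
# shared time points (normalizing by the sampled maximum would not)
hrf_peak_value <- function(params) {
  opt <- stats::optimize(function(t) hrf_fun(t, params),
                         interval = c(0, params$undershoot_delay), maximum = TRUE)
  opt$objective
}

#' Sample the canonical HRF on a scan-time grid
#'
#' Evaluates the double-gamma kernel at `0, tr, 2 tr, ...` over
#' `kernel_length` seconds and normalizes so the continuous kernel's peak
#' equals 1.  Subsampling is therefore consistent: doubling `tr` returns the
#' same function evaluated on the coarser grid.
#'
#' @param params An [hrf_params()] object.
#' @param tr Sampling interval, seconds (> 0).
#' @return Numeric vector of kernel values, with attribute `times`.
#' @export
canonical_hrf <- function(params = hrf_params(), tr) {
  if (!inherits(params, "hrf_params")) params <- do.call(hrf_params, as.list(params))
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a single positive number")
  times <- seq(0, params$kernel_length, by = tr)
  h <- hrf_fun(times, params) / hrf_peak_value(params)
  attr(h, "times") <- times
  h
}
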