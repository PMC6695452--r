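#' Gaussian smoothing kernel specification for spike density functions
#'
#' @param sigma_ms kernel SD in ms (default 30).
#' @param width_sigma total kernel support in multiples of sigma (default
#'   4, i.e. truncation at +/- 2 sigma); the truncated kernel is
#'   renormalized to unit mass so spike counts are preserved.
#' @return a `kernel_spec` list.
#' @export
kernel_spec <- function(sigma_ms = 30, width_sigma = 4) {
  check_number(sigma_ms, "sigma_ms", lower = 0, strict_lower = TRUE)
  check_number(width_sigma, "width_sigma", lower = 0, strict_lower = TRUE)
  structure(list(sigma_ms = sigma_ms, width_sigma = width_sigma),
            class = "kernel_spec")
}

kernel_weights <- function(kernel, bin_ms = 1) {
  half <- floor(kernel$sigma_ms * kernel$width_sigma / 2 / bin_ms)
  x <- (-half:half) * bin_ms
  w <- exp(-x^2 / (2 * kernel$sigma_ms^2))
  w / sum(w)
}

#' Trial-averaged spike density function
#'
#' Event-aligned spikes are binned at 1 ms, convolved with the truncated,
#' mass-renormalized Gaussian kernel, and averaged over trials; the result
#' is an instantaneous rate in Hz. Spikes up to half the kernel support
#' outside the requested window are included so the smoothed rate is
#' unbiased at the window edges.
#'
#' @param aligned_spikes list with one numeric vector per trial of spike
#'   times in seconds relative to the alignment event.
#' @param window_ms `c(start, end)` of the output grid in ms.
#' @param kernel a [kernel_spec()].
#' @param bin_ms grid step (1 ms by default, matching the spike-time
#'   resolution of the recordings being emulated).
#' @return data frame `time_ms`, `rate_hz` with attribute `n_trials`.
#' @export
spike_density <- function(aligned_spikes, window_ms = c(-500, 1000),
                          kernel = kernel_spec(), bin_ms = 1) {
  stop_if(!is.list(aligned_spikes) || length(aligned_spikes) == 0L,
          "`aligned_spikes` must be a non-empty list of spike-time vectors")
  stop_if(window_ms[1] >= window_ms[2], "window start must precede its end")
  w <- kernel_weights(kernel, bin_ms)
  half <- (length(w) - 1L) / 2L
  # pad so edge bins receive full kernel mass from just-outside spikes
  lo <- window_ms[1] - half * bin_ms
  hi <- window_ms[2] + half * bin_ms
  breaks <- seq(lo, hi + bin_ms, by = bin_ms) - bin_ms / 2
  n_bins <- length(breaks) - 1L
  acc <- numeric(n_bins)
  for (s in aligned_spikes) {
    ms <- s * 1000
    ms <- ms[ms >= lo - bin_ms / 2 & ms < hi + bin_ms / 2]
    if (length(ms)) {
      acc <- acc + tabulate(findInterval(ms, breaks), nbins = n_bins)
    }
  }
  n_trials <- length(aligned_spikes)
  sm <- as.numeric(stats::filter(acc, w, sides = 2))
  centers <- seq(lo, hi, by = bin_ms)
  keep <- centers >= window_ms[1] & centers <= window_ms[2]
  out <- data.frame(time_ms = centers[keep],
                    rate_hz = sm[keep] / n_trials * (1000 / bin_ms))
  attr(out, "n_trials") <- n_trials
  attr(out, "kernel") <- kernel
  out
}
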