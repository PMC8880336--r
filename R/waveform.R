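#' Pulsatile flow waveform
#'
#' Builds a periodic volumetric flow waveform \eqn{Q(t)} for a pump-driven
#' circulation loop. The default shape is a raised-cosine systolic pulse on a
#' constant diastolic baseline: within the systolic fraction \eqn{s} of the
#' cycle the flow rises as \eqn{(1 - \cos(2\pi t / sT))/2} from baseline to
#' peak and back; for the rest of the cycle it stays at baseline. Baseline is
#' chosen so the time average equals `mean_flow_ml_s` exactly.
#'
#' @param mean_flow_ml_s Cycle-averaged flow in mL/s (>= 0).
#' @param peak_flow_ml_s Peak instantaneous flow in mL/s. Must exceed the mean
#'   for the pulsatile shape; ignored for `shape = "steady"`.
#' @param period_ms Cardiac period in ms (default 800).
#' @param n_phases Number of reconstructed cardiac phases (default 24).
#' @param systolic_fraction Fraction of the cycle occupied by the pulse
#'   (default 0.35).
#' @param shape `"raised-cosine"` (default) or `"steady"` (constant flow).
#'
#' @return An object of class `pulse_waveform`: a list with the configured
#'   parameters and a vectorized function `flow(t_ms)` returning mL/s.
#' @examples
#' wf <- pulsatile_waveform(1.2, peak_flow_ml_s = 2.1)
#' mean(wf$flow(seq(0, 800, length.out = 4801)[-4801]))
#' @export
pulsatile_waveform <- function(mean_flow_ml_s, peak_flow_ml_s = NULL,
                               period_ms = 800, n_phases = 24,
                               systolic_fraction = 0.35,
                               shape = c("raised-cosine", "steady")) {
  shape <- match.arg(shape)
  if (!is.numeric(mean_flow_ml_s) || mean_flow_ml_s < 0) {
    stop("`mean_flow_ml_s` must be a non-negative number.")
  }
  stopifnot(period_ms > 0, n_phases >= 2,
            systolic_fraction > 0, systolic_fraction < 1)

  if (shape == "steady") {
    peak_flow_ml_s <- mean_flow_ml_s
    flow <- local({
      q <- mean_flow_ml_s
      function(t_ms) rep_len(q, length(t_ms))
    })
    q_base <- mean_flow_ml_s
  } else {
    if (is.null(peak_flow_ml_s)) {
      stop("`peak_flow_ml_s` is required for the raised-cosine shape.")
    }
    if (peak_flow_ml_s < mean_flow_ml_s) {
      stop("`peak_flow_ml_s` must not be below `mean_flow_ml_s`.")
    }
    s <- systolic_fraction
    # mean of the unit pulse over the cycle is s/2
    q_base <- (mean_flow_ml_s - peak_flow_ml_s * s / 2) / (1 - s / 2)
    if (q_base < 0) {
      stop("Waveform infeasible: baseline flow would be negative; ",
           "raise the mean flow or lower the peak.")
    }
    flow <- local({
      qb <- q_base; qp <- peak_flow_ml_s; s <- s; T <- period_ms
      function(t_ms) {
        tau <- (t_ms %% T) / T
        p <- ifelse(tau < s, 0.5 * (1 - cos(2 * pi * tau / s)), 0)
        qb + (qp - qb) * p
      }
    })
  }

  structure(
    list(period_ms = period_ms, n_phases = n_phases,
         mean_flow_ml_s = mean_flow_ml_s, peak_flow_ml_s = peak_flow_ml_s,
         base_flow_ml_s = q_base, systolic_fraction = systolic_fraction,
         shape = shape, flow = flow),
    class = "pulse_waveform")
}

#' Cardiac phase sampling times of a waveform
#'
#' @param waveform A [pulsatile_waveform()] object.
#' @return Numeric vector of `n_phases` times in ms, starting at 0.
#' @export
phase_times <- function(waveform) {
  stopifnot(inherits(waveform, "pulse_waveform"))
  waveform$period_ms * (seq_len(waveform$n_phases) - 1) / waveform$n_phases
}

#' @export
print.pulse_waveform <- function(x, ...) {
  cat(sprintf(
    "<pulse_waveform> %s: mean %.3g mL/s, peak %.3g mL/s, period %g ms, %d phases\n",
    x$shape, x$mean_flow_ml_s, x$peak_flow_ml_s, x$period_ms, x$n_phases))
  invisible(x)
}

# Fourier decomposition of the flow waveform: returns list(a0, c) where
# Q(t) ~ a0 + Re(sum_n c[n] * exp(i * n * w0 * t)), w0 = 2*pi/period.
waveform_harmonics <- function(waveform, n_harmonics = 8, n_samples = 512) {
  t <- waveform$period_ms * (seq_len(n_samples) - 1) / n_samples
  q <- waveform$flow(t)
  F <- fft(q) / n_samples
  a0 <- Re(F[1])
  n_harmonics <- min(n_harmonics, floor((n_samples - 1) / 2))
  c_n <- 2 * F[seq_len(n_harmonics) + 1]
  list(a0 = a0, c = c_n)
}
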