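#' Neuron parameters
#'
#' Membrane, synaptic and adaptation constants shared by all neurons of a
#' simulation. Defaults are the case-example constants: threshold 20 mV,
#' membrane time constant 20 ms, synaptic time constant 2 ms, integration
#' step 0.1 ms. Adaptation is off by default (`gamma = 0`); the discrete
#' mutual-inhibition case example uses `tau_a = 350`, `gamma = 0.44` and the
#' continuum case example `tau_a = 650`, `gamma = 0.013`.
#'
#' @param theta spike threshold (mV), > 0.
#' @param tau_m membrane time constant (ms), > 0.
#' @param tau_s synaptic time constant (ms), > 0.
#' @param tau_a adaptation time constant (ms), > 0.
#' @param gamma adaptation strength (dimensionless multiplier on the
#'   per-neuron adaptation trace).
#' @param h integration step (ms); must satisfy `0 < h <= tau_s / 2`.
#' @return An object of class `neuron_params`.
#' @examples
#' neuron_params()                        # non-adapting defaults
#' neuron_params(tau_a = 350, gamma = 0.44)  # discrete case example
#' @export
neuron_params <- function(theta = 20, tau_m = 20, tau_s = 2,
                          tau_a = 350, gamma = 0, h = 0.1) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(tau_m), is.numeric(tau_s), is.numeric(tau_a),
            is.numeric(gamma), is.numeric(h))
  if (theta <= 0) stop("theta must be positive")
  if (tau_m <= 0 || tau_s <= 0 || tau_a <= 0)
    stop("all time constants must be positive")
  if (h <= 0) stop("integration step h must be positive")
  if (h > tau_s / 2)
    stop("integration step h must not exceed tau_s/2 (got h = ", h, ")")
  if (gamma < 0) stop("gamma must be non-negative")
  structure(list(theta = theta, tau_m = tau_m, tau_s = tau_s,
                 tau_a = tau_a, gamma = gamma, h = h),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("LIF neuron parameters: theta =", x$theta, "mV, tau_m =", x$tau_m,
      "ms, tau_s =", x$tau_s, "ms, tau_a =", x$tau_a, "ms, gamma =",
      x$gamma, ", h =", x$h, "ms\n")
  invisible(x)
}

#' Case-example neuron parameters per architecture
#'
#' Convenience constructor returning the reference case-example adaptation
#' settings for each architecture: no adaptation for the unstructured
#' network, `(tau_a, gamma) = (350, 0.44)` for the discrete
#' mutual-inhibition network, and `(650, 0.013)` for the continuum network.
#'
#' @param architecture one of `"unstructured"`, `"discrete"`, `"continuum"`.
#' @param h integration step (ms).
#' @return A `neuron_params` object.
#' @export
case_neuron_params <- function(architecture = c("unstructured", "discrete",
                                                "continuum"), h = 0.1) {
  architecture <- match.arg(architecture)
  switch(architecture,
         unstructured = neuron_params(gamma = 0, h = h),
         discrete = neuron_params(tau_a = 350, gamma = 0.44, h = h),
         continuum = neuron_params(tau_a = 650, gamma = 0.013, h = h))
}
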