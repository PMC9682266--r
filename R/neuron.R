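#' Neuron parameters
#'
#' Integer parameterization of a current-based leaky integrate-and-fire
#' unit.  Decay constants are Loihi's integer encoding of exponential time
#' constants, `delta = 2^12 / tau`: `delta = 4096` decays fully in one step,
#' `delta = 0` is a perfect integrator.
#'
#' @param decay_I Synaptic-input decay, integer in [0, 4096].
#' @param decay_v Voltage decay, integer in [0, 4096].
#' @param threshold Spike threshold, positive integer; a spike fires when
#'   the voltage strictly exceeds it.
#' @param bias Constant bias added to the voltage update each step.
#' @param refractory Refractory length in steps (>= 1); the voltage is
#'   clamped to zero and thresholding suspended for that many steps after a
#'   spike.
#' @return A list of class `neuron_params`.
#' @export
neuron_params <- function(decay_I, decay_v, threshold, bias = 0,
                          refractory = 1) {
  chk_int <- function(x, name, lo, hi) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x != floor(x) || x < lo || x > hi) {
      stop(sprintf("%s: must be an integer in [%s, %s]", name,
                   format(lo), format(hi)), call. = FALSE)
    }
    as.numeric(x)
  }
  structure(list(
    decay_I    = chk_int(decay_I, "decay_I", 0, 4096),
    decay_v    = chk_int(decay_v, "decay_v", 0, 4096),
    threshold  = chk_int(threshold, "threshold", 1, Inf),
    bias       = chk_int(bias, "bias", -Inf, Inf),
    refractory = chk_int(refractory, "refractory", 1, Inf)
  ), class = "neuron_params")
}

#' Synaptic input update
#'
#' One forward-Euler step of the current-based synapse in integer
#' arithmetic: the previous input is decayed by `(4096 - decay_I) / 4096`,
#' rounded away from zero, and the summed effective weights of spikes
#' delivered this step are added.  A spike into a quiescent synapse
#' therefore sets the input exactly to its weight `J`.
#'
#' @param I_prev Previous synaptic input (integer vector, one per unit).
#' @param decay_I Decay constant in [0, 4096].
#' @param weighted_spike_sum Sum of effective weights `J` delivered this
#'   step, per unit.
#' @return Updated integer synaptic input.
#' @examples
#' update_synaptic_input(1000, 128, 0)  # 969
#' @export
update_synaptic_input <- function(I_prev, decay_I, weighted_spike_sum = 0) {
  if (!is.numeric(decay_I) || length(decay_I) != 1L || !is.finite(decay_I) ||
      decay_I < 0 || decay_I > 4096) {
    stop("decay_I: must be in [0, 4096]", call. = FALSE)
  }
  round_away_from_zero(I_prev * (4096 - decay_I) / 4096) + weighted_spike_sum
}

#' Voltage update
#'
#' One forward-Euler step of the membrane voltage: decay by
#' `(4096 - decay_v) / 4096` with round-away-from-zero, then add the current
#' synaptic input and the bias.  Refractory units are clamped to zero
#' instead (the synaptic input keeps evolving; only the voltage is held).
#'
#' @param v_prev Previous voltage (integer vector).
#' @param decay_v Decay constant in [0, 4096].
#' @param I Current synaptic input.
#' @param bias Constant bias current.
#' @param refractory Logical vector: units currently refractory.
#' @return Updated integer voltage.
#' @examples
#' update_voltage(100, 2048, 0)  # 50
#' @export
update_voltage <- function(v_prev, decay_v, I, bias = 0,
                           refractory = FALSE) {
  if (!is.numeric(decay_v) || length(decay_v) != 1L || !is.finite(decay_v) ||
      decay_v < 0 || decay_v > 4096) {
    stop("decay_v: must be in [0, 4096]", call. = FALSE)
  }
  v <- round_away_from_zero(v_prev * (4096 - decay_v) / 4096) + I + bias
  v[refractory] <- 0
  v
}

#' Threshold, reset and refractory bookkeeping
#'
#' Applies the spike condition to a population state: a non-refractory unit
#' spikes iff its voltage strictly exceeds the threshold (`v == threshold`
#' does not fire); spiking units are reset to zero voltage and enter the
#' refractory period.  Refractory counters of units that entered the step
#' refractory are decremented by one.
#'
#' @param state Population state list with numeric `v` and integer
#'   `refractory_remaining`, as produced by [neuron_state].
#' @param params A [neuron_params].
#' @return The updated state; `state$spiked` flags this step's spikes.
#' @export
threshold_and_reset <- function(state, params) {
  was_refractory <- state$refractory_remaining > 0
  spiked <- !was_refractory & (state$v > params$threshold)
  state$v[spiked] <- 0
  state$refractory_remaining[spiked] <- params$refractory
  dec <- was_refractory
  state$refractory_remaining[dec] <- state$refractory_remaining[dec] - 1
  state$spiked <- spiked
  state
}

#' Fresh neuron state for a population
#'
#' All state variables are integers held in doubles: synaptic input `I`,
#' voltage `v`, remaining refractory steps, and the spike flag of the most
#' recent step.
#'
#' @param n Population size.
#' @return A list of class `neuron_state`.
#' @export
neuron_state <- function(n) {
  structure(list(
    I = numeric(n),
    v = numeric(n),
    refractory_remaining = numeric(n),
    spiked = logical(n)
  ), class = "neuron_state")
}
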