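#' Resting initial state of the modified TP06 cell
#'
#' The published TP06 resting values: membrane voltage, the 12
#' Hodgkin--Huxley-type gates, intracellular / sarcoplasmic-reticulum /
#' dyadic-subspace ion concentrations and the ryanodine-release recovery
#' variable `R_bar`.
#'
#' @return Named numeric vector of length 19 (class `cell_state`).
#' @export
cell_state_rest <- function() {
  s <- c(V = -86.2,
         m = 0, h = 0.75, j = 0.75,
         d = 0, f = 1, f2 = 1, fCass = 1,
         r = 0, s = 1,
         xr1 = 0, xr2 = 1, xs = 0,
         Na_i = 7.67, K_i = 138.3,
         Ca_i = 0.00007, Ca_SS = 0.00007, Ca_SR = 1.3,
         R_bar = 1)
  structure(s, class = "cell_state")
}

state_field_names <- function() names(unclass(cell_state_rest()))

check_cell_state <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 19) stop("cell state must have 19 fields", call. = FALSE)
  nm <- state_field_names()
  gates <- s[c(2:13, 19)]
  if (any(!is.finite(s)))
    stop("non-finite value in state field ", nm[which(!is.finite(s))[1]],
         call. = FALSE)
  if (any(gates < -1e-12 | gates > 1 + 1e-12))
    stop("gate out of [0,1]: ", nm[c(2:13, 19)][which(gates < 0 | gates > 1)[1]],
         call. = FALSE)
  if (any(s[14:18] <= 0))
    stop("non-positive concentration: ", nm[14:18][which(s[14:18] <= 0)[1]],
         call. = FALSE)
  invisible(TRUE)
}

#' Membrane currents at a given state
#'
#' Evaluates every TP06 membrane current (with the effective, multiplier-scaled
#' conductances) at the instantaneous state `s`.  The total `I_ion` is the
#' exact sum of the twelve components.
#'
#' @param s A `cell_state` vector (see [cell_state_rest()]).
#' @param p A `tp06_params` object.
#' @return A one-row tibble with columns `I_Na`, `I_K1`, `I_to`, `I_Kr`,
#'   `I_Ks`, `I_CaL`, `I_NaCa`, `I_NaK`, `I_pCa`, `I_pK`, `I_bCa`, `I_bNa`
#'   and their sum `I_ion`, all in pA/pF.
#' @export
compute_currents <- function(s, p) {
  stopifnot(inherits(p, "tp06_params"))
  check_cell_state(s)
  v <- cpp_currents(as.numeric(s), p)
  tibble::as_tibble(as.list(v))
}

#' Advance a single cell by one explicit time step
#'
#' Voltage and ion concentrations are advanced by forward Euler; gates by the
#' Rush--Larsen exact-exponential update (or forward Euler when
#' `euler_gates = TRUE`, a fidelity-check mode).  A positive `i_stim`
#' depolarizes the cell.
#'
#' @param s A `cell_state` vector.
#' @param p A `tp06_params` object.
#' @param i_stim Stimulus amplitude in pA/pF (positive depolarizes).
#' @param dt Time step in (0, 0.1] ms.
#' @param euler_gates Integrate gates by forward Euler instead of Rush--Larsen.
#' @return The advanced `cell_state`.
#' @export
step_cell <- function(s, p, i_stim = 0, dt = 0.02, euler_gates = FALSE) {
  stopifnot(inherits(p, "tp06_params"))
  check_cell_state(s)
  out <- cpp_step_cell(as.numeric(s), p, -i_stim, dt, euler_gates)
  names(out) <- state_field_names()
  structure(out, class = "cell_state")
}

#' Simulate paced action potentials in a single cell
#'
#' Applies `n_beats` stimuli at the given cycle length starting from the
#' resting state and records the voltage (and optionally every membrane
#' current) at `record_every` ms, integrating at `dt`.
#'
#' @param p A `tp06_params` object.
#' @param n_beats Number of stimuli (>= 1).
#' @param cycle_length Pacing cycle length in ms (>= 300).
#' @param record_currents Record the full current decomposition.
#' @param tail_ms Extra unstimulated time simulated after the last stimulus
#'   (default 5000 ms, enough for the 3-s classification window).
#' @param stim_amp,stim_dur Stimulus amplitude (pA/pF) and duration (ms).
#' @param dt Integration step in ms.
#' @param record_every Output sampling interval in ms.
#' @param init Initial `cell_state` (defaults to [cell_state_rest()]).
#' @param euler_gates Forward-Euler gate integration (fidelity checks).
#' @return An `ap_trace`: a tibble with columns `t`, `V` (and the currents if
#'   recorded), carrying the stimulus schedule and sampling metadata as
#'   attributes.
#' @examples
#' \donttest{
#' tr <- simulate_ap(make_params(), n_beats = 1, tail_ms = 1000)
#' range(tr$V)
#' }
#' @export
simulate_ap <- function(p, n_beats = 1, cycle_length = 1000,
                        record_currents = FALSE, tail_ms = 5000,
                        stim_amp = 20, stim_dur = 2, dt = 0.02,
                        record_every = 1, init = cell_state_rest(),
                        euler_gates = FALSE) {
  stopifnot(inherits(p, "tp06_params"), n_beats >= 1)
  if (cycle_length < 300) stop("cycle_length must be >= 300 ms", call. = FALSE)
  onsets <- 10 + (seq_len(n_beats) - 1) * cycle_length
  duration <- max(onsets) + stim_dur + tail_ms
  res <- cpp_run_cell(as.numeric(init), p, dt, duration, onsets, stim_dur,
                      stim_amp, record_every, record_currents, euler_gates)
  tr <- tibble::tibble(t = res$t, V = res$V)
  if (record_currents) {
    cur <- res$currents
    colnames(cur) <- c("I_Na", "I_K1", "I_to", "I_Kr", "I_Ks", "I_CaL",
                       "I_NaCa", "I_NaK", "I_pCa", "I_pK", "I_bCa", "I_bNa",
                       "I_ion")
    tr <- dplyr::bind_cols(tr, tibble::as_tibble(cur))
  }
  final <- res$final_state
  names(final) <- state_field_names()
  new_ap_trace(tr,
               stim = list(onsets = onsets, amp = stim_amp, dur = stim_dur),
               dt = dt, params = p,
               final_state = structure(final, class = "cell_state"))
}

new_ap_trace <- function(df, stim, dt, params = NULL, final_state = NULL,
                         truth = NULL) {
  structure(df, class = unique(c("ap_trace", class(df))),
            stim = stim, dt = dt, params = params,
            final_state = final_state, truth = truth)
}

#' Action-potential duration at a repolarization fraction
#'
#' APD measured from the upstroke (maximum dV/dt after the stimulus) to the
#' first return below the given repolarization fraction of the AP amplitude.
#'
#' @param tr An `ap_trace`.
#' @param frac Repolarization fraction (0.9 gives APD90).
#' @return APD in ms (NA if the trace never repolarizes to that level).
#' @export
apd <- function(tr, frac = 0.9) {
  t <- tr$t; V <- tr$V
  up <- which.max(diff(V))
  vmax <- max(V[up:length(V)])
  vrest <- V[1]
  thr <- vmax - frac * (vmax - vrest)
  below <- which(V[-seq_len(up)] < thr)
  if (!length(below)) return(NA_real_)
  t[up + below[1]] - t[up]
}

#' @export
print.ap_trace <- function(x, ...) {
  st <- attr(x, "stim")
  cat(sprintf("AP trace: %d samples, t in [%g, %g] ms, %d stimulus(es)\n",
              nrow(x), min(x$t), max(x$t), length(st$onsets)))
  NextMethod()
}
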