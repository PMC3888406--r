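#' Classifier thresholds for AP morphology
#'
#' @param rise_min Minimum secondary rise after a plateau-phase local minimum
#'   to count as an EAD [mV].
#' @param plateau_floor EADs are only counted while V is above this level
#'   [mV]; reversals below it belong to the resting approach, not the plateau.
#' @param rest_threshold Return below this voltage counts as repolarization
#'   to rest [mV].
#' @param window_rest If V never falls below `rest_threshold` within this
#'   window after the last stimulus, the AP is oscillatory [ms].
#' @param blank_after_upstroke Reversals within this window after the
#'   upstroke are ignored [ms]: the spike-notch-dome of a healthy human
#'   ventricular AP is an early reversal that is not an EAD.
#' @return A list of thresholds.
#' @export
classifier_config <- function(rise_min = 1, plateau_floor = -40,
                              rest_threshold = -75, window_rest = 3000,
                              blank_after_upstroke = 100) {
  list(rise_min = rise_min, plateau_floor = plateau_floor,
       rest_threshold = rest_threshold, window_rest = window_rest,
       blank_after_upstroke = blank_after_upstroke)
}

# local minima indices of v, strict on the left, non-strict on the right
local_minima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n]) + 1L
}

#' Classify an action-potential trace
#'
#' Labels a trace `NORMAL`, `EAD` or `OSCILLATORY`.  An EAD is a local
#' minimum of V during the plateau (above `plateau_floor`) followed by a
#' rise of at least `rise_min` mV, occurring after the upstroke and before
#' the first return below `rest_threshold`.  A trace that never returns
#' below `rest_threshold` within `window_rest` after the last stimulus is
#' `OSCILLATORY` (non-repolarization dominates any EAD count).
#'
#' @param tr An `ap_trace` (simulated or synthetic).
#' @param cfg Threshold set from [classifier_config()].
#' @return An `ap_class` object: label, `ead_count`, `returned_to_rest`,
#'   `ead_times` [ms].  Use [tidy()] for a one-row tibble.
#' @export
classify_ap <- function(tr, cfg = classifier_config()) {
  st <- attr(tr, "stim")
  last_on <- if (!is.null(st) && length(st$onsets)) max(st$onsets) else tr$t[1]
  if (max(tr$t) - last_on < cfg$window_rest)
    stop(sprintf("trace covers only %g ms after the last stimulus; %g ms needed",
                 max(tr$t) - last_on, cfg$window_rest), call. = FALSE)
  w <- tr$t >= last_on
  t <- tr$t[w]; V <- tr$V[w]

  up <- which.max(diff(V))                     # upstroke sample
  seg_t <- t[-seq_len(up)]; seg_v <- V[-seq_len(up)]
  below <- which(seg_v < cfg$rest_threshold)
  osc_deadline <- last_on + cfg$window_rest
  returned <- length(below) > 0 && seg_t[below[1]] <= osc_deadline

  if (!returned) {
    return(new_ap_class("OSCILLATORY", 0L, FALSE, numeric(0)))
  }
  end <- below[1]
  pv <- seg_v[seq_len(end)]
  pt <- seg_t[seq_len(end)]
  mins <- local_minima(pv)
  mins <- mins[pv[mins] > cfg$plateau_floor &
               pt[mins] > pt[1] + cfg$blank_after_upstroke]
  ead_times <- numeric(0)
  for (i in mins) {
    if (max(pv[i:end]) - pv[i] >= cfg$rise_min)
      ead_times <- c(ead_times, pt[i])
  }
  n <- length(ead_times)
  new_ap_class(if (n > 0) "EAD" else "NORMAL", n, TRUE, ead_times)
}

new_ap_class <- function(label, ead_count, returned, ead_times) {
  structure(list(label = label, ead_count = as.integer(ead_count),
                 returned_to_rest = returned, ead_times = ead_times),
            class = "ap_class")
}

#' @export
print.ap_class <- function(x, ...) {
  cat(sprintf("AP class: %s (%d EAD%s, %srepolarized)\n", x$label,
              x$ead_count, if (x$ead_count == 1) "" else "s",
              if (x$returned_to_rest) "" else "not "))
  invisible(x)
}

#' @export
tidy.ap_class <- function(x, ...) {
  tibble::tibble(label = x$label, ead_count = x$ead_count,
                 returned_to_rest = x$returned_to_rest,
                 ead_times = list(x$ead_times))
}

#' Current balance at each EAD onset
#'
#' For every detected EAD, reports each membrane current at the onset (the
#' local minimum of V, i.e. the dV/dt zero crossing that starts the
#' secondary depolarization) and whether the L-type Ca current is the
#' largest inward term there.
#'
#' @param tr An `ap_trace` simulated with `record_currents = TRUE`.
#' @param cfg Classifier thresholds (see [classifier_config()]).
#' @return A tibble with one row per EAD: `ead`, `t_onset`, one column per
#'   current [pA/pF], and `ical_dominant_inward`.  Zero rows when the trace
#'   has no EADs.
#' @export
detect_ead_drivers <- function(tr, cfg = classifier_config()) {
  if (!"I_CaL" %in% names(tr))
    stop("trace was not recorded with currents; rerun simulate_ap(record_currents = TRUE)",
         call. = FALSE)
  cl <- classify_ap(tr, cfg)
  cur_names <- c("I_Na", "I_K1", "I_to", "I_Kr", "I_Ks", "I_CaL", "I_NaCa",
                 "I_NaK", "I_pCa", "I_pK", "I_bCa", "I_bNa")
  if (cl$ead_count == 0)
    return(tibble::tibble(ead = integer(0), t_onset = numeric(0)))
  rows <- lapply(seq_along(cl$ead_times), function(k) {
    i <- which.min(abs(tr$t - cl$ead_times[k]))
    cur <- as.numeric(tr[i, cur_names])
    names(cur) <- cur_names
    inward <- cur[cur < 0]
    dom <- length(inward) > 0 && names(which.min(inward)) == "I_CaL"
    dplyr::bind_cols(tibble::tibble(ead = k, t_onset = tr$t[i]),
                     tibble::as_tibble(as.list(cur)),
                     tibble::tibble(ical_dominant_inward = dom))
  })
  dplyr::bind_rows(rows)
}
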