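#' Two-parameter phase diagram of single-cell AP morphology
#'
#' Sweeps the L-type Ca conductance multiplier against a multiplier of one
#' potassium-side channel (`Ks`, `Kr`) or the Na/Ca exchanger (`NaCa`),
#' classifying one independently simulated AP per grid point.  The sweep is
#' deterministic; a grid point whose simulation fails is labelled `FAILED`
#' and the sweep continues.
#'
#' @param x_mults Ascending G_CaL multipliers (x axis).
#' @param y_channel Which channel the y axis scales: `"Ks"`, `"Kr"` or
#'   `"NaCa"`.
#' @param y_mults Ascending multipliers for that channel (y axis).
#' @param tau_f_scale Passed to [make_params()] (default 0.5).
#' @param cfg Classifier thresholds ([classifier_config()]).
#' @param n_beats,cycle_length Pacing for each simulated AP.
#' @param tail_ms Unstimulated tail per AP (must exceed the classifier's
#'   rest window).
#' @return A `phase_diagram`: tibble with columns `mult_CaL`, `mult_y`,
#'   `label`, `ead_count`, `returned_to_rest`, plus sweep metadata in
#'   attributes.
#' @examples
#' \donttest{
#' pd <- sweep_phase_diagram(c(1, 4, 8), "Ks", c(0.2, 1))
#' dplyr::count(pd, label)
#' }
#' @export
sweep_phase_diagram <- function(x_mults, y_channel = c("Ks", "Kr", "NaCa"),
                                y_mults, tau_f_scale = 0.5,
                                cfg = classifier_config(),
                                n_beats = 1, cycle_length = 1000,
                                tail_ms = 5000) {
  y_channel <- match.arg(y_channel)
  if (!length(x_mults) || !length(y_mults))
    stop("multiplier lists must be non-empty", call. = FALSE)
  if (is.unsorted(x_mults) || is.unsorted(y_mults))
    stop("multiplier lists must be sorted ascending", call. = FALSE)
  grid <- tidyr::expand_grid(mult_CaL = x_mults, mult_y = y_mults)
  res <- purrr::pmap(grid, function(mult_CaL, mult_y) {
    args <- list(mult_CaL = mult_CaL, tau_f_scale = tau_f_scale)
    args[[paste0("mult_", y_channel)]] <- mult_y
    tryCatch({
      p <- do.call(make_params, args)
      tr <- simulate_ap(p, n_beats = n_beats, cycle_length = cycle_length,
                        tail_ms = tail_ms)
      cl <- classify_ap(tr, cfg)
      tibble::tibble(label = cl$label, ead_count = cl$ead_count,
                     returned_to_rest = cl$returned_to_rest)
    }, error = function(e) {
      warning(sprintf("sweep cell (CaL %g, %s %g) failed: %s",
                      mult_CaL, y_channel, mult_y, conditionMessage(e)),
              call. = FALSE)
      tibble::tibble(label = "FAILED", ead_count = NA_integer_,
                     returned_to_rest = NA)
    })
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  structure(out, class = unique(c("phase_diagram", class(out))),
            y_channel = y_channel, tau_f_scale = tau_f_scale)
}

#' Check the monotone regime ordering along each sweep row
#'
#' Along increasing G_CaL at fixed y, the regime sequence should only ever
#' step forward through NORMAL -> EAD -> OSCILLATORY (reduced repolarization
#' reserve never restores a normal AP).  Violations are reported, not
#' silently accepted.
#'
#' @param pd A `phase_diagram`.
#' @return Tibble of violations (zero rows when the ordering holds).
#' @export
check_regime_ordering <- function(pd) {
  stopifnot(inherits(pd, "phase_diagram"))
  rank <- c(NORMAL = 1, EAD = 2, OSCILLATORY = 3)
  pd |>
    dplyr::filter(label %in% names(rank)) |>
    dplyr::group_by(mult_y) |>
    dplyr::arrange(mult_CaL, .by_group = TRUE) |>
    dplyr::mutate(r = rank[label], drop = r < cummax(r)) |>
    dplyr::ungroup() |>
    dplyr::filter(drop) |>
    dplyr::select(mult_CaL, mult_y, label)
}

#' @export
print.phase_diagram <- function(x, ...) {
  if (all(c("mult_CaL", "mult_y", "label") %in% names(x)))
    cat(sprintf("AP phase diagram: G_CaL x %s multipliers, %d points\n",
                attr(x, "y_channel"), nrow(x)))
  NextMethod()
}

#' @rdname autoplot.phase_diagram
#' @export
plot_phase_diagram <- function(object, ...) autoplot.phase_diagram(object, ...)

#' Plot a phase diagram of AP classes
#'
#' @param object A `phase_diagram`.
#' @param ... Unused.
#' @return A ggplot tile plot of the classified grid.
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(mult_CaL), factor(mult_y),
                               fill = label)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::labs(x = "G_CaL multiplier",
                  y = paste0("G_", attr(object, "y_channel"), " multiplier"),
                  fill = "AP class") +
    ggplot2::theme_minimal()
}
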