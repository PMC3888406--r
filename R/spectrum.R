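#' Averaged temporal power spectrum of a voltage movie
#'
#' Computes, at `n_points` nodes evenly distributed over the domain, the
#' mean-removed periodogram of each node's voltage time series and sums them,
#' the standard characterization of fibrillatory activity by its dominant
#' temporal frequencies.  No taper is applied by default.
#'
#' @param fs A `frame_series`.
#' @param n_points Number of sample nodes (clipped to the grid size); nodes
#'   are taken on an even sublattice.
#' @param t_min Discard frames before this time [ms] (transient removal).
#' @param require_resolution Error if the usable record is too short to
#'   resolve this bandwidth [Hz]; `NULL` disables the check.
#' @param offset Sublattice starting offset in nodes (stationarity checks).
#' @param window Optional taper function (e.g. [signal::hanning]-like)
#'   mapping a length to weights; `NULL` (default) applies none.
#' @param peak_factor A frequency is reported as a peak if it is a local
#'   maximum exceeding `peak_factor` times the median spectral power.
#' @return A `power_spectrum`: tibble with `freq` [Hz] and `power`, with the
#'   detected peaks (sorted by power) and sampling metadata as attributes.
#' @export
mean_power_spectrum <- function(fs, n_points = 10000, t_min = 0,
                                require_resolution = 0.25, offset = 0,
                                window = NULL, peak_factor = 5) {
  stopifnot(inherits(fs, "frame_series"))
  keep <- fs$times >= t_min
  tt <- fs$times[keep]
  nt <- length(tt)
  dt_s <- if (nt > 1) tt[2] - tt[1] else stop("not enough frames", call. = FALSE)
  span <- tt[nt] - tt[1]
  if (!is.null(require_resolution) && 1000 / span > require_resolution)
    stop(sprintf("record of %.0f ms resolves only %.3g Hz; %.3g Hz required",
                 span, 1000 / span, require_resolution), call. = FALSE)
  d <- dim(fs$V)
  nx <- d[1]; ny <- d[2]
  stride <- max(1L, floor(sqrt(nx * ny / n_points)))
  xs <- seq(1 + offset %% stride, nx, by = stride)
  ys <- seq(1 + offset %% stride, ny, by = stride)
  V <- fs$V[xs, ys, keep, drop = FALSE]
  m <- matrix(V, nrow = length(xs) * length(ys), ncol = nt)
  m <- m - rowMeans(m)
  if (!is.null(window)) m <- sweep(m, 2, window(nt), `*`)
  ft <- stats::mvfft(t(m))
  pow <- rowSums(Mod(ft)^2)
  nf <- floor(nt / 2)
  freq <- (seq_len(nf) - 1) / (nt * dt_s / 1000)   # Hz
  pow <- pow[seq_len(nf)]
  new_power_spectrum(freq, pow, n_points = length(xs) * length(ys),
                     dt_sample = dt_s, peak_factor = peak_factor)
}

#' Power spectrum of a single voltage trace
#'
#' Same mean-removed periodogram as [mean_power_spectrum()] for one series,
#' e.g. a single-cell recording in the oscillatory regime.
#'
#' @param tr An `ap_trace` (or any tibble with `t` [ms] and `V`).
#' @param t_min Discard samples before this time [ms].
#' @param peak_factor See [mean_power_spectrum()].
#' @return A `power_spectrum`.
#' @export
trace_power_spectrum <- function(tr, t_min = 0, peak_factor = 5) {
  keep <- tr$t >= t_min
  t <- tr$t[keep]; v <- tr$V[keep]
  dt_s <- t[2] - t[1]
  v <- v - mean(v)
  n <- length(v)
  pow <- Mod(stats::fft(v))^2
  nf <- floor(n / 2)
  freq <- (seq_len(nf) - 1) / (n * dt_s / 1000)
  new_power_spectrum(freq, pow[seq_len(nf)], n_points = 1, dt_sample = dt_s,
                     peak_factor = peak_factor)
}

new_power_spectrum <- function(freq, power, n_points, dt_sample, peak_factor) {
  sp <- tibble::tibble(freq = freq, power = power)
  pk <- find_spectral_peaks(freq, power, peak_factor)
  structure(sp, class = unique(c("power_spectrum", class(sp))),
            peaks = pk, n_points = n_points, dt_sample = dt_sample,
            df = if (length(freq) > 1) freq[2] - freq[1] else NA_real_)
}

find_spectral_peaks <- function(freq, power, peak_factor) {
  n <- length(power)
  if (n < 4) return(tibble::tibble(freq = numeric(0), power = numeric(0)))
  pos <- freq > 0
  thr <- peak_factor * median(power[pos])
  idx <- which(power[2:(n - 1)] > power[1:(n - 2)] &
               power[2:(n - 1)] >= power[3:n] &
               power[2:(n - 1)] > thr) + 1L
  idx <- idx[freq[idx] > 0]
  ord <- order(power[idx], decreasing = TRUE)
  tibble::tibble(freq = freq[idx][ord], power = power[idx][ord])
}

#' Peaks / dominant frequency of a power spectrum
#'
#' @param sp A `power_spectrum`.
#' @return `spectral_peaks()`: tibble of peaks sorted by power;
#'   `dominant_frequency()`: the strongest peak's frequency [Hz] (NA when no
#'   peak clears the threshold).
#' @export
spectral_peaks <- function(sp) attr(sp, "peaks")

#' @rdname spectral_peaks
#' @export
dominant_frequency <- function(sp) {
  pk <- attr(sp, "peaks")
  if (nrow(pk) == 0) NA_real_ else pk$freq[1]
}

#' @export
print.power_spectrum <- function(x, ...) {
  pk <- attr(x, "peaks")
  cat(sprintf("power spectrum: df = %.3g Hz, %d sample point(s), %d peak(s)\n",
              attr(x, "df"), attr(x, "n_points"), nrow(pk)))
  if (nrow(pk)) print(utils::head(pk, 5))
  invisible(x)
}

#' Plot a power spectrum
#'
#' @param object A `power_spectrum`.
#' @param fmax Upper frequency limit for the plot [Hz].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_spectrum <- function(object, fmax = 15, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), freq > 0, freq <= fmax)
  ggplot2::ggplot(df, ggplot2::aes(freq, power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency [Hz]", y = "summed power") +
    ggplot2::theme_minimal()
}
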