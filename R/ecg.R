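#' Pseudo-ECG of a tissue run
#'
#' Far-field potential proxy: for each frame,
#' \eqn{ECG(t) = \sum_{nodes} \nabla V \cdot \nabla(1/r)\, dA}, with
#' \eqn{\nabla V} the in-plane central-difference voltage gradient
#' (one-sided at the domain edges), \eqn{r} the node-to-electrode distance
#' and \eqn{dA = dx^2}.  The default electrode sits over the domain centre
#' at a perpendicular distance of 2.5 mm.
#'
#' @param fs A `frame_series`.
#' @param electrode Numeric length-3 `(x, y, z)` in mm; `NULL` for the
#'   default centre electrode at height 2.5 mm.
#' @return An `ecg_trace` tibble with columns `t` [ms] and `ecg`
#'   (dimensionless), the electrode position as an attribute.
#' @export
pseudo_ecg <- function(fs, electrode = NULL) {
  stopifnot(inherits(fs, "frame_series"))
  d <- dim(fs$V); nx <- d[1]; ny <- d[2]; nf <- d[3]
  dx <- fs$dx
  xs <- (seq_len(nx) - 1) * dx
  ys <- (seq_len(ny) - 1) * dx
  if (is.null(electrode))
    electrode <- c(mean(range(xs)), mean(range(ys)), 2.5)
  ex <- electrode[1]; ey <- electrode[2]; ez <- electrode[3]
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  r2 <- (X - ex)^2 + (Y - ey)^2 + ez^2
  if (any(r2 < (dx * 1e-9)^2))
    stop("electrode coincides with a tissue node; pseudo-ECG is singular",
         call. = FALSE)
  r3 <- r2^1.5
  wx <- (ex - X) / r3          # d(1/r)/dx at the node
  wy <- (ey - Y) / r3
  ecg <- vapply(seq_len(nf), function(k) {
    v <- fs$V[, , k]
    gx <- grad_central(v, dx, along = 1)
    gy <- grad_central(v, dx, along = 2)
    sum(gx * wx + gy * wy) * dx^2
  }, numeric(1))
  structure(tibble::tibble(t = fs$times, ecg = ecg),
            class = unique(c("ecg_trace", class(tibble::tibble()))),
            electrode = electrode)
}

# central differences in the interior, one-sided at the edges
grad_central <- function(v, dx, along) {
  if (along == 2) return(t(grad_central(t(v), dx, along = 1)))
  n <- nrow(v)
  g <- v
  if (n == 1) return(g * 0)
  g[2:(n - 1), ] <- (v[3:n, , drop = FALSE] - v[1:(n - 2), , drop = FALSE]) / (2 * dx)
  g[1, ] <- (v[2, ] - v[1, ]) / dx
  g[n, ] <- (v[n, ] - v[n - 1, ]) / dx
  g
}

#' Plot a pseudo-ECG
#'
#' @param object An `ecg_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecg_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(t, ecg)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [ms]", y = "pseudo-ECG [a.u.]") +
    ggplot2::theme_minimal()
}
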