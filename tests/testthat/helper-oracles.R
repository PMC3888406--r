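# Independent oracles, deliberately naive implementations.

# 5-point Laplacian via explicit ghost nodes: the domain is padded by
# mirroring across each boundary/barrier edge (zero flux), then the plain
# stencil is applied.
oracle_laplacian <- function(field, dx, conn_r = NULL, conn_u = NULL) {
  nx <- nrow(field); ny <- ncol(field)
  if (is.null(conn_r)) conn_r <- matrix(TRUE, nx, ny)
  if (is.null(conn_u)) conn_u <- matrix(TRUE, nx, ny)
  out <- matrix(0, nx, ny)
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    c <- field[x, y]
    e <- if (x < nx && conn_r[x, y]) field[x + 1, y] else c   # ghost = mirror
    w <- if (x > 1 && conn_r[x - 1, y]) field[x - 1, y] else c
    n <- if (y < ny && conn_u[x, y]) field[x, y + 1] else c
    s <- if (y > 1 && conn_u[x, y - 1]) field[x, y - 1] else c
    out[x, y] <- (e + w + n + s - 4 * c) / dx^2
  }
  out
}

# pseudo-ECG by direct double loop over nodes for a single frame
oracle_ecg_frame <- function(v, dx, electrode) {
  nx <- nrow(v); ny <- ncol(v)
  total <- 0
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    px <- (x - 1) * dx; py <- (y - 1) * dx
    gx <- if (x == 1) (v[2, y] - v[1, y]) / dx
          else if (x == nx) (v[nx, y] - v[nx - 1, y]) / dx
          else (v[x + 1, y] - v[x - 1, y]) / (2 * dx)
    gy <- if (y == 1) (v[x, 2] - v[x, 1]) / dx
          else if (y == ny) (v[x, ny] - v[x, ny - 1]) / dx
          else (v[x, y + 1] - v[x, y - 1]) / (2 * dx)
    r3 <- ((px - electrode[1])^2 + (py - electrode[2])^2 + electrode[3]^2)^1.5
    wx <- (electrode[1] - px) / r3
    wy <- (electrode[2] - py) / r3
    total <- total + (gx * wx + gy * wy) * dx^2
  }
  total
}

# algebraic rest-state solver: V* with all gates at steady state and the
# published resting concentrations, such that I_ion(V*) = 0
oracle_rest_voltage <- function(p) {
  s0 <- as.numeric(cell_state_rest())
  iion_of_v <- function(V) {
    gr <- eadwave:::cpp_gate_rates(V, p$tau_f_scale)
    s <- s0
    s[1] <- V
    s[c(2:7, 9:13)] <- gr[c("m_inf", "h_inf", "j_inf", "d_inf", "f_inf",
                            "f2_inf", "r_inf", "s_inf", "xr1_inf", "xr2_inf",
                            "xs_inf")]
    # fCass_inf at resting subspace Ca
    q <- (s0[17] / 0.05)^2
    s[8] <- 0.6 / (1 + q) + 0.4
    unname(eadwave:::cpp_currents(s, p)["I_ion"])
  }
  uniroot(iion_of_v, c(-95, -75), tol = 1e-10)$root
}

# wrap a plain (t, V) pair as an ap_trace with a given stimulus schedule
wrap_trace <- function(t, V, onsets = 10) {
  eadwave:::new_ap_trace(tibble::tibble(t = t, V = V),
                         stim = list(onsets = onsets, amp = 20, dur = 2),
                         dt = t[2] - t[1])
}
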