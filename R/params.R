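#' Build a modified TP06 endocardial parameter set
#'
#' Returns the full constant set of the ten Tusscher--Panfilov 2006 (TP06)
#' endocardial human ventricular cell model with the EAD-promoting
#' modifications used throughout this package: the baseline L-type Ca
#' conductance is twice the published TP06 value and the voltage inactivation
#' time constant \eqn{\tau_f(V)} is multiplied by `tau_f_scale` (default 0.5,
#' i.e. halved).  The four conductances that set the repolarization reserve
#' are exposed as dimensionless multipliers on their baselines:
#' \eqn{G_{CaL} = } `mult_CaL` \eqn{\times 2 \times 3.980\times10^{-5}}
#' mm\eqn{^3 \mu}F\eqn{^{-1}} ms\eqn{^{-1}},
#' \eqn{G_{Ks} = } `mult_Ks` \eqn{\times 0.3923027} nS/pF,
#' \eqn{G_{Kr} = } `mult_Kr` \eqn{\times 0.1532432} nS/pF,
#' \eqn{k_{NaCa} = } `mult_NaCa` \eqn{\times 1000} pA/pF.
#'
#' @param mult_CaL,mult_Ks,mult_Kr,mult_NaCa Non-negative dimensionless
#'   multipliers on the baseline maximal conductances.
#' @param tau_f_scale Positive scale applied uniformly to the TP06
#'   \eqn{\tau_f(V)} curve.  The default 0.5 is the EAD-promoting setting;
#'   use 1 to recover the published kinetics.
#' @return A named list of class `tp06_params` holding every model constant
#'   under its published TP06 name, plus the multipliers.
#' @examples
#' p <- make_params()                  # baseline (no-EAD) regime
#' p_ead <- make_params(mult_CaL = 4, mult_Ks = 0.2)
#' @export
make_params <- function(mult_CaL = 1, mult_Ks = 1, mult_Kr = 1,
                        mult_NaCa = 1, tau_f_scale = 0.5) {
  for (m in c(mult_CaL, mult_Ks, mult_Kr, mult_NaCa))
    if (!is.finite(m) || m < 0)
      stop("conductance multipliers must be finite and >= 0", call. = FALSE)
  if (!is.finite(tau_f_scale) || tau_f_scale <= 0)
    stop("tau_f_scale must be finite and > 0", call. = FALSE)

  p <- list(
    # exposed scaling knobs
    mult_CaL = mult_CaL, mult_Ks = mult_Ks, mult_Kr = mult_Kr,
    mult_NaCa = mult_NaCa, tau_f_scale = tau_f_scale,
    # baselines of the altered channels (G_CaL already includes the factor-2
    # increase relative to published TP06)
    G_CaL_base = 2 * 0.00003980,  # mm^3 uF^-1 ms^-1
    G_Ks_base  = 0.3923027,       # nS/pF (endocardial)
    G_Kr_base  = 0.1532432,       # nS/pF
    k_NaCa_base = 1000,           # pA/pF
    # physical constants
    R = 8314.472, T = 310, F = 96485.3415,
    # extracellular milieu [mM]
    K_o = 5.4, Na_o = 140, Ca_o = 2,
    # cell geometry and capacitance
    C_m = 0.185,                  # uF/cm^2 (flux-conversion capacitance)
    V_c = 0.016404, V_sr = 0.001094, V_ss = 0.00005468,  # um^3 (x 1e-9)
    # fixed maximal conductances (endocardial)
    G_Na = 14.838, G_K1 = 5.405, G_to = 0.073,
    G_pCa = 0.1238, K_pCa = 0.0005, G_pK = 0.0146,
    G_bNa = 0.00029, G_bCa = 0.000592,
    # Na/K pump and Na/Ca exchanger
    P_NaK = 2.724, K_mK = 1, K_mNa = 40,
    K_mNai = 87.5, K_mCa = 1.38, k_sat = 0.1,
    gamma_NaCa = 0.35, alpha_NaCa = 2.5,
    p_KNa = 0.03,
    # SR calcium handling
    V_maxup = 0.006375, K_up = 0.00025,
    V_rel = 0.102, k1_prime = 0.15, k2_prime = 0.045, k3 = 0.06, k4 = 0.005,
    EC = 1.5, max_sr = 2.5, min_sr = 1, V_leak = 0.00036, V_xfer = 0.0038,
    # cytosolic / SR / subspace buffering
    Buf_c = 0.2, K_bufc = 0.001,
    Buf_sr = 10, K_bufsr = 0.3,
    Buf_ss = 0.4, K_bufss = 0.00025
  )
  structure(p, class = "tp06_params")
}

#' @export
print.tp06_params <- function(x, ...) {
  cat("Modified TP06 endocardial parameter set\n")
  cat(sprintf("  multipliers: CaL %.3g, Ks %.3g, Kr %.3g, NaCa %.3g; tau_f scale %.3g\n",
              x$mult_CaL, x$mult_Ks, x$mult_Kr, x$mult_NaCa, x$tau_f_scale))
  cat(sprintf("  effective G_CaL %.4g mm^3/(uF ms), G_Ks %.4g nS/pF, G_Kr %.4g nS/pF, k_NaCa %.4g pA/pF\n",
              x$G_CaL_base * x$mult_CaL, x$G_Ks_base * x$mult_Ks,
              x$G_Kr_base * x$mult_Kr, x$k_NaCa_base * x$mult_NaCa))
  invisible(x)
}

#' Effective conductances after applying the multipliers
#'
#' @param p A `tp06_params` object.
#' @return A tibble with one row per scaled channel: baseline, multiplier,
#'   effective value.
#' @export
effective_conductances <- function(p) {
  stopifnot(inherits(p, "tp06_params"))
  tibble::tibble(
    channel   = c("G_CaL", "G_Ks", "G_Kr", "k_NaCa"),
    baseline  = c(p$G_CaL_base, p$G_Ks_base, p$G_Kr_base, p$k_NaCa_base),
    multiplier = c(p$mult_CaL, p$mult_Ks, p$mult_Kr, p$mult_NaCa),
    effective = baseline * multiplier
  )
}

#' Serialize / deserialize parameter sets
#'
#' Parameter sets round-trip through YAML (or JSON) using the published TP06
#' constant names, so a run is fully reconstructable from its config snapshot.
#'
#' @param p A `tp06_params` object.
#' @param path File path; extension `.json` selects JSON, anything else YAML.
#' @return `write_params` returns `path` invisibly; `read_params` the
#'   reconstructed `tp06_params`.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "tp06_params"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(p), path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  ref <- make_params()
  missing <- setdiff(names(unclass(ref)), names(raw))
  if (length(missing))
    stop("parameter file lacks constants: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(raw[names(unclass(ref))], class = "tp06_params")
}
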