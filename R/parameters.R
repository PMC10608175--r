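#' @keywords internal
"_PACKAGE"

# Internal unit system: energies in kB*T at T = 300 K, lengths in nm.
# The conversion constant is fixed so that 0.1 mN/m ~ 0.024 kB*T/nm^2,
# which reproduces the printed spontaneous stretching 8e-4 after rounding.
.kBT_J <- 4.141e-21   # J at T = 300 K

#' Convert a lateral tension from mN/m to kB*T/nm^2
#'
#' @param sigma_mN_per_m tension in mN/m.
#' @param temperature absolute temperature in K; the energy unit is kB*T at
#'   300 K regardless, `temperature` rescales the Boltzmann factor.
#' @return tension in kB*T/nm^2.
#' @export
sigma_to_kBT_per_nm2 <- function(sigma_mN_per_m, temperature = 300) {
  # 1 mN/m = 1e-3 J/m^2 = 1e-21 J/nm^2
  kBT <- .kBT_J * temperature / 300
  sigma_mN_per_m * 1e-21 / kBT
}

#' Convert a lateral tension from kB*T/nm^2 to mN/m
#' @inheritParams sigma_to_kBT_per_nm2
#' @param sigma_kBT_per_nm2 tension in kB*T/nm^2.
#' @return tension in mN/m.
#' @export
sigma_to_mN_per_m <- function(sigma_kBT_per_nm2, temperature = 300) {
  kBT <- .kBT_J * temperature / 300
  sigma_kBT_per_nm2 * kBT / 1e-21
}

#' Higher-order elastic moduli from the tilt modulus and monolayer thickness
#'
#' Closed-form theoretical estimates for the splay-tilt cross modulus
#' \eqn{k_c = -k_t h^2/6}, the splay-gradient modulus
#' \eqn{k_{gr} = k_t h^4/20}, the tilt-stretch-gradient modulus
#' \eqn{B = -k_t h/2} and the stretch-gradient-splay modulus
#' \eqn{C = k_t h^3/8}.
#'
#' @param kt tilt modulus, kB*T/nm^2 (> 0).
#' @param h monolayer hydrophobic thickness, nm (>= 0).
#' @return named list with `kc` (kB*T), `kgr` (kB*T nm^2), `B` (kB*T/nm)
#'   and `C` (kB*T nm).
#' @examples
#' derive_higher_moduli(kt = 12, h = 1.3)
#' @export
derive_higher_moduli <- function(kt, h) {
  if (!is.numeric(kt) || length(kt) != 1 || !is.finite(kt) || kt <= 0)
    stop("parameter validation: 'kt' must be a single positive number", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h < 0)
    stop("parameter validation: 'h' must be a single non-negative number", call. = FALSE)
  list(
    kc  = -kt * h^2 / 6,
    kgr =  kt * h^4 / 20,
    B   = -kt * h / 2,
    C   =  kt * h^3 / 8
  )
}

#' Spontaneous stretching-compression from tension and stretching modulus
#'
#' \eqn{\alpha_0 = \sigma / k_A}. A tension given in mN/m is converted to
#' kB*T/nm^2 first.
#'
#' @param sigma lateral tension per monolayer; kB*T/nm^2 unless
#'   `unit = "mN/m"`.
#' @param kA stretching-compression modulus, kB*T/nm^2 (> 0).
#' @param unit `"kBT/nm2"` (default) or `"mN/m"`.
#' @param temperature absolute temperature in K, used for the unit conversion.
#' @return dimensionless spontaneous stretching.
#' @examples
#' spontaneous_stretching(0.1, kA = 30, unit = "mN/m")  # ~8e-4
#' @export
spontaneous_stretching <- function(sigma, kA, unit = c("kBT/nm2", "mN/m"),
                                   temperature = 300) {
  unit <- match.arg(unit)
  if (!is.numeric(kA) || length(kA) != 1 || !is.finite(kA) || kA <= 0)
    stop("parameter validation: 'kA' must be a single positive number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma < 0)
    stop("parameter validation: 'sigma' must be a single non-negative number", call. = FALSE)
  if (unit == "mN/m") sigma <- sigma_to_kBT_per_nm2(sigma, temperature)
  sigma / kA
}

#' Elastic parameters of one monolayer phase
#'
#' Bundles the per-monolayer elastic constants of one phase (liquid-ordered or
#' liquid-disordered). Higher-order moduli omitted from the call are filled in
#' by [derive_higher_moduli()]; `alpha0` is derived from the system tension
#' when the phase is assembled into a parameter set.
#'
#' @param phase `"ordered"` or `"disordered"`.
#' @param h monolayer hydrophobic thickness, nm.
#' @param km monolayer bending modulus, kB*T.
#' @param kt tilt modulus, kB*T/nm^2.
#' @param kA stretching-compression modulus, kB*T/nm^2.
#' @param J0 monolayer spontaneous curvature, 1/nm.
#' @param kc,kgr,B,C higher-order moduli; `NULL` to derive from `kt` and `h`.
#' @param alpha0 spontaneous stretching-compression (dimensionless).
#' @return object of class `phase_params`.
#' @export
phase_parameters <- function(phase = c("ordered", "disordered"),
                             h, km, kt, kA, J0 = 0,
                             kc = NULL, kgr = NULL, B = NULL, C = NULL,
                             alpha0 = 0) {
  phase <- match.arg(phase)
  for (nm_ in c("h", "km", "kt", "kA")) {
    v <- get(nm_)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("parameter validation: '%s' must be a single positive number", nm_),
           call. = FALSE)
  }
  derived <- derive_higher_moduli(kt, h)
  p <- list(
    phase = phase, h = h, km = km, kt = kt, kA = kA, J0 = J0,
    kc  = if (is.null(kc))  derived$kc  else kc,
    kgr = if (is.null(kgr)) derived$kgr else kgr,
    B   = if (is.null(B))   derived$B   else B,
    C   = if (is.null(C))   derived$C   else C,
    alpha0 = alpha0
  )
  if (p$kgr < 0)
    stop("parameter validation: 'kgr' must be non-negative", call. = FALSE)
  class(p) <- "phase_params"
  p
}

#' @export
print.phase_params <- function(x, ...) {
  cat(sprintf("<phase_params> %s phase\n", x$phase))
  cat(sprintf("  h = %.3g nm, km = %.3g kBT, kt = %.3g kBT/nm^2, kA = %.3g kBT/nm^2\n",
              x$h, x$km, x$kt, x$kA))
  cat(sprintf("  kc = %.3g kBT, kgr = %.3g kBT nm^2, B = %.3g kBT/nm, C = %.3g kBT nm\n",
              x$kc, x$kgr, x$B, x$C))
  cat(sprintf("  J0 = %.3g 1/nm, alpha0 = %.3g\n", x$J0, x$alpha0))
  invisible(x)
}

#' System-level constants
#'
#' @param sigma_mN_per_m lateral tension per monolayer, mN/m.
#' @param misregistration_density energy per unit misregistered area where an
#'   ordered monolayer faces a disordered one across the midplane, kB*T/nm^2.
#' @param temperature absolute temperature, K.
#' @return object of class `system_constants` with the tension also stored in
#'   kB*T/nm^2.
#' @export
system_constants <- function(sigma_mN_per_m = 0.1,
                             misregistration_density = 0.016,
                             temperature = 300) {
  if (sigma_mN_per_m < 0 || misregistration_density < 0)
    stop("parameter validation: tension and misregistration density must be >= 0",
         call. = FALSE)
  s <- list(
    sigma_mN_per_m = sigma_mN_per_m,
    sigma = sigma_to_kBT_per_nm2(sigma_mN_per_m, temperature),
    misregistration_density = misregistration_density,
    temperature = temperature
  )
  class(s) <- "system_constants"
  s
}

#' Geometric descriptors of an adsorbed amphipathic peptide
#'
#' @param delta_L alpha-helix diameter, nm.
#' @param Lp alpha-helix length, nm (used only by the absolute-energy
#'   estimates, not by the 1D solver).
#' @return object of class `peptide_params`.
#' @export
peptide_parameters <- function(delta_L = 1.3, Lp = 3.5) {
  if (delta_L <= 0 || Lp <= 0)
    stop("parameter validation: 'delta_L' and 'Lp' must be positive", call. = FALSE)
  p <- list(delta_L = delta_L, Lp = Lp)
  class(p) <- "peptide_params"
  p
}

#' Default parameter set
#'
#' The full default parameterization: hydrophobic thicknesses 1.8 nm (Lo) and
#' 1.3 nm (Ld); bending moduli 20 and 10 kB*T; tilt modulus 12 kB*T/nm^2 and
#' stretching modulus 30 kB*T/nm^2 in both phases; zero spontaneous
#' curvature; lateral tension 0.1 mN/m per monolayer; misregistration penalty
#' 0.016 kB*T/nm^2; peptide helix diameter 1.3 nm and length 3.5 nm. The
#' higher-order moduli and the spontaneous stretching are derived.
#'
#' @return object of class `parameter_set`: a list with `ordered`,
#'   `disordered` (`phase_params`), `system` (`system_constants`) and
#'   `peptide` (`peptide_params`).
#' @examples
#' p <- default_parameter_set()
#' p$ordered$kc    # -6.5 kBT (approximately)
#' @export
default_parameter_set <- function() {
  sys <- system_constants()
  a0 <- spontaneous_stretching(sys$sigma, kA = 30)
  ps <- list(
    ordered = phase_parameters("ordered", h = 1.8, km = 20, kt = 12, kA = 30,
                               J0 = 0, alpha0 = a0),
    disordered = phase_parameters("disordered", h = 1.3, km = 10, kt = 12, kA = 30,
                                  J0 = 0, alpha0 = a0),
    system = sys,
    peptide = peptide_parameters()
  )
  class(ps) <- "parameter_set"
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  print(x$ordered); print(x$disordered)
  cat(sprintf("  sigma = %.3g mN/m (= %.4g kBT/nm^2), misregistration = %.3g kBT/nm^2\n",
              x$system$sigma_mN_per_m, x$system$sigma, x$system$misregistration_density))
  cat(sprintf("  peptide: delta_L = %.3g nm, Lp = %.3g nm\n",
              x$peptide$delta_L, x$peptide$Lp))
  invisible(x)
}
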