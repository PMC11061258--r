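# Physical constants and residue-level tables shared across the package.
# Internal energies are kJ/mol, lengths nm, times ns, angles degrees at the
# user surface (radians internally).

#' Boltzmann constant in kJ/(mol K)
#'
#' Gas constant expressed per mole, the conventional energy scale for
#' coarse-grained membrane simulations.
#'
#' @format A length-one numeric, 0.0083145 kJ/(mol K).
#' @export
kB_kJ_mol_K <- 0.0083145

#' Standard-state volume per molecule at 1 M, in nm^3
#'
#' Volume available to one solute molecule at the 1 mol/L standard
#' concentration (1660 A^3 = 1.660 nm^3), used as the default reference
#' volume V0 when converting partition coefficients into standard-state
#' adsorption free energies.
#'
#' @seealso [standard_state_volume()] for the value recomputed from
#'   Avogadro's number.
#' @format A length-one numeric, 1.660 nm^3.
#' @export
V0_nm3 <- 1.660

#' Recompute the 1 M standard-state volume from Avogadro's number
#'
#' Self-check companion of [V0_nm3]: the volume per molecule at a 1 mol/L
#' concentration is \eqn{1 / (N_A \times 10^3 mol/m^3)}, i.e. about
#' 1660.54 A^3.
#'
#' @param units `"nm3"` (default) or `"A3"`.
#' @return The volume per molecule at 1 M in the requested units.
#' @examples
#' standard_state_volume("A3") # ~1660.5
#' @export
standard_state_volume <- function(units = c("nm3", "A3")) {
  units <- match.arg(units)
  avogadro <- 6.02214076e23 # 1/mol
  v_m3 <- 1e-3 / avogadro   # 1 mol/L = 1e3 mol/m^3
  v_nm3 <- v_m3 * 1e27
  if (units == "A3") v_nm3 * 1e3 else v_nm3
}

#' Fauchere-Pliska residue hydrophobicity scale
#'
#' Per-residue hydrophobic weights (dimensionless, octanol/water transfer
#' scale of Fauchere & Pliska 1983) used to build the hydrophobic dipole
#' moment of a helical peptide. Named by one-letter amino-acid code.
#'
#' @format Named numeric vector of length 20.
#' @export
fauchere_pliska <- c(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
  Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
  L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
  S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22
)

# Residue classification used for composition pie-charts and contact
# fingerprints. Exactly one class per standard residue.
.residue_classes <- c(
  K = "basic", R = "basic", H = "basic",
  D = "acidic", E = "acidic",
  S = "polar", T = "polar", N = "polar", Q = "polar",
  G = "hydrophobic", A = "hydrophobic", V = "hydrophobic",
  L = "hydrophobic", I = "hydrophobic", P = "hydrophobic",
  F = "hydrophobic", M = "hydrophobic", W = "hydrophobic",
  C = "hydrophobic", Y = "hydrophobic"
)

# Formal charge bookkeeping at physiological pH: +1 for K/R, -1 for D/E,
# histidine neutral. Zwitterionic termini contribute +1 and -1 (net zero).
.residue_charges <- c(
  K = 1L, R = 1L, D = -1L, E = -1L
)

#' Residue class labels in canonical order
#' @keywords internal
.class_levels <- c("basic", "acidic", "polar", "hydrophobic")

#' Convert a lateral diffusion coefficient from nm^2/ns to cm^2/s
#'
#' Dimensional chain: 1 nm^2 = 1e-14 cm^2 and 1 ns = 1e-9 s, hence
#' 1 nm^2/ns = 1e-5 cm^2/s.
#'
#' @param d_nm2_ns diffusion coefficient(s) in nm^2/ns.
#' @return The same coefficient(s) in cm^2/s.
#' @export
nm2ns_to_cm2s <- function(d_nm2_ns) d_nm2_ns * 1e-5

#' Convert a lateral diffusion coefficient from cm^2/s to nm^2/ns
#' @param d_cm2_s diffusion coefficient(s) in cm^2/s.
#' @return The same coefficient(s) in nm^2/ns.
#' @export
cm2s_to_nm2ns <- function(d_cm2_s) d_cm2_s * 1e5

# Degrees/radians helpers
.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180
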