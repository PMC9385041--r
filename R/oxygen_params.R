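#' Oxygen transport parameters
#'
#' Physical constants for the Green's function oxygen solver. Defaults follow
#' the standard parameter set of the Green's function literature for brain
#' and mesentery tissue, with the maximum metabolic rate set to the human
#' grey-matter value and the arteriole inlet PO2 at 90 mmHg. Units: oxygen
#' amounts in cm^3 O2, partial pressures in mmHg, lengths in um at the
#' interface (converted internally to cm).
#'
#' @param alpha_b effective oxygen solubility in blood (cm^3 O2 / cm^3 / mmHg).
#' @param alpha_t oxygen solubility in tissue (cm^3 O2 / cm^3 / mmHg).
#' @param D_t oxygen diffusivity in tissue (cm^2/s).
#' @param C_Hb oxygen binding capacity of red blood cells (cm^3 O2 / cm^3 RBC).
#' @param hill_n Hill equation exponent (>= 1).
#' @param p50 PO2 at half-maximal haemoglobin saturation (mmHg).
#' @param M0 maximum (oxygen-saturated) metabolic rate
#'   (cm^3 O2 / cm^3 tissue / s).
#' @param P0 Michaelis constant of oxygen consumption (mmHg).
#' @param inlet_po2 blood PO2 at the arteriole inlet (mmHg).
#' @param hypoxia_threshold tissue PO2 below which a voxel counts as hypoxic
#'   (mmHg).
#' @param voxel_um nominal tissue voxel edge (um); each axis is adjusted to
#'   tile the box exactly.
#' @param max_element_um maximum vessel source element length (um).
#' @param max_iter,tol_po2,relax fixed-point controls: iteration cap,
#'   convergence threshold on the max tissue PO2 change (mmHg), and
#'   under-relaxation factor.
#' @param iv_resistance optional intravascular resistance (mmHg.s/cm^3 O2 per
#'   cm of vessel); 0 disables the blood-to-wall PO2 drop.
#' @return list of class `oxy_params`.
#' @export
oxy_params <- function(alpha_b = 3.1e-5, alpha_t = 3.89e-5, D_t = 2.41e-5,
                       C_Hb = 0.5, hill_n = 3, p50 = 38,
                       M0 = 6.72e-4, P0 = 1, inlet_po2 = 90,
                       hypoxia_threshold = 10, voxel_um = 15,
                       max_element_um = 30, max_iter = 200, tol_po2 = 0.1,
                       relax = 1, iv_resistance = 0) {
  stopifnot(alpha_b > 0, alpha_t > 0, D_t > 0, C_Hb >= 0, hill_n >= 1,
            p50 > 0, M0 >= 0, P0 > 0, inlet_po2 > 0, voxel_um > 0,
            hypoxia_threshold < inlet_po2)
  structure(as.list(environment()), class = "oxy_params")
}

#' Hill haemoglobin saturation
#'
#' `S = P^N / (P50^N + P^N)`; strictly increasing in `P`, `S(P50) = 1/2`.
#'
#' @param p_b blood PO2 (mmHg, >= 0), vectorised.
#' @param n Hill exponent.
#' @param p50 half-saturation PO2 (mmHg).
#' @return saturation in `[0, 1)`.
#' @export
hill_saturation <- function(p_b, n = 3, p50 = 38) {
  if (any(p_b < 0)) stop("blood PO2 must be non-negative")
  p_b^n / (p50^n + p_b^n)
}

#' Blood oxygen content and its inverse
#'
#' Content is the sum of oxygen dissolved in plasma and oxygen bound to
#' haemoglobin: `C_b = alpha_b P + C_Hb H S(P)` (cm^3 O2 / cm^3 blood).
#' Being strictly increasing in P it is inverted by safeguarded Newton
#' iteration.
#'
#' @param p_b blood PO2 (mmHg), vectorised.
#' @param params [oxy_params()].
#' @param haematocrit discharge haematocrit.
#' @return `blood_oxygen_content`: content (cm^3 O2/cm^3);
#'   `content_to_po2`: PO2 (mmHg).
#' @export
blood_oxygen_content <- function(p_b, params = oxy_params(), haematocrit = 0.45) {
  params$alpha_b * p_b +
    params$C_Hb * haematocrit * hill_saturation(p_b, params$hill_n, params$p50)
}

#' @rdname blood_oxygen_content
#' @param content blood oxygen content (cm^3 O2 / cm^3 blood).
#' @export
content_to_po2 <- function(content, params = oxy_params(), haematocrit = 0.45) {
  n <- params$hill_n; p50 <- params$p50
  chb <- params$C_Hb * haematocrit
  fc <- function(p) params$alpha_b * p + chb * p^n / (p50^n + p^n)
  vapply(content, function(cc) {
    if (cc <= 0) return(0)
    hi <- 200
    while (fc(hi) < cc) hi <- hi * 2
    stats::uniroot(function(p) fc(p) - cc, c(0, hi), tol = 1e-12)$root
  }, numeric(1))
}

#' Michaelis-Menten oxygen consumption
#'
#' `M = M0 P / (P + P0)`: increasing in tissue PO2, bounded by `M0`, and equal
#' to `M0/2` at the Michaelis constant `P0`.
#'
#' @param p_t tissue PO2 (mmHg, >= 0), vectorised.
#' @param M0 maximum metabolic rate (cm^3 O2/cm^3/s).
#' @param P0 Michaelis constant (mmHg).
#' @return consumption rate (cm^3 O2/cm^3/s).
#' @export
metabolic_rate <- function(p_t, M0 = 6.72e-4, P0 = 1) {
  if (any(p_t < 0)) stop("tissue PO2 must be non-negative")
  M0 * p_t / (p_t + P0)
}

#' Infinite-domain diffusion kernel
#'
#' The potential at `x` of a unit point oxygen source at `x_star` in an
#' infinite homogeneous tissue: `G = 1 / (4 pi D_t alpha_t |x - x_star|)`,
#' in mmHg per (cm^3 O2/s). Positions are in um.
#'
#' @param x,x_star numeric length-3 positions (um), or matrices with 3 columns.
#' @param D_t tissue diffusivity (cm^2/s).
#' @param alpha_t tissue solubility (cm^3 O2/cm^3/mmHg).
#' @return kernel value(s).
#' @export
greens_kernel <- function(x, x_star, D_t = 2.41e-5, alpha_t = 3.89e-5) {
  x <- matrix(x, ncol = 3); x_star <- matrix(x_star, ncol = 3)
  r_cm <- sqrt(rowSums((x - x_star)^2)) / .UM_PER_CM
  if (any(r_cm == 0)) stop("point-form kernel is singular at zero distance")
  1 / (4 * pi * D_t * alpha_t * r_cm)
}
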