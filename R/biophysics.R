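#' Membrane charging time (Schwan model)
#'
#' RC timescale for building up the induced transmembrane voltage of a
#' spherical vesicle in a DC field, `tau_c = R * C_m * (1/lambda_e + 1/lambda_i)`.
#'
#' @param R vesicle radius (m).
#' @param C_m membrane capacitance per unit area (F/m^2).
#' @param lambda_e,lambda_i external and internal solution conductivities (S/m).
#' @return charging time in seconds.
#' @seealso [transmembrane_voltage()]
#' @export
#' @examples
#' charging_time(10e-6, 0.01, 0.05, 0.05)
charging_time <- function(R, C_m, lambda_e, lambda_i) {
  stopifnot(is.numeric(R), is.numeric(C_m), is.numeric(lambda_e), is.numeric(lambda_i))
  if (any(R <= 0) || any(C_m <= 0) || any(lambda_e <= 0) || any(lambda_i <= 0))
    stop("charging_time: all inputs must be > 0")
  R * C_m * (1 / lambda_e + 1 / lambda_i)
}

#' Induced transmembrane voltage (Schwan model)
#'
#' Pole value of the pulse-induced transmembrane voltage of a spherical
#' vesicle, `Psi_m = 1.5 * R * E * (1 - exp(-t / tau_c))`.
#'
#' @param R vesicle radius (m).
#' @param E applied field strength (V/m).
#' @param t time since pulse onset (s); may be a vector.
#' @param tau_c membrane charging time (s), see [charging_time()].
#' @return transmembrane voltage in volts.
#' @export
#' @examples
#' tc <- charging_time(10e-6, 0.01, 0.05, 0.05)
#' transmembrane_voltage(10e-6, 150e3, 500e-6, tc)
transmembrane_voltage <- function(R, E, t, tau_c) {
  if (any(R <= 0) || any(tau_c <= 0)) stop("transmembrane_voltage: R and tau_c must be > 0")
  if (any(t < 0)) stop("transmembrane_voltage: t must be >= 0")
  1.5 * R * E * (1 - exp(-t / tau_c))
}

#' Field strength required for a target transmembrane voltage
#'
#' Inverse of [transmembrane_voltage()]: the field `E` such that the induced
#' voltage reaches `psi_m` at time `t` into the pulse.
#'
#' @param psi_m target transmembrane voltage (V).
#' @param R vesicle radius (m).
#' @param t time into the pulse (s), must be > 0.
#' @param tau_c membrane charging time (s).
#' @return field strength in V/m.
#' @export
field_for_voltage <- function(psi_m, R, t, tau_c) {
  if (any(R <= 0) || any(tau_c <= 0)) stop("field_for_voltage: R and tau_c must be > 0")
  if (any(t <= 0)) stop("field_for_voltage: t must be > 0")
  psi_m / (1.5 * R * (1 - exp(-t / tau_c)))
}

#' Macropore relaxation (closure) timescale
#'
#' Scaling estimate `tau_pore = eta_s * r / (2 * gamma)` for the closure of a
#' macropore of radius `r` in a fluid membrane with surface viscosity `eta_s`
#' and edge tension `gamma`.
#'
#' @param eta_s membrane surface viscosity (N s/m).
#' @param r pore radius (m).
#' @param gamma edge tension, line energy per unit length of the pore rim (N).
#' @return pore relaxation time in seconds.
#' @export
pore_relaxation_time <- function(eta_s, r, gamma) {
  if (any(eta_s <= 0) || any(r <= 0) || any(gamma <= 0))
    stop("pore_relaxation_time: all inputs must be > 0")
  eta_s * r / (2 * gamma)
}

#' Number of cortical actin filaments in a vesicle
#'
#' Estimates the total filament count for monomer concentration `c0`, vesicle
#' radius `R`, monomer size `d` and mean filament length `l`:
#' `N_f = c0 * (4/3) * pi * R^3 * d / l`.
#'
#' @param c0 initial actin monomer concentration (1/m^3).
#' @param R vesicle radius (m).
#' @param d actin monomer size (m).
#' @param l mean filament length (m).
#' @return real-valued filament count (order-of-magnitude estimate).
#' @export
#' @examples
#' filament_count(4.2e21, 10e-6, 2.5e-9, 4e-6)  # ~1e4
filament_count <- function(c0, R, d, l) {
  if (any(c0 <= 0) || any(R <= 0) || any(d <= 0) || any(l <= 0))
    stop("filament_count: all inputs must be > 0")
  c0 * (4 / 3) * pi * R^3 * d / l
}

#' Volume-conserving spheroid axes for a given deformation ratio
#'
#' Maps an equivalent-sphere radius `R` and deformation ratio `e = a/b` to the
#' semi-axes of the volume-conserving spheroid: along-field (polar) semi-axis
#' `a = e^(2/3) R` and perpendicular (equatorial) semi-axis `b = e^(-1/3) R`,
#' so that `(4/3) pi a b^2 = (4/3) pi R^3` and `a/b = e`.
#'
#' @param R equivalent sphere radius (any length unit; output in the same unit).
#' @param e deformation ratio a/b; > 1 prolate (tubelike), < 1 oblate (disklike).
#' @return list with elements `a` and `b`.
#' @export
spheroid_axes <- function(R, e) {
  if (any(R <= 0) || any(e <= 0)) stop("spheroid_axes: R and e must be > 0")
  list(a = e^(2 / 3) * R, b = e^(-1 / 3) * R)
}

#' Surface area of a spheroid
#'
#' Exact closed-form surface area of the spheroid with symmetry (along-field)
#' semi-axis `a` and equatorial semi-axis `b`: prolate form for a > b, oblate
#' form for a < b, sphere for a = b. A series expansion is used near a = b
#' where the closed forms are 0/0.
#'
#' @param a along-field (symmetry axis) semi-axis.
#' @param b equatorial semi-axis (the cross-section perpendicular to the
#'   symmetry axis is a circle of radius `b`).
#' @return surface area in squared input units.
#' @export
spheroid_surface_area <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("spheroid_surface_area: axes must be > 0")
  area_one <- function(a, b) {
    if (a == b) return(4 * pi * a^2)
    if (a > b) {                      # prolate: eccentricity of the meridian
      ec2 <- 1 - (b / a)^2
      ec <- sqrt(ec2)
      if (ec < 1e-4)                  # asin(x)/x series, O(x^8) accurate
        fac <- 1 + ec2 / 6 + 3 * ec2^2 / 40 + 15 * ec2^3 / 336
      else
        fac <- asin(ec) / ec
      2 * pi * b^2 + 2 * pi * a * b * fac
    } else {                          # oblate
      ec2 <- 1 - (a / b)^2
      ec <- sqrt(ec2)
      if (ec < 1e-4)                  # atanh(x)/x series
        fac <- 1 + ec2 / 3 + ec2^2 / 5 + ec2^3 / 7
      else
        fac <- atanh(ec) / ec
      2 * pi * b^2 + 2 * pi * a^2 * fac
    }
  }
  mapply(area_one, a, b)
}

#' Cortex mesh size on a sphere and on the deformed spheroid
#'
#' The mesh size of a network of `N_f` filaments spread over a membrane of
#' area A is estimated as `zeta = sqrt(A / N_f)`. Under an affine deformation
#' of the cortex the mesh stretches with the membrane area, so the stretch
#' imposed on inter-filament connections when the sphere deforms into the
#' volume-conserving spheroid of ratio `e` is
#' `delta_zeta = zeta_spheroid - zeta_sphere`.
#'
#' @param R equivalent sphere radius (m).
#' @param e deformation ratio a/b.
#' @param N_f filament count, see [filament_count()].
#' @return list with `zeta_sphere`, `zeta_spheroid`, `delta_zeta` (m).
#' @export
mesh_stretch <- function(R, e, N_f) {
  if (any(R <= 0) || any(e <= 0) || any(N_f <= 0))
    stop("mesh_stretch: all inputs must be > 0")
  ax <- spheroid_axes(R, e)
  A_sphere <- 4 * pi * R^2
  A_spheroid <- spheroid_surface_area(ax$a, ax$b)
  zs <- sqrt(A_sphere / N_f)
  ze <- sqrt(A_spheroid / N_f)
  list(zeta_sphere = zs, zeta_spheroid = ze, delta_zeta = ze - zs)
}

#' Mechanical force from cortex mesh stretching
#'
#' Force on an inter-filament connection stretched by `delta_zeta` with
#' stretching stiffness `k_stretch`: `f_m = k_stretch * delta_zeta`.
#'
#' @param delta_zeta mesh-size stretch (m), >= 0.
#' @param k_stretch stretching stiffness (N/m).
#' @return force in newtons.
#' @export
mechanical_force <- function(delta_zeta, k_stretch) {
  if (any(delta_zeta < 0)) stop("mechanical_force: delta_zeta must be >= 0")
  if (any(k_stretch <= 0)) stop("mechanical_force: k_stretch must be > 0")
  k_stretch * delta_zeta
}

#' Electrophoretic force on a membrane-bound actin filament
#'
#' Once the membrane is permeabilized the field penetrates the vesicle
#' (maximum ~`penetration_factor * E` at the poles) and drives charged
#' filaments. The force per unit length is `xi_h * mu_B * E_inside`; for a
#' filament of length `l` held against the membrane and oriented
#' perpendicular to the field (the maximum) the total force is
#' `f = xi_h * mu_B * penetration_factor * E * l`.
#'
#' @param xi_h hydrodynamic friction coefficient per unit filament length
#'   (N s/m^2).
#' @param mu_B electrophoretic mobility of actin (m^2/(V s)).
#' @param E applied field strength (V/m).
#' @param penetration_factor fraction of the applied field reaching the
#'   filaments at the poles of a porated vesicle (default 0.8).
#' @param l filament length (m).
#' @return force in newtons.
#' @export
electrophoretic_force <- function(xi_h, mu_B, E, penetration_factor = 0.8, l) {
  if (any(xi_h < 0) || any(mu_B < 0) || any(E < 0))
    stop("electrophoretic_force: xi_h, mu_B, E must be >= 0")
  if (any(penetration_factor <= 0) || any(penetration_factor > 1))
    stop("electrophoretic_force: penetration_factor must be in (0, 1]")
  if (any(l <= 0)) stop("electrophoretic_force: l must be > 0")
  xi_h * mu_B * (penetration_factor * E) * l
}

#' Actin-cortex parameter set
#'
#' Default values describe a biomimetic actin shell polymerized from ~7 uM
#' monomer inside a GUV: monomer concentration 4.2e21 m^-3, monomer size
#' 2.5 nm, filament length 4 um, inter-filament stretching stiffness
#' 48 pN/nm, perpendicular hydrodynamic friction 0.034 N s/m^2,
#' electrophoretic mobility 1e-8 m^2/(V s), and a 100-400 pN range for
#' filament-network rupture/depolymerization forces.
#'
#' @param c0 monomer concentration (1/m^3).
#' @param d monomer size (m).
#' @param l filament length (m).
#' @param k_stretch stretching stiffness (N/m).
#' @param xi_h hydrodynamic friction per unit length (N s/m^2).
#' @param mu_B electrophoretic mobility (m^2/(V s)).
#' @param rupture_range length-2 numeric, force range (N) needed to rupture
#'   filaments or initiate network depolymerization.
#' @return list of class `cortex_params`.
#' @export
cortex_params <- function(c0 = 4.2e21, d = 2.5e-9, l = 4e-6,
                          k_stretch = 48e-12 / 1e-9, xi_h = 0.034,
                          mu_B = 1e-8, rupture_range = c(100e-12, 400e-12)) {
  stopifnot(c0 > 0, d > 0, l > 0, k_stretch > 0, xi_h > 0, mu_B > 0,
            length(rupture_range) == 2, rupture_range[1] > 0,
            rupture_range[1] <= rupture_range[2])
  structure(list(c0 = c0, d = d, l = l, k_stretch = k_stretch, xi_h = xi_h,
                 mu_B = mu_B, rupture_range = rupture_range),
            class = "cortex_params")
}

#' Pulse parameter set
#'
#' @param E_V_per_mm field strength in V/mm (stored internally in V/m).
#' @param duration_s pulse duration (s); 500 us default.
#' @param penetration_factor pole-field penetration fraction for porated
#'   vesicles (default 0.8).
#' @return list of class `pulse_params` with `E` in V/m.
#' @export
pulse_params <- function(E_V_per_mm = 150, duration_s = 500e-6,
                         penetration_factor = 0.8) {
  stopifnot(E_V_per_mm >= 0, duration_s > 0,
            penetration_factor > 0, penetration_factor <= 1)
  structure(list(E = E_V_per_mm * 1e3, E_V_per_mm = E_V_per_mm,
                 duration_s = duration_s,
                 penetration_factor = penetration_factor),
            class = "pulse_params")
}

#' Actin-cortex force balance for a deformed, porated vesicle
#'
#' Assembles the full force-balance argument for the stability of a
#' membrane-bound actin network under an electroporating pulse: filament
#' count, mesh size on the sphere and on the volume-conserving spheroid of
#' deformation ratio `e`, the mesh stretch, the resulting mechanical
#' (stretching) force, and the electrophoretic force on a filament once the
#' field penetrates the permeabilized membrane. Each force is compared with
#' the rupture/depolymerization force range of the network.
#'
#' @param R_um equivalent sphere radius in micrometres.
#' @param e deformation ratio a/b at maximum deformation.
#' @param pulse a [pulse_params()] object.
#' @param cortex a [cortex_params()] object.
#' @param porated logical; if `FALSE` the field does not penetrate the vesicle
#'   and the electrophoretic force is zero (the penetration factor only
#'   applies above the poration threshold).
#' @return object of class `force_report`: all inputs, `N_f`, mesh sizes and
#'   stretch (m), forces (N), and character verdicts comparing each force to
#'   `cortex$rupture_range`.
#' @export
#' @examples
#' rep <- force_report(R_um = 10, e = 1.18)
#' rep$f_electrophoretic * 1e12  # pN
force_report <- function(R_um = 10, e = 1.18, pulse = pulse_params(),
                         cortex = cortex_params(), porated = TRUE) {
  stopifnot(R_um > 0, e > 0, inherits(pulse, "pulse_params"),
            inherits(cortex, "cortex_params"))
  R <- R_um * 1e-6
  N_f <- filament_count(cortex$c0, R, cortex$d, cortex$l)
  mesh <- mesh_stretch(R, e, N_f)
  f_m <- mechanical_force(mesh$delta_zeta, cortex$k_stretch)
  f_ep <- if (porated)
    electrophoretic_force(cortex$xi_h, cortex$mu_B, pulse$E,
                          pulse$penetration_factor, cortex$l)
  else 0
  verdict <- function(f) {
    lo <- cortex$rupture_range[1]; hi <- cortex$rupture_range[2]
    if (f < lo) "below rupture range: insufficient alone"
    else if (f <= hi) "within rupture range: sufficient to disrupt the network"
    else "above rupture range: sufficient to disrupt the network"
  }
  structure(list(
    R = R, e = e, porated = porated, pulse = pulse, cortex = cortex,
    N_f = N_f,
    zeta_sphere = mesh$zeta_sphere, zeta_spheroid = mesh$zeta_spheroid,
    delta_zeta = mesh$delta_zeta,
    f_m = f_m, f_electrophoretic = f_ep,
    verdict_mechanical = verdict(f_m),
    verdict_electrophoretic = verdict(f_ep)
  ), class = "force_report")
}

#' @export
print.force_report <- function(x, ...) {
  pN <- function(f) sprintf("%.1f pN", f * 1e12)
  cat("Actin-cortex force balance\n")
  cat(sprintf("  R = %.2f um, e = a/b = %.3f, E = %.0f V/mm (porated: %s)\n",
              x$R * 1e6, x$e, x$pulse$E_V_per_mm, x$porated))
  cat(sprintf("  filaments N_f         : %.3g\n", x$N_f))
  cat(sprintf("  mesh size (sphere)    : %.1f nm\n", x$zeta_sphere * 1e9))
  cat(sprintf("  mesh size (spheroid)  : %.1f nm\n", x$zeta_spheroid * 1e9))
  cat(sprintf("  mesh stretch dzeta    : %.3f nm\n", x$delta_zeta * 1e9))
  cat(sprintf("  mechanical force      : %s (%s)\n", pN(x$f_m), x$verdict_mechanical))
  cat(sprintf("  electrophoretic force : %s (%s)\n", pN(x$f_electrophoretic),
              x$verdict_electrophoretic))
  invisible(x)
}
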