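#' Blood rheology constants
#'
#' Container for the fluid constants shared by the large-vessel solver
#' and the structured-tree admittance: density `rho`, dynamic viscosity
#' `mu` and the derived kinematic viscosity `nu = mu / rho`.
#' Defaults are whole blood at 1.0e3 kg m^-3 and 4.0e-3 kg m^-1 s^-1.
#'
#' @param rho density in kg m^-3.
#' @param mu dynamic viscosity in kg m^-1 s^-1.
#' @return an object of class `fluid_properties` with fields
#'   `rho`, `mu`, `nu`.
#' @examples
#' fl <- fluid_properties()
#' fl$nu * fl$rho == fl$mu
#' @export
fluid_properties <- function(rho = 1.0e3, mu = 4.0e-3) {
  if (!is.numeric(rho) || rho <= 0) stop("density must be positive")
  if (!is.numeric(mu) || mu <= 0) stop("viscosity must be positive")
  structure(list(rho = rho, mu = mu, nu = mu / rho),
            class = "fluid_properties")
}

#' Elastic wall law for a compliant vessel
#'
#' The transmural pressure of a thin-walled elastic vessel is
#' p - p0 = (4/3) (Eh/R0) (sqrt(A/A0) - 1), where Eh/R0 is the wall
#' stiffness, A0 = pi R0^2 the reference cross-section and p0 the
#' external pressure.  Stiffness and external pressure are quoted in
#' mmHg, the reference radius in metres; internally everything is Pa.
#'
#' @param EhR0_mmHg wall stiffness Eh/R0 in mmHg.
#' @param R0 reference (zero transmural pressure) radius in m.
#' @param p0_mmHg external pressure in mmHg (default 0).
#' @return an object of class `wall_law` with fields `EhR0` (Pa),
#'   `R0` (m), `A0` (m^2), `p0` (Pa) and `f = (4/3) EhR0` (Pa).
#' @examples
#' law <- wall_law(150, R0 = 0.0155)
#' tube_law_pressure(law$A0, law) # == p0
#' @export
wall_law <- function(EhR0_mmHg, R0, p0_mmHg = 0) {
  if (!is.numeric(EhR0_mmHg) || EhR0_mmHg <= 0) stop("stiffness must be positive")
  if (!is.numeric(R0) || R0 <= 0) stop("reference radius must be positive")
  EhR0 <- mmHg_to_Pa(EhR0_mmHg)
  structure(list(EhR0 = EhR0, R0 = R0, A0 = pi * R0^2,
                 p0 = mmHg_to_Pa(p0_mmHg), f = (4 / 3) * EhR0),
            class = "wall_law")
}

#' Tube law: pressure from area
#'
#' @param A cross-sectional area in m^2 (vectorised).
#' @param law a [wall_law()].
#' @return pressure in Pa.
#' @export
tube_law_pressure <- function(A, law) {
  if (any(!is.finite(A)) || any(A <= 0)) stop("area must be positive")
  law$p0 + law$f * (sqrt(A / law$A0) - 1)
}

#' Tube law: area from pressure (exact inverse)
#'
#' Inverts the elastic tube law; defined for transmural pressures above
#' the collapse bound p0 - (4/3) Eh/R0 where the positive root exists.
#'
#' @param p pressure in Pa (vectorised).
#' @inheritParams tube_law_pressure
#' @return area in m^2.
#' @export
tube_law_area <- function(p, law) {
  s <- 1 + (p - law$p0) / law$f
  if (any(!is.finite(s)) || any(s <= 0))
    stop("pressure below collapse bound of the tube law")
  law$A0 * s^2
}

#' Local pulse wave velocity
#'
#' c = sqrt((A/rho) dp/dA) = sqrt( (2 Eh / (3 rho R0)) sqrt(A/A0) )
#' for the elastic tube law.
#'
#' @inheritParams tube_law_pressure
#' @param fluid a [fluid_properties()].
#' @return wave speed in m/s.
#' @examples
#' wave_speed(wall_law(150, 0.01)$A0, wall_law(150, 0.01)) # ~3.65 m/s
#' @export
wave_speed <- function(A, law, fluid = fluid_properties()) {
  if (any(!is.finite(A)) || any(A <= 0)) stop("area must be positive")
  sqrt((2 * law$EhR0) / (3 * fluid$rho) * sqrt(A / law$A0))
}

#' Radius-dependent stiffness of the small vessels
#'
#' Empirical stiffness law for the microvascular tree,
#' Eh/R0 = k1 exp(k2 R0) + k3 with k1 = 187.5 mmHg, k2 = -10 cm^-1 and
#' k3 = 37.5 mmHg.  The radius is taken in cm to match the units of k2;
#' the returned stiffness is in mmHg (convert with [mmHg_to_Pa()] for
#' internal use).
#'
#' @param R0_cm reference radius in cm (vectorised).
#' @param k1,k2,k3 law constants (mmHg, cm^-1, mmHg).
#' @return stiffness Eh/R0 in mmHg.
#' @examples
#' small_vessel_stiffness(0.003) # ~219.5 mmHg at the 30 micron cutoff
#' @export
small_vessel_stiffness <- function(R0_cm, k1 = 187.5, k2 = -10, k3 = 37.5) {
  if (any(!is.finite(R0_cm)) || any(R0_cm < 0)) stop("radius must be non-negative")
  k1 * exp(k2 * R0_cm) + k3
}

#' Area compliance per unit length
#'
#' C = dA/dp evaluated at the reference state,
#' C = 3 A0 R0 / (2 Eh) = 3 A0 / (2 (Eh/R0)), in m^2 Pa^-1.
#'
#' @inheritParams tube_law_pressure
#' @return compliance in m^2 Pa^-1.
#' @export
compliance <- function(law) {
  3 * law$A0 / (2 * law$EhR0)
}

#' Boundary-layer thickness for the flat-profile friction model
#'
#' The large-vessel momentum balance uses a flat core velocity profile
#' with a thin linear boundary layer of constant thickness eps, giving
#' the friction source -(2 pi nu R / eps) q / A.  The default thickness
#' is the oscillatory (Stokes) layer for the cardiac period,
#' eps = sqrt(nu T / (2 pi)).
#'
#' @param period cardiac period in s.
#' @param fluid a [fluid_properties()].
#' @return boundary-layer thickness in m.
#' @export
boundary_layer_thickness <- function(period = 0.8, fluid = fluid_properties()) {
  sqrt(fluid$nu * period / (2 * pi))
}
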