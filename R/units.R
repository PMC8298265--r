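#' Unit conversions
#'
#' All internal computation in pulmonet is in SI units (m, s, kg, Pa).
#' Pressures are quoted in mmHg and lengths in cm at the user-facing
#' boundaries only, and every conversion funnels through these helpers
#' with 1 mmHg = 133.322 Pa exactly.
#'
#' @param p pressure in mmHg (or Pa for the inverse).
#' @return converted numeric vector.
#' @examples
#' Pa_to_mmHg(mmHg_to_Pa(150)) # 150
#' @export
mmHg_to_Pa <- function(p) p * 133.322

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(p) p / 133.322

#' @rdname mmHg_to_Pa
#' @param x length in cm (or m for the inverse).
#' @export
cm_to_m <- function(x) x / 100

#' @rdname mmHg_to_Pa
#' @export
m_to_cm <- function(x) x * 100

# internal: mL/s <-> m^3/s
mLs_to_m3s <- function(q) q * 1e-6
m3s_to_mLs <- function(q) q * 1e6
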