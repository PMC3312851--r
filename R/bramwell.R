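# 1 mmHg in pascal; all distensibilities are carried internally in Pa^-1
MMHG_TO_PA <- 133.322

#' Blood constants
#' @param rho Blood density, kg m^-3 (default 1059).
#' @return An object of class `blood_constants`.
#' @export
blood_constants <- function(rho = 1059) {
  if (!is.finite(rho) || rho <= 0)
    pwv_abort("domain_error", "rho must be positive")
  structure(list(rho = rho), class = "blood_constants")
}

#' Aortic distensibility from area distension and pulse pressure
#'
#' Distensibility = delta_A / (A_minimal * delta_P), the relative luminal
#' area change over the local pulse pressure, converted to Pa^-1
#' (1 mmHg = 133.322 Pa). Also reported in 1e-3 mmHg^-1 for readability.
#'
#' @param delta_A_mm2 Luminal area distension (max - min), mm^2, >= 0.
#' @param A_min_mm2 Minimal luminal area, mm^2, > 0.
#' @param delta_P_mmHg Local pulse pressure, mmHg, > 0.
#' @return An object of class `distensibility_result` with `D_per_Pa` and
#'   `D_per_mmHg_e3`.
#' @export
distensibility <- function(delta_A_mm2, A_min_mm2, delta_P_mmHg) {
  if (!is.finite(A_min_mm2) || A_min_mm2 <= 0)
    pwv_abort("domain_error", "A_min_mm2 must be > 0")
  if (!is.finite(delta_P_mmHg) || delta_P_mmHg <= 0)
    pwv_abort("domain_error", "delta_P_mmHg must be > 0")
  if (!is.finite(delta_A_mm2) || delta_A_mm2 < 0)
    pwv_abort("domain_error", "delta_A_mm2 must be >= 0")
  D <- (delta_A_mm2 / A_min_mm2) / (delta_P_mmHg * MMHG_TO_PA)
  structure(list(delta_A_mm2 = delta_A_mm2, A_min_mm2 = A_min_mm2,
                 delta_P_mmHg = delta_P_mmHg,
                 D_per_Pa = D, D_per_mmHg_e3 = D * MMHG_TO_PA * 1e3),
            class = "distensibility_result")
}

#' @export
print.distensibility_result <- function(x, ...) {
  cat(sprintf("<distensibility> D = %.4g Pa^-1 (%.3g x 10^-3 mmHg^-1); dA=%.3g mm^2, Amin=%.3g mm^2, dP=%.3g mmHg\n",
              x$D_per_Pa, x$D_per_mmHg_e3, x$delta_A_mm2, x$A_min_mm2,
              x$delta_P_mmHg))
  invisible(x)
}

#' Theoretical PWV from distensibility (Bramwell-Hill)
#'
#' PWV = (rho * Distensibility)^(-1/2).
#'
#' @param d A `distensibility_result` or a distensibility in Pa^-1.
#' @param constants A `blood_constants` object.
#' @return PWV in m/s.
#' @export
theoretical_pwv <- function(d, constants = blood_constants()) {
  D <- if (inherits(d, "distensibility_result")) d$D_per_Pa else d
  if (!is.finite(D) || D <= 0)
    pwv_abort("domain_error", "distensibility must be > 0 (finite PWV)")
  (constants$rho * D)^(-0.5)
}

#' Local pulse pressure from PWV (inverse Bramwell-Hill)
#'
#' delta_P = rho * PWV^2 * (delta_A / A_min), converted to mmHg. The model
#' applied inversely: with PWV and the area distension known, the local
#' pulse pressure follows.
#'
#' @param pwv_m_per_s PWV, m/s, > 0.
#' @param delta_A_mm2 Area distension, mm^2, > 0.
#' @param A_min_mm2 Minimal area, mm^2, > 0.
#' @param constants A `blood_constants` object.
#' @return Pulse pressure in mmHg.
#' @export
pulse_pressure_from_pwv <- function(pwv_m_per_s, delta_A_mm2, A_min_mm2,
                                    constants = blood_constants()) {
  if (!is.finite(pwv_m_per_s) || pwv_m_per_s <= 0 ||
      !is.finite(delta_A_mm2) || delta_A_mm2 <= 0 ||
      !is.finite(A_min_mm2) || A_min_mm2 <= 0)
    pwv_abort("domain_error", "all inputs must be positive")
  constants$rho * pwv_m_per_s^2 * (delta_A_mm2 / A_min_mm2) / MMHG_TO_PA
}
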