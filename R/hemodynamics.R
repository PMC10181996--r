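#' Hemodynamic model parameters
#'
#' Bundles the constants and per-beat quantities of the closed-form model that
#' links pulse timing to blood pressure. Pulse pressure follows a
#' Moens-Korteweg / Bramwell-Hill argument: stroke volume is proportional to
#' the pre-ejection period, and pulse pressure is proportional to
#' `PEP / (PIR * PTT^2)` times a Womersley correction for pulsatile viscous
#' flow; diastolic pressure is an affine function of the natural log of the
#' same drive term. The proportionalities are made generative with explicit
#' constants `k_pp` (pulse-pressure scale, mmHg) and `a_dbp`/`b_dbp`
#' (log-model slope and intercept, mmHg).
#'
#' @param pep Pre-ejection period (s, > 0).
#' @param pir Pulse intensity ratio (dimensionless, > 0).
#' @param ptt Pulse transit time (s, > 0).
#' @param alpha Womersley number (dimensionless, > 0.56/sqrt(2)).
#' @param k_pp Pulse-pressure proportionality constant (mmHg, > 0).
#' @param a_dbp,b_dbp Slope and intercept of the diastolic log model (mmHg).
#' @param k1,k2 Constants of the log pressure/pulse-wave-velocity relation
#'   (mmHg and s/m); used by [bp_from_pwv()].
#' @return An object of class `hemo_params` (a named list).
#' @seealso [pulse_pressure()], [dbp_from_params()], [bp_from_pwv()]
#' @export
hemo_params <- function(pep = 0.08, pir = 2, ptt = 0.2, alpha = 3,
                        k_pp = 24, a_dbp = 22, b_dbp = 78,
                        k1 = 10, k2 = 0.1) {
  check_number(pep, "pep", positive = TRUE)
  check_number(pir, "pir", positive = TRUE)
  check_number(ptt, "ptt", positive = TRUE)
  check_number(alpha, "alpha")
  check_number(k_pp, "k_pp", positive = TRUE)
  check_number(a_dbp, "a_dbp")
  check_number(b_dbp, "b_dbp")
  check_number(k1, "k1")
  check_number(k2, "k2")
  if (alpha <= 0.56 / sqrt(2)) {
    bp_abort("alpha must exceed 0.56/sqrt(2) for the Womersley factor to be defined")
  }
  structure(
    list(pep = pep, pir = pir, ptt = ptt, alpha = alpha,
         k_pp = k_pp, a_dbp = a_dbp, b_dbp = b_dbp, k1 = k1, k2 = k2),
    class = "hemo_params"
  )
}

#' Womersley correction factor
#'
#' The factor `(1 - 0.56 / (sqrt(2) * alpha))^-2` that corrects the plug-flow
#' pulse-pressure relation for the pulsatile velocity profile. It is strictly
#' decreasing in `alpha` and tends to 1 as `alpha` grows (inertia-dominated
#' flow).
#'
#' @param alpha Womersley number(s); each must exceed `0.56/sqrt(2)`.
#' @return Numeric vector of correction factors (>= 1 for alpha where the
#'   parenthesis is in (0, 1)).
#' @export
womersley_factor <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) < 1L || any(!is.finite(alpha))) {
    bp_abort("alpha must be finite numeric")
  }
  if (any(alpha <= 0.56 / sqrt(2))) {
    bp_abort("womersley_factor undefined for alpha <= 0.56/sqrt(2)")
  }
  (1 - 0.56 / (sqrt(2) * alpha))^-2
}

# shared drive term PEP / (PIR * PTT^2) * womersley_factor(alpha)
hemo_drive <- function(params) {
  stopifnot(inherits(params, "hemo_params"))
  (params$pep / (params$pir * params$ptt^2)) * womersley_factor(params$alpha)
}

#' Pulse pressure from hemodynamic parameters
#'
#' `PP = k_pp * PEP / (PIR * PTT^2) * (1 - 0.56/(sqrt(2)*alpha))^-2` (mmHg).
#' Strictly decreasing in `ptt` and `pir`, increasing in `pep`.
#'
#' @param params A [hemo_params()] object.
#' @return Pulse pressure in mmHg.
#' @export
pulse_pressure <- function(params) {
  params$k_pp * hemo_drive(params)
}

#' Diastolic pressure from hemodynamic parameters
#'
#' `DBP = a_dbp * ln(drive) + b_dbp` where `drive` is the same term that sets
#' pulse pressure. The natural logarithm is used throughout; any base change
#' is absorbed by `a_dbp`.
#'
#' @param params A [hemo_params()] object.
#' @return Diastolic pressure in mmHg.
#' @export
dbp_from_params <- function(params) {
  drive <- hemo_drive(params)
  if (!is.finite(drive) || drive <= 0) {
    bp_abort("log argument of the diastolic model must be positive")
  }
  params$a_dbp * log(drive) + params$b_dbp
}

#' Systolic pressure from pulse pressure and diastolic pressure
#'
#' @param pp Pulse pressure (mmHg, > 0).
#' @param dbp Diastolic pressure (mmHg).
#' @return `pp + dbp` (mmHg).
#' @export
sbp_from_pp_dbp <- function(pp, dbp) {
  if (!is.numeric(pp) || !is.numeric(dbp) || any(!is.finite(pp)) || any(!is.finite(dbp))) {
    bp_abort("pp and dbp must be finite numeric")
  }
  if (any(pp <= 0)) bp_abort("pulse pressure must be > 0")
  pp + dbp
}

#' Mean arterial pressure from systolic and diastolic pressure
#'
#' The standard weighted average `MAP = (2*DBP + SBP) / 3`, reflecting the
#' greater fraction of the cardiac cycle spent in diastole.
#'
#' @param sbp Systolic pressure (mmHg); must exceed `dbp` elementwise.
#' @param dbp Diastolic pressure (mmHg).
#' @return MAP in mmHg, strictly between `dbp` and `sbp`.
#' @export
map_from_sbp_dbp <- function(sbp, dbp) {
  if (!is.numeric(sbp) || !is.numeric(dbp) || any(!is.finite(sbp)) || any(!is.finite(dbp))) {
    bp_abort("sbp and dbp must be finite numeric")
  }
  if (any(sbp <= dbp)) bp_abort("sbp must exceed dbp")
  (2 * dbp + sbp) / 3
}

#' Blood pressure from pulse wave velocity
#'
#' The log form of the Moens-Korteweg pressure/velocity association:
#' `BP = k1 * log(1/PWV + k2)` (natural log). Monotone decreasing in `pwv`
#' for `k1 > 0`.
#'
#' @param pwv Pulse wave velocity (m/s, > 0).
#' @param k1 Scale constant (mmHg).
#' @param k2 Offset constant (s/m).
#' @return Pressure in mmHg.
#' @export
bp_from_pwv <- function(pwv, k1 = 10, k2 = 0.1) {
  if (!is.numeric(pwv) || any(!is.finite(pwv)) || any(pwv <= 0)) {
    bp_abort("pwv must be finite and > 0")
  }
  arg <- 1 / pwv + k2
  if (any(arg <= 0)) bp_abort("log argument 1/pwv + k2 must be positive")
  k1 * log(arg)
}

#' Blood-pressure triple from hemodynamic parameters
#'
#' Convenience wrapper composing [dbp_from_params()], [pulse_pressure()],
#' [sbp_from_pp_dbp()] and [map_from_sbp_dbp()].
#'
#' @param params A [hemo_params()] object.
#' @return Named list with `sbp`, `dbp`, `map` and `pp` (mmHg).
#' @export
bp_triple <- function(params) {
  dbp <- dbp_from_params(params)
  pp <- pulse_pressure(params)
  sbp <- sbp_from_pp_dbp(pp, dbp)
  list(sbp = sbp, dbp = dbp, map = map_from_sbp_dbp(sbp, dbp), pp = pp)
}
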