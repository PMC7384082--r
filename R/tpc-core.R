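# Closed-form Sharpe-Schoolfield machinery: the model with the peak
# temperature Tpk as an explicit parameter, plus the two derived curve
# descriptors (maximum height Bpk and operational niche width Wop).

#' Construct a validated Sharpe-Schoolfield parameter set
#'
#' The four-parameter Sharpe-Schoolfield model describes a unimodal thermal
#' performance curve (TPC): performance rises with temperature following a
#' Boltzmann-Arrhenius factor with activation energy `e_act`, and falls above
#' the peak temperature `t_pk` under the control of the deactivation energy
#' `e_d`.  `b0` sets the vertical offset: it is the rate at the reference
#' temperature `t_ref` before high-temperature deactivation is accounted for.
#'
#' @param b0 Rate (time^-1) at the reference temperature, pre-deactivation.
#'   Must be positive.
#' @param e_act Activation energy E (eV); sets the steepness of the rise.
#'   Must be positive.
#' @param t_pk Peak temperature (K); the exact argmax of the curve under this
#'   parameterization.
#' @param e_d Deactivation energy ED (eV); must exceed `e_act` by at least
#'   1e-6 eV so the denominator factor E/(ED - E) stays away from a pole.
#' @param t_ref Reference temperature (K).
#'
#' @return An object of class `tpc_params`.
#' @export
tpc_params <- function(b0, e_act, t_pk, e_d, t_ref = 273.15) {
  stopifnot(length(b0) == 1L, length(e_act) == 1L, length(t_pk) == 1L,
            length(e_d) == 1L, length(t_ref) == 1L)
  if (!is.finite(b0) || b0 <= 0)
    stop("invalid TPC parameters: b0 must be positive (b0 > 0)")
  if (!is.finite(e_act) || e_act <= 0)
    stop("invalid TPC parameters: e_act must be positive (e_act > 0)")
  if (!is.finite(t_pk) || t_pk <= 0)
    stop("invalid TPC parameters: t_pk must be positive (t_pk > 0)")
  if (!is.finite(t_ref) || t_ref <= 0)
    stop("invalid TPC parameters: t_ref must be positive (t_ref > 0)")
  if (!is.finite(e_d) || e_d - e_act < 1e-6)
    stop("invalid TPC parameters: e_d must exceed e_act (e_d > e_act)")
  structure(list(b0 = b0, e_act = e_act, t_pk = t_pk, e_d = e_d,
                 t_ref = t_ref),
            class = "tpc_params")
}

#' @export
print.tpc_params <- function(x, ...) {
  cat(sprintf(
    "Sharpe-Schoolfield parameters (Tref = %.2f K):\n  B0 = %.4g  E = %.4g eV  Tpk = %.2f K  ED = %.4g eV\n",
    x$t_ref, x$b0, x$e_act, x$t_pk, x$e_d))
  invisible(x)
}

#' Evaluate the Sharpe-Schoolfield curve
#'
#' Computes
#' \deqn{B(T) = B_0 \exp\!\left(-\frac{E}{k}\Big(\frac{1}{T}-\frac{1}{T_{ref}}\Big)\right)
#'   \Big/ \left(1 + \frac{E}{E_D - E}
#'   \exp\!\left(\frac{E_D}{k}\Big(\frac{1}{T_{pk}}-\frac{1}{T}\Big)\right)\right)}
#' with \eqn{k} the Boltzmann constant in eV/K.  The value is strictly
#' positive for all temperatures.
#'
#' @param params A [tpc_params()] object.
#' @param temperature Temperature(s) in kelvin; vectorized.
#'
#' @return Rate value(s), same length as `temperature`.
#' @export
evaluate_tpc <- function(params, temperature) {
  if (!inherits(params, "tpc_params"))
    params <- do.call(tpc_params, as.list(unclass(params)))
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperature must be positive and finite (kelvin)")
  k <- boltzmann_k
  num <- params$b0 *
    exp(-params$e_act / k * (1 / temperature - 1 / params$t_ref))
  den <- 1 + params$e_act / (params$e_d - params$e_act) *
    exp(params$e_d / k * (1 / params$t_pk - 1 / temperature))
  num / den
}

#' Maximum height of the thermal performance curve
#'
#' Under the explicit-Tpk parameterization the peak temperature is the exact
#' argmax, so the maximum height is simply the curve evaluated at `t_pk`.
#'
#' @param params A [tpc_params()] object.
#' @return Bpk, the maximum rate (time^-1).
#' @export
compute_bpk <- function(params) {
  if (!inherits(params, "tpc_params"))
    params <- do.call(tpc_params, as.list(unclass(params)))
  evaluate_tpc(params, params$t_pk)
}

#' Curve value at the reference temperature
#'
#' The nominal `b0` parameter is only an approximation of the curve value at
#' `t_ref` (the denominator is not exactly 1 there), so the trait used
#' downstream as "B0" is the curve evaluated at the reference temperature.
#'
#' @param params A [tpc_params()] object.
#' @return B(Tref) (time^-1).
#' @export
compute_b_at_ref <- function(params) {
  if (!inherits(params, "tpc_params"))
    params <- do.call(tpc_params, as.list(unclass(params)))
  evaluate_tpc(params, params$t_ref)
}

#' Operational niche width
#'
#' Wop is the distance (K) between the peak temperature and the temperature
#' on the *rising* branch where the rate equals half the maximum height.  The
#' half-height temperature is located by bisection on a verified bracket to a
#' tolerance of 1e-6 K.
#'
#' @param params A [tpc_params()] object.
#' @param search_floor Lowest temperature considered for the half-height
#'   point (K); defaults to `t_pk - 150`.  If the rate at the floor is still
#'   above half the maximum, the half-height point is unreachable in the
#'   physically sensible range and an error is raised (callers record Wop as
#'   missing).
#' @param tol Bisection tolerance in kelvin.
#'
#' @return Wop (K), strictly positive.
#' @export
compute_wop <- function(params, search_floor = NULL, tol = 1e-6) {
  if (!inherits(params, "tpc_params"))
    params <- do.call(tpc_params, as.list(unclass(params)))
  if (is.null(search_floor)) search_floor <- params$t_pk - 150
  if (search_floor >= params$t_pk)
    stop("search_floor must lie below t_pk")
  half <- compute_bpk(params) / 2
  f <- function(tt) evaluate_tpc(params, tt) - half
  lo <- search_floor
  hi <- params$t_pk
  if (f(lo) > 0)
    stop("half-height not reached above the search floor")
  # bisection: f(lo) <= 0 < f(hi) on the monotone rising branch
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  t_half <- (lo + hi) / 2
  params$t_pk - t_half
}

#' All derived TPC quantities at once
#'
#' @param params A [tpc_params()] object.
#' @return A list with `b_pk`, `w_op` (NA if the half-height point is not
#'   reachable), and `b_at_ref`.
#' @export
derive_tpc <- function(params) {
  list(
    b_pk = compute_bpk(params),
    w_op = tryCatch(compute_wop(params), error = function(e) NA_real_),
    b_at_ref = compute_b_at_ref(params)
  )
}
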