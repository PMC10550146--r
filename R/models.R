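#' Parameters of the tumor-angiogenesis-resources growth model
#'
#' Constructs the parameter set of the semi-mechanistic ODE system describing
#' unperturbed, non-monotonic tumor growth through the interplay of cancer
#' cells (tumor volume, TV, mm^3), angiogenesis (ANG, arbitrary units) and
#' growth resources such as oxygen and nutrients (RES, arbitrary units):
#'
#' \deqn{dTV/dt  = \lambda \, TV \, RES - k_{death} \, TV}
#' \deqn{dANG/dt = k_{ang} \, TV - k_{death} \, ANG}
#' \deqn{dRES/dt = k_{res} \, ANG - k_{consumption} \, TV}
#'
#' ANG and RES are initialized at 1 au; TV at `tv0`.
#'
#' @param tv0 Tumor volume at inoculation (mm^3), > 0.
#' @param lambda Second-order growth rate constant (au^-1 day^-1), > 0.
#' @param k_ang First-order angiogenesis proliferation constant
#'   (au mm^-3 day^-1), > 0.
#' @param k_res First-order resource proliferation constant (day^-1), > 0.
#' @param k_consumption First-order resource consumption constant
#'   (au mm^-3 day^-1), > 0.
#' @param k_death First-order natural degradation constant (day^-1), > 0.
#' @return An object of class `final_model_params` (named list).
#' @seealso [final_model_defaults()] for the published population estimates.
#' @export
final_model_params <- function(tv0, lambda, k_ang, k_res, k_consumption, k_death) {
  p <- list(tv0 = tv0, lambda = lambda, k_ang = k_ang, k_res = k_res,
            k_consumption = k_consumption, k_death = k_death)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("final model parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(p, class = "final_model_params")
}

#' Published population estimates for the tumor-angiogenesis-resources model
#'
#' Population parameter estimates obtained by SAEM from the pooled unperturbed
#' xenograft study (85 mice, 12 cell lines, 6 tumor types): fixed effects,
#' inter-individual variability (IIV, as coefficients of variation of the
#' log-normal random effects; none on `k_res`), and the additive residual
#' standard deviation on the log(mm^3) scale.
#'
#' @return A list with elements `theta` (a [final_model_params()] object),
#'   `iiv_cv` (named CV per parameter; parameters without IIV absent),
#'   `omega` (log-scale random-effect SDs, `sqrt(log(1 + CV^2))`) and
#'   `sigma` (residual SD, log(mm^3)).
#' @export
final_model_defaults <- function() {
  theta <- final_model_params(tv0 = 69.06, lambda = 0.046, k_ang = 0.00036,
                              k_res = 0.11, k_consumption = 0.00069,
                              k_death = 0.0081)
  iiv_cv <- c(tv0 = 0.29, lambda = 0.44, k_ang = 0.31,
              k_consumption = 0.35, k_death = 0.27)
  list(theta = theta,
       iiv_cv = iiv_cv,
       omega = sqrt(log(1 + iiv_cv^2)),
       sigma = 0.17)
}

#' Simulate the tumor-angiogenesis-resources system
#'
#' Numerically integrates the three coupled ODEs with an adaptive
#' Dormand-Prince 5(4) scheme. RES (and, in principle, ANG) may transiently
#' approach or cross zero: the vector field is polynomial and the oscillation
#' mechanism requires RES to fall below the effective growth threshold
#' `k_death / lambda`; no positivity clamp is applied, but the returned object
#' carries a `negative_state` attribute flagging whether RES or ANG was ever
#' negative at an output time.
#'
#' @param params A [final_model_params()] object.
#' @param times Increasing, non-negative output times (days). Integration
#'   always starts at day 0.
#' @param init Initial state `c(tv, ang, res)`; defaults to `(tv0, 1, 1)`.
#' @param rtol,atol Relative / absolute solver tolerances.
#' @return A data.frame with columns `time`, `tv`, `ang`, `res` and attribute
#'   `negative_state` (logical).
#' @export
simulate_final_model <- function(params, times, init = NULL,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "final_model_params"))
  if (is.null(init)) init <- c(params$tv0, 1, 1)
  if (length(init) != 3L || init[1] <= 0)
    stop("init must be c(tv, ang, res) with tv > 0", call. = FALSE)
  pv <- c(params$lambda, params$k_ang, params$k_res, params$k_consumption,
          params$k_death)
  m <- solve_final_cpp(pv, as.numeric(init), as.numeric(times), rtol, atol)
  out <- data.frame(time = as.numeric(times), tv = m[, 1], ang = m[, 2],
                    res = m[, 3])
  attr(out, "negative_state") <- any(m[, 2] < 0) || any(m[, 3] < 0)
  out
}

# --- classical tumor growth models -----------------------------------------

.classical_models <- c("linear", "exponential", "logistic", "gompertz", "simeoni")

#' Parameters of a classical tumor growth model
#'
#' Supported monotone models and their parameters (rates in day^-1 unless
#' noted):
#' \itemize{
#'   \item `linear`: `tv0 + k t`, `k` in mm^3/day.
#'   \item `exponential`: `tv0 e^{k t}`.
#'   \item `logistic`: `tv0 K e^{k t} / (K + tv0 (e^{k t} - 1))`, plateau `K`
#'     in mm^3.
#'   \item `gompertz`: `tv0 exp((alpha/beta)(1 - e^{-beta t}))`, plateau
#'     `tv0 e^{alpha/beta}`.
#'   \item `simeoni`: unperturbed exponential-then-linear growth,
#'     `dTV/dt = l0 TV / [1 + (l0 TV / l1)^psi]^{1/psi}` with smooth switch
#'     exponent `psi` (default 20); `l0` in 1/day, `l1` in mm^3/day.
#' }
#'
#' @param model_id One of `"linear"`, `"exponential"`, `"logistic"`,
#'   `"gompertz"`, `"simeoni"`.
#' @param tv0 Initial volume (same scale as the data; > 0).
#' @param ... Model-specific rate parameters (see Details), all > 0.
#' @return An object of class `classical_params`.
#' @export
classical_params <- function(model_id, tv0, ...) {
  model_id <- match.arg(model_id, .classical_models)
  extra <- list(...)
  need <- switch(model_id,
                 linear = "k", exponential = "k", logistic = c("k", "K"),
                 gompertz = c("alpha", "beta"), simeoni = c("l0", "l1"))
  missing <- setdiff(need, names(extra))
  if (length(missing))
    stop("model '", model_id, "' requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (model_id == "simeoni" && is.null(extra$psi)) extra$psi <- 20
  vals <- c(list(tv0 = tv0), extra[c(need, if (model_id == "simeoni") "psi")])
  for (nm in names(vals))
    if (!is.finite(vals[[nm]]) || vals[[nm]] <= 0)
      stop("parameter '", nm, "' must be positive and finite", call. = FALSE)
  structure(c(list(model_id = model_id), vals), class = "classical_params")
}

#' Number of free parameters of a classical model (used for adjusted R^2 / AIC)
#' @param model_id Model identifier.
#' @return Integer count including `tv0` (psi is fixed, not counted).
#' @export
n_params_classical <- function(model_id) {
  switch(match.arg(model_id, .classical_models),
         linear = 2L, exponential = 2L, logistic = 3L, gompertz = 3L,
         simeoni = 3L)
}

#' Predict tumor volume under a classical growth model
#'
#' @param params A [classical_params()] object.
#' @param times Non-negative, non-decreasing times (days).
#' @param rtol,atol Solver tolerances (simeoni only).
#' @return Numeric vector of volumes at `times`.
#' @export
predict_classical <- function(params, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "classical_params"))
  t <- as.numeric(times)
  with(params, switch(model_id,
    linear = tv0 + k * t,
    exponential = tv0 * exp(k * t),
    logistic = tv0 * K * exp(k * t) / (K + tv0 * (exp(k * t) - 1)),
    gompertz = tv0 * exp((alpha / beta) * (1 - exp(-beta * t))),
    simeoni = solve_simeoni_cpp(tv0, l0, l1, psi, t, rtol, atol),
    stop("unknown model_id '", model_id, "'", call. = FALSE)))
}
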