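# Dynamical analysis of the tumor-angiogenesis-resources system and the
# virtual-treatment exploration machinery (scenarios, LHS sweep, Sobol
# indices).

.final_rhs <- function(p, s) {
  c(tv = p$lambda * s[1] * s[3] - p$k_death * s[1],
    ang = p$k_ang * s[1] - p$k_death * s[2],
    res = p$k_res * s[2] - p$k_consumption * s[1])
}

.final_jacobian <- function(p, s) {
  matrix(c(p$lambda * s[3] - p$k_death, 0, p$lambda * s[1],
           p$k_ang, -p$k_death, 0,
           -p$k_consumption, p$k_res, 0),
         3, 3, byrow = TRUE,
         dimnames = list(c("tv", "ang", "res"), c("tv", "ang", "res")))
}

#' Equilibria of the tumor-angiogenesis-resources system
#'
#' Solves the stationarity conditions: `TV = ANG = 0` with RES arbitrary is
#' always an equilibrium family (the tumor-free states). A positive
#' equilibrium (a line with `RES* = k_death / lambda`, `ANG = k_ang TV /
#' k_death`, TV free) exists only on the measure-zero parameter set where
#' `k_res k_ang = k_consumption k_death`; the report carries the condition
#' residual. Jacobian eigenvalues are evaluated at representative points and
#' each reported point is verified to satisfy `|dState/dt| < tol`.
#'
#' @param params A [final_model_params()] object.
#' @param tol Vector-field residual tolerance (default 1e-10).
#' @return Object of class `equilibrium_report`: list with `tumor_free`
#'   (representative states + eigenvalues), `positive_exists`,
#'   `condition_residual` (`k_res k_ang - k_consumption k_death`),
#'   `condition_relative` (scaled by `k_consumption k_death`), and (when it
#'   exists) `positive_family` with `res_star` and a representative point.
#' @export
equilibria <- function(params, tol = 1e-10) {
  stopifnot(inherits(params, "final_model_params"))
  p <- unclass(params)
  resid <- p$k_res * p$k_ang - p$k_consumption * p$k_death
  rel <- resid / (p$k_consumption * p$k_death)
  exists_pos <- abs(rel) < 1e-8

  reps <- list(origin = c(tv = 0, ang = 0, res = 0),
               tumor_free_res1 = c(tv = 0, ang = 0, res = 1))
  tumor_free <- lapply(reps, function(s) {
    stopifnot(max(abs(.final_rhs(p, s))) < tol)
    list(state = s, eigenvalues = eigen(.final_jacobian(p, s),
                                        only.values = TRUE)$values)
  })
  out <- list(tumor_free = tumor_free,
              positive_exists = exists_pos,
              condition_residual = resid,
              condition_relative = rel,
              tol = tol)
  if (exists_pos) {
    res_star <- p$k_death / p$lambda
    tv_rep <- p$tv0
    s <- c(tv = tv_rep, ang = p$k_ang * tv_rep / p$k_death, res = res_star)
    stopifnot(max(abs(.final_rhs(p, s))) < max(tol, 1e-8 * tv_rep))
    out$positive_family <- list(res_star = res_star, representative = s,
                                eigenvalues = eigen(.final_jacobian(p, s),
                                                    only.values = TRUE)$values)
  }
  structure(out, class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("equilibrium_report\n")
  cat("  tumor-free family TV = ANG = 0 (any RES); eigenvalues at RES = 1:",
      paste(signif(Re(x$tumor_free$tumor_free_res1$eigenvalues), 3),
            collapse = ", "), "\n")
  cat(sprintf("  positive equilibrium: %s (condition residual %.3g, relative %.3g)\n",
              if (x$positive_exists) "exists (line of equilibria)" else "none",
              x$condition_residual, x$condition_relative))
  invisible(x)
}

#' Ensemble of trajectories from perturbed initial conditions
#'
#' Integrates `n` solutions whose initial states are Gaussian perturbations
#' of `(tv0, 1, 1)` with the given variances; draws with non-positive initial
#' tumor volume are redrawn (counted in `n_redrawn`).
#'
#' @param params A [final_model_params()] object.
#' @param times Output time grid (days), default 0..100 by 0.5.
#' @param n Number of trajectories (default 50).
#' @param variances Named variances for the initial perturbation, default
#'   `c(tv = 1, ang = 0.1, res = 0.1)`.
#' @param seed Integer seed.
#' @return List with `typical` (unperturbed trajectory), `trajectories`
#'   (list of data.frames), `inits` (matrix), `n_redrawn`, and `spread`
#'   (per-time min/max/relative spread of TV across the ensemble).
#' @export
integrate_ensemble <- function(params, times = seq(0, 100, by = 0.5), n = 50,
                               variances = c(tv = 1, ang = 0.1, res = 0.1),
                               seed = 1) {
  stopifnot(inherits(params, "final_model_params"), all(variances >= 0))
  set.seed(as.integer(seed))
  typical <- simulate_final_model(params, times)
  sds <- sqrt(variances[c("tv", "ang", "res")])
  inits <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("tv", "ang", "res")))
  trajs <- vector("list", n)
  n_redrawn <- 0L
  for (i in seq_len(n)) {
    repeat {
      ini <- c(params$tv0, 1, 1) + stats::rnorm(3, 0, sds)
      if (ini[1] > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    inits[i, ] <- ini
    trajs[[i]] <- simulate_final_model(params, times, init = ini)
  }
  tv_mat <- vapply(trajs, function(tr) tr$tv, numeric(length(times)))
  spread <- data.frame(time = times,
                       tv_min = apply(tv_mat, 1, min),
                       tv_max = apply(tv_mat, 1, max),
                       tv_typical = typical$tv)
  spread$rel_spread <- (spread$tv_max - spread$tv_min) / spread$tv_typical
  list(typical = typical, trajectories = trajs, inits = inits,
       n_redrawn = n_redrawn, spread = spread)
}

#' One-at-a-time local sensitivity analysis
#'
#' Each parameter is scaled up and down by `fraction`; TV, ANG and RES at
#' `t_eval` days are reported as percentage change versus the reference
#' solution.
#'
#' @param params A [final_model_params()] object.
#' @param fraction Perturbation fraction in (0, 1), default 0.5.
#' @param t_eval Evaluation time (days), default 20.
#' @return data.frame with `parameter`, `direction` (`"+"`/`"-"`),
#'   `multiplier`, `pct_tv`, `pct_ang`, `pct_res`.
#' @export
local_sensitivity <- function(params, fraction = 0.5, t_eval = 20) {
  stopifnot(inherits(params, "final_model_params"),
            fraction > 0, fraction < 1)
  ref <- simulate_final_model(params, c(0, t_eval))
  ref <- as.numeric(ref[nrow(ref), c("tv", "ang", "res")])
  pn <- names(unclass(params))
  rows <- list()
  for (nm in pn) for (mult in c(1 + fraction, 1 - fraction)) {
    p <- unclass(params)
    p[[nm]] <- p[[nm]] * mult
    tr <- simulate_final_model(do.call(final_model_params, p), c(0, t_eval))
    v <- as.numeric(tr[nrow(tr), c("tv", "ang", "res")])
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = nm, direction = if (mult > 1) "+" else "-",
      multiplier = mult,
      pct_tv = 100 * (v[1] / ref[1] - 1),
      pct_ang = 100 * (v[2] / ref[2] - 1),
      pct_res = 100 * (v[3] / ref[3] - 1))
  }
  do.call(rbind, rows)
}

#' Time at which the typical solution reaches half the ethical limit
#'
#' The local sensitivity analysis is most meaningful at the time the tumor
#' reaches about half of the maximum size allowed by the ethics protocol;
#' this helper computes that time for a given parameter set by simulation
#' with linear interpolation between grid points.
#'
#' @param params A [final_model_params()] object.
#' @param upper_limit Ethical limit (mm^3), default 2000.
#' @param t_max Search horizon (days).
#' @return Crossing time in days (or `NA` if not reached by `t_max`).
#' @export
time_to_half_limit <- function(params, upper_limit = 2000, t_max = 150) {
  tt <- seq(0, t_max, by = 0.25)
  tv <- simulate_final_model(params, tt)$tv
  half <- upper_limit / 2
  i <- which(tv >= half)[1]
  if (is.na(i) || i == 1L) return(NA_real_)
  t0 <- tt[i - 1]; t1 <- tt[i]
  t0 + (t1 - t0) * (half - tv[i - 1]) / (tv[i] - tv[i - 1])
}

#' Area under the tumor-volume-versus-time curve
#'
#' Trapezoidal integral of TV over `[t0, t1]` (default days 0 to 100).
#'
#' @param trajectory data.frame with `time` and `tv` covering `[t0, t1]`.
#' @param t0,t1 Integration limits (days).
#' @return AUTC in mm^3 day.
#' @export
autc <- function(trajectory, t0 = 0, t1 = 100) {
  stopifnot(is.data.frame(trajectory), all(c("time", "tv") %in%
                                             names(trajectory)))
  tt <- trajectory$time
  if (min(tt) > t0 + 1e-9 || max(tt) < t1 - 1e-9)
    stop("trajectory does not cover [", t0, ", ", t1, "]", call. = FALSE)
  tv_at <- function(t) stats::approx(tt, trajectory$tv, xout = t)$y
  inside <- tt > t0 & tt < t1
  gt <- c(t0, tt[inside], t1)
  gv <- c(tv_at(t0), trajectory$tv[inside], tv_at(t1))
  sum(diff(gt) * (gv[-1] + gv[-length(gv)]) / 2)
}

#' Virtual single-treatment scenario grid
#'
#' One parameter at a time scaled by `1 +/- 0.25` and `1 +/- 0.75` for the
#' treatment-accessible parameters, plus combination archetypes
#' (anti-angiogenic: lower `k_ang` and `k_res`; cytotoxic: higher `k_death`;
#' resource elimination: higher `k_consumption`), each simulated to
#' `t_end` and summarized by the AUTC and its difference versus the untreated
#' reference.
#'
#' @param params Reference [final_model_params()].
#' @param targets Parameters scanned one at a time.
#' @param t_end Horizon (days), default 100.
#' @param dt Output grid step (days).
#' @return data.frame of class `scenario_result`: `label`, one multiplier
#'   column per parameter, `autc`, `delta_autc` (reference row has 0).
#' @export
treatment_scenarios <- function(params,
                                targets = c("k_ang", "k_res",
                                            "k_consumption", "k_death"),
                                t_end = 100, dt = 0.5) {
  stopifnot(inherits(params, "final_model_params"))
  pn <- names(unclass(params))
  stopifnot(all(targets %in% pn))
  times <- seq(0, t_end, by = dt)
  run <- function(mult) {
    p <- unclass(params)
    for (nm in names(mult)) p[[nm]] <- p[[nm]] * mult[[nm]]
    autc(simulate_final_model(do.call(final_model_params, p), times),
         0, t_end)
  }
  ref_autc <- run(list())
  rows <- list(data.frame(label = "reference", autc = ref_autc))
  for (nm in targets) for (m in c(0.25, 0.75, 1.25, 1.75)) {
    lab <- sprintf("%s x%.2f", nm, m)
    rows[[length(rows) + 1L]] <- data.frame(label = lab,
                                            autc = run(stats::setNames(list(m),
                                                                       nm)))
  }
  combos <- list(
    "anti-angiogenic (k_ang, k_res x0.5)" =
      list(k_ang = 0.5, k_res = 0.5),
    "cytotoxic (k_death x1.75)" = list(k_death = 1.75),
    "resource elimination (k_consumption x1.75)" =
      list(k_consumption = 1.75),
    "combination (k_res x0.5, k_death x1.75)" =
      list(k_res = 0.5, k_death = 1.75))
  for (lab in names(combos))
    rows[[length(rows) + 1L]] <- data.frame(label = lab,
                                            autc = run(combos[[lab]]))
  out <- do.call(rbind, rows)
  out$delta_autc <- out$autc - ref_autc
  class(out) <- c("scenario_result", "data.frame")
  out
}

# Latin hypercube sample on [0,1]^k
.lhs <- function(n, k) {
  vapply(seq_len(k), function(j) (sample.int(n) - stats::runif(n)) / n,
         numeric(n))
}

#' Sobol sensitivity indices by the Saltelli design
#'
#' Generic estimator of first-order and total Sobol indices of
#' `f : [0,1]^k -> R` using two independent uniform sample matrices `A`, `B`
#' and the `k` column-swapped hybrids (`n (k + 2)` evaluations): first-order
#' by the Saltelli-2010 estimator `mean(f(B) (f(AB_j) - f(A))) / V`, total by
#' the Jansen estimator `mean((f(A) - f(AB_j))^2) / (2 V)`. Rows where any
#' evaluation is non-finite are dropped (count reported).
#'
#' @param f Vectorized function taking an `n x k` matrix of unit-cube points
#'   and returning `n` values.
#' @param k Input dimension.
#' @param n Base sample size.
#' @param seed Integer seed.
#' @return List with `indices` (data.frame `first_order`, `total`),
#'   `n_dropped`, `variance`.
#' @export
sobol_saltelli <- function(f, k, n = 256, seed = 1) {
  set.seed(as.integer(seed))
  A <- matrix(stats::runif(n * k), n)
  B <- matrix(stats::runif(n * k), n)
  fA <- f(A)
  fB <- f(B)
  fAB <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    ABj <- A; ABj[, j] <- B[, j]
    fAB[, j] <- f(ABj)
  }
  ok <- is.finite(fA) & is.finite(fB) & apply(is.finite(fAB), 1, all)
  fa <- fA[ok]; fb <- fB[ok]; fab <- fAB[ok, , drop = FALSE]
  ctr <- mean(c(fa, fb))   # centering reduces estimator variance
  fa <- fa - ctr; fb <- fb - ctr; fab <- fab - ctr
  vy <- stats::var(c(fa, fb))
  first <- vapply(seq_len(k), function(j)
    mean(fb * (fab[, j] - fa)) / vy, numeric(1))
  total <- vapply(seq_len(k), function(j)
    mean((fa - fab[, j])^2) / (2 * vy), numeric(1))
  list(indices = data.frame(first_order = first, total = total),
       n_dropped = sum(!ok), variance = vy)
}

#' Global exploration: LHS parameter sweep and Sobol sensitivity indices
#'
#' Two complementary analyses over a log-uniform box around the reference
#' values of the target parameters (default `k_consumption`, `k_ang`,
#' `k_res`, spanning x1/4 to x4):
#' \itemize{
#'   \item a Latin hypercube sweep of `n` combinations, each summarized by
#'     the AUTC to `t_end` and its delta versus the reference (the
#'     virtual-combination-therapy picture);
#'   \item first-order and total Sobol indices of the AUTC, estimated with
#'     the Saltelli design (base sample `n_sobol`, `n_sobol (k + 2)` model
#'     runs) and the Saltelli-2010/Jansen estimators, on a separate sample.
#' }
#'
#' @param params Reference [final_model_params()].
#' @param targets Parameters explored.
#' @param n LHS combinations (default 200).
#' @param span Multiplier range `c(lo, hi)` applied to each reference value
#'   (log-uniform), default `c(0.25, 4)`.
#' @param n_sobol Saltelli base-sample size (default 256).
#' @param t_end,dt Simulation horizon and grid step (days).
#' @param seed Integer seed.
#' @return List with `scenarios` (data.frame: multipliers, parameter values,
#'   `autc`, `delta_autc`, `failed` flag), `sobol` (data.frame: `parameter`,
#'   `first_order`, `total`) or `NULL` with `degenerate = TRUE` when the span
#'   collapses, `n_failed`, and `reference_autc`.
#' @export
global_exploration <- function(params,
                               targets = c("k_consumption", "k_ang", "k_res"),
                               n = 200, span = c(0.25, 4), n_sobol = 256,
                               t_end = 100, dt = 0.5, seed = 1) {
  stopifnot(inherits(params, "final_model_params"),
            all(targets %in% names(unclass(params))),
            length(span) == 2L, all(span > 0), span[1] <= span[2])
  set.seed(as.integer(seed))
  k <- length(targets)
  times <- seq(0, t_end, by = dt)
  ref_traj <- simulate_final_model(params, times)
  ref_autc <- autc(ref_traj, 0, t_end)
  lo <- log(span[1]); hi <- log(span[2])

  run_mult <- function(mult) {  # mult: named multipliers; NA on failure
    p <- unclass(params)
    for (j in seq_along(targets)) p[[targets[j]]] <- p[[targets[j]]] * mult[j]
    tr <- try(simulate_final_model(do.call(final_model_params, p), times),
              silent = TRUE)
    if (inherits(tr, "try-error")) return(NA_real_)
    autc(tr, 0, t_end)
  }

  degenerate <- span[1] == span[2]
  u <- .lhs(n, k)
  mults <- exp(lo + (hi - lo) * u)
  colnames(mults) <- targets
  autcs <- apply(mults, 1, run_mult)
  scen <- as.data.frame(mults)
  names(scen) <- paste0("mult_", targets)
  for (j in seq_len(k))
    scen[[targets[j]]] <- unclass(params)[[targets[j]]] * mults[, j]
  scen$autc <- autcs
  scen$delta_autc <- autcs - ref_autc
  scen$failed <- !is.finite(autcs)

  sobol <- NULL
  n_failed_sobol <- 0L
  if (!degenerate) {
    # AUTC spans orders of magnitude over the exploration box (growth is
    # near-exponential in the explored rates), so the variance decomposition
    # is performed on log AUTC; raw-scale indices would be dominated by the
    # single most explosive corner of the box
    tox <- function(U) exp(lo + (hi - lo) * U)
    g <- function(U) log(apply(tox(U), 1, run_mult))
    ss <- sobol_saltelli(g, k, n = n_sobol, seed = seed + 1L)
    n_failed_sobol <- ss$n_dropped
    sobol <- data.frame(parameter = targets,
                        first_order = ss$indices$first_order,
                        total = ss$indices$total)
  }
  list(scenarios = scen, sobol = sobol, degenerate = degenerate,
       n_failed = sum(scen$failed), n_failed_sobol = n_failed_sobol,
       reference_autc = ref_autc, scale = "log")
}
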