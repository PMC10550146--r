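# Nonlinear mixed-effects estimation by SAEM.
#
# Statistical model: individual parameters p_i = theta * exp(eta_i) with
# eta_i ~ N(0, diag(omega^2)) on the log scale (log-normal IIV), observation
# model log y_ij = log f(t_ij; p_i) + eps_ij, eps ~ N(0, sigma^2) (additive
# error on the log scale). ANG and RES are latent; only TV enters the
# likelihood. Working scale throughout: phi_i = log p_i, mu = log theta.

#' Population model specification for SAEM
#'
#' @param model `"final"` or a classical model id.
#' @param theta Initial fixed effects: a [final_model_params()] /
#'   [classical_params()] object. For `model = "final"` the default initial
#'   values are deliberately generic (not the published estimates):
#'   `tv0` from the data at fit time, rates at round order-of-magnitude
#'   guesses.
#' @param iiv Names of parameters with estimated inter-individual variability;
#'   default: all parameters except `k_res` for the final model (IIV on
#'   `k_res` is associated with instabilities), all parameters for classical
#'   models.
#' @param omega_init Initial log-scale IIV SD (scalar or named vector).
#' @param sigma_init Initial residual SD on the log scale.
#' @return Object of class `nlme_spec`.
#' @export
nlme_spec <- function(model = "final", theta = NULL, iiv = NULL,
                      omega_init = 0.3, sigma_init = 0.3) {
  if (identical(model, "final")) {
    if (is.null(theta))
      theta <- final_model_params(tv0 = 70, lambda = 0.03, k_ang = 1e-3,
                                  k_res = 0.2, k_consumption = 1e-3,
                                  k_death = 0.02)
    stopifnot(inherits(theta, "final_model_params"))
    pnames <- names(unclass(theta))
    if (is.null(iiv)) iiv <- setdiff(pnames, "k_res")
  } else {
    model <- match.arg(model, .classical_models)
    if (is.null(theta))
      stop("theta is required for classical models", call. = FALSE)
    stopifnot(inherits(theta, "classical_params"),
              identical(theta$model_id, model))
    pnames <- setdiff(names(unclass(theta)), c("model_id", "psi"))
    if (is.null(iiv)) iiv <- pnames
  }
  stopifnot(all(iiv %in% pnames), sigma_init > 0, all(omega_init >= 0))
  om <- if (length(omega_init) == 1L)
    stats::setNames(rep(omega_init, length(iiv)), iiv)
  else {
    stopifnot(all(iiv %in% names(omega_init)))
    omega_init[iiv]
  }
  structure(list(model = model, theta = theta, pnames = pnames, iiv = iiv,
                 omega_init = om, sigma_init = sigma_init),
            class = "nlme_spec")
}

#' SAEM tuning settings
#'
#' @param n_explore Exploratory-phase iterations (step size 1).
#' @param n_smooth Smoothing-phase iterations (step size `1/k^0.7`).
#' @param n_mcmc MCMC transitions per animal per iteration.
#' @param anneal Exploratory-phase variance annealing factor: variance
#'   estimates may shrink by at most this factor per iteration (guards
#'   against premature collapse of omega / sigma).
#' @param omega_floor Artificial residual variability used for parameters
#'   without IIV (decays to this floor; the MCMC still needs a nonzero
#'   conditional spread to move their population values).
#' @param rtol,atol ODE solver tolerances used inside estimation.
#' @return List of settings.
#' @export
saem_settings <- function(n_explore = 300, n_smooth = 200, n_mcmc = 3,
                          anneal = 0.95, omega_floor = 0.05,
                          rtol = 1e-6, atol = 1e-8) {
  list(n_explore = n_explore, n_smooth = n_smooth, n_mcmc = n_mcmc,
       anneal = anneal, omega_floor = omega_floor, rtol = rtol, atol = atol)
}

# structural model abstraction on the log-parameter scale; `code` is the
# integer model id used by the C++ kernels
.model_codes <- c(final = 1L, linear = 2L, exponential = 3L, logistic = 4L,
                  gompertz = 5L, simeoni = 6L)

.structural <- function(model, rtol = 1e-6, atol = 1e-8) {
  pn <- switch(model,
               final = c("tv0", "lambda", "k_ang", "k_res", "k_consumption",
                         "k_death"),
               linear = c("tv0", "k"), exponential = c("tv0", "k"),
               logistic = c("tv0", "k", "K"),
               gompertz = c("tv0", "alpha", "beta"),
               simeoni = c("tv0", "l0", "l1"))
  code <- .model_codes[[model]]
  list(pnames = pn, code = code,
       predict_log = function(p, times)
         predict_log_cpp(code, as.numeric(p), as.numeric(times), rtol, atol))
}

# observation loglik for one animal given phi (log parameters)
.obs_ll <- function(struct, phi, times, logy, sigma,
                    rtol = 1e-6, atol = 1e-8) {
  obs_ll_cpp(struct$code, as.numeric(phi), times, logy, sigma, rtol, atol)
}

#' Fit a population model by stochastic approximation EM (SAEM)
#'
#' MCMC E-step: per animal, `n_mcmc` Metropolis transitions on the log
#' individual parameters (one independent proposal from the current
#' population distribution, then random-walk proposals with an adaptive
#' scale). Stochastic approximation of the complete-data sufficient
#' statistics with step size 1 during the exploratory phase and `1/k^0.7`
#' during smoothing; exploratory-phase annealing stops omega/sigma from
#' collapsing early. Parameters declared without IIV carry a small artificial
#' variability that decays to `omega_floor` (their population value is still
#' estimated; the artificial spread only services the MCMC).
#'
#' @param dataset A [study_dataset()]; every animal needs >= 2 observations.
#' @param spec An [nlme_spec()].
#' @param settings [saem_settings()].
#' @param seed Integer seed; identical seeds give bit-identical fits.
#' @param init `"pooled"` (default): refine the spec's initial fixed effects
#'   by a naive pooled least-squares fit of the typical curve to all log
#'   observations before starting SAEM (standard practice to land the
#'   stochastic search in the right basin); `"spec"`: use the spec's initial
#'   values as-is.
#' @param init_tv0_from_data Initialize `tv0` from the geometric mean of each
#'   animal's first observation (default TRUE; applied before the pooled
#'   refinement).
#' @return Object of class `nlme_fit`: `theta`, `omega` (estimated IIV SDs),
#'   `sigma`, `ebe` (per-animal MAP parameter matrix, natural scale),
#'   `trace` (iteration history), `converged`, `seed`, plus the internal
#'   data/`spec` needed by [loglik_and_aic()], [rse_and_cv()] and the
#'   diagnostics. `loglik`/`aic` are `NA` until [loglik_and_aic()] is called.
#' @export
saem_fit <- function(dataset, spec, settings = saem_settings(), seed = 1,
                     init = c("pooled", "spec"), init_tv0_from_data = TRUE,
                     n_chains = 16, n_pilot = 100) {
  stopifnot(inherits(dataset, "study_dataset"), inherits(spec, "nlme_spec"))
  init <- match.arg(init)
  set.seed(as.integer(seed))
  struct <- .structural(spec$model, settings$rtol, settings$atol)
  K <- length(struct$pnames)
  profs <- split_animals(dataset)
  N <- length(profs)
  times <- lapply(profs, function(p) as.numeric(p$time))
  logy <- lapply(profs, function(p) log(as.numeric(p$tv)))
  n_obs <- sum(lengths(logy))

  mu0 <- log(unlist(unclass(spec$theta)[struct$pnames]))
  if (init_tv0_from_data && "tv0" %in% struct$pnames)
    mu0["tv0"] <- mean(vapply(logy, `[`, numeric(1), 1))
  cand <- if (init == "pooled") {
    top <- .pooled_init_multi(struct, mu0, times, logy, n_top = 2L)
    # the system has soft rescaling symmetries in (lambda, k_res,
    # k_consumption) and (k_ang, k_res), broken only by the unit initial
    # conditions of ANG and RES; a pooled fit can land anywhere along these
    # near-flat directions, so pilot chains are seeded across them and ranked
    # by marginal likelihood
    cc <- c(top, .ridge_variants(top[[1]], struct$pnames))
    cc[seq_len(min(length(cc), n_chains))]
  } else list(mu0)

  iiv <- struct$pnames %in% spec$iiv
  omega0 <- rep(settings$omega_floor, K)
  omega0[iiv] <- spec$omega_init[struct$pnames[iiv]]
  mk_state <- function(mu) {
    phi <- matrix(rep(mu, each = N), N, K,
                  dimnames = list(names(profs), struct$pnames))
    ll <- vapply(seq_len(N), function(i)
      .obs_ll(struct, phi[i, ], times[[i]], logy[[i]], spec$sigma_init),
      numeric(1))
    list(mu = mu, omega = omega0, sigma = spec$sigma_init, phi = phi,
         ll_cur = ll, prop_scale = rep(0.4, N), s1 = colSums(phi),
         s2 = colSums(phi^2), se = n_obs * spec$sigma_init^2, it = 0L,
         trace = NULL)
  }

  # multiple candidate basins: tournament of short pilot chains ranked by a
  # fast importance-sampling marginal likelihood (wide field, short pilots;
  # survivors continue), then the winner runs to the end
  if (length(cand) > 1L) {
    n_a <- max(30L, n_pilot %/% 2L)
    pilots <- lapply(cand, function(mu)
      .saem_run(mk_state(mu), n_a, 0L, struct, spec, settings, iiv,
                times, logy, n_obs))
    score <- vapply(pilots, function(st)
      .with_fixed_rng(9902L, .quick_marginal_ll(st, struct, iiv, times, logy,
                                                M = 100)), numeric(1))
    keep <- order(score, decreasing = TRUE)[seq_len(min(4L, length(pilots)))]
    pilots <- lapply(pilots[keep], function(st)
      .saem_run(st, n_pilot, 0L, struct, spec, settings, iiv,
                times, logy, n_obs))
    score <- vapply(pilots, function(st) {
      om_eff <- rep(settings$omega_floor, K)
      om_eff[iiv] <- st$omega[iiv]
      ph <- .map_phi(struct, st$phi, st$mu, om_eff, st$sigma, times, logy)
      .laplace_ll(struct, ph, st$mu, st$omega[iiv], iiv, st$sigma,
                  times, logy)
    }, numeric(1))
    state <- pilots[[which.max(score)]]
    n_explore_left <- max(settings$n_explore - n_a - n_pilot, 50L)
  } else {
    state <- mk_state(cand[[1]])
    n_explore_left <- settings$n_explore
  }
  state <- .saem_run(state, n_explore_left, settings$n_smooth, struct, spec,
                     settings, iiv, times, logy, n_obs)

  # deterministic GLS polish of the fixed effects followed by a short SAEM
  # re-equilibration of the variance parameters (twice)
  if (init == "pooled") {
    for (round in 1:2) {
      mu_before <- state$mu
      state <- .gls_polish(state, struct, iiv, times, logy, settings)
      if (sqrt(sum((state$mu - mu_before)^2)) < 1e-3) break
      state$ll_cur <- vapply(seq_along(times), function(i)
        .obs_ll(struct, state$phi[i, ], times[[i]], logy[[i]], state$sigma),
        numeric(1))
      state <- .saem_run(state, 60L, 60L, struct, spec, settings, iiv,
                         times, logy, n_obs)
    }
  }

  mu <- state$mu; omega <- state$omega; sigma <- state$sigma
  phi <- state$phi; trace <- state$trace
  n_iter <- nrow(trace)
  theta <- exp(mu)
  names(theta) <- struct$pnames
  om_out <- stats::setNames(omega[iiv], struct$pnames[iiv])
  collapsed <- om_out < 0.01
  if (any(collapsed)) {
    warning("IIV collapsed for: ",
            paste(names(om_out)[collapsed], collapse = ", "),
            "; effectively fixed to 0", call. = FALSE)
  }
  # convergence heuristic: relative drift of theta over the last 20% of the
  # smoothing phase
  tail_ix <- seq(max(1L, n_iter - ceiling(max(settings$n_smooth, 5L) / 5)),
                 n_iter)
  drift <- apply(trace[tail_ix, seq_len(K), drop = FALSE], 2,
                 function(z) diff(range(z)) / max(abs(mean(z)), 1e-12))
  converged <- all(drift < 0.10)

  fit <- structure(list(spec = spec, model = spec$model, theta = theta,
                        omega = om_out, sigma = sigma, mu = mu,
                        iiv_mask = iiv, struct_pnames = struct$pnames,
                        phi = phi, ebe = NULL,
                        times = times, logy = logy, animal_ids = names(profs),
                        n_obs = n_obs, trace = trace, converged = converged,
                        loglik = NA_real_, aic = NA_real_,
                        settings = settings, seed = as.integer(seed)),
                   class = "nlme_fit")
  fit$ebe <- .compute_ebes(fit)
  fit
}

# Core SAEM iteration loop operating on a chain state; the iteration counter
# (annealing, artificial-variability decay, exploratory/smoothing switch)
# carries across calls so a pilot chain can be continued seamlessly.
.saem_run <- function(state, n_explore, n_smooth, struct, spec, settings,
                      iiv, times, logy, n_obs) {
  K <- length(state$mu)
  omega_art0 <- 0.3
  art_decay <- 0.985
  smooth_start <- state$it + n_explore  # global iteration index of last explore
  n_new <- n_explore + n_smooth
  trace_new <- matrix(NA_real_, n_new, K + sum(iiv) + 1,
                      dimnames = list(NULL, c(struct$pnames,
                                              paste0("omega_",
                                                     struct$pnames[iiv]),
                                              "sigma")))
  N <- nrow(state$phi)
  for (step in seq_len(n_new)) {
    it <- state$it + step
    explore <- it <= smooth_start
    om_eff <- state$omega
    if (any(!iiv))
      om_eff[!iiv] <- max(omega_art0 * art_decay^it, settings$omega_floor)

    res2 <- saem_estep_cpp(struct$code, state$phi, state$ll_cur, state$mu,
                           om_eff, state$sigma, state$prop_scale, times, logy,
                           settings$n_mcmc, compwise = (it %% 5L == 0L),
                           settings$rtol, settings$atol)
    bad <- !is.finite(res2)
    if (any(bad)) res2[bad] <- lengths(logy)[bad] * state$sigma^2

    gamma <- if (explore) 1 else 1 / (it - smooth_start)^0.7
    state$s1 <- (1 - gamma) * state$s1 + gamma * colSums(state$phi)
    state$s2 <- (1 - gamma) * state$s2 + gamma * colSums(state$phi^2)
    state$se <- (1 - gamma) * state$se + gamma * sum(res2)

    state$mu <- state$s1 / N
    v <- pmax(state$s2 / N - state$mu^2, 1e-8)
    if (explore) {  # annealing: variances shrink by at most `anneal` per iter
      v <- pmax(v, settings$anneal * state$omega^2)
      sig2 <- max(state$se / n_obs, settings$anneal * state$sigma^2)
    } else sig2 <- state$se / n_obs
    state$omega[iiv] <- sqrt(v[iiv])
    state$sigma <- sqrt(sig2)
    state$ll_cur <- -0.5 * res2 / state$sigma^2 -
      lengths(logy) * (log(state$sigma) + 0.5 * log(2 * pi))
    trace_new[step, ] <- c(exp(state$mu), state$omega[iiv], state$sigma)
  }
  state$it <- state$it + n_new
  state$trace <- rbind(state$trace, trace_new)
  state
}

# initial-value variants along the approximate rescaling symmetries of the
# tumor-angiogenesis-resources system: RES -> RES/c maps (lambda, k_res,
# k_consumption) -> (c lambda, k_res/c, k_consumption/c); ANG -> ANG/b maps
# (k_ang, k_res) -> (k_ang/b, b k_res)
.ridge_variants <- function(mu, pnames) {
  if (!all(c("lambda", "k_res", "k_consumption", "k_ang", "k_death")
           %in% pnames))
    return(list())
  out <- list()
  for (cb in list(c(2, 1), c(0.5, 1), c(1, 2), c(1, 0.5))) {
    v <- mu
    v["lambda"] <- v["lambda"] + log(cb[1])
    v["k_res"] <- v["k_res"] - log(cb[1]) + log(cb[2])
    v["k_consumption"] <- v["k_consumption"] - log(cb[1])
    v["k_ang"] <- v["k_ang"] - log(cb[2])
    out[[length(out) + 1L]] <- v
  }
  # k_death is weakly identified by a pooled mean curve; scan it while
  # preserving the net early growth rate lambda - k_death (RES starts at 1),
  # alone and crossed with the RES-scale direction
  kd_scan <- function(mu, d) {
    v <- mu
    kd_old <- exp(mu["k_death"])
    kd_new <- d * kd_old
    la_new <- exp(mu["lambda"]) - kd_old + kd_new
    if (la_new <= 0) return(NULL)
    v["k_death"] <- log(kd_new)
    v["lambda"] <- log(la_new)
    v
  }
  for (d in c(0.25, 0.5, 2)) {
    v <- kd_scan(mu, d)
    if (!is.null(v)) out[[length(out) + 1L]] <- v
  }
  for (d in c(0.25, 0.5)) for (cc in c(0.5, 2)) {
    v <- kd_scan(mu, d)
    if (is.null(v)) next
    v["lambda"] <- v["lambda"] + log(cc)
    v["k_res"] <- v["k_res"] - log(cc)
    v["k_consumption"] <- v["k_consumption"] - log(cc)
    out[[length(out) + 1L]] <- v
  }
  out
}

# evaluate expr under a fixed RNG state, restoring the ambient stream after
# (used to compare marginal-likelihood estimates with common random numbers)
.with_fixed_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = .GlobalEnv))
  expr
}

# fast importance-sampling marginal log-likelihood used only to rank pilot
# chains: proposal centered at each animal's current phi draw, spread from
# the current omega (no EBE optimization, modest sample count)
.quick_marginal_ll <- function(state, struct, iiv, times, logy, M = 150,
                               df = 5) {
  ki <- which(iiv)
  scale <- pmax(0.5 * state$omega[ki], 0.05)
  ll <- 0
  for (i in seq_along(times)) {
    z <- matrix(stats::rt(M * length(ki), df), M)
    phi_s <- matrix(rep(state$phi[i, ], each = M), M)
    phi_s[, ki] <- phi_s[, ki] + sweep(z, 2, scale, `*`)
    phi_s[, !iiv] <- matrix(rep(state$mu[!iiv], each = M), M)
    lobs <- obs_ll_batch_cpp(struct$code, phi_s, times[[i]], logy[[i]],
                             state$sigma, 1e-6, 1e-8)
    lpri <- rowSums(matrix(stats::dnorm(phi_s[, ki],
                                        rep(state$mu[ki], each = M),
                                        rep(state$omega[ki], each = M),
                                        log = TRUE), M))
    lq <- rowSums(matrix(stats::dt(z, df, log = TRUE), M)) - sum(log(scale))
    lw <- lobs + lpri - lq
    mx <- max(lw)
    ll <- ll + mx + log(mean(exp(lw - mx)))
  }
  ll
}

# Naive pooled least-squares refinement of the initial fixed effects: fit the
# typical curve to the pooled log observations. Sacrifice dropout truncates
# fast growers, so the late pooled mean is biased toward slow animals; only
# times at which at least `min_frac` of the animals are still under follow-up
# enter the objective. The typical model is solved once per objective
# evaluation on the union of the retained times.
.pooled_init_multi <- function(struct, mu0, times, logy, min_frac = 0.7,
                               n_top = 4L) {
  N <- length(times)
  last <- vapply(times, max, numeric(1))
  tmax <- stats::quantile(last, 1 - min_frac, names = FALSE)
  keep <- lapply(times, function(tt) tt <= tmax)
  if (sum(unlist(keep)) < 20) keep <- lapply(times, function(tt) tt <= Inf)
  ut <- sort(unique(unlist(Map(`[`, times, keep))))
  y <- unlist(Map(`[`, logy, keep))
  ii <- match(unlist(Map(`[`, times, keep)), ut)
  # mild ridge toward the generic starting values (log-scale SD 1.5) keeps the
  # 6-parameter typical-curve fit, which is weakly identified on a short
  # smooth curve, out of absurd corners of the parameter space
  obj <- function(mu) {
    lf <- try(struct$predict_log(exp(mu), ut), silent = TRUE)
    if (inherits(lf, "try-error") || any(!is.finite(lf))) return(1e10)
    sum((y - lf[ii])^2) / 0.09 + sum(((mu - mu0) / 1.5)^2)
  }
  starts <- .init_starts(struct, mu0, ut, y, ii)
  sols <- list(list(par = mu0, value = obj(mu0)))
  for (s in starts) {
    o <- try(stats::optim(s, obj, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-9)),
             silent = TRUE)
    if (!inherits(o, "try-error") && is.finite(o$value))
      sols[[length(sols) + 1L]] <- o[c("par", "value")]
  }
  sols <- sols[order(vapply(sols, `[[`, numeric(1), "value"))]
  # deduplicate near-identical optima (Euclidean distance in log space)
  uniq <- list()
  for (s in sols) {
    if (!any(vapply(uniq, function(u)
      sqrt(sum((u$par - s$par)^2)) < 0.35, logical(1))))
      uniq[[length(uniq) + 1L]] <- s
    if (length(uniq) >= n_top) break
  }
  # polish the incumbent
  o2 <- try(stats::optim(uniq[[1]]$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 3000, reltol = 1e-11)),
            silent = TRUE)
  if (!inherits(o2, "try-error") && is.finite(o2$value) &&
      o2$value < uniq[[1]]$value)
    uniq[[1]] <- o2[c("par", "value")]
  lapply(uniq, `[[`, "par")
}

# multi-start grid for the pooled typical-curve fit. For the final model the
# early log-slope of the pooled data ties lambda - k_death (RES starts at 1),
# so lambda is slaved to each candidate k_death; the remaining rate constants
# scan order-of-magnitude combinations around plausible preclinical values.
.init_starts <- function(struct, mu0, ut, y, ii) {
  pn <- struct$pnames
  if (!identical(sort(pn), sort(c("tv0", "lambda", "k_ang", "k_res",
                                  "k_consumption", "k_death"))))
    return(list(mu0))
  early <- ut <= stats::quantile(ut, 0.4, names = FALSE)
  s0 <- if (sum(ii %in% which(early)) >= 4) {
    sel <- ii %in% which(early)
    stats::lm.fit(cbind(1, ut[ii[sel]]), y[sel])$coefficients[[2]]
  } else 0.04
  s0 <- max(s0, 5e-3)
  g <- expand.grid(k_death = c(0.005, 0.02, 0.08),
                   k_res = c(0.05, 0.2),
                   k_ang = c(2e-4, 2e-3),
                   k_consumption = c(2e-4, 2e-3))
  lapply(seq_len(nrow(g)), function(r) {
    mu <- mu0
    mu["k_death"] <- log(g$k_death[r])
    mu["lambda"] <- log(s0 + g$k_death[r])
    mu["k_res"] <- log(g$k_res[r])
    mu["k_ang"] <- log(g$k_ang[r])
    mu["k_consumption"] <- log(g$k_consumption[r])
    mu[pn]
  })
}

# MAP individual estimates (posterior modes, log scale) given population
# parameters; phi_start supplies per-animal starting points
.map_phi <- function(struct, phi_start, mu, om_eff, sigma, times, logy) {
  ebe <- phi_start
  for (i in seq_along(times)) {
    obj <- function(phi)
      -(.obs_ll(struct, phi, times[[i]], logy[[i]], sigma) -
          0.5 * sum(((phi - mu) / om_eff)^2))
    o <- try(stats::optim(phi_start[i, ], obj, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-9)),
             silent = TRUE)
    if (!inherits(o, "try-error") && is.finite(o$value))
      ebe[i, ] <- o$par
  }
  ebe
}

# MAP empirical Bayes estimates (posterior mode per animal)
.compute_ebes <- function(fit) {
  struct <- .structural(fit$model, fit$settings$rtol, fit$settings$atol)
  om_eff <- rep(fit$settings$omega_floor, length(fit$mu))
  om_eff[fit$iiv_mask] <- fit$omega
  exp(.map_phi(struct, fit$phi, fit$mu, om_eff, fit$sigma, fit$times,
               fit$logy))
}

# sensitivity of the log-scale predictions to the log parameters at phi
.sens_matrix <- function(struct, phi, times, h = 1e-4) {
  K <- length(phi)
  f0 <- struct$predict_log(exp(phi), times)
  Fm <- matrix(0, length(f0), K)
  for (k in seq_len(K)) {
    up <- phi; up[k] <- up[k] + h
    dn <- phi; dn[k] <- dn[k] - h
    Fm[, k] <- (struct$predict_log(exp(up), times) -
                  struct$predict_log(exp(dn), times)) / (2 * h)
  }
  list(f0 = f0, F = Fm)
}

# deterministic Laplace approximation of the marginal log-likelihood:
# integrate over the random-effect components only (non-IIV parameters are
# fixed effects, held at mu within phi), Gauss-Newton Hessian
.laplace_ll <- function(struct, phi_hat, mu, omega_iiv, iiv, sigma,
                        times, logy) {
  ki <- which(iiv)
  ll <- 0
  for (i in seq_along(times)) {
    s <- try(.sens_matrix(struct, phi_hat[i, ], times[[i]]), silent = TRUE)
    if (inherits(s, "try-error")) return(-Inf)
    r <- logy[[i]] - s$f0
    lobs <- -0.5 * sum(r^2) / sigma^2 -
      length(r) * (log(sigma) + 0.5 * log(2 * pi))
    lpri <- sum(stats::dnorm(phi_hat[i, ki], mu[ki], omega_iiv, log = TRUE))
    Fk <- s$F[, ki, drop = FALSE]
    H <- crossprod(Fk) / sigma^2 + diag(1 / omega_iiv^2,
                                        length(ki))
    ld <- determinant(H, logarithm = TRUE)$modulus
    ll <- ll + lobs + lpri + 0.5 * length(ki) * log(2 * pi) - 0.5 * ld
  }
  ll
}

# FOCE-style GLS polish of the fixed effects: linearize the log predictions
# around the current MAP individual estimates, solve the generalized
# least-squares update for mu in closed form, and keep it only if the
# importance-sampling marginal likelihood improves. This jumps directly along
# the soft (near-flat) parameter directions that the stochastic E/M updates
# traverse very slowly.
.gls_polish <- function(state, struct, iiv, times, logy, settings,
                        max_rounds = 3L) {
  K <- length(state$mu)
  om_eff <- rep(settings$omega_floor, K)
  om_eff[iiv] <- state$omega[iiv]
  om2 <- rep(0, K); om2[iiv] <- state$omega[iiv]^2
  om_iiv <- state$omega[iiv]
  score_of <- function(phi_hat, mu)
    .laplace_ll(struct, phi_hat, mu, om_iiv, iiv, state$sigma, times, logy)
  phi_hat <- .map_phi(struct, state$phi, state$mu, om_eff, state$sigma,
                      times, logy)
  base_score <- score_of(phi_hat, state$mu)
  for (round in seq_len(max_rounds)) {
    A <- matrix(0, K, K); b <- numeric(K)
    ok <- TRUE
    for (i in seq_along(times)) {
      s <- try(.sens_matrix(struct, phi_hat[i, ], times[[i]]), silent = TRUE)
      if (inherits(s, "try-error")) { ok <- FALSE; break }
      V <- s$F %*% (om2 * t(s$F)) + diag(state$sigma^2, nrow(s$F))
      Vi <- try(solve(V), silent = TRUE)
      if (inherits(Vi, "try-error")) { ok <- FALSE; break }
      W <- t(s$F) %*% Vi
      A <- A + W %*% s$F
      b <- b + W %*% (logy[[i]] - s$f0 + s$F %*% phi_hat[i, ])
    }
    if (!ok) break
    mu_full <- try(drop(solve(A, b)), silent = TRUE)
    if (inherits(mu_full, "try-error") || any(!is.finite(mu_full))) break
    names(mu_full) <- names(state$mu)
    # step-halving line search on the GLS direction, scored by the
    # deterministic Laplace marginal likelihood
    best <- NULL
    for (frac in c(1, 0.5, 0.25)) {
      mu_try <- state$mu + frac * (mu_full - state$mu)
      phi_try <- .map_phi(struct, phi_hat, mu_try, om_eff, state$sigma,
                          times, logy)
      sc <- score_of(phi_try, mu_try)
      if (is.finite(sc) && (is.null(best) || sc > best$score))
        best <- list(mu = mu_try, phi = phi_try, score = sc)
    }
    if (is.null(best) || best$score <= base_score + 0.5) break
    moved <- sqrt(sum((best$mu - state$mu)^2))
    state$mu <- best$mu
    state$phi <- best$phi
    phi_hat <- best$phi
    base_score <- best$score
    if (moved < 1e-3) break
  }
  state
}

#' @export
print.nlme_fit <- function(x, ...) {
  cat("nlme_fit (", x$model, " model, SAEM, seed ", x$seed, ")\n", sep = "")
  cat(if (x$converged) "  converged\n" else "  NOT converged (drift > 10%)\n")
  est <- data.frame(estimate = signif(x$theta, 4),
                    iiv_sd = signif(ifelse(x$struct_pnames %in% names(x$omega),
                                           x$omega[x$struct_pnames], NA), 3))
  print(est)
  cat("  sigma (log scale):", signif(x$sigma, 4), "\n")
  if (is.finite(x$aic))
    cat("  loglik:", round(x$loglik, 2), " AIC:", round(x$aic, 2), "\n")
  invisible(x)
}

#' Predicted log tumor volume for one animal at its EBEs
#' @param fit An [saem_fit()] result.
#' @param i Animal index.
#' @param times Times (defaults to the animal's observation times).
#' @return Numeric vector of log-scale predictions.
#' @export
predict_individual_log <- function(fit, i, times = NULL) {
  struct <- .structural(fit$model, fit$settings$rtol, fit$settings$atol)
  if (is.null(times)) times <- fit$times[[i]]
  struct$predict_log(fit$ebe[i, ], times)
}

#' Marginal log-likelihood and AIC by importance sampling
#'
#' Per animal, the marginal likelihood integral over the random effects is
#' estimated by importance sampling with a multivariate t proposal (5 df)
#' centered at the MAP individual estimate with a spread inflated from the
#' population covariance. The AIC counts fixed effects, non-fixed IIV SDs and
#' sigma. The effective sample size of the weights is monitored; if it drops
#' below 5% of `n_importance` for an animal the proposal is widened and that
#' animal re-estimated.
#'
#' @param fit An [saem_fit()] result.
#' @param n_importance Importance samples per animal (default 1000).
#' @param seed Integer seed.
#' @return The fit, with `loglik`, `aic` and `loglik_se` filled in.
#' @export
loglik_and_aic <- function(fit, n_importance = 1000, seed = 1) {
  stopifnot(inherits(fit, "nlme_fit"))
  set.seed(as.integer(seed))
  struct <- .structural(fit$model, fit$settings$rtol, fit$settings$atol)
  iiv <- fit$iiv_mask
  K <- length(fit$mu)
  om <- rep(1e-10, K)  # parameters without IIV integrate as point masses
  om[iiv] <- fit$omega
  ki <- which(iiv)
  df <- 5
  ll <- 0; var_ll <- 0
  for (i in seq_along(fit$times)) {
    mode_phi <- log(fit$ebe[i, ])
    scale <- pmax(0.3 * om[ki], 0.05)
    attempt <- 1L
    repeat {
      z <- matrix(stats::rt(n_importance * length(ki), df), n_importance)
      phi_s <- matrix(rep(mode_phi, each = n_importance), n_importance, K)
      phi_s[, ki] <- phi_s[, ki] +
        sweep(z, 2, scale, `*`)
      lobs <- obs_ll_batch_cpp(struct$code, phi_s, fit$times[[i]],
                               fit$logy[[i]], fit$sigma,
                               fit$settings$rtol, fit$settings$atol)
      lpri <- rowSums(matrix(stats::dnorm(phi_s[, ki],
                                          rep(fit$mu[ki], each = n_importance),
                                          rep(om[ki], each = n_importance),
                                          log = TRUE), n_importance))
      lq <- rowSums(matrix(stats::dt(z, df, log = TRUE), n_importance)) -
        sum(log(scale))
      lw <- lobs + lpri - lq
      mx <- max(lw)
      w <- exp(lw - mx)
      ess <- sum(w)^2 / sum(w^2)
      if (ess >= 0.05 * n_importance || attempt >= 3L) break
      warning("low importance-sampling ESS for animal ", fit$animal_ids[i],
              "; widening proposal", call. = FALSE)
      scale <- scale * 2
      attempt <- attempt + 1L
    }
    ll_i <- mx + log(mean(w))
    ll <- ll + ll_i
    var_ll <- var_ll + stats::var(w) / (n_importance * mean(w)^2)
  }
  n_par <- K + sum(iiv) + 1L
  fit$loglik <- ll
  fit$loglik_se <- sqrt(var_ll)
  fit$aic <- -2 * ll + 2 * n_par
  fit$n_par <- n_par
  fit
}

#' Relative standard errors and IIV coefficients of variation
#'
#' Standard errors come from a linearized Fisher information: the model is
#' linearized in the log individual parameters around each animal's EBE;
#' with `F_i` the resulting sensitivity matrix, the marginal covariance is
#' `V_i = F_i Omega F_i' + sigma^2 I` and the information for the log fixed
#' effects is `sum_i F_i' V_i^{-1} F_i`. Standard errors of the variance
#' parameters use the standard Gaussian variance-part information
#' `0.5 tr(V^{-1} dV V^{-1} dV)`. On the log-parameter scale the SE of
#' `log theta` is directly the relative SE of `theta`, so
#' `RSE% = 100 * SE(log theta)`. A nonparametric bootstrap over animals is
#' available as a fallback when the information matrix is singular.
#'
#' IIV is reported as a coefficient of variation `CV = sqrt(exp(omega^2)-1)`.
#'
#' @param fit An [saem_fit()] result.
#' @param bootstrap_n Bootstrap resamples used only on the singular-FIM
#'   fallback path.
#' @param seed Seed for the bootstrap fallback.
#' @return List with `rse_theta` (%, named), `rse_omega` (%, named),
#'   `rse_sigma` (%), `cv` (IIV CVs, named), and `method`
#'   (`"fim"` or `"bootstrap"`).
#' @export
rse_and_cv <- function(fit, bootstrap_n = 100, seed = 1) {
  stopifnot(inherits(fit, "nlme_fit"))
  struct <- .structural(fit$model, fit$settings$rtol, fit$settings$atol)
  K <- length(fit$mu)
  iiv <- fit$iiv_mask
  ki <- which(iiv)
  om2 <- rep(0, K); om2[ki] <- fit$omega^2
  sig2 <- fit$sigma^2
  N <- length(fit$times)

  Fi <- vector("list", N)
  h <- 1e-4
  for (i in seq_len(N)) {
    phi0 <- log(fit$ebe[i, ])
    f0 <- struct$predict_log(exp(phi0), fit$times[[i]])
    Fm <- matrix(0, length(f0), K)
    for (k in seq_len(K)) {
      up <- phi0; up[k] <- up[k] + h
      dn <- phi0; dn[k] <- dn[k] - h
      Fm[, k] <- (struct$predict_log(exp(up), fit$times[[i]]) -
                    struct$predict_log(exp(dn), fit$times[[i]])) / (2 * h)
    }
    Fi[[i]] <- Fm
  }

  n_var <- length(ki) + 1L
  A_mu <- matrix(0, K, K)
  A_v <- matrix(0, n_var, n_var)  # parameters: omega_k^2 (k in ki), sigma^2
  ok <- TRUE
  for (i in seq_len(N)) {
    Fm <- Fi[[i]]
    V <- Fm %*% (om2 * t(Fm)) + diag(sig2, nrow(Fm))
    Vi <- try(solve(V), silent = TRUE)
    if (inherits(Vi, "try-error")) { ok <- FALSE; break }
    A_mu <- A_mu + t(Fm) %*% Vi %*% Fm
    dV <- c(lapply(ki, function(k) tcrossprod(Fm[, k])),
            list(diag(1, nrow(Fm))))
    for (a in seq_len(n_var)) for (b in seq_len(a)) {
      v <- 0.5 * sum(diag(Vi %*% dV[[a]] %*% Vi %*% dV[[b]]))
      A_v[a, b] <- A_v[a, b] + v
      if (a != b) A_v[b, a] <- A_v[b, a] + v
    }
  }
  cov_mu <- if (ok) try(solve(A_mu), silent = TRUE) else
    structure("singular", class = "try-error")
  cov_v <- if (ok) try(solve(A_v), silent = TRUE) else
    structure("singular", class = "try-error")

  if (inherits(cov_mu, "try-error") || inherits(cov_v, "try-error") ||
      any(!is.finite(diag(as.matrix(cov_mu)))) || any(diag(as.matrix(cov_mu)) < 0)) {
    message("singular information matrix; falling back to bootstrap SEs")
    return(.bootstrap_rse(fit, bootstrap_n, seed))
  }
  se_mu <- sqrt(diag(cov_mu))
  rse_theta <- stats::setNames(100 * se_mu, fit$struct_pnames)
  se_v <- sqrt(diag(cov_v))
  # delta method: omega = sqrt(omega^2) -> se(omega) = se(omega^2)/(2 omega)
  se_om <- se_v[seq_along(ki)] / (2 * fit$omega)
  rse_omega <- stats::setNames(100 * se_om / fit$omega, names(fit$omega))
  se_sig <- se_v[n_var] / (2 * fit$sigma)
  list(rse_theta = rse_theta, rse_omega = rse_omega,
       rse_sigma = 100 * se_sig / fit$sigma,
       cv = sqrt(exp(fit$omega^2) - 1), method = "fim")
}

.bootstrap_rse <- function(fit, B, seed) {
  set.seed(as.integer(seed))
  N <- length(fit$times)
  th <- matrix(NA_real_, B, length(fit$mu))
  om <- matrix(NA_real_, B, length(fit$omega))
  sg <- numeric(B)
  for (b in seq_len(B)) {
    ix <- sample.int(N, N, replace = TRUE)
    phi_b <- fit$phi[ix, , drop = FALSE]
    th[b, ] <- colMeans(phi_b)
    om[b, ] <- apply(phi_b[, fit$iiv_mask, drop = FALSE], 2, stats::sd)
    sg[b] <- fit$sigma
  }
  list(rse_theta = stats::setNames(100 * apply(th, 2, stats::sd),
                                   fit$struct_pnames),
       rse_omega = stats::setNames(100 * apply(om, 2, stats::sd) / fit$omega,
                                   names(fit$omega)),
       rse_sigma = NA_real_,
       cv = sqrt(exp(fit$omega^2) - 1), method = "bootstrap")
}

# rebuild a minimal nlme_fit from the CLI's serialized fit.json fields; used
# by `oscitumor diagnose` so diagnostics can run without re-estimating
.fit_from_json <- function(fj, dataset) {
  struct <- .structural(fj$model)
  profs <- split_animals(dataset)
  times <- lapply(profs, function(p) as.numeric(p$time))
  logy <- lapply(profs, function(p) log(as.numeric(p$tv)))
  theta <- unlist(fj$theta)[struct$pnames]
  omega <- unlist(fj$omega)
  iiv <- struct$pnames %in% names(omega)
  ebe <- as.matrix(as.data.frame(fj$ebe))[, struct$pnames, drop = FALSE]
  if (nrow(ebe) != length(profs))
    stop("fit.json EBEs do not match the dataset's animals", call. = FALSE)
  structure(list(spec = NULL, model = fj$model, theta = theta, omega = omega,
                 sigma = fj$sigma, mu = log(theta), iiv_mask = iiv,
                 struct_pnames = struct$pnames, phi = log(ebe), ebe = ebe,
                 times = times, logy = logy, animal_ids = names(profs),
                 n_obs = sum(lengths(logy)), trace = NULL, converged = TRUE,
                 loglik = NA_real_, aic = NA_real_,
                 settings = saem_settings(),
                 seed = if (is.null(fj$seed)) 0L else fj$seed),
            class = "nlme_fit")
}
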