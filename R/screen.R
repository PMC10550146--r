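# Empirical oscillation screen: per-animal classical fits vs a smoothing
# spline reference, half-periods of the difference signal, a white-noise
# simulation null, and a KS uniformity test of the null percentiles.

.screen_candidates <- c("linear", "exponential", "logistic", "gompertz",
                        "simeoni")

# build a classical_params object without constructor positivity checks:
# screening fits are unconstrained least squares and may legitimately land on
# boundary/negative rates (e.g. a flat linear fit).
.raw_classical <- function(model_id, par) {
  p <- c(list(model_id = model_id), as.list(par))
  if (model_id == "simeoni" && is.null(p$psi)) p$psi <- 20
  structure(p, class = "classical_params")
}

# Least-squares fit of one classical model to (t, y) on the transformed scale.
# Returns list(params, sse, n_par) or NULL on failure.
.fit_classical_one <- function(model_id, t, y) {
  n <- length(t)
  res <- switch(model_id,
    linear = {
      fit <- stats::lm.fit(cbind(1, t), y)
      list(par = c(tv0 = fit$coefficients[[1]], k = fit$coefficients[[2]]),
           sse = sum(fit$residuals^2))
    },
    exponential = {
      cf <- stats::lm.fit(cbind(1, t), log(y))$coefficients
      st <- list(tv0 = exp(cf[[1]]), k = max(cf[[2]], 1e-6))
      .nls_sse(y ~ tv0 * exp(k * t), data = list(t = t, y = y), start = st)
    },
    logistic = {
      cf <- stats::lm.fit(cbind(1, t), log(y))$coefficients
      st <- list(tv0 = max(min(y), 1e-4), k = max(cf[[2]], 0.01),
                 K = max(y) * 1.2)
      .nls_sse(y ~ tv0 * K * exp(k * t) / (K + tv0 * (exp(k * t) - 1)),
               data = list(t = t, y = y), start = st,
               lower = c(1e-8, 1e-4, max(y) * 0.5))
    },
    gompertz = {
      st <- .gompertz_start(t, y)
      .nls_sse(y ~ tv0 * exp((alpha / beta) * (1 - exp(-beta * t))),
               data = list(t = t, y = y), start = st,
               lower = c(1e-8, 1e-6, 1e-4))
    },
    simeoni = {
      cf <- stats::lm.fit(cbind(1, pmin(t, stats::median(t))), log(y))$coefficients
      l0 <- max(cf[[2]], 0.02)
      st <- list(tv0 = max(exp(cf[[1]]), 1e-4), l0 = l0,
                 l1 = max(l0 * max(y) / 2, 1e-5))
      .nls_sse(y ~ solve_simeoni_cpp(tv0, l0, l1, 20, t, 1e-7, 1e-9),
               data = list(t = t, y = y), start = st,
               lower = c(1e-8, 1e-4, 1e-8))
    })
  if (is.null(res)) return(NULL)
  list(params = .raw_classical(model_id, res$par), sse = res$sse,
       n_par = n_params_classical(model_id))
}

.nls_sse <- function(formula, data, start, lower = NULL) {
  ctl <- stats::nls.control(maxiter = 100, warnOnly = TRUE)
  fit <- if (is.null(lower))
    try(stats::nls(formula, data = data, start = start, control = ctl),
        silent = TRUE)
  else
    try(stats::nls(formula, data = data, start = start, control = ctl,
                   algorithm = "port", lower = lower), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  par <- stats::coef(fit)
  if (any(!is.finite(par))) return(NULL)
  list(par = par, sse = sum(stats::resid(fit)^2))
}

.gompertz_start <- function(t, y) {
  ly <- log(y)
  best <- NULL
  for (beta in c(0.02, 0.05, 0.1, 0.2)) {
    x <- 1 - exp(-beta * t)
    cf <- stats::lm.fit(cbind(1, x), ly)
    sse <- sum(cf$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, tv0 = exp(cf$coefficients[[1]]),
                   ab = cf$coefficients[[2]], beta = beta)
  }
  list(tv0 = max(best$tv0, 1e-6), alpha = max(best$ab * best$beta, 1e-5),
       beta = best$beta)
}

.adj_r2 <- function(sse, y, n_par) {
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  1 - (1 - r2) * (n - 1) / (n - n_par - 1)
}

#' Fit classical growth models and a smoothing-spline reference to one animal
#'
#' Fits each candidate classical model (`linear`, `exponential`, `logistic`,
#' `gompertz`, `simeoni`) to the transformed profile by nonlinear least
#' squares, selects the winner by adjusted R-squared
#' (`1 - (1 - R^2)(n - 1)/(n - p - 1)`, ties broken toward fewer parameters),
#' and fits a cubic smoothing spline to the same data (generalized
#' cross-validation by default, or a fixed `spar`).
#'
#' @param profile data.frame with `time` and `tv` for one animal (>= 5 rows).
#' @param transform `"unit"` (default, screening scale) or `"log"`.
#' @param animal_id Identifier carried into the result.
#' @param candidates Subset of candidate model ids to fit.
#' @param spar Optional fixed smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` uses GCV.
#' @return An object of class `individual_fit`: winner `model_id`, `params`,
#'   `adjusted_r2` (all candidates, named), `residual_variance`
#'   (winner SSE / (n - p)), `spline` (smooth.spline fit), the transformed
#'   data (`t`, `y`) and `transform`.
#' @export
fit_individual <- function(profile, transform = c("unit", "log"),
                           animal_id = NA_character_,
                           candidates = .screen_candidates, spar = NULL) {
  transform <- match.arg(transform)
  t <- as.numeric(profile$time)
  if (nrow(profile) < 5L)
    stop("fit_individual requires >= 5 observations", call. = FALSE)
  y <- transform_profile(profile$tv, transform)
  fits <- list()
  for (m in candidates) {
    f <- .fit_classical_one(m, t, y)
    if (is.null(f)) {
      warning("model '", m, "' failed to converge for animal ", animal_id,
              "; excluded", call. = FALSE)
      next
    }
    f$adj_r2 <- .adj_r2(f$sse, y, f$n_par)
    fits[[m]] <- f
  }
  if (!length(fits))
    stop("all classical models failed for animal ", animal_id, call. = FALSE)
  a2 <- vapply(fits, `[[`, numeric(1), "adj_r2")
  npar <- vapply(fits, `[[`, integer(1), "n_par")
  best <- names(fits)[order(-a2, npar)][1]
  w <- fits[[best]]
  sp <- if (is.null(spar)) stats::smooth.spline(t, y)
        else stats::smooth.spline(t, y, spar = spar)
  structure(list(animal_id = animal_id, model_id = best, params = w$params,
                 adjusted_r2 = a2, residual_variance = w$sse / (length(y) - w$n_par),
                 spline = sp, t = t, y = y, transform = transform,
                 candidates = names(fits)),
            class = "individual_fit")
}

# events (zero crossings of v on grid g) by sign change + linear interpolation
.zero_crossings <- function(g, v) {
  s <- sign(v)
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (!length(idx)) return(numeric(0))
  g[idx] + (g[idx + 1] - g[idx]) * abs(v[idx]) / (abs(v[idx]) + abs(v[idx + 1]))
}

#' Half-periods of the spline-minus-classical difference signal
#'
#' Evaluates `d(t) = spline(t) - classical(t)` on a dense grid spanning the
#' animal's observed time range, locates zero-crossings (sign changes, with
#' linear interpolation) and interior extrema (sign changes of the numerical
#' derivative), and returns the oscillatory half-periods: gaps between
#' successive zero-crossings and between successive extrema. Events within
#' half a grid step of either boundary are discarded (edge-effect guard).
#' Fewer than two events of a kind yields an empty half-period vector, not an
#' error.
#'
#' @param fit An [fit_individual()] result (or any list with `spline`,
#'   `params`, `t`).
#' @param grid Dense evaluation grid; default 201 points across the observed
#'   span.
#' @return List with `grid`, `diff` (the difference signal),
#'   `zero_crossings`, `extrema` (times), `extrema_kind` (`"max"`/`"min"`),
#'   `hp_zero`, `hp_extrema`.
#' @export
oscillation_features <- function(fit, grid = NULL) {
  if (is.null(grid)) grid <- seq(min(fit$t), max(fit$t), length.out = 201L)
  d <- stats::predict(fit$spline, grid)$y - predict_classical(fit$params, grid)
  guard <- (grid[2] - grid[1]) / 2
  lo <- grid[1] + guard
  hi <- grid[length(grid)] - guard
  zc <- .zero_crossings(grid, d)
  zc <- zc[zc > lo & zc < hi]
  dd <- diff(d)
  s <- sign(dd)
  ii <- which(s[-1] * s[-length(s)] < 0)  # extremum between grid[ii+1]
  ext <- (grid[ii + 1] + grid[ii + 2]) / 2
  kind <- ifelse(s[ii] > 0, "max", "min")
  keep <- ext > lo & ext < hi
  ext <- ext[keep]; kind <- kind[keep]
  list(grid = grid, diff = d,
       zero_crossings = zc, extrema = ext, extrema_kind = kind,
       hp_zero = if (length(zc) >= 2) diff(zc) else numeric(0),
       hp_extrema = if (length(ext) >= 2) diff(ext) else numeric(0))
}

#' One-sample Kolmogorov-Smirnov test against Uniform(0, 1)
#'
#' @param percentiles Values in `[0, 1]` (>= 5 of them).
#' @return List with `statistic` and `p_value`.
#' @export
ks_uniformity <- function(percentiles) {
  if (length(percentiles) < 5L)
    stop("need at least 5 percentiles", call. = FALSE)
  if (any(percentiles < 0 | percentiles > 1))
    stop("percentiles must lie in [0, 1]", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(percentiles, "punif"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Simulated white-noise null distribution of half-periods
#'
#' For each animal, the winning classical fit is taken as the monotone truth
#' and perturbed with iid Gaussian noise at the observed times, with the same
#' variance as the animal's residuals; each replicate is refit and its
#' half-periods extracted exactly as in the observed analysis. The percentile
#' of each observed half-period is the fraction of that animal's simulated
#' half-periods strictly above it (computed per animal against the animal's
#' own null pool).
#'
#' @param fits List of [fit_individual()] results.
#' @param features List of [oscillation_features()] results, parallel to
#'   `fits`.
#' @param n_sims Number of noise replicates per animal (study-scale default
#'   5000; tests use fewer).
#' @param seed Integer seed.
#' @param refit `"winner"` (default): replicates are refit with the animal's
#'   winning model family only, matching the null's generating family;
#'   `"all"`: replicates rerun the full candidate competition.
#' @param method Half-period flavor driving the percentiles:
#'   `"zero_crossing"` or `"extrema"`.
#' @param noise `"log"` (default): replicate noise is multiplicative,
#'   `mu * exp(N(0, s))` with `s` the log-scale residual SD of the winner fit
#'   -- matching the additive-on-log error model of the measurement process
#'   (tumor volume noise scales with tumor size); `"unit"`: literal additive
#'   white noise on the analysis scale with the residual variance of the
#'   winner fit. The additive variant is anticonservative: it injects too
#'   much noise where the signal is small and too little where it is large,
#'   so observed half-periods look systematically extreme even for
#'   noise-only data.
#' @return List with per-animal simulated half-period pools (`null_hp`),
#'   `percentiles` (data.frame: animal_id, hp, percentile), pooled simulated
#'   HP count `n_sim_hp`, and the [ks_uniformity()] result (`ks`), or
#'   `ks = NULL` when fewer than 5 observed half-periods exist.
#' @export
null_hp_study <- function(fits, features, n_sims = 5000, seed = 1,
                          refit = c("winner", "all"),
                          method = c("zero_crossing", "extrema"),
                          noise = c("log", "unit")) {
  refit <- match.arg(refit)
  method <- match.arg(method)
  noise <- match.arg(noise)
  set.seed(as.integer(seed))
  hp_of <- function(ft) if (method == "zero_crossing") ft$hp_zero else ft$hp_extrema
  null_hp <- vector("list", length(fits))
  names(null_hp) <- vapply(fits, `[[`, character(1), "animal_id")
  perc <- list()
  for (i in seq_along(fits)) {
    fit <- fits[[i]]
    mu <- predict_classical(fit$params, fit$t)
    if (noise == "log") {
      pos <- mu > 0 & fit$y > 0
      n_par <- n_params_classical(fit$model_id)
      s_log <- sqrt(sum((log(fit$y[pos]) - log(mu[pos]))^2) /
                      max(sum(pos) - n_par, 1L))
    }
    sdv <- sqrt(fit$residual_variance)
    pool <- vector("list", n_sims)
    for (s in seq_len(n_sims)) {
      ystar <- if (noise == "log")
        mu * exp(stats::rnorm(length(mu), 0, s_log))
      else
        mu + stats::rnorm(length(mu), 0, sdv)
      rf <- .refit_replicate(fit, ystar, refit)
      if (is.null(rf)) next
      pool[[s]] <- hp_of(oscillation_features(rf))
    }
    pool <- unlist(pool)
    null_hp[[i]] <- pool
    obs <- hp_of(features[[i]])
    if (length(obs) && length(pool))
      perc[[i]] <- data.frame(animal_id = fit$animal_id, hp = obs,
                              percentile = vapply(obs, function(h)
                                mean(pool > h), numeric(1)))
  }
  perc <- if (length(perc)) do.call(rbind, perc) else
    data.frame(animal_id = character(0), hp = numeric(0),
               percentile = numeric(0))
  ks <- if (nrow(perc) >= 5L) ks_uniformity(perc$percentile) else NULL
  list(null_hp = null_hp, percentiles = perc,
       n_sim_hp = sum(lengths(null_hp)), ks = ks, method = method,
       n_sims = n_sims, refit = refit)
}

# refit one noise replicate; returns an object oscillation_features() accepts
.refit_replicate <- function(fit, ystar, refit) {
  t <- fit$t
  if (refit == "all") {
    fits <- list()
    cands <- if (is.null(fit$candidates)) .screen_candidates else fit$candidates
    for (m in cands) {
      f <- try(.fit_classical_one(m, t, ystar), silent = TRUE)
      if (!is.null(f) && !inherits(f, "try-error")) {
        f$adj_r2 <- .adj_r2(f$sse, ystar, f$n_par)
        fits[[m]] <- f
      }
    }
    if (!length(fits)) return(NULL)
    a2 <- vapply(fits, `[[`, numeric(1), "adj_r2")
    npar <- vapply(fits, `[[`, integer(1), "n_par")
    w <- fits[[names(fits)[order(-a2, npar)][1]]]
  } else {
    w <- .refit_winner(fit, ystar)
    if (is.null(w)) return(NULL)
  }
  sp <- try(stats::smooth.spline(t, ystar), silent = TRUE)
  if (inherits(sp, "try-error")) return(NULL)
  list(spline = sp, params = w$params, t = t)
}

# model value + Jacobian for the damped Gauss-Newton replicate refits;
# returns NULL for out-of-domain parameters (triggers step halving)
.model_fj <- list(
  exponential = function(p, t) {
    f <- p[1] * exp(p[2] * t)
    list(f = f, J = cbind(exp(p[2] * t), p[1] * t * exp(p[2] * t)))
  },
  gompertz = function(p, t) {
    if (p[3] < 1e-5) return(NULL)
    e <- exp(-p[3] * t)
    g <- (1 - e) / p[3]
    f <- p[1] * exp(p[2] * g)
    list(f = f, J = cbind(f / p[1], f * g,
                          f * p[2] * (t * e / p[3] - g / p[3])))
  },
  logistic = function(p, t) {
    if (p[1] <= 0 || p[3] <= 0) return(NULL)
    e <- exp(p[2] * t)
    d <- p[3] + p[1] * (e - 1)
    if (any(d <= 0)) return(NULL)
    f <- p[1] * p[3] * e / d
    list(f = f,
         J = cbind(p[3] * e / d - p[1] * p[3] * e * (e - 1) / d^2,
                   p[1] * p[3] * t * e / d - p[1]^2 * p[3] * t * e^2 / d^2,
                   p[1] * e / d - p[1] * p[3] * e / d^2))
  },
  simeoni = function(p, t) {
    if (any(p <= 0)) return(NULL)
    h <- 1e-5
    f <- try(solve_simeoni_cpp(p[1], p[2], p[3], 20, t, 1e-6, 1e-8),
             silent = TRUE)
    if (inherits(f, "try-error")) return(NULL)
    J <- vapply(1:3, function(k) {
      q <- p; q[k] <- q[k] * (1 + h)
      (solve_simeoni_cpp(q[1], q[2], q[3], 20, t, 1e-6, 1e-8) - f) /
        (p[k] * h)
    }, numeric(length(t)))
    list(f = f, J = J)
  })

# damped Gauss-Newton least squares from a warm start (replicate refits are
# started at the observed-data estimates, so a handful of iterations suffice)
.gn_refit <- function(model_id, t, y, start, max_iter = 8) {
  fj <- .model_fj[[model_id]]
  if (is.null(fj)) return(NULL)
  par <- as.numeric(start)
  v <- fj(par, t)
  if (is.null(v)) return(NULL)
  sse <- sum((y - v$f)^2)
  for (it in seq_len(max_iter)) {
    delta <- tryCatch(stats::.lm.fit(v$J, y - v$f)$coefficients,
                      error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) break
    step <- 1
    improved <- FALSE
    while (step >= 1 / 64) {
      cand <- par + step * delta
      vc <- fj(cand, t)
      if (!is.null(vc)) {
        s2 <- sum((y - vc$f)^2)
        if (is.finite(s2) && s2 <= sse) {
          par <- cand; v <- vc
          improved <- TRUE
          conv <- (sse - s2) < 1e-9 * (s2 + 1e-12)
          sse <- s2
          if (conv) return(list(par = par, sse = sse))
          break
        }
      }
      step <- step / 2
    }
    if (!improved) break
  }
  list(par = par, sse = sse)
}

# fast refit of the winning family, initialized at the original estimates
.refit_winner <- function(fit, ystar) {
  t <- fit$t
  m <- fit$model_id
  p <- unclass(fit$params)
  res <- switch(m,
    linear = {
      cf <- stats::lm.fit(cbind(1, t), ystar)$coefficients
      list(par = c(tv0 = cf[[1]], k = cf[[2]]))
    },
    exponential = .gn_refit(m, t, ystar, p[c("tv0", "k")]),
    logistic = .gn_refit(m, t, ystar, p[c("tv0", "k", "K")]),
    gompertz = .gn_refit(m, t, ystar, p[c("tv0", "alpha", "beta")]),
    simeoni = .gn_refit(m, t, ystar, p[c("tv0", "l0", "l1")]))
  if (!is.null(res)) {
    names(res$par) <- setdiff(names(p), c("model_id", "psi"))
  } else {
    res <- .fit_classical_one(m, t, ystar)
  }
  if (is.null(res)) return(NULL)
  list(params = .raw_classical(m, res$par))
}

#' Run the full empirical oscillation screen on a dataset
#'
#' Per animal with at least `min_obs` observations: transform the profile,
#' fit the classical candidates and the spline reference
#' ([fit_individual()]), extract difference-signal half-periods
#' ([oscillation_features()]); then build the white-noise null
#' ([null_hp_study()]) and test the observed-percentile uniformity
#' ([ks_uniformity()]).
#'
#' @param dataset A [study_dataset()].
#' @param transform `"unit"` (default) or `"log"`.
#' @param n_sims Null replicates per animal; `0` skips the null study.
#' @param seed Integer seed for the null study.
#' @param min_obs Minimum observations per screened animal (default 5).
#' @param refit,method,noise Passed to [null_hp_study()].
#' @param candidates Classical model families competing per animal.
#' @param spar Optional fixed smoothing parameter.
#' @return An object of class `oscillation_report`: `fits`, `features`,
#'   per-animal and pooled half-periods (`hp_zero`, `hp_extrema`,
#'   `mean_hp_zero`, `mean_hp_extrema`), group summaries (`by_tumor_type`),
#'   number of skipped animals, and (if `n_sims > 0`) the `null` study with
#'   percentiles and KS result.
#' @export
oscillation_screen <- function(dataset, transform = c("unit", "log"),
                               n_sims = 0, seed = 1, min_obs = 5L,
                               refit = c("winner", "all"),
                               method = c("zero_crossing", "extrema"),
                               noise = c("log", "unit"), spar = NULL,
                               candidates = .screen_candidates) {
  stopifnot(inherits(dataset, "study_dataset"))
  transform <- match.arg(transform)
  profiles <- split_animals(dataset)
  keep <- vapply(profiles, nrow, integer(1)) >= min_obs
  skipped <- sum(!keep)
  profiles <- profiles[keep]
  fits <- vector("list", length(profiles))
  feats <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    fits[[i]] <- fit_individual(profiles[[i]], transform = transform,
                                animal_id = names(profiles)[i], spar = spar,
                                candidates = candidates)
    feats[[i]] <- oscillation_features(fits[[i]])
  }
  hp_zero <- lapply(feats, `[[`, "hp_zero")
  hp_extrema <- lapply(feats, `[[`, "hp_extrema")
  names(hp_zero) <- names(hp_extrema) <- names(profiles)
  ttype <- vapply(profiles, function(p) as.character(p$tumor_type[1]),
                  character(1))
  pooled_z <- unlist(hp_zero)
  by_tt <- if (!all(is.na(ttype))) {
    tapply(seq_along(profiles), ttype, function(ix)
      mean(unlist(hp_zero[ix])))
  } else NULL
  nul <- if (n_sims > 0)
    null_hp_study(fits, feats, n_sims = n_sims, seed = seed,
                  refit = refit, method = method, noise = noise)
  else NULL
  structure(list(fits = fits, features = feats,
                 hp_zero = hp_zero, hp_extrema = hp_extrema,
                 mean_hp_zero = mean(pooled_z),
                 mean_hp_extrema = mean(unlist(hp_extrema)),
                 by_tumor_type = by_tt, n_skipped = skipped,
                 transform = transform, null = nul),
            class = "oscillation_report")
}

#' @export
print.oscillation_report <- function(x, ...) {
  cat("oscillation_report:", length(x$fits), "animals screened (",
      x$n_skipped, "skipped)\n")
  cat(sprintf("  mean half-period: %.2f days (zero-crossing), %.2f days (extrema)\n",
              x$mean_hp_zero, x$mean_hp_extrema))
  win <- table(vapply(x$fits, `[[`, character(1), "model_id"))
  cat("  winning models:", paste(names(win), win, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$null) && !is.null(x$null$ks))
    cat(sprintf("  null study: %d sims/animal, KS D = %.3f, p = %.3g\n",
                x$null$n_sims, x$null$ks$statistic, x$null$ks$p_value))
  invisible(x)
}
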