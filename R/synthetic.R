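#' Specification for a study-shaped synthetic dataset
#'
#' Describes a virtual xenograft study: a structural growth model with typical
#' parameters, log-normal inter-individual variability (IIV), additive
#' residual error on the log scale, a sampling schedule, and sacrifice dropout
#' at an ethical upper tumor size limit. Defaults emulate the pooled study
#' shape this package targets: 85 animals across 12 cell lines from 6 tumor
#' types, an ethical limit of 2000 mm^3 (a common institutional ceiling; the
#' source study does not state its numeric limit), and a sampling schedule of
#' day 7 then every 4 days to day 80, calibrated once so that the default
#' population lands near 1,064 total observations after dropout.
#'
#' @param model `"final"` for the tumor-angiogenesis-resources system, or a
#'   classical model id (`"linear"`, `"exponential"`, `"logistic"`,
#'   `"gompertz"`, `"simeoni"`).
#' @param theta Typical parameters: a [final_model_params()] or
#'   [classical_params()] object matching `model`. Default: the published
#'   population estimates ([final_model_defaults()]) when `model = "final"`.
#' @param omega Named vector of log-scale IIV standard deviations (subset of
#'   parameter names; omitted parameters have no IIV). Default for the final
#'   model: IIV on all parameters except `k_res`.
#' @param sigma Additive residual SD on the log(mm^3) scale, > 0.
#' @param n_animals Number of animals, >= 1.
#' @param schedule Increasing measurement days.
#' @param upper_limit Ethical limit (mm^3); measurements strictly above it end
#'   the animal's follow-up (the exceeding record and all later ones are
#'   dropped). `Inf` disables dropout.
#' @param groups Optional data.frame with columns `cell_line`, `tumor_type`,
#'   `n` partitioning `n_animals`; default distributes animals evenly over the
#'   12 cell lines / 6 tumor types of the emulated study.
#' @return An object of class `generation_spec`.
#' @export
generation_spec <- function(model = "final", theta = NULL, omega = NULL,
                            sigma = NULL, n_animals = 85,
                            schedule = seq(7, 80, by = 4),
                            upper_limit = 2000, groups = NULL) {
  defaults <- final_model_defaults()
  if (identical(model, "final")) {
    if (is.null(theta)) theta <- defaults$theta
    stopifnot(inherits(theta, "final_model_params"))
    if (is.null(omega)) omega <- defaults$omega
    if (is.null(sigma)) sigma <- defaults$sigma
  } else {
    model <- match.arg(model, .classical_models)
    if (is.null(theta))
      stop("theta (classical_params) is required for model '", model, "'",
           call. = FALSE)
    stopifnot(inherits(theta, "classical_params"),
              identical(theta$model_id, model))
    if (is.null(omega)) omega <- c(tv0 = 0)[0]  # empty named numeric
    if (is.null(sigma)) sigma <- defaults$sigma
  }
  par_names <- setdiff(names(unclass(theta)), c("model_id", "psi"))
  if (length(omega)) {
    stopifnot(!is.null(names(omega)), all(names(omega) %in% par_names),
              all(omega >= 0))
  }
  stopifnot(sigma > 0, n_animals >= 1, length(schedule) >= 2,
            all(diff(schedule) > 0), all(schedule >= 0), upper_limit > 0)
  if (is.null(groups)) groups <- default_study_groups(n_animals)
  stopifnot(is.data.frame(groups),
            all(c("cell_line", "tumor_type", "n") %in% names(groups)),
            sum(groups$n) == n_animals)
  structure(list(model = model, theta = theta, omega = omega, sigma = sigma,
                 n_animals = as.integer(n_animals), schedule = schedule,
                 upper_limit = upper_limit, groups = groups),
            class = "generation_spec")
}

#' Default cell-line / tumor-type panel, animals distributed evenly
#' @param n_animals Total number of animals.
#' @return data.frame with `cell_line`, `tumor_type`, `n`.
#' @export
default_study_groups <- function(n_animals = 85) {
  panel <- data.frame(
    cell_line = c("MB-321", "MV411", "A549", "Calu-6", "H1650", "H1975",
                  "H2122", "H441", "JEKO-1", "A2058", "A375", "MIA PaCa-2"),
    tumor_type = c("breast", "leukemia", rep("lung", 6), "lymphoma",
                   rep("melanoma", 2), "pancreas"),
    stringsAsFactors = FALSE)
  k <- nrow(panel)
  n <- rep(n_animals %/% k, k)
  extra <- n_animals %% k
  if (extra > 0) n[seq_len(extra)] <- n[seq_len(extra)] + 1L
  panel$n <- n
  panel[panel$n > 0, , drop = FALSE]
}

.predict_structural <- function(model, params, times) {
  if (identical(model, "final"))
    simulate_final_model(params, times)$tv
  else
    predict_classical(params, times)
}

.perturb_params <- function(theta, eta) {
  p <- unclass(theta)
  for (nm in names(eta)) p[[nm]] <- p[[nm]] * exp(eta[[nm]])
  if (inherits(theta, "final_model_params"))
    do.call(final_model_params, p)
  else
    do.call(classical_params, p[c("model_id",
                                  setdiff(names(p), c("model_id")))])
}

#' Generate a synthetic study population
#'
#' Per animal: draw log-normal individual parameters
#' `p_i = theta * exp(eta_i)`, `eta_i ~ N(0, omega^2)`; simulate the
#' structural model at the schedule; add N(0, sigma^2) noise on the log scale;
#' then apply sacrifice dropout: the first measured value strictly above
#' `upper_limit` and every later record are removed (dropout only ever removes
#' a suffix of the record sequence). Values exactly at the limit are retained.
#'
#' @param spec A [generation_spec()].
#' @param seed Integer seed; the spec plus the seed reproduce the dataset
#'   bit-for-bit.
#' @return A [study_dataset()] with attribute `truth`: list with the spec,
#'   seed, per-animal `eta` matrix and individual parameter table.
#' @export
generate_population <- function(spec, seed) {
  stopifnot(inherits(spec, "generation_spec"))
  set.seed(as.integer(seed))
  ids <- sprintf("A%03d", seq_len(spec$n_animals))
  grp <- spec$groups[rep(seq_len(nrow(spec$groups)), spec$groups$n), , drop = FALSE]
  on <- names(spec$omega)
  eta <- matrix(0, spec$n_animals, length(on), dimnames = list(ids, on))
  rows <- vector("list", spec$n_animals)
  ipars <- vector("list", spec$n_animals)
  for (i in seq_len(spec$n_animals)) {
    if (length(on))
      eta[i, ] <- stats::rnorm(length(on), 0, spec$omega)
    pi <- .perturb_params(spec$theta, eta[i, ])
    f <- .predict_structural(spec$model, pi, spec$schedule)
    y <- exp(log(f) + stats::rnorm(length(f), 0, spec$sigma))
    cut <- which(y > spec$upper_limit)[1]
    keep <- if (is.na(cut)) length(y) else cut - 1L
    if (keep >= 1L)
      rows[[i]] <- data.frame(animal_id = ids[i],
                              time = spec$schedule[seq_len(keep)],
                              tv = y[seq_len(keep)],
                              cell_line = grp$cell_line[i],
                              tumor_type = grp$tumor_type[i],
                              stringsAsFactors = FALSE)
    ipars[[i]] <- unlist(unclass(pi)[setdiff(names(unclass(pi)), "model_id")])
  }
  m <- do.call(rbind, rows)
  cnt <- table(m$animal_id)
  if (is.null(m) || all(cnt < 2))
    stop("all animals dropped before 2 observations; raise upper_limit or ",
         "add earlier schedule points", call. = FALSE)
  # animals reduced to < 2 records by dropout are removed (as sacrificed early)
  keep_ids <- names(cnt)[cnt >= 2]
  m <- m[m$animal_id %in% keep_ids, , drop = FALSE]
  ds <- study_dataset(m, upper_limit = spec$upper_limit)
  attr(ds, "truth") <- list(spec = spec, seed = as.integer(seed), eta = eta,
                            params = do.call(rbind, ipars))
  ds
}

#' Generate a monotone-growth null dataset
#'
#' Same machinery as [generate_population()], restricted to monotone classical
#' structural models. Used for type-I calibration of the oscillation screen:
#' any apparent oscillation in such data is residual noise by construction.
#'
#' @param spec A [generation_spec()] whose `model` is classical.
#' @param seed Integer seed.
#' @return A [study_dataset()] with `truth` attribute.
#' @export
generate_null_dataset <- function(spec, seed) {
  stopifnot(inherits(spec, "generation_spec"))
  if (identical(spec$model, "final"))
    stop("null datasets require a monotone classical model", call. = FALSE)
  generate_population(spec, seed)
}
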