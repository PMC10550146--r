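# Shared fixtures: all synthetic, built in code at test time.

# study-shaped monotone (gompertz) null world used for screen calibration:
# curvature-rich sigmoid growth toward ~2200 mm^3, study-like log-scale noise
gompertz_null_spec <- function(n_animals = 8) {
  generation_spec(model = "gompertz",
                  theta = classical_params("gompertz", tv0 = 69,
                                           alpha = 0.1, beta = 0.025),
                  omega = c(tv0 = 0.28, alpha = 0.2), sigma = 0.17,
                  n_animals = n_animals, schedule = seq(7, 80, by = 4))
}

final_spec <- function(n_animals = 85, schedule = seq(7, 80, by = 4)) {
  generation_spec(n_animals = n_animals, schedule = schedule)
}

published <- final_model_defaults()

# fabricated spline-like object whose predictions are an arbitrary function;
# lets feature-extraction tests use analytic difference signals
fake_spline <- function(f) structure(list(f = f), class = "fake_spline")
predict.fake_spline <- function(object, x, ...) list(x = x, y = object$f(x))
.S3method("predict", "fake_spline", predict.fake_spline)

# a fit-like object for oscillation_features with difference signal
# d(t) = g(t): classical part is a flat linear model at level c, spline
# predicts g(t) + c
feature_fixture <- function(g, t_range, level = 1) {
  list(spline = fake_spline(function(x) g(x) + level),
       params = structure(list(model_id = "linear", tv0 = level, k = 0),
                          class = "classical_params"),
       t = t_range)
}
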