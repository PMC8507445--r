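# Shared fixtures, all built in code (no files).

test_config <- synthetic_config(seed = 42)
test_stack <- synthetic_stack(test_config)

# life table with constant annual hazard h: l(a) = exp(-h a)
const_hazard_table <- function(h, sex = "male", amax = 110) {
  life_table(sex, 0:amax, exp(-h * (0:amax)))
}

immortal_table <- life_table("male", 0:110, rep(1, 111))

# age-flat baseline rate for one or more sites/sexes/kinds
flat_baseline <- function(rate_per_100k, site = "stomach", sex = "male",
                          kind = c("incidence", "mortality")) {
  df <- expand.grid(site = site, sex = sex, age = c(0, 110), kind = kind,
                    stringsAsFactors = FALSE)
  df$rate_per_100k <- rate_per_100k
  baseline_rates(df[, c("site", "sex", "age", "rate_per_100k", "kind")])
}

# age-independent model: ERR = beta_err, EAR = beta_ear everywhere
flat_params <- function(beta_err = 0, beta_ear = 0, w = if (beta_err > 0) 1 else 0,
                        ddref = 1, latency = 5, site = "stomach",
                        sex = "male", ...) {
  risk_model_params(site, sex, beta_err = beta_err, beta_ear = beta_ear,
                    gamma = 0, eta = 0, transport_weight = w,
                    ddref = ddref, latency = latency, ...)
}

# force every site of a model set to the linear dose response
all_linear <- function(models) {
  out <- lapply(models, function(p) { p$dose_response <- "linear"; p$theta <- 0; p })
  attr(out, "ground_truth") <- attr(models, "ground_truth")
  out
}

linear_test_stack <- lar_stack(
  life_tables = test_stack$life_tables,
  baselines = test_stack$baselines,
  models = lapply(test_stack$models, all_linear),
  dose_coefficients = test_stack$dose_coefficients)
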