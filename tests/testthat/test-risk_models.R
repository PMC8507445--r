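test_that("ERR follows the age-at-exposure and attained-age modifiers", {
  flat <- risk_model_params("stomach", "male", beta_err = 0.5, beta_ear = 0,
                            gamma = 0, eta = 0)
  expect_equal(err(flat, 20, 60), 0.5)
  expect_equal(err(flat, 50, 80), 0.5)

  p <- risk_model_params("stomach", "male", beta_err = 0.5, beta_ear = 0,
                         gamma = -0.3, eta = -1.4)
  expect_equal(err(p, 30, 60), 0.5, tolerance = 1e-12) # reference ages cancel
  expect_equal(err(p, 10, 60), 0.5 * exp(0.6), tolerance = 1e-12)

  expect_error(err(p, 40, 42), "latency")
})

test_that("EAR shares the age structure, with the exposure-age cap at 30", {
  flat <- risk_model_params("lung", "female", beta_err = 0, beta_ear = 1.2)
  expect_equal(ear(flat, 5, 30), 1.2)

  p <- risk_model_params("lung", "female", beta_err = 0, beta_ear = 1,
                         gamma = 0, eta = 3.5, latency = 0)
  expect_equal(ear(p, 30, 30) / ear(p, 30, 60), (30 / 60)^3.5,
               tolerance = 1e-12)

  pc <- risk_model_params("lung", "female", beta_err = 0, beta_ear = 1,
                          gamma = -0.3, eta = 0)
  expect_equal(ear(pc, 40, 70), ear(pc, 30, 70), tolerance = 1e-15)
})

test_that("excess rate combines dose, transport and baseline as specified", {
  # pure ERR: f(D)/ddref * err * lambda
  p1 <- flat_params(beta_err = 0.5, w = 1, ddref = 1.5)
  b1 <- flat_baseline(200)
  expect_equal(excess_rate(p1, b1, 0.01, 30, 60),
               0.01 / 1.5 * 0.5 * 200 / 1e5, tolerance = 1e-12)

  # pure EAR: f(D) * ear / 10,000
  p2 <- flat_params(beta_ear = 2, w = 0, ddref = 1)
  expect_equal(excess_rate(p2, b1, 0.005, 30, 60), 0.005 * 2 / 1e4,
               tolerance = 1e-12)

  # no dose, no excess
  expect_equal(excess_rate(p1, b1, 0, 30, 40:100), rep(0, 61))
  expect_error(excess_rate(p1, b1, -0.1, 30, 60), "dose")
})

test_that("excess rate is linear in dose, convex in transport, scaled by DDREF", {
  b <- flat_baseline(300)
  base <- risk_model_params("stomach", "male", beta_err = 0.4, beta_ear = 2,
                            gamma = -0.3, eta = -1.4, transport_weight = 0.35,
                            ddref = 1)
  a <- 40:109
  m1 <- excess_rate(base, b, 0.002, 30, a)
  m2 <- excess_rate(base, b, 0.004, 30, a)
  expect_identical(m2, 2 * m1) # exact linearity for the linear response

  # intermediate w is the convex combination of the two pure transports
  at_w <- function(w) {
    p <- base; p$transport_weight <- w
    excess_rate(p, b, 0.002, 30, a)
  }
  expect_equal(at_w(0.35), 0.35 * at_w(1) + 0.65 * at_w(0), tolerance = 1e-14)

  # DDREF divides the rate exactly
  p15 <- base; p15$ddref <- 1.5
  expect_equal(excess_rate(p15, b, 0.002, 30, a), m1 / 1.5, tolerance = 1e-14)

  # continuity in e and a over the allowed domain
  eps <- 1e-7
  expect_equal(excess_rate(base, b, 0.002, 30 + eps, a + eps), m1,
               tolerance = 1e-5)

  # linear-quadratic response: f(D) = D (1 + theta D)
  lq <- risk_model_params("leukaemia", "male", beta_err = 0.4, beta_ear = 2,
                          transport_weight = 0.35, ddref = 1, latency = 2,
                          dose_response = "linear_quadratic", theta = 0.9)
  lin <- lq; lin$dose_response <- "linear"
  blq <- flat_baseline(300, site = "leukaemia")
  expect_equal(excess_rate(lq, blq, 0.01, 30, a),
               excess_rate(lin, blq, 0.01, 30, a) * (1 + 0.9 * 0.01),
               tolerance = 1e-12)
})

test_that("baseline lookup interpolates and holds the boundary values", {
  df <- data.frame(site = "colon", sex = "male", age = c(40, 50, 60),
                   rate_per_100k = c(10, 30, 90), kind = "incidence")
  b <- baseline_rates(df)
  expect_equal(baseline_rate_at(b, "colon", "male", "incidence", 45), 20)
  expect_equal(baseline_rate_at(b, "colon", "male", "incidence", c(0, 30)),
               c(10, 10)) # below the first tabulated age
  expect_equal(baseline_rate_at(b, "colon", "male", "incidence", 110), 90)
  expect_error(baseline_rate_at(b, "colon", "female", "incidence", 45),
               "no baseline")
  expect_error(baseline_rates(transform(df, site = "elbow")), "unknown")
})
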