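# flat EAR-only configuration giving a constant excess rate m per person-year
flat_m_params <- function() flat_params(beta_ear = 1, w = 0, ddref = 1)
flat_m_dose <- function(m) m * 1e4 # D such that M = D * beta_ear / 1e4 = m

test_that("constant excess rate on an immortal population gives the closed form", {
  m <- 1e-5
  lar <- lar_site(flat_m_params(), flat_baseline(100), immortal_table,
                  D = flat_m_dose(m), e = 40)
  expect_equal(lar, m * (110 - 45), tolerance = 1e-12)
})

test_that("constant-hazard populations match the analytic survival integral", {
  m <- 1e-5; h <- 0.05; e <- 40; L <- 5
  analytic <- m * (1 - exp(-h * (110 - e - L))) / h # ~1.923e-4
  lt <- const_hazard_table(h)
  annual <- lar_site(flat_m_params(), flat_baseline(100), lt,
                     D = flat_m_dose(m), e = e)
  expect_equal(annual, analytic, tolerance = 0.02)
})

test_that("quadrature refinement converges on a smooth age-varying excess rate", {
  # M(a) = m0 (a/60)^2 on an immortal population: the integral has the
  # closed form m0 (110^3 - 45^3) / (3 * 60^2)
  p <- risk_model_params("stomach", "male", beta_err = 0, beta_ear = 1,
                         gamma = 0, eta = 2, transport_weight = 0,
                         ddref = 1)
  b <- flat_baseline(100)
  m0 <- 1e-5
  exact <- m0 * (110^3 - 45^3) / (3 * 60^2)
  errs <- vapply(c(1, 0.5, 0.25), function(s)
    abs(lar_site(p, b, immortal_table, D = m0 * 1e4, e = 40, step = s) - exact),
    numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[1] / exact, 1e-4)
})

test_that("zero dose and spent lifetimes give zero LAR", {
  expect_equal(lar_site(flat_m_params(), flat_baseline(100),
                        test_stack$life_tables$male, D = 0, e = 40), 0)
  expect_warning(
    z <- lar_site(flat_m_params(), flat_baseline(100),
                  test_stack$life_tables$male, D = 0.01, e = 107),
    "upper age limit")
  expect_equal(z, 0)
})

test_that("per-site LARs add up to the total and scale with activity", {
  sc <- exposure_scenario("male", 35, 500)
  doses <- organ_doses(test_stack$dose_coefficients, 500, 35)
  res <- lar_total(sc, test_stack$models$male, test_stack$baselines,
                   test_stack$life_tables$male, doses)
  expect_s3_class(res, "lar_result")
  expect_equal(res$total, sum(res$per_site), tolerance = 1e-12)
  expect_true(all(res$per_site >= 0))
  expect_lt(res$total, 1)
  expect_setequal(names(res$per_site), sites_for_sex("male")$site)

  # two flat sites on an immortal table: total is the sum of closed forms
  ms <- list(flat_params(beta_ear = 1, w = 0, site = "stomach"),
             flat_params(beta_ear = 2, w = 0, site = "colon"))
  b2 <- flat_baseline(100, site = c("stomach", "colon"))
  d2 <- c(stomach = 1e-3, colon = 2e-3)
  res2 <- lar_total(exposure_scenario("male", 40), ms, b2, immortal_table, d2)
  expect_equal(res2$total, 65 * (1e-3 * 1 + 2e-3 * 2) / 1e4, tolerance = 1e-12)

  # all-linear configuration: doubling every dose doubles the total
  lin <- all_linear(test_stack$models$male)
  r1 <- lar_total(sc, lin, test_stack$baselines,
                  test_stack$life_tables$male, doses)
  r2 <- lar_total(sc, lin, test_stack$baselines,
                  test_stack$life_tables$male, 2 * doses)
  expect_equal(r2$total, 2 * r1$total, tolerance = 1e-12)
})

test_that("mortality LAR scales with the mortality baseline under pure ERR", {
  p <- flat_params(beta_err = 0.5, w = 1)
  lt <- test_stack$life_tables$male
  df <- expand.grid(site = "stomach", sex = "male", age = 0:110,
                    kind = "incidence", stringsAsFactors = FALSE)
  df$rate_per_100k <- 50 + 2 * df$age
  dfm <- transform(df, kind = "mortality", rate_per_100k = 0.5 * rate_per_100k)
  b <- baseline_rates(rbind(df, dfm))
  sc <- exposure_scenario("male", 40)
  d <- c(stomach = 1e-3)
  inc <- lar_total(sc, list(p), b, lt, d, kind = "incidence")
  mor <- lar_mortality(sc, list(p), b, lt, d)
  expect_identical(mor$kind, "mortality")
  expect_equal(mor$total, 0.5 * inc$total, tolerance = 1e-12)

  # identical baselines give identical results; zero baselines give zero
  b_eq <- baseline_rates(rbind(df, transform(df, kind = "mortality")))
  expect_equal(lar_mortality(sc, list(p), b_eq, lt, d)$total,
               lar_total(sc, list(p), b_eq, lt, d, kind = "incidence")$total,
               tolerance = 1e-15)
  b0 <- baseline_rates(rbind(df, transform(dfm, rate_per_100k = 0)))
  expect_equal(lar_mortality(sc, list(p), b0, lt, d)$total, 0)
})

test_that("missing organ doses are reported with the gap list", {
  sc <- exposure_scenario("male", 35)
  expect_error(
    lar_total(sc, test_stack$models$male, test_stack$baselines,
              test_stack$life_tables$male, c(stomach = 1e-3)),
    "no organ dose supplied for")
})

test_that("uniformly higher mortality lowers LAR", {
  p <- flat_params(beta_ear = 1, w = 0)
  b <- flat_baseline(100)
  lars <- vapply(c(0.01, 0.03, 0.06), function(h)
    lar_site(p, b, const_hazard_table(h), D = 0.1, e = 30), numeric(1))
  expect_true(all(diff(lars) < 0))
})

test_that("lifetime baseline risk integrates survival-weighted rates", {
  b <- flat_baseline(100) # lambda = 1e-3 per person-year
  expect_equal(lifetime_baseline_risk(b, immortal_table, "male"),
               110 * 1e-3, tolerance = 1e-12)
  expect_equal(
    lifetime_baseline_risk(flat_baseline(0), immortal_table, "male"), 0)

  # lambda = 0.004, constant hazard 0.02: 0.004 (1 - e^-2.2)/0.02
  lt <- const_hazard_table(0.02)
  expect_equal(lifetime_baseline_risk(flat_baseline(400), lt, "male"),
               0.004 * (1 - exp(-2.2)) / 0.02, tolerance = 1e-3)
})

test_that("nominal effective-dose risk uses the ICRP coefficients", {
  expect_equal(effective_dose_risk(0, "whole"), 0)
  expect_equal(effective_dose_risk(0.003, "whole"), 1.65e-4, tolerance = 1e-12)
  expect_equal(effective_dose_risk(1, "worker"), 0.041)
  expect_error(effective_dose_risk(-0.1), ">= 0")
})
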