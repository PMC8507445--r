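test_that("generation is deterministic in the seed and varies across seeds", {
  c1 <- synthetic_config(seed = 7)
  c2 <- synthetic_config(seed = 8)
  expect_identical(make_lifetable(c1, "male"), make_lifetable(c1, "male"))
  expect_identical(make_baseline_rates(c1), make_baseline_rates(c1))
  expect_identical(make_dose_coefficients(c1), make_dose_coefficients(c1))
  expect_identical(make_risk_params(c1, "female"), make_risk_params(c1, "female"))
  expect_false(identical(make_baseline_rates(c1), make_baseline_rates(c2)))
  expect_false(identical(make_risk_params(c1, "male"),
                         make_risk_params(c2, "male")))
  # the generator must not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(make_baseline_rates(c1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("Gompertz-Makeham life tables have plausible defaults and exact limits", {
  cfg <- synthetic_config()
  for (sx in c("male", "female")) {
    lt <- make_lifetable(cfg, sx)
    expect_true(all(diff(lt$lx) < 0)) # strictly decreasing
    expect_lt(lt$lx[111], 0.01)
    e0 <- life_expectancy(lt)
    expect_gt(e0, 75); expect_lt(e0, 90)
  }
  # Makeham-only limit: constant hazard
  ch <- synthetic_config(gompertz = list(alpha = 0, beta = 0.09, makeham = 0.01))
  expect_warning(lt <- make_lifetable(ch, "male"), "implausible")
  expect_equal(lt$lx, exp(-0.01 * (0:110)), tolerance = 1e-12)
  # no hazard at all: immortal (warns for both l(110) and life expectancy)
  im <- synthetic_config(gompertz = list(alpha = 0, beta = 0.09, makeham = 0))
  expect_warning(expect_warning(lt0 <- make_lifetable(im, "male"),
                                "implausible"))
  expect_true(all(lt0$lx == 1))
})

test_that("baseline rates follow the recorded power laws and calibration", {
  cfg <- synthetic_config(seed = 5)
  b <- make_baseline_rates(cfg)
  truth <- attr(b, "ground_truth")
  # rates reproduce base * max(0, a - onset)^p for every site
  for (i in withr::with_seed(1, sample(nrow(truth), 6))) {
    tr <- truth[i, ]
    got <- baseline_rate_at(b, tr$site, tr$sex, "incidence", c(10, 50, 80, 100))
    expect_equal(got, tr$base * pmax(0, c(10, 50, 80, 100) - tr$onset)^tr$power,
                 tolerance = 1e-9)
    mor <- baseline_rate_at(b, tr$site, tr$sex, "mortality", c(50, 80))
    inc <- baseline_rate_at(b, tr$site, tr$sex, "incidence", c(50, 80))
    expect_equal(mor, inc * tr$lethality, tolerance = 1e-12)
    expect_gt(tr$lethality, 0); expect_lte(tr$lethality, 1)
  }
  # survival-weighted lifetime incidence risk is calibrated per sex
  expect_equal(lifetime_baseline_risk(b, make_lifetable(cfg, "male"), "male"),
               0.393, tolerance = 1e-9)
  expect_equal(lifetime_baseline_risk(b, make_lifetable(cfg, "female"), "female"),
               0.377, tolerance = 1e-9)
})

test_that("dose coefficients decrease from age 1 to adult within the ratio bounds", {
  cfg <- synthetic_config(seed = 3)
  t <- make_dose_coefficients(cfg)
  expect_true(t$bone_seeker)
  for (o in t$organs) {
    co <- t$coefficients[o, ]
    expect_true(all(diff(co) < 0)) # age-1 > age-5 > ... > adult
    ratio <- co[["1"]] / co[["adult"]]
    expect_gte(ratio, 2); expect_lte(ratio, 10)
  }
  expect_setequal(t$organs, unique(site_registry()$target_organ))
})

test_that("risk-parameter sets cover the registry with the right families", {
  cfg <- synthetic_config(seed = 11)
  male <- make_risk_params(cfg, "male")
  female <- make_risk_params(cfg, "female")
  expect_setequal(names(male), sites_for_sex("male")$site)
  expect_setequal(names(female), sites_for_sex("female")$site)
  expect_identical(length(union(names(male), names(female))), 15L)
  expect_false("breast" %in% names(male))
  expect_false("prostate" %in% names(female))

  leu <- male$leukaemia
  expect_identical(leu$dose_response, "linear_quadratic")
  expect_identical(as.integer(leu$latency), 2L)
  expect_equal(leu$ddref, 1)
  solid <- male$stomach
  expect_identical(solid$dose_response, "linear")
  expect_identical(as.integer(solid$latency), 5L)
  expect_equal(solid$ddref, 1.5)

  # recorded ground truth round-trips through config serialization
  truth <- attr(male, "ground_truth")
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_params(list(male = male), path)
  back <- read_risk_params(path)$male
  for (s in names(male)) {
    expect_equal(back[[s]]$beta_err, truth$beta_err[truth$site == s],
                 tolerance = 1e-12)
    expect_equal(back[[s]]$eta, truth$eta[truth$site == s], tolerance = 1e-12)
  }
})

test_that("beta coefficients are recoverable from LAR outputs by least squares", {
  # LAR is linear in (beta_err, beta_ear) for a linear dose response, so
  # regressing synthetic LAR values on the unit-coefficient basis curves
  # recovers the generating betas
  models <- all_linear(test_stack$models$male)
  truth <- attr(test_stack$models$male, "ground_truth")
  lt <- test_stack$life_tables$male
  b <- test_stack$baselines
  es <- seq(5, 85, by = 10)
  for (site in c("stomach", "lung")) {
    p <- models[[site]]
    y <- vapply(es, function(e) lar_site(p, b, lt, D = 2e-3, e = e), numeric(1))
    p1 <- p; p1$beta_err <- 1; p1$beta_ear <- 0
    p2 <- p; p2$beta_err <- 0; p2$beta_ear <- 1
    x1 <- vapply(es, function(e) lar_site(p1, b, lt, D = 2e-3, e = e), numeric(1))
    x2 <- vapply(es, function(e) lar_site(p2, b, lt, D = 2e-3, e = e), numeric(1))
    fit <- stats::lm(y ~ 0 + x1 + x2)
    est <- stats::coef(fit)
    expect_equal(unname(est["x1"]), truth$beta_err[truth$site == site],
                 tolerance = 0.01)
    expect_equal(unname(est["x2"]), truth$beta_ear[truth$site == site],
                 tolerance = 0.01)
  }
})
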