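# Reference risks computed by hand from the published full-model equation
# (intercept -6.7892; age 0.0287 about 62; female 0.6011; family history
# 0.2961; emphysema 0.2953; size -5.3854 * ((d/10)^-0.5 - (4/10)^-0.5);
# upper lobe 0.6581; part-solid 0.3776; count -0.0824 about 4; spiculation
# 0.7729), independently of the package's coefficient file.
hand_brock_lp <- function(age, female, famhx, emph, d, upper, ps, count, spic) {
  -6.7892 + 0.0287 * (age - 62) + 0.6011 * female + 0.2961 * famhx +
    0.2953 * emph - 5.3854 * ((d / 10)^(-0.5) - 1.58113883) +
    0.6581 * upper + 0.3776 * ps - 0.0824 * (count - 4) + 0.7729 * spic
}

brock_case <- function(age, sex, famhx, emph, upper, type, count, spic) {
  tibble::tibble(age_years = age, sex = sex, family_history = famhx,
                 emphysema = emph, upper_lobe = upper, nodule_type = type,
                 nodule_count = count, spiculation = spic)
}

test_that("full-model risk matches an independent hand evaluation", {
  cases <- list(
    list(brock_case(62, "male", FALSE, FALSE, FALSE, "solid", 4, FALSE), 8),
    list(brock_case(70, "female", TRUE, FALSE, TRUE, "solid", 1, TRUE), 14),
    list(brock_case(55, "female", FALSE, TRUE, FALSE, "part_solid", 2, FALSE), 10),
    list(brock_case(66, "male", TRUE, TRUE, TRUE, "part_solid", 6, TRUE), 22),
    list(brock_case(59, "male", FALSE, FALSE, TRUE, "solid", 3, FALSE), 6.5)
  )
  for (cs in cases) {
    d <- cs[[1]]
    expected_lp <- hand_brock_lp(d$age_years, d$sex == "female",
                                 d$family_history, d$emphysema, cs[[2]],
                                 d$upper_lobe, d$nodule_type == "part_solid",
                                 d$nodule_count, d$spiculation)
    got <- brock_risk(d, cs[[2]])
    expect_equal(got$brock_lp, expected_lp, tolerance = 1e-9)
    expect_equal(got$brock_probability, plogis(expected_lp), tolerance = 1e-6)
  }
})

test_that("variant term removal is exact", {
  d <- brock_case(67, "female", TRUE, TRUE, TRUE, "part_solid", 2, TRUE)
  lp_full <- brock_linear_predictor(d, 12, "full")
  lp_nospic <- brock_linear_predictor(d, 12, "no_spiculation")
  expect_equal(lp_full - lp_nospic, 0.7729, tolerance = 1e-12)

  # morphological + non-morphological partition the full predictor
  lp_m <- brock_linear_predictor(d, 12, "morphological_only")
  lp_nm <- brock_linear_predictor(d, 12, "non_morphological")
  b0 <- brock_coefficients()$intercept
  expect_equal((lp_m - b0) + (lp_nm - b0), lp_full - b0, tolerance = 1e-12)
})

test_that("the linear predictor reduces to the intercept at reference values", {
  ref <- brock_case(62, "male", FALSE, FALSE, FALSE, "solid", 4, FALSE)
  lp <- brock_linear_predictor(ref, 4, "full")
  # the published centring constant is printed to 8 decimals, so the size
  # term at the 4 mm reference leaves a sub-nano residue
  expect_equal(lp, brock_coefficients()$intercept, tolerance = 1e-8)
})

test_that("risk increases strictly with nodule size", {
  d <- brock_case(62, "male", FALSE, FALSE, FALSE, "solid", 4, FALSE)
  sizes <- seq(6, 30, by = 0.5)
  risks <- vapply(sizes, function(s) brock_risk(d, s)$brock_probability,
                  numeric(1))
  expect_true(all(diff(risks) > 0))
  r8 <- brock_risk(d, 8)$brock_probability
  r16 <- brock_risk(d, 16)$brock_probability
  expect_gt(r16, r8)
})

test_that("probabilities stay in (0,1) over random valid inputs", {
  set.seed(31)
  n <- 10000
  df <- tibble::tibble(
    age_years = sample(45:90, n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    family_history = sample(c(TRUE, FALSE), n, TRUE),
    emphysema = sample(c(TRUE, FALSE), n, TRUE),
    upper_lobe = sample(c(TRUE, FALSE), n, TRUE),
    nodule_type = sample(c("solid", "part_solid"), n, TRUE),
    nodule_count = sample(1:10, n, TRUE),
    spiculation = sample(c(TRUE, FALSE), n, TRUE))
  p <- brock_risk(df, runif(n, 1, 30))$brock_probability
  expect_true(all(p > 0 & p < 1))
})

test_that("sizes and coefficients are validated", {
  d <- brock_case(62, "male", FALSE, FALSE, FALSE, "solid", 4, FALSE)
  expect_error(brock_linear_predictor(d, -1), "positive")
  expect_warning(brock_linear_predictor(d, 32), "30 mm")
  broken <- brock_coefficients()
  broken$terms$size <- NULL
  expect_error(brock_linear_predictor(d, 10, coefficients = broken), "missing")
})

test_that("AUC is invariant between probabilities and linear predictors", {
  set.seed(8)
  cfg <- tiny_cohort_config(seed = 8, n = 200)
  co <- generate_cohort(cfg)
  scored <- suppressWarnings(brock_risk(co, "manual_diameter_mm"))
  expect_equal(auc(scored$brock_probability, co$malignant),
               auc(scored$brock_lp, co$malignant))
})

test_that("refit mode recovers generative structure directionally", {
  cfg <- tiny_cohort_config(seed = 15, n = 400)
  co <- generate_cohort(cfg)
  fit <- brock_refit(co, "manual_diameter_mm", co$malignant, "full")
  expect_true("size" %in% fit$term)
  # the refitted coefficient on the (d/10)^-0.5 transform must share the
  # published negative sign, since the transform decreases with size
  expect_lt(fit$estimate[fit$term == "size"], 0)
  expect_length(attr(fit, "fitted"), nrow(co))
})
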