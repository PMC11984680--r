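test_that("age_accel is the OLS residual of GrimAge on age", {
  age <- c(60, 65, 70, 75, 80)
  expect_equal(age_accel(2 * age, age), rep(0, 5), tolerance = 1e-12)

  set.seed(3)
  grim <- 0.8 * age + rnorm(5, 0, 2)
  r <- age_accel(grim, age)
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(abs(cor(r, age)), 1e-10)

  # closed-form simple regression oracle
  b <- cov(grim, age) / var(age)
  a <- mean(grim) - b * mean(age)
  expect_equal(r, grim - a - b * age, tolerance = 1e-10)

  # invariance to adding a constant to grimage
  expect_equal(age_accel(grim + 11.3, age), r, tolerance = 1e-10)
  expect_error(age_accel(grim, rep(70, 5)), "degenerate")
  expect_error(age_accel(grim[1:2], age[1:2]), "length")
})

test_that("fit_glm matches the normal-equations oracle", {
  set.seed(10)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1 + 2 * x1 - 0.5 * x2 + rnorm(n)
  res <- fit_glm(y, list(x1 = x1, x2 = x2), "x1")

  X <- cbind(1, x1, x2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  e <- y - X %*% beta
  s2 <- sum(e^2) / (n - 3)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(res$terms$estimate, unname(drop(beta)), tolerance = 1e-8)
  expect_equal(res$terms$t, unname(drop(beta) / se), tolerance = 1e-8)
  expect_equal(res$df_residual, n - 3)

  # zero-noise planted slope: exact coefficient, p numerically zero
  y0 <- 3 + 0.7 * x1
  r0 <- suppressWarnings(fit_glm(y0, list(x1 = x1, x2 = x2), "x1"))
  expect_equal(glm_term(r0)$estimate, 0.7, tolerance = 1e-10)
  expect_lt(glm_term(r0)$p, 1e-12)

  # t and p invariant under affine rescaling of a covariate
  r1 <- fit_glm(y, list(x1 = 10 * x1 + 5, x2 = x2), "x1")
  expect_equal(glm_term(r1)$t, glm_term(res)$t, tolerance = 1e-10)
  expect_equal(glm_term(r1)$estimate, glm_term(res)$estimate / 10,
               tolerance = 1e-10)

  expect_error(fit_glm(y, list(x1 = x1, x1b = x1), "x1"), "collinearity")
})

test_that("change-score ANCOVA reduces to the t^2 identity", {
  set.seed(12)
  n <- 30
  yb <- rnorm(n); yf <- yb + 0.3 + rnorm(n, 0, 0.5)
  sex <- rbinom(n, 1, 0.5); age <- runif(n, 58, 81); aag <- rnorm(n, 0, 4)
  res <- longitudinal_model(yb, yf, list(age_accel_grim = aag, sex = sex,
                                         age_baseline = age),
                            "age_accel_grim")
  ref <- lm(I(yf - yb) ~ aag + sex + age)
  tval <- summary(ref)$coefficients["aag", 3]
  expect_equal(res$F_statistic, tval^2, tolerance = 1e-10)
  expect_equal(res$df_numerator, 1L)
  expect_equal(res$df_denominator, n - 4)

  # identical timepoints: mean-change F ~ 0, p ~ 1
  null <- longitudinal_model(yb, yb, list(sex = sex, age_baseline = age))
  expect_equal(null$F_statistic, 0)
  expect_equal(null$p_value, 1)

  expect_error(longitudinal_model(yb, rep(NA_real_, n)), "complete")
})

test_that("the planted generative longitudinal interaction is detectable", {
  # peri-lesional free-water growth in the generator carries the
  # AgeAccelGrim x time interaction even before any imaging
  hits <- 0
  for (s in 1:10) {
    sim <- generate_cohort(60, cohort_effects(), seed = s)
    co <- sim$cohort[sim$cohort$timepoint == "baseline", ]
    ret <- which(co$retained_at_followup)
    pen_delta <- vapply(co$subject_id[ret], function(id) {
      ph <- sim$phantoms[[id]]
      ph$followup$lesions[[1]]$penumbra_delta_eci -
        ph$baseline$lesions[[1]]$penumbra_delta_eci
    }, 0)
    res <- longitudinal_model(rep(0, length(ret)), pen_delta,
                              list(age_accel_grim = co$age_accel_grim[ret],
                                   sex = co$sex01[ret],
                                   age_baseline = co$age_years[ret]),
                              "age_accel_grim")
    if (res$p_value < 0.05 && res$estimate > 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("missingness t-tests match the pooled-variance closed form", {
  co <- data.frame(timepoint = "baseline",
                   retained_at_followup = c(TRUE, TRUE, FALSE, FALSE),
                   age_years = c(60, 62, 64, 70),
                   sex01 = c(0, 1, 0, 1))
  out <- missingness_tests(co, variables = c("age_years", "sex01"))
  x <- c(60, 62); y <- c(64, 70)
  sp <- sqrt((var(x) + var(y)) / 2)
  t_hand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 2 + 1 / 2))
  expect_equal(out$t_statistic[1], t_hand, tolerance = 1e-12)
  expect_equal(out$df[1], 2)

  co2 <- co; co2$age_years <- c(60, 62, 60, 62); co2$sex01 <- c(0, 1, 0, 1)
  out2 <- missingness_tests(co2, variables = c("age_years", "sex01"))
  expect_equal(out2$t_statistic, c(0, 0))
  expect_equal(out2$p, c(1, 1))

  co3 <- co; co3$retained_at_followup <- TRUE
  expect_error(missingness_tests(co3), "non-empty")
})
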