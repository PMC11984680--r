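test_that("cohort generation is deterministic and respects its invariants", {
  sim1 <- generate_cohort(30, cohort_effects(), seed = 4)
  sim2 <- generate_cohort(30, cohort_effects(), seed = 4)
  expect_identical(sim1$cohort, sim2$cohort)

  base <- sim1$cohort[sim1$cohort$timepoint == "baseline", ]
  expect_equal(nrow(base), 30)
  expect_true(all(base$age_years >= 58 & base$age_years <= 81))
  expect_lt(abs(mean(base$age_accel_grim)), 1e-9)
  expect_lt(abs(cor(base$age_accel_grim, base$age_years)), 1e-9)
  expect_equal(sum(base$retained_at_followup), round(30 * 41 / 98))
  fu <- sim1$cohort[sim1$cohort$timepoint == "followup", ]
  expect_equal(nrow(fu), sum(base$retained_at_followup))
  expect_true(all(fu$age_years - base$age_years[match(fu$subject_id,
                                                      base$subject_id)] == 2))
  expect_true(all(base$wmh_volume > 0))
  # follow-up lesions never shrink
  expect_true(all(fu$wmh_volume >=
                    base$wmh_volume[match(fu$subject_id, base$subject_id)]))

  expect_error(generate_cohort(5), "n_subjects")
  expect_error(cohort_effects(wmh_sd = -1), "negative variance")
  expect_error(cohort_effects(nonsense = 1), "unknown effect")
})

test_that("a null WMH slope is covered and a planted one is recovered", {
  null_cover <- 0
  pos_sign <- 0
  for (s in 1:20) {
    sim0 <- generate_cohort(150, cohort_effects(wmh_gamma1 = 0), seed = s)
    b0 <- sim0$cohort[sim0$cohort$timepoint == "baseline", ]
    r0 <- fit_glm(b0$wmh_volume, list(age_accel_grim = b0$age_accel_grim),
                  "age_accel_grim")
    tt <- glm_term(r0)
    ci <- tt$estimate + c(-1, 1) * qt(0.975, r0$df_residual) * tt$se
    if (ci[1] <= 0 && ci[2] >= 0) null_cover <- null_cover + 1

    sim1 <- generate_cohort(98, cohort_effects(), seed = s)
    b1 <- sim1$cohort[sim1$cohort$timepoint == "baseline", ]
    r1 <- fit_glm(b1$wmh_volume, list(age_accel_grim = b1$age_accel_grim),
                  "age_accel_grim")
    if (glm_term(r1)$estimate > 0) pos_sign <- pos_sign + 1
  }
  expect_gte(null_cover, 18)   # >= 90% coverage of the null
  expect_gte(pos_sign, 19)     # >= 95% sign recovery of the planted slope
})

test_that("follow-up specs drift identically in whole-mask free water", {
  sim <- generate_cohort(12, cohort_effects(retention_frac = 1), seed = 2)
  drift <- vapply(sim$phantoms, function(ph) {
    rb <- lesionometry:::rasterize_phantom(ph$baseline)
    rf <- lesionometry:::rasterize_phantom(ph$followup)
    mean(rf$frac[rf$mask, 1]) - mean(rb$frac[rb$mask, 1])
  }, 0)
  # balanced to the common drift: no subject-specific component
  expect_lt(max(abs(drift - cohort_effects()$drift_eci)), 1e-9)
})
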