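test_that("cardiac metric identities hold record-wise to machine precision", {
  set.seed(41)
  rec <- data.frame(dlvv_ml = runif(50, 0.03, 0.07))
  rec$slvv_ml <- rec$dlvv_ml * runif(50, 0.3, 0.9)
  rec$hr_bpm <- runif(50, 300, 600)
  rec$weight_g <- runif(50, 20, 50)
  out <- derive_metrics(rec)
  expect_equal(out$sv_ml, out$dlvv_ml - out$slvv_ml)
  expect_equal(out$ef_pct, 100 * out$sv_ml / out$dlvv_ml)
  expect_equal(out$co_ml_min, out$sv_ml * out$hr_bpm)
  expect_equal(out$ci_ml_min_g, out$co_ml_min / out$weight_g)
  expect_true(all(out$ef_pct >= 0 & out$ef_pct <= 100))
  # group-mean linearity: mean SV = mean DLVV - mean SLVV on any subset
  sub <- out[seq(1, 50, by = 3), ]
  expect_equal(mean(sub$sv_ml), mean(sub$dlvv_ml) - mean(sub$slvv_ml))
})

test_that("metric closed forms and degenerate records", {
  r <- derive_metrics(data.frame(dlvv_ml = 0.045, slvv_ml = 0.022,
                                 hr_bpm = 450, weight_g = 30))
  expect_equal(r$sv_ml, 0.023)
  r2 <- derive_metrics(data.frame(dlvv_ml = 0.05, slvv_ml = 0.03,
                                  hr_bpm = 450, weight_g = 40))
  expect_equal(r2$sv_ml, 0.02)
  expect_equal(r2$ef_pct, 40)
  expect_equal(r2$co_ml_min, 9)
  expect_equal(r2$ci_ml_min_g, 0.225)
  r3 <- derive_metrics(data.frame(dlvv_ml = 0.04, slvv_ml = 0.04,
                                  hr_bpm = 400, weight_g = 30))
  expect_equal(c(r3$sv_ml, r3$ef_pct, r3$co_ml_min, r3$ci_ml_min_g),
               c(0, 0, 0, 0))
  expect_error(derive_metrics(data.frame(dlvv_ml = 0, slvv_ml = 0,
                                         hr_bpm = 400, weight_g = 30)),
               "DLVV")
  expect_error(derive_metrics(data.frame(dlvv_ml = 0.03, slvv_ml = 0.05,
                                         hr_bpm = 400, weight_g = 30)),
               "SLVV")
})

test_that("cohort summaries reproduce the reference composition exactly", {
  cs <- summarize_cohort(cohort_counts())
  expect_equal(cs$total, 123)
  s <- cs$summary
  expect_equal(s$male[s$genotype == "APOE2"], 17)
  expect_equal(s$female[s$genotype == "APOE2"], 10)
  ref <- data.frame(genotype = c("APOE2", "APOE3", "APOE4", "APOE KO"),
                    pct_hn = c(44.4, 47.6, 57.1, NA),
                    pct_hfd = c(55.6, 66.7, 51.4, 52.6))
  m <- match(ref$genotype, s$genotype)
  expect_equal(round(s$pct_hn[m], 1), ref$pct_hn)
  expect_equal(round(s$pct_hfd[m], 1), ref$pct_hfd)
  # all-control toy cohort
  toy <- data.frame(diet = "CTRL", genotype = c("APOE2", "APOE3"),
                    sex = "Male", count = c(3, 4))
  expect_equal(summarize_cohort(toy)$summary$pct_hfd, c(0, 0))
})

test_that("age outliers are removed by the 1.5 IQR rule per genotype x sex", {
  rec <- data.frame(genotype = "APOE2", sex = "Male",
                    age_months = c(9, 9, 9, 9, 30))
  out <- remove_age_outliers(rec)
  expect_equal(nrow(out$records), 4)
  expect_equal(out$removed$age_months, 30)
  # identical ages: IQR 0, nothing removed
  same <- data.frame(genotype = "APOE3", sex = "Female",
                     age_months = rep(12, 6))
  expect_equal(nrow(remove_age_outliers(same)$records), 6)
  # undersized group passes through with a warning
  small <- data.frame(genotype = "APOE4", sex = "Male", age_months = c(5, 40))
  expect_warning(out2 <- remove_age_outliers(small), "fewer than 4")
  expect_equal(nrow(out2$records), 2)
  # quantile convention: type-7 (linear interpolation)
  g <- c(8, 9, 10, 11, 20)
  q <- quantile(g, c(.25, .75), type = 7)
  hi <- q[2] + 1.5 * (q[2] - q[1])
  rec2 <- data.frame(genotype = "KO", sex = "Male", age_months = g)
  expect_equal(nrow(remove_age_outliers(rec2)$records), sum(g <= hi))
})

test_that("single-factor ANOVA F equals the squared pooled t statistic", {
  set.seed(43)
  d <- data.frame(g = factor(rep(c("a", "b"), each = 12)),
                  y = rnorm(24) + rep(c(0, 1), each = 12))
  fit <- fit_factorial_model(d, "y", formula = y ~ g)
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_lt(abs(fit$anova$F[fit$anova$term == "g"] - tt$statistic^2), 1e-9)
  # constant response: all F statistics are zero
  d$y <- 5
  fit0 <- fit_factorial_model(d, "y", formula = y ~ g)
  expect_equal(fit0$anova$F[fit0$anova$term == "g"], 0)
})

test_that("the factorial model tolerates the structural HN aliasing in KO", {
  rec <- derive_metrics(simulate_cohort(seed = 2))
  fit <- fit_factorial_model(rec, "co_ml_min")
  expect_true(all(is.finite(fit$anova$p[!is.na(fit$anova$p)])))
  expect_true(any(grepl("KO", fit$aliased))) # HN-within-KO columns dropped
  expect_true("Residuals" %in% fit$anova$term)
  expect_true(all(fit$anova$p >= 0 & fit$anova$p <= 1, na.rm = TRUE))
  expect_error(fit_factorial_model(rec, "not_a_column"), "not found")
})

test_that("Tukey-adjusted post hocs via estimated marginal means", {
  rec <- derive_metrics(simulate_cohort(seed = 3, diet_effect_hr = -40))
  fit <- stats::lm(hr_bpm ~ sex + weight_g + diet * genotype, data = rec)
  ct <- posthoc_contrasts(fit, ~ diet | genotype)
  expect_equal(nrow(ct), 4) # one CTRL-HFD pair per genotype
  # family of one: adjusted equals unadjusted
  expect_equal(ct$p_adj, ct$p_unadj, tolerance = 1e-12)
  # k = 3 family: monotone adjustment
  ct3 <- posthoc_contrasts(stats::lm(hr_bpm ~ genotype, data = rec),
                           ~ genotype)
  expect_true(all(ct3$p_adj >= ct3$p_unadj - 1e-12))
})

test_that("biserial correlation endpoints", {
  # equal group means -> exactly zero
  x <- c(1, 2, 3, 1, 2, 3)
  b <- c("a", "a", "a", "h", "h", "h")
  expect_equal(biserial_correlation(b, x)$r, 0)
  # full separation with degenerate within-group values -> |r| = 1
  xs <- c(rep(0, 5), rep(1, 7))
  bs <- c(rep("ctrl", 5), rep("hfd", 7))
  expect_equal(abs(biserial_correlation(bs, xs)$r), 1)
  expect_error(biserial_correlation(rep("a", 4), 1:4), "two levels")
  # null simulation: p roughly uniform, |r| small
  set.seed(44)
  ps <- replicate(100, {
    biserial_correlation(rep(c("a", "b"), each = 20), rnorm(40))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Cohen's f matches its closed form and hand computation", {
  # single factor with SS_factor == SS_residual -> eta2 = 0.5 -> f = 1
  d <- data.frame(g = factor(rep(c("a", "b"), each = 2)),
                  y = c(-1, 1, 1, 3))
  fit <- fit_factorial_model(d, "y", formula = y ~ g)
  ss_f <- fit$anova$sum_sq[fit$anova$term == "g"]
  ss_r <- fit$anova$sum_sq[fit$anova$term == "Residuals"]
  expect_equal(ss_f, ss_r) # both 4
  expect_equal(cohen_f(fit, "g"), 1, tolerance = 1e-9)
  # hand computation on an unbalanced toy set
  d2 <- data.frame(g = factor(c("a", "a", "b", "b", "b")),
                   y = c(1, 3, 4, 6, 8))
  fit2 <- fit_factorial_model(d2, "y", formula = y ~ g)
  eta2 <- fit2$anova$sum_sq[1] / sum(fit2$anova$sum_sq)
  expect_lt(abs(cohen_f(fit2, "g") - sqrt(eta2 / (1 - eta2))), 1e-9)
  expect_equal(cohen_f(fit_factorial_model(
    data.frame(g = factor(c("a", "a", "b", "b")), y = c(1, 2, 1, 2)),
    "y", formula = y ~ g), "g"), 0)
  expect_error(cohen_f(fit2, "nope"), "not in")
})

test_that("synthetic cohort generator mirrors the packaged group structure", {
  rec <- simulate_cohort(seed = 5)
  expect_equal(nrow(rec), 123)
  expect_setequal(unique(rec$genotype), c("APOE2", "APOE3", "APOE4", "APOE KO"))
  expect_true(all(rec$hn[rec$genotype == "APOE KO"] == 0))
  expect_true(all(rec$slvv_ml <= rec$dlvv_ml))
  expect_identical(simulate_cohort(seed = 5), rec)
})
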