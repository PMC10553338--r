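# Reproducible study harnesses: heart-rate recovery over seeded noise
# realizations, and the power of the factorial model to detect an injected
# sex effect. These are the simulation experiments the package's validation
# reports are built from.

#' Heart-rate recovery study
#'
#' For each truth heart rate, simulates a beating phantom, acquires a
#' 1000-view scan at the 100 Hz view rate with counting noise, and runs the
#' full intrinsic gating chain; repeated over independent noise seeds.
#'
#' @param rates truth heart rates, bpm.
#' @param n_seeds noise realizations per rate.
#' @param seed base seed.
#' @param views,n_rotations scan protocol.
#' @param n,voxel_mm simulation grid (desk-scale default 64 at 0.375 mm).
#' @return data.frame: rate, seed, recovered (bpm), abs_error.
#' @export
gating_recovery_study <- function(rates = c(320, 450, 580), n_seeds = 7,
                                  seed = 1, views = 1000, n_rotations = 5,
                                  n = 64, voxel_mm = 0.375) {
  proj <- projector(n, voxel_mm)
  rows <- list()
  for (r in rates) {
    ph <- make_dynamic_phantom(n = n, voxel_mm = voxel_mm, heart_rate = r)
    for (k in seq_len(n_seeds)) {
      s <- stage_seed(seed, sprintf("hr%g_%d", r, k))
      sino <- acquire(ph, acquisition_config(views = views,
                                             n_rotations = n_rotations,
                                             seed = s), proj)
      gr <- intrinsic_gating(sino, proj = proj)
      rows[[length(rows) + 1]] <- data.frame(rate = r, seed = s,
                                             recovered = gr$heart_rate,
                                             abs_error = abs(gr$heart_rate - r))
    }
  }
  do.call(rbind, rows)
}

#' Power of the factorial model for an injected sex effect
#'
#' Simulates cohorts of size `n` with a pure additive sex effect of
#' `effect_sd` standard deviations (all other factors null), fits the full
#' factorial model, and reports the fraction of repetitions in which the
#' sex term is detected below `alpha`.
#'
#' @param n_reps simulation repetitions.
#' @param n animals per cohort.
#' @param effect_sd effect size in residual standard deviations.
#' @param alpha detection level.
#' @param seed base seed.
#' @return list with `power`, `p_values`, and the settings.
#' @export
sex_effect_power <- function(n_reps = 500, n = 120, effect_sd = 2,
                             alpha = 0.01, seed = 1) {
  p_values <- with_seed(seed, vapply(seq_len(n_reps), function(i) {
    genotype <- sample(c("APOE2", "APOE3", "APOE4", "APOE KO"), n, replace = TRUE)
    d <- data.frame(
      sex = sample(rep(c("Male", "Female"), length.out = n)),
      age_months = stats::rnorm(n, 12, 1),
      weight_g = stats::rnorm(n, 30, 5),
      genotype = genotype,
      hn = ifelse(genotype == "APOE KO", 0L, stats::rbinom(n, 1, 0.5)))
    d$y <- effect_sd * (d$sex == "Male") + stats::rnorm(n)
    fit <- fit_factorial_model(d, "y", terms = "sex")
    fit$anova$p[fit$anova$term == "sex"]
  }, numeric(1)))
  list(power = mean(p_values < alpha), p_values = p_values,
       n = n, effect_sd = effect_sd, alpha = alpha)
}
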