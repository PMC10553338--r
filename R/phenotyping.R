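# Cardiac function metrics, cohort bookkeeping, and the statistical
# analysis: metric identities (SV, EF, CO, CI), IQR age-outlier removal,
# factorial linear models with aliasing-tolerant type-II ANOVA, Tukey
# post hocs via estimated marginal means, Cohen's f effect sizes and the
# point-biserial diet-weight correlation.

#' Derive cardiac function metrics for one or more records
#'
#' Populates stroke volume `SV = DLVV - SLVV` (mL), ejection fraction
#' `EF = 100 * SV / DLVV` (%), cardiac output `CO = SV * HR` (mL/min) and
#' cardiac index `CI = CO / weight` (mL/(min*g)).
#'
#' @param records data.frame with columns `dlvv_ml`, `slvv_ml`, `hr_bpm`,
#'   `weight_g`.
#' @return the data.frame with `sv_ml`, `ef_pct`, `co_ml_min`,
#'   `ci_ml_min_g` columns added.
#' @export
derive_metrics <- function(records) {
  need <- c("dlvv_ml", "slvv_ml", "hr_bpm", "weight_g")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  with(records, {
    if (any(slvv_ml > dlvv_ml)) stopf("SLVV exceeds DLVV in some records")
    if (any(dlvv_ml <= 0)) stopf("EF undefined: DLVV must be positive")
    if (any(weight_g <= 0) || any(hr_bpm <= 0)) stopf("weight and HR must be positive")
  })
  records$sv_ml <- records$dlvv_ml - records$slvv_ml
  records$ef_pct <- 100 * records$sv_ml / records$dlvv_ml
  records$co_ml_min <- records$sv_ml * records$hr_bpm
  records$ci_ml_min_g <- records$co_ml_min / records$weight_g
  records
}

#' Summarize cohort composition by APOE isoform
#'
#' From group counts keyed by (diet, genotype-with-HN-line, sex), pools the
#' HN and non-HN lines of each isoform and reports male/female totals, %HN
#' and %HFD per isoform (HN not applicable to the knockout).
#'
#' @param counts data.frame with columns `diet` (CTRL/HFD), `genotype`
#'   (e.g. APOE2, APOE2HN, APOE KO), `sex` (Male/Female), `count`.
#' @return list with `summary` (one row per isoform: male, female, pct_hn,
#'   pct_hfd) and `total` subjects.
#' @export
summarize_cohort <- function(counts) {
  iso <- sub("HN$", "", counts$genotype)
  hn <- grepl("HN$", counts$genotype)
  isoforms <- unique(iso)
  rows <- lapply(isoforms, function(g) {
    k <- iso == g
    tot <- sum(counts$count[k])
    data.frame(
      genotype = g,
      male = sum(counts$count[k & counts$sex == "Male"]),
      female = sum(counts$count[k & counts$sex == "Female"]),
      pct_hn = if (any(hn[k])) 100 * sum(counts$count[k & hn]) / tot else NA_real_,
      pct_hfd = 100 * sum(counts$count[k & counts$diet == "HFD"]) / tot)
  })
  list(summary = do.call(rbind, rows), total = sum(counts$count))
}

#' Load the packaged cohort group counts
#'
#' @return data.frame of per-group subject counts (diet x genotype line x
#'   sex) for the 123-mouse APOE cohort.
#' @export
cohort_counts <- function() {
  utils::read.csv(system.file("extdata", "cohort_counts.csv",
                              package = "pcctcardiac"),
                  stringsAsFactors = FALSE)
}

#' Remove age outliers by the 1.5 IQR rule within genotype x sex groups
#'
#' Within each of the eight groups (four isoforms x two sexes), records with
#' age outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (type-7 quantiles) are
#' dropped. Groups with fewer than 4 records pass through unfiltered with a
#' warning.
#'
#' @param records data.frame with `genotype` (isoform, HN pooled or not),
#'   `sex`, `age_months`.
#' @return list with `records` (filtered) and `removed` (log of removals).
#' @export
remove_age_outliers <- function(records) {
  iso <- sub("HN$", "", records$genotype)
  grp <- interaction(iso, records$sex, drop = TRUE)
  keep <- rep(TRUE, nrow(records))
  removed <- list()
  for (g in levels(grp)) {
    k <- which(grp == g)
    if (length(k) < 4) {
      warnf("group %s has fewer than 4 records: not filtered", g)
      next
    }
    q <- stats::quantile(records$age_months[k], c(0.25, 0.75), type = 7)
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr; hi <- q[2] + 1.5 * iqr
    out <- k[records$age_months[k] < lo | records$age_months[k] > hi]
    if (length(out)) {
      keep[out] <- FALSE
      removed[[g]] <- data.frame(group = g, row = out,
                                 age_months = records$age_months[out])
    }
  }
  list(records = records[keep, , drop = FALSE],
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(group = character(), row = integer(), age_months = numeric()))
}

# terms of a formula containing all factors of term t (higher-order relatives)
relatives <- function(term, terms_all) {
  tf <- strsplit(term, ":", fixed = TRUE)[[1]]
  vapply(terms_all, function(o) {
    of <- strsplit(o, ":", fixed = TRUE)[[1]]
    o != term && all(tf %in% of)
  }, logical(1))
}

#' Factorial linear model with type-II ANOVA
#'
#' Fits `response ~ Sex * Age * Weight * HN * Genotype` (body weight in
#' place of diet) by ordinary least squares and computes a type-II ANOVA by
#' model comparison: each term is tested against the model containing all
#' terms except itself and its higher-order relatives. Structurally aliased
#' columns (e.g. HN within the knockout genotype, where HN is identically
#' 0) are tolerated: rank-deficient fits drop them and the dropped count is
#' reported.
#'
#' @param records data.frame with columns `sex`, `age_months`, `weight_g`,
#'   `hn` (0/1), `genotype` (isoform factor incl. KO), and the response.
#' @param response one of `dlvv_ml`, `slvv_ml`, `hr_bpm`, `sv_ml`,
#'   `ef_pct`, `co_ml_min`, `ci_ml_min_g` (or any numeric column).
#' @param formula optional model formula overriding the default factorial.
#' @param terms optional character vector restricting the ANOVA table to
#'   these terms (all model terms by default); useful in simulation loops.
#' @return object of class `factorial_fit`: `$fit` (the `lm`), `$anova`
#'   (data.frame: term, df, sum_sq, F, p), `$aliased` dropped-column names.
#' @export
fit_factorial_model <- function(records, response, formula = NULL, terms = NULL) {
  if (!response %in% names(records)) stopf("response %s not found", response)
  if ("genotype" %in% names(records)) {
    records$genotype <- factor(records$genotype)
    if ("APOE2" %in% levels(records$genotype))
      records$genotype <- stats::relevel(records$genotype, ref = "APOE2")
  }
  if ("sex" %in% names(records)) records$sex <- factor(records$sex)
  if (is.null(formula))
    formula <- stats::as.formula(
      sprintf("%s ~ sex * age_months * weight_g * hn * genotype", response))
  fit <- stats::lm(formula, data = records, singular.ok = TRUE)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  # residual variance from the full fit
  rss_full <- sum(stats::residuals(fit)^2)
  df_res <- fit$df.residual
  if (df_res <= 0) stopf("no residual degrees of freedom")
  s2 <- rss_full / df_res
  trm <- attr(stats::terms(fit), "term.labels")
  rss_of <- function(terms_inc) {
    if (length(terms_inc) == 0) {
      m <- stats::lm(stats::as.formula(sprintf("%s ~ 1", response)), data = records)
      return(c(rss = sum(stats::residuals(m)^2), rank = 1))
    }
    f <- stats::as.formula(paste(response, "~", paste(terms_inc, collapse = "+")))
    m <- stats::lm(f, data = records, singular.ok = TRUE)
    c(rss = sum(stats::residuals(m)^2), rank = m$rank)
  }
  wanted <- if (is.null(terms)) trm else intersect(trm, terms)
  rows <- lapply(wanted, function(t) {
    rel <- trm[relatives(t, trm)]
    base_terms <- setdiff(trm, c(t, rel))
    m0 <- rss_of(base_terms)
    m1 <- rss_of(c(base_terms, t))
    df <- m1["rank"] - m0["rank"]
    if (is.na(df) || df == 0)
      return(data.frame(term = t, df = 0, sum_sq = 0, F = NA_real_, p = NA_real_))
    ss <- max(m0["rss"] - m1["rss"], 0)
    Fv <- if (ss <= 1e-12 && s2 <= 1e-12) 0 else (ss / df) / s2
    data.frame(term = t, df = unname(df), sum_sq = unname(ss),
               F = unname(Fv), p = unname(stats::pf(Fv, df, df_res, lower.tail = FALSE)))
  })
  an <- do.call(rbind, rows)
  an <- rbind(an, data.frame(term = "Residuals", df = df_res, sum_sq = rss_full,
                             F = NA_real_, p = NA_real_))
  structure(list(fit = fit, anova = an, aliased = aliased,
                 response = response, data = records),
            class = "factorial_fit")
}

#' Tukey-adjusted post hoc contrasts
#'
#' Estimated marginal means (covariates at their means) over the cells of
#' `spec`, with pairwise differences and Tukey-method multiplicity
#' adjustment, via the emmeans machinery.
#'
#' @param fit a [fit_factorial_model()] result or an `lm`.
#' @param spec emmeans specification, e.g. `~ diet | genotype` for
#'   CTRL-vs-HFD within each genotype, or `~ hn | genotype * diet`.
#' @return data.frame of contrasts: contrast, grouping columns, estimate,
#'   SE, df, t, `p_adj` (Tukey within each family) and `p_unadj`.
#' @export
posthoc_contrasts <- function(fit, spec) {
  lmfit <- if (inherits(fit, "factorial_fit")) fit$fit else fit
  em <- emmeans::emmeans(lmfit, spec)
  adj <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  una <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  adj$p_adj <- adj$p.value
  adj$p_unadj <- una$p.value
  adj$p.value <- NULL
  adj
}

#' Point-biserial correlation
#'
#' Correlation between a binary grouping (e.g. diet) and a continuous
#' variable (e.g. body weight), with the p-value from the exact t
#' transformation `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param binary two-level factor/character/logical vector.
#' @param continuous numeric vector.
#' @return list with `r` and `p`.
#' @export
biserial_correlation <- function(binary, continuous) {
  b <- as.integer(factor(binary)) - 1L
  if (length(unique(b)) != 2) stopf("binary variable must have exactly two levels")
  ct <- stats::cor.test(continuous, b)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Cohen's f effect size for a model term
#'
#' `f = sqrt(eta2 / (1 - eta2))` with the (partial) eta squared
#' `eta2 = SS_term / (SS_term + SS_residual)` from the type-II ANOVA table;
#' equal to the classical eta squared in single-factor designs.
#'
#' @param fit a [fit_factorial_model()] result.
#' @param term term label as it appears in `fit$anova`.
#' @return scalar effect size.
#' @export
cohen_f <- function(fit, term) {
  an <- fit$anova
  if (!term %in% an$term) stopf("term %s not in the ANOVA table", term)
  ss <- an$sum_sq[an$term == term]
  ss_res <- an$sum_sq[an$term == "Residuals"]
  eta2 <- ss / (ss + ss_res)
  sqrt(eta2 / (1 - eta2))
}

#' Simulate a synthetic cohort mirroring the packaged group structure
#'
#' Expands the packaged group counts into per-animal records with
#' configurable group effects, for power studies and pipeline demos. Ages
#' are drawn around 12 months; weights around sex- and diet-dependent
#' means; cardiac metrics from plausible murine ranges.
#'
#' @param seed RNG seed.
#' @param sex_effect_dlvv additive DLVV shift (in SD units) for males.
#' @param diet_effect_hr additive HR shift (bpm) under HFD.
#' @return data.frame of records (one row per animal) with covariates and
#'   DLVV/SLVV/HR/weight, ready for [derive_metrics()].
#' @export
simulate_cohort <- function(seed = 1, sex_effect_dlvv = 0, diet_effect_hr = 0) {
  counts <- cohort_counts()
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(counts)), function(i) {
      k <- counts$count[i]
      male <- counts$sex[i] == "Male"
      hfd <- counts$diet[i] == "HFD"
      dlvv <- stats::rnorm(k, 0.045 + if (male) sex_effect_dlvv * 0.010 else 0, 0.010)
      dlvv <- pmax(dlvv, 0.02)
      efr <- clamp(stats::rnorm(k, 0.50, 0.10), 0.2, 0.8)
      data.frame(
        id = sprintf("%s_%s_%s_%d", counts$diet[i], counts$genotype[i], counts$sex[i], seq_len(k)),
        genotype = sub("HN$", "", counts$genotype[i]),
        hn = as.integer(grepl("HN$", counts$genotype[i])),
        sex = counts$sex[i], diet = counts$diet[i],
        age_months = stats::rnorm(k, 12, 0.8),
        weight_g = pmax(stats::rnorm(k, 28 + 4 * male + 12 * hfd, 4), 15),
        dlvv_ml = dlvv, slvv_ml = dlvv * (1 - efr),
        hr_bpm = clamp(stats::rnorm(k, 450 + diet_effect_hr * hfd, 35), 300, 600))
    })
    do.call(rbind, rows)
  })
}
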