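test_that("laterality index follows the left-minus-right rule", {
  rec <- gen_clinical(1, item3_4_left = 2, item3_5_left = 3,
                      item3_4_right = 4, item3_5_right = 4)
  expect_equal(laterality_index(rec), (2 + 3) - (4 + 4))
  expect_equal(laterality_index(gen_clinical(1)), 0)
  sym <- gen_clinical(1, item3_6_left = 2, item3_6_right = 2)
  expect_equal(laterality_index(sym), 0)
  # antisymmetry under a full left/right swap
  set.seed(71)
  rec2 <- gen_clinical(5)
  for (it in c("3_4", "3_5", "3_6", "3_7", "3_8")) {
    rec2[[paste0("item", it, "_right")]] <- sample(0:4, 5, TRUE)
    rec2[[paste0("item", it, "_left")]] <- sample(0:4, 5, TRUE)
  }
  swapped <- rec2
  for (it in c("3_4", "3_5", "3_6", "3_7", "3_8")) {
    swapped[[paste0("item", it, "_right")]] <- rec2[[paste0("item", it, "_left")]]
    swapped[[paste0("item", it, "_left")]] <- rec2[[paste0("item", it, "_right")]]
  }
  expect_equal(laterality_index(swapped), -laterality_index(rec2))
  expect_error(laterality_index(rec2[, -1]), "item3_4_right")
})

test_that("bradykinesia sums respect bounds and missing items error", {
  rec <- gen_clinical(1, item3_4_right = 1, item3_5_right = 2,
                      item3_6_right = 0, item3_7_right = 3,
                      item3_8_right = 1)
  expect_identical(bradykinesia_sum(rec, "right"), 7L)
  all4 <- gen_clinical(1)
  for (it in c("3_4", "3_5", "3_6", "3_7", "3_8")) {
    all4[[paste0("item", it, "_left")]] <- 4L
  }
  expect_identical(bradykinesia_sum(all4, "left"), 20L)
  expect_identical(bradykinesia_sum(gen_clinical(1), "right"), 0L)
  expect_error(bradykinesia_sum(rec[, -2], "right"), "missing item")
  bad <- gen_clinical(1, item3_4_right = 5)
  expect_error(bradykinesia_sum(bad, "right"), "0-4")
})

test_that("subtype classification implements the ratio rule with edge cases", {
  akr <- gen_clinical(1, item3_4_right = 2, item3_4_left = 2)  # tremor mean 0
  expect_identical(subtype_classify(akr)$subtype, "akinetic_rigid_dominant")
  trem <- gen_clinical(1, item3_15 = 1)                        # brady mean 0
  expect_identical(subtype_classify(trem)$subtype, "tremor_dominant")
  both0 <- gen_clinical(1)
  expect_true(is.na(subtype_classify(both0)$subtype))
  # ratio 1.6 vs 1.4 around the 1.5 boundary (boundary itself is akinetic)
  mk <- function(trem_mean) {
    r <- gen_clinical(1, item3_14 = 1)
    for (it in c("3_4", "3_5", "3_6", "3_7", "3_8")) {
      r[[paste0("item", it, "_right")]] <- 1L
      r[[paste0("item", it, "_left")]] <- 1L
    }
    # brady mean = 1; choose tremor items summing to 4 * trem_mean
    tv <- rep(floor(trem_mean), 4)
    tv[seq_len(round((trem_mean - floor(trem_mean)) * 4))] <-
      floor(trem_mean) + 1
    for (i in 1:4) r[[paste0("item3_", 14 + i)]] <- tv[i]
    r
  }
  expect_identical(subtype_classify(mk(1.75))$subtype, "tremor_dominant")
  expect_identical(subtype_classify(mk(1.25))$subtype,
                   "akinetic_rigid_dominant")
  expect_identical(subtype_classify(mk(1.5))$subtype,
                   "akinetic_rigid_dominant")
})

test_that("item-4 exclusion removes exactly the flagged observations", {
  d <- gen_clinical(5, item3_4_right = c(0, 4, 2, 4, 1))
  out <- exclude_item4_observations(d, "item3_4_right")
  expect_identical(nrow(out), 3L)
  expect_identical(attr(out, "n_removed"), 2L)
  none <- exclude_item4_observations(gen_clinical(3), "item3_4_right")
  expect_identical(nrow(none), 3L)
  expect_identical(attr(none, "n_removed"), 0L)
  all4 <- gen_clinical(2, item3_4_right = 4)
  expect_warning(empty <- exclude_item4_observations(all4, "item3_4_right"),
                 "all observations")
  expect_identical(nrow(empty), 0L)
  expect_error(exclude_item4_observations(d, "item9"), "item9")
})

test_that("therapy-state LME detects a planted state effect", {
  set.seed(80)
  n_s <- 10; n_t <- 12
  d <- expand.grid(subject_id = sprintf("S%02d", 1:n_s),
                   event_index = 1:n_t,
                   med_state = c("OFF", "ON"), stim_state = c("OFF", "ON"))
  eff <- c("OFF/OFF" = 0, "ON/OFF" = 0.3, "OFF/ON" = 0.35, "ON/ON" = 0.8)
  u <- rnorm(n_s, 0, 0.5)
  d$norm_accel_magnitude <- eff[paste(d$med_state, d$stim_state, sep = "/")] +
    u[as.integer(factor(d$subject_id))] + rnorm(nrow(d), 0, 0.5)
  fit <- lme_single_trial(d, "norm_accel_magnitude")
  expect_identical(fit$anova$term, "therapy_state")
  expect_lt(fit$anova$p, 0.001)
  expect_identical(fit$anova$df_method, "satterthwaite")
  ph <- tukey_posthoc(fit)
  expect_identical(nrow(ph), 6L)
  expect_true(all(ph$p_adj >= 2 * pt(abs(ph$t), ph$df, lower.tail = FALSE) -
                    1e-12))
  # the extreme contrast is the largest and significant
  extreme <- ph[ph$contrast == "OFF/OFF - ON/ON", ]
  expect_lt(extreme$p_adj, 0.01)
  expect_error(lme_single_trial(d[d$subject_id == "S01", ],
                                "norm_accel_magnitude"), "2 subjects")
  expect_error(lme_single_trial(d[1:5, ], "nope"), "missing column")
})

test_that("with random variances forced to zero the F test equals one-way ANOVA", {
  set.seed(81)
  d <- expand.grid(subject_id = sprintf("S%02d", 1:8), event_index = 1:10,
                   med_state = c("OFF", "ON"), stim_state = c("OFF", "ON"))
  mu <- c("OFF/OFF" = 0, "ON/OFF" = 0.1, "OFF/ON" = 0.2, "ON/ON" = 0.4)
  d$y <- mu[paste(d$med_state, d$stim_state, sep = "/")] + rnorm(nrow(d))
  fit <- lme_single_trial(d, "y", random = "none")
  expect_true(any(grepl("least squares", fit$notes)))
  d$state <- factor(paste(d$med_state, d$stim_state, sep = "/"))
  aov_f <- anova(lm(y ~ state, data = d))
  expect_equal(fit$anova$F, aov_f[["F value"]][1], tolerance = 1e-6)
  expect_equal(fit$anova$p, aov_f[["Pr(>F)"]][1], tolerance = 1e-6)
  expect_equal(fit$anova$ddf, aov_f$Df[2])
})

test_that("Tukey table matches the classical HSD oracle on balanced data", {
  set.seed(82)
  d <- expand.grid(subject_id = sprintf("S%02d", 1:6), event_index = 1:5,
                   med_state = c("OFF", "ON"), stim_state = c("OFF", "ON"))
  d$y <- rnorm(nrow(d), mean = c(0, 0.5, 1, 2)[as.integer(
    factor(paste(d$med_state, d$stim_state, sep = "/")))])
  fit <- lme_single_trial(d, "y")          # singular -> OLS path
  ph <- tukey_posthoc(fit)
  want <- oracle_tukey_hsd(d$y, factor(paste(d$med_state, d$stim_state,
                                             sep = "/"),
                                       levels = c("OFF/OFF", "ON/OFF",
                                                  "OFF/ON", "ON/ON")))
  got <- ph[match(want$contrast, ph$contrast), ]
  expect_equal(got$estimate, want$estimate, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(got$p_adj, want$p_adj, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("identical group means give Tukey p values of one", {
  set.seed(83)
  # y depends only on subject and trial; every (subject, trial) cell is
  # observed once per state, so the four state means are exactly equal
  d <- expand.grid(subject_id = sprintf("S%02d", 1:6), event_index = 1:8,
                   med_state = c("OFF", "ON"), stim_state = c("OFF", "ON"))
  cell <- rnorm(6 * 8)
  d$y <- cell[as.integer(interaction(d$subject_id, d$event_index))]
  fit <- lme_single_trial(d, "y")
  ph <- tukey_posthoc(fit)
  expect_equal(ph$estimate, rep(0, 6), tolerance = 1e-10)
  expect_equal(ph$p_adj, rep(1, 6), tolerance = 1e-8)
})

test_that("profile-on-outcome models recover coefficients and join safely", {
  set.seed(84)
  n_s <- 15
  d <- expand.grid(subject_id = sprintf("S%02d", 1:n_s),
                   med_state = c("OFF", "ON"), stim_state = c("OFF", "ON"))
  d$ft_profile <- rnorm(nrow(d))
  u <- rnorm(n_s, 0, 1)
  clin <- gen_clinical(nrow(d))
  clin$subject_id <- d$subject_id
  clin$med_state <- d$med_state
  clin$stim_state <- d$stim_state
  clin$updrs3_total <- round(20 + 3 * d$ft_profile +
                               u[as.integer(factor(d$subject_id))] +
                               rnorm(nrow(d), 0, 1))
  clin$laterality_index <- 0
  fit <- lme_profile_on_updrs(d[, c("subject_id", "med_state", "stim_state",
                                    "ft_profile")],
                              clin, outcome = "updrs3_total",
                              profile_cols = "ft_profile",
                              laterality = FALSE)
  b <- fit$coef$estimate[fit$coef$term == "ft_profile"]
  expect_lt(abs(b - 3) / 3, 0.2)
  expect_gt(fit$r2$conditional, fit$r2$marginal - 1e-12)
  # join mismatch errors list the orphan keys
  expect_error(lme_profile_on_updrs(d[-1, c("subject_id", "med_state",
                                            "stim_state", "ft_profile")],
                                    clin, outcome = "updrs3_total",
                                    profile_cols = "ft_profile"),
               "unmatched keys")
  expect_error(lme_profile_on_updrs(d[, c("subject_id", "med_state",
                                          "stim_state", "ft_profile")],
                                    clin, outcome = "nope",
                                    profile_cols = "ft_profile"), "nope")
})

test_that("near-noiseless linear outcome drives conditional R2 toward one", {
  set.seed(85)
  d <- expand.grid(subject_id = sprintf("S%02d", 1:10),
                   med_state = c("OFF", "ON"), stim_state = c("OFF", "ON"))
  d$ft_profile <- rnorm(nrow(d))
  clin <- gen_clinical(nrow(d))
  clin$subject_id <- d$subject_id
  clin$med_state <- d$med_state
  clin$stim_state <- d$stim_state
  clin$updrs3_total <- 5 * d$ft_profile + rnorm(nrow(d), 0, 0.01)
  clin$laterality_index <- 0
  fit <- lme_profile_on_updrs(d[, c("subject_id", "med_state", "stim_state",
                                    "ft_profile")], clin,
                              outcome = "updrs3_total",
                              profile_cols = "ft_profile", laterality = FALSE)
  expect_gt(fit$r2$conditional, 0.99)
})
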