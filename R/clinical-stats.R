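# Clinical derivations from MDS-UPDRS Part III item scores and the
# mixed-model layer relating kinematic profiles and therapy state to them.
# Clinical records are data.frames with one row per subject x therapy state
# and columns item3_4_right ... item3_8_left (the five bradykinesia items
# with a left/right component), item3_14 (global bradykinesia), item3_15 ..
# item3_18 (tremor items) and updrs3_total.

brady_item_cols <- function(side) {
  paste0("item", c("3_4", "3_5", "3_6", "3_7", "3_8"), "_", side)
}

check_items <- function(record, cols, fun) {
  missing_cols <- setdiff(cols, names(record))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing item(s): %s", fun,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  vals <- as.matrix(record[, cols, drop = FALSE])
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 4) ||
      any(vals != round(vals))) {
    stop(sprintf("%s: item scores must be integers in 0-4", fun),
         call. = FALSE)
  }
  invisible(vals)
}

#' Symptom laterality index
#'
#' Left-sided bradykinesia sum (items 3.4-3.8) minus the right-sided sum.
#' Negative values indicate right-dominant symptom profiles, positive
#' values left-dominant ones.
#'
#' @param record data.frame of clinical records (one or more rows).
#' @return Numeric vector, one signed index per row.
#' @export
laterality_index <- function(record) {
  bradykinesia_sum(record, "left") - bradykinesia_sum(record, "right")
}

#' One-sided bradykinesia sum score
#'
#' Integer sum of items 3.4 (finger tapping), 3.5 (hand movements), 3.6
#' (pronation-supination), 3.7 (toe tapping) and 3.8 (leg agility) for one
#' body side; range 0-20.
#'
#' @param record data.frame of clinical records.
#' @param side `"right"` or `"left"`.
#' @return Integer vector, one sum per row.
#' @export
bradykinesia_sum <- function(record, side = c("right", "left")) {
  side <- match.arg(side)
  cols <- brady_item_cols(side)
  vals <- check_items(record, cols, "bradykinesia_sum")
  as.integer(rowSums(vals))
}

#' Symptom-subtype classification
#'
#' Ratio of the mean tremor item sub-scores (items 3.15-3.18) to the mean
#' bradykinesia item sub-scores (items 3.4-3.8 both sides, plus item 3.14).
#' A zero numerator classifies as akinetic-rigid dominant and a zero
#' denominator as tremor dominant; otherwise ratios above 1.5 are tremor
#' dominant and ratios of 1.5 or below akinetic-rigid dominant. Rows with
#' both means zero are flagged indeterminate (`NA` subtype).
#'
#' @param record data.frame of clinical records.
#' @return data.frame with `ratio` and `subtype`
#'   (`"tremor_dominant"` / `"akinetic_rigid_dominant"` / `NA`).
#' @export
subtype_classify <- function(record) {
  trem_cols <- paste0("item", c("3_15", "3_16", "3_17", "3_18"))
  brady_cols <- c(brady_item_cols("right"), brady_item_cols("left"), "item3_14")
  trem <- check_items(record, trem_cols, "subtype_classify")
  brady <- check_items(record, brady_cols, "subtype_classify")
  num <- rowMeans(trem)
  den <- rowMeans(brady)
  ratio <- ifelse(den == 0, Inf, num / den)
  subtype <- ifelse(num == 0 & den == 0, NA_character_,
             ifelse(num == 0, "akinetic_rigid_dominant",
             ifelse(den == 0, "tremor_dominant",
             ifelse(ratio > 1.5, "tremor_dominant",
                    "akinetic_rigid_dominant"))))
  data.frame(ratio = ifelse(num == 0 & den == 0, NA_real_, ratio),
             subtype = subtype)
}

#' Drop observations rated 4 on an item
#'
#' A sub-score of 4 conventionally denotes inability to perform the task;
#' such observations are excluded from item-level analyses. The number of
#' removed rows is attached as attribute `n_removed` (and a warning is
#' raised if nothing remains).
#'
#' @param dataset data.frame containing the item column.
#' @param item_id item column name, e.g. `"item3_4_right"`.
#' @return The filtered data.frame.
#' @export
exclude_item4_observations <- function(dataset, item_id) {
  if (!item_id %in% names(dataset)) {
    stop(sprintf("exclude_item4_observations: no column '%s'", item_id),
         call. = FALSE)
  }
  drop <- dataset[[item_id]] == 4
  out <- dataset[!drop, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("exclude_item4_observations: all observations removed")
  }
  attr(out, "n_removed") <- sum(drop)
  out
}

# therapy-state factor with OFF/OFF as reference, worst-to-best order
therapy_state_factor <- function(med, stim) {
  factor(paste(med, stim, sep = "/"),
         levels = c("OFF/OFF", "ON/OFF", "OFF/ON", "ON/ON"))
}

new_lme_fit <- function(model, anova_table, notes = character(0)) {
  is_mixed <- inherits(model, "lmerMod")
  beta <- if (is_mixed) lme4::fixef(model) else stats::coef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  coef_table <- data.frame(term = names(beta), estimate = as.numeric(beta),
                           SE = se, row.names = NULL)
  r2 <- if (is_mixed) nakagawa_r2(model) else
    list(marginal = summary(model)$r.squared,
         conditional = summary(model)$r.squared)
  ranef_var <- if (is_mixed) {
    vc <- as.data.frame(lme4::VarCorr(model))
    stats::setNames(vc$vcov, paste(vc$grp, vc$var1, sep = ":"))
  } else NULL
  structure(list(model = model, coef = coef_table, anova = anova_table,
                 r2 = r2, ranef_var = ranef_var, notes = notes),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat("<lme_fit>", deparse(stats::formula(x$model)), "\n")
  print(x$anova, digits = 4)
  cat(sprintf("  R2 marginal = %.3f, conditional = %.3f\n",
              x$r2$marginal, x$r2$conditional))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Therapy-state mixed model for single-trial metrics
#'
#' Fits the single-trial metric on the four-level therapy-state factor with
#' random intercepts for subject and for trial-within-subject (the nested
#' random effect), by REML, and tests the state factor with a Satterthwaite
#' denominator df F test. Singular fits trigger the documented degenerate-
#' fit ladder: drop the nested trial term, then fall back to ordinary least
#' squares; each step is flagged in `notes`.
#'
#' @param trial_table long data.frame with `subject_id`, `med_state`,
#'   `stim_state`, `event_index` and the metric column.
#' @param metric metric column name, e.g. `"norm_accel_magnitude"`.
#' @param random random-effect structure: `"nested"` (default; subject and
#'   trial-within-subject intercepts), `"subject"` (subject intercept only)
#'   or `"none"` (ordinary least squares; with balanced data the state F
#'   test then equals the one-way fixed-effects ANOVA).
#' @return An `lme_fit`.
#' @export
lme_single_trial <- function(trial_table, metric = "norm_accel_magnitude",
                             random = c("nested", "subject", "none")) {
  random <- match.arg(random)
  need <- c("subject_id", "med_state", "stim_state", "event_index", metric)
  missing_cols <- setdiff(need, names(trial_table))
  if (length(missing_cols)) {
    stop(sprintf("lme_single_trial: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  d <- trial_table[!is.na(trial_table[[metric]]), ]
  d$therapy_state <- therapy_state_factor(d$med_state, d$stim_state)
  if (length(unique(d$therapy_state)) < 2L) {
    stop("lme_single_trial: need at least 2 therapy states", call. = FALSE)
  }
  if (length(unique(d$subject_id)) < 2L) {
    stop("lme_single_trial: need at least 2 subjects", call. = FALSE)
  }
  d$y <- d[[metric]]
  d$subject_id <- factor(d$subject_id)
  d$trial <- factor(d$event_index)
  notes <- character(0)
  fit <- NULL
  if (random == "nested") {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(y ~ therapy_state + (1 | subject_id) +
                     (1 | subject_id:trial), data = d, REML = TRUE))),
      error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
      notes <- c(notes, "nested trial term dropped (singular fit)")
      fit <- NULL
    }
  }
  if (is.null(fit) && random != "none") {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(y ~ therapy_state + (1 | subject_id), data = d,
                   REML = TRUE))),
      error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
      notes <- c(notes, "random intercept dropped: ordinary least squares")
      fit <- NULL
    }
  }
  if (is.null(fit)) {
    if (!any(grepl("least squares", notes))) {
      notes <- c(notes, "ordinary least squares (no random effects)")
    }
    fit <- stats::lm(y ~ therapy_state, data = d)
    at <- stats::anova(fit)
    anova_table <- data.frame(term = "therapy_state",
                              F = at[["F value"]][1L],
                              ndf = at$Df[1L], ddf = at$Df[2L],
                              p = at[["Pr(>F)"]][1L], df_method = "residual")
  } else {
    anova_table <- satterthwaite_anova(fit)
  }
  new_lme_fit(fit, anova_table, notes)
}

#' Mixed model of clinical outcomes on movement-profile scores
#'
#' Regresses a clinical outcome (total UPDRS Part III, an item sub-score,
#' or the right-sided bradykinesia sum) on one or two movement-profile
#' scores, controlling for the symptom laterality index, with a random
#' intercept by subject. With two profiles their interaction is included;
#' profile x laterality interactions are optional. Reports unstandardized
#' coefficients, Satterthwaite F tests per term, and Nakagawa marginal /
#' conditional R^2.
#'
#' @param profiles data.frame with `subject_id`, `med_state`, `stim_state`
#'   and one or two profile columns (e.g. `ft_profile`, `rot_profile`).
#' @param clinical data.frame of clinical records including derived
#'   `laterality_index` and the outcome column.
#' @param outcome outcome column name (e.g. `"updrs3_total"`,
#'   `"item3_4_right"`, `"brady_right_sum"`).
#' @param profile_cols profile column name(s) in `profiles`.
#' @param laterality include the laterality covariate (default TRUE).
#' @param profile_interaction include the profile x profile interaction
#'   when two profiles are given (default TRUE).
#' @param laterality_interaction include profile x laterality terms
#'   (default FALSE).
#' @return An `lme_fit` with the joined data in `$data`.
#' @export
lme_profile_on_updrs <- function(profiles, clinical, outcome = "updrs3_total",
                                 profile_cols = "ft_profile",
                                 laterality = TRUE,
                                 profile_interaction = TRUE,
                                 laterality_interaction = FALSE) {
  keys <- c("subject_id", "med_state", "stim_state")
  d <- merge(profiles, clinical, by = keys)
  orphans_p <- setdiff(do.call(paste, profiles[keys]), do.call(paste, d[keys]))
  orphans_c <- setdiff(do.call(paste, clinical[keys]), do.call(paste, d[keys]))
  if (length(orphans_p) || length(orphans_c)) {
    stop(sprintf("lme_profile_on_updrs: unmatched keys — profiles: [%s]; clinical: [%s]",
                 paste(orphans_p, collapse = ", "),
                 paste(orphans_c, collapse = ", ")), call. = FALSE)
  }
  if (!outcome %in% names(d)) {
    stop(sprintf("lme_profile_on_updrs: no outcome column '%s'", outcome),
         call. = FALSE)
  }
  if (laterality && !"laterality_index" %in% names(d)) {
    d$laterality_index <- laterality_index(d)
  }
  rhs <- if (length(profile_cols) == 2L && profile_interaction) {
    paste(profile_cols, collapse = " * ")
  } else {
    paste(profile_cols, collapse = " + ")
  }
  if (laterality) {
    rhs <- paste(rhs, "+ laterality_index")
    if (laterality_interaction) {
      rhs <- paste(rhs, "+",
                   paste(profile_cols, "laterality_index", sep = ":",
                         collapse = " + "))
    }
  }
  d$subject_id <- factor(d$subject_id)
  form <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 | subject_id)"))
  notes <- character(0)
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(form, data = d, REML = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    notes <- c(notes, "random intercept dropped: ordinary least squares")
    form_lm <- stats::as.formula(paste(outcome, "~", rhs))
    fit <- stats::lm(form_lm, data = d)
    at <- stats::anova(fit)
    terms_lm <- setdiff(rownames(at), "Residuals")
    anova_table <- data.frame(term = terms_lm,
                              F = at[terms_lm, "F value"],
                              ndf = at[terms_lm, "Df"],
                              ddf = at["Residuals", "Df"],
                              p = at[terms_lm, "Pr(>F)"],
                              df_method = "residual")
  } else {
    anova_table <- satterthwaite_anova(fit)
  }
  out <- new_lme_fit(fit, anova_table, notes)
  out$data <- d
  out
}
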