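# Inference helpers for lme4 fits: Satterthwaite denominator degrees of
# freedom, Tukey-adjusted pairwise comparisons of estimated marginal means,
# and Nakagawa marginal/conditional R^2. Kept dependency-free beyond lme4.

# central-difference gradient of scalar-valued f
num_grad <- function(f, x, rel_h = 1e-5) {
  h <- pmax(abs(x), 1e-2) * rel_h
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    (f(xp) - f(xm)) / (2 * h[i])
  }, numeric(1))
}

# central-difference Hessian of scalar-valued f
num_hess <- function(f, x, rel_h = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x), 1e-2) * rel_h
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[i] <- xpp[i] + h[i]; xpp[j] <- xpp[j] + h[j]
      xpm[i] <- xpm[i] + h[i]; xpm[j] <- xpm[j] - h[j]
      xmp[i] <- xmp[i] - h[i]; xmp[j] <- xmp[j] + h[j]
      xmm[i] <- xmm[i] - h[i]; xmm[j] <- xmm[j] - h[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

# Deviance (-2 REML log-likelihood) as a function of the variance
# parameters varpar = c(theta * sigma, sigma), i.e. relative covariance
# factor entries on the SD scale plus the residual SD. Uses the standard
# REML criterion for the linear mixed model in lme4's penalized
# least-squares formulation:
#   -2 l = log|L|^2 + log|R_X|^2 + (n - p) log(2 pi sigma^2) + r^2 / sigma^2
# where r^2 is the penalized residual sum of squares at theta.
make_devfun_varpar <- function(model) {
  fr <- stats::model.frame(model)
  devfun <- suppressWarnings(
    lme4::lmer(stats::formula(model), data = fr, REML = TRUE,
               devFunOnly = TRUE))
  env <- environment(devfun)
  n <- length(env$resp$y)
  function(varpar) {
    k <- length(varpar)
    sigma <- varpar[k]
    sigma2 <- sigma^2
    theta <- varpar[-k] / sigma
    devfun(theta)   # updates the PLS structures at this theta
    r2 <- env$resp$wrss() + env$pp$sqrL(1)
    RX <- env$pp$RX()
    p <- ncol(RX)
    env$pp$ldL2() + 2 * c(determinant(RX)$modulus) +
      (n - p) * log(2 * pi * sigma2) + r2 / sigma2
  }
}

# vcov of the fixed effects as a function of varpar (same parameterization)
make_vcovbeta_fun <- function(model) {
  fr <- stats::model.frame(model)
  devfun <- suppressWarnings(
    lme4::lmer(stats::formula(model), data = fr, REML = TRUE,
               devFunOnly = TRUE))
  env <- environment(devfun)
  function(varpar) {
    k <- length(varpar)
    sigma2 <- varpar[k]^2
    devfun(varpar[-k] / varpar[k])
    sigma2 * env$pp$unsc()
  }
}

#' Satterthwaite machinery for a fitted mixed model
#'
#' Precomputes the asymptotic covariance of the variance parameters (twice
#' the inverse Hessian of the REML criterion) needed for Satterthwaite
#' denominator degrees of freedom. Returns `NULL` (with a message in
#' `attr(, "why")`) when the Hessian is not positive definite, e.g. at a
#' singular fit.
#'
#' @param model a fitted `lmerMod` (REML).
#' @return List with `varpar`, `vcov_varpar`, `vcov_beta_fun`, or `NULL`.
#' @keywords internal
satterthwaite_prep <- function(model) {
  varpar <- c(lme4::getME(model, "theta") * stats::sigma(model),
              stats::sigma(model))
  objective <- make_devfun_varpar(model)
  H <- tryCatch(num_hess(objective, varpar), error = function(e) NULL)
  if (is.null(H) || any(!is.finite(H))) {
    return(NULL)
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(abs(ev))) {
    return(NULL)  # boundary/singular fit: caller falls back to residual df
  }
  list(varpar = varpar, vcov_varpar = 2 * solve(H),
       vcov_beta_fun = make_vcovbeta_fun(model))
}

# Satterthwaite df for a single contrast l of the fixed effects
contrast_ddf <- function(l, prep) {
  g <- num_grad(function(vp) {
    V <- prep$vcov_beta_fun(vp)
    as.numeric(t(l) %*% V %*% l)
  }, prep$varpar)
  v <- as.numeric(t(l) %*% prep$vcov_beta_fun(prep$varpar) %*% l)
  denom <- as.numeric(t(g) %*% prep$vcov_varpar %*% g)
  if (denom <= 0) return(Inf)
  2 * v^2 / denom
}

# Multi-df Satterthwaite F test of H0: L beta = 0 (rows of L are contrasts),
# using the eigen-decomposition form: each eigen-contrast gets its own
# one-dimensional Satterthwaite df nu_i, and the denominator df solves
# E[F] matching with E = sum nu_i / (nu_i - 2).
contrast_F <- function(L, model, prep, resid_df) {
  L <- matrix(L, ncol = length(lme4::fixef(model)))
  beta <- lme4::fixef(model)
  Vb <- as.matrix(stats::vcov(model))
  M <- L %*% Vb %*% t(L)
  q <- qr(M)$rank
  Fstat <- as.numeric(t(L %*% beta) %*% solve(M, L %*% beta)) / q
  if (is.null(prep)) {
    return(list(F = Fstat, ndf = q, ddf = resid_df,
                p = stats::pf(Fstat, q, resid_df, lower.tail = FALSE),
                df_method = "residual"))
  }
  ee <- eigen(M, symmetric = TRUE)
  pos <- ee$values > max(ee$values) * 1e-10
  P <- t(ee$vectors[, pos, drop = FALSE]) %*% L
  nus <- vapply(seq_len(nrow(P)), function(i) contrast_ddf(P[i, ], prep),
                numeric(1))
  ok <- nus > 2
  if (!any(ok)) {
    ddf <- resid_df
  } else {
    E <- sum(nus[ok] / (nus[ok] - 2))
    ddf <- if (E > q) 2 * E / (E - q) else resid_df
  }
  list(F = Fstat, ndf = q, ddf = ddf,
       p = stats::pf(Fstat, q, ddf, lower.tail = FALSE),
       df_method = "satterthwaite")
}

#' Per-term F tests with Satterthwaite denominator df
#'
#' Tests each fixed-effect term of a fitted `lmerMod` (marginal test of its
#' coefficients) with the Satterthwaite approximation to the denominator
#' degrees of freedom; falls back to the residual df when the variance-
#' parameter Hessian is degenerate (boundary/singular fits), flagged in
#' `df_method`.
#'
#' @param model a fitted `lmerMod`.
#' @return data.frame with one row per term: `term`, `F`, `ndf`, `ddf`, `p`,
#'   `df_method`.
#' @export
satterthwaite_anova <- function(model) {
  stopifnot(inherits(model, "lmerMod"))
  prep <- satterthwaite_prep(model)
  asgn <- attr(lme4::getME(model, "X"), "assign")
  labels <- attr(stats::terms(model), "term.labels")
  nbeta <- length(lme4::fixef(model))
  n <- length(lme4::getME(model, "y"))
  resid_df <- n - nbeta
  rows <- lapply(seq_along(labels), function(k) {
    idx <- which(asgn == k)
    L <- matrix(0, length(idx), nbeta)
    L[cbind(seq_along(idx), idx)] <- 1
    res <- contrast_F(L, model, prep, resid_df)
    data.frame(term = labels[k], F = res$F, ndf = res$ndf, ddf = res$ddf,
               p = res$p, df_method = res$df_method)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# estimated marginal means for one factor: average over the observed
# covariate means / factor frequencies of everything else
emm_grid <- function(model, factor_name) {
  mf <- stats::model.frame(model)
  tt <- stats::delete.response(stats::terms(model))
  vars <- all.vars(tt)
  if (!factor_name %in% vars) {
    stop(sprintf("emm_grid: '%s' is not a fixed-effect variable", factor_name),
         call. = FALSE)
  }
  f <- mf[[factor_name]]
  if (!is.factor(f)) stop("emm_grid: variable is not a factor", call. = FALSE)
  levs <- levels(f)
  grid <- data.frame(row.names = seq_along(levs))
  grid[[factor_name]] <- factor(levs, levels = levs)
  for (v in setdiff(vars, factor_name)) {
    col <- mf[[v]]
    if (is.numeric(col)) {
      grid[[v]] <- mean(col)
    } else {
      stop(sprintf("emm_grid: non-numeric covariate '%s' unsupported", v),
           call. = FALSE)
    }
  }
  xlev <- list()
  xlev[[factor_name]] <- levs
  X <- stats::model.matrix(tt, grid, xlev = xlev)
  list(levels = levs, X = X)
}

#' Tukey-adjusted pairwise comparisons of a factor
#'
#' All pairwise contrasts of the estimated marginal means of a fixed-effect
#' factor (other covariates held at their means), with per-contrast
#' Satterthwaite degrees of freedom and p values adjusted via the
#' studentized range distribution (Tukey's method). Works on `lmerMod` fits
#' and on plain `lm` fits (residual df), the latter reproducing the
#' classical Tukey HSD on balanced one-way layouts.
#'
#' @param fit an `lme_fit` object (from the clinical model wrappers), or a
#'   raw `lmerMod` / `lm`.
#' @param factor_name name of the factor (default `"therapy_state"`).
#' @return data.frame of class `posthoc_table`: `contrast`, `estimate`,
#'   `SE`, `df`, `t`, `p_adj`.
#' @export
tukey_posthoc <- function(fit, factor_name = "therapy_state") {
  model <- if (inherits(fit, "lme_fit")) fit$model else fit
  is_mixed <- inherits(model, "lmerMod")
  g <- emm_grid(model, factor_name)
  k <- length(g$levels)
  if (k < 2L) stop("tukey_posthoc: factor has fewer than 2 levels", call. = FALSE)
  beta <- if (is_mixed) lme4::fixef(model) else stats::coef(model)
  Vb <- as.matrix(stats::vcov(model))
  prep <- if (is_mixed) satterthwaite_prep(model) else NULL
  resid_df <- if (is_mixed) {
    length(lme4::getME(model, "y")) - length(beta)
  } else stats::df.residual(model)
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    l <- g$X[i1, ] - g$X[i2, ]
    est <- sum(l * beta)
    se <- sqrt(as.numeric(t(l) %*% Vb %*% l))
    df <- if (is_mixed && !is.null(prep)) contrast_ddf(l, prep) else resid_df
    tval <- est / se
    data.frame(contrast = paste(g$levels[i1], "-", g$levels[i2]),
               estimate = est, SE = se, df = df, t = tval,
               p_adj = stats::ptukey(sqrt(2) * abs(tval), nmeans = k,
                                     df = df, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("posthoc_table", "data.frame")
  out
}

#' Nakagawa marginal and conditional R-squared
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed
#' plus random effects (conditional), relative to the total of fixed,
#' random and residual variance. The random-effect variance is the mean
#' per-observation variance of the random part `diag(Z G Z')`.
#'
#' @param model a fitted `lmerMod`.
#' @return List with `marginal` and `conditional`.
#' @export
nakagawa_r2 <- function(model) {
  stopifnot(inherits(model, "lmerMod"))
  X <- lme4::getME(model, "X")
  var_f <- stats::var(as.numeric(X %*% lme4::fixef(model)))
  Z <- lme4::getME(model, "Z")
  Lt <- lme4::getME(model, "Lambdat")
  G <- stats::sigma(model)^2 * Matrix::crossprod(Lt)
  var_r <- mean(Matrix::rowSums((Z %*% G) * Z))
  var_e <- stats::sigma(model)^2
  tot <- var_f + var_r + var_e
  list(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}
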