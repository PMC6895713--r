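## Mixed-effects analysis of repeated tubule measurements: random-intercept
## models fitted by REML (lme4), with Satterthwaite degrees of freedom and
## p-values computed in-package from the REML criterion (the environment has
## no lmerTest), and Nakagawa-Schielzeth marginal/conditional r2.

## ---- internal: random-intercept LMM engine -------------------------------

## REML log-likelihood (up to an additive constant) for y = X b + Z u + e,
## u ~ N(0, s2b I) grouped by `group`, e ~ N(0, s2e I). Dense n x n algebra;
## tables here are a few hundred rows.
reml_loglik_ri <- function(vc, y, X, group) {
  s2b <- vc[1L]; s2e <- vc[2L]
  if (s2b < 0 || s2e <= 0) return(-Inf)
  n <- length(y)
  Z <- stats::model.matrix(~ 0 + group)
  V <- s2b * tcrossprod(Z) + diag(s2e, n)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdetV <- 2 * sum(log(diag(R)))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  -0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus +
          sum(r * Vi_r))
}

## GLS covariance of the fixed effects at variance components vc.
beta_cov_ri <- function(vc, X, group) {
  s2b <- vc[1L]; s2e <- vc[2L]
  n <- nrow(X)
  Z <- stats::model.matrix(~ 0 + group)
  V <- s2b * tcrossprod(Z) + diag(s2e, n)
  solve(crossprod(X, solve(V, X)))
}

## Satterthwaite df for each fixed effect of a random-intercept fit:
## df_j = 2 f_j^2 / (g_j' A g_j) with f_j(vc) = Var(beta_j | vc), g_j its
## gradient in vc, and A the asymptotic covariance of the REML variance
## component estimates (inverse observed information, finite differences).
satterthwaite_df_ri <- function(vc, y, X, group) {
  p <- ncol(X)
  n <- length(y)
  if (vc[1L] < 1e-8 * max(vc[2L], 1)) {
    ## boundary fit: no usable curvature in s2b; fall back to residual df
    return(rep(n - p, p))
  }
  h <- pmax(vc * 1e-4, 1e-8)
  ll <- function(v) reml_loglik_ri(v, y, X, group)
  H <- matrix(0, 2L, 2L)
  for (i in 1:2) for (j in 1:2) {
    if (i > j) { H[i, j] <- H[j, i]; next }
    ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, j] <- (ll(vc + ei) - 2 * ll(vc) + ll(vc - ei)) / h[i]^2
    } else {
      H[i, j] <- (ll(vc + ei + ej) - ll(vc + ei - ej) -
                  ll(vc - ei + ej) + ll(vc - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  A <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(A) || any(diag(A) <= 0)) return(rep(n - p, p))
  f <- function(v) diag(beta_cov_ri(v, X, group))
  g <- matrix(0, 2L, p)
  for (i in 1:2) {
    ei <- c(0, 0); ei[i] <- h[i]
    g[i, ] <- (f(vc + ei) - f(vc - ei)) / (2 * h[i])
  }
  f0 <- f(vc)
  vapply(seq_len(p), function(j) {
    denom <- drop(t(g[, j]) %*% A %*% g[, j])
    if (denom <= 0) return(n - p)
    max(2 * f0[j]^2 / denom, 1)
  }, numeric(1))
}

## Fit y ~ X (no implicit intercept) + (1 | group) by REML via lme4, with an
## exact-OLS fallback for degenerate (perfect fit / zero variance) tables.
fit_lmm_ri <- function(y, X, group, term_labels) {
  group <- factor(group)
  if (nlevels(group) < 2L)
    stop("mixed model needs >= 2 birds: the bird random effect is unidentifiable from a single bird")
  stopifnot(ncol(X) == length(term_labels))
  ols <- stats::lm.fit(X, y)
  ols_sigma <- sqrt(sum(ols$residuals^2) / max(1, length(y) - ncol(X)))
  if (ols_sigma < 1e-8 * max(1, stats::sd(y))) {
    ## response is an exact linear function of the predictors
    beta <- ols$coefficients
    fixed_var <- stats::var(drop(X %*% ifelse(is.na(beta), 0, beta)))
    terms <- data.frame(term = term_labels, estimate = as.numeric(beta),
                        se = 0, t = NA_real_, df = NA_real_, p = NA_real_)
    return(list(terms = terms, sd_intercept = 0, sd_residual = 0,
                r2_marginal = if (fixed_var > 0) 1 else NA_real_,
                r2_conditional = if (fixed_var > 0) 1 else NA_real_,
                n_obs = length(y), n_groups = nlevels(group),
                singular = TRUE, exact_fit = TRUE, fitted_fixed = drop(X %*% beta)))
  }

  ## fit on unit-SD-scaled predictors (no centering) for optimizer health;
  ## estimates and SEs are mapped back to the original scale afterwards
  col_sd <- apply(X, 2L, stats::sd)
  scl <- ifelse(col_sd > 0, col_sd, 1)
  Xs <- sweep(X, 2L, scl, "/")
  dat <- as.data.frame(Xs)
  names(dat) <- paste0("x", seq_len(ncol(X)))
  dat$.y <- y
  dat$.g <- group
  fml <- stats::as.formula(paste(".y ~ 0 +", paste(names(dat)[seq_len(ncol(X))],
                                                   collapse = " + "),
                                 "+ (1 | .g)"))
  fit <- lme4::lmer(fml, data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  vcd <- as.data.frame(lme4::VarCorr(fit))
  s2b <- vcd$vcov[vcd$grp == ".g"]
  s2e <- vcd$vcov[vcd$grp == "Residual"]
  beta <- lme4::fixef(fit) / scl
  se <- sqrt(diag(as.matrix(stats::vcov(fit)))) / scl
  df <- satterthwaite_df_ri(c(s2b, s2e), y, X, group)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  fitted_fixed <- drop(X %*% beta)
  fixed_var <- stats::var(fitted_fixed)
  tot <- fixed_var + s2b + s2e
  terms <- data.frame(term = term_labels, estimate = as.numeric(beta),
                      se = se, t = as.numeric(tval), df = df, p = as.numeric(pval))
  rownames(terms) <- NULL
  list(terms = terms, sd_intercept = sqrt(s2b), sd_residual = sqrt(s2e),
       r2_marginal = fixed_var / tot, r2_conditional = (fixed_var + s2b) / tot,
       n_obs = length(y), n_groups = nlevels(group),
       singular = lme4::isSingular(fit), exact_fit = FALSE,
       fitted_fixed = fitted_fixed, lmer_fit = fit)
}

new_model_fit <- function(core, model, distance = NULL, parameterization = NULL) {
  core$model <- model
  core$distance <- distance
  core$parameterization <- parameterization
  class(core) <- "sst_model_fit"
  core
}

#' @export
print.sst_model_fit <- function(x, ...) {
  cat(sprintf("<sst_model_fit> %s (%d obs, %d birds)%s\n", x$model,
              x$n_obs, x$n_groups,
              if (isTRUE(x$singular)) " [singular fit]" else ""))
  tf <- x$terms
  tf$estimate <- signif(tf$estimate, 5)
  tf$se <- signif(tf$se, 4)
  tf$t <- signif(tf$t, 4)
  tf$df <- round(tf$df, 1)
  tf$p <- signif(tf$p, 3)
  print(tf, row.names = FALSE)
  cat(sprintf("random effects: bird intercept SD %.4g, residual SD %.4g\n",
              x$sd_intercept, x$sd_residual))
  cat(sprintf("r2 marginal %.4f, conditional %.4f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

## ---- exported model fits -------------------------------------------------

#' Fit the quadratic diameter-profile mixed model
#'
#' Mean cross-sectional diameter `(d1 + d2)/2` as a function of the distance
#' of the sample point from the orifice (linear + quadratic) and the tubule
#' total length, with a random intercept per bird (REML). Inference uses
#' Satterthwaite degrees of freedom; r2 is Nakagawa-Schielzeth.
#'
#' @param table measurement table (the shared schema; see
#'   [read_measurement_csv()]). Bare-name columns (`s`, `d1`, ...) are
#'   accepted.
#' @param distance `"um"` (default; raw distance in micrometres) or
#'   `"normalized"` (distance divided by tubule length, the scale on which
#'   the synthetic generator states its quadratic).
#' @param parameterization `"raw"` (default) fits `distance + distance^2`;
#'   `"orthogonal"` fits orthogonal polynomial contrasts of degree 2.
#' @return an `sst_model_fit` with terms `(Intercept)`, `distance`,
#'   `distance^2` (or `poly1`, `poly2`), `total_length`.
#' @export
fit_diameter_model <- function(table, distance = c("um", "normalized"),
                               parameterization = c("raw", "orthogonal")) {
  distance <- match.arg(distance)
  parameterization <- match.arg(parameterization)
  tb <- normalize_measurement_table(table)
  check_model_table(tb)
  dist <- if (distance == "um") tb$s_um else tb$s_um / tb$total_length_um
  y <- tb$mean_diameter_um
  if (parameterization == "raw") {
    X <- cbind(1, dist, dist^2, tb$total_length_um)
    labels <- c("(Intercept)", "distance", "distance^2", "total_length")
  } else {
    P <- stats::poly(dist, 2)
    X <- cbind(1, P[, 1L], P[, 2L], tb$total_length_um)
    labels <- c("(Intercept)", "poly1", "poly2", "total_length")
  }
  core <- fit_lmm_ri(y, X, tb$bird_id, labels)
  new_model_fit(core, "mean_diameter ~ distance + distance^2 + total_length + (1 | bird)",
                distance = distance, parameterization = parameterization)
}

#' Fit the circularity mixed model
#'
#' Circularity index `d1/d2` as a function of tubule total length, the
#' diameter magnitude `d1 + d2`, distance from the orifice, and the
#' `(d1 + d2) : distance` interaction, with a random intercept per bird.
#'
#' @inheritParams fit_diameter_model
#' @return an `sst_model_fit` with terms `(Intercept)`, `total_length`,
#'   `d1_plus_d2`, `distance`, `d1_plus_d2:distance`.
#' @export
fit_circularity_model <- function(table, distance = c("um", "normalized")) {
  distance <- match.arg(distance)
  tb <- normalize_measurement_table(table)
  check_model_table(tb)
  dist <- if (distance == "um") tb$s_um else tb$s_um / tb$total_length_um
  dsum <- tb$d1_um + tb$d2_um
  X <- cbind(1, tb$total_length_um, dsum, dist, dsum * dist)
  labels <- c("(Intercept)", "total_length", "d1_plus_d2", "distance",
              "d1_plus_d2:distance")
  core <- fit_lmm_ri(tb$circularity, X, tb$bird_id, labels)
  new_model_fit(core, "circularity ~ total_length + (d1+d2) + distance + (d1+d2):distance + (1 | bird)",
                distance = distance)
}

check_model_table <- function(tb) {
  if (length(unique(tb$bird_id)) < 2L)
    stop("mixed model needs >= 2 birds: the bird random effect is unidentifiable from a single bird")
  pts <- table(tb$bird_id)
  if (any(pts < 3L))
    stop("mixed model needs >= 3 sample points per bird")
  invisible(tb)
}

#' Marginal and conditional r2 of a random-intercept fit
#'
#' Nakagawa-Schielzeth decomposition for a Gaussian identity-link mixed
#' model: marginal r2 is the variance of the fixed-effect predictions over
#' the total (fixed + random-intercept + residual) variance; conditional r2
#' adds the random-intercept variance to the numerator. Always
#' `r2_marginal <= r2_conditional <= 1`.
#'
#' @param fit an `sst_model_fit`.
#' @return named numeric `c(r2_marginal, r2_conditional)`.
#' @export
r2_mixed <- function(fit) {
  stopifnot(inherits(fit, "sst_model_fit"))
  var_f <- stats::var(fit$fitted_fixed)
  tot <- var_f + fit$sd_intercept^2 + fit$sd_residual^2
  if (!is.finite(tot) || tot <= 1e-12)
    stop("r2_mixed: zero total variance, r2 undefined")
  c(r2_marginal = var_f / tot,
    r2_conditional = (var_f + fit$sd_intercept^2) / tot)
}

#' Satterthwaite confidence intervals for the fixed effects
#' @param fit an `sst_model_fit`.
#' @param level confidence level (default 0.95).
#' @return data.frame with `term`, `lower`, `upper`.
#' @export
confint_fixed <- function(fit, level = 0.95) {
  tf <- fit$terms
  q <- stats::qt(1 - (1 - level) / 2, tf$df)
  data.frame(term = tf$term, lower = tf$estimate - q * tf$se,
             upper = tf$estimate + q * tf$se)
}

## ---- lumen scaling -------------------------------------------------------

#' Fit the linear lumen-scaling model
#'
#' The lumen diameter scales linearly with the outer (internuclear or
#' autofluorescence) diameter of the tubule -- epithelial cells keep a
#' constant cross-sectional thickness -- so shape information measured on the
#' outer envelope extrapolates to the lumen. Ordinary least squares on
#' paired observations.
#'
#' @param outer_diameter,lumen_diameter paired observations, um (>= 3 pairs).
#' @return object of class `lumen_scaling_fit` with `intercept`, `slope`,
#'   `sigma` (residual SD), and the underlying `lm` fit.
#' @export
fit_lumen_scaling <- function(outer_diameter, lumen_diameter) {
  if (length(outer_diameter) != length(lumen_diameter))
    stop("fit_lumen_scaling: inputs must be paired")
  if (length(outer_diameter) < 3L)
    stop("fit_lumen_scaling: need at least 3 pairs")
  if (stats::sd(outer_diameter) < 1e-12)
    stop("fit_lumen_scaling: outer diameters are degenerate (zero variance)")
  fit <- stats::lm(lumen_diameter ~ outer_diameter)
  sigma <- sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  structure(list(intercept = unname(stats::coef(fit)[1L]),
                 slope = unname(stats::coef(fit)[2L]),
                 sigma = sigma, lm_fit = fit),
            class = "lumen_scaling_fit")
}

#' @export
print.lumen_scaling_fit <- function(x, ...) {
  cat(sprintf("<lumen_scaling_fit> lumen = %.4g + %.4g * outer (residual SD %.3g um)\n",
              x$intercept, x$slope, x$sigma))
  invisible(x)
}

#' Predict lumen diameter from outer diameter
#' @param fit a `lumen_scaling_fit`.
#' @param outer_diameter outer diameters, um.
#' @return predicted lumen diameters, um.
#' @export
predict_lumen <- function(fit, outer_diameter) {
  stopifnot(inherits(fit, "lumen_scaling_fit"))
  fit$intercept + fit$slope * outer_diameter
}

#' Tidy coefficient table of a model fit
#' @param fit an `sst_model_fit`.
#' @return data.frame `term, estimate, se, t, df, p` plus attributes.
#' @export
model_fit_table <- function(fit) {
  stopifnot(inherits(fit, "sst_model_fit"))
  fit$terms
}
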