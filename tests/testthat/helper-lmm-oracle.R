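## Independent random-intercept REML oracle, sharing no code with the
## package's lme4-based path. The REML criterion is profiled to one
## dimension: with V = s2e (I + phi Z Z'), the residual variance has the
## closed form s2e(phi) = r' W r / (n - p), W = (I + phi Z Z')^{-1}, leaving
## a 1D maximization over phi = s2b / s2e.

oracle_fit_ri <- function(y, X, group) {
  group <- factor(group)
  Z <- stats::model.matrix(~ 0 + group)
  n <- length(y)
  p <- ncol(X)
  ZZt <- tcrossprod(Z)

  prof <- function(phi) {
    W <- solve(diag(n) + phi * ZZt)
    XtWX <- crossprod(X, W %*% X)
    beta <- solve(XtWX, crossprod(X, W %*% y))
    r <- y - X %*% beta
    s2e <- drop(crossprod(r, W %*% r)) / (n - p)
    ## -2 * REML log-likelihood, up to a constant
    val <- (n - p) * log(s2e) - determinant(W, logarithm = TRUE)$modulus +
      determinant(XtWX, logarithm = TRUE)$modulus + (n - p)
    list(val = as.numeric(val), beta = beta, s2e = s2e)
  }
  ## maximize over log(phi); include the boundary phi ~ 0
  obj <- function(lphi) prof(exp(lphi))$val
  opt <- stats::optimize(obj, interval = c(-12, 12), tol = 1e-12)
  cand_lphi <- opt$minimum
  best <- prof(exp(cand_lphi))
  if (prof(1e-12)$val < best$val - 1e-10) {
    cand_lphi <- log(1e-12)
    best <- prof(1e-12)
  }
  phi <- exp(cand_lphi)
  s2b <- phi * best$s2e
  fitted_fixed <- drop(X %*% best$beta)
  var_f <- stats::var(fitted_fixed)
  tot <- var_f + s2b + best$s2e
  list(beta = drop(best$beta), s2b = s2b, s2e = best$s2e,
       r2_marginal = var_f / tot, r2_conditional = (var_f + s2b) / tot)
}
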