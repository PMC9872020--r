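## Satterthwaite degrees of freedom for lme4 fixed effects.
##
## For a fixed effect with estimated variance v(sigma) = [vcov(beta)]_jj,
## a function of the variance parameters sigma (random-effect SDs and the
## residual SD), the Satterthwaite df is
##
##     df_j = 2 v^2 / Var(v),   Var(v) ~ g' A g,
##
## with g the gradient of v with respect to sigma and A the asymptotic
## covariance of sigma, taken as 2 * inverse Hessian of the REML criterion.
## Both derivative and Hessian are computed by central finite differences
## on lme4's deviance function; no external mixed-model packages are used.

## REML criterion as a function of varpar = (sd_re..., sigma), and the
## fixed-effect covariance at the same point, via lme4's devfun internals.
lmer_varpar_funs <- function(model) {
  devfun <- lme4::lmer(formula(model), data = model.frame(model),
                       REML = TRUE, devFunOnly = TRUE)
  rho <- environment(devfun)
  n <- nrow(model.frame(model))
  p <- length(lme4::fixef(model))
  objective <- function(vp) {
    sig <- vp[length(vp)]
    theta <- vp[-length(vp)] / sig
    devfun(theta)
    pwrss <- rho$resp$wrss() + rho$pp$sqrL(1)
    rho$pp$ldL2() + rho$pp$ldRX2() + (n - p) * log(2 * pi * sig^2) +
      pwrss / sig^2
  }
  vcov_beta <- function(vp) {
    sig <- vp[length(vp)]
    theta <- vp[-length(vp)] / sig
    devfun(theta)
    sig^2 * as.matrix(rho$pp$unsc())
  }
  est <- c(lme4::getME(model, "theta") * stats::sigma(model),
           stats::sigma(model))
  list(objective = objective, vcov_beta = vcov_beta, est = est,
       n = n, p = p)
}

#' Satterthwaite degrees of freedom for the fixed effects of an lmer fit
#'
#' @param model A fitted `lmerMod` (REML).
#' @return List with per-coefficient `df`, the `vcov` of the fixed
#'   effects at the estimate, and `ok` (FALSE when the variance-parameter
#'   Hessian was not positive definite, e.g. singular fits; callers should
#'   then fall back to residual df).
#' @export
satterthwaite_df <- function(model) {
  fns <- lmer_varpar_funs(model)
  vp <- fns$est
  V0 <- fns$vcov_beta(vp)
  df <- rep(NA_real_, nrow(V0))
  ok <- TRUE
  H <- tryCatch(fd_hess(fns$objective, vp), error = function(e) NULL)
  A <- if (!is.null(H))
    tryCatch(2 * solve(H), error = function(e) NULL) else NULL
  if (is.null(A) || any(!is.finite(A)) || any(diag(A) < 0)) {
    ok <- FALSE
  } else {
    # one central difference of the whole vcov matrix per variance
    # parameter, rather than one per coefficient
    h <- pmax(abs(vp) * 1e-4, 1e-6)
    dV <- lapply(seq_along(vp), function(i) {
      e <- rep(0, length(vp)); e[i] <- h[i]
      (fns$vcov_beta(vp + e) - fns$vcov_beta(vp - e)) / (2 * h[i])
    })
    for (j in seq_len(nrow(V0))) {
      g <- vapply(dV, function(M) M[j, j], numeric(1))
      denom <- drop(t(g) %*% A %*% g)
      df[j] <- if (denom > 0) 2 * V0[j, j]^2 / denom else NA_real_
    }
    if (anyNA(df) || any(df <= 0)) ok <- FALSE
  }
  list(df = df, vcov = V0, ok = ok)
}
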