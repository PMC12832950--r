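#' Bivariate random-effects meta-analysis of paired log hazard ratios
#'
#' Jointly models the observed per-trial effect pairs
#' \eqn{(y_{1i}, y_{2i})} (log HR on the surrogate and true endpoint) as
#' \deqn{(y_{1i}, y_{2i})' \sim N_2((\theta_{1i}, \theta_{2i})', S_i), \quad
#'       (\theta_{1i}, \theta_{2i})' \sim N_2((\mu_1, \mu_2)', \Sigma),}
#' where \eqn{S_i} is the known within-trial covariance (variances
#' \eqn{se_{1i}^2, se_{2i}^2}, correlation `within_corr`) and
#' \eqn{\Sigma} is the between-trial covariance parameterized by
#' \eqn{(\tau_1, \tau_2, \rho)}. The between-trial correlation \eqn{\rho}
#' squared is the trial-level surrogacy \eqn{R^2}.
#'
#' The marginal (restricted) likelihood is maximized numerically over
#' \eqn{(\log\tau_1, \log\tau_2, \mathrm{atanh}\,\rho)} — a parameterization
#' that keeps \eqn{\Sigma} positive semidefinite by construction — with the
#' pooled means profiled out by generalized least squares. Optimization uses
#' bounded quasi-Newton iterations from multiple starting points, including a
#' moment start derived from the weighted regression of `y2` on `y1`.
#' \eqn{\tau} estimates are floored at `tau_floor` to avoid `log(0)`; a
#' solution on the correlation boundary (\eqn{|\rho| \to 1}), which occurs
#' whenever the observed correlation of the effect estimates exceeds what the
#' between-trial variation can support, is reported as-is, not treated as an
#' error (see the methods vignette for the practical consequences and the
#' [fit_shrinkage()] alternative).
#'
#' @param effects an `effect_table` (see [to_effects()]) with at least 4 rows.
#' @param within_corr assumed within-trial correlation between the two log-HR
#'   estimates; not estimable from published summaries, default 0.
#' @param method `"reml"` (default, preferred at small trial counts) or
#'   `"ml"`.
#' @param n_starts number of optimizer starts (>= 5 including the moment
#'   start).
#' @param tau_floor lower bound for the between-trial SDs.
#' @return object of class `brma_fit`: pooled means `mu1`, `mu2`,
#'   between-trial SDs `tau1`, `tau2`, correlation `rho`, `r2 = rho^2`,
#'   achieved `loglik`, `converged`, `n_trials`, `within_corr`, `method`,
#'   plus internals used by [r2_interval()] and [predict_new()].
#' @export
fit_brma <- function(effects, within_corr = 0, method = c("reml", "ml"),
                     n_starts = 5L, tau_floor = 1e-6) {
  method <- match.arg(method)
  check_effects(effects, min_trials = 4L)
  if (nrow(effects) < 4L) stop("insufficient trials for BRMA", call. = FALSE)
  if (abs(within_corr) >= 1) stop("within_corr must be in (-1, 1)", call. = FALSE)

  reml <- method == "reml"
  lb <- c(log(tau_floor), log(tau_floor), -6)
  ub <- c(2, 2, 6)

  starts <- brma_starts(effects, n_starts)
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      optim(pmin(pmax(st, lb), ub), brma_negll,
            effects = effects, within_corr = within_corr, reml = reml,
            method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-10 ||
        (abs(o$value - best$value) <= 1e-10 &&
         sum(o$par^2) < sum(best$par^2))) best <- o
  }
  if (is.null(best))
    stop("BRMA optimization failed from all starting points", call. = FALSE)

  par <- best$par
  tau1 <- exp(par[1]); tau2 <- exp(par[2]); rho <- tanh(par[3])
  mu <- brma_gls_mu(par, effects, within_corr)
  structure(
    list(mu1 = mu[1], mu2 = mu[2], tau1 = tau1, tau2 = tau2,
         rho = rho, r2 = rho^2, loglik = -best$value,
         converged = best$convergence == 0L,
         n_trials = nrow(effects), within_corr = within_corr,
         method = method, par = par, effects = effects),
    class = "brma_fit"
  )
}

# starting values: moment estimate from the weighted regression plus spread
brma_starts <- function(effects, n_starts) {
  v1 <- max(var(effects$y1) - mean(effects$se1^2), 1e-4)
  v2 <- max(var(effects$y2) - mean(effects$se2^2), 1e-4)
  w <- 1 / effects$se2^2
  r <- weighted_pearson(effects$y1, effects$y2, w)
  r <- max(min(r, 0.95), -0.95)
  moment <- c(log(sqrt(v1)), log(sqrt(v2)), atanh(r))
  extra <- list(c(-2, -2, 0.5), c(-1, -1, 1.5), c(-2, -3, 0), c(-3, -1, -0.5),
                c(-1.5, -2.5, 2.5), c(-2.5, -1.5, 1))
  c(list(moment), extra[seq_len(max(n_starts - 1L, 4L))])
}

# negative (restricted) log marginal likelihood, mu profiled out by GLS.
# fully vectorized over trials; par = (log tau1, log tau2, atanh rho)
brma_negll <- function(par, effects, within_corr, reml) {
  t1 <- exp(par[1]); t2 <- exp(par[2]); rho <- tanh(par[3])
  a <- t1^2 + effects$se1^2
  d <- t2^2 + effects$se2^2
  b <- rho * t1 * t2 + within_corr * effects$se1 * effects$se2
  det <- a * d - b^2
  if (any(det <= 0) || any(!is.finite(det))) return(1e10)
  # elements of V_i^{-1}
  i11 <- d / det; i22 <- a / det; i12 <- -b / det
  A <- matrix(c(sum(i11), sum(i12), sum(i12), sum(i22)), 2L)
  rhs <- c(sum(i11 * effects$y1 + i12 * effects$y2),
           sum(i12 * effects$y1 + i22 * effects$y2))
  mu <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(mu)) return(1e10)
  r1 <- effects$y1 - mu[1]; r2 <- effects$y2 - mu[2]
  quad <- sum(i11 * r1^2 + 2 * i12 * r1 * r2 + i22 * r2^2)
  ll <- -0.5 * (sum(log(det)) + quad + 2 * nrow(effects) * log(2 * pi))
  if (reml) {
    detA <- A[1, 1] * A[2, 2] - A[1, 2]^2
    if (detA <= 0) return(1e10)
    ll <- ll - 0.5 * log(detA) + log(2 * pi)
  }
  -ll
}

brma_gls_mu <- function(par, effects, within_corr) {
  t1 <- exp(par[1]); t2 <- exp(par[2]); rho <- tanh(par[3])
  a <- t1^2 + effects$se1^2
  d <- t2^2 + effects$se2^2
  b <- rho * t1 * t2 + within_corr * effects$se1 * effects$se2
  det <- a * d - b^2
  i11 <- d / det; i22 <- a / det; i12 <- -b / det
  A <- matrix(c(sum(i11), sum(i12), sum(i12), sum(i22)), 2L)
  rhs <- c(sum(i11 * effects$y1 + i12 * effects$y2),
           sum(i12 * effects$y1 + i22 * effects$y2))
  solve(A, rhs)
}

# GLS covariance of the pooled means at the fitted variance parameters
brma_mu_cov <- function(fit) {
  t1 <- fit$tau1; t2 <- fit$tau2; rho <- fit$rho
  eff <- fit$effects
  a <- t1^2 + eff$se1^2
  d <- t2^2 + eff$se2^2
  b <- rho * t1 * t2 + fit$within_corr * eff$se1 * eff$se2
  det <- a * d - b^2
  A <- matrix(c(sum(d / det), -sum(b / det), -sum(b / det), sum(a / det)), 2L)
  solve(A)
}

#' @export
print.brma_fit <- function(x, ...) {
  cat(sprintf("Bivariate random-effects meta-analysis (%s), %d trials\n",
              toupper(x$method), x$n_trials))
  cat(sprintf("  pooled means: mu1 = %.4f, mu2 = %.4f\n", x$mu1, x$mu2))
  cat(sprintf("  between-trial SDs: tau1 = %.4f, tau2 = %.4f\n", x$tau1, x$tau2))
  cat(sprintf("  between-trial correlation: rho = %.4f (R2 = %.4f)\n", x$rho, x$r2))
  if (abs(x$rho) > 0.999)
    cat("  note: correlation at/near boundary; see fit_shrinkage() and vignette\n")
  cat(sprintf("  log-likelihood: %.4f (converged: %s)\n", x$loglik, x$converged))
  invisible(x)
}

#' Confidence interval for the trial-level R-squared
#'
#' For `method = "fisher_z"` the interval is built on the
#' \eqn{z = \mathrm{atanh}(\rho)} scale with the standard error taken from
#' the inverse observed information (numerical Hessian of the profile
#' (restricted) log-likelihood at the optimum), back-transformed and squared
#' with endpoint ordering preserved and bounds clipped to `[0, 1]`. If the
#' information matrix is singular or yields a non-positive variance (typical
#' at a correlation boundary), the function falls back to the parametric
#' bootstrap with a warning. `method = "parametric_bootstrap"` resamples
#' datasets from the fitted model with the observed within-trial errors,
#' refits, and takes the percentile interval; it is reproducible under
#' `seed`.
#'
#' @param fit a converged [fit_brma()] object.
#' @param level confidence level.
#' @param method `"fisher_z"` (default) or `"parametric_bootstrap"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return list of class `interval_estimate`: `point`, `lower`, `upper`,
#'   `level`, `method`.
#' @export
r2_interval <- function(fit, level = 0.95, method = c("fisher_z", "parametric_bootstrap"),
                        n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "brma_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (method == "fisher_z") {
    se_z <- tryCatch({
      H <- optimHess(fit$par, brma_negll, effects = fit$effects,
                     within_corr = fit$within_corr, reml = fit$method == "reml")
      V <- solve(H)
      vz <- V[3, 3]
      if (!is.finite(vz) || vz <= 0) stop("non-positive variance")
      sqrt(vz)
    }, error = function(e) NA_real_)
    if (is.na(se_z)) {
      warning("singular observed information; falling back to parametric bootstrap",
              call. = FALSE)
      return(r2_interval(fit, level, "parametric_bootstrap", n_boot, seed))
    }
    z <- atanh(fit$rho)
    q <- z_level(level)
    rb <- sort(tanh(c(z - q * se_z, z + q * se_z))^2)
    # squaring can reorder when the rho interval straddles 0
    if (fit$rho^2 < min(rb) || sign(tanh(z - q * se_z)) != sign(tanh(z + q * se_z)))
      rb[1] <- 0
    interval_estimate(fit$r2, max(rb[1], 0), min(rb[2], 1), level, "fisher_z")
  } else {
    set.seed(seed)
    r2s <- replicate(n_boot, {
      sim <- simulate_from_brma(fit)
      f <- tryCatch(
        fit_brma(sim, within_corr = fit$within_corr, method = fit$method),
        error = function(e) NULL
      )
      if (is.null(f)) NA_real_ else f$r2
    })
    r2s <- r2s[!is.na(r2s)]
    qs <- quantile(r2s, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    interval_estimate(fit$r2, max(qs[1], 0), min(qs[2], 1), level,
                      "parametric_bootstrap")
  }
}

interval_estimate <- function(point, lower, upper, level, method) {
  structure(list(point = point, lower = lower, upper = upper,
                 level = level, method = method),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.3f (%g%% CI: %.3f, %.3f) [%s]\n",
              x$point, 100 * x$level, x$lower, x$upper, x$method))
  invisible(x)
}

# one parametric-bootstrap dataset from a fitted bivariate model
simulate_from_brma <- function(fit) {
  eff <- fit$effects
  n <- nrow(eff)
  th1 <- rnorm(n, fit$mu1, fit$tau1)
  cond_sd <- fit$tau2 * sqrt(max(1 - fit$rho^2, 0))
  th2 <- fit$mu2 + if (fit$tau1 > 0)
    fit$rho * fit$tau2 / fit$tau1 * (th1 - fit$mu1) + rnorm(n, 0, cond_sd)
  else rnorm(n, 0, fit$tau2)
  wc <- fit$within_corr
  e1 <- rnorm(n)
  e2 <- wc * e1 + sqrt(1 - wc^2) * rnorm(n)
  out <- data.frame(trial_id = eff$trial_id,
                    y1 = th1 + eff$se1 * e1, se1 = eff$se1,
                    y2 = th2 + eff$se2 * e2, se2 = eff$se2,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Between-study conditional-mean line implied by a bivariate fit
#'
#' The conditional mean of the true-endpoint effect given the surrogate
#' effect under the fitted between-trial law:
#' slope \eqn{= \rho\,\tau_2/\tau_1}, intercept
#' \eqn{= \mu_2 - \mathrm{slope}\cdot\mu_1}. Works for both [fit_brma()] and
#' [fit_shrinkage()] objects.
#'
#' @param fit fitted model.
#' @return named numeric vector `c(intercept, slope)`.
#' @export
implied_line <- function(fit) UseMethod("implied_line")

#' @export
implied_line.brma_fit <- function(fit) {
  if (fit$tau1 <= 1e-5)
    stop("surrogate effects homogeneous; line undefined", call. = FALSE)
  slope <- fit$rho * fit$tau2 / fit$tau1
  c(intercept = fit$mu2 - slope * fit$mu1, slope = slope)
}

#' Predict the true-endpoint effect of a new trial
#'
#' Conditional-normal prediction of a new trial's observed log HR on the
#' true endpoint given its observed surrogate log HR:
#' \deqn{m = \mu_2 + \frac{\rho\tau_1\tau_2 + c\,se_1 se_2}{\tau_1^2 + se_1^2}(y_1 - \mu_1),}
#' \deqn{v = (\tau_2^2 + se_2^2) - \frac{(\rho\tau_1\tau_2 + c\,se_1 se_2)^2}{\tau_1^2 + se_1^2},}
#' with \eqn{c} the within-trial correlation. With
#' `param_uncertainty = TRUE` the variance is additionally inflated by
#' delta-method propagation of the uncertainty in
#' \eqn{(\mu_1, \mu_2, \log\tau_1, \log\tau_2, \mathrm{atanh}\rho)}
#' (GLS covariance for the means, inverse observed information for the
#' variance parameters).
#'
#' @param fit a [fit_brma()] or [fit_shrinkage()] object.
#' @param y1_new observed surrogate log HR of the new trial.
#' @param se1_new,se2_new its within-trial standard errors (`se2_new = 0`
#'   predicts the latent true effect instead of the observed one).
#' @param level interval level.
#' @param param_uncertainty add parameter-estimation uncertainty
#'   (only available for likelihood fits).
#' @return list: `mean`, `var`, `lower`, `upper`, `level`.
#' @export
predict_new <- function(fit, y1_new, se1_new, se2_new = 0, level = 0.95,
                        param_uncertainty = FALSE) {
  stopifnot(inherits(fit, "brma_fit") || inherits(fit, "shrinkage_fit"))
  wc <- fit$within_corr %||% 0
  cov_num <- fit$rho * fit$tau1 * fit$tau2 + wc * se1_new * se2_new
  denom <- fit$tau1^2 + se1_new^2
  m <- fit$mu2 + cov_num / denom * (y1_new - fit$mu1)
  v <- (fit$tau2^2 + se2_new^2) - cov_num^2 / denom
  if (v < 0) {
    warning("negative predictive variance clipped at 0", call. = FALSE)
    v <- 0
  }
  if (param_uncertainty && inherits(fit, "brma_fit")) {
    k <- cov_num / denom
    Vmu <- brma_mu_cov(fit)
    v_mu <- drop(t(c(-k, 1)) %*% Vmu %*% c(-k, 1))
    v_var <- tryCatch({
      H <- optimHess(fit$par, brma_negll, effects = fit$effects,
                     within_corr = fit$within_corr, reml = fit$method == "reml")
      Vp <- solve(H)
      g <- numeric(3)
      eps <- 1e-5
      mfun <- function(p) {
        t1 <- exp(p[1]); t2 <- exp(p[2]); r <- tanh(p[3])
        cn <- r * t1 * t2 + wc * se1_new * se2_new
        fit$mu2 + cn / (t1^2 + se1_new^2) * (y1_new - fit$mu1)
      }
      for (j in 1:3) {
        up <- fit$par; up[j] <- up[j] + eps
        dn <- fit$par; dn[j] <- dn[j] - eps
        g[j] <- (mfun(up) - mfun(dn)) / (2 * eps)
      }
      drop(t(g) %*% Vp %*% g)
    }, error = function(e) 0)
    v <- v + max(v_mu, 0) + max(v_var, 0)
  }
  q <- z_level(level)
  list(mean = m, var = v, lower = m - q * sqrt(v), upper = m + q * sqrt(v),
       level = level)
}
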