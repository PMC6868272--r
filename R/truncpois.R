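#' Right-truncated Poisson probability mass function
#'
#' \deqn{P(k) = \frac{\lambda^k / k!}{\sum_{j=0}^{K} \lambda^j / j!}, \quad
#'   k \in \{0, \dots, K\}.}
#' Hip scores bounded at grade 3 are modelled with \code{K = 3}: the
#' support is truncated and renormalised (not censored).
#'
#' @param k score value(s) in \code{0:K}.
#' @param lambda positive rate(s) (recycled against \code{k}).
#' @param K truncation bound (default 3).
#' @return Probabilities.
#' @export
dtruncpois <- function(k, lambda, K = 3) {
  if (any(k < 0 | k > K | k != round(k))) stop("k must be an integer in 0..K")
  if (any(lambda <= 0)) stop("lambda must be positive")
  denom <- rowSums(outer(log(lambda), 0:K, function(ll, j)
    exp(j * ll - lfactorial(j))))
  exp(k * log(lambda) - lfactorial(k)) / denom
}

# mean and variance of the truncated pmf, vectorised over lambda
.tp_moments <- function(lambda, K = 3) {
  j <- 0:K
  w <- exp(outer(log(lambda), j, `*`) - rep(lfactorial(j), each = length(lambda)))
  p <- w / rowSums(w)
  m <- drop(p %*% j)
  v <- drop(p %*% j^2) - m^2
  list(mean = m, var = v)
}

#' Expected score under the truncated Poisson model
#'
#' \eqn{E[Y] = \sum_k k P(k)}; bounded by \code{K} and increasing in
#' \code{lambda}.
#'
#' @inheritParams dtruncpois
#' @return Expected values.
#' @export
truncpois_mean <- function(lambda, K = 3) .tp_moments(lambda, K)$mean

#' Right-truncated Poisson regression
#'
#' Log-link regression of a bounded ordinal count (maximum hip score, 0-3)
#' on covariates: \eqn{\log \lambda_i = x_i'\beta} with the truncated pmf of
#' [dtruncpois()]. The maximum-likelihood fit uses Newton--Raphson with the
#' analytic score \eqn{(y_i - E[Y_i]) x_i} and expected-information Hessian
#' \eqn{-\sum_i Var[Y_i] x_i x_i'}, with step-halving so the log-likelihood
#' never decreases. Optionally a posterior sample under improper flat priors
#' is drawn by adaptive random-walk Metropolis started at the MLE, giving
#' 95\% credible intervals for derived prediction curves.
#'
#' Covariates are standardised internally (mean 0, SD 1) for numerical
#' stability; reported coefficients are back-transformed to the original
#' scale.
#'
#' @param formula model formula, e.g. \code{max_score ~ mean_ancestor_score
#'   + age_days + sex}.
#' @param data data frame containing the variables.
#' @param K truncation bound (default 3).
#' @param method \code{"mle"} or \code{"bayes"} (MLE plus Metropolis
#'   posterior).
#' @param chains,iter,burn Metropolis settings (per chain) when
#'   \code{method = "bayes"}.
#' @param seed optional RNG seed for the posterior sample.
#' @return Object of class \code{trunc_pois} with \code{coef}, \code{vcov},
#'   \code{logLik}, \code{summary}, \code{predict} methods; when sampled,
#'   component \code{draws} holds the pooled posterior draws (one column
#'   per coefficient) and \code{chain} their chain index.
#' @export
fit_trunc_poisson <- function(formula, data, K = 3,
                              method = c("mle", "bayes"),
                              chains = 4, iter = 2000, burn = 500,
                              seed = NULL) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0 | y > K | y != round(y)))
    stop("response must be integers in 0..", K)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (nrow(X) < length(stats::coef(stats::lm.fit(X, y))) + 1)
    stop("too few records for the requested covariates")
  # standardize non-intercept columns
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  keep <- colnames(X) == "(Intercept)" | scl == 0
  ctr[keep] <- 0; scl[keep | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  ll_fun <- function(beta) {
    lam <- exp(drop(Xs %*% beta))
    j <- 0:K
    lS <- log(rowSums(exp(outer(log(lam), j, `*`) -
                            rep(lfactorial(j), each = length(lam)))))
    sum(y * log(lam) - lfactorial(y) - lS)
  }
  beta <- qr.solve(crossprod(Xs) + diag(1e-8, ncol(Xs)),
                          crossprod(Xs, log(pmax(y, 0.25))))
  ll <- ll_fun(beta)
  ridge_used <- FALSE
  for (it in 1:100) {
    lam <- exp(drop(Xs %*% beta))
    mo <- .tp_moments(lam, K)
    g <- crossprod(Xs, y - mo$mean)
    H <- crossprod(Xs * mo$var, Xs)
    step <- tryCatch(solve(H, g), error = function(e) {
      ridge_used <<- TRUE
      solve(H + diag(1e-6 * max(diag(H)), ncol(H)), g)
    })
    # step-halving: never decrease the log-likelihood
    sh <- 1; repeat {
      cand <- beta + sh * step
      llc <- ll_fun(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      sh <- sh / 2
      if (sh < 1e-8) { cand <- beta; llc <- ll; break }
    }
    done <- max(abs(cand - beta)) < 1e-10 || abs(llc - ll) < 1e-12
    beta <- cand; ll <- llc
    if (done) break
  }
  if (ridge_used) warning("singular Hessian; ridge-stabilized Newton steps used")
  lam <- exp(drop(Xs %*% beta))
  V <- solve(crossprod(Xs * .tp_moments(lam, K)$var, Xs) +
               diag(if (ridge_used) 1e-6 else 0, ncol(Xs)))
  # back-transform to original covariate scale
  b_orig <- beta / scl
  b_orig[1] <- beta[1] - sum((ctr / scl * beta)[-1])
  Tm <- diag(1 / scl); Tm[1, ] <- -ctr / scl; Tm[1, 1] <- 1
  V_orig <- Tm %*% V %*% t(Tm)
  dimnames(V_orig) <- list(colnames(X), colnames(X))
  names(b_orig) <- colnames(X)

  out <- list(coefficients = drop(b_orig), vcov = V_orig, logLik = ll,
              K = K, formula = formula, terms = attr(mf, "terms"),
              xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
              n = length(y), std = list(ctr = ctr, scl = scl),
              ridge = ridge_used, method = method)
  class(out) <- "trunc_pois"

  if (method == "bayes") {
    if (!is.null(seed)) set.seed(seed)
    prop_chol <- chol(V + diag(1e-10, ncol(V)))
    p <- ncol(Xs)
    all_draws <- vector("list", chains)
    for (ch in seq_len(chains)) {
      b <- drop(beta) + drop(crossprod(prop_chol, stats::rnorm(p)))
      llb <- ll_fun(b)
      sc <- 2.38 / sqrt(p)
      acc <- 0
      dr <- matrix(NA_real_, iter - burn, p)
      for (t in seq_len(iter)) {
        prop <- b + sc * drop(crossprod(prop_chol, stats::rnorm(p)))
        llp <- ll_fun(prop)
        if (log(stats::runif(1)) < llp - llb) { b <- prop; llb <- llp; acc <- acc + 1 }
        if (t <= burn && t %% 50 == 0) {     # adapt toward ~30% acceptance
          sc <- sc * exp((acc / t - 0.3))
        }
        if (t > burn) dr[t - burn, ] <- b
      }
      all_draws[[ch]] <- dr
    }
    draws <- do.call(rbind, all_draws)
    # back-transform draws
    dr_o <- sweep(draws, 2, scl, "/")
    dr_o[, 1] <- draws[, 1] - draws[, -1, drop = FALSE] %*% (ctr / scl)[-1]
    colnames(dr_o) <- colnames(X)
    out$draws <- dr_o
    out$chain <- rep(seq_len(chains), each = iter - burn)
  }
  out
}

#' @export
coef.trunc_pois <- function(object, ...) object$coefficients

#' @export
vcov.trunc_pois <- function(object, ...) object$vcov

#' @export
logLik.trunc_pois <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.trunc_pois <- function(x, ...) {
  cat(sprintf("Truncated Poisson regression (K = %d, log link), n = %d\n",
              x$K, x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.trunc_pois <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               z = object$coefficients / se,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(object$coefficients / se)))
  if (!is.null(object$draws)) {
    qs <- t(apply(object$draws, 2, stats::quantile, c(0.025, 0.975)))
    tab <- cbind(tab, `2.5%` = qs[, 1], `97.5%` = qs[, 2])
  }
  structure(list(coefficients = tab, logLik = object$logLik, n = object$n,
                 K = object$K), class = "summary.trunc_pois")
}

#' @export
print.summary.trunc_pois <- function(x, ...) {
  cat(sprintf("Truncated Poisson regression (K = %d), n = %d, logLik = %.2f\n",
              x$K, x$n, x$logLik))
  stats::printCoefmat(x$coefficients, has.Pvalue = TRUE)
  invisible(x)
}

#' Predictions from a truncated Poisson regression
#'
#' @param object a [fit_trunc_poisson()] fit.
#' @param newdata covariate data frame.
#' @param type \code{"mean"} for the expected (truncated) score
#'   \eqn{E[Y]}, \code{"lambda"} for the untruncated rate.
#' @param interval if \code{TRUE} and posterior draws are available, add
#'   95\% credible bounds (otherwise delta-method normal bounds).
#' @param ... unused.
#' @return Data frame with \code{fit} and optionally \code{lwr}, \code{upr}.
#' @export
predict.trunc_pois <- function(object, newdata, type = c("mean", "lambda"),
                               interval = FALSE, ...) {
  type <- match.arg(type)
  X <- stats::model.matrix(stats::delete.response(object$terms), newdata,
                           xlev = object$xlevels)
  f1 <- function(beta) {
    lam <- exp(drop(X %*% beta))
    if (type == "mean") truncpois_mean(lam, object$K) else lam
  }
  fit <- f1(object$coefficients)
  if (!interval) return(data.frame(fit = fit))
  if (!is.null(object$draws)) {
    sims <- apply(object$draws, 1, f1)
    if (is.null(dim(sims))) sims <- matrix(sims, nrow = 1)
    qs <- apply(sims, 1, stats::quantile, c(0.025, 0.975))
    data.frame(fit = fit, lwr = qs[1, ], upr = qs[2, ])
  } else {
    eta <- drop(X %*% object$coefficients)
    se_eta <- sqrt(rowSums((X %*% object$vcov) * X))
    lo <- exp(eta - 1.96 * se_eta); hi <- exp(eta + 1.96 * se_eta)
    if (type == "mean") {
      data.frame(fit = fit, lwr = truncpois_mean(pmax(lo, 1e-12), object$K),
                 upr = truncpois_mean(hi, object$K))
    } else data.frame(fit = fit, lwr = lo, upr = hi)
  }
}

#' Predicted mean-score curve over a covariate grid
#'
#' Convenience wrapper around [predict.trunc_pois()] for selection-response
#' curves: evaluates the expected maximum score (with 95\% interval) on a
#' grid of one focal covariate, holding the others at reference values.
#'
#' @param object a [fit_trunc_poisson()] fit.
#' @param grid data frame of covariate values (e.g. generations of
#'   selection by sex).
#' @return \code{grid} with columns \code{fit}, \code{lwr}, \code{upr}.
#' @export
predict_score_curve <- function(object, grid) {
  cbind(grid, predict(object, grid, type = "mean", interval = TRUE))
}

#' Percent reduction in expected score between two covariate settings
#'
#' Computes \eqn{1 - E[Y \mid x_2] / E[Y \mid x_1]} (as a percentage), with
#' a 95\% interval over posterior draws when available.
#'
#' @param object a [fit_trunc_poisson()] fit.
#' @param at1,at2 single-row data frames of covariate values (e.g.
#'   generation 1 and generation 8).
#' @return List with \code{reduction_pct} and, given draws, \code{lwr},
#'   \code{upr}.
#' @export
score_reduction <- function(object, at1, at2) {
  e <- function(beta, X) truncpois_mean(exp(drop(X %*% beta)), object$K)
  Xt <- stats::delete.response(object$terms)
  X1 <- stats::model.matrix(Xt, at1, xlev = object$xlevels)
  X2 <- stats::model.matrix(Xt, at2, xlev = object$xlevels)
  red <- function(beta) unname(100 * (1 - e(beta, X2) / e(beta, X1)))
  out <- list(reduction_pct = red(object$coefficients))
  if (!is.null(object$draws)) {
    sims <- apply(object$draws, 1, red)
    out$lwr <- stats::quantile(sims, 0.025, names = FALSE)
    out$upr <- stats::quantile(sims, 0.975, names = FALSE)
  }
  out
}

#' Residual body mass against generations of selection
#'
#' Gaussian linear model of residual body mass (kg) on the mean ancestor
#' score (generations of selective breeding), with age and sex adjustments.
#' The slope is the correlated response of body mass in kg per generation;
#' the implied change after \code{horizon} generations is slope times
#' horizon.
#'
#' @param data data frame with columns used in \code{formula}.
#' @param formula model formula; default
#'   \code{residual_mass ~ mean_ancestor_score + age_days + sex}.
#' @param horizon generations over which to report the cumulative change
#'   (default 8).
#' @return Object of class \code{mass_trend}: the underlying \code{lm} plus
#'   \code{slope_kg_per_gen}, its 95\% CI and \code{change_after_horizon}.
#' @export
fit_mass_vs_generations <- function(data,
                                    formula = residual_mass ~
                                      mean_ancestor_score + age_days + sex,
                                    horizon = 8) {
  fit <- stats::lm(formula, data = data)
  if (any(!is.finite(stats::coef(fit))))
    warning("collinear covariates; some coefficients not estimable")
  gen_var <- "mean_ancestor_score"
  if (!gen_var %in% names(stats::coef(fit)))
    gen_var <- grep("ancestor|gener", names(stats::coef(fit)), value = TRUE)[1]
  slope <- stats::coef(fit)[[gen_var]]
  ci <- stats::confint(fit)[gen_var, ]
  out <- list(lm = fit, slope_kg_per_gen = slope,
              slope_ci = unname(ci), horizon = horizon,
              change_after_horizon = horizon * slope,
              change_ci = horizon * unname(ci))
  class(out) <- "mass_trend"
  out
}

#' @export
print.mass_trend <- function(x, ...) {
  cat(sprintf("Residual body mass vs generations of selection:\n"))
  cat(sprintf("  slope: %+.1f g per generation (95%% CI %.1f to %.1f)\n",
              1000 * x$slope_kg_per_gen, 1000 * x$slope_ci[1],
              1000 * x$slope_ci[2]))
  cat(sprintf("  implied change after %d generations: %+.3f kg\n",
              x$horizon, x$change_after_horizon))
  invisible(x)
}

#' @export
coef.mass_trend <- function(object, ...) stats::coef(object$lm)
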