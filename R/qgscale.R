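#' Latent-scale heritability of an ordinal threshold model
#'
#' On the latent (liability) scale the phenotypic variance is
#' \eqn{V_A + V_{PE} + 1} (the residual variance being fixed at 1 for
#' identification), so \eqn{h^2 = V_A / (V_A + V_{PE} + 1)}. When vectors
#' of posterior draws are supplied the heritability is computed per draw;
#' summarising (mean, credible interval) is done afterwards, never by
#' plugging posterior means into the formula.
#'
#' @param va,vpe additive-genetic and permanent-environment variance
#'   (scalars or vectors of posterior draws).
#' @return Heritability value(s) in \code{[0, 1]}.
#' @export
h2_latent <- function(va, vpe = 0) {
  stopifnot(all(va >= 0), all(vpe >= 0))
  va / (va + vpe + 1)
}

#' Observed (data-scale) heritability of an ordinal threshold model
#'
#' Transforms latent-scale variance components of a probit threshold model
#' for an ordinal score \eqn{y \in \{0, \dots, K\}} to the observed data
#' scale. Writing \eqn{\ell} for the non-residual part of the liability
#' (fixed-effect mean plus genetic and permanent-environment deviations,
#' \eqn{\ell \sim N(\mu, V_A + V_{PE})}) and \eqn{\gamma} for the
#' cutpoints, the conditional mean and variance of the score are
#' \deqn{\psi(\ell) = \sum_{k=1}^{K} \Phi(\ell - \gamma_k), \qquad
#'   v(\ell) = \sum_{k=1}^{K} (2k - 1) \Phi(\ell - \gamma_k) - \psi(\ell)^2.}
#' Expectations over \eqn{\ell} are taken by Gauss--Hermite quadrature and
#' give
#' \deqn{V_{P,obs} = Var[\psi(\ell)] + E[v(\ell)], \qquad
#'   V_{A,obs} = V_A \, (E[\psi'(\ell)])^2, \qquad
#'   h^2_{obs} = V_{A,obs} / V_{P,obs},}
#' with \eqn{\psi'(\ell) = \sum_k \phi(\ell - \gamma_k)}. All arguments are
#' vectorised over posterior draws; the transform is applied per draw.
#'
#' @param va,vpe latent variance components (draws).
#' @param mu population mean of the latent liability, i.e. the average
#'   fixed-effect predictor (draws).
#' @param cutpoints numeric vector of increasing finite cutpoints
#'   \eqn{(\gamma_1, \dots, \gamma_K)} (first one 0 under the package's
#'   identification), or a matrix with one row per draw.
#' @param nodes number of Gauss--Hermite nodes (default 48).
#' @return Data frame per draw: \code{h2_obs}, \code{va_obs}, \code{vp_obs},
#'   \code{mean_obs}.
#' @export
h2_observed_scale <- function(va, vpe, mu, cutpoints, nodes = 48) {
  if (is.null(dim(cutpoints)))
    cutpoints <- matrix(cutpoints, nrow = length(va),
                        ncol = length(cutpoints), byrow = TRUE)
  stopifnot(length(va) == length(vpe), length(va) == length(mu),
            nrow(cutpoints) == length(va))
  if (any(apply(cutpoints, 1, function(g) any(diff(g) <= 0))))
    stop("cutpoints must be strictly increasing")
  gq <- statmod::gauss.quad.prob(nodes, dist = "normal")
  K <- ncol(cutpoints)
  kk <- seq_len(K)
  out <- vapply(seq_along(va), function(i) {
    sd_l <- sqrt(va[i] + vpe[i])
    l <- mu[i] + sd_l * gq$nodes          # quadrature points for ell
    z <- outer(l, cutpoints[i, ], `-`)    # nodes x K
    Phi <- stats::pnorm(z); phi <- stats::dnorm(z)
    psi <- drop(Phi %*% rep(1, K))
    ey2 <- drop(Phi %*% (2 * kk - 1))
    dpsi <- drop(phi %*% rep(1, K))
    m <- sum(gq$weights * psi)
    var_psi <- sum(gq$weights * psi^2) - m^2
    e_v <- sum(gq$weights * (ey2 - psi^2))
    vp <- var_psi + e_v
    va_obs <- va[i] * sum(gq$weights * dpsi)^2
    c(va_obs / vp, va_obs, vp, m)
  }, numeric(4))
  data.frame(h2_obs = out[1, ], va_obs = out[2, ], vp_obs = out[3, ],
             mean_obs = out[4, ])
}

#' Genetic correlation from genetic-covariance draws
#'
#' \eqn{r_G = COV_A / \sqrt{V_{A1} V_{A2}}}, computed per posterior draw and
#' then summarised. Draws in which either genetic variance is non-positive
#' are excluded and counted.
#'
#' @param va1,va2,cov_a vectors of posterior draws of the two genetic
#'   variances and their covariance, or a 3-column matrix/data frame in
#'   that order passed as \code{va1}.
#' @param level credible-interval level (default 0.95).
#' @return List with \code{mean}, \code{ci}, \code{draws},
#'   \code{n_excluded}.
#' @export
genetic_correlation <- function(va1, va2 = NULL, cov_a = NULL, level = 0.95) {
  if (is.null(va2)) {
    m <- as.matrix(va1); va1 <- m[, 1]; va2 <- m[, 2]; cov_a <- m[, 3]
  }
  ok <- va1 > 0 & va2 > 0
  r <- cov_a[ok] / sqrt(va1[ok] * va2[ok])
  a <- (1 - level) / 2
  list(mean = mean(r),
       ci = stats::quantile(r, c(a, 1 - a), names = FALSE),
       draws = r, n_excluded = sum(!ok))
}
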