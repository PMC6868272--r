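## Bayesian animal models on a pedigree.
##
## The univariate threshold sampler follows the data-augmentation scheme of
## probit ordinal mixed models: latent liabilities from truncated normals,
## location effects (fixed + breeding values + permanent environment)
## jointly from the sparse mixed-model equations, variance components from
## their scaled-inverse-chi-square full conditionals, and free cutpoints by
## a marginal (liability-integrated) random-walk Metropolis step with the
## liabilities refreshed afterwards. Identification: first cutpoint 0,
## residual variance 1, intercept free.

# design pieces shared by the samplers
.am_design <- function(records, pedigree, fixed, response) {
  stopifnot(inherits(pedigree, "pedigree"))
  pos <- match(records$id, pedigree$id)
  if (anyNA(pos))
    stop("phenotyped id(s) missing from the pedigree: ",
         records$id[is.na(pos)][1])
  X <- stats::model.matrix(fixed, records)
  n <- nrow(records); m <- nrow(pedigree)
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = pos, x = 1, dims = c(n, m))
  uid <- unique(records$id)
  Zp <- Matrix::sparseMatrix(i = seq_len(n), j = match(records$id, uid),
                             x = 1, dims = c(n, length(uid)))
  list(X = X, Za = Za, Zp = Zp, pos = pos, n = n, m = m, n_pe = length(uid),
       y = records[[response]])
}

# scaled inverse chi-square full conditional draw
.riscs <- function(ssq, ndat, nu, s2) (ssq + nu * s2) / stats::rchisq(1, ndat + nu)

# Draw theta ~ N(C^{-1} b, C^{-1}) for C = sum_k Q_k' Q_k by the
# perturbed-right-hand-side construction: theta = C^{-1}(b + e) with
# e ~ N(0, C) assembled from the square roots of the individual precision
# terms, needing only one sparse solve with the (updated) CHMfactor.
.mvn_mme <- function(ch, b_plus_e) {
  drop(as.matrix(Matrix::solve(ch, b_plus_e, system = "A")))
}

# sparse S with S'S = Ainv: rows (1, -1/2, -1/2)/sqrt(m_i) over
# {individual, sire, dam} (Henderson's decomposition Ainv = T' D^{-1} T)
.ainv_sqrt <- function(ped) {
  n <- nrow(ped)
  si <- attr(ped, "sire_ix"); di <- attr(ped, "dam_ix")
  F <- .ml_inbreeding(si, di)
  Fs <- ifelse(si > 0L, F[pmax(si, 1L)], -1)
  Fd <- ifelse(di > 0L, F[pmax(di, 1L)], -1)
  w <- 1 / sqrt(0.5 - 0.25 * (Fs + Fd))
  ii <- seq_len(n)
  hs <- si > 0L; hd <- di > 0L
  Matrix::sparseMatrix(
    i = c(ii, ii[hs], ii[hd]), j = c(ii, si[hs], di[hd]),
    x = c(w, -w[hs] / 2, -w[hd] / 2), dims = c(n, n))
}

# Group-scale ("sandwich") move for the probit samplers: jointly rescale
# liabilities, location effects, cutpoints (and afterwards the variance
# components, via their conditional on the rescaled effects) by sigma drawn
# from the move conditional sigma^2 ~ chisq(n + K - 1) / sum(resid^2),
# obtained from the scale-group Haar measure with the Jacobian of the
# transformation. Decouples the cutpoint scale from the variance
# components, whose joint direction is only weakly identified with single
# records; without it the h2 posteriors under-cover.
.scale_move <- function(resid, n, k_free) {
  sqrt(stats::rchisq(1, n + k_free) / sum(resid^2))
}

# marginal-likelihood Metropolis update of free cutpoints (first fixed at 0)
.update_cutpoints <- function(gam, eta, y, step) {
  K <- length(gam)                      # gam = (0, g2, ..., gK)
  if (K < 2) return(list(gam = gam, acc = FALSE))
  ldel <- log(diff(c(0, gam[-1])))      # log increments above gamma_1 = 0
  ldel_p <- ldel + step * stats::rnorm(K - 1)
  gam_p <- c(0, cumsum(exp(ldel_p)))
  lo <- c(-Inf, gam); up <- c(gam, Inf)
  lo_p <- c(-Inf, gam_p); up_p <- c(gam_p, Inf)
  yy <- y + 1L
  llo <- sum(log(pmax(stats::pnorm(up[yy] - eta) - stats::pnorm(lo[yy] - eta),
                      1e-300)))
  llp <- sum(log(pmax(stats::pnorm(up_p[yy] - eta) - stats::pnorm(lo_p[yy] - eta),
                      1e-300)))
  # log-increment walk: Jacobian ratio = prod(delta')/prod(delta)
  if (log(stats::runif(1)) < llp - llo + sum(ldel_p) - sum(ldel))
    list(gam = gam_p, acc = TRUE)
  else list(gam = gam, acc = FALSE)
}

#' Univariate threshold animal model for an ordinal hip score
#'
#' Gibbs sampler for the probit ("threshold") animal model of an ordinal
#' score \eqn{y \in \{0, \dots, K\}}: liability
#' \eqn{\ell_i = x_i'\beta + a_{id(i)} + pe_{id(i)} + e_i}, \eqn{e_i \sim
#' N(0,1)} fixed for identification, breeding values \eqn{a \sim N(0, A
#' V_A)} with A the pedigree relationship matrix (used through its sparse
#' inverse), and a permanent-environment effect per individual absorbing
#' repeated-measure covariance. The first cutpoint is fixed at 0 and the
#' intercept estimated; remaining cutpoints move by a marginal Metropolis
#' step. Variance components get conjugate scaled-inverse-chi-square
#' updates under weakly informative defaults (\code{nu = 0.002, s2 = 1}).
#'
#' @param records a \code{hip_records} data frame (or any data frame with
#'   the response and fixed-effect columns plus \code{id}).
#' @param pedigree a [as_pedigree()] object containing every phenotyped id.
#' @param response name of the ordinal response column (default
#'   \code{"max_score"}).
#' @param fixed one-sided fixed-effects formula (default
#'   \code{~ sex + scale(age_days)}).
#' @param n_iter,burn,thin,n_chains chain settings. Draws are pooled across
#'   chains with a chain index retained for diagnostics.
#' @param prior list with \code{nu_a}, \code{s2_a}, \code{nu_pe},
#'   \code{s2_pe}.
#' @param start optional list with \code{va}, \code{vpe}, \code{cutpoints}.
#' @param seed RNG seed; chain c uses \code{seed + c - 1}.
#' @param verbose print progress.
#' @return Object of class \code{threshold_animal_model} with a pooled
#'   draws matrix (columns \code{va}, \code{vpe}, \code{h2_latent},
#'   cutpoints, \code{mu}, fixed effects), methods \code{print},
#'   \code{summary}, \code{plot}, and input metadata.
#' @seealso [h2_observed_scale()] to transform the draws to the data scale,
#'   [mcmc_diagnostics()] for convergence checks.
#' @export
fit_threshold_animal_model <- function(records, pedigree,
                                       response = "max_score",
                                       fixed = ~ sex + scale(age_days),
                                       n_iter = 3000, burn = 1000, thin = 2,
                                       n_chains = 2,
                                       prior = list(nu_a = 0.002, s2_a = 1,
                                                    nu_pe = 0.002, s2_pe = 1),
                                       start = NULL, seed = 1,
                                       verbose = FALSE) {
  des <- .am_design(records, pedigree, fixed, response)
  y <- as.integer(des$y)
  if (any(y < 0) || length(unique(y)) < 2)
    stop("ordinal response needs >= 2 observed categories, all >= 0")
  ncat <- max(y) + 1L
  K <- ncat - 1L                       # cutpoints gamma_1..gamma_K
  Ainv <- relationship_inverse(pedigree)
  W <- cbind(des$X, des$Za, des$Zp)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  p <- ncol(des$X)
  pad <- function(M, at) Matrix::bdiag(
    Matrix::Diagonal(at[1], x = 0), M, Matrix::Diagonal(at[2], x = 0))
  Pa <- Matrix::forceSymmetric(pad(Ainv, c(p, des$n_pe)))
  Pp <- Matrix::forceSymmetric(pad(Matrix::Diagonal(des$n_pe),
                                   c(p + des$m, 0)))
  Rb <- Matrix::forceSymmetric(pad(Matrix::Diagonal(p, x = 1e-8),
                                   c(0, des$m + des$n_pe)))
  Sa <- .ainv_sqrt(pedigree)
  a_ix <- p + seq_len(des$m); pe_ix <- p + des$m + seq_len(des$n_pe)

  keep <- floor((n_iter - burn) / thin)
  par_names <- c("va", "vpe", "h2_latent",
                 if (K >= 2) paste0("gamma", 2:ncat - 1)[-1],
                 "mu", colnames(des$X))
  draws <- matrix(NA_real_, keep * n_chains, length(par_names),
                  dimnames = list(NULL, par_names))
  chain_ix <- rep(seq_len(n_chains), each = keep)
  acc_tot <- 0

  for (ch_i in seq_len(n_chains)) {
    set.seed(seed + ch_i - 1)
    va <- if (!is.null(start$va)) start$va else 0.5 + 0.5 * ch_i
    vpe <- if (!is.null(start$vpe)) start$vpe else 0.25 * ch_i
    gam <- if (!is.null(start$cutpoints)) start$cutpoints
           else cumsum(c(0, rep(0.8, K - 1)))
    theta <- numeric(p + des$m + des$n_pe)
    lo_all <- c(-Inf, gam); up_all <- c(gam, Inf)
    l <- truncnorm::rtruncnorm(des$n, a = lo_all[y + 1L], b = up_all[y + 1L],
                               mean = 0, sd = 1)
    C <- WtW + Rb + Pa * (1 / va) + Pp * (1 / vpe)
    chf <- Matrix::Cholesky(C, LDLt = FALSE, perm = TRUE, super = FALSE)
    step <- 0.05
    acc_ch <- 0
    it_keep <- 0
    for (it in seq_len(n_iter)) {
      # 1. location effects | liabilities, variances
      C <- WtW + Rb + Pa * (1 / va) + Pp * (1 / vpe)
      chf <- Matrix::update(chf, C)
      e <- drop(Matrix::crossprod(W, stats::rnorm(des$n)))
      e[a_ix] <- e[a_ix] +
        drop(Matrix::crossprod(Sa, stats::rnorm(des$m))) / sqrt(va)
      e[pe_ix] <- e[pe_ix] + stats::rnorm(des$n_pe) / sqrt(vpe)
      e[seq_len(p)] <- e[seq_len(p)] + 1e-4 * stats::rnorm(p)
      theta <- .mvn_mme(chf, drop(Matrix::crossprod(W, l)) + e)
      eta <- as.numeric(W %*% theta)
      # 2. cutpoints | eta (liabilities integrated out), then liabilities
      if (K >= 2) {
        upd <- .update_cutpoints(gam, eta, y, step)
        gam <- upd$gam
        acc_ch <- acc_ch + upd$acc
        acc_tot <- acc_tot + upd$acc
        if (it <= burn && it %% 25 == 0)
          step <- step * exp(0.5 * (acc_ch / it - 0.25))
        lo_all <- c(-Inf, gam); up_all <- c(gam, Inf)
      }
      l <- truncnorm::rtruncnorm(des$n, a = lo_all[y + 1L],
                                 b = up_all[y + 1L], mean = eta, sd = 1)
      # 3. joint rescale of the latent scale (group move)
      s_gs <- .scale_move(l - eta, des$n, K - 1L)
      l <- l * s_gs; theta <- theta * s_gs; gam <- gam * s_gs
      lo_all <- c(-Inf, gam); up_all <- c(gam, Inf)
      # 4. variance components
      a <- theta[a_ix]
      va <- .riscs(as.numeric(Matrix::crossprod(a, Ainv %*% a)), des$m,
                   prior$nu_a, prior$s2_a)
      pe <- theta[pe_ix]
      vpe <- .riscs(sum(pe^2), des$n_pe, prior$nu_pe, prior$s2_pe)
      if (it > burn && (it - burn) %% thin == 0) {
        it_keep <- it_keep + 1
        row <- (ch_i - 1) * keep + it_keep
        mu <- mean(des$X %*% theta[seq_len(p)])
        draws[row, ] <- c(va, vpe, va / (va + vpe + 1),
                          if (K >= 2) gam[-1], mu, theta[seq_len(p)])
      }
      if (verbose && it %% 500 == 0)
        message("chain ", ch_i, " iter ", it, " va=", round(va, 3))
    }
  }
  out <- list(draws = draws, chain = chain_ix, K = K, response = response,
              fixed = fixed, n = des$n, m = des$m,
              settings = list(n_iter = n_iter, burn = burn, thin = thin,
                              n_chains = n_chains, seed = seed,
                              prior = prior),
              cutpoint_acceptance = acc_tot / (n_iter * n_chains))
  class(out) <- c("threshold_animal_model", "animal_model")
  out
}

#' Gaussian animal model (e.g. for residual body mass)
#'
#' Same machinery as [fit_threshold_animal_model()] but with a Gaussian
#' response observed directly: no liabilities or cutpoints, and the
#' residual variance is estimated. The permanent-environment term is
#' optional (with one record per individual it is not separable from the
#' residual and is off by default).
#'
#' @inheritParams fit_threshold_animal_model
#' @param response name of the Gaussian response column.
#' @param include_pe include a permanent-environment effect.
#' @param prior list with \code{nu_a}, \code{s2_a}, \code{nu_e},
#'   \code{s2_e} (and \code{nu_pe}, \code{s2_pe} if \code{include_pe}).
#' @return Object of class \code{gaussian_animal_model} with draws of
#'   \code{va}, (\code{vpe}), \code{ve} and \code{h2}.
#' @export
fit_gaussian_animal_model <- function(records, pedigree, response,
                                      fixed = ~ sex + scale(age_days),
                                      include_pe = FALSE,
                                      n_iter = 3000, burn = 1000, thin = 2,
                                      n_chains = 2,
                                      prior = list(nu_a = 0.002, s2_a = 1,
                                                   nu_pe = 0.002, s2_pe = 1,
                                                   nu_e = 0.002, s2_e = 1),
                                      seed = 1) {
  keep_rows <- !is.na(records[[response]])
  records <- records[keep_rows, , drop = FALSE]
  des <- .am_design(records, pedigree, fixed, response)
  y <- as.numeric(des$y)
  Ainv <- relationship_inverse(pedigree)
  W <- if (include_pe) cbind(des$X, des$Za, des$Zp) else cbind(des$X, des$Za)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  p <- ncol(des$X)
  pad <- function(M, at) Matrix::bdiag(
    Matrix::Diagonal(at[1], x = 0), M, Matrix::Diagonal(at[2], x = 0))
  n_pe <- if (include_pe) des$n_pe else 0L
  Pa <- Matrix::forceSymmetric(pad(Ainv, c(p, n_pe)))
  Pp <- if (include_pe)
    Matrix::forceSymmetric(pad(Matrix::Diagonal(n_pe), c(p + des$m, 0)))
  Rb <- Matrix::forceSymmetric(pad(Matrix::Diagonal(p, x = 1e-8),
                                   c(0, des$m + n_pe)))
  Sa <- .ainv_sqrt(pedigree)
  a_ix <- p + seq_len(des$m); pe_ix <- p + des$m + seq_len(n_pe)

  keep <- floor((n_iter - burn) / thin)
  par_names <- c("va", if (include_pe) "vpe", "ve", "h2", "mu",
                 colnames(des$X))
  draws <- matrix(NA_real_, keep * n_chains, length(par_names),
                  dimnames = list(NULL, par_names))
  chain_ix <- rep(seq_len(n_chains), each = keep)

  vy <- stats::var(y)
  for (ch_i in seq_len(n_chains)) {
    set.seed(seed + ch_i - 1)
    va <- vy * 0.3 * ch_i; ve <- vy * 0.5; vpe <- vy * 0.1
    C <- Matrix::forceSymmetric(WtW * (1 / ve) + Rb + Pa * (1 / va) +
      (if (include_pe) Pp * (1 / vpe) else 0))
    chf <- Matrix::Cholesky(C, LDLt = FALSE, perm = TRUE, super = FALSE)
    it_keep <- 0
    for (it in seq_len(n_iter)) {
      C <- WtW * (1 / ve) + Rb + Pa * (1 / va) +
        (if (include_pe) Pp * (1 / vpe) else 0)
      chf <- Matrix::update(chf, Matrix::forceSymmetric(C))
      pert <- drop(Matrix::crossprod(W, stats::rnorm(des$n))) / sqrt(ve)
      pert[a_ix] <- pert[a_ix] +
        drop(Matrix::crossprod(Sa, stats::rnorm(des$m))) / sqrt(va)
      if (include_pe)
        pert[pe_ix] <- pert[pe_ix] + stats::rnorm(n_pe) / sqrt(vpe)
      pert[seq_len(p)] <- pert[seq_len(p)] + 1e-4 * stats::rnorm(p)
      theta <- .mvn_mme(chf, drop(Matrix::crossprod(W, y)) / ve + pert)
      e <- y - as.numeric(W %*% theta)
      ve <- .riscs(sum(e^2), des$n, prior$nu_e, prior$s2_e)
      a <- theta[a_ix]
      va <- .riscs(as.numeric(Matrix::crossprod(a, Ainv %*% a)), des$m,
                   prior$nu_a, prior$s2_a)
      if (include_pe) {
        pe <- theta[pe_ix]
        vpe <- .riscs(sum(pe^2), n_pe, prior$nu_pe, prior$s2_pe)
      }
      if (it > burn && (it - burn) %% thin == 0) {
        it_keep <- it_keep + 1
        row <- (ch_i - 1) * keep + it_keep
        h2 <- va / (va + (if (include_pe) vpe else 0) + ve)
        draws[row, ] <- c(va, if (include_pe) vpe, ve, h2,
                          mean(des$X %*% theta[seq_len(p)]),
                          theta[seq_len(p)])
      }
    }
  }
  out <- list(draws = draws, chain = chain_ix, response = response,
              fixed = fixed, n = des$n, m = des$m,
              settings = list(n_iter = n_iter, burn = burn, thin = thin,
                              n_chains = n_chains, seed = seed,
                              prior = prior, include_pe = include_pe))
  class(out) <- c("gaussian_animal_model", "animal_model")
  out
}

#' @export
print.animal_model <- function(x, ...) {
  cat(class(x)[1], sprintf(": %d records, %d pedigree members\n", x$n, x$m))
  s <- summary(x)
  print(round(s$table[intersect(rownames(s$table),
                                c("va", "vpe", "ve", "h2", "h2_latent")), ],
              3))
  invisible(x)
}

#' Posterior summary of an animal model
#'
#' Posterior means, SDs and central 95\% credible intervals per parameter.
#'
#' @param object an \code{animal_model} fit.
#' @param level interval level.
#' @param ... unused.
#' @export
summary.animal_model <- function(object, level = 0.95, ...) {
  a <- (1 - level) / 2
  tab <- t(apply(object$draws, 2, function(d)
    c(mean = mean(d), sd = stats::sd(d),
      lwr = stats::quantile(d, a, names = FALSE),
      upr = stats::quantile(d, 1 - a, names = FALSE))))
  out <- list(table = tab, n = object$n, level = level,
              settings = object$settings)
  class(out) <- "summary.animal_model"
  out
}

#' @export
print.summary.animal_model <- function(x, ...) {
  cat(sprintf("Posterior summaries (%d%% credible intervals):\n",
              round(100 * x$level)))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
as.matrix.animal_model <- function(x, ...) x$draws

#' Trace plots of animal-model draws
#'
#' @param x an \code{animal_model} fit.
#' @param pars parameters to plot (default the variance components).
#' @param ... passed to [graphics::plot()].
#' @export
plot.animal_model <- function(x, pars = NULL, ...) {
  if (is.null(pars))
    pars <- intersect(colnames(x$draws),
                      c("va", "vpe", "ve", "h2", "h2_latent", "rg"))
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (pp in pars) {
    graphics::plot(x$draws[, pp], type = "l", ylab = pp, xlab = "", ...)
    if (max(x$chain) > 1)
      graphics::abline(v = which(diff(x$chain) != 0), lty = 3)
  }
  invisible(x)
}

#' Export posterior draws as CSV
#'
#' One column per parameter plus the chain index, one row per retained
#' draw.
#'
#' @param fit an \code{animal_model} object.
#' @param path output CSV file.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "animal_model"))
  utils::write.csv(data.frame(chain = fit$chain, fit$draws,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
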