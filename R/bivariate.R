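#' Bivariate animal model (ordinal hip score with a second trait)
#'
#' Gibbs sampler partitioning variance between two traits observed on an
#' overlapping set of pedigree individuals: trait 1 is the ordinal hip
#' score (probit liability, residual variance fixed at 1), trait 2 either
#' Gaussian (residual body mass; residual variance estimated) or a second
#' ordinal score (e.g. the other hip). Breeding values are bivariate,
#' \eqn{(a_1, a_2) \sim N(0, G \otimes A)}, and G is updated from its
#' inverse-Wishart full conditional
#' \eqn{G \mid a \sim IW(\nu_0 + m,\ \Lambda_0 + S)} with
#' \eqn{S_{rs} = a_r' A^{-1} a_s}. The residual covariance between traits
#' is fixed at 0 by default (with a single record per cat and trait it is
#' only weakly identified on the liability scale); set
#' \code{estimate_residual_cov} for a bivariate-Gaussian residual when both
#' traits are Gaussian-like enough to carry it.
#'
#' Missing values in either trait are allowed; each trait uses its observed
#' rows only.
#'
#' @param records data frame holding both trait columns, \code{id} and the
#'   fixed-effect covariates.
#' @param pedigree a [as_pedigree()] object.
#' @param trait1 name of the ordinal response column (default
#'   \code{"max_score"}).
#' @param trait2 name of the second response column (e.g.
#'   \code{"residual_mass"} or \code{"right"}).
#' @param family2 \code{"gaussian"} or \code{"ordinal"}.
#' @param include_pe include a permanent-environment effect for the
#'   ordinal trait 1 (as in the univariate threshold model).
#' @param fixed one-sided fixed-effects formula used for both traits.
#' @param n_iter,burn,thin,n_chains chain settings.
#' @param prior list with \code{nu_g} (inverse-Wishart df, default 3),
#'   \code{lambda_g} (scale matrix, default \code{diag(1e-3, 2)}),
#'   \code{nu_e}, \code{s2_e} for the Gaussian residual, \code{nu_pe},
#'   \code{s2_pe} for the trait-1 permanent-environment variance.
#' @param seed RNG seed; chain c uses \code{seed + c - 1}.
#' @return Object of class \code{bivariate_animal_model} (an
#'   \code{animal_model}): draws of \code{va1}, \code{va2}, \code{cov_a},
#'   \code{rg}, \code{ve2}, cutpoints and fixed effects.
#' @seealso [genetic_correlation()] for the posterior of \eqn{r_G}.
#' @export
fit_bivariate_animal_model <- function(records, pedigree,
                                       trait1 = "max_score",
                                       trait2 = "residual_mass",
                                       family2 = c("gaussian", "ordinal"),
                                       include_pe = TRUE,
                                       fixed = ~ sex + scale(age_days),
                                       n_iter = 3000, burn = 1000, thin = 2,
                                       n_chains = 2,
                                       prior = list(nu_g = 3,
                                                    lambda_g = diag(1e-3, 2),
                                                    nu_e = 0.002, s2_e = 1,
                                                    nu_pe = 0.002, s2_pe = 1),
                                       seed = 1, verbose = FALSE) {
  family2 <- match.arg(family2)
  stopifnot(inherits(pedigree, "pedigree"))
  m <- nrow(pedigree)
  obs1 <- which(!is.na(records[[trait1]]))
  obs2 <- which(!is.na(records[[trait2]]))
  if (!length(obs1) || !length(obs2)) stop("each trait needs observations")
  r1 <- records[obs1, , drop = FALSE]; r2 <- records[obs2, , drop = FALSE]
  pos1 <- match(r1$id, pedigree$id); pos2 <- match(r2$id, pedigree$id)
  if (anyNA(pos1) || anyNA(pos2))
    stop("phenotyped id(s) missing from the pedigree")
  X1 <- stats::model.matrix(fixed, r1); X2 <- stats::model.matrix(fixed, r2)
  n1 <- nrow(X1); n2 <- nrow(X2); p1 <- ncol(X1); p2 <- ncol(X2)
  y1 <- as.integer(r1[[trait1]])
  ncat1 <- max(y1) + 1L; K1 <- ncat1 - 1L
  y2 <- if (family2 == "ordinal") as.integer(r2[[trait2]])
        else as.numeric(r2[[trait2]])
  K2 <- if (family2 == "ordinal") max(y2) else 0L

  Ainv <- relationship_inverse(pedigree)
  # block layout: beta1 | beta2 | a1 (m) | a2 (m) | pe1 (n_pe, optional)
  Z1 <- Matrix::sparseMatrix(i = seq_len(n1), j = pos1, x = 1, dims = c(n1, m))
  Z2 <- Matrix::sparseMatrix(i = seq_len(n2), j = pos2, x = 1, dims = c(n2, m))
  zero <- function(nr, nc) Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                x = numeric(0), dims = c(nr, nc))
  uid1 <- unique(r1$id)
  n_pe <- if (include_pe) length(uid1) else 0L
  Zp1 <- Matrix::sparseMatrix(i = seq_len(n1), j = match(r1$id, uid1),
                              x = 1, dims = c(n1, length(uid1)))
  W1 <- cbind(Matrix::Matrix(X1, sparse = TRUE), zero(n1, p2), Z1,
              zero(n1, m), if (include_pe) Zp1)
  W2 <- cbind(zero(n2, p1), Matrix::Matrix(X2, sparse = TRUE), zero(n2, m),
              Z2, if (include_pe) zero(n2, n_pe))
  a1_ix <- p1 + p2 + seq_len(m); a2_ix <- p1 + p2 + m + seq_len(m)
  pe_ix <- p1 + p2 + 2 * m + seq_len(n_pe)
  Rb <- Matrix::forceSymmetric(Matrix::bdiag(
    Matrix::Diagonal(p1 + p2, x = 1e-8),
    Matrix::Diagonal(2 * m + n_pe, x = 0)))
  pad_g <- function(Ginv, vpe) Matrix::forceSymmetric(Matrix::bdiag(
    Matrix::Diagonal(p1 + p2, x = 0), Matrix::kronecker(Ginv, Ainv),
    Matrix::Diagonal(n_pe, x = 1 / vpe)))
  Sa <- .ainv_sqrt(pedigree)
  W1tW1 <- Matrix::crossprod(W1); W2tW2 <- Matrix::crossprod(W2)

  keep <- floor((n_iter - burn) / thin)
  par_names <- c("va1", "va2", "cov_a", "rg",
                 if (family2 == "gaussian") "ve2",
                 if (include_pe) "vpe1",
                 "h2_1_latent",
                 if (K1 >= 2) paste0("gamma1_", 2:K1),
                 if (K2 >= 2) paste0("gamma2_", 2:K2),
                 "mu1", "mu2",
                 paste0("t1_", colnames(X1)), paste0("t2_", colnames(X2)))
  draws <- matrix(NA_real_, keep * n_chains, length(par_names),
                  dimnames = list(NULL, par_names))
  chain_ix <- rep(seq_len(n_chains), each = keep)

  vy2 <- if (family2 == "gaussian") stats::var(y2) else 1
  for (ch_i in seq_len(n_chains)) {
    set.seed(seed + ch_i - 1)
    # start with a small genetic covariance so the sparsity pattern of
    # kron(Ginv, Ainv) (and hence the symbolic Cholesky analysis) already
    # contains the cross-trait blocks
    G <- matrix(c(0.5 * ch_i, 0.05, 0.05, 0.4 * vy2), 2, 2)
    vpe1 <- 0.2
    ve2 <- if (family2 == "gaussian") 0.5 * vy2 else 1
    gam1 <- cumsum(c(0, rep(0.8, max(K1 - 1, 0))))
    gam2 <- cumsum(c(0, rep(0.8, max(K2 - 1, 0))))
    lo1 <- c(-Inf, gam1); up1 <- c(gam1, Inf)
    l1 <- truncnorm::rtruncnorm(n1, a = lo1[y1 + 1L], b = up1[y1 + 1L], 0, 1)
    l2 <- if (family2 == "ordinal") {
      lo2 <- c(-Inf, gam2); up2 <- c(gam2, Inf)
      truncnorm::rtruncnorm(n2, a = lo2[y2 + 1L], b = up2[y2 + 1L], 0, 1)
    } else y2
    C0 <- Matrix::forceSymmetric(
      W1tW1 + W2tW2 * (1 / ve2) + Rb + pad_g(solve(G), vpe1))
    chf <- Matrix::Cholesky(C0, LDLt = FALSE, perm = TRUE, super = FALSE)
    step1 <- step2 <- 0.05; acc1 <- acc2 <- 0
    it_keep <- 0
    for (it in seq_len(n_iter)) {
      Ginv <- solve(G)
      C <- Matrix::forceSymmetric(W1tW1 + W2tW2 * (1 / ve2) + Rb +
                                    pad_g(Ginv, vpe1))
      chf <- Matrix::update(chf, C)
      rhs <- drop(Matrix::crossprod(W1, l1)) +
        drop(Matrix::crossprod(W2, l2)) / ve2
      pert <- drop(Matrix::crossprod(W1, stats::rnorm(n1))) +
        drop(Matrix::crossprod(W2, stats::rnorm(n2))) / sqrt(ve2)
      U <- chol(Ginv)
      Zg <- matrix(stats::rnorm(2 * m), m, 2)
      pert[c(a1_ix, a2_ix)] <- pert[c(a1_ix, a2_ix)] +
        as.vector(Matrix::crossprod(Sa, Zg) %*% U)
      if (include_pe)
        pert[pe_ix] <- pert[pe_ix] + stats::rnorm(n_pe) / sqrt(vpe1)
      pert[seq_len(p1 + p2)] <- pert[seq_len(p1 + p2)] +
        1e-4 * stats::rnorm(p1 + p2)
      theta <- .mvn_mme(chf, rhs + pert)
      eta1 <- as.numeric(W1 %*% theta); eta2 <- as.numeric(W2 %*% theta)
      # trait-1 cutpoints and liabilities
      if (K1 >= 2) {
        upd <- .update_cutpoints(gam1, eta1, y1, step1)
        gam1 <- upd$gam; acc1 <- acc1 + upd$acc
        if (it <= burn && it %% 25 == 0)
          step1 <- step1 * exp(0.5 * (acc1 / it - 0.25))
      }
      lo1 <- c(-Inf, gam1); up1 <- c(gam1, Inf)
      l1 <- truncnorm::rtruncnorm(n1, a = lo1[y1 + 1L], b = up1[y1 + 1L],
                                  mean = eta1, sd = 1)
      if (family2 == "ordinal") {
        if (K2 >= 2) {
          upd <- .update_cutpoints(gam2, eta2, y2, step2)
          gam2 <- upd$gam; acc2 <- acc2 + upd$acc
          if (it <= burn && it %% 25 == 0)
            step2 <- step2 * exp(0.5 * (acc2 / it - 0.25))
        }
        lo2 <- c(-Inf, gam2); up2 <- c(gam2, Inf)
        l2 <- truncnorm::rtruncnorm(n2, a = lo2[y2 + 1L], b = up2[y2 + 1L],
                                    mean = eta2, sd = 1)
      } else {
        e2 <- y2 - eta2
        ve2 <- .riscs(sum(e2^2), n2, prior$nu_e, prior$s2_e)
      }
      # joint rescale of the trait-1 latent scale (group move)
      s_gs <- .scale_move(l1 - eta1, n1, max(K1 - 1L, 0L))
      l1 <- l1 * s_gs
      t1_ix <- c(seq_len(p1), a1_ix, if (include_pe) pe_ix)
      theta[t1_ix] <- theta[t1_ix] * s_gs
      gam1 <- gam1 * s_gs
      # G | a: inverse-Wishart full conditional
      a1 <- theta[a1_ix]; a2 <- theta[a2_ix]
      Aa1 <- Ainv %*% a1; Aa2 <- Ainv %*% a2
      S <- matrix(c(as.numeric(Matrix::crossprod(a1, Aa1)),
                    as.numeric(Matrix::crossprod(a1, Aa2)),
                    as.numeric(Matrix::crossprod(a1, Aa2)),
                    as.numeric(Matrix::crossprod(a2, Aa2))), 2, 2)
      df <- prior$nu_g + m
      Wdraw <- stats::rWishart(1, df, solve(prior$lambda_g + S))[, , 1]
      G <- solve(Wdraw)
      if (include_pe) {
        pe1 <- theta[pe_ix]
        vpe1 <- .riscs(sum(pe1^2), n_pe, prior$nu_pe, prior$s2_pe)
      }
      if (it > burn && (it - burn) %% thin == 0) {
        it_keep <- it_keep + 1
        row <- (ch_i - 1) * keep + it_keep
        beta1 <- theta[seq_len(p1)]; beta2 <- theta[p1 + seq_len(p2)]
        draws[row, ] <- c(G[1, 1], G[2, 2], G[1, 2],
                          G[1, 2] / sqrt(G[1, 1] * G[2, 2]),
                          if (family2 == "gaussian") ve2,
                          if (include_pe) vpe1,
                          G[1, 1] / (G[1, 1] + (if (include_pe) vpe1 else 0) + 1),
                          if (K1 >= 2) gam1[-1], if (K2 >= 2) gam2[-1],
                          mean(X1 %*% beta1), mean(X2 %*% beta2),
                          beta1, beta2)
      }
      if (verbose && it %% 500 == 0)
        message("chain ", ch_i, " iter ", it, " rg=",
                round(G[1, 2] / sqrt(G[1, 1] * G[2, 2]), 3))
    }
  }
  out <- list(draws = draws, chain = chain_ix, traits = c(trait1, trait2),
              family2 = family2, fixed = fixed, n = c(n1, n2), m = m,
              settings = list(n_iter = n_iter, burn = burn, thin = thin,
                              n_chains = n_chains, seed = seed, prior = prior))
  class(out) <- c("bivariate_animal_model", "animal_model")
  out
}

#' Convergence diagnostics for animal-model chains
#'
#' Split-\eqn{\hat{R}} (each chain halved, between/within variance ratio)
#' and effective sample size per parameter. The conventional pass criterion
#' is \eqn{\hat{R} < 1.01} with ESS > 200; constant chains give
#' \code{NA} with a warning.
#'
#' @param fit an \code{animal_model} object (or a draws matrix plus a
#'   \code{chain} index vector).
#' @param chain chain index when \code{fit} is a plain matrix.
#' @return Data frame with \code{parameter}, \code{rhat}, \code{ess} and a
#'   logical \code{ok}.
#' @export
mcmc_diagnostics <- function(fit, chain = NULL) {
  if (inherits(fit, "animal_model")) {
    draws <- fit$draws; chain <- fit$chain
  } else {
    draws <- as.matrix(fit)
    if (is.null(chain)) chain <- rep(1L, nrow(draws))
  }
  rhat <- apply(draws, 2, .split_rhat, chain = chain)
  ess <- apply(draws, 2, function(d) {
    if (stats::sd(d) == 0) return(NA_real_)
    sum(vapply(split(d, chain), function(x)
      as.numeric(coda::effectiveSize(x)), 0))
  })
  if (anyNA(rhat)) warning("constant chain(s): R-hat undefined for ",
                           paste(colnames(draws)[is.na(rhat)], collapse = ", "))
  data.frame(parameter = colnames(draws), rhat = rhat, ess = ess,
             ok = !is.na(rhat) & rhat < 1.01 & ess > 200,
             row.names = NULL)
}

# split R-hat: halve each chain, then classic Gelman-Rubin over the halves
.split_rhat <- function(d, chain) {
  halves <- unlist(lapply(split(d, chain), function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  halves <- halves[lengths(halves) >= 2]
  if (length(halves) < 2) return(NA_real_)
  nn <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(nn)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  B <- nn * stats::var(means)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
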