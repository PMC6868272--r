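#' Configuration of the synthetic breeding-programme generator
#'
#' Bundles the full generative truth of a simulated screening programme:
#' a liability-threshold model for the two hip scores (additive genetic +
#' permanent-environment + independent unit residual per hip), body mass
#' from a sex-specific Gompertz curve plus a genetic effect correlated
#' with hip liability, and generation-on-generation selection against high
#' scores following the programme's breeding recommendation (cats with
#' grade 2 or 3 on either hip excluded; grade-1 cats mated only to grade-0
#' partners).
#'
#' The default truth reproduces the published study conditions: latent
#' heritability of the hip score 0.5 (\code{v_a / (v_a + v_pe + 1)}), mass
#' heritability 0.57, genetic correlation 0.285, founder liability mean and
#' cutpoints tuned so the programme shows roughly 37\% prevalence overall,
#' about 37\% unilateral cases among affected cats, and a mean maximum
#' score near 0.85 in the first selected generation.
#'
#' @param n_founders founders in generation 0.
#' @param n_generations breeding generations after the founders.
#' @param n_per_gen offspring born per generation.
#' @param litter_size mean litter size (litters are 1 + Poisson).
#' @param selection_threshold exclude breeding candidates with maximum
#'   score >= this (default 2; a value > 3 disables selection entirely).
#' @param grade1_rule if \code{TRUE}, grade-1 candidates may only be mated
#'   to grade-0 partners.
#' @param prop_sires fraction of eligible males actually used as sires
#'   (popular-sire effect; increases male selection intensity).
#' @param v_a,v_pe additive-genetic and permanent-environment variance of
#'   the hip liability (per-hip residual variance is 1).
#' @param cutpoints increasing liability cutpoints \eqn{(\gamma_1, \gamma_2,
#'   \gamma_3)} separating scores 0-3.
#' @param mu_liability founder mean liability.
#' @param growth per-sex Gompertz parameters \code{A} (kg), \code{b},
#'   \code{c} (1/day).
#' @param v_mass_a,v_mass_e genetic and environmental variance of adult
#'   body mass (kg^2).
#' @param cov_a genetic covariance between hip liability and mass.
#' @param frac_massed fraction of submitted cats with a recorded mass.
#' @param male_submission probability a male cat is submitted for
#'   screening (females always are; matches the female-skewed database).
#' @param age_meanlog,age_sdlog log-normal assessment-age distribution
#'   (days); the default median is 520 days.
#' @param start_year programme start; generation g is assessed around
#'   \code{start_year + g * gen_interval_years}.
#' @param gen_interval_years generation interval.
#' @param mass_year_trend drift in expected body mass (kg per calendar
#'   year), emulating gradual change in the composition of submitted cats;
#'   0 by default.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_founders = 300, n_generations = 8, n_per_gen = 770,
                       litter_size = 4, selection_threshold = 2,
                       grade1_rule = TRUE, prop_sires = 0.7,
                       v_a = 4, v_pe = 3,
                       cutpoints = c(0, 1.9, 3.86), mu_liability = 0.8,
                       growth = list(female = c(A = 5.5, b = 4, c = 0.006),
                                     male = c(A = 8.0, b = 4, c = 0.006)),
                       v_mass_a = 0.2, v_mass_e = 0.15,
                       cov_a = 0.285 * sqrt(0.2 * 4),
                       frac_massed = 0.43, male_submission = 0.53,
                       age_meanlog = log(520), age_sdlog = 0.35,
                       start_year = 2000, gen_interval_years = 2.4,
                       mass_year_trend = 0) {
  cfg <- as.list(environment())
  stopifnot(n_founders >= 20, n_generations >= 1, litter_size >= 1,
            v_a >= 0, v_pe >= 0, v_mass_a >= 0, v_mass_e >= 0,
            all(diff(cutpoints) > 0), length(cutpoints) == 3)
  G <- matrix(c(v_a, cov_a, cov_a, v_mass_a), 2, 2)
  if (min(eigen(G, only.values = TRUE)$values) < -1e-12)
    stop("implied genetic covariance matrix is not positive semi-definite")
  cfg$G <- G
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Breeding-programme simulation config\n")
  cat(sprintf("  %d founders + %d generations x %d offspring\n",
              x$n_founders, x$n_generations, x$n_per_gen))
  cat(sprintf("  latent h2 = %.3f, mass h2 = %.3f, r_G = %.3f\n",
              x$v_a / (x$v_a + x$v_pe + 1),
              x$v_mass_a / (x$v_mass_a + x$v_mass_e),
              x$cov_a / sqrt(x$v_a * x$v_mass_a)))
  cat(sprintf("  selection: exclude max score >= %s%s\n",
              format(x$selection_threshold),
              if (x$grade1_rule) ", grade-1 x grade-0 only" else ""))
  invisible(x)
}

# upper-triangular factor used to colour iid normals; an all-zero G maps
# to exactly zero effects
.psd_sqrt <- function(G) {
  if (all(G == 0)) return(matrix(0, nrow(G), ncol(G)))
  chol(G + diag(1e-12, nrow(G)))
}

# Gompertz expected mass
.growth_mass <- function(growth, sex, age) {
  p <- do.call(rbind, growth[sex])
  p[, "A"] * exp(-p[, "b"] * exp(-p[, "c"] * age))
}

# score two hips given cat-level liability
.score_hips <- function(liab, cutpoints) {
  n <- length(liab)
  left <- findInterval(liab + stats::rnorm(n), cutpoints)
  right <- findInterval(liab + stats::rnorm(n), cutpoints)
  cbind(left = left, right = right)
}

#' Simulate a complete screening-and-selection programme
#'
#' Generation by generation: breeding values for hip liability and mass
#' descend with Mendelian sampling (variance reduced by parental
#' inbreeding), per-hip scores arise from the cat's liability plus an
#' independent unit-normal residual per hip cut at the configured
#' thresholds, and the next generation's parents are drawn only from
#' screened cats passing the selection rule.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (required for reproducible truth).
#' @return Object of class \code{fhd_sim}: list with \code{pedigree} (a
#'   [as_pedigree()] with a \code{generation} attribute), \code{records}
#'   (a \code{hip_records} data frame of submitted cats), \code{truth}
#'   (per-individual breeding values, permanent-environment effects,
#'   liabilities and generation) and \code{config}.
#' @export
simulate_programme <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  select_on <- is.finite(cfg$selection_threshold) &&
    cfg$selection_threshold <= 3
  Gch <- .psd_sqrt(cfg$G)

  id <- character(0); sire <- character(0); dam <- character(0)
  sex <- character(0); gen <- integer(0)
  bv <- matrix(numeric(0), 0, 2)  # liability, mass
  si_ix <- integer(0); di_ix <- integer(0)

  new_cats <- function(k, g, s_ix, d_ix) {
    # BVs: founder draw or parental average + Mendelian deviation
    if (g == 0) {
      b <- matrix(stats::rnorm(2 * k), k, 2) %*% Gch
    } else {
      Fped <- .ml_inbreeding(si_ix, di_ix)
      fs <- Fped[s_ix]; fd <- Fped[d_ix]
      mend <- matrix(stats::rnorm(2 * k), k, 2) %*% Gch *
        sqrt(0.5 * (1 - (fs + fd) / 2))
      b <- 0.5 * (bv[s_ix, , drop = FALSE] + bv[d_ix, , drop = FALSE]) + mend
    }
    b
  }

  all_rec <- list()
  truth <- list()
  prev_ix <- integer(0)
  for (g in 0:cfg$n_generations) {
    if (g == 0) {
      k <- cfg$n_founders
      s_ix <- d_ix <- rep(0L, k)
      sx <- sample(rep(c("male", "female"), length.out = k))
    } else {
      prev <- prev_ix
      scr <- attr(all_rec[[g]], "screen")   # screening info of generation g-1
      if (select_on) {
        elig <- scr$submitted & scr$max < cfg$selection_threshold
      } else {
        elig <- rep(TRUE, length(prev))
      }
      cand <- prev[elig]
      cand_sex <- sex[cand]; cand_max <- scr$max[elig]
      males <- cand[cand_sex == "male"]; fems <- cand[cand_sex == "female"]
      if (length(males) < 2 || length(fems) < 2)
        stop("selection rule leaves too few breeding candidates in ",
             "generation ", g - 1, "; relax selection_threshold")
      n_sires <- max(2L, round(cfg$prop_sires * length(males)))
      sires <- sample(males, n_sires)
      sire_max <- scr$max[match(sires, prev)]
      k <- cfg$n_per_gen
      s_ix <- integer(k); d_ix <- integer(k); filled <- 0L
      dams_pool <- sample(fems)
      di <- 0L
      while (filled < k) {
        di <- di + 1L
        if (di > length(dams_pool)) { dams_pool <- sample(fems); di <- 1L }
        dm <- dams_pool[di]
        dm_max <- scr$max[match(dm, prev)]
        ok_sires <- if (select_on && cfg$grade1_rule && dm_max >= 1)
          sires[sire_max == 0] else sires
        if (!length(ok_sires)) next
        srx <- if (length(ok_sires) == 1) ok_sires else sample(ok_sires, 1)
        litter <- min(1L + stats::rpois(1, cfg$litter_size - 1), k - filled)
        s_ix[filled + seq_len(litter)] <- srx
        d_ix[filled + seq_len(litter)] <- dm
        filled <- filled + litter
      }
      sx <- ifelse(stats::runif(k) < 0.5, "male", "female")
    }
    new_id <- sprintf("G%d_%04d", g, seq_len(k))
    base <- length(id)
    id <- c(id, new_id)
    sire <- c(sire, ifelse(s_ix > 0, id[pmax(s_ix, 1L)], NA))
    dam <- c(dam, ifelse(d_ix > 0, id[pmax(d_ix, 1L)], NA))
    sex <- c(sex, sx); gen <- c(gen, rep(g, k))
    si_ix <- c(si_ix, s_ix); di_ix <- c(di_ix, d_ix)
    b <- new_cats(k, g, s_ix, d_ix)
    bv <- rbind(bv, b)
    ix <- base + seq_len(k)

    # phenotypes of this generation
    pe <- stats::rnorm(k, 0, sqrt(cfg$v_pe))
    liab <- cfg$mu_liability + b[, 1] + pe
    scores <- .score_hips(liab, cfg$cutpoints)
    mx <- pmax(scores[, 1], scores[, 2])
    age <- pmax(round(stats::rlnorm(k, cfg$age_meanlog, cfg$age_sdlog)), 180)
    year <- round(cfg$start_year + g * cfg$gen_interval_years +
                    stats::runif(k, 0, cfg$gen_interval_years - 0.01))
    submitted <- sx == "female" | stats::runif(k) < cfg$male_submission
    massed <- submitted & stats::runif(k) < cfg$frac_massed
    mass <- pmax(.growth_mass(cfg$growth, sx, age) + b[, 2] +
                   cfg$mass_year_trend * (year - cfg$start_year) +
                   stats::rnorm(k, 0, sqrt(cfg$v_mass_e)), 0.3)
    rec <- data.frame(id = new_id, sex = sx, age_days = age,
                      year = year, left = scores[, 1], right = scores[, 2],
                      mass_kg = ifelse(massed, round(mass, 2), NA),
                      stringsAsFactors = FALSE)
    attr(rec, "screen") <- list(submitted = submitted, max = mx)
    all_rec[[g + 1]] <- rec
    truth[[g + 1]] <- data.frame(id = new_id, generation = g,
                                 bv_liability = b[, 1], bv_mass = b[, 2],
                                 pe = pe, liability = liab,
                                 stringsAsFactors = FALSE)
    prev_ix <- ix
  }

  ped <- as_pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                                stringsAsFactors = FALSE))
  attr(ped, "generation") <- gen[match(ped$id, id)]
  submitted_all <- unlist(lapply(all_rec, function(r) attr(r, "screen")$submitted))
  rec_all <- do.call(rbind, all_rec)
  records <- as_hip_records(rec_all[submitted_all, , drop = FALSE])
  out <- list(pedigree = ped, records = records,
              truth = do.call(rbind, truth), config = cfg, seed = seed)
  class(out) <- "fhd_sim"
  out
}

#' @export
print.fhd_sim <- function(x, ...) {
  cat(sprintf("Simulated programme: %d pedigree members, %d screened records, %d generations (seed %d)\n",
              nrow(x$pedigree), nrow(x$records), max(x$truth$generation),
              x$seed))
  cat(sprintf("  prevalence %.1f%%, mean max score %.3f\n",
              100 * mean(x$records$max_score >= 1), mean(x$records$max_score)))
  invisible(x)
}

#' Simulate a selected pedigree only
#'
#' Runs the full programme engine and returns just the pedigree with its
#' generation labels (phenotypes are simulated internally because the
#' selection rule needs them, then discarded).
#'
#' @inheritParams simulate_programme
#' @return A [as_pedigree()] with a \code{generation} attribute.
#' @export
simulate_pedigree <- function(config = sim_config(), seed = 1) {
  simulate_programme(config, seed)$pedigree
}

#' Simulate breeding values down a fixed pedigree
#'
#' Founders are drawn from \eqn{N(0, G)}; every non-founder is the
#' parental average plus a Mendelian deviation
#' \eqn{N(0, G (1 - (F_s + F_d)/2)/2)} (a missing parent contributes a 0
#' average and a correspondingly larger deviation; its F enters as 0).
#'
#' @param pedigree a [as_pedigree()] object.
#' @param G genetic covariance matrix (any dimension >= 1).
#' @param seed RNG seed.
#' @return Matrix of breeding values, one row per pedigree member, in
#'   pedigree order.
#' @export
simulate_breeding_values <- function(pedigree, G, seed = 1) {
  stopifnot(inherits(pedigree, "pedigree"))
  G <- as.matrix(G)
  set.seed(seed)
  si <- attr(pedigree, "sire_ix"); di <- attr(pedigree, "dam_ix")
  Fped <- .ml_inbreeding(si, di)
  n <- nrow(pedigree); q <- ncol(G)
  Gch <- .psd_sqrt(G)
  bv <- matrix(0, n, q)
  z <- matrix(stats::rnorm(n * q), n, q) %*% Gch
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    pa <- (if (s > 0) bv[s, ] else 0) / 2 + (if (d > 0) bv[d, ] else 0) / 2
    fs <- if (s > 0) Fped[s] else 0
    fd <- if (d > 0) Fped[d] else 0
    # Mendelian-sampling variance; a missing parent contributes its full
    # founder share (G/4) on top of the within-family term
    vshare <- 0.5 * (1 - (fs + fd) / 2) + 0.25 * (s == 0) + 0.25 * (d == 0)
    bv[i, ] <- pa + z[i, ] * sqrt(vshare)
  }
  rownames(bv) <- pedigree$id
  bv
}

#' Simulate phenotypes given breeding values
#'
#' Applies the liability-threshold and growth models of the generator to a
#' fixed pedigree and fixed breeding values: per cat, liability = mean +
#' genetic value + permanent-environment effect; each hip adds its own
#' unit-normal residual before cutting at the thresholds (so laterality
#' emerges from per-hip sampling alone); mass = Gompertz(sex, age) +
#' genetic value + environmental deviation.
#'
#' @param pedigree a [as_pedigree()] object.
#' @param bv matrix from [simulate_breeding_values()] with columns
#'   (liability, mass).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param generation optional generation labels used for assessment years
#'   (defaults to the pedigree's \code{generation} attribute, else 0).
#' @return A \code{hip_records} data frame for all individuals, with the
#'   realised permanent-environment effects and liabilities attached as
#'   attributes \code{"pe"} and \code{"liability"}.
#' @export
simulate_phenotypes <- function(pedigree, bv, config = sim_config(),
                                seed = 1, generation = NULL) {
  stopifnot(inherits(pedigree, "pedigree"))
  set.seed(seed)
  n <- nrow(pedigree)
  if (is.null(generation))
    generation <- attr(pedigree, "generation") %||% rep(0L, n)
  sx <- ifelse(pedigree$sex == "unknown", "female", pedigree$sex)
  pe <- stats::rnorm(n, 0, sqrt(config$v_pe))
  liab <- config$mu_liability + bv[, 1] + pe
  scores <- .score_hips(liab, config$cutpoints)
  age <- pmax(round(stats::rlnorm(n, config$age_meanlog, config$age_sdlog)), 180)
  year <- round(config$start_year + generation * config$gen_interval_years +
                  stats::runif(n, 0, max(config$gen_interval_years - 0.01, 0)))
  mass <- pmax(.growth_mass(config$growth, sx, age) +
                 (if (ncol(bv) >= 2) bv[, 2] else 0) +
                 config$mass_year_trend * (year - config$start_year) +
                 stats::rnorm(n, 0, sqrt(config$v_mass_e)), 0.3)
  massed <- stats::runif(n) < config$frac_massed
  rec <- as_hip_records(data.frame(
    id = pedigree$id, sex = sx, age_days = age, year = year,
    left = scores[, 1], right = scores[, 2],
    mass_kg = ifelse(massed, round(mass, 2), NA), stringsAsFactors = FALSE))
  attr(rec, "pe") <- pe
  attr(rec, "liability") <- liab
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated dataset to disk
#'
#' Emits \code{pedigree.csv}, \code{phenotypes.csv} and \code{truth.csv}
#' in the pipeline's input dialects; the first two round-trip losslessly
#' through [read_pedigree()] and [load_records()].
#'
#' @param sim an [simulate_programme()] result.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(sim, out_dir) {
  stopifnot(inherits(sim, "fhd_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ped <- as.data.frame(sim$pedigree)
  ped$sire[is.na(ped$sire)] <- ""
  ped$dam[is.na(ped$dam)] <- ""
  ped$generation <- attr(sim$pedigree, "generation")
  paths <- file.path(out_dir, c("pedigree.csv", "phenotypes.csv", "truth.csv"))
  utils::write.csv(ped, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(sim$records), paths[2],
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(sim$truth, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
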