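#' Run the full analysis pipeline on a pedigree + phenotype dataset
#'
#' Chains the package's stages on one dataset: demographic score summaries
#' and laterality; sex-specific growth curves and residual body mass;
#' mean-ancestor selection scores; truncated-Poisson selection-response
#' regressions; and the Bayesian animal models (univariate threshold for
#' the maximum hip score, Gaussian for residual mass, bivariate for the
#' genetic correlation). Emits a single report object that can be written
#' to JSON/CSV with [write_report()].
#'
#' @param pedigree a [as_pedigree()] object or path to a pedigree CSV.
#' @param records a \code{hip_records} data frame or path to a phenotype
#'   CSV.
#' @param stages character vector of stages to run, any of
#'   \code{"demography"}, \code{"growth"}, \code{"glm"},
#'   \code{"animal_model"}.
#' @param seed seed for the samplers.
#' @param n_iter,burn,thin,n_chains animal-model chain settings.
#' @param glm_method \code{"mle"} or \code{"bayes"} for the
#'   truncated-Poisson fits.
#' @param selection_formula formula for the generation (selection-response)
#'   model of the maximum score.
#' @param rhat_gate flag (and mark as failed) an animal-model fit whose
#'   reported heritability has split-R-hat above this (default 1.1). The
#'   gate applies to \code{h2_latent}, not to \code{va}/\code{vpe}
#'   individually: with single records only their combination is well
#'   identified and the components themselves are expected to mix slowly.
#' @return Object of class \code{fhd_report}: nested list of stage
#'   results, convergence diagnostics, and provenance (config, seed,
#'   package version). Stage failures are caught and recorded under
#'   \code{$failures} rather than aborting the remaining stages.
#' @export
run_analysis <- function(pedigree, records,
                         stages = c("demography", "growth", "glm",
                                    "animal_model"),
                         seed = 1, n_iter = 3000, burn = 1000, thin = 2,
                         n_chains = 2, glm_method = "bayes",
                         selection_formula = max_score ~ mean_ancestor_score +
                           sex + age_days,
                         rhat_gate = 1.1) {
  if (is.character(pedigree)) pedigree <- read_pedigree(pedigree)
  if (is.character(records)) records <- load_records(records)
  stopifnot(inherits(pedigree, "pedigree"), inherits(records, "hip_records"))
  report <- list(provenance = list(
    seed = seed, version = as.character(utils::packageVersion("felhip")),
    n_records = nrow(records), n_pedigree = nrow(pedigree),
    stages = stages, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  failures <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  dat <- records
  if ("demography" %in% stages) {
    report$demography <- run_stage("demography", {
      tab <- summarize_scores(dat)
      lat <- laterality_from_records(dat)
      list(score_table = tab,
           prevalence_pct = tab$prevalence_pct,
           laterality = lat[c("unilateral_frac", "bilateral_frac",
                              "n_affected")],
           trend = if (length(unique(dat$year)) > 2)
             stats::coef(fit_multinomial_trend(dat)$fit))
    })
  }
  if ("growth" %in% stages) {
    gr <- run_stage("growth", {
      g <- fit_growth_curve(dat)
      list(model = g, residuals = residual_mass(g, dat))
    })
    if (!is.null(gr)) {
      dat$residual_mass <- gr$residuals
      report$growth <- list(
        model = gr$model,
        mass_at_520d = c(female = predict_mass(gr$model, "female", 520),
                         male = predict_mass(gr$model, "male", 520)))
    }
  }
  if (is.null(dat$residual_mass) && !all(is.na(dat$mass_kg))) {
    g <- run_stage("growth_residuals", {
      gm <- fit_growth_curve(dat)
      residual_mass(gm, dat)
    })
    if (!is.null(g)) dat$residual_mass <- g
  }
  # ancestor scores are used by both GLM stages
  screened <- stats::setNames(dat$year, dat$id)
  anc <- mean_ancestor_scores(pedigree, screened, subjects = dat$id)
  dat$mean_ancestor_score <- anc$mean_ancestor_score

  if ("glm" %in% stages) {
    report$glm <- run_stage("glm", {
      # generation model: year is omitted here because programmes with
      # discrete generations make year and ancestor score collinear;
      # pass selection_formula to restore the year adjustment
      sel <- fit_trunc_poisson(selection_formula, dat,
                               method = glm_method, seed = seed)
      grid <- data.frame(mean_ancestor_score = c(1, 8),
                         sex = "female", age_days = 520,
                         year = stats::median(dat$year))
      curve <- predict_score_curve(sel, grid)
      red <- score_reduction(sel, grid[1, ], grid[2, ])
      covariate_fit <- if (!all(is.na(dat$residual_mass)))
        fit_trunc_poisson(max_score ~ age_days + residual_mass + sex + year,
                          dat[!is.na(dat$residual_mass), ],
                          method = glm_method, seed = seed)
      mass_trend <- if (!all(is.na(dat$residual_mass)))
        fit_mass_vs_generations(dat[!is.na(dat$residual_mass), ])
      list(selection_model = summary(sel)$coefficients,
           score_curve = curve,
           reduction_g1_to_g8_pct = red,
           covariate_model = if (!is.null(covariate_fit))
             summary(covariate_fit)$coefficients,
           mass_trend = if (!is.null(mass_trend))
             list(slope_kg_per_gen = mass_trend$slope_kg_per_gen,
                  slope_ci = mass_trend$slope_ci,
                  change_after_8_gen_kg = mass_trend$change_after_horizon))
    })
  }
  if ("animal_model" %in% stages) {
    report$animal_model <- run_stage("animal_model", {
      thr <- fit_threshold_animal_model(dat, pedigree, seed = seed,
                                        n_iter = n_iter, burn = burn,
                                        thin = thin, n_chains = n_chains)
      obs <- h2_observed_scale(thr$draws[, "va"], thr$draws[, "vpe"],
                               thr$draws[, "mu"],
                               cbind(0, thr$draws[, "gamma2"],
                                     thr$draws[, "gamma3"]))
      diag_thr <- mcmc_diagnostics(thr)
      out <- list(
        h2_latent = .post_sum(thr$draws[, "h2_latent"]),
        h2_observed = .post_sum(obs$h2_obs),
        va = .post_sum(thr$draws[, "va"]),
        vpe = .post_sum(thr$draws[, "vpe"]),
        diagnostics = diag_thr)
      if (!all(is.na(dat$residual_mass))) {
        biv <- fit_bivariate_animal_model(dat, pedigree, seed = seed,
                                          n_iter = n_iter, burn = burn,
                                          thin = thin, n_chains = n_chains)
        rg <- genetic_correlation(biv$draws[, c("va1", "va2", "cov_a")])
        mass <- fit_gaussian_animal_model(dat, pedigree, "residual_mass",
                                          seed = seed, n_iter = n_iter,
                                          burn = burn, thin = thin,
                                          n_chains = n_chains)
        out$h2_mass <- .post_sum(mass$draws[, "h2"])
        out$rg_score_mass <- list(mean = rg$mean, lwr = rg$ci[1],
                                  upr = rg$ci[2], n_excluded = rg$n_excluded)
        out$diagnostics_bivariate <- mcmc_diagnostics(biv)
      }
      bad <- out$diagnostics$rhat[out$diagnostics$parameter ==
                                    "h2_latent"] > rhat_gate
      out$converged <- !any(bad, na.rm = TRUE)
      out
    })
    if (isFALSE(report$animal_model$converged))
      failures$convergence <- "animal-model R-hat above gate"
  }
  report$failures <- failures
  class(report) <- "fhd_report"
  report
}

.post_sum <- function(d) list(mean = mean(d),
                              lwr = stats::quantile(d, 0.025, names = FALSE),
                              upr = stats::quantile(d, 0.975, names = FALSE))

#' @export
print.fhd_report <- function(x, ...) {
  cat("Analysis report (seed ", x$provenance$seed, ", ",
      x$provenance$n_records, " records)\n", sep = "")
  if (!is.null(x$demography))
    cat(sprintf("  prevalence: %.1f%% (unilateral %.1f%% of affected)\n",
                x$demography$prevalence_pct,
                100 * x$demography$laterality$unilateral_frac))
  if (!is.null(x$glm))
    cat(sprintf("  score reduction g1 -> g8: %.1f%%\n",
                x$glm$reduction_g1_to_g8_pct$reduction_pct))
  if (!is.null(x$animal_model)) {
    am <- x$animal_model
    cat(sprintf("  h2 latent %.2f (%.2f-%.2f), data scale %.2f (%.2f-%.2f)\n",
                am$h2_latent$mean, am$h2_latent$lwr, am$h2_latent$upr,
                am$h2_observed$mean, am$h2_observed$lwr, am$h2_observed$upr))
    if (!is.null(am$rg_score_mass))
      cat(sprintf("  r_G (score, mass): %.3f (%.3f-%.3f)\n",
                  am$rg_score_mass$mean, am$rg_score_mass$lwr,
                  am$rg_score_mass$upr))
  }
  if (length(x$failures))
    cat("  FAILED stages:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Write a report to JSON (+ CSV tables)
#'
#' @param report an [run_analysis()] report.
#' @param out_dir output directory; writes \code{report.json} and, when
#'   present, \code{tables/score_counts_<sex>.csv} and
#'   \code{tables/score_curve.csv}.
#' @return Invisibly, the path of \code{report.json}.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "fhd_report"))
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE,
             recursive = TRUE)
  r <- report
  if (!is.null(r$demography$score_table)) {
    for (sx in names(r$demography$score_table$counts))
      utils::write.csv(r$demography$score_table$counts[[sx]],
                       file.path(out_dir, "tables",
                                 paste0("score_counts_", sx, ".csv")))
    r$demography$score_table <- lapply(r$demography$score_table$counts,
                                       function(m) as.data.frame(m))
  }
  if (!is.null(r$growth$model)) {
    r$growth$model <- lapply(r$growth$model$fits, function(f)
      list(type = f$type, pars = as.list(f$pars), sigma = f$sigma))
  }
  if (!is.null(r$glm$score_curve))
    utils::write.csv(r$glm$score_curve,
                     file.path(out_dir, "tables", "score_curve.csv"),
                     row.names = FALSE)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(.strip_classes(r), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, na = "null")
  invisible(path)
}

.strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .strip_classes)
    attributes(x) <- list(names = names(x))
    x
  } else if (is.matrix(x)) as.data.frame(x) else unclass(x)
}
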