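#' Load hip-score phenotype records
#'
#' Reads a CSV with header \code{id,sex,age_days,year,left,right[,mass_kg]}
#' (case-insensitive; \code{mass_kg} optional). The per-cat maximum hip score
#' is always recomputed as \code{max(left, right)}, never read from file.
#'
#' @param path CSV file path.
#' @return A validated data frame of class \code{hip_records} with columns
#'   \code{id}, \code{sex}, \code{age_days}, \code{year}, \code{left},
#'   \code{right}, \code{max_score}, \code{mass_kg}.
#' @export
load_records <- function(path) {
  df <- utils::read.csv(path, strip.white = TRUE)
  as_hip_records(df)
}

#' Validate a data frame of hip-score records
#'
#' @param df data frame with columns \code{id}, \code{sex}, \code{age_days},
#'   \code{year}, \code{left}, \code{right} and optionally \code{mass_kg}.
#' @return The validated \code{hip_records} data frame (see [load_records()]).
#' @export
as_hip_records <- function(df) {
  names(df) <- tolower(names(df))
  need <- c("id", "sex", "age_days", "year", "left", "right")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (side in c("left", "right")) {
    sc <- df[[side]]
    bad <- which(is.na(sc) | sc != round(sc) | sc < 0 | sc > 3)
    if (length(bad)) stop(side, " hip score outside 0-3 at row ", bad[1])
  }
  bad <- which(is.na(df$age_days) | df$age_days <= 0)
  if (length(bad)) stop("non-positive assessment age at row ", bad[1])
  sex <- .norm_sex(df$sex)
  if (any(sex == "unknown"))
    stop("sex must be female or male at row ", which(sex == "unknown")[1])
  out <- data.frame(id = as.character(df$id), sex = sex,
                    age_days = as.numeric(df$age_days),
                    year = as.numeric(df$year),
                    left = as.integer(df$left), right = as.integer(df$right),
                    max_score = pmax(as.integer(df$left), as.integer(df$right)),
                    mass_kg = if ("mass_kg" %in% names(df))
                      as.numeric(df$mass_kg) else NA_real_,
                    stringsAsFactors = FALSE)
  if (any(!is.na(out$mass_kg) & out$mass_kg <= 0))
    stop("non-positive body mass at row ",
         which(!is.na(out$mass_kg) & out$mass_kg <= 0)[1])
  class(out) <- c("hip_records", "data.frame")
  out
}

#' Score-distribution summary and prevalence
#'
#' Per-sex counts and proportions of left, right and maximum hip scores,
#' and the prevalence of radiographic signs (maximum score >= 1).
#'
#' @param records a \code{hip_records} data frame ([load_records()]).
#' @return Object of class \code{score_table}: list with \code{counts}
#'   (per-sex 4 x 3 count matrices over score 0-3 and side
#'   left/right/maximum), \code{proportions}, per-sex totals \code{n},
#'   \code{prevalence_pct} (pooled, percent) and \code{prevalence_by_sex_pct}.
#' @export
summarize_scores <- function(records) {
  stopifnot(inherits(records, "hip_records"))
  if (nrow(records) == 0) stop("no records to summarize")
  sexes <- c("female", "male")
  counts <- lapply(sexes, function(s) {
    r <- records[records$sex == s, ]
    m <- sapply(c("left", "right", "max_score"), function(col)
      tabulate(r[[col]] + 1L, nbins = 4L))
    dimnames(m) <- list(score = 0:3, side = c("left", "right", "maximum"))
    m
  })
  names(counts) <- sexes
  n <- vapply(counts, function(m) sum(m[, "maximum"]), 0)
  props <- lapply(counts, function(m) sweep(m, 2, colSums(m), "/"))
  affected <- sum(records$max_score >= 1)
  by_sex <- vapply(sexes, function(s)
    100 * sum(counts[[s]][2:4, "maximum"]) / max(n[[s]], 1), 0)
  out <- list(counts = counts, proportions = props, n = n,
              prevalence_pct = 100 * affected / nrow(records),
              prevalence_by_sex_pct = by_sex)
  class(out) <- "score_table"
  out
}

#' Assemble a score table directly from per-sex marginal counts
#'
#' For replaying published count tables when individual records are not
#' available. Each sex needs a 4 x 3 matrix of counts of scores 0-3 (rows)
#' for the left, right and maximum-score columns.
#'
#' @param female,male 4 x 3 count matrices (rows = scores 0:3, columns =
#'   left, right, maximum).
#' @return A \code{score_table}, as from [summarize_scores()].
#' @export
score_table_from_counts <- function(female, male) {
  counts <- list(female = female, male = male)
  counts <- lapply(counts, function(m) {
    m <- as.matrix(m)
    stopifnot(nrow(m) == 4, ncol(m) == 3, all(m >= 0))
    dimnames(m) <- list(score = 0:3, side = c("left", "right", "maximum"))
    if (length(unique(colSums(m))) != 1)
      stop("left, right and maximum columns must have equal totals")
    m
  })
  n <- vapply(counts, function(m) sum(m[, "maximum"]), 0)
  props <- lapply(counts, function(m) sweep(m, 2, colSums(m), "/"))
  affected <- sum(vapply(counts, function(m) sum(m[2:4, "maximum"]), 0))
  by_sex <- vapply(counts, function(m)
    100 * sum(m[2:4, "maximum"]) / sum(m[, "maximum"]), 0)
  out <- list(counts = counts, proportions = props, n = n,
              prevalence_pct = 100 * affected / sum(n),
              prevalence_by_sex_pct = by_sex)
  class(out) <- "score_table"
  out
}

#' @export
print.score_table <- function(x, digits = 3, ...) {
  cat(sprintf("Hip-score summary: %d cats (female %d, male %d)\n",
              sum(x$n), x$n[["female"]], x$n[["male"]]))
  cat(sprintf("Prevalence (max score >= 1): %.1f%%\n", x$prevalence_pct))
  for (s in names(x$counts)) {
    cat("\n", s, ":\n", sep = "")
    m <- x$counts[[s]]
    p <- x$proportions[[s]][, "maximum"]
    tab <- cbind(m, `prop(max)` = round(p, digits))
    print(tab)
  }
  invisible(x)
}

#' Laterality of lesions among affected cats, from individual records
#'
#' Over cats with a maximum score >= 1, the fraction with exactly one
#' affected hip (unilateral) versus both (bilateral), plus a severity
#' cross-tabulation (maximum score by laterality).
#'
#' @param records a \code{hip_records} data frame.
#' @return List with \code{unilateral_frac}, \code{bilateral_frac},
#'   \code{n_affected} and \code{severity_by_laterality} (counts).
#' @export
laterality_from_records <- function(records) {
  stopifnot(inherits(records, "hip_records"))
  aff <- records[records$max_score >= 1, ]
  if (nrow(aff) == 0) stop("no affected cats (max score >= 1)")
  uni <- (aff$left > 0) != (aff$right > 0)
  tab <- table(laterality = ifelse(uni, "unilateral", "bilateral"),
               max_score = factor(aff$max_score, levels = 1:3))
  list(unilateral_frac = mean(uni), bilateral_frac = mean(!uni),
       n_affected = nrow(aff), severity_by_laterality = tab)
}

#' Laterality from marginal counts by inclusion-exclusion
#'
#' The number of bilateral cases is recovered from the marginals as
#' |left affected| + |right affected| - |maximum affected|, per sex, then
#' pooled. Works directly on published count tables.
#'
#' @param table a \code{score_table} (from [summarize_scores()] or
#'   [score_table_from_counts()]).
#' @return List with pooled \code{unilateral_frac}, \code{bilateral_frac},
#'   \code{n_affected} and the per-sex breakdown \code{by_sex}.
#' @export
laterality_from_marginals <- function(table) {
  stopifnot(inherits(table, "score_table"))
  per_sex <- lapply(table$counts, function(m) {
    aL <- sum(m[2:4, "left"]); aR <- sum(m[2:4, "right"])
    aM <- sum(m[2:4, "maximum"])
    bil <- aL + aR - aM
    if (bil < 0 || bil > aM)
      stop("inconsistent marginal counts (implied bilateral count ", bil, ")")
    c(affected = aM, bilateral = bil, unilateral = aM - bil)
  })
  tot <- Reduce(`+`, per_sex)
  list(unilateral_frac = tot[["unilateral"]] / tot[["affected"]],
       bilateral_frac = tot[["bilateral"]] / tot[["affected"]],
       n_affected = tot[["affected"]],
       by_sex = lapply(per_sex, function(v)
         c(v, unilateral_frac = v[["unilateral"]] / v[["affected"]])))
}

#' Multinomial year-trend model for score-category proportions
#'
#' Cross-sectional multinomial logistic regression of the maximum hip-score
#' category (reference category 0) on assessment year (continuous, as years
#' since \code{year0}) and sex. Used because the proportional-odds
#' assumption of a cumulative-logit model does not generally hold for these
#' data; [proportional_odds_check()] quantifies that.
#'
#' @param records a \code{hip_records} data frame.
#' @param formula right-hand side for the category log-odds; terms may use
#'   \code{years} (years since \code{year0}) and \code{sex}.
#' @param year0 origin for the year covariate (default 2000).
#' @return Object of class \code{fhd_multinom} wrapping the fit, with
#'   \code{coef}, \code{predict} (per-category probabilities) and
#'   \code{summary} methods.
#' @export
fit_multinomial_trend <- function(records, formula = ~ years + sex,
                                  year0 = 2000) {
  stopifnot(inherits(records, "hip_records"))
  dat <- data.frame(score = factor(records$max_score, levels = 0:3),
                    years = records$year - year0, sex = factor(records$sex))
  dat$score <- droplevels(dat$score)
  if (nlevels(dat$score) < 2) stop("need at least 2 observed score categories")
  full <- stats::update(formula, score ~ .)
  fit <- nnet::multinom(full, data = dat, trace = FALSE, maxit = 1000,
                        reltol = 1e-14, abstol = 1e-12)
  if (max(abs(stats::coef(fit))) > 15) {
    warning("apparent separation; refitting with a small ridge penalty")
    fit <- nnet::multinom(full, data = dat, trace = FALSE, maxit = 1000,
                          reltol = 1e-14, abstol = 1e-12, decay = 1e-6)
  }
  out <- list(fit = fit, formula = full, year0 = year0, data = dat,
              levels = levels(dat$score))
  class(out) <- "fhd_multinom"
  out
}

#' @export
coef.fhd_multinom <- function(object, ...) stats::coef(object$fit)

#' @export
logLik.fhd_multinom <- function(object, ...) stats::logLik(object$fit)

#' Predicted score-category proportions on a covariate grid
#'
#' @param object an \code{fhd_multinom} fit.
#' @param newdata data frame with the model covariates (\code{years},
#'   \code{sex}); defaults to a year grid for each sex.
#' @param ... unused.
#' @return Data frame of covariates plus one predicted-probability column
#'   per score category (rows sum to 1).
#' @export
predict.fhd_multinom <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    yrs <- seq(min(object$data$years), max(object$data$years), length.out = 25)
    newdata <- expand.grid(years = yrs, sex = levels(object$data$sex))
  }
  p <- stats::predict(object$fit, newdata = newdata, type = "probs")
  if (is.null(dim(p))) {
    # nnet returns a vector for 2-category fits (P of the second class)
    # and for single-row newdata (one probability per class)
    p <- if (length(object$levels) == 2) cbind(1 - p, p)
         else matrix(p, nrow = nrow(newdata), byrow = TRUE)
  }
  colnames(p) <- paste0("p", object$levels)
  cbind(newdata, as.data.frame(p))
}

#' @export
print.fhd_multinom <- function(x, ...) {
  cat("Multinomial score-trend model (reference category 0)\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' Likelihood-ratio check of the proportional-odds assumption
#'
#' Compares a cumulative-logit (proportional-odds) fit against the more
#' general multinomial fit of the same linear predictor. A small p-value
#' indicates the proportional-odds assumption is untenable and the
#' multinomial model should be preferred.
#'
#' @inheritParams fit_multinomial_trend
#' @return List with \code{statistic} (2 * log-likelihood difference),
#'   \code{df} and \code{p_value}.
#' @export
proportional_odds_check <- function(records, formula = ~ years + sex,
                                    year0 = 2000) {
  mn <- fit_multinomial_trend(records, formula, year0)
  po <- MASS::polr(stats::update(formula, score ~ .), data = mn$data,
                   method = "logistic", Hess = FALSE)
  stat <- as.numeric(2 * (stats::logLik(mn$fit) - stats::logLik(po)))
  df <- attr(stats::logLik(mn$fit), "df") - attr(stats::logLik(po), "df")
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
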