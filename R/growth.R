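#' Fit sex-specific growth curves of body mass on age
#'
#' Fits, separately per sex, the Gompertz curve
#' \deqn{m(a) = A \exp(-b e^{-c a})}
#' to body mass (kg) against assessment age (days) by nonlinear least
#' squares. \code{A} is the asymptotic adult mass (kg), \code{b} the
#' dimensionless displacement and \code{c} the rate (1/day); the curve is
#' strictly increasing in age. If the nonlinear fit fails to converge for a
#' sex, a quadratic polynomial in log age is used instead and flagged in
#' the returned object.
#'
#' @param records a \code{hip_records} data frame; rows without
#'   \code{mass_kg} are ignored.
#' @param min_per_sex minimum number of massed records required per sex.
#' @return Object of class \code{growth_model}: per-sex parameter list,
#'   fit type (\code{"gompertz"} or \code{"log_poly"}), residual SD.
#' @export
fit_growth_curve <- function(records, min_per_sex = 10) {
  stopifnot(inherits(records, "hip_records"))
  dat <- records[!is.na(records$mass_kg), c("sex", "age_days", "mass_kg")]
  fits <- lapply(c("female", "male"), function(sx) {
    d <- dat[dat$sex == sx, ]
    if (nrow(d) < min_per_sex)
      stop("need >= ", min_per_sex, " massed records for sex ", sx)
    if (max(d$age_days) / min(d$age_days) < 2)
      stop("massed ages for sex ", sx, " span less than a 2-fold range")
    .fit_gompertz_one(d)
  })
  names(fits) <- c("female", "male")
  out <- list(fits = fits, n = table(dat$sex))
  class(out) <- "growth_model"
  out
}

.fit_gompertz_one <- function(d) {
  A0 <- max(d$mass_kg) * 1.05
  c0 <- 2 / stats::median(d$age_days)
  b0 <- max(log(A0 / max(min(d$mass_kg), 0.05)), 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(mass_kg ~ A * exp(-b * exp(-cc * age_days)),
                      data = d, start = list(A = A0, b = b0, cc = c0),
                      lower = c(1e-3, 1e-3, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit) && all(stats::coef(fit) > 0)) {
    cf <- stats::coef(fit)
    return(list(type = "gompertz",
                pars = c(A = unname(cf["A"]), b = unname(cf["b"]),
                         c = unname(cf["cc"])),
                sigma = stats::sigma(fit),
                age_range = range(d$age_days)))
  }
  warning("Gompertz fit did not converge; using log-age quadratic fallback")
  pf <- stats::lm(mass_kg ~ stats::poly(log(age_days), 2, raw = TRUE), data = d)
  list(type = "log_poly", pars = stats::coef(pf), sigma = stats::sigma(pf),
       age_range = range(d$age_days))
}

#' Predicted body mass at a given age
#'
#' @param model a [fit_growth_curve()] model.
#' @param sex \code{"female"} or \code{"male"} (vectorised).
#' @param age_days assessment age in days (vectorised); ages outside the
#'   fitted range are extrapolated with a warning. The default, 520 days,
#'   is the programme's mean assessment age.
#' @return Predicted mass in kg.
#' @export
predict_mass <- function(model, sex, age_days = 520) {
  stopifnot(inherits(model, "growth_model"))
  n <- max(length(sex), length(age_days))
  sex <- rep_len(.norm_sex(sex), n); age_days <- rep_len(age_days, n)
  out <- numeric(n)
  for (sx in unique(sex)) {
    f <- model$fits[[sx]]
    if (is.null(f)) stop("no fitted curve for sex ", sx)
    sel <- sex == sx
    a <- age_days[sel]
    if (any(a < f$age_range[1] | a > f$age_range[2]))
      warning("extrapolating the ", sx, " growth curve outside [",
              f$age_range[1], ", ", f$age_range[2], "] days")
    out[sel] <- if (f$type == "gompertz")
      f$pars[["A"]] * exp(-f$pars[["b"]] * exp(-f$pars[["c"]] * a))
    else
      cbind(1, log(a), log(a)^2) %*% f$pars
  }
  out
}

#' @export
predict.growth_model <- function(object, newdata, ...) {
  predict_mass(object, newdata$sex, newdata$age_days)
}

#' Sex- and age-adjusted residual body mass
#'
#' Observed minus predicted mass in kg: negative residuals are cats
#' smaller (lighter) than expected for their sex and age. Records without a
#' mass yield \code{NA}, not an error.
#'
#' @param model a [fit_growth_curve()] model.
#' @param records a \code{hip_records} data frame.
#' @return Numeric vector of residual mass (kg), one per record.
#' @export
residual_mass <- function(model, records) {
  stopifnot(inherits(records, "hip_records"))
  out <- rep(NA_real_, nrow(records))
  has <- !is.na(records$mass_kg)
  out[has] <- records$mass_kg[has] -
    predict_mass(model, records$sex[has], records$age_days[has])
  out
}

#' @export
print.growth_model <- function(x, ...) {
  cat("Sex-specific growth curves (mass ~ age):\n")
  for (sx in names(x$fits)) {
    f <- x$fits[[sx]]
    if (f$type == "gompertz")
      cat(sprintf("  %s: Gompertz A = %.2f kg, b = %.2f, c = %.5f /day (sigma %.3f)\n",
                  sx, f$pars[["A"]], f$pars[["b"]], f$pars[["c"]], f$sigma))
    else
      cat(sprintf("  %s: log-age quadratic fallback (sigma %.3f)\n", sx, f$sigma))
  }
  invisible(x)
}

#' Serialize growth-curve parameters to JSON
#'
#' @param model a [fit_growth_curve()] model.
#' @param path output file.
#' @export
write_growth_model <- function(model, path) {
  jsonlite::write_json(lapply(model$fits, function(f)
    list(type = f$type, pars = as.list(f$pars), sigma = f$sigma,
         age_range = f$age_range)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
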