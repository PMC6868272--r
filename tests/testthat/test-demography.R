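test_that("records load with recomputed maximum scores and validation", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sex,age_days,year,left,right,mass_kg",
               "a,f,400,2005,1,2,4.5",
               "b,m,600,2010,0,0,",
               "c,f,520,2015,3,1,6.0"), f)
  rec <- load_records(f)
  expect_equal(rec$max_score, c(2, 0, 3))
  expect_true(is.na(rec$mass_kg[2]))

  bad <- data.frame(id = "x", sex = "f", age_days = 500, year = 2001,
                    left = 4, right = 0)
  expect_error(as_hip_records(bad), "outside 0-3.*row 1")
  bad$left <- 1; bad$age_days <- 0
  expect_error(as_hip_records(bad), "age at row 1")
})

test_that("score summaries equal a direct tally", {
  set.seed(42)
  n <- 400
  rec <- as_hip_records(data.frame(
    id = paste0("r", 1:n), sex = sample(c("female", "male"), n, TRUE),
    age_days = sample(300:900, n, TRUE), year = sample(2000:2019, n, TRUE),
    left = sample(0:3, n, TRUE, prob = c(.6, .2, .13, .07)),
    right = sample(0:3, n, TRUE, prob = c(.6, .2, .13, .07))))
  tab <- summarize_scores(rec)
  mx <- pmax(rec$left, rec$right)
  expect_equal(tab$prevalence_pct, 100 * mean(mx >= 1))
  for (sx in c("female", "male")) {
    sel <- rec$sex == sx
    expect_equal(unname(tab$counts[[sx]][, "maximum"]),
                 unname(table(factor(mx[sel], levels = 0:3))),
                 ignore_attr = TRUE)
    expect_equal(unname(colSums(tab$counts[[sx]])), rep(sum(sel), 3))
    expect_equal(colSums(tab$proportions[[sx]]), rep(1, 3),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }

  zero <- rec; zero$left <- 0L; zero$right <- 0L; zero$max_score <- 0L
  expect_equal(summarize_scores(zero)$prevalence_pct, 0)
  expect_error(summarize_scores(rec[0, ]), "no records")
})

test_that("laterality from records and from marginals agree", {
  two <- as_hip_records(data.frame(
    id = c("a", "b"), sex = "female", age_days = 500, year = 2005,
    left = c(1, 2), right = c(0, 2)))
  expect_equal(laterality_from_records(two)$unilateral_frac, 0.5)

  bil <- as_hip_records(data.frame(
    id = c("a", "b"), sex = "female", age_days = 500, year = 2005,
    left = c(1, 2), right = c(3, 2)))
  expect_equal(laterality_from_records(bil)$unilateral_frac, 0)

  none <- as_hip_records(data.frame(id = "a", sex = "m", age_days = 500,
                                    year = 2005, left = 0, right = 0))
  expect_error(laterality_from_records(none), "no affected")

  # right column all zero -> all affected cats are unilateral
  uni <- as_hip_records(data.frame(
    id = letters[1:4], sex = "female", age_days = 500, year = 2005,
    left = c(1, 2, 3, 0), right = 0))
  expect_equal(laterality_from_marginals(summarize_scores(uni))$unilateral_frac,
               1)

  # inclusion-exclusion equals the direct count on simulated data
  for (s in 1:3) {
    set.seed(s)
    n <- 300
    rec <- as_hip_records(data.frame(
      id = paste0("r", 1:n), sex = sample(c("female", "male"), n, TRUE),
      age_days = 520, year = 2010,
      left = sample(0:3, n, TRUE, prob = c(.55, .25, .13, .07)),
      right = sample(0:3, n, TRUE, prob = c(.55, .25, .13, .07))))
    expect_equal(laterality_from_marginals(summarize_scores(rec))$unilateral_frac,
                 laterality_from_records(rec)$unilateral_frac,
                 tolerance = 1e-12)
  }

  # inconsistent marginals are refused
  bad <- summarize_scores(two)
  bad$counts$female[1, "maximum"] <- bad$counts$female[1, "maximum"] + 2
  bad$counts$female[2, "maximum"] <- bad$counts$female[2, "maximum"] - 2
  expect_error(laterality_from_marginals(bad), "inconsistent")
})

test_that("published marginal counts replay into consistent records", {
  tab <- pawpeds_counts()
  rec <- records_from_marginals(tab)
  expect_equal(nrow(rec), 5038)
  back <- summarize_scores(rec)
  for (sx in c("female", "male"))
    expect_equal(back$counts[[sx]], tab$counts[[sx]])
  expect_equal(laterality_from_records(rec)$unilateral_frac,
               laterality_from_marginals(tab)$unilateral_frac,
               tolerance = 1e-12)
})

test_that("multinomial trend model matches closed-form and logistic oracles", {
  set.seed(7)
  n <- 600
  rec <- as_hip_records(data.frame(
    id = paste0("r", 1:n), sex = sample(c("female", "male"), n, TRUE),
    age_days = 520, year = sample(2000:2019, n, TRUE),
    left = sample(0:3, n, TRUE, prob = c(.5, .25, .15, .1)), right = 0))
  fit <- fit_multinomial_trend(rec)
  pr <- predict(fit)
  expect_equal(rowSums(pr[, paste0("p", 0:3)]), rep(1, nrow(pr)),
               tolerance = 1e-10, ignore_attr = TRUE)

  # intercept-only fit reproduces observed category frequencies
  fit0 <- fit_multinomial_trend(rec, ~ 1)
  p0 <- predict(fit0, data.frame(years = 0, sex = "female"))
  expect_equal(unname(unlist(p0[paste0("p", 0:3)])),
               unname(prop.table(table(factor(rec$max_score, 0:3)))),
               tolerance = 1e-6, ignore_attr = TRUE)

  # two observed categories: equals a plain logistic regression
  rec2 <- rec
  rec2$left <- as.integer(rec2$max_score >= 2)
  rec2$right <- 0L
  rec2$max_score <- rec2$left
  fit2 <- fit_multinomial_trend(rec2, ~ years)
  glmfit <- stats::glm(max_score ~ I(year - 2000), binomial(), rec2)
  expect_equal(unname(coef(fit2)), unname(stats::coef(glmfit)),
               tolerance = 1e-5)

  pchk <- proportional_odds_check(rec)
  expect_gte(pchk$p_value, 0)
  expect_lte(pchk$p_value, 1)
  expect_gt(pchk$df, 0)
})
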