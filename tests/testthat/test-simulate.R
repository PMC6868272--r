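small_cfg <- function(...) {
  args <- list(n_founders = 40, n_generations = 3, n_per_gen = 80,
               male_submission = 1)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("the generator is deterministic given its seed", {
  s1 <- simulate_programme(small_cfg(), seed = 4)
  s2 <- simulate_programme(small_cfg(), seed = 4)
  expect_identical(as.data.frame(s1$pedigree), as.data.frame(s2$pedigree))
  expect_identical(as.data.frame(s1$records), as.data.frame(s2$records))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_programme(small_cfg(), seed = 5)
  expect_false(identical(s1$truth, s3$truth))
})

test_that("one generation without selection descends only from founders", {
  sim <- simulate_programme(sim_config(n_founders = 30, n_generations = 1,
                                       n_per_gen = 50,
                                       selection_threshold = 99), seed = 2)
  gen <- attr(sim$pedigree, "generation")
  kids <- sim$pedigree[gen == 1, ]
  founders <- sim$pedigree$id[gen == 0]
  expect_true(all(kids$sire %in% founders))
  expect_true(all(kids$dam %in% founders))
})

test_that("selection lowers offspring liability; no selection leaves it flat", {
  cfg <- sim_config(n_founders = 120, n_generations = 1, n_per_gen = 400,
                    selection_threshold = 1)   # only score-0 parents
  sim <- simulate_programme(cfg, seed = 8)
  g <- sim$truth$generation
  expect_lt(mean(sim$truth$liability[g == 1]),
            mean(sim$truth$liability[g == 0]))

  # with selection off, per-generation mean liability shows no systematic
  # trend beyond genetic drift (bounded well below any selection response),
  # while selection produces a strong decline on the same scale
  cfg0 <- sim_config(n_founders = 300, n_generations = 5, n_per_gen = 300,
                     selection_threshold = 99)
  sim0 <- simulate_programme(cfg0, seed = 9)
  sl0 <- stats::coef(stats::lm(liability ~ generation, sim0$truth))[2]
  expect_lt(abs(sl0), 0.1)
  cfg1 <- sim_config(n_founders = 300, n_generations = 5, n_per_gen = 300)
  sim1 <- simulate_programme(cfg1, seed = 9)
  sl1 <- stats::coef(stats::lm(liability ~ generation, sim1$truth))[2]
  expect_lt(sl1, sl0 - 0.1)

  # an impossible rule errors informatively
  expect_error(simulate_programme(sim_config(n_founders = 20,
                                             n_per_gen = 50,
                                             cutpoints = c(-9, -8.5, -8)),
                                  seed = 1),
               "relax selection_threshold")
})

test_that("breeding values have the configured moments", {
  ped <- as_pedigree(data.frame(id = sprintf("f%05d", 1:8000),
                                sire = NA, dam = NA))
  G <- matrix(c(1.3, 0.145, 0.145, 0.2), 2)
  bv <- simulate_breeding_values(ped, G, seed = 3)
  expect_lt(max(abs(stats::cov(bv) - G) / max(G)), 0.05)

  # parent-offspring covariance is half the additive variance
  n <- 3000
  trio <- as_pedigree(data.frame(
    id = c(sprintf("s%d", 1:n), sprintf("d%d", 1:n), sprintf("o%d", 1:n)),
    sire = c(rep(NA, 2 * n), sprintf("s%d", 1:n)),
    dam = c(rep(NA, 2 * n), sprintf("d%d", 1:n)),
    sex = c(rep("m", n), rep("f", n), rep("f", n))))
  bv1 <- simulate_breeding_values(trio, matrix(1.3), seed = 6)
  sires <- bv1[seq_len(n), 1]; off <- bv1[2 * n + seq_len(n), 1]
  expect_equal(stats::cov(sires, off), 1.3 / 2, tolerance = 0.08)

  expect_equal(unname(simulate_breeding_values(ped, matrix(0, 2, 2),
                                               seed = 1)),
               matrix(0, 8000, 2), ignore_attr = TRUE)
})

test_that("phenotype generation follows the liability-threshold model", {
  ped <- as_pedigree(data.frame(id = sprintf("f%04d", 1:2000),
                                sire = NA, dam = NA,
                                sex = rep(c("m", "f"), 1000)))
  cfg <- small_cfg()
  bv <- simulate_breeding_values(ped, cfg$G, seed = 2)

  # cutpoints pushed to infinity give all-zero scores
  hi <- small_cfg(cutpoints = c(40, 41, 42))
  rec <- simulate_phenotypes(ped, bv, hi, seed = 3)
  expect_true(all(rec$max_score == 0))

  # more shared (genetic) variance makes affected cats more bilateral
  bilat <- sapply(c(0.3, 1.3, 3.5), function(va) {
    cfgv <- sim_config(n_founders = 40, n_generations = 3, n_per_gen = 80,
                       v_a = va, cov_a = 0)
    bvv <- simulate_breeding_values(ped, cfgv$G, seed = 4)
    r <- simulate_phenotypes(ped, bvv, cfgv, seed = 5)
    aff <- r[r$max_score >= 1, ]
    mean(aff$left > 0 & aff$right > 0)
  })
  expect_true(all(diff(bilat) > 0))
})

test_that("datasets round-trip through the text formats", {
  sim <- simulate_programme(small_cfg(frac_massed = 0.6,
                                      male_submission = 0.6), seed = 12)
  out <- withr::local_tempdir()
  paths <- write_dataset(sim, out)
  ped2 <- read_pedigree(file.path(out, "pedigree.csv"))
  rec2 <- load_records(file.path(out, "phenotypes.csv"))
  expect_equal(as.data.frame(ped2)[c("id", "sire", "dam", "sex")],
               as.data.frame(sim$pedigree)[c("id", "sire", "dam", "sex")])
  expect_equal(rec2$max_score, sim$records$max_score)
  expect_equal(rec2$mass_kg, sim$records$mass_kg)
  truth <- utils::read.csv(file.path(out, "truth.csv"))
  expect_equal(nrow(truth), nrow(sim$pedigree))
  # same seed, same files
  sim_b <- simulate_programme(small_cfg(frac_massed = 0.6,
                                        male_submission = 0.6), seed = 12)
  out_b <- withr::local_tempdir()
  write_dataset(sim_b, out_b)
  for (fl in c("pedigree.csv", "phenotypes.csv", "truth.csv"))
    expect_identical(readLines(file.path(out, fl)),
                     readLines(file.path(out_b, fl)))
})
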