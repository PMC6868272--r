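test_that("pedigrees are read, validated and topologically sorted", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,sex", "C,A,B,f", "A,,,m", "B,0,0,f"), f)
  ped <- read_pedigree(f)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  expect_lt(match("A", ped$id), match("C", ped$id))
  expect_lt(match("B", ped$id), match("C", ped$id))

  # whitespace-delimited variant
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("id sire dam sex", "A 0 0 m", "B 0 0 f", "C A B f"), f2)
  expect_equal(read_pedigree(f2)$id, ped$id)

  # self-parenting, duplicates, unresolved parents, cycles
  expect_error(as_pedigree(data.frame(id = "C", sire = "A", dam = "C")),
               "own parent")
  expect_error(as_pedigree(data.frame(id = c("A", "A"), sire = NA, dam = NA)),
               "duplicate")
  expect_error(as_pedigree(data.frame(id = "K", sire = "Q", dam = NA)),
               "not in pedigree")
  perm <- as_pedigree(data.frame(id = "K", sire = "Q", dam = NA),
                      permissive = TRUE)
  expect_setequal(perm$id, c("K", "Q"))
  expect_error(as_pedigree(data.frame(id = c("A", "B", "D"),
                                      sire = c("B", "A", "A"),
                                      dam = c(NA, NA, NA))),
               "cycle")
})

test_that("inbreeding matches the recursive coancestry oracle", {
  # all founders
  ped0 <- as_pedigree(data.frame(id = letters[1:5], sire = NA, dam = NA))
  expect_equal(unname(inbreeding(ped0)), rep(0, 5))

  # offspring of full sibs: F = 0.25
  ped <- as_pedigree(data.frame(
    id = c("A", "B", "C", "D", "E"),
    sire = c(NA, NA, "A", "A", "C"),
    dam = c(NA, NA, "B", "B", "D"),
    sex = c("m", "f", "m", "f", "f")))
  expect_equal(unname(inbreeding(ped)[["E"]]), 0.25)

  # random pedigrees vs brute-force coancestry: F_i = f(sire_i, dam_i)
  for (s in 1:3) {
    rp <- random_pedigree(30, seed = s)
    f <- coancestry_oracle(rp)
    si <- attr(rp, "sire_ix"); di <- attr(rp, "dam_ix")
    Fo <- ifelse(si > 0 & di > 0,
                 f[cbind(pmax(si, 1), pmax(di, 1))], 0)
    expect_equal(unname(inbreeding(rp)), unname(Fo), tolerance = 1e-12)
  }
})

test_that("tabular A equals 2x coancestry and inverts against sparse Ainv", {
  ped <- as_pedigree(data.frame(
    id = c("S", "D", "O", "O2", "H"),
    sire = c(NA, NA, "S", "S", "S"),
    dam = c(NA, NA, "D", "D", NA),
    sex = c("m", "f", "f", "f", "f")))
  A <- relationship_matrix(ped)
  expect_equal(A["S", "O"], 0.5)    # parent-offspring
  expect_equal(A["O", "O2"], 0.5)   # full sibs
  expect_equal(A["O", "H"], 0.25)   # half sibs

  for (s in 1:4) {
    rp <- random_pedigree(sample(20:50, 1), seed = s)
    A <- relationship_matrix(rp)
    expect_equal(unname(A), 2 * coancestry_oracle(rp), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(unname(diag(A)), unname(1 + inbreeding(rp)))
    Ai <- relationship_inverse(rp)
    expect_lt(max(abs(as.matrix(Ai) %*% A - diag(nrow(A)))), 1e-8)
  }

  # founders only: Ainv = I; sparsity confined to parent triples
  ped0 <- as_pedigree(data.frame(id = letters[1:6], sire = NA, dam = NA))
  expect_equal(as.matrix(relationship_inverse(ped0)), diag(6),
               ignore_attr = TRUE)
  rp <- random_pedigree(40, seed = 9)
  tri <- Matrix::mat2triplet(relationship_inverse(rp))
  si <- attr(rp, "sire_ix"); di <- attr(rp, "dam_ix")
  fam <- lapply(seq_len(nrow(rp)), function(i)
    c(i, si[i], di[i])[c(TRUE, si[i] > 0, di[i] > 0)])
  ok <- mapply(function(i, j) any(vapply(fam, function(g)
    i %in% g && j %in% g, TRUE)), tri$i, tri$j)
  expect_true(all(ok))
})

test_that("the sparse inverse round-trips through the triplet export", {
  rp <- random_pedigree(25, seed = 21)
  Ai <- relationship_inverse(rp)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ainv_triplets(Ai, f)
  tri <- utils::read.csv(f)
  back <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$value,
                               dims = dim(Ai), symmetric = TRUE)
  expect_lt(max(abs(back - Ai)), 1e-12)
})

test_that("A is symmetric positive semi-definite on larger pedigrees", {
  rp <- random_pedigree(200, seed = 11)
  A <- relationship_matrix(rp)
  expect_equal(A, t(A))
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("mean ancestor score follows the screening-depth recursion", {
  ped <- as_pedigree(data.frame(
    id = c("GGm1", "GGf1", "GGm2", "GGf2",
           "Gm1", "Gf1", "Gm2", "Gf2", "P_s", "P_d", "X"),
    sire = c(NA, NA, NA, NA, "GGm1", "GGm2", "GGm2", "GGm1", "Gm1", "Gm2",
             "P_s"),
    dam = c(NA, NA, NA, NA, "GGf1", "GGf2", "GGf2", "GGf1", "Gf2", "Gf1",
            "P_d"),
    sex = c("m", "f", "m", "f", "m", "f", "m", "f", "m", "f", "f")))
  all_before <- stats::setNames(rep(1, nrow(ped) - 1),
                                setdiff(ped$id, "X"))

  # both parents unscreened
  r0 <- mean_ancestor_score(ped, c(GGm1 = 1), "X", subject_date = 2)
  expect_equal(r0$mean_score, 0)
  # both parents screened, nothing above them
  r1 <- mean_ancestor_score(ped, c(P_s = 1, P_d = 1), "X", subject_date = 2)
  expect_equal(r1$maternal, 1)
  expect_equal(r1$paternal, 1)
  expect_equal(r1$mean_score, 1)
  # complete screened ancestry to depth 3 on both sides
  r3 <- mean_ancestor_score(ped, all_before, "X", subject_date = 2)
  expect_equal(r3$mean_score, 3)
  # strict variant agrees on complete ancestry
  expect_equal(mean_ancestor_score(ped, all_before, "X", subject_date = 2,
                                   method = "strict")$mean_score, 3)

  # ties (screened at the same date) do not count as previous
  tie <- stats::setNames(c(rep(1, 9), 2), c(setdiff(ped$id, c("X", "P_d")),
                                            "P_d"))
  rt <- mean_ancestor_score(ped, tie, "X", subject_date = 2)
  expect_equal(rt$maternal, 0)   # dam screened at the subject's own date
  expect_equal(rt$paternal, 3)

  expect_error(mean_ancestor_score(ped, all_before, "nope"), "unknown subject")

  # monotone non-decreasing as more ancestors become screened
  partial <- c(P_s = 1, P_d = 1, Gm1 = 1)
  rp <- mean_ancestor_score(ped, partial, "X", subject_date = 2)
  expect_gte(rp$mean_score, r1$mean_score)
  expect_gte(r3$mean_score, rp$mean_score)

  # batch version agrees with the per-subject recursion
  batch <- mean_ancestor_scores(ped, all_before, subjects = c("X", "P_s"))
  expect_equal(batch$mean_ancestor_score[batch$id == "X"], 3)
  one <- mean_ancestor_score(ped, all_before, "P_s")
  expect_equal(batch$mean_ancestor_score[batch$id == "P_s"], one$mean_score)
})
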