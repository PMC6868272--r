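#' Published PawPeds screening counts (2000-2019 Maine Coon programme)
#'
#' Per-sex counts of left, right and maximum hip scores for the 5038 cats
#' (3287 female, 1751 male) evaluated in the PawPeds hip-dysplasia health
#' programme, as printed in the programme's published summary table. These
#' counts are a directly usable input for replaying the demographic
#' summaries without access to the individual-level database.
#'
#' @return A \code{score_table} (see [score_table_from_counts()]).
#' @export
pawpeds_counts <- function() {
  male <- cbind(left = c(1217, 312, 165, 57),
                right = c(1197, 331, 157, 66),
                maximum = c(1085, 372, 217, 77))
  female <- cbind(left = c(2309, 605, 287, 86),
                  right = c(2279, 630, 282, 96),
                  maximum = c(2068, 723, 370, 126))
  score_table_from_counts(female = female, male = male)
}

#' Reconstruct individual records from per-sex marginal score counts
#'
#' Builds a set of individual \code{hip_records} whose left, right and
#' maximum-score marginal distributions all match the given count table
#' exactly. Because only marginals are given, the joint (left, right)
#' allocation is not unique; a deterministic completion is used that, for
#' each maximum-score category, pairs as many cats as possible at equal
#' left/right grades and assigns the unavoidable unilateral remainder a
#' normal (grade 0) other hip. Ages and years are placeholders
#' (\code{age_days}, \code{year}) since the marginal table carries neither.
#'
#' @param table a \code{score_table}, e.g. [pawpeds_counts()].
#' @param age_days,year placeholder covariate values for every record.
#' @return A \code{hip_records} data frame with one row per counted cat.
#' @export
records_from_marginals <- function(table, age_days = 520, year = 2010) {
  stopifnot(inherits(table, "score_table"))
  out <- lapply(names(table$counts), function(sx) {
    m <- table$counts[[sx]]
    J <- .complete_joint(L = m[, "left"], R = m[, "right"],
                         M = m[, "maximum"])
    cells <- which(J > 0, arr.ind = TRUE)
    left <- rep(cells[, 1] - 1L, J[cells])
    right <- rep(cells[, 2] - 1L, J[cells])
    data.frame(id = paste0(substr(sx, 1, 1), seq_along(left)), sex = sx,
               age_days = age_days, year = year,
               left = left, right = right, stringsAsFactors = FALSE)
  })
  as_hip_records(do.call(rbind, out))
}

# Complete a 4x4 joint (left, right) count matrix from its left, right and
# max marginals. Processing max categories from severe to mild, the row-k
# and column-k remainders after the diagonal cell are pushed towards grade-0
# partners (then upwards) which is always feasible for tables whose
# inclusion-exclusion bilateral count is admissible.
.complete_joint <- function(L, R, M) {
  J <- matrix(0, 4, 4)
  usedL <- numeric(4); usedR <- numeric(4)
  for (k in 4:2) {
    availL <- L[k] - usedL[k]
    availR <- R[k] - usedR[k]
    dd <- availL + availR - M[k]
    if (dd < 0 || dd > min(availL, availR))
      stop("inconsistent marginal counts for score ", k - 1)
    J[k, k] <- dd
    a <- availL - dd   # row k, partner hip below k
    b <- availR - dd   # col k, partner hip below k
    for (r in c(1, seq_len(k - 1)[-1])) {   # grade 0 first, then 1, 2, ...
      if (a <= 0) break
      take <- min(a, R[r] - usedR[r])
      J[k, r] <- J[k, r] + take
      usedR[r] <- usedR[r] + take
      a <- a - take
    }
    for (l in c(1, seq_len(k - 1)[-1])) {
      if (b <= 0) break
      take <- min(b, L[l] - usedL[l])
      J[l, k] <- J[l, k] + take
      usedL[l] <- usedL[l] + take
      b <- b - take
    }
    if (a > 0 || b > 0) stop("marginal counts cannot be completed")
    usedL[k] <- L[k]; usedR[k] <- R[k]
  }
  J[1, 1] <- L[1] - usedL[1]
  if (J[1, 1] != M[1] || J[1, 1] != R[1] - usedR[1])
    stop("marginal counts cannot be completed")
  J
}
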