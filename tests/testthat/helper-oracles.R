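# Independent oracles and small random generators used across the suite.

# Brute-force recursive coancestry f(i, j) with memoisation, computed purely
# from the sorted pedigree's parent indices. Independent of the package's
# tabular/Meuwissen-Luo code paths.
coancestry_oracle <- function(ped) {
  si <- attr(ped, "sire_ix"); di <- attr(ped, "dam_ix")
  n <- nrow(ped)
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + f(si[i], di[i]))
    } else {
      # j is later in the pedigree, so its parents precede it
      0.5 * (f(i, si[j]) + f(i, di[j]))
    }
    memo[[key]] <- val
    val
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) out[i, j] <- out[j, i] <- f(i, j)
  out
}

# Random valid pedigree: founders plus descendants whose parents are drawn
# from earlier individuals of the right sex.
random_pedigree <- function(n, n_founders = max(4L, n %/% 4L), seed = 1) {
  set.seed(seed)
  sex <- sample(rep(c("male", "female"), length.out = n))
  sire <- dam <- rep(NA_character_, n)
  id <- sprintf("X%03d", seq_len(n))
  for (i in seq_len(n)) {
    if (i <= n_founders) next
    males <- which(sex[seq_len(i - 1)] == "male")
    fems <- which(sex[seq_len(i - 1)] == "female")
    if (!length(males) || !length(fems)) next
    sire[i] <- id[males[sample.int(length(males), 1)]]
    dam[i] <- id[fems[sample.int(length(fems), 1)]]
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                         stringsAsFactors = FALSE))
}

# Monte-Carlo oracle for the latent -> observed scale transform, fully
# simulation-based: draws liabilities, scores them with a fresh unit
# residual, and uses Stein's identity Cov(l, y)/Var(l) for E[psi'(l)].
h2_obs_mc_oracle <- function(va, vpe, mu, cutpoints, n = 1e6, seed = 1) {
  set.seed(seed)
  l <- rnorm(n, mu, sqrt(va + vpe))
  y <- findInterval(l + rnorm(n), cutpoints)
  slope <- stats::cov(l, y) / stats::var(l)
  (va * slope^2) / stats::var(y)
}

# small deterministic hip-record table
toy_records <- function() {
  as_hip_records(data.frame(
    id = paste0("c", 1:8),
    sex = rep(c("female", "male"), 4),
    age_days = c(400, 500, 600, 700, 450, 550, 650, 750),
    year = c(2001, 2003, 2005, 2007, 2009, 2011, 2013, 2015),
    left = c(0, 1, 2, 3, 0, 0, 1, 2),
    right = c(0, 0, 2, 1, 0, 2, 0, 3)))
}
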