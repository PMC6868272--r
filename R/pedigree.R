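#' Construct a validated, topologically sorted pedigree
#'
#' A pedigree is a data frame with columns \code{id}, \code{sire}, \code{dam}
#' and \code{sex}, ordered so that every parent precedes its offspring.
#' Unknown parents are coded \code{NA}; on input, \code{""} and \code{"0"}
#' are also accepted as unknown. Unknown parents are treated as unrelated,
#' non-inbred founders.
#'
#' @param x data frame with columns \code{id}, \code{sire}, \code{dam} and
#'   optionally \code{sex} (values \code{"female"}, \code{"male"},
#'   \code{"unknown"}; abbreviations \code{"f"}/\code{"m"} accepted).
#'   Column matching is case-insensitive.
#' @param permissive if \code{TRUE}, a parent id that does not occur as an
#'   individual is silently inserted as a founder record; if \code{FALSE}
#'   (default) this is an error.
#' @return An object of class \code{pedigree}: the sorted data frame with
#'   integer parent-position attributes and the original input order stored
#'   as the \code{orig_order} attribute.
#' @examples
#' ped <- as_pedigree(data.frame(id = c("A", "B", "C"),
#'                               sire = c(NA, NA, "A"),
#'                               dam  = c(NA, NA, "B"),
#'                               sex  = c("m", "f", "f")))
#' inbreeding(ped)
#' @export
as_pedigree <- function(x, permissive = FALSE) {
  stopifnot(is.data.frame(x))
  names(x) <- tolower(names(x))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(x)))
    stop("pedigree needs columns id, sire, dam (case-insensitive); missing: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  id   <- trimws(as.character(x$id))
  sire <- .norm_parent(x$sire)
  dam  <- .norm_parent(x$dam)
  sex  <- if ("sex" %in% names(x)) .norm_sex(x$sex) else rep("unknown", length(id))

  if (any(!nzchar(id) | is.na(id))) stop("empty individual id at row ",
                                         which(!nzchar(id) | is.na(id))[1])
  if (anyDuplicated(id)) stop("duplicate individual id: ",
                              id[duplicated(id)][1])
  self <- which(!is.na(sire) & sire == id | !is.na(dam) & dam == id)
  if (length(self)) stop("individual '", id[self[1]],
                         "' is listed as its own parent")

  parents <- setdiff(unique(c(sire, dam)), c(NA, id))
  if (length(parents)) {
    if (!permissive)
      stop("parent id(s) not in pedigree: ",
           paste(utils::head(parents, 5), collapse = ", "),
           " (use permissive = TRUE to add them as founders)")
    id   <- c(parents, id)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam  <- c(rep(NA_character_, length(parents)), dam)
    sex  <- c(rep("unknown", length(parents)), sex)
  }

  # an id may act as sire or as dam, never both
  both <- intersect(stats::na.omit(sire), stats::na.omit(dam))
  if (length(both)) stop("id(s) appear both as sire and as dam: ",
                         paste(utils::head(both, 5), collapse = ", "))
  # sex consistency with parental role
  is_sire <- id %in% sire
  is_dam  <- id %in% dam
  bad <- which((is_sire & sex == "female") | (is_dam & sex == "male"))
  if (length(bad)) stop("sex of '", id[bad[1]], "' contradicts its parental role")
  sex[is_sire & sex == "unknown"] <- "male"
  sex[is_dam & sex == "unknown"] <- "female"

  ord <- .topo_order(id, sire, dam)
  ped <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    sex = sex[ord], stringsAsFactors = FALSE)
  attr(ped, "sire_ix") <- match(ped$sire, ped$id, nomatch = 0L)
  attr(ped, "dam_ix")  <- match(ped$dam,  ped$id, nomatch = 0L)
  attr(ped, "orig_order") <- match(id, ped$id)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

.norm_parent <- function(p) {
  p <- trimws(as.character(p))
  p[!nzchar(p) | p == "0" | is.na(p)] <- NA_character_
  p
}

.norm_sex <- function(s) {
  s <- tolower(trimws(as.character(s)))
  out <- rep("unknown", length(s))
  out[s %in% c("f", "female", "2")] <- "female"
  out[s %in% c("m", "male", "1")] <- "male"
  out
}

# Kahn topological sort over the parent -> offspring DAG; reports a cycle.
.topo_order <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id, nomatch = 0L)
  di <- match(dam, id, nomatch = 0L)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (p > 0L) {
      indeg[i] <- indeg[i] + 1L
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    # stable: keep input order among ready nodes
    queue <- sort(queue)
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    # walk parent links among the leftovers to exhibit one cycle
    cyc <- left[1]; cur <- cyc
    repeat {
      nxt <- if (si[cur] %in% left) si[cur] else di[cur]
      if (nxt %in% cyc) { cyc <- c(cyc[which(cyc == nxt):length(cyc)], nxt); break }
      cyc <- c(cyc, nxt); cur <- nxt
    }
    stop("pedigree contains a cycle: ", paste(id[cyc], collapse = " -> "))
  }
  ord
}

#' Read a pedigree file
#'
#' Accepts a comma-separated file with header columns \code{id}, \code{sire},
#' \code{dam}, \code{sex} (case-insensitive), or the whitespace-delimited
#' 4-column variant. \code{""} and \code{"0"} encode an unknown parent.
#'
#' @param path file path.
#' @param permissive passed to [as_pedigree()]: auto-insert unlisted parents
#'   as founders instead of erroring.
#' @return A [as_pedigree()] object.
#' @export
read_pedigree <- function(path, permissive = FALSE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl(",", header)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          strip.white = TRUE, comment.char = "")
  as_pedigree(df, permissive = permissive)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "individuals (",
      sum(attr(x, "sire_ix") == 0L & attr(x, "dam_ix") == 0L), "founders )\n")
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Inbreeding coefficients
#'
#' Wright's inbreeding coefficient for every individual, computed with the
#' Meuwissen--Luo recursive algorithm. Founders and individuals with a
#' missing parent have F = 0 (unknown parents are unrelated founders).
#'
#' @param ped a [as_pedigree()] object.
#' @return Named numeric vector of F, in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  F <- .ml_inbreeding(attr(ped, "sire_ix"), attr(ped, "dam_ix"))
  names(F) <- ped$id
  F
}

#' Additive relationship matrix
#'
#' Dense numerator relationship matrix A by the tabular method:
#' \eqn{a_{ij} = (a_{i,s_j} + a_{i,d_j})/2} for \eqn{i < j} and
#' \eqn{a_{jj} = 1 + a_{s_j,d_j}/2}, with missing-parent terms contributing 0.
#' The diagonal equals \eqn{1 + F_i}.
#'
#' @param ped a [as_pedigree()] object.
#' @return Symmetric n x n matrix with dimnames the individual ids and the
#'   inbreeding coefficients attached as attribute \code{"F"}.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- attr(ped, "sire_ix"); di <- attr(ped, "dam_ix")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      i <- seq_len(j - 1L)
      v <- 0.5 * ((if (s > 0L) A[i, s] else 0) + (if (d > 0L) A[i, d] else 0))
      A[i, j] <- v
      A[j, i] <- v
    }
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  attr(A, "F") <- diag(A) - 1
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with the inbreeding adjustment: individual i with
#' parents s, d contributes \eqn{1/m_i} to the (i,i) entry, where
#' \eqn{m_i = 0.5 - 0.25 (F_s + F_d)} is the Mendelian-sampling variance
#' (an unknown parent enters with F = -1), plus the usual -1/2 and 1/4
#' parent cross terms. Nonzeros only arise within
#' \{individual, sire, dam\} triples.
#'
#' @param ped a [as_pedigree()] object.
#' @return A sparse symmetric [Matrix::sparseMatrix()] with dimnames.
#' @export
relationship_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- attr(ped, "sire_ix"); di <- attr(ped, "dam_ix")
  F <- .ml_inbreeding(si, di)
  Fs <- ifelse(si > 0L, F[pmax(si, 1L)], -1)
  Fd <- ifelse(di > 0L, F[pmax(di, 1L)], -1)
  m <- 0.5 - 0.25 * (Fs + Fd)
  b <- 1 / m
  ii <- seq_len(n)
  I <- ii; J <- ii; X <- b                       # (i,i)
  hs <- si > 0L
  I <- c(I, ii[hs], si[hs]); J <- c(J, si[hs], ii[hs])
  X <- c(X, -b[hs] / 2, -b[hs] / 2)              # (i,s) both triangles
  hd <- di > 0L
  I <- c(I, ii[hd], di[hd]); J <- c(J, di[hd], ii[hd])
  X <- c(X, -b[hd] / 2, -b[hd] / 2)              # (i,d)
  I <- c(I, si[hs]); J <- c(J, si[hs]); X <- c(X, b[hs] / 4)   # (s,s)
  I <- c(I, di[hd]); J <- c(J, di[hd]); X <- c(X, b[hd] / 4)   # (d,d)
  both <- hs & hd
  I <- c(I, si[both], di[both]); J <- c(J, di[both], si[both])
  X <- c(X, b[both] / 4, b[both] / 4)            # (s,d)
  Ainv <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}

#' Export a sparse relationship-matrix inverse as triplets
#'
#' Writes the lower triangle of \code{Ainv} in coordinate format
#' (columns \code{i}, \code{j}, \code{value}, 1-based pedigree positions).
#'
#' @param Ainv matrix from [relationship_inverse()].
#' @param path output file.
#' @export
write_ainv_triplets <- function(Ainv, path) {
  tri <- Matrix::mat2triplet(Matrix::tril(Ainv))
  utils::write.csv(data.frame(i = tri$i, j = tri$j, value = tri$x),
                   path, row.names = FALSE)
  invisible(path)
}

#' Generations of screened ancestry ("mean ancestor score")
#'
#' For a focal individual, counts how many generations of its ancestors were
#' screened in the programme before the focal individual's own assessment,
#' separately through the dam ("maternal") and the sire ("paternal"), then
#' averages the two. The default \code{"fractional"} recursion is
#' \eqn{g(x) = 0} if x is unknown or not screened before the subject, and
#' \eqn{g(x) = 1 + (g(sire_x) + g(dam_x))/2} otherwise, so a chain broken by
#' an unscreened ancestor is discounted rather than cut. The
#' \code{"strict"} variant replaces the mean by the minimum, counting only
#' unbroken fully screened generations.
#'
#' @param ped a [as_pedigree()] object.
#' @param screened named vector of assessment dates (anything orderable:
#'   numeric year, Date, ...), names are screened ids. Unnamed ids are
#'   unscreened.
#' @param subject focal id (must be in the pedigree).
#' @param subject_date the subject's own assessment date; ancestors count
#'   only if screened strictly before it. Defaults to the subject's entry in
#'   \code{screened}, or \code{Inf} (all screened ancestors count) if absent.
#' @param method \code{"fractional"} (default) or \code{"strict"}.
#' @return List with \code{maternal}, \code{paternal}, \code{mean_score}.
#' @export
mean_ancestor_score <- function(ped, screened, subject, subject_date = NULL,
                                method = c("fractional", "strict")) {
  stopifnot(inherits(ped, "pedigree"))
  method <- match.arg(method)
  pos <- match(subject, ped$id)
  if (is.na(pos)) stop("unknown subject id: ", subject)
  if (is.null(subject_date)) {
    subject_date <- if (subject %in% names(screened)) screened[[subject]] else Inf
  }
  si <- attr(ped, "sire_ix"); di <- attr(ped, "dam_ix")
  sdate <- rep(Inf, nrow(ped))
  hit <- match(names(screened), ped$id)
  sdate[hit[!is.na(hit)]] <- as.numeric(screened)[!is.na(hit)]
  ok <- sdate < as.numeric(subject_date)
  g <- rep(NA_real_, nrow(ped))
  depth <- function(i) {
    if (i == 0L || !ok[i]) return(0)
    if (!is.na(g[i])) return(g[i])
    up <- c(depth(si[i]), depth(di[i]))
    val <- 1 + if (method == "fractional") mean(up) else min(up)
    g[i] <<- val
    val
  }
  maternal <- depth(di[pos])
  paternal <- depth(si[pos])
  list(maternal = maternal, paternal = paternal,
       mean_score = (maternal + paternal) / 2)
}

#' Mean ancestor scores for many individuals
#'
#' Vectorised form of [mean_ancestor_score()]. When the screening dates are
#' consistent with the pedigree order (every screened parent assessed before
#' each of its screened offspring) a single forward pass is used; otherwise
#' it falls back to the per-subject recursion.
#'
#' @inheritParams mean_ancestor_score
#' @param subjects ids to score; default all screened ids in the pedigree.
#' @return Data frame with \code{id}, \code{maternal}, \code{paternal},
#'   \code{mean_ancestor_score}.
#' @export
mean_ancestor_scores <- function(ped, screened, subjects = NULL,
                                 method = c("fractional", "strict")) {
  stopifnot(inherits(ped, "pedigree"))
  method <- match.arg(method)
  if (is.null(subjects)) subjects <- intersect(ped$id, names(screened))
  si <- attr(ped, "sire_ix"); di <- attr(ped, "dam_ix")
  sdate <- rep(NA_real_, nrow(ped))
  hit <- match(names(screened), ped$id)
  sdate[hit[!is.na(hit)]] <- as.numeric(screened)[!is.na(hit)]
  scr <- !is.na(sdate)
  pd <- function(ix) ifelse(ix > 0L, sdate[pmax(ix, 1L)], NA_real_)
  ordered_ok <- all(pd(si)[scr] < sdate[scr] | is.na(pd(si)[scr])) &&
    all(pd(di)[scr] < sdate[scr] | is.na(pd(di)[scr]))
  if (ordered_ok) {
    # h[i]: screened-generation depth counting i itself
    h <- numeric(nrow(ped))
    for (i in seq_len(nrow(ped))) {
      if (!scr[i]) next
      up <- c(if (si[i] > 0L) h[si[i]] else 0, if (di[i] > 0L) h[di[i]] else 0)
      h[i] <- 1 + if (method == "fractional") mean(up) else min(up)
    }
    pos <- match(subjects, ped$id)
    if (anyNA(pos)) stop("unknown subject id: ", subjects[is.na(pos)][1])
    mat <- ifelse(di[pos] > 0L, h[pmax(di[pos], 1L)], 0)
    pat <- ifelse(si[pos] > 0L, h[pmax(si[pos], 1L)], 0)
    data.frame(id = subjects, maternal = mat, paternal = pat,
               mean_ancestor_score = (mat + pat) / 2)
  } else {
    out <- lapply(subjects, function(s)
      mean_ancestor_score(ped, screened, s, method = method))
    data.frame(id = subjects,
               maternal = vapply(out, `[[`, 0, "maternal"),
               paternal = vapply(out, `[[`, 0, "paternal"),
               mean_ancestor_score = vapply(out, `[[`, 0, "mean_score"))
  }
}
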