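new_relmat <- function(values, ids, kind) {
  dimnames(values) <- list(ids, ids)
  structure(values, kind = kind, class = c("relmat", "matrix", "array"))
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d individuals\n",
              attr(x, "kind"), nrow(x)))
  cat(sprintf("  diag mean %.3f, off-diag mean %.3f\n",
              mean(diag(x)), (sum(x) - sum(diag(x))) / (nrow(x)^2 - nrow(x))))
  invisible(x)
}

#' Kind of a relationship matrix
#' @param k a relationship matrix from [amat()] or [gmat_vanraden()].
#' @return `"pedigree"` or `"genomic"`.
#' @export
relmat_kind <- function(k) attr(k, "kind")

#' Pedigree (numerator) additive relationship matrix
#'
#' Computes additive genetic relationships by the tabular method:
#' a(i,i) = 1 + 0.5 a(s_i, d_i) and a(i,j) = 0.5 (a(j, s_i) + a(j, d_i))
#' for j preceding i, with unknown parents contributing 0. Founder
#' diagonals are exactly 1; diagonals are 1 + F (inbreeding coefficient).
#'
#' @param ped a [pedigree_table()] (topologically ordered by construction).
#' @return A `relmat` of kind `"pedigree"` with individual ids as dimnames.
#' @examples
#' ped <- pedigree_table(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
#' amat(ped)
#' @export
amat <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  ids <- ped$individual
  n <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      as_ <- if (is.na(s)) 0 else A[prev, s]
      ad_ <- if (is.na(d)) 0 else A[prev, d]
      rij <- 0.5 * (as_ + ad_)
      A[prev, i] <- rij
      A[i, prev] <- rij
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  new_relmat(A, ids, "pedigree")
}

#' Inbreeding coefficients from a pedigree
#'
#' @param ped a [pedigree_table()].
#' @return Named numeric vector F = a(i,i) - 1.
#' @export
inbreeding <- function(ped) {
  A <- amat(ped)
  setNames(diag(A) - 1, rownames(A))
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' G = W W' / (2 * sum_k p_k (1 - p_k)) where W is the dosage matrix with
#' each column centered at twice the sample alternate-allele frequency
#' p_k. With sample frequencies every row of G sums to zero.
#'
#' @param g a [genotype_matrix()] with no missing entries (run
#'   [impute_mean()] first) and no monomorphic sites.
#' @return A `relmat` of kind `"genomic"`.
#' @export
gmat_vanraden <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$dosage)) {
    stop("genotype matrix contains missing dosages; run impute_mean() first")
  }
  p <- colMeans(g$dosage) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    stop(sum(mono), " monomorphic site(s) present (e.g. ",
         colnames(g$dosage)[which(mono)[1L]],
         "); remove them with filter_sites()")
  }
  W <- sweep(g$dosage, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  new_relmat(G, rownames(g$dosage), "genomic")
}

#' Ensure a relationship matrix is positive definite
#'
#' Returns `k` unchanged when a Cholesky factorization succeeds; otherwise
#' blends with the identity, (1 - epsilon) k + epsilon I, which preserves
#' labels and nearly preserves values, and logs the adjustment.
#'
#' @param k a symmetric relationship matrix.
#' @param epsilon blending weight in (0, 1].
#' @return A positive-definite matrix of the same kind and dimnames.
#' @export
make_invertible <- function(k, epsilon = 1e-4) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("epsilon must be a positive scalar")
  }
  ok <- is.null(tryCatch({ chol(k); NULL }, error = function(e) e))
  if (ok) return(k)
  message("make_invertible: blending with identity (epsilon = ", epsilon, ")")
  out <- (1 - epsilon) * unclass(k) + epsilon * diag(nrow(k))
  dimnames(out) <- dimnames(k)
  out <- structure(out, kind = attr(k, "kind"), class = class(k))
  chol(out)  # errors if still not PD
  out
}

#' Write / read a relationship matrix as labeled CSV
#'
#' First column `id`, remaining columns one per individual.
#'
#' @param k a relationship matrix with dimnames.
#' @param path file path.
#' @param kind kind label to attach on read (`"pedigree"` or `"genomic"`).
#' @return `write_relmat()` returns `path` invisibly; `read_relmat()` a `relmat`.
#' @export
write_relmat <- function(k, path) {
  dt <- data.table::as.data.table(as.matrix(unclass(k)))
  names(dt) <- colnames(k)
  dt <- cbind(data.table::data.table(id = rownames(k)), dt)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path, kind = c("pedigree", "genomic")) {
  kind <- match.arg(kind)
  dt <- data.table::fread(path, header = TRUE)
  ids <- as.character(dt[[1L]])
  vals <- as.matrix(dt[, -1L, with = FALSE])
  new_relmat(vals, ids, kind)
}
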