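#' Additive (numerator) relationship matrix
#'
#' Computes the additive relationship matrix A of a pedigree by the tabular
#' (recursive) method, with inbreeding: working in topological order,
#' `A[i,i] = 1 + 0.5 * A[dam_i, sire_i]` and
#' `A[i,j] = 0.5 * (A[j, dam_i] + A[j, sire_i])` for each earlier individual
#' `j`; an unknown parent contributes 0. Founders are unrelated with
#' inbreeding coefficient 0. `A[i,j]` is twice the kinship coefficient, and
#' the diagonal is `1 + F`.
#'
#' @param ped a [pedigree()] object.
#' @return A list of class `"relationship_matrix"` with elements
#'   `order` (ids, topological order), `A` (dense symmetric matrix) and
#'   `F` (named vector of inbreeding coefficients).
#' @examples
#' ped <- pedigree(c("d", "s", "o"), c(NA, NA, "d"), c(NA, NA, "s"),
#'                 c("f", "m", "f"))
#' additive_relationship(ped)$A
#' @export
additive_relationship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  di <- attr(ped, "dam_idx"); si <- attr(ped, "sire_idx")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    d <- di[i]; s <- si[i]
    A[i, i] <- 1 + 0.5 * (if (!is.na(d) && !is.na(s)) A[d, s] else 0)
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (!is.na(d)) A[j, d] else 0) + (if (!is.na(s)) A[j, s] else 0))
      A[j, i] <- aj
      A[i, j] <- aj
    }
  }
  Fcoef <- diag(A) - 1
  names(Fcoef) <- ped$id
  structure(list(order = ped$id, A = A, F = Fcoef),
            class = "relationship_matrix")
}

#' @method print relationship_matrix
#' @export
print.relationship_matrix <- function(x, ...) {
  cat("Additive relationship matrix:", length(x$order), "individuals, mean F =",
      format(mean(x$F), digits = 4), "\n")
  invisible(x)
}

#' Sparse inverse of the additive relationship matrix
#'
#' Assembles the inverse of the numerator relationship matrix directly from
#' the pedigree by Henderson's rules, using exact inbreeding coefficients
#' (computed by the tabular method) in the Mendelian-sampling variances:
#' for individual `i` with parents `p`, `q` the sampling variance is
#' `d_i = 0.5 - 0.25 * (F_p + F_q)` (both parents known),
#' `0.75 - 0.25 * F_p` (one known) or `1` (founder), and `A^-1` accumulates
#' `(1/d_i) * w w'` with `w` = +1 on `i` and -0.5 on each known parent.
#'
#' @param ped a [pedigree()] object.
#' @return A sparse symmetric [Matrix::Matrix] in the pedigree's topological
#'   order (`dimnames` carry the ids).
#' @export
inverse_relationship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  di <- attr(ped, "dam_idx"); si <- attr(ped, "sire_idx")
  Fcoef <- additive_relationship(ped)$F
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    par <- c(di[i], si[i]); par <- par[!is.na(par)]
    d_i <- switch(length(par) + 1L,
                  1,
                  0.75 - 0.25 * Fcoef[par],
                  0.5 - 0.25 * sum(Fcoef[par]))
    w_idx <- c(i, par)
    w_val <- c(1, rep(-0.5, length(par)))
    k <- length(w_idx)
    ii <- c(ii, rep(w_idx, each = k))
    jj <- c(jj, rep(w_idx, times = k))
    xx <- c(xx, as.numeric(outer(w_val, w_val)) / d_i)
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}
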