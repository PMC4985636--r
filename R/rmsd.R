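#' Superposition RMSD between two conformations
#'
#' Root-mean-square deviation between two equally sized coordinate sets,
#' optionally after optimal least-squares rigid superposition (Kabsch
#' algorithm via SVD, with the determinant correction that excludes
#' reflections). With `fit = TRUE` the result is invariant under any proper
#' rigid motion of either input.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices (angstroms).
#' @param fit Apply Kabsch superposition first? Default `TRUE`.
#' @return RMSD in angstroms (non-negative scalar).
#' @export
superpose_rmsd <- function(coords_a, coords_b, fit = TRUE) {
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  if (!identical(dim(a), dim(b)) || ncol(a) != 3) {
    abort("coordinate sets must be n x 3 matrices of equal size",
          class = "ptb_error_contract")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    abort("non-finite coordinates", class = "ptb_error_contract")
  }
  if (fit) {
    if (nrow(a) < 3) {
      abort("superposition needs at least 3 points",
            class = "ptb_error_contract")
    }
    a <- sweep(a, 2, colMeans(a))
    b <- sweep(b, 2, colMeans(b))
    b <- b %*% kabsch_rotation(b, a)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

## Optimal proper rotation R such that b %*% R best matches a
## (both centered). Classic SVD solution with det correction.
kabsch_rotation <- function(b, a) {
  h <- crossprod(b, a)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}
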