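#' Coerce to a dense data tensor
#'
#' A data tensor is an ordinary dense numeric array of order \eqn{D \ge 2}
#' carrying the observed data \eqn{\mathcal{X}} or an estimate
#' \eqn{\hat{\mathcal{U}}}. `as_tensor()` validates a numeric vector, matrix or
#' array and returns it as an array with a `dim` attribute.
#'
#' @param x Numeric vector, matrix or array.
#' @param dims Integer vector of mode lengths. Required when `x` is a bare
#'   vector; otherwise defaults to `dim(x)`.
#' @return A dense numeric array with at least two modes.
#' @examples
#' as_tensor(1:24, dims = c(2, 3, 4))
#' @export
as_tensor <- function(x, dims = dim(x)) {
  if (is.null(dims)) stop("`dims` must be supplied for a bare vector")
  dims <- as.integer(dims)
  if (length(dims) < 2L) stop("a data tensor needs at least two modes")
  if (any(dims < 1L)) stop("every mode length must be >= 1")
  x <- as.double(x)
  if (length(x) != prod(dims)) stop("length of `x` does not match `dims`")
  if (!all(is.finite(x))) stop("tensor entries must be finite")
  array(x, dim = dims)
}

#' Vectorize a tensor
#'
#' Column-major vectorization of the mode-1 matricization: element
#' \eqn{(i_1,\dots,i_D)} lands at linear position
#' \eqn{i_1 + \sum_{d\ge 2} (i_d - 1) \prod_{j<d} n_j} (1-based). For dense
#' arrays stored column-major this is a flat copy of the data.
#'
#' @param x A dense numeric array.
#' @return Numeric vector of length `prod(dim(x))`.
#' @export
tensor_vec <- function(x) {
  as.vector(x)
}

#' Restore a vectorized tensor to array form
#'
#' Inverse of [tensor_vec()]: the round trip reproduces the array exactly.
#'
#' @param v Numeric vector.
#' @param dims Mode lengths of the target array.
#' @return Dense array of shape `dims`.
#' @export
tensor_unvec <- function(v, dims) {
  dims <- as.integer(dims)
  if (length(v) != prod(dims)) stop("length mismatch in tensor_unvec")
  array(as.double(v), dim = dims)
}

#' Mode-d matricization
#'
#' Rearranges a tensor so that its mode-`d` fibers become the columns of an
#' \eqn{n_d \times n_{-d}} matrix, \eqn{n_{-d} = \prod_{j \ne d} n_j}. Columns
#' are ordered with the remaining modes in increasing order, earlier modes
#' varying fastest, so that `tensor_vec(x)` equals the column-major flattening
#' of `tensor_unfold(x, 1)`.
#'
#' @param x A dense numeric array.
#' @param mode Mode index in `1..D`.
#' @return An `n_d` by `n_{-d}` matrix.
#' @export
tensor_unfold <- function(x, mode) {
  d <- dim(x)
  D <- length(d)
  if (mode < 1L || mode > D) stop("mode index out of range")
  perm <- c(mode, seq_len(D)[-mode])
  matrix(aperm(x, perm), nrow = d[mode])
}

#' Invert a mode-d matricization
#'
#' @param m Matrix produced by [tensor_unfold()] with the same `mode`/`dims`.
#' @param mode Mode index that was unfolded.
#' @param dims Shape of the original tensor (the `mode` entry may differ from
#'   `nrow(m)` when folding the result of a mode product).
#' @return Dense array of shape `dims` with `dims[mode] = nrow(m)`.
#' @export
tensor_fold <- function(m, mode, dims) {
  dims <- as.integer(dims)
  D <- length(dims)
  if (mode < 1L || mode > D) stop("mode index out of range")
  dims[mode] <- nrow(m)
  perm <- c(mode, seq_len(D)[-mode])
  a <- array(as.double(m), dim = dims[perm])
  aperm(a, order(perm))
}

#' d-mode (matrix) product
#'
#' Multiplies a tensor along mode `d` by a matrix `b` with `ncol(b) = n_d`:
#' the result's mode-`d` matricization is `b %*% tensor_unfold(x, d)`. Its
#' vectorization satisfies the Kronecker identity
#' \eqn{\mathrm{vec}(\mathcal{X} \times_d B) = (I_{n_D} \otimes \cdots \otimes
#' B \otimes \cdots \otimes I_{n_1})\,\mathrm{vec}(\mathcal{X})}.
#'
#' @param x A dense numeric array.
#' @param b Matrix with `ncol(b) == dim(x)[mode]`.
#' @param mode Mode index.
#' @return Array with mode `d` length replaced by `nrow(b)`.
#' @export
ttm <- function(x, b, mode) {
  d <- dim(x)
  b <- as.matrix(b)
  if (ncol(b) != d[mode]) stop("ncol(b) must equal the length of mode ", mode)
  tensor_fold(b %*% tensor_unfold(x, mode), mode, d)
}

#' Frobenius norm of a tensor
#'
#' Square root of the sum of squares of all entries; equals the l2 norm of the
#' vectorization.
#'
#' @param x A dense numeric array.
#' @return Nonnegative scalar.
#' @export
tensor_norm <- function(x) {
  sqrt(sum(as.vector(x)^2))
}

#' Edge-difference operator for one mode
#'
#' Builds the linear map sending a vectorized tensor `u` to the stacked
#' per-edge difference blocks: block `l` for edge \eqn{(i,j)} is
#' \eqn{\mathrm{vec}(\mathcal{U} \times_d \Delta_{d,ij})} with
#' \eqn{\Delta_{d,ij} = e_i^\top - e_j^\top}, i.e. the difference of the
#' \eqn{i}th and \eqn{j}th mode-`d` subarrays. Internally the map is realized
#' matrix-free through the sparse oriented incidence matrix \eqn{\Phi_d} of
#' the mode-`d` similarity graph (+1 on the smaller index `i`, -1 on `j`),
#' acting on the mode-`d` matricization; dense Kronecker factors are never
#' assembled.
#'
#' @param dims Shape of the tensors the operator acts on.
#' @param mode Mode index `d`.
#' @param edges Two-column integer matrix of edges, each row `(i, j)` with
#'   `i < j`, no duplicates, endpoints in `1..n_d`.
#' @return An object of class `"difference_op"` with fields `mode`, `edges`,
#'   `phi` (sparse incidence matrix `|E_d| x n_d`), `dims`.
#' @export
difference_op <- function(dims, mode, edges) {
  dims <- as.integer(dims)
  nd <- dims[mode]
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > nd)) stop("edge endpoint out of range")
    if (any(edges[, 1L] >= edges[, 2L])) stop("edges must satisfy i < j")
    key <- paste(edges[, 1L], edges[, 2L])
    if (anyDuplicated(key)) stop("duplicate edges")
  }
  m <- nrow(edges)
  phi <- Matrix::sparseMatrix(
    i = rep(seq_len(m), 2L),
    j = c(edges[, 1L], edges[, 2L]),
    x = rep(c(1, -1), each = m),
    dims = c(m, nd)
  )
  structure(list(mode = mode, edges = edges, phi = phi, dims = dims),
            class = "difference_op")
}

#' Apply a difference operator
#'
#' Returns the per-edge difference blocks as an \eqn{n_{-d} \times |E_d|}
#' matrix whose `l`th column is \eqn{A_{d,l} u}.
#'
#' @param op A `"difference_op"`.
#' @param x Tensor (array) or its vectorization.
#' @return Matrix `n_{-d} x |E_d|`.
#' @export
diff_apply <- function(op, x) {
  if (is.null(dim(x)) || length(dim(x)) != length(op$dims)) {
    x <- tensor_unvec(x, op$dims)
  }
  m <- tensor_unfold(x, op$mode)
  t(as.matrix(op$phi %*% m))
}

#' Transpose-apply a difference operator
#'
#' Adjoint of [diff_apply()]: maps a block matrix \eqn{\Lambda_d}
#' (`n_{-d} x |E_d|`) back to a vectorized tensor,
#' \eqn{A_d^\top \lambda_d}.
#'
#' @param op A `"difference_op"`.
#' @param lambda Matrix `n_{-d} x |E_d|` of blocks.
#' @return Numeric vector of length `prod(op$dims)`.
#' @export
diff_apply_t <- function(op, lambda) {
  md <- as.matrix(Matrix::crossprod(op$phi, t(lambda)))
  as.vector(tensor_fold(md, op$mode, op$dims))
}
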