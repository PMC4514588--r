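#' Close a vector of nonnegative parts to a composition
#'
#' Rescales a vector of nonnegative parts so that they sum to 1, the closure
#' operation that maps raw amounts (e.g. activities in Bq/kg) onto the
#' simplex. Compositions carry only relative information: any two inputs that
#' differ by a positive scalar close to the same point.
#'
#' @param x numeric vector of nonnegative parts with at least one strictly
#'   positive entry.
#' @param labels optional character vector of part names; defaults to existing
#'   names or `p1..pD`.
#' @return A `composition`: a named numeric vector summing to 1.
#' @examples
#' closure(c(1, 1, 2))
#' closure(c(Ol = 120, Of = 900, Oh = 850), labels = c("w1", "w2", "w3"))
#' @export
closure <- function(x, labels = NULL) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop("`x` must be a numeric vector with at least 2 parts", call. = FALSE)
  }
  if (anyNA(x)) stop("`x` contains missing values", call. = FALSE)
  if (any(x < 0)) stop("`x` contains negative parts", call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("`x` must have at least one positive part", call. = FALSE)
  out <- as.numeric(x) / s
  names(out) <- labels %||% names(x) %||% paste0("p", seq_along(x))
  structure(out, class = "composition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.composition <- function(x, digits = 4, ...) {
  cat("composition (", length(x), " parts)\n", sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

as_composition <- function(x) {
  if (inherits(x, "composition")) x else closure(x)
}

# strict positivity required by the log-ratio transforms
check_positive <- function(x, what = "composition") {
  if (any(x <= 0)) {
    stop(what, " has zero or negative parts; apply zero_replace() first",
         call. = FALSE)
  }
  invisible(x)
}

check_same_length <- function(x, y) {
  if (length(x) != length(y)) {
    stop("compositions have different lengths (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  invisible(NULL)
}

#' Perturbation: the simplex analogue of vector addition
#'
#' The perturbation of `x` by `v` is the closed component-wise product.
#' It shifts the point `x` along the direction `v`; the neutral element is the
#' uniform composition and the inverse of `x` is `closure(1/x)`.
#'
#' @param x,v compositions (or positive vectors, closed on entry) of equal
#'   length.
#' @return A `composition`.
#' @seealso [powering()], [linear_process_point()]
#' @export
perturb <- function(x, v) {
  x <- as_composition(x); v <- as_composition(v)
  check_same_length(x, v)
  check_positive(x); check_positive(v, "perturbing vector")
  closure(unclass(x) * unclass(v), labels = names(x))
}

#' Powering: the simplex analogue of scalar multiplication
#'
#' Raises every part of `x` to the power `t` and re-closes. `t = 0` gives the
#' uniform composition (the simplex origin), `t = 1` leaves `x` unchanged and
#' `t = -1` gives the perturbation inverse.
#'
#' @param x a composition (positive parts).
#' @param t a single real scalar.
#' @return A `composition`.
#' @export
powering <- function(x, t) {
  x <- as_composition(x)
  check_positive(x)
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  closure(unclass(x)^t, labels = names(x))
}

#' Perturbation inverse of a composition
#'
#' @param x a composition with positive parts.
#' @return The composition `u` with `perturb(x, u)` equal to the uniform
#'   composition.
#' @export
comp_inverse <- function(x) powering(x, -1)

#' Point on a compositional line (linear process)
#'
#' Evaluates the linear process `x(t) = x0 + t * v` in Aitchison geometry,
#' i.e. `perturb(x0, powering(v, t))`. With `x0` an initial composition and
#' `v` a direction, the track `x(t)` is a straight line in the simplex; it
#' models a process whose stage of progress `t` differs between observations
#' while the mechanism (the direction `v`) is fixed.
#'
#' @param x0 initial composition.
#' @param v direction composition.
#' @param t real scalar (stage of process progress).
#' @return A `composition`.
#' @export
linear_process_point <- function(x0, v, t) {
  perturb(x0, powering(v, t))
}

#' Centred log-ratio (clr) transform and its inverse
#'
#' `clr()` maps a strictly positive composition to the vector of logarithms of
#' each part over the geometric mean of all parts. The coordinates sum to 0,
#' so clr vectors live on a hyperplane of dimension D-1. Euclidean geometry on
#' clr coordinates is exactly Aitchison geometry on the simplex. `clr_inv()`
#' maps any real vector back by closure of the exponentials (components of a
#' nonzero-sum vector are first centred implicitly by the closure).
#'
#' @param x a composition with strictly positive parts.
#' @param y a real vector of clr coordinates.
#' @return `clr()`: a named numeric vector summing to 0; `clr_inv()`: a
#'   `composition`.
#' @examples
#' clr(closure(c(exp(1), 1, 1)))  # (2/3, -1/3, -1/3)
#' clr_inv(clr(closure(c(1, 2, 3))))
#' @export
clr <- function(x) {
  x <- as_composition(x)
  check_positive(x)
  lx <- log(unclass(x))
  out <- lx - mean(lx)
  names(out) <- names(x)
  out
}

#' @rdname clr
#' @export
clr_inv <- function(y) {
  stopifnot(is.numeric(y))
  closure(exp(as.numeric(y) - max(y)), labels = names(y))
}

#' Orthonormal log-contrast (ilr) basis
#'
#' Builds the default Helmert-type contrast matrix used for isometric
#' log-ratio coordinates: `D - 1` rows, each summing to 0 with unit Euclidean
#' norm, mutually orthogonal. Row `k` balances parts `1..k` against part
#' `k + 1`. Any matrix with these properties is a valid basis; downstream
#' distance-based results do not depend on the choice.
#'
#' @param D number of parts (>= 2).
#' @return A `(D-1) x D` contrast matrix.
#' @export
ilr_basis <- function(D) {
  stopifnot(D >= 2)
  V <- matrix(0, D - 1L, D)
  for (k in seq_len(D - 1L)) {
    V[k, seq_len(k)] <- 1 / sqrt(k * (k + 1))
    V[k, k + 1L] <- -k / sqrt(k * (k + 1))
  }
  V
}

check_basis <- function(V, D) {
  if (!is.matrix(V) || nrow(V) != D - 1L || ncol(V) != D) {
    stop("basis must be a (D-1) x D matrix", call. = FALSE)
  }
  if (max(abs(rowSums(V))) > 1e-8) stop("basis rows must sum to 0", call. = FALSE)
  G <- tcrossprod(V)
  if (max(abs(G - diag(D - 1L))) > 1e-8) {
    stop("basis rows must be orthonormal", call. = FALSE)
  }
  invisible(V)
}

#' Isometric log-ratio (ilr) coordinates and their inverse
#'
#' Projects the clr vector of `x` onto an orthonormal contrast basis, giving
#' `D - 1` unconstrained real coordinates. The map is an isometry: Euclidean
#' distances between ilr coordinates equal Aitchison distances between the
#' compositions, for any valid basis.
#'
#' @param x a composition (or matrix of compositions in rows).
#' @param basis a `(D-1) x D` orthonormal contrast matrix; default
#'   [ilr_basis()].
#' @param y numeric vector (or matrix) of ilr coordinates.
#' @return `ilr()`: numeric vector of length `D - 1` (or an `n x (D-1)`
#'   matrix); `ilr_inv()`: a `composition` (or matrix of compositions).
#' @export
ilr <- function(x, basis = NULL) {
  if (is.matrix(x)) {
    basis <- basis %||% ilr_basis(ncol(x))
    check_basis(basis, ncol(x))
    lx <- log(x)
    cl <- lx - rowMeans(lx)
    return(cl %*% t(basis))
  }
  x <- as_composition(x)
  basis <- basis %||% ilr_basis(length(x))
  check_basis(basis, length(x))
  drop(basis %*% clr(x))
}

#' @rdname ilr
#' @export
ilr_inv <- function(y, basis = NULL) {
  if (is.matrix(y)) {
    basis <- basis %||% ilr_basis(ncol(y) + 1L)
    check_basis(basis, ncol(y) + 1L)
    cl <- y %*% basis
    e <- exp(cl - apply(cl, 1, max))
    return(e / rowSums(e))
  }
  stopifnot(is.numeric(y))
  basis <- basis %||% ilr_basis(length(y) + 1L)
  check_basis(basis, length(y) + 1L)
  clr_inv(drop(crossprod(basis, y)))
}

#' Aitchison distance between two compositions
#'
#' The Euclidean distance between the clr vectors of `x` and `y`. It is
#' symmetric, positive-definite, invariant under perturbation of both points
#' by the same composition, and equals the Euclidean distance between ilr
#' coordinates in any orthonormal basis.
#'
#' @param x,y compositions of equal length with positive parts.
#' @return A nonnegative scalar.
#' @export
aitchison_dist <- function(x, y) {
  x <- as_composition(x); y <- as_composition(y)
  check_same_length(x, y)
  sqrt(sum((clr(x) - clr(y))^2))
}

#' Compositional centre (closed geometric mean)
#'
#' The centre of a set of compositions is the closure of the column-wise
#' geometric means. It is the simplex analogue of the arithmetic mean and is
#' perturbation-equivariant: perturbing every observation by `p` perturbs the
#' centre by `p`.
#'
#' @param X an `n x D` matrix of positive parts, one composition per row
#'   (rows need not be closed).
#' @return A `composition`.
#' @export
comp_center <- function(X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (nrow(X) < 1L) stop("empty set of compositions", call. = FALSE)
  if (any(X <= 0)) stop("all parts must be positive", call. = FALSE)
  closure(exp(colMeans(log(X))), labels = colnames(X))
}
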