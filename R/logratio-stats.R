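#' Variance of a pairwise log-ratio
#'
#' The co-variability statistic VR = var(ln(a/b)) for two positive series.
#' If the two series are exactly proportional the log-ratio is constant and
#' VR is 0; large VR means weak or no proportionality. The sample variance
#' uses the n-1 denominator.
#'
#' @param a,b strictly positive numeric vectors of equal length `n >= 2`.
#' @return A nonnegative scalar.
#' @export
vr_pair <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(a <= 0) || any(b <= 0)) stop("series must be strictly positive", call. = FALSE)
  stats::var(log(a / b))
}

#' Variation matrix of a compositional dataset
#'
#' The symmetric `D x D` matrix with entries `T[i, j] = var(ln(X[, i] / X[, j]))`.
#' Its entries are subcompositionally coherent: the matrix computed on any
#' column subset equals the corresponding block of the full matrix, which is
#' what makes it the preferred dispersion summary for compositions.
#'
#' @param X an `n x D` matrix of strictly positive parts (closure is
#'   irrelevant: the statistic only uses ratios), `n >= 2`.
#' @return A `variation_matrix`: symmetric with zero diagonal.
#' @export
variation_matrix <- function(X) {
  if (!is.matrix(X)) stop("`X` must be a matrix", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (any(X <= 0)) stop("`X` must be strictly positive", call. = FALSE)
  L <- log(X)
  C <- stats::cov(L)
  v <- diag(C)
  Tm <- outer(v, rep(1, length(v))) + outer(rep(1, length(v)), v) - 2 * C
  Tm <- (Tm + t(Tm)) / 2
  diag(Tm) <- 0
  dimnames(Tm) <- list(colnames(X), colnames(X))
  structure(Tm, class = c("variation_matrix", "matrix"))
}

#' Construct a variation matrix from its lower-triangle entries
#'
#' Convenience constructor for typing a published table of pairwise
#' log-ratio variances.
#'
#' @param lower numeric vector of the strict lower triangle in column-major
#'   order (`T[2,1], T[3,1], ..., T[D,D-1]`).
#' @param labels part names of length `D`.
#' @return A `variation_matrix`.
#' @export
vr_matrix <- function(lower, labels) {
  D <- length(labels)
  if (length(lower) != D * (D - 1) / 2) {
    stop("`lower` must have D(D-1)/2 entries", call. = FALSE)
  }
  if (any(lower < 0)) stop("log-ratio variances cannot be negative", call. = FALSE)
  Tm <- matrix(0, D, D, dimnames = list(labels, labels))
  Tm[lower.tri(Tm)] <- lower
  Tm <- Tm + t(Tm)
  structure(Tm, class = c("variation_matrix", "matrix"))
}

check_vr <- function(Tm) {
  if (!is.matrix(Tm) || nrow(Tm) != ncol(Tm)) {
    stop("variation matrix must be square", call. = FALSE)
  }
  if (max(abs(Tm - t(Tm))) > 1e-8) stop("variation matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(Tm))) > 1e-10) stop("variation matrix must have a zero diagonal", call. = FALSE)
  if (any(Tm < -1e-12)) stop("variation matrix entries must be nonnegative", call. = FALSE)
  invisible(Tm)
}

#' clr covariance matrix implied by a variation matrix
#'
#' Converts a variation matrix to the covariance matrix of the clr-transformed
#' data through the identity `Sigma = -1/2 * G T G` with `G = I - J/D` the
#' centring projector. For a data-derived variation matrix this reproduces the
#' sample clr covariance exactly; for a rounded published matrix small negative
#' eigenvalues can appear and are clipped at zero with a warning.
#'
#' @param Tm a `variation_matrix` (or plain symmetric zero-diagonal matrix).
#' @param clip clip negative eigenvalues of the result at zero (default TRUE).
#' @return A `D x D` matrix with rows and columns summing to 0.
#' @export
clr_cov_from_vr <- function(Tm, clip = TRUE) {
  check_vr(Tm)
  D <- nrow(Tm)
  G <- diag(D) - 1 / D
  S <- -0.5 * G %*% unclass(Tm) %*% G
  S <- (S + t(S)) / 2
  if (clip) {
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) < -1e-10) {
      warning("variation matrix is not conditionally negative semidefinite; ",
              "clipping negative eigenvalues at 0 (likely rounding in the input)")
      vals <- pmax(e$values, 0)
      S <- e$vectors %*% (vals * t(e$vectors))
      S <- (S + t(S)) / 2
    }
  }
  dimnames(S) <- dimnames(Tm)
  S
}

#' Balance coefficients for a two-group log-contrast
#'
#' A balance contrasts the geometric mean of a "+" group of `r` parts against
#' that of a "-" group of `s` parts:
#' `z = sqrt(rs/(r+s)) * ln( gm(+)/gm(-) )`. Its coefficient vector has value
#' `sqrt(rs/(r+s))/r` on "+" parts, `-sqrt(rs/(r+s))/s` on "-" parts and 0
#' elsewhere; it sums to 0 and has unit Euclidean norm, so the balance is an
#' orthonormal log-contrast coordinate.
#'
#' @param plus,minus disjoint nonempty integer index sets within `1..D`.
#' @param D total number of parts.
#' @param labels optional part names.
#' @return A `balance` object: list with `plus`, `minus`, `coeffs`.
#' @export
balance_coefficients <- function(plus, minus, D, labels = NULL) {
  plus <- sort(unique(as.integer(plus)))
  minus <- sort(unique(as.integer(minus)))
  if (length(plus) == 0L || length(minus) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (length(intersect(plus, minus)) > 0L) stop("groups overlap", call. = FALSE)
  if (any(c(plus, minus) < 1L) || any(c(plus, minus) > D)) {
    stop("indices outside 1..D", call. = FALSE)
  }
  r <- length(plus); s <- length(minus)
  a <- numeric(D)
  a[plus] <- sqrt(r * s / (r + s)) / r
  a[minus] <- -sqrt(r * s / (r + s)) / s
  names(a) <- labels %||% paste0("p", seq_len(D))
  structure(list(plus = plus, minus = minus, coeffs = a), class = "balance")
}

#' @export
print.balance <- function(x, ...) {
  nm <- names(x$coeffs)
  cat("balance: ", paste(nm[x$plus], collapse = "·"), " | ",
      paste(nm[x$minus], collapse = "·"), "\n", sep = "")
  invisible(x)
}

#' Balance values of a compositional dataset
#'
#' Evaluates a balance row-wise as the log-contrast `sum_k a_k ln X[, k]`,
#' which equals the scaled log-ratio of the two group geometric means
#' exactly.
#'
#' @param X an `n x D` strictly positive matrix.
#' @param b a `balance`.
#' @return Numeric vector of length `n`.
#' @export
balance_values <- function(X, b) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (any(X <= 0)) stop("`X` must be strictly positive", call. = FALSE)
  if (ncol(X) != length(b$coeffs)) stop("dimension mismatch", call. = FALSE)
  drop(log(X) %*% b$coeffs)
}

#' Balance variance from a variation matrix
#'
#' For any zero-sum coefficient vector `a`, `var(a' ln x) = -1/2 a' T a`
#' where `T` is the variation matrix. This scores a balance directly from a
#' (possibly published) variation matrix, with no row data needed; when `T`
#' is the empirical variation matrix of a table, the result equals the sample
#' variance of [balance_values()] on that table exactly.
#'
#' @param Tm a variation matrix.
#' @param b a `balance`.
#' @return A scalar variance (nonnegative for any valid variation matrix).
#' @export
balance_variance_from_vr <- function(Tm, b) {
  check_vr(Tm)
  a <- b$coeffs
  if (length(a) != nrow(Tm)) stop("dimension mismatch", call. = FALSE)
  -0.5 * drop(crossprod(a, unclass(Tm) %*% a))
}

#' Enumerate all two-group balances over subcompositions
#'
#' For every subset `S` of the `D` parts with size in `sizes`, and every
#' unordered split of `S` into two nonempty groups, emits one balance. The
#' orientation is canonical — the group containing the lowest part index is
#' "+" — so each unordered split is listed once. The total count is
#' `sum_k choose(D, k) * (2^(k-1) - 1)` over `k` in `sizes`.
#'
#' @param D number of parts.
#' @param sizes integer vector of subcomposition sizes (each in `2..D`).
#' @param labels optional part names.
#' @return List of `balance` objects.
#' @export
enumerate_balances <- function(D, sizes = 2:D, labels = NULL) {
  sizes <- sort(unique(as.integer(sizes)))
  if (min(sizes) < 2L || max(sizes) > D) {
    stop("sizes must lie in 2..D", call. = FALSE)
  }
  out <- vector("list", sum(choose(D, sizes) * (2^(sizes - 1) - 1)))
  pos <- 0L
  for (k in sizes) {
    subsets <- utils::combn(D, k, simplify = FALSE)
    for (S in subsets) {
      # canonical "+": always contains the smallest index of S
      rest <- S[-1]
      for (m in 0:(2^length(rest) - 1L)) {
        sel <- rest[bitwAnd(m, bitwShiftL(1L, seq_along(rest) - 1L)) > 0L]
        plus <- c(S[1], sel)
        minus <- setdiff(S, plus)
        if (length(minus) == 0L) next
        pos <- pos + 1L
        out[[pos]] <- balance_coefficients(plus, minus, D, labels)
      }
    }
  }
  out[seq_len(pos)]
}

#' Screen all balances of a dataset or variation matrix by variance
#'
#' Enumerates every two-group balance over subcompositions with sizes in
#' `sizes` and ranks them by variance, ascending. Low-variance balances
#' indicate near-constant ratios of group geometric-mean products — the
#' signature of components tied by a process near (thermodynamic)
#' equilibrium; high-variance balances indicate groups far from mutual
#' equilibrium.
#'
#' @param x either an `n x D` strictly positive data matrix or a
#'   `variation_matrix`.
#' @param sizes subcomposition sizes to screen (default `2:D`).
#' @return A data frame with columns `rank`, `variance`, `size`, `r`, `s`,
#'   `plus_parts`, `minus_parts` (labels joined by ";"), sorted by
#'   ascending variance.
#' @export
balance_screen <- function(x, sizes = NULL) {
  if (inherits(x, "variation_matrix")) {
    Tm <- x
  } else if (is.matrix(x) && nrow(x) == ncol(x) &&
             max(abs(x - t(x))) < 1e-10 && max(abs(diag(x))) < 1e-12) {
    Tm <- structure(x, class = c("variation_matrix", "matrix"))
  } else {
    Tm <- variation_matrix(x)
  }
  D <- nrow(Tm)
  sizes <- sizes %||% (2:D)
  labels <- colnames(Tm) %||% paste0("p", seq_len(D))
  bals <- enumerate_balances(D, sizes, labels)
  v <- vapply(bals, function(b) balance_variance_from_vr(Tm, b), numeric(1))
  df <- data.frame(
    variance = v,
    size = vapply(bals, function(b) length(b$plus) + length(b$minus), integer(1)),
    r = vapply(bals, function(b) length(b$plus), integer(1)),
    s = vapply(bals, function(b) length(b$minus), integer(1)),
    plus_parts = vapply(bals, function(b) paste(labels[b$plus], collapse = ";"), character(1)),
    minus_parts = vapply(bals, function(b) paste(labels[b$minus], collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$variance, df$size, df$plus_parts, df$minus_parts), ]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Orthonormal balance basis from a sequential binary partition
#'
#' A sequential binary partition (SBP) splits the full part set into two
#' groups, then recursively splits each group, until only singletons remain:
#' `D - 1` splits in total, each defining one balance. The resulting
#' coefficient rows form an orthonormal contrast matrix usable as an ilr
#' basis.
#'
#' @param signs a `(D-1) x D` matrix of +1 / -1 / 0 codes, one row per split:
#'   the nonzero entries of a row mark the group being split, +1 the "+"
#'   side, -1 the "-" side. Rows may be in any order but must describe a
#'   full recursive partition.
#' @param labels optional part names.
#' @return List with `balances` (list of `balance`) and `basis` (the
#'   `(D-1) x D` contrast matrix, rows in the order splits were validated,
#'   top split first).
#' @export
sbp_basis <- function(signs, labels = NULL) {
  if (!is.matrix(signs)) stop("`signs` must be a matrix", call. = FALSE)
  D <- ncol(signs)
  if (nrow(signs) != D - 1L) {
    stop("an SBP of D parts needs exactly D-1 splits", call. = FALSE)
  }
  if (!all(signs %in% c(-1, 0, 1))) stop("`signs` entries must be -1, 0 or +1", call. = FALSE)
  labels <- labels %||% colnames(signs) %||% paste0("p", seq_len(D))

  used <- rep(FALSE, nrow(signs))
  order_out <- integer(0)
  # recursively consume rows: each block must be split by exactly one row
  split_block <- function(block) {
    if (length(block) == 1L) return(invisible(NULL))
    hit <- which(!used & apply(signs, 1, function(r) {
      all(r[block] != 0) && all(r[-block] == 0) &&
        any(r[block] > 0) && any(r[block] < 0)
    }))
    if (length(hit) != 1L) {
      stop("`signs` is not a valid sequential binary partition", call. = FALSE)
    }
    used[hit] <<- TRUE
    order_out <<- c(order_out, hit)
    split_block(block[signs[hit, block] > 0])
    split_block(block[signs[hit, block] < 0])
  }
  split_block(seq_len(D))
  if (!all(used)) stop("`signs` is not a valid sequential binary partition", call. = FALSE)

  bals <- lapply(order_out, function(i) {
    balance_coefficients(which(signs[i, ] > 0), which(signs[i, ] < 0), D, labels)
  })
  basis <- do.call(rbind, lapply(bals, function(b) b$coeffs))
  list(balances = bals, basis = basis)
}
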