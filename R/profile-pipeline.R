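#' Relative activities of the first layers of one profile
#'
#' Closes the activities of the first `layers` horizons (ordered from the
#' surface) of a single profile: `a_r[k] = a[k] / sum(a[1..layers])`. Using
#' relative rather than absolute activities removes the effect of unequal
#' initial contamination between sampling sites. Zeros pass through and must
#' be replaced (see [zero_replace()]) before any log-ratio computation.
#'
#' @param activities numeric vector of activities (Bq/kg) in order from the
#'   surface.
#' @param layers number of layers to retain (default 5); horizons beyond
#'   `layers` are dropped and the closure is over the retained ones only.
#' @return Numeric vector of length `layers` summing to 1.
#' @export
relative_activities <- function(activities, layers = 5L) {
  if (length(activities) < layers) {
    stop("profile has ", length(activities), " horizons; ", layers,
         " required", call. = FALSE)
  }
  a <- activities[seq_len(layers)]
  if (anyNA(a) || any(a < 0) || any(!is.finite(a))) {
    stop("activities must be finite and nonnegative", call. = FALSE)
  }
  s <- sum(a)
  if (s <= 0) stop("all retained activities are zero", call. = FALSE)
  out <- a / s
  names(out) <- layer_labels(layers)
  out
}

#' Map a profile's horizons to depth-ordered layers
#'
#' Assigns layer labels `w1..wL` to the first `layers` horizons in surface
#' order, retaining the original horizon names as metadata. The abstraction
#' drops horizon identity (an `Oh` and an `A` horizon in third position both
#' become `w3`), keeping only the position in the profile.
#'
#' @param horizon_names character vector of horizon names in surface order.
#' @param layers number of layers (default 5).
#' @return Data frame with columns `layer`, `horizon_name`, `order`.
#' @export
map_layers <- function(horizon_names, layers = 5L) {
  if (length(horizon_names) < layers) {
    stop("profile has ", length(horizon_names), " horizons; ", layers,
         " required", call. = FALSE)
  }
  data.frame(
    layer = layer_labels(layers),
    horizon_name = as.character(horizon_names[seq_len(layers)]),
    order = seq_len(layers),
    stringsAsFactors = FALSE
  )
}

#' Multiplicative zero replacement
#'
#' Log-ratio transforms are undefined at zero, yet measured activity shares
#' can print as 0 (values below detection). Multiplicative replacement sets
#' each zero to a small `delta` and rescales the nonzero parts so each row
#' still sums to 1, preserving all ratios among the nonzero parts. With
#' `delta = "auto"` the replacement value is column-wise: 0.65 times the
#' smallest positive value observed in that column.
#'
#' @param X an `n x D` matrix of proportions (rows closed to 1), or a single
#'   vector.
#' @param delta a positive scalar, a vector of length `D` (per column), or
#'   `"auto"`.
#' @return Matrix (or vector) of the same shape, strictly positive, rows
#'   summing to 1.
#' @export
zero_replace <- function(X, delta = "auto") {
  vec <- !is.matrix(X)
  if (vec) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  if (any(X < 0)) stop("negative proportions", call. = FALSE)
  if (!any(X == 0)) return(if (vec) drop(X) else X)
  if (identical(delta, "auto")) {
    delta <- apply(X, 2, function(col) {
      pos <- col[col > 0]
      if (length(pos) == 0L) stop("a column is entirely zero", call. = FALSE)
      0.65 * min(pos)
    })
  }
  delta <- rep_len(delta, ncol(X))
  for (j in seq_len(ncol(X))) {
    pos <- X[, j][X[, j] > 0]
    if (length(pos) && delta[j] >= min(pos)) {
      stop("delta (", signif(delta[j], 3), ") not below the smallest positive ",
           "value in column ", j, call. = FALSE)
    }
  }
  out <- t(apply(X, 1, function(row) {
    z <- row == 0
    if (!any(z)) return(row)
    row[z] <- delta[z]
    row[!z] <- row[!z] * (1 - sum(delta[z])) / sum(row[!z])
    row
  }))
  colnames(out) <- colnames(X)
  if (vec) drop(out) else out
}

#' Build the layer-composition table from raw profile records
#'
#' Converts a tidy table of horizon-level activities into an `n x layers`
#' matrix of relative activities (one closed composition per profile),
#' rejecting profiles with fewer than `layers` horizons and replacing zeros.
#'
#' @param profiles data frame with columns `profile_id`, `soil_type`,
#'   `horizon_order`, `horizon_name`, `activity_bq_kg`.
#' @param layers number of layers from the surface (default 5).
#' @param delta zero-replacement delta passed to [zero_replace()].
#' @return List with `comp` (matrix of closed compositions, rownames =
#'   profile ids), `soil_type`, `horizons` (layer/horizon-name map per
#'   profile), `rejected` (data frame of profile id + reason).
#' @export
layer_compositions <- function(profiles, layers = 5L, delta = "auto") {
  req <- c("profile_id", "soil_type", "horizon_order", "horizon_name", "activity_bq_kg")
  miss <- setdiff(req, names(profiles))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  ids <- unique(profiles$profile_id)
  rows <- list(); st <- character(0); hz <- list(); rej <- list()
  for (id in ids) {
    p <- profiles[profiles$profile_id == id, ]
    p <- p[order(p$horizon_order), ]
    if (nrow(p) < layers) {
      rej[[length(rej) + 1L]] <- data.frame(
        profile_id = id,
        reason = paste0("only ", nrow(p), " horizons (", layers, " required)"),
        stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- relative_activities(p$activity_bq_kg, layers)
    st <- c(st, as.character(p$soil_type[1]))
    hz[[length(hz) + 1L]] <- cbind(profile_id = id,
                                   map_layers(p$horizon_name, layers))
    names(rows)[length(rows)] <- as.character(id)
  }
  if (length(rows) == 0L) stop("no profile has the required number of horizons", call. = FALSE)
  M <- do.call(rbind, rows)
  colnames(M) <- layer_labels(layers)
  M <- zero_replace(M, delta)
  list(comp = M,
       soil_type = st,
       horizons = do.call(rbind, hz),
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(profile_id = character(0), reason = character(0)))
}

#' Per-layer summary statistics of relative activities
#'
#' Order statistics (min, lower quartile, median, upper quartile, max; type-7
#' linear-interpolation quantiles), arithmetic mean and geometric mean of the
#' relative activity in each layer across profiles.
#'
#' @param M an `n x D` matrix of closed compositions (strictly positive).
#' @return Data frame with one row per layer.
#' @export
layer_summary <- function(M) {
  if (!is.matrix(M) || nrow(M) < 1L) stop("need a nonempty matrix", call. = FALSE)
  if (any(M <= 0)) stop("apply zero_replace() first", call. = FALSE)
  data.frame(
    layer  = colnames(M) %||% layer_labels(ncol(M)),
    min    = apply(M, 2, min),
    q1     = apply(M, 2, stats::quantile, probs = 0.25, names = FALSE),
    median = apply(M, 2, stats::median),
    mean   = colMeans(M),
    gmean  = exp(colMeans(log(M))),
    q3     = apply(M, 2, stats::quantile, probs = 0.75, names = FALSE),
    max    = apply(M, 2, max),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Geometric mean of the ratio of two layers
#'
#' The geometric mean over profiles of `M[, i] / M[, j]`, which identically
#' equals the ratio of the two layers' geometric means. A value near 1 means
#' the two layers hold similar shares of the profile's activity.
#'
#' @param M strictly positive composition matrix.
#' @param i,j column indices or labels.
#' @return A positive scalar.
#' @export
gm_ratio <- function(M, i, j) {
  if (!is.matrix(M)) M <- matrix(M, nrow = 1, dimnames = list(NULL, names(M)))
  if (any(M <= 0)) stop("apply zero_replace() first", call. = FALSE)
  exp(mean(log(M[, i]) - log(M[, j])))
}

#' Pair-plus-rest three-part subcomposition
#'
#' For a chosen layer pair `(i, j)` of a D-part composition, forms the closed
#' 3-part composition `[x_i, x_j, g(rest)]` per profile, where `g(rest)` is
#' the geometric mean of the remaining parts. This is the amalgam used to
#' study the joint behaviour of two layers against the background of the
#' others, e.g. when fitting a compositional line to a scatterplot panel.
#'
#' @param M strictly positive `n x D` matrix, `D >= 3`.
#' @param i,j distinct column indices or labels.
#' @return An `n x 3` matrix of closed compositions with columns
#'   `(label_i, label_j, "rest")`.
#' @export
pair_rest_subcomposition <- function(M, i, j) {
  if (!is.matrix(M)) stop("`M` must be a matrix", call. = FALSE)
  if (any(M <= 0)) stop("apply zero_replace() first", call. = FALSE)
  cn <- colnames(M) %||% paste0("p", seq_len(ncol(M)))
  ii <- if (is.character(i)) match(i, cn) else as.integer(i)
  jj <- if (is.character(j)) match(j, cn) else as.integer(j)
  if (anyNA(c(ii, jj)) || ii == jj || any(c(ii, jj) < 1) || any(c(ii, jj) > ncol(M))) {
    stop("invalid layer pair", call. = FALSE)
  }
  rest <- M[, -c(ii, jj), drop = FALSE]
  X3 <- cbind(M[, ii], M[, jj], exp(rowMeans(log(rest))))
  colnames(X3) <- c(cn[ii], cn[jj], "rest")
  X3 / rowSums(X3)
}

#' Fit a linear process (compositional line) to a 3-part table
#'
#' Models the rows of `X3` as stages of one process along a line in the
#' simplex, `x(t) = x0 + t * v` (perturbation/powering arithmetic). The
#' centre `x0` is the closed geometric mean; the direction `v` is the closure
#' of the exponentiated first principal component of the clr-transformed
#' data. `share_of_variance` is the fraction of total clr variance carried by
#' that component (1 for an exact line). The sign of `v` is fixed so the clr
#' coordinate of the first column is positive (second column breaks a tie at
#' zero).
#'
#' @param X3 an `n x 3` strictly positive matrix, `n >= 3`.
#' @return A `linear_process_fit`: list with `x0`, `v` (compositions),
#'   `share_of_variance`, `eigenvalues`.
#' @export
fit_linear_process <- function(X3) {
  if (!is.matrix(X3) || nrow(X3) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (any(X3 <= 0)) stop("apply zero_replace() first", call. = FALSE)
  lx <- log(X3)
  cl <- lx - rowMeans(lx)
  S <- stats::cov(cl)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[1] < 1e-14) {
    stop("degenerate input: all rows identical, direction undefined", call. = FALSE)
  }
  u <- e$vectors[, 1]
  if (abs(u[1]) > 1e-12) {
    if (u[1] < 0) u <- -u
  } else if (u[2] < 0) u <- -u
  names(u) <- colnames(X3)
  structure(list(
    x0 = comp_center(X3),
    v = clr_inv(u),
    share_of_variance = e$values[1] / sum(pmax(e$values, 0)),
    eigenvalues = e$values
  ), class = "linear_process_fit")
}

#' @export
print.linear_process_fit <- function(x, digits = 3, ...) {
  cat("compositional line fit\n  x0: ",
      paste(round(unclass(x$x0), digits), collapse = " "), "\n  v:  ",
      paste(round(unclass(x$v), digits), collapse = " "),
      "\n  share of variance: ", round(x$share_of_variance, digits), "\n", sep = "")
  invisible(x)
}

#' Linear-process fits for every layer pair
#'
#' For each of the `choose(D, 2)` unordered layer pairs, forms the
#' pair-plus-rest subcomposition, fits the compositional line, and tabulates
#' the direction vector together with the pair's log-ratio variance and
#' geometric-mean ratio. Directions that are similar across pairs point to a
#' common transport mechanism; a small `vr` flags near-proportional layers.
#'
#' @param M strictly positive `n x D` composition matrix.
#' @return Data frame with one row per pair: `i`, `j`, `v1`, `v2`, `v_rest`,
#'   `x0_1`, `x0_2`, `x0_rest`, `share_of_variance`, `vr`, `gm_ratio`.
#' @export
pairwise_process_report <- function(M) {
  cn <- colnames(M) %||% paste0("p", seq_len(ncol(M)))
  Tm <- variation_matrix(M)
  pairs <- utils::combn(ncol(M), 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    X3 <- pair_rest_subcomposition(M, pr[1], pr[2])
    f <- fit_linear_process(X3)
    data.frame(
      i = cn[pr[1]], j = cn[pr[2]],
      v1 = f$v[[1]], v2 = f$v[[2]], v_rest = f$v[[3]],
      x0_1 = f$x0[[1]], x0_2 = f$x0[[2]], x0_rest = f$x0[[3]],
      share_of_variance = f$share_of_variance,
      vr = Tm[pr[1], pr[2]],
      gm_ratio = gm_ratio(M, pr[1], pr[2]),
      stringsAsFactors = FALSE
    )
  }))
}
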