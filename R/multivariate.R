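#' Aitchison distance matrix of a composition table
#'
#' Pairwise Aitchison distances between profile compositions: Euclidean
#' distances of the clr-transformed rows. Invariant under perturbing all
#' profiles by a common composition, and identical to Euclidean distances of
#' ilr coordinates in any orthonormal basis.
#'
#' @param M strictly positive `n x D` matrix, `n >= 2`.
#' @return A symmetric `n x n` matrix with zero diagonal and the row names of
#'   `M`.
#' @export
distance_matrix <- function(M) {
  if (!is.matrix(M) || nrow(M) < 2L) stop("need at least 2 profiles", call. = FALSE)
  if (any(M <= 0)) stop("apply zero_replace() first", call. = FALSE)
  lx <- log(M)
  cl <- lx - rowMeans(lx)
  Dm <- as.matrix(stats::dist(cl))
  dimnames(Dm) <- list(rownames(M), rownames(M))
  Dm
}

#' Hierarchical clustering of profiles on Aitchison distances
#'
#' `cluster_agglomerative()` applies agglomerative nesting (`cluster::agnes`,
#' average linkage by default); `cluster_divisive()` applies divisive
#' analysis (`cluster::diana`, the classical splinter-group algorithm that
#' repeatedly splits the cluster of largest diameter). Both return the merge
#' tree as an `hclust` wrapped with the method tag and leaf labels.
#'
#' @param Dm a symmetric distance matrix (e.g. from [distance_matrix()]).
#' @param linkage agglomerative linkage method (default `"average"`).
#' @param labels optional leaf labels; default the rownames of `Dm`.
#' @return A `soil_dendrogram`: list with `hclust`, `method`, `labels`,
#'   `coefficient` (agglomerative/divisive coefficient from `cluster`).
#' @export
cluster_agglomerative <- function(Dm, linkage = "average", labels = NULL) {
  d <- stats::as.dist(Dm)
  fit <- cluster::agnes(d, diss = TRUE, method = linkage)
  make_dendro(fit, paste0("agglomerative(", linkage, ")"),
              labels %||% rownames(Dm), fit$ac)
}

#' @rdname cluster_agglomerative
#' @export
cluster_divisive <- function(Dm, labels = NULL) {
  d <- stats::as.dist(Dm)
  fit <- cluster::diana(d, diss = TRUE)
  make_dendro(fit, "divisive", labels %||% rownames(Dm), fit$dc)
}

make_dendro <- function(fit, method, labels, coefficient) {
  hc <- stats::as.hclust(fit)
  if (!is.null(labels)) hc$labels <- labels
  structure(list(hclust = hc, method = method,
                 labels = hc$labels %||% as.character(seq_len(nrow(fit$merge) + 1L)),
                 coefficient = coefficient),
            class = "soil_dendrogram")
}

#' @export
print.soil_dendrogram <- function(x, ...) {
  cat("hierarchical clustering (", x$method, "), ",
      length(x$labels), " leaves, coefficient ",
      round(x$coefficient, 3), "\n", sep = "")
  invisible(x)
}

#' Cut a dendrogram into k groups
#'
#' @param d a `soil_dendrogram`.
#' @param k number of groups.
#' @return Integer membership vector named by leaf labels.
#' @export
cut_dendrogram <- function(d, k) {
  stats::cutree(d$hclust, k = k)
}

#' Serialize a dendrogram to Newick text
#'
#' Writes the merge tree as a rooted ultrametric Newick string with branch
#' lengths derived from merge heights (each node's branch is its parent's
#' height minus its own). Children are ordered with the lexicographically
#' smallest descendant leaf first, so the output is deterministic regardless
#' of the input row order.
#'
#' @param d a `soil_dendrogram` (or plain `hclust`).
#' @param digits significant digits for branch lengths.
#' @return A single Newick string (terminated by ";").
#' @export
dendrogram_to_newick <- function(d, digits = 10) {
  hc <- if (inherits(d, "soil_dendrogram")) d$hclust else d
  labels <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  # returns list(text=, minleaf=) for node index (negative = leaf)
  node <- function(idx, parent_height) {
    if (idx < 0) {
      lab <- labels[-idx]
      return(list(text = paste0(lab, ":", fmt(parent_height)), minleaf = lab))
    }
    h <- hc$height[idx]
    ch <- lapply(hc$merge[idx, ], node, parent_height = h)
    if (ch[[2]]$minleaf < ch[[1]]$minleaf) ch <- ch[c(2, 1)]
    list(text = paste0("(", ch[[1]]$text, ",", ch[[2]]$text, "):",
                       fmt(parent_height - h)),
         minleaf = min(ch[[1]]$minleaf, ch[[2]]$minleaf))
  }
  root_h <- hc$height[length(hc$height)]
  ch <- lapply(hc$merge[nrow(hc$merge), ], node, parent_height = root_h)
  if (ch[[2]]$minleaf < ch[[1]]$minleaf) ch <- ch[c(2, 1)]
  paste0("(", ch[[1]]$text, ",", ch[[2]]$text, ");")
}

#' Principal component analysis of clr-transformed compositions
#'
#' Standard PCA is misleading on raw closed data, so components are extracted
#' from the clr-transformed table. With `estimator = "classical"` the sample
#' covariance of the clr rows is eigen-decomposed; with `estimator = "mcd"`
#' the covariance and centre are the minimum-covariance-determinant robust
#' estimates computed in ilr coordinates and mapped back to clr space, which
#' prevents a minority of outlying profiles from rotating the components.
#' The closure constraint forces at least one zero eigenvalue in clr space.
#'
#' @param M strictly positive `n x D` matrix, `n > D` recommended.
#' @param estimator `"classical"` or `"mcd"`.
#' @param ... passed to [mcd_fit()] (e.g. `h`, `nstarts`).
#' @return A `clr_pca`: list with `eigenvalues`, `loadings` (clr-space, one
#'   column per component), `scores`, `var_explained`, `center` (clr),
#'   `estimator`, and for `"mcd"` the underlying `mcd` fit.
#' @export
pca_clr <- function(M, estimator = c("classical", "mcd"), ...) {
  estimator <- match.arg(estimator)
  if (any(M <= 0)) stop("apply zero_replace() first", call. = FALSE)
  lx <- log(M)
  cl <- lx - rowMeans(lx)
  D <- ncol(M)
  mcd <- NULL
  if (estimator == "classical") {
    ctr <- colMeans(cl)
    S <- stats::cov(cl)
  } else {
    V <- ilr_basis(D)
    Y <- cl %*% t(V)
    mcd <- mcd_fit(Y, ...)
    ctr <- drop(crossprod(V, mcd$location))
    S <- t(V) %*% mcd$scatter %*% V
  }
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  scores <- sweep(cl, 2, ctr) %*% e$vectors
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  loadings <- e$vectors
  dimnames(loadings) <- list(colnames(M), paste0("PC", seq_len(D)))
  structure(list(
    eigenvalues = vals,
    loadings = loadings,
    scores = scores,
    var_explained = vals / sum(vals),
    center = ctr,
    estimator = estimator,
    mcd = mcd
  ), class = "clr_pca")
}

#' @export
print.clr_pca <- function(x, ...) {
  cat("clr PCA (", x$estimator, " estimator)\n", sep = "")
  cat("  variance explained:",
      paste0(round(100 * x$var_explained, 1), "%", collapse = " "), "\n")
  invisible(x)
}

#' Minimum covariance determinant estimate of location and scatter
#'
#' Finds the subset of `h` observations whose sample covariance has the
#' smallest determinant and returns its (consistency-corrected) mean and
#' covariance, together with robust Mahalanobis distances and outlier flags.
#' For small samples (`n <= 20`) the search is exhaustive over all
#' `h`-subsets; otherwise a FAST-MCD search is used: random `(p+1)`-point
#' elemental starts, two concentration steps each (a concentration step
#' re-selects the `h` points closest in Mahalanobis distance and provably
#' never increases the determinant), and the best candidates iterated to
#' convergence.
#'
#' @param Y an `n x p` numeric matrix (e.g. ilr coordinates), `n > 2p`.
#' @param h subset size; default `floor((n + p + 1) / 2)` (maximal
#'   breakdown).
#' @param nstarts number of random elemental starts (default 500).
#' @param nbest number of candidates refined to convergence (default 10).
#' @param quantile chi-squared quantile for the outlier cutoff
#'   (default 0.975).
#' @param seed optional integer seed for the random starts.
#' @return An `mcd` object: list with `location`, `scatter`
#'   (consistency-corrected), `raw_scatter`, `best_subset`, `det`,
#'   `distances` (robust squared Mahalanobis), `cutoff`, `outlier` (logical),
#'   `h`, `method`.
#' @export
mcd_fit <- function(Y, h = NULL, nstarts = 500L, nbest = 10L,
                    quantile = 0.975, seed = NULL) {
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  if (n <= 2 * p) stop("need n > 2p observations", call. = FALSE)
  h <- h %||% floor((n + p + 1) / 2)
  if (h < floor((n + p + 1) / 2) || h > n) {
    stop("h must lie in [floor((n+p+1)/2), n]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  if (h == n) {
    best <- list(subset = seq_len(n), mu = colMeans(Y), S = stats::cov(Y))
    method <- "full-sample"
  } else if (n <= 20L) {
    best <- mcd_exhaustive(Y, h)
    method <- "exhaustive"
  } else {
    best <- mcd_fast(Y, h, nstarts, nbest)
    method <- "fast-mcd"
  }
  raw_S <- best$S
  dt <- det(raw_S)
  # Fisher consistency factor for the h/n-trimmed normal
  alpha <- h / n
  cc <- alpha / stats::pchisq(stats::qchisq(alpha, df = p), df = p + 2)
  S <- raw_S * cc
  d2 <- stats::mahalanobis(Y, best$mu, S)
  cutoff <- stats::qchisq(quantile, df = p)
  structure(list(
    location = best$mu, scatter = S, raw_scatter = raw_S,
    best_subset = sort(best$subset), det = dt,
    distances = d2, cutoff = cutoff, outlier = d2 > cutoff,
    h = h, method = method
  ), class = "mcd")
}

#' @export
print.mcd <- function(x, ...) {
  cat("MCD fit (", x$method, "), h = ", x$h, ", ",
      sum(x$outlier), " flagged outliers\n", sep = "")
  invisible(x)
}

subset_stats <- function(Y, idx) {
  list(subset = idx, mu = colMeans(Y[idx, , drop = FALSE]),
       S = stats::cov(Y[idx, , drop = FALSE]))
}

#' One concentration step of the MCD search
#'
#' Given a current subset estimate, selects the `h` observations with the
#' smallest Mahalanobis distances to it. The determinant of the covariance of
#' the new subset is never larger than that of the old one.
#'
#' @param Y data matrix.
#' @param st list with `mu` and `S` (current estimates).
#' @param h subset size.
#' @return Updated list (`subset`, `mu`, `S`).
#' @export
c_step <- function(Y, st, h) {
  d2 <- stats::mahalanobis(Y, st$mu, st$S)
  subset_stats(Y, order(d2)[seq_len(h)])
}

mcd_exhaustive <- function(Y, h) {
  subs <- utils::combn(nrow(Y), h, simplify = FALSE)
  best <- NULL; best_det <- Inf
  for (idx in subs) {
    st <- subset_stats(Y, idx)
    dt <- det(st$S)
    if (is.finite(dt) && dt < best_det) { best <- st; best_det <- dt }
  }
  if (is.null(best)) stop("all size-h subsets are singular", call. = FALSE)
  best
}

mcd_fast <- function(Y, h, nstarts, nbest) {
  n <- nrow(Y); p <- ncol(Y)
  cands <- vector("list", nstarts)
  dets <- rep(Inf, nstarts)
  for (k in seq_len(nstarts)) {
    idx <- sample.int(n, p + 1L)
    st <- subset_stats(Y, idx)
    # grow a singular elemental set until its covariance is invertible
    while (det(st$S) < .Machine$double.eps && length(idx) < n) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1L))
      st <- subset_stats(Y, idx)
    }
    if (det(st$S) < .Machine$double.eps) next
    st <- c_step(Y, st, h)
    st <- c_step(Y, st, h)
    cands[[k]] <- st
    dets[k] <- det(st$S)
  }
  if (all(!is.finite(dets))) stop("all starts singular", call. = FALSE)
  keep <- order(dets)[seq_len(min(nbest, sum(is.finite(dets))))]
  best <- NULL; best_det <- Inf
  for (k in keep) {
    st <- cands[[k]]
    repeat {
      dt_old <- det(st$S)
      st2 <- c_step(Y, st, h)
      dt_new <- det(st2$S)
      st <- st2
      if (dt_new >= dt_old - 1e-14 * max(1, abs(dt_old))) break
    }
    dt <- det(st$S)
    if (dt < best_det) { best <- st; best_det <- dt }
  }
  best
}

#' Flag outlying profiles from their layer compositions
#'
#' Convenience wrapper: ilr-transforms the composition table, runs
#' [mcd_fit()], and returns a per-profile table of robust distances and
#' flags.
#'
#' @param M strictly positive `n x D` composition matrix.
#' @param quantile chi-squared cutoff quantile (default 0.975).
#' @param ... passed to [mcd_fit()].
#' @return Data frame with `profile_id`, `robust_distance` (squared
#'   Mahalanobis), `outlier`.
#' @export
flag_outliers <- function(M, quantile = 0.975, ...) {
  Y <- ilr(M)
  fit <- mcd_fit(Y, quantile = quantile, ...)
  data.frame(
    profile_id = rownames(M) %||% as.character(seq_len(nrow(M))),
    robust_distance = fit$distances,
    outlier = fit$outlier,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
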