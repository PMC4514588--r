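test_that("the distance matrix is Aitchison and perturbation-invariant", {
  set.seed(31)
  M <- rand_comp_matrix(12, 5)
  M[3, ] <- M[7, ]                       # duplicate profiles
  rownames(M) <- sprintf("P%02d", 1:12)
  Dm <- distance_matrix(M)
  expect_true(isSymmetric(Dm))
  expect_equal(unname(diag(Dm)), rep(0, 12))
  expect_equal(Dm[3, 7], 0)
  # equals pairwise aitchison_dist and ilr Euclidean distance
  Y <- ilr(M)
  expect_equal(Dm, as.matrix(dist(Y)), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(Dm[1, 2], aitchison_dist(closure(M[1, ]), closure(M[2, ])),
               tolerance = 1e-12)
  p <- rand_comp(5)
  Mp <- t(apply(M, 1, function(r) unclass(perturb(closure(r), p))))
  expect_equal(distance_matrix(Mp), Dm, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("both clustering methods recover a planted two-blob partition", {
  tb <- make_fixture("two_blobs", n = 30, seed = 3)
  Dm <- distance_matrix(tb$comp)
  for (d in list(cluster_agglomerative(Dm), cluster_divisive(Dm))) {
    k <- cut_dendrogram(d, 2)
    agree <- max(mean((k == 1) == (tb$truth$block == 1)),
                 mean((k == 2) == (tb$truth$block == 1)))
    expect_equal(agree, 1)
  }
  # agglomerative average-linkage heights are monotone nondecreasing
  hc <- cluster_agglomerative(Dm)$hclust
  expect_true(!is.unsorted(hc$height))
})

test_that("clustering is invariant to input row order (up to leaf permutation)", {
  tb <- make_fixture("two_blobs", n = 16, seed = 9)
  Dm <- distance_matrix(tb$comp)
  perm <- sample(nrow(Dm))
  Dp <- Dm[perm, perm]
  nw1 <- dendrogram_to_newick(cluster_agglomerative(Dm))
  nw2 <- dendrogram_to_newick(cluster_agglomerative(Dp))
  expect_equal(nw1, nw2)   # lexicographic child order makes this byte-identical
})

test_that("Newick export round-trips through a standard parser", {
  skip_if_not_installed("ape")
  tb <- make_fixture("two_blobs", n = 10, seed = 4)
  Dm <- distance_matrix(tb$comp)
  d <- cluster_agglomerative(Dm)
  nw <- dendrogram_to_newick(d)
  phy <- ape::read.tree(text = nw)
  expect_equal(sort(phy$tip.label), sort(d$labels))
  expect_equal(ape::Ntip(phy), 10)
  # ultrametric: every leaf is at the same depth (root height of the tree)
  depths <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-8)
  expect_equal(max(depths), max(d$hclust$height), tolerance = 1e-8)
  # two leaves merged at height h sit at depth h/2 each... reserialize check
  nw2 <- dendrogram_to_newick(d)
  expect_identical(nw, nw2)
})

test_that("clr PCA has the closure-forced null direction and rank-1 data give PC1 share 1", {
  lt <- make_fixture("line_track", n = 12)
  p <- pca_clr(lt$comp)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-10)
  expect_lt(p$eigenvalues[2], 1e-12)
  set.seed(33)
  M <- rand_comp_matrix(40, 5)
  p <- pca_clr(M)
  expect_lt(p$eigenvalues[5], 1e-12)          # closure constraint
  expect_equal(sum(p$var_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  # scores in all D-1 retained components preserve Aitchison distances
  expect_equal(as.matrix(dist(p$scores[, 1:4])), distance_matrix(M),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("classical and robust PCA agree on clean data", {
  # h = 0.75n is the usual efficiency-oriented subset fraction; with
  # max-breakdown h the raw MCD eigenvectors are too noisy for a tight
  # agreement bound at any moderate n
  cl <- make_fixture("clean", n = 2000, seed = 1)
  M <- cl$truth$comp
  p1 <- pca_clr(M, "classical")
  p2 <- pca_clr(M, "mcd", h = 1500, seed = 1)
  ang <- acos(min(1, abs(sum(p1$loadings[, 1] * p2$loadings[, 1])))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("MCD: exhaustive small-n search, consistency on clean data, c-step monotone", {
  set.seed(35)
  Y <- matrix(rnorm(18 * 2), 18, 2)
  fit <- mcd_fit(Y)
  expect_equal(fit$method, "exhaustive")
  expect_equal(length(fit$best_subset), fit$h)
  # the exhaustive optimum beats (or ties) any random h-subset
  for (rep in 1:20) {
    idx <- sample(18, fit$h)
    expect_gte(det(cov(Y[idx, ])) + 1e-12, fit$det)
  }
  # clean multivariate normal: robust location close to the true mean
  set.seed(36)
  Y <- matrix(rnorm(500 * 3), 500, 3)
  fit <- mcd_fit(Y, seed = 36)
  # the raw half-sample MCD location has per-coordinate sampling sd ~ 0.11
  # at n = 500, p = 3 (Monte Carlo); bound = 3 of its standard errors
  expect_lt(max(abs(fit$location)), 0.33)
  expect_lt(mean(fit$outlier), 0.10)
  # scatter consistency: eigenvalues near 1 for unit covariance
  expect_lt(max(abs(eigen(fit$scatter)$values - 1)), 0.35)
  # concentration step never increases the determinant
  set.seed(37)
  st <- list(mu = colMeans(Y[1:50, ]), S = cov(Y[1:50, ]))
  for (k in 1:5) {
    st2 <- c_step(Y, st, h = 250)
    expect_lte(det(st2$S), det(cov(Y[1:50, ])) + 1e-12)
    expect_lte(det(c_step(Y, st2, 250)$S), det(st2$S) + 1e-12)
    st <- st2
  }
})

test_that("MCD flags a planted 25% outlier cluster and spares the clean points", {
  s <- sample_profiles(generator_params(n = 200), seed = 1)
  fl <- flag_outliers(s$truth$comp, seed = 1)
  tr <- s$truth$outlier
  expect_gte(mean(fl$outlier[tr]), 0.90)
  expect_lte(mean(fl$outlier[!tr]), 0.10)
})

test_that("MCD flags do not depend on the ilr basis", {
  s <- sample_profiles(generator_params(n = 120), seed = 11)
  M <- s$truth$comp
  B1 <- ilr_basis(5)
  B2 <- B1[, 5:1]
  f1 <- mcd_fit(ilr(M, B1), seed = 5)
  f2 <- mcd_fit(ilr(M, B2), seed = 5)
  expect_equal(f1$outlier, f2$outlier)
  expect_equal(f1$distances, f2$distances, tolerance = 1e-8)
})

test_that("MCD agrees with an independent implementation on the same data", {
  skip_if_not_installed("MASS")
  set.seed(38)
  Y <- rbind(matrix(rnorm(150 * 2), 150, 2),
             matrix(rnorm(50 * 2, mean = 6), 50, 2))
  h <- floor((200 + 2 + 1) / 2)
  fit <- mcd_fit(Y, h = h, seed = 38)
  ref <- MASS::cov.mcd(Y, quantile.used = h)
  # both searches should isolate the clean block; compare subset determinants
  expect_lt(abs(log(fit$det) - log(det(cov(Y[ref$best, ])))), 0.2)
  expect_lt(max(abs(fit$location - colMeans(Y[ref$best, ]))), 0.3)
})
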