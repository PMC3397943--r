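test_that("covariance matrix matches its closed forms", {
  set.seed(31)
  base <- matrix(rnorm(24, sd = 4), 8, 3)
  ident <- noisy_coordset(base, 4, 0)
  expect_true(all(covariance_matrix(ident) == 0))

  # n = 2 closed form with divisor n: C = (1/4) * outer(delta, delta)
  cs2 <- noisy_coordset(base, 2, 1.5)
  delta <- cs2$coords[1, ] - cs2$coords[2, ]
  expect_equal(covariance_matrix(cs2), outer(delta, delta) / 4,
               tolerance = 1e-12)

  # diagonal equals per-coordinate population variances
  cs <- noisy_coordset(base, 15, 0.8)
  v <- apply(cs$coords, 2, function(x) mean((x - mean(x))^2))
  expect_equal(diag(covariance_matrix(cs)), v, tolerance = 1e-12)
  C <- covariance_matrix(cs)
  expect_equal(C, t(C))
  expect_true(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) > -1e-9)
})

test_that("pca satisfies its spectral invariants", {
  set.seed(32)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  # rank-1 ensemble: all variance on one planted direction
  dir1 <- rnorm(30); dir1 <- dir1 / sqrt(sum(dir1^2))
  coords <- t(sapply(seq_len(12), function(i)
    as.numeric(t(base)) + rnorm(1, sd = 2) * dir1))
  cs1 <- new_coordset(as.character(1:10), coords)
  m1 <- pca_ensemble(cs1)
  expect_equal(m1$eigenvalues[1] / sum(m1$eigenvalues), 1, tolerance = 1e-9)

  cs <- noisy_coordset(base, 25, 0.6)
  m <- pca_ensemble(cs)
  # orthonormal modes, non-negative descending eigenvalues, trace identity
  expect_equal(crossprod(m$modes), diag(30), tolerance = 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-9))
  expect_true(all(m$eigenvalues >= 0))
  expect_equal(sum(m$eigenvalues), sum(diag(covariance_matrix(cs))),
               tolerance = 1e-6)
  # completeness: back-projection with all modes reproduces centered coords
  centered <- sweep(cs$coords, 2, m$mean)
  recon <- (centered %*% m$modes) %*% t(m$modes)
  expect_equal(recon, centered, tolerance = 1e-8)
})

test_that("pca recovers a planted 9:1 two-mode variance split", {
  set.seed(33)
  base <- as.numeric(t(matrix(rnorm(60, sd = 6), 20, 3)))
  d1 <- rnorm(60); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- rnorm(60); d2 <- d2 - sum(d2 * d1) * d1; d2 <- d2 / sqrt(sum(d2^2))
  n <- 100
  coords <- t(sapply(seq_len(n), function(i)
    base + rnorm(1, sd = 3) * d1 + rnorm(1, sd = 1) * d2))
  m <- pca_ensemble(new_coordset(as.character(1:20), coords))
  frac1 <- m$eigenvalues[1] / sum(m$eigenvalues)
  expect_gt(frac1, 0.88)
  expect_lt(frac1, 0.92)
  expect_error(pca_ensemble(new_coordset(as.character(1:20),
                                         coords[1, , drop = FALSE])),
               "at least 2")
})

test_that("projections reproduce eigenvalues and planted separations", {
  set.seed(34)
  sp <- synthetic_spec(n_residues = 50, n_per_state = c(15, 15),
                       amplitude = 2, sigma = 0.3, seed = 5)
  cs <- make_two_state_ensemble(sp)
  m <- pca_ensemble(cs)
  sc <- project_pca(m, cs, n_modes = 5)
  # training-set score variance equals eigenvalues (population variance)
  v <- apply(sc, 2, function(x) mean((x - mean(x))^2))
  expect_equal(unname(v), m$eigenvalues[1:5], tolerance = 1e-6)
  # mean structure projects to zero
  mean_cs <- new_coordset(cs$labels, rbind(m$mean, m$mean))
  expect_equal(max(abs(project_pca(m, mean_cs, 3))), 0, tolerance = 1e-8)
  # held-out members of each state separate along PC1
  sp2 <- synthetic_spec(n_residues = 50, n_per_state = c(10, 10),
                        amplitude = 2, sigma = 0.3, seed = 6)
  held <- make_two_state_ensemble(sp2)
  sc2 <- project_pca(m, held, n_modes = 1)
  expect_gt(abs(mean(sc2[held$state == "GTP", 1]) -
                mean(sc2[held$state == "GDP", 1])), 1)
  # label mismatch guards
  expect_error(project_pca(m, make_two_state_ensemble(
    synthetic_spec(n_residues = 40, n_per_state = c(2, 2), seed = 1))),
    "labels")
})

test_that("cumulative variance is monotone and complete", {
  set.seed(35)
  cs <- noisy_coordset(matrix(rnorm(24, sd = 3), 8, 3), 30, 0.5)
  m <- pca_ensemble(cs)
  cum <- vapply(1:24, cumulative_variance, numeric(1), model = m)
  expect_true(all(diff(cum) >= -1e-12))
  expect_equal(cum[24], 1, tolerance = 1e-9)
  expect_error(cumulative_variance(m, 0), "out of range")
  expect_error(cumulative_variance(m, 25), "out of range")
})

test_that("average-linkage clustering recovers planted blobs deterministically", {
  set.seed(36)
  # two distinct conformations (pairwise RMSD is superposition-based, so the
  # blobs must differ in shape, not merely by a rigid motion)
  baseA <- matrix(rnorm(30, sd = 3), 10, 3)
  baseB <- matrix(rnorm(30, sd = 3), 10, 3)
  coords <- rbind(
    t(sapply(1:6, function(i) as.numeric(t(baseA)) + rnorm(30, 0, 0.2))),
    t(sapply(1:4, function(i) as.numeric(t(baseB)) + rnorm(30, 0, 0.2))))
  cs <- new_coordset(as.character(1:10), coords)
  M <- pairwise_rmsd(cs)
  part <- cluster_rmsd(M, k = 2)
  # clusters ranked by population: the 6-member blob is cluster 1
  expect_equal(part$labels, rep(c(1L, 2L), c(6, 4)))
  expect_equal(part$sizes, c(6L, 4L))

  expect_equal(cluster_rmsd(M, k = 1)$labels, rep(1L, 10))
  expect_equal(sort(cluster_rmsd(M, k = 10)$labels), 1:10)
  expect_error(cluster_rmsd(M, k = 11), "exceeds")

  # permutation invariance up to relabeling
  perm <- sample(10)
  part2 <- cluster_rmsd(M[perm, perm], k = 2)
  expect_equal(length(unique(paste(part$labels[perm], part2$labels))), 2)
})

test_that("representatives are the exhaustive closest-to-average members", {
  set.seed(37)
  sp <- synthetic_spec(n_residues = 20, n_per_state = c(5, 5),
                       amplitude = 4, sigma = 0.4, seed = 8)
  cs <- make_two_state_ensemble(sp)
  M <- pairwise_rmsd(cs)
  part <- cluster_rmsd(M, k = 2)
  part <- select_representatives(cs, part)
  expect_length(part$representatives, 2)
  for (g in 1:2) {
    members <- which(part$labels == g)
    expect_true(part$representatives[g] %in% members)
    # brute-force oracle: fit members to the cluster mean, pick argmin RMSD
    X <- cs$coords[members, , drop = FALSE]
    for (i in seq_len(nrow(X)))
      X[i, ] <- as.numeric(t(superpose(matrix(X[i, ], ncol = 3, byrow = TRUE),
                                       matrix(X[1, ], ncol = 3, byrow = TRUE))$xyz))
    avg <- colMeans(X)
    for (i in seq_len(nrow(X)))
      X[i, ] <- as.numeric(t(superpose(matrix(X[i, ], ncol = 3, byrow = TRUE),
                                       matrix(avg, ncol = 3, byrow = TRUE))$xyz))
    avg <- colMeans(X)
    d <- vapply(seq_len(nrow(X)), function(i)
      superpose(matrix(X[i, ], ncol = 3, byrow = TRUE),
                matrix(avg, ncol = 3, byrow = TRUE))$rmsd, numeric(1))
    expect_equal(part$representatives[g], members[which.min(d)])
  }
  # singleton cluster is its own representative
  p1 <- cluster_rmsd(M, k = nrow(M))
  p1 <- select_representatives(cs, p1)
  expect_setequal(p1$representatives, seq_len(nrow(M)))
})

test_that("rmsf matches the isotropic-noise closed form and the trace identity", {
  set.seed(38)
  base <- matrix(rnorm(15, sd = 5), 5, 3)
  ident <- noisy_coordset(base, 6, 0)
  expect_true(all(rmsf_profile(ident)$rmsf == 0))

  # one residue jittered with sigma = 1 isotropic: RMSF -> sqrt(3)
  n <- 1000
  coords <- matrix(rep(as.numeric(t(base)), n), n, byrow = TRUE)
  coords[, 7:9] <- coords[, 7:9] + rnorm(3 * n)
  cs <- new_coordset(as.character(1:5), coords)
  prof <- rmsf_profile(cs)
  expect_equal(prof$rmsf[3], sqrt(3), tolerance = 0.05)
  expect_true(all(prof$rmsf[-3] == 0))
  # sum of squared RMSF equals the covariance trace
  expect_equal(sum(prof$rmsf^2), sum(diag(covariance_matrix(cs))),
               tolerance = 1e-9)
})

test_that("cross-correlation hits +/-1 extremes and a null near zero", {
  set.seed(39)
  base <- matrix(rnorm(12, sd = 5), 4, 3)
  n <- 40
  shift <- rnorm(n)
  coords <- t(sapply(seq_len(n), function(i) {
    x <- as.numeric(t(base))
    x[1:3] <- x[1:3] + shift[i] * c(1, 0, 0)   # residue 1
    x[4:6] <- x[4:6] + shift[i] * c(1, 0, 0)   # residue 2: identical motion
    x[7:9] <- x[7:9] - shift[i] * c(1, 0, 0)   # residue 3: opposite motion
    x                                           # residue 4: static
  }))
  cc <- cross_correlation(new_coordset(as.character(1:4), coords))
  expect_equal(cc[1, 2], 1, tolerance = 1e-9)
  expect_equal(cc[1, 3], -1, tolerance = 1e-9)
  expect_true(is.na(cc[1, 4]))  # zero fluctuation -> undefined
  expect_equal(cc, t(cc))

  # independent isotropic noise: off-diagonals within +/-0.05 of zero
  cs <- noisy_coordset(matrix(rnorm(30, sd = 5), 10, 3), 2000, 1)
  ccn <- cross_correlation(cs)
  expect_lt(max(abs(ccn[upper.tri(ccn)])), 0.05)
  expect_true(all(diag(ccn) == 1))

  # agreement with an independent implementation
  small <- noisy_coordset(matrix(rnorm(18, sd = 4), 6, 3), 25, 0.8)
  ref <- bio3d::dccm.xyz(small$coords)
  ours <- cross_correlation(small)
  expect_equal(unname(ours), unname(ref[seq_len(6), seq_len(6)]),
               tolerance = 1e-6)
})

test_that("cross-correlation is invariant under a joint rigid motion", {
  set.seed(40)
  cs <- noisy_coordset(matrix(rnorm(24, sd = 4), 8, 3), 30, 0.5)
  cc <- cross_correlation(cs)
  R <- random_rotation(); tr <- rnorm(3, sd = 10)
  moved <- cs
  for (i in seq_len(nrow(cs$coords))) {
    xyz <- matrix(cs$coords[i, ], ncol = 3, byrow = TRUE) %*% t(R)
    moved$coords[i, ] <- as.numeric(t(sweep(xyz, 2, tr, `+`)))
  }
  expect_equal(cross_correlation(moved), cc, tolerance = 1e-9)
})
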