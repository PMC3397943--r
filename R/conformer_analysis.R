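#' Coordinate covariance matrix of a superposed ensemble
#'
#' Entry (i, j) is the ensemble average of the coordinate deviations
#' \eqn{\langle (r_i - \langle r_i \rangle)(r_j - \langle r_j \rangle) \rangle}
#' over the n structures (population form, divisor n; multiply by
#' \code{n/(n-1)} for the sample form). The input must already share a common
#' frame (see \code{\link{superpose_ensemble}}) -- this is a documented
#' contract, not detectable from the matrix itself.
#'
#' @param cs A superposed \code{coordset} (>= 2 structures).
#' @return Symmetric positive semi-definite 3N x 3N matrix (Angstrom^2).
#' @export
covariance_matrix <- function(cs) {
  X <- cs$coords
  stopifnot(nrow(X) >= 2L)
  Xc <- sweep(X, 2, colMeans(X))
  crossprod(Xc) / nrow(X)
}

#' Principal component analysis of a coordinate ensemble
#'
#' Diagonalizes the coordinate covariance matrix. Eigenvalues are the
#' variances (Angstrom^2) along the corresponding orthonormal modes, sorted
#' descending. For reproducible projections each mode's largest-magnitude
#' component is made positive.
#'
#' @param cs A superposed \code{coordset}.
#' @return A \code{pca_model}: list with \code{mean} (3N vector), \code{modes}
#'   (3N x 3N orthonormal matrix, columns are modes), \code{eigenvalues},
#'   \code{N} (residue count) and \code{labels}.
#' @export
pca_ensemble <- function(cs) {
  if (nrow(cs$coords) < 2L) stop("PCA requires at least 2 structures")
  C <- covariance_matrix(cs)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(list(mean = colMeans(cs$coords), modes = vecs,
                 eigenvalues = vals, N = length(cs$labels),
                 labels = cs$labels),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  fr <- x$eigenvalues / sum(x$eigenvalues)
  cat("pca_model over", x$N, "residues;",
      sprintf("PC1 %.1f%%, PC1-2 %.1f%%, PC1-3 %.1f%% of variance\n",
              100 * fr[1], 100 * sum(fr[1:2]), 100 * sum(fr[1:3])))
  invisible(x)
}

#' Project conformers onto principal components
#'
#' Scores are dot products of mean-centered coordinates with the model's
#' modes, so the variance of the training set's scores along mode m equals
#' the m-th eigenvalue.
#'
#' @param model A \code{pca_model}.
#' @param cs A \code{coordset} with the model's label set (or supply
#'   \code{index_map}, positions of the model labels within \code{cs}).
#' @param n_modes Number of leading modes to project onto.
#' @param index_map Optional integer map from model residues to \code{cs}
#'   residues.
#' @return n x n_modes matrix of scores (Angstrom).
#' @export
project_pca <- function(model, cs, n_modes = 2, index_map = NULL) {
  X <- cs$coords
  if (!is.null(index_map)) {
    cols <- as.numeric(rbind(3 * index_map - 2, 3 * index_map - 1, 3 * index_map))
    X <- X[, cols, drop = FALSE]
  } else if (!identical(cs$labels, model$labels)) {
    stop("residue labels differ from the model's; supply index_map")
  }
  scores <- sweep(X, 2, model$mean) %*% model$modes[, seq_len(n_modes), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(n_modes))
  rownames(scores) <- cs$ids
  scores
}

#' Cumulative fraction of variance captured by the first k modes
#'
#' @param model A \code{pca_model}.
#' @param k Number of leading modes (1 <= k <= 3N).
#' @return Fraction in [0, 1].
#' @export
cumulative_variance <- function(model, k) {
  if (k < 1 || k > length(model$eigenvalues)) stop("k out of range")
  sum(model$eigenvalues[seq_len(k)]) / sum(model$eigenvalues)
}

#' Average-linkage clustering of a pairwise RMSD matrix
#'
#' Cuts the average-linkage dendrogram into exactly k groups and renumbers
#' clusters by decreasing population (ties broken by the lowest structure
#' index they contain).
#'
#' @param mat Symmetric pairwise RMSD matrix.
#' @param k Number of clusters (default 24, the conventional trajectory
#'   partition depth).
#' @return A \code{cluster_partition}: list with \code{labels} (per-structure
#'   cluster index in 1..k), \code{k}, \code{sizes} and \code{representatives}
#'   (NULL until \code{\link{select_representatives}} is applied).
#' @export
cluster_rmsd <- function(mat, k = 24) {
  n <- nrow(mat)
  if (k > n) stop("k exceeds the number of structures")
  if (k == n) {
    labels <- seq_len(n)
  } else {
    hc <- stats::hclust(stats::as.dist(mat), method = "average")
    raw <- stats::cutree(hc, k = k)
    sizes <- tabulate(raw, k)
    first <- vapply(seq_len(k), function(g) min(which(raw == g)), integer(1))
    rank <- order(-sizes, first)
    relabel <- integer(k); relabel[rank] <- seq_len(k)
    labels <- relabel[raw]
  }
  structure(list(labels = labels, k = k, sizes = tabulate(labels, k),
                 representatives = NULL),
            class = "cluster_partition")
}

#' Select the closest-to-average structure of each cluster
#'
#' Within each cluster the members are superposed onto the first member, the
#' coordinate-wise mean is taken, the members are re-fitted once onto that
#' mean, and the member with the smallest RMSD to the mean is chosen (ties go
#' to the lowest structure index).
#'
#' @param cs The \code{coordset} the partition was computed over.
#' @param part A \code{cluster_partition}.
#' @return The partition with \code{representatives} filled in (one structure
#'   index per cluster, ordered by cluster).
#' @export
select_representatives <- function(cs, part) {
  reps <- integer(part$k)
  for (g in seq_len(part$k)) {
    members <- which(part$labels == g)
    if (length(members) == 1L) { reps[g] <- members; next }
    X <- cs$coords[members, , drop = FALSE]
    for (i in seq_len(nrow(X)))
      X[i, ] <- as.numeric(t(superpose(.as_xyz_mat(X[i, ]),
                                       .as_xyz_mat(X[1, ]))$xyz))
    avg <- colMeans(X)
    d <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) {
      fit <- superpose(.as_xyz_mat(X[i, ]), .as_xyz_mat(avg))
      X[i, ] <- as.numeric(t(fit$xyz))
    }
    avg <- colMeans(X)
    for (i in seq_len(nrow(X)))
      d[i] <- superpose(.as_xyz_mat(X[i, ]), .as_xyz_mat(avg))$rmsd
    reps[g] <- members[which.min(d)] # which.min: ties -> lowest index
  }
  part$representatives <- reps
  part
}

#' Per-residue fluctuation and mean B-factor
#'
#' RMSF_i is the root mean square deviation of residue i's position from its
#' ensemble mean, over a superposed ensemble.
#'
#' @param cs A superposed \code{coordset}.
#' @return Data frame with columns \code{label}, \code{resno}, \code{rmsf}
#'   (Angstrom) and \code{mean_b} (Angstrom^2).
#' @export
rmsf_profile <- function(cs) {
  X <- sweep(cs$coords, 2, colMeans(cs$coords))
  sq <- colMeans(X^2)
  idx <- rep(seq_along(cs$labels), each = 3L)
  rmsf <- sqrt(as.numeric(tapply(sq, idx, sum)))
  data.frame(label = cs$labels, resno = cs$resno, rmsf = rmsf,
             mean_b = colMeans(cs$bfactors), stringsAsFactors = FALSE)
}

#' Residue-residue cross-correlation map
#'
#' Normalized covariance of C-alpha displacement vectors:
#' \eqn{c_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#' \sqrt{\langle |\Delta r_i|^2 \rangle \langle |\Delta r_j|^2 \rangle}}.
#' Fully correlated motion gives +1, anti-correlated -1. Residues with zero
#' fluctuation yield \code{NA} rows/columns.
#'
#' @param cs A superposed \code{coordset} with >= 3 members.
#' @return Symmetric N x N matrix in [-1, 1] with unit diagonal.
#' @export
cross_correlation <- function(cs) {
  stopifnot(nrow(cs$coords) >= 3L)
  Xc <- sweep(cs$coords, 2, colMeans(cs$coords))
  n3 <- ncol(Xc)
  ix <- seq(1, n3, by = 3)
  S <- (crossprod(Xc[, ix]) + crossprod(Xc[, ix + 1]) +
        crossprod(Xc[, ix + 2])) / nrow(Xc)
  v <- diag(S)
  denom <- sqrt(outer(v, v))
  out <- S / denom
  out[denom == 0] <- NA_real_
  diag(out)[v > 0] <- 1
  dimnames(out) <- list(cs$labels, cs$labels)
  out
}
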