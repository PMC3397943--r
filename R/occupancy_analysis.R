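#' Per-residue probe occupancy over an ensemble
#'
#' The occupancy of a residue is the fraction of structures in which it
#' contacts any probe: the summed binary contact count normalized by the
#' number of structures. 1 means a proximal binding site exists in every
#' structure of the set, 0 means complete absence.
#'
#' @param contacts List of contact vectors (from
#'   \code{\link{residue_contacts}}) or a binary structures x residues matrix.
#' @param state State label of the set (annotation only).
#' @return An \code{occupancy_profile}: list with \code{occupancy} (named,
#'   in [0, 1]), \code{n_structures}, \code{state} and the retained binary
#'   \code{contact_matrix}.
#' @export
occupancy <- function(contacts, state = "ALL") {
  M <- if (is.matrix(contacts)) contacts else {
    labs <- lapply(contacts, names)
    if (!all(vapply(labs, identical, logical(1), labs[[1]])))
      stop("contact vectors carry inconsistent residue labels")
    do.call(rbind, contacts)
  }
  stopifnot(nrow(M) >= 1L, all(M %in% c(0L, 1L)))
  structure(list(occupancy = colMeans(M), n_structures = nrow(M),
                 state = state, contact_matrix = M),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("occupancy_profile [", x$state, "]:", x$n_structures, "structures,",
      length(x$occupancy), "residues,",
      sum(x$occupancy > 0), "contacted\n")
  invisible(x)
}

#' State-differential probe occupancy
#'
#' Compares per-residue occupancy between two state-labeled sub-ensembles.
#' \code{method = "fisher"} runs a two-sided exact test on the 2x2 table of
#' contact counts versus structure counts; \code{method = "permutation"}
#' builds a null for |delta occupancy| from random relabelings of structures
#' across the two sets, with p = (1 + #(null >= observed)) / (1 + n_perm).
#' Residues with p strictly below 0.05 are flagged significant. A
#' Benjamini-Hochberg adjusted column is included for convenience but does
#' not drive the flag.
#'
#' @param profile_a,profile_b \code{occupancy_profile} objects with retained
#'   contact matrices over common residue labels.
#' @param method "fisher" (default; exact, deterministic) or "permutation".
#' @param n_perm Number of permutations (permutation method).
#' @param seed Seed for the permutation null (ignored by fisher).
#' @param alpha Significance level (default 0.05, strict).
#' @return Data frame with \code{label}, \code{occupancy_a},
#'   \code{occupancy_b}, \code{delta}, \code{p}, \code{p_bh},
#'   \code{significant}.
#' @export
differential_occupancy <- function(profile_a, profile_b,
                                   method = c("fisher", "permutation"),
                                   n_perm = 2000, seed = NULL, alpha = 0.05) {
  method <- match.arg(method)
  A <- profile_a$contact_matrix
  B <- profile_b$contact_matrix
  if (!identical(colnames(A), colnames(B)))
    stop("profiles cover different residue labels")
  nA <- nrow(A); nB <- nrow(B)
  if (nA == 0L || nB == 0L) stop("a state has zero structures")
  occA <- colMeans(A); occB <- colMeans(B)
  delta <- occA - occB
  if (method == "fisher") {
    a <- colSums(A); b <- colSums(B)
    p <- vapply(seq_along(a), function(i) {
      stats::fisher.test(matrix(c(a[i], nA - a[i], b[i], nB - b[i]), 2))$p.value
    }, numeric(1))
  } else {
    if (!is.null(seed)) set.seed(seed)
    M <- rbind(A, B)
    obs <- abs(delta)
    exceed <- integer(ncol(M))
    for (r in seq_len(n_perm)) {
      idx <- sample.int(nA + nB, nA)
      d <- abs(colMeans(M[idx, , drop = FALSE]) -
               colMeans(M[-idx, , drop = FALSE]))
      exceed <- exceed + (d >= obs - 1e-12)
    }
    p <- (1 + exceed) / (1 + n_perm)
  }
  labels <- colnames(A)
  if (is.null(labels)) labels <- names(profile_a$occupancy)
  if (is.null(labels)) labels <- as.character(seq_along(occA))
  data.frame(label = labels, occupancy_a = unname(occA),
             occupancy_b = unname(occB), delta = unname(delta),
             p = unname(p), p_bh = unname(stats::p.adjust(p, "BH")),
             significant = unname(p) < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation between two occupancy profiles
#'
#' @param profile_a,profile_b \code{occupancy_profile} objects over common
#'   labels.
#' @param subset Optional character vector of residue labels to restrict to.
#' @return Pearson r in [-1, 1]; \code{NA} with a warning when either profile
#'   is constant on the subset.
#' @export
profile_correlation <- function(profile_a, profile_b, subset = NULL) {
  x <- profile_a$occupancy
  y <- profile_b$occupancy
  labs <- intersect(names(x), names(y))
  if (!is.null(subset)) labs <- intersect(labs, subset)
  x <- x[labs]; y <- y[labs]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant occupancy profile: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Residues contacted exclusively in one of two sets
#'
#' @param profile_a,profile_b \code{occupancy_profile} objects over common
#'   labels.
#' @return List with \code{only_a} (occupancy > 0 in A, = 0 in B) and
#'   \code{only_b}.
#' @export
occupancy_set_difference <- function(profile_a, profile_b) {
  x <- profile_a$occupancy
  y <- profile_b$occupancy[names(x)]
  list(only_a = names(x)[x > 0 & y == 0],
       only_b = names(x)[y > 0 & x == 0])
}

#' Write occupancy into the B-factor column of a PDB copy
#'
#' For visualization in any molecular viewer: every atom of a residue gets
#' that residue's occupancy (scaled by 100) as its B-factor.
#'
#' @param s The \code{structure3d} to annotate.
#' @param profile An \code{occupancy_profile} (labels = resno + insertion).
#' @param file Output PDB path.
#' @return The path, invisibly.
#' @export
write_occupancy_pdb <- function(s, profile, file) {
  out <- s
  lab <- paste0(out$atoms$resno, out$atoms$ins)
  occ <- profile$occupancy[lab]
  occ[is.na(occ)] <- 0
  out$atoms$b <- round(100 * as.numeric(occ), 2)
  write_structure(out, file)
}
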