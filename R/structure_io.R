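#' Read a protein chain from a PDB file
#'
#' Parses a standard PDB coordinate file (via \code{bio3d::read.pdb}) and
#' returns the heavy atoms of one chain together with the set of HET residue
#' codes present on that chain (nucleotides, ions, waters, ...). Hydrogens are
#' dropped everywhere in this package; alternate locations are resolved to the
#' highest-occupancy conformer, ties broken by file order.
#'
#' @param file Path to a PDB file.
#' @param chain Chain identifier. May be omitted when the file holds a single
#'   chain.
#' @param id Identifier stored on the returned object; defaults to
#'   \code{basename(file)} plus the chain.
#' @return An object of class \code{structure3d}: a list with elements
#'   \code{id}, \code{atoms} (data frame with columns \code{elety},
#'   \code{elem}, \code{resid}, \code{resno}, \code{ins}, \code{chain},
#'   \code{x}, \code{y}, \code{z}, \code{b}, \code{o}, \code{het}) and
#'   \code{het_codes}.
#' @export
read_structure <- function(file, chain = NULL, id = NULL) {
  .check_coordinate_lines(file)
  pdb <- bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  chains <- unique(at$chain)
  chains[is.na(chains)] <- " "
  at$chain[is.na(at$chain)] <- " "
  if (is.null(chain)) {
    if (length(unique(chains)) > 1L)
      stop("multiple chains present (", paste(sort(unique(chains)), collapse = ", "),
           "); supply `chain`")
    chain <- chains[1L]
  }
  if (!chain %in% at$chain)
    stop("chain '", chain, "' not found; available chains: ",
         paste(sort(unique(at$chain)), collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]

  elem <- .atom_element(at$elesy, at$elety)
  keep <- !(elem %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]

  ins <- at$insert
  ins[is.na(ins)] <- ""
  atoms <- data.frame(
    elety = at$elety, elem = elem, resid = at$resid,
    resno = at$resno, ins = ins, chain = at$chain,
    x = at$x, y = at$y, z = at$z,
    b = ifelse(is.na(at$b), 0, at$b),
    o = ifelse(is.na(at$o), 1, at$o),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  alt <- at$alt
  alt[is.na(alt)] <- ""
  atoms <- .resolve_altloc(atoms, alt)

  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in chain '", chain, "'")

  if (is.null(id)) id <- paste0(basename(file), "_", chain)
  structure(
    list(id = id, atoms = atoms,
         het_codes = unique(atoms$resid[atoms$het])),
    class = "structure3d"
  )
}

# Scan raw ATOM/HETATM records so a malformed coordinate field is reported
# with its line number (read.pdb is silently tolerant).
.check_coordinate_lines <- function(file) {
  lines <- readLines(file, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(fields)))))
      stop("unparsable coordinate record at line ", i, ": ", lines[i])
  }
  invisible(TRUE)
}

.atom_element <- function(elesy, elety) {
  elem <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- elem == ""
  if (any(miss)) {
    # derive from atom name: strip digits, take leading character(s)
    nm <- gsub("[0-9']", "", toupper(trimws(elety[miss])))
    elem[miss] <- substr(nm, 1, 1)
  }
  elem
}

.resolve_altloc <- function(atoms, alt) {
  if (all(alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$resid, atoms$elety)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[alt != ""])) {
    rows <- which(key == k)
    if (length(rows) < 2L) next
    best <- rows[which.max(atoms$o[rows])] # which.max: ties -> first in file
    keep[setdiff(rows, best)] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Write a structure to a PDB file
#'
#' @param s A \code{structure3d} object.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_structure <- function(s, file) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = a$chain, insert = ifelse(a$ins == "", NA, a$ins),
    o = a$o, b = a$b, elesy = a$elem
  )
  invisible(file)
}

#' Default mapping from HET codes to nucleotide states
#'
#' GTP and its non-hydrolysable analogs map to the active state; GDP to the
#' inactive state. Overridable wherever a \code{ligand_map} is accepted.
#' @return Named character vector (HET code -> state label).
#' @export
default_ligand_map <- function() {
  c(GTP = "GTP", GNP = "GTP", GSP = "GTP", GCP = "GTP", GDP = "GDP")
}

#' Classify the nucleotide state of a structure
#'
#' Pure function of the structure's HET codes and the ligand map: returns
#' \code{"GTP"} or \code{"GDP"} when codes of exactly one class are present,
#' \code{"APO"} when none are, and \code{"UNKNOWN"} when both classes occur.
#'
#' @param s A \code{structure3d} object.
#' @param ligand_map Named character vector mapping HET codes to state labels;
#'   defaults to \code{\link{default_ligand_map}}.
#' @return One of \code{"GTP"}, \code{"GDP"}, \code{"APO"}, \code{"UNKNOWN"}.
#' @export
classify_nucleotide_state <- function(s, ligand_map = default_ligand_map()) {
  codes <- if (inherits(s, "structure3d")) s$het_codes else as.character(s)
  states <- unique(unname(ligand_map[intersect(codes, names(ligand_map))]))
  if (length(states) == 0L) return("APO")
  if (length(states) > 1L) return("UNKNOWN")
  states
}

#' Build an aligned C-alpha coordinate set from an ensemble
#'
#' The shared label set is the intersection of residues having a C-alpha in
#' every member (optionally clipped to \code{residue_range}), ordered by
#' residue number then insertion code. Coordinates are returned unsuperposed;
#' see \code{\link{superpose_ensemble}}.
#'
#' @param structures List of \code{structure3d} objects (>= 2).
#' @param residue_range Optional numeric length-2 vector of residue numbers
#'   (inclusive) to clip the shared set to.
#' @param states Optional character vector of per-structure state labels; when
#'   absent, \code{\link{classify_nucleotide_state}} is applied.
#' @return A \code{coordset}: list with \code{labels} (character),
#'   \code{resno} (numeric), \code{coords} (n_structures x 3N matrix, xyz
#'   interleaved), \code{state}, \code{bfactors} (n_structures x N), \code{ids}.
#' @export
extract_calpha <- function(structures, residue_range = NULL, states = NULL) {
  stopifnot(length(structures) >= 2L)
  ca_tabs <- lapply(structures, function(s) {
    a <- s$atoms
    ca <- a[a$elety == "CA" & !a$het, , drop = FALSE]
    ca$key <- paste0(ca$resno, ca$ins)
    ca[!duplicated(ca$key), , drop = FALSE]
  })
  shared <- Reduce(intersect, lapply(ca_tabs, `[[`, "key"))
  if (!is.null(residue_range)) {
    resno0 <- ca_tabs[[1]]$resno[match(shared, ca_tabs[[1]]$key)]
    shared <- shared[resno0 >= residue_range[1] & resno0 <= residue_range[2]]
  }
  if (length(shared) == 0L) stop("no shared C-alpha positions across the ensemble")
  resno <- ca_tabs[[1]]$resno[match(shared, ca_tabs[[1]]$key)]
  ins <- ca_tabs[[1]]$ins[match(shared, ca_tabs[[1]]$key)]
  ord <- order(resno, ins)
  shared <- shared[ord]
  resno <- resno[ord]

  n <- length(structures)
  N <- length(shared)
  coords <- matrix(NA_real_, n, 3L * N)
  bf <- matrix(NA_real_, n, N)
  for (i in seq_len(n)) {
    tab <- ca_tabs[[i]][match(shared, ca_tabs[[i]]$key), , drop = FALSE]
    coords[i, ] <- as.numeric(t(as.matrix(tab[, c("x", "y", "z")])))
    bf[i, ] <- tab$b
  }
  if (is.null(states))
    states <- vapply(structures, classify_nucleotide_state, character(1))
  new_coordset(labels = shared, resno = resno, coords = coords,
               state = states, bfactors = bf,
               ids = vapply(structures, `[[`, character(1), "id"))
}

#' Construct a coordset
#'
#' Low-level constructor; checks the type invariants (consistent dimensions,
#' finite coordinates).
#' @param labels Character residue labels, length N.
#' @param coords n x 3N numeric matrix, xyz interleaved per residue.
#' @param state Per-structure state labels (recycled if length 1).
#' @param bfactors Optional n x N matrix.
#' @param resno Optional numeric residue numbers (defaults to parsed labels).
#' @param ids Optional per-structure identifiers.
#' @return A \code{coordset} object.
#' @export
new_coordset <- function(labels, coords, state = "UNKNOWN", bfactors = NULL,
                         resno = NULL, ids = NULL) {
  coords <- as.matrix(coords)
  N <- length(labels)
  stopifnot(ncol(coords) == 3L * N, all(is.finite(coords)))
  n <- nrow(coords)
  state <- rep_len(as.character(state), n)
  if (is.null(bfactors)) bfactors <- matrix(0, n, N)
  if (is.null(resno)) {
    resno <- suppressWarnings(as.numeric(gsub("[^0-9-]", "", labels)))
    if (any(is.na(resno))) resno <- seq_len(N)
  }
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  structure(list(labels = as.character(labels), resno = resno, coords = coords,
                 state = state, bfactors = bfactors, ids = ids),
            class = "coordset")
}

#' @export
print.coordset <- function(x, ...) {
  cat("coordset:", nrow(x$coords), "structures x", length(x$labels),
      "residues; states:", paste(names(table(x$state)), table(x$state),
                                 sep = "=", collapse = " "), "\n")
  invisible(x)
}

.as_xyz_mat <- function(x) {
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1) and translation minimizing the
#' RMSD between \code{mobile} and \code{reference} over the \code{core}
#' positions, and applies it to all of \code{mobile}.
#'
#' @param mobile,reference N x 3 coordinate matrices (or interleaved 3N
#'   vectors).
#' @param core Integer indices of positions used for the fit (default: all).
#' @return List with \code{xyz} (transformed mobile, N x 3), \code{rmsd}
#'   (over the core, in Angstrom), \code{R} (rotation), \code{t} (translation).
#' @export
superpose <- function(mobile, reference, core = NULL) {
  M <- .as_xyz_mat(mobile)
  Rf <- .as_xyz_mat(reference)
  stopifnot(nrow(M) == nrow(Rf))
  if (is.null(core)) core <- seq_len(nrow(M))
  if (length(core) < 3L) stop("need at least 3 core positions")
  Mc <- M[core, , drop = FALSE]
  Rc <- Rf[core, , drop = FALSE]
  mm <- colMeans(Mc); rm <- colMeans(Rc)
  X <- sweep(Mc, 2, mm); Y <- sweep(Rc, 2, rm)
  # degenerate cores (coincident or collinear points) leave the rotation
  # under-determined
  if (svd(Y, nu = 0, nv = 0)$d[2] < 1e-8 || svd(X, nu = 0, nv = 0)$d[2] < 1e-8)
    stop("degenerate core: positions are collinear or coincident")
  H <- crossprod(X, Y)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  A <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- sweep(sweep(M, 2, mm) %*% A, 2, rm, `+`)
  rmsd <- sqrt(mean(rowSums((fitted[core, , drop = FALSE] - Rc)^2)))
  list(xyz = fitted, rmsd = rmsd, R = A, t = rm - as.numeric(mm %*% A))
}

#' RMSD between two coordinate sets after optimal superposition
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(mobile, reference, core = NULL)
  superpose(mobile, reference, core)$rmsd

#' Superpose an ensemble onto its mean structure
#'
#' Members are fitted to the first member, then iteratively re-fitted to the
#' ensemble mean until the mean converges. With \code{refine_core = TRUE} an
#' iterated-core refinement additionally excludes the highest-variance
#' positions from the fit (10\% per round, never below \code{min_core_frac})
#' and re-fits until the core stabilizes.
#'
#' @param cs A \code{coordset}.
#' @param core Optional integer indices of fit positions (default all).
#' @param refine_core Logical; iterated-core refinement (off by default).
#' @param min_core_frac Smallest core size as a fraction of N.
#' @param max_iter,tol Convergence controls on the mean structure.
#' @return The superposed \code{coordset}; the fit core used is stored in
#'   attribute \code{"core"}.
#' @export
superpose_ensemble <- function(cs, core = NULL, refine_core = FALSE,
                               min_core_frac = 0.5, max_iter = 20, tol = 1e-6) {
  X <- cs$coords
  N <- length(cs$labels)
  if (is.null(core)) core <- seq_len(N)
  fit_all <- function(X, ref, core) {
    t(apply(X, 1, function(v) {
      as.numeric(t(superpose(.as_xyz_mat(v), .as_xyz_mat(ref), core)$xyz))
    }))
  }
  ref <- X[1, ]
  for (it in seq_len(max_iter)) {
    X <- fit_all(X, ref, core)
    new_ref <- colMeans(X)
    if (sqrt(mean((new_ref - ref)^2)) < tol) { ref <- new_ref; break }
    ref <- new_ref
  }
  if (refine_core) {
    repeat {
      v <- .position_variance(X)
      keep <- max(ceiling(length(core) * 0.9), ceiling(N * min_core_frac))
      if (keep >= length(core)) break
      new_core <- core[order(v[core])][seq_len(keep)]
      new_core <- sort(new_core)
      X <- fit_all(X, colMeans(X), new_core)
      if (identical(new_core, core)) break
      core <- new_core
      if (length(core) <= ceiling(N * min_core_frac)) break
    }
  }
  out <- cs
  out$coords <- X
  attr(out, "core") <- core
  out
}

.position_variance <- function(X) {
  C <- sweep(X, 2, colMeans(X))
  per_coord <- colMeans(C^2)
  idx <- rep(seq_len(ncol(X) / 3L), each = 3L)
  as.numeric(tapply(per_coord, idx, sum))
}

#' Pairwise RMSD matrix over an ensemble
#'
#' Each entry is computed with a fresh optimal superposition of the pair.
#'
#' @param cs A \code{coordset}.
#' @return Symmetric n x n matrix of RMSD values (Angstrom), zero diagonal.
#' @export
pairwise_rmsd <- function(cs) {
  X <- cs$coords
  n <- nrow(X)
  M <- matrix(0, n, n, dimnames = list(cs$ids, cs$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- superpose(.as_xyz_mat(X[i, ]), .as_xyz_mat(X[j, ]))$rmsd
    M[i, j] <- M[j, i] <- r
  }
  M
}

#' Read an ensemble manifest and ingest the listed structures
#'
#' The manifest is delimited text with columns \code{id}, \code{file},
#' \code{chain} and optionally \code{state}; relative paths are resolved
#' against the manifest's directory.
#'
#' @param manifest Path to the manifest file.
#' @param sep Field separator (default tab, falls back to comma).
#' @return List with \code{structures} (list of \code{structure3d}) and
#'   \code{states} (character vector).
#' @export
read_ensemble_manifest <- function(manifest, sep = "\t") {
  tab <- utils::read.table(manifest, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 1L)
    tab <- utils::read.table(manifest, header = TRUE, sep = ",",
                             stringsAsFactors = FALSE)
  stopifnot(all(c("id", "file", "chain") %in% names(tab)))
  dir <- dirname(manifest)
  structures <- lapply(seq_len(nrow(tab)), function(i) {
    f <- tab$file[i]
    if (!file.exists(f)) f <- file.path(dir, f)
    read_structure(f, chain = tab$chain[i], id = tab$id[i])
  })
  states <- if ("state" %in% names(tab)) tab$state
    else vapply(structures, classify_nucleotide_state, character(1))
  list(structures = structures, states = states)
}
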