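#' Construct a probe set
#'
#' @param structure_id Identifier of the structure the probes belong to.
#' @param probes List of probes, each a list with \code{type} (label),
#'   \code{cluster} (id) and \code{coords} (heavy-atom n x 3 matrix).
#' @return A \code{probe_set} object.
#' @export
new_probe_set <- function(structure_id, probes) {
  for (p in probes) {
    stopifnot(is.matrix(p$coords), ncol(p$coords) == 3L,
              nrow(p$coords) >= 1L, all(is.finite(p$coords)))
  }
  structure(list(structure_id = structure_id, probes = probes),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat("probe_set for", x$structure_id, "with", length(x$probes), "probes\n")
  invisible(x)
}

#' Read fragment-probe poses from a multi-model PDB-style file
#'
#' Each MODEL block becomes one probe (files without MODEL records are split
#' on residue-number blocks). Hydrogens are dropped; the cluster id is the
#' model number. Atom counts may differ between models, as is typical for
#' mapping-tool outputs.
#'
#' @param file Path to the probe file.
#' @param structure_id Identifier of the mapped structure.
#' @param allow_empty Return an empty probe set instead of erroring when the
#'   file holds no probe heavy atoms (mapping tools emit empty files for
#'   structures without hits).
#' @return A \code{probe_set}.
#' @export
read_probe_poses <- function(file, structure_id, allow_empty = FALSE) {
  lines <- readLines(file, warn = FALSE)
  model_no <- 0L
  current <- 0L
  recs <- list()
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (grepl("^MODEL", l)) {
      model_no <- suppressWarnings(as.integer(substr(l, 11, 14)))
      if (is.na(model_no)) model_no <- current + 1L
      current <- model_no
    } else if (grepl("^(ATOM  |HETATM)", l)) {
      xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                           substr(l, 39, 46),
                                           substr(l, 47, 54))))
      if (any(is.na(xyz)))
        stop("unparsable coordinate record at line ", i, ": ", l)
      elem <- toupper(trimws(substr(l, 77, 78)))
      name <- trimws(substr(l, 13, 16))
      if (elem == "") elem <- substr(gsub("[0-9']", "", toupper(name)), 1, 1)
      recs[[length(recs) + 1L]] <- list(
        model = if (current == 0L) NA_integer_ else current,
        resno = suppressWarnings(as.integer(substr(l, 23, 26))),
        resid = trimws(substr(l, 18, 20)),
        elem = elem, xyz = xyz)
    }
  }
  recs <- Filter(function(r) !(r$elem %in% c("H", "D")), recs)
  if (length(recs) == 0L) {
    if (allow_empty) return(new_probe_set(structure_id, list()))
    stop("no probe heavy atoms found in ", file)
  }
  grp <- vapply(recs, function(r)
    if (is.na(r$model)) paste0("r", r$resno) else paste0("m", r$model),
    character(1))
  probes <- lapply(split(seq_along(recs), factor(grp, levels = unique(grp))),
    function(idx) {
      list(type = recs[[idx[1]]]$resid,
           cluster = recs[[idx[1]]]$model,
           coords = do.call(rbind, lapply(recs[idx], `[[`, "xyz")))
    })
  names(probes) <- NULL
  new_probe_set(structure_id, probes)
}

#' Write probe poses as a multi-model PDB-style file
#'
#' @param ps A \code{probe_set}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_probe_poses <- function(ps, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(ps$probes)) {
    p <- ps$probes[[k]]
    writeLines(sprintf("MODEL %8d", k), con)
    for (i in seq_len(nrow(p$coords))) {
      writeLines(sprintf(
        "HETATM%5d  C%-2d %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i %% 100, substr(p$type, 1, 3), k,
        p$coords[i, 1], p$coords[i, 2], p$coords[i, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  invisible(file)
}

#' Geometric pseudo-probe scan
#'
#' Places a Cartesian grid over the structure, keeps points that hug the
#' surface (distance to the nearest protein heavy atom within
#' [2.5 Angstrom, \code{shell}]) and are sheltered from solvent (at least
#' \code{burial} protein heavy atoms within 8 Angstrom), then groups retained
#' points into pseudo-probes by 6-neighbor connected components. Components
#' smaller than 3 points are discarded. Entirely deterministic and invariant
#' to atom order.
#'
#' @param s A \code{structure3d}.
#' @param spacing Grid spacing in Angstrom (> 0; default 1.0).
#' @param shell Maximum distance to the protein surface (default 4.5).
#' @param burial Minimum number of heavy atoms within 8 Angstrom (default 50).
#' @return A \code{probe_set} of pseudo-probes (possibly empty).
#' @export
geometric_probe_scan <- function(s, spacing = 1.0, shell = 4.5, burial = 50) {
  stopifnot(spacing > 0)
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min) - shell
  hi <- apply(xyz, 2, max) + shell
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  # chunked distance evaluation keeps memory bounded
  keep <- logical(nrow(grid))
  dmin <- numeric(nrow(grid))
  n8 <- integer(nrow(grid))
  chunk <- 20000L
  for (start in seq(1L, nrow(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(grid))
    d2 <- outer(rowSums(grid[idx, , drop = FALSE]^2), rowSums(xyz^2), `+`) -
      2 * grid[idx, , drop = FALSE] %*% t(xyz)
    d2[d2 < 0] <- 0
    dmin[idx] <- sqrt(apply(d2, 1, min))
    n8[idx] <- rowSums(d2 <= 64)
  }
  keep <- dmin >= 2.5 & dmin <= shell & n8 >= burial
  if (!any(keep)) return(new_probe_set(s$id, list()))
  pts <- grid[keep, , drop = FALSE]
  comp <- .connected_components(pts, spacing)
  probes <- lapply(split(seq_len(nrow(pts)), comp), function(idx) {
    if (length(idx) < 3L) return(NULL)
    list(type = "PSE", cluster = NA_integer_,
         coords = pts[idx, , drop = FALSE])
  })
  probes <- Filter(Negate(is.null), probes)
  names(probes) <- NULL
  # order components by size then position for determinism
  if (length(probes) > 1L) {
    key <- vapply(probes, function(p)
      sprintf("%06d_%012.3f", 1e6 - nrow(p$coords), sum(p$coords)), character(1))
    probes <- probes[order(key)]
  }
  for (k in seq_along(probes)) probes[[k]]$cluster <- k
  new_probe_set(s$id, probes)
}

# 6-neighbor connected components on grid points via integer lattice keys
.connected_components <- function(pts, spacing) {
  ijk <- round(sweep(pts, 2, apply(pts, 2, min)) / spacing)
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3])
  lookup <- stats::setNames(seq_len(nrow(pts)), key)
  comp <- integer(nrow(pts))
  cur <- 0L
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (i in seq_len(nrow(pts))) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      nb_keys <- paste(ijk[p, 1] + offsets[, 1], ijk[p, 2] + offsets[, 2],
                       ijk[p, 3] + offsets[, 3])
      nb <- lookup[nb_keys]
      nb <- nb[!is.na(nb)]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Residue-probe contact indicator
#'
#' A residue is in contact when any of its heavy atoms lies strictly closer
#' than \code{cutoff} to any probe heavy atom (default 5.0 Angstrom). The
#' indicator is binary per residue per structure, regardless of how many
#' probes are touched.
#'
#' @param s A \code{structure3d}.
#' @param ps A \code{probe_set} (may be empty: all-zero vector).
#' @param cutoff Contact cutoff in Angstrom (> 0; strict inequality).
#' @param labels Residue labels indexing the returned vector; defaults to the
#'   structure's polymer residues (resno + insertion code).
#' @return Named integer vector of 0/1 contact indicators.
#' @export
residue_contacts <- function(s, ps, cutoff = 5.0, labels = NULL) {
  stopifnot(cutoff > 0)
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  lab_atom <- paste0(a$resno, a$ins)
  if (is.null(labels)) labels <- unique(lab_atom)
  out <- stats::setNames(integer(length(labels)), labels)
  if (length(ps$probes) == 0L) return(out)
  P <- do.call(rbind, lapply(ps$probes, `[[`, "coords"))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(P^2), `+`) - 2 * xyz %*% t(P)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  res_min <- tapply(mind, lab_atom, min)
  hit <- names(res_min)[res_min < cutoff]
  out[intersect(hit, labels)] <- 1L
  out
}
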