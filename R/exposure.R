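#' @name exposure
#' @title Solvent-accessible surface area and relative exposure
#' @description Shrake-Rupley style SASA: each atom's sphere of radius
#'   (vdW + probe) is sampled with a fixed deterministic point set and the
#'   unoccluded fraction gives its area. A residue is classified exposed when
#'   its area exceeds 40\% of a reference maximum area for that residue type
#'   in an extended tripeptide context.
NULL

#' Default van der Waals radii (Angstrom) per element
#'
#' Bondi-style protein set; user-replaceable via the \code{radii} argument of
#' \code{\link{sasa}}.
#' @return Named numeric vector.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
    "F" = 1.47, CL = 1.75, BR = 1.85, I = 1.98, MG = 1.73, ZN = 1.39,
    CA = 2.31, "NA" = 2.27, K = 2.75, MN = 1.97, FE = 1.94)
}

# deterministic quasi-uniform sphere points (golden-spiral lattice); no RNG
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area of a structure
#'
#' @param s A \code{structure3d} (heavy atoms; hydrogens are already dropped
#'   on reading).
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Sphere sample points per atom (default 1920; deterministic
#'   lattice, no randomness; 1920 keeps per-residue quadrature error below 1%
#'   under point-density doubling on tightly packed fixtures).
#' @param radii Named vector of per-element vdW radii overriding/extending
#'   \code{\link{default_vdw_radii}}.
#' @param include_het Include HETATM records (default FALSE: polymer only).
#' @return A \code{sasa_result}: list with \code{atom_area} (Angstrom^2,
#'   parallel to the atoms used), \code{residue_area} (named by residue
#'   label), \code{residue_name} and the atom table used.
#' @export
sasa <- function(s, probe = 1.4, n_points = 1920, radii = NULL,
                 include_het = FALSE) {
  rt <- default_vdw_radii()
  if (!is.null(radii)) rt[names(radii)] <- radii
  a <- s$atoms
  if (!include_het) a <- a[!a$het, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms to analyze")
  unknown <- setdiff(unique(a$elem), names(rt))
  if (length(unknown))
    stop("no vdW radius for element(s): ", paste(unknown, collapse = ", "),
         "; supply via `radii`")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- unname(rt[a$elem]) + probe
  pts <- .sphere_points(n_points)
  n <- nrow(xyz)
  area <- numeric(n)
  # neighbor candidates once, from squared distances
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cut <- (r[i] + r)^2
    nb <- which(d2[i, ] < cut & seq_len(n) != i)
    sp <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
              (sp[, 3] - xyz[j, 3])^2
        free <- free & (dj >= r[j]^2)
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    area[i] <- frac * 4 * pi * r[i]^2
  }
  label <- paste0(a$resno, a$ins)
  res_area <- tapply(area, factor(label, levels = unique(label)), sum)
  res_name <- a$resid[!duplicated(label)]
  structure(list(atom_area = area,
                 residue_area = as.numeric(res_area),
                 residue_label = names(res_area),
                 residue_name = res_name,
                 atoms = a),
            class = "sasa_result")
}

#' Reference maximum accessible areas per residue type
#'
#' Published theoretical maximum solvent accessibilities of residue X in an
#' extended tripeptide context (Tien et al. 2013, PLoS ONE 8:e80635),
#' shipped as plain text and user-replaceable via \code{file}.
#'
#' @param file Optional path to a two-column (residue, area) table.
#' @return Named numeric vector, Angstrom^2 per three-letter residue name.
#' @export
reference_max_asa <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "max_asa_reference.tsv",
                        package = "pocketscan", mustWork = TRUE)
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(tab$area, toupper(tab$residue))
}

#' Compute a reference area table from user tripeptide structures
#'
#' Runs \code{\link{sasa}} on each supplied structure (one extended
#' tripeptide per residue type) and records the central residue's area,
#' yielding a table usable in place of the shipped reference.
#'
#' @param tripeptides Named list of \code{structure3d} objects (name =
#'   three-letter code of the central residue).
#' @param central_index Position of the central residue (default 2).
#' @param ... Passed to \code{\link{sasa}}.
#' @return Named numeric vector of areas (Angstrom^2).
#' @export
reference_sasa_from_structures <- function(tripeptides, central_index = 2, ...) {
  vapply(tripeptides, function(s) {
    res <- sasa(s, ...)
    res$residue_area[central_index]
  }, numeric(1))
}

#' Relative exposure and exposed classification
#'
#' Percent exposure is 100 x area / reference(residue type); a residue is
#' exposed when this strictly exceeds the cutoff (default 40\%). Values above
#' 100\% are possible for distorted geometries and are reported as-is.
#'
#' @param sr A \code{sasa_result}.
#' @param reference Named numeric vector (three-letter residue name -> area),
#'   default \code{\link{reference_max_asa}()}.
#' @param cutoff Exposure threshold in percent (default 40, strict).
#' @return Data frame with \code{label}, \code{residue}, \code{area},
#'   \code{percent}, \code{exposed}.
#' @export
relative_exposure <- function(sr, reference = reference_max_asa(), cutoff = 40) {
  res <- toupper(sr$residue_name)
  missing_ref <- setdiff(unique(res), names(reference))
  if (length(missing_ref))
    stop("no reference area for residue(s): ",
         paste(missing_ref, collapse = ", "))
  pct <- 100 * sr$residue_area / unname(reference[res])
  data.frame(label = sr$residue_label, residue = sr$residue_name,
             area = sr$residue_area, percent = pct,
             exposed = pct > cutoff, stringsAsFactors = FALSE)
}

#' Mean and maximum relative exposure over an ensemble
#'
#' @param exposures List of data frames from \code{\link{relative_exposure}},
#'   one per structure.
#' @return Data frame with \code{label}, \code{mean_percent},
#'   \code{max_percent}, \code{n} (structures containing the residue).
#' @export
exposure_profile <- function(exposures) {
  all_labels <- unique(unlist(lapply(exposures, `[[`, "label")))
  rows <- lapply(all_labels, function(l) {
    v <- unlist(lapply(exposures, function(e) e$percent[e$label == l]))
    data.frame(label = l, mean_percent = mean(v), max_percent = max(v),
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
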