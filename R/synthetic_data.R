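#' Specification of a synthetic two-state benchmark
#'
#' Describes the generative model every stage of the pipeline can be
#' validated against: a two-state coordinate ensemble separated along a
#' planted collective mode localized to a contiguous "switch" block, probe
#' poses placed over a planted pocket with state-dependent probability, and
#' alignments with controlled per-column letter distributions.
#'
#' @param n_residues Chain length (default 200, GTPase-domain sized).
#' @param n_per_state Structures per state, length-2 (default c(30, 30)).
#' @param amplitude Per-residue displacement of the switch block between the
#'   two states, in Angstrom (default 3).
#' @param sigma Within-state isotropic coordinate noise, Angstrom (default 0.2).
#' @param switch_block Residue indices of the displaced block (default 24:40,
#'   the span of a GTPase switch 1 loop, clipped to the chain).
#' @param pocket Residue indices of the planted pocket (default 57:70).
#' @param probe_prob Per-state probe-presence probability, length-2
#'   (default c(0.9, 0.1): pocket open in the first state).
#' @param background_prob Contact probability of non-pocket residues, equal in
#'   both states (used by \code{\link{make_contact_ensemble}}; default 0.2).
#' @param states State labels (default c("GDP", "GTP")).
#' @param n_seq Rows of the synthetic alignment (default 200).
#' @param alignment_columns List of named probability vectors over letters
#'   (20 amino acids and "-"), one per column; NULL = no alignment.
#' @param seed Integer seed; every generator below is deterministic given it.
#' @return A \code{synthetic_spec} object (validated list).
#' @export
synthetic_spec <- function(n_residues = 200, n_per_state = c(30, 30),
                           amplitude = 3, sigma = 0.2,
                           switch_block = NULL, pocket = NULL,
                           probe_prob = c(0.9, 0.1), background_prob = 0.2,
                           states = c("GDP", "GTP"), n_seq = 200,
                           alignment_columns = NULL, seed = 1) {
  clip_block <- function(lo, hi, n) {
    b <- intersect(lo:hi, seq_len(n))
    if (length(b) == 0L) b <- seq(max(1L, n - (hi - lo)), n) # short chains
    b
  }
  if (is.null(switch_block)) switch_block <- clip_block(24, 40, n_residues)
  if (is.null(pocket)) pocket <- clip_block(57, 70, n_residues)
  stopifnot(sigma >= 0, all(probe_prob >= 0 & probe_prob <= 1),
            background_prob >= 0, background_prob <= 1,
            all(pocket >= 1 & pocket <= n_residues),
            all(switch_block >= 1 & switch_block <= n_residues),
            length(n_per_state) == 2L, length(states) == 2L)
  structure(list(n_residues = n_residues, n_per_state = n_per_state,
                 amplitude = amplitude, sigma = sigma,
                 switch_block = sort(unique(switch_block)),
                 pocket = sort(unique(pocket)),
                 probe_prob = probe_prob, background_prob = background_prob,
                 states = states, n_seq = n_seq,
                 alignment_columns = alignment_columns, seed = seed),
            class = "synthetic_spec")
}

# smooth helical backbone, ~3.8 Angstrom consecutive C-alpha spacing
.helix_backbone <- function(n) {
  t <- seq_len(n)
  ang <- t * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
}

#' Generate a two-state coordinate ensemble with a planted mode
#'
#' State A lies on a helical backbone; state B displaces every switch-block
#' residue by \code{amplitude} Angstrom along its outward radial direction (a
#' localized collective mode). Each member then adds i.i.d. isotropic Gaussian
#' noise of sd \code{sigma}. All members share one frame: no rigid-body
#' jitter is applied, so the ensemble can be analyzed directly or after
#' \code{\link{superpose_ensemble}}.
#'
#' @param spec A \code{synthetic_spec}.
#' @return A \code{coordset} with ground truth attached as attributes:
#'   \code{mode} (unit 3N displacement direction), \code{displacement}
#'   (raw 3N vector), \code{block}, \code{state_truth}.
#' @export
make_two_state_ensemble <- function(spec) {
  if (spec$amplitude == 0 && spec$sigma == 0)
    stop("degenerate spec: amplitude and sigma are both zero")
  set.seed(spec$seed)
  n <- spec$n_residues
  base <- .helix_backbone(n)
  disp <- matrix(0, n, 3)
  radial <- cbind(base[, 1], base[, 2], 0)
  radial <- radial / sqrt(rowSums(radial^2))
  disp[spec$switch_block, ] <- spec$amplitude * radial[spec$switch_block, ]
  d3n <- as.numeric(t(disp))
  nA <- spec$n_per_state[1]; nB <- spec$n_per_state[2]
  coords <- matrix(NA_real_, nA + nB, 3 * n)
  flatA <- as.numeric(t(base))
  for (i in seq_len(nA))
    coords[i, ] <- flatA + stats::rnorm(3 * n, 0, spec$sigma)
  for (i in seq_len(nB))
    coords[nA + i, ] <- flatA + d3n + stats::rnorm(3 * n, 0, spec$sigma)
  states <- rep(spec$states, c(nA, nB))
  cs <- new_coordset(labels = as.character(seq_len(n)), coords = coords,
                     state = states,
                     ids = sprintf("%s_%02d", states,
                                   c(seq_len(nA), seq_len(nB))))
  attr(cs, "mode") <- d3n / sqrt(sum(d3n^2))
  attr(cs, "displacement") <- d3n
  attr(cs, "block") <- spec$switch_block
  attr(cs, "state_truth") <- states
  cs
}

#' View one ensemble member as a C-alpha structure
#'
#' Builds a \code{structure3d} (alanine C-alpha trace) from one row of a
#' coordinate set, so geometry-level operations (SASA, probe scan, contacts)
#' can run on synthetic ensembles.
#'
#' @param cs A \code{coordset}.
#' @param i Member index.
#' @param resid Residue name used for every position (default "ALA").
#' @return A \code{structure3d}.
#' @export
calpha_structure <- function(cs, i, resid = "ALA") {
  xyz <- .as_xyz_mat(cs$coords[i, ])
  n <- length(cs$labels)
  atoms <- data.frame(
    elety = "CA", elem = "C", resid = resid,
    resno = cs$resno, ins = "", chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = cs$bfactors[i, ], o = 1, het = FALSE,
    stringsAsFactors = FALSE
  )
  structure(list(id = cs$ids[i], atoms = atoms, het_codes = character(0)),
            class = "structure3d")
}

#' Place state-dependent probe poses over the planted pocket
#'
#' For each ensemble member, a 4-atom probe is placed 3.5 Angstrom outward of
#' the pocket centroid with its state's presence probability; otherwise the
#' member gets an empty probe set. Deterministic given \code{spec$seed}.
#'
#' @param cs The ensemble from \code{\link{make_two_state_ensemble}}.
#' @param spec The same \code{synthetic_spec}.
#' @return List of \code{probe_set} objects (one per member), with attribute
#'   \code{present} (logical ground truth).
#' @export
make_probe_sets <- function(cs, spec) {
  set.seed(spec$seed + 1L)
  n <- nrow(cs$coords)
  pstate <- stats::setNames(spec$probe_prob, spec$states)
  present <- stats::runif(n) < pstate[cs$state]
  tet <- rbind(c(0.5, 0.5, 0.5), c(-0.5, -0.5, 0.5),
               c(-0.5, 0.5, -0.5), c(0.5, -0.5, -0.5))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (!present[i]) { out[[i]] <- new_probe_set(cs$ids[i], list()); next }
    xyz <- .as_xyz_mat(cs$coords[i, ])
    pc <- colMeans(xyz[spec$pocket, , drop = FALSE])
    outward <- pc - colMeans(xyz)
    outward <- outward / sqrt(sum(outward^2))
    center <- pc + 3.5 * outward
    out[[i]] <- new_probe_set(cs$ids[i], list(list(
      type = "SYN", cluster = 1L, coords = sweep(tet, 2, center, `+`))))
  }
  attr(out, "present") <- unname(present)
  out
}

#' Sample binary contact matrices for two states directly
#'
#' Bypasses geometry: each pocket residue contacts a probe with its state's
#' probability independently per structure; every other residue contacts with
#' the state-shared \code{background_prob}. This is the generator for
#' calibration studies of the differential-occupancy test, where per-residue
#' independent contacts (rather than the all-or-none probe placement of
#' \code{\link{make_probe_sets}}) are the relevant null.
#'
#' @param spec A \code{synthetic_spec}.
#' @return List with binary matrices \code{A} and \code{B}
#'   (structures x residues, residue labels as colnames) and \code{pocket}.
#' @export
make_contact_ensemble <- function(spec) {
  set.seed(spec$seed + 3L)
  n <- spec$n_residues
  labels <- as.character(seq_len(n))
  draw <- function(n_struct, p_pocket) {
    p <- rep(spec$background_prob, n)
    p[spec$pocket] <- p_pocket
    M <- matrix(stats::rbinom(n_struct * n, 1L, rep(p, each = n_struct)),
                n_struct, n)
    colnames(M) <- labels
    M
  }
  list(A = draw(spec$n_per_state[1], spec$probe_prob[1]),
       B = draw(spec$n_per_state[2], spec$probe_prob[2]),
       pocket = spec$pocket)
}

#' Generate an alignment with controlled per-column distributions
#'
#' Rows are sampled i.i.d. per column from the spec's letter distributions.
#'
#' @param spec A \code{synthetic_spec} with non-NULL \code{alignment_columns}.
#' @return An \code{alignment}, with attribute \code{target_entropy21}
#'   (entropy of each generating distribution under the 21-letter alphabet,
#'   bits).
#' @export
make_alignment <- function(spec) {
  cols <- spec$alignment_columns
  if (is.null(cols)) stop("spec carries no alignment column distributions")
  set.seed(spec$seed + 2L)
  for (k in seq_along(cols)) {
    if (abs(sum(cols[[k]]) - 1) > 1e-9)
      stop("column ", k, " distribution does not sum to 1")
  }
  seqs <- vapply(cols, function(p)
    sample(names(p), spec$n_seq, replace = TRUE, prob = p),
    character(spec$n_seq))
  aln <- new_alignment(paste0("seq", seq_len(spec$n_seq)), seqs)
  attr(aln, "target_entropy21") <- vapply(cols, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  aln
}

#' Write a synthetic benchmark to disk
#'
#' Emits one PDB per member, one probe file per member, a tab-separated
#' manifest (id, file, chain, state) and, when alignment columns are
#' specified, an aligned FASTA -- the on-disk mirror of the in-memory
#' generators, used for round-trip testing of the readers.
#'
#' @param spec A \code{synthetic_spec}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_synthetic_benchmark <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- make_two_state_ensemble(spec)
  probes <- make_probe_sets(cs, spec)
  n <- nrow(cs$coords)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pdb <- file.path(dir, paste0(cs$ids[i], ".pdb"))
    write_structure(calpha_structure(cs, i), pdb)
    pf <- file.path(dir, paste0(cs$ids[i], "_probes.pdb"))
    write_probe_poses(probes[[i]], pf)
    rows[[i]] <- data.frame(id = cs$ids[i], file = basename(pdb),
                            chain = "A", state = cs$state[i],
                            probe_file = basename(pf),
                            stringsAsFactors = FALSE)
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(spec$alignment_columns)) {
    aln <- make_alignment(spec)
    fa <- file.path(dir, "alignment.fasta")
    con <- file(fa, "w")
    for (i in seq_len(aln$n_seq)) {
      writeLines(paste0(">", aln$ids[i]), con)
      writeLines(paste(aln$seqs[i, ], collapse = ""), con)
    }
    close(con)
  }
  invisible(manifest)
}
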