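#' @name conservation
#' @title Shannon-entropy sequence conservation
#' @description Per-column conservation of a multiple sequence alignment under
#'   a 21-letter alphabet (20 amino acids + gap) and a reduced 7-letter
#'   alphabet (six physicochemical classes + gap). Entropy is normalized so
#'   fully conserved columns score 1 and maximally diverse columns score 0;
#'   columns with more than 30\% gaps are masked, and a position is called
#'   conserved when either normalized score exceeds 0.6.
NULL

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

# reduced physicochemical classes: aliphatic, aromatic, polar, positive,
# negative, special (G/P); gap is its own letter in both alphabets
.AA7_CLASS <- c(A = "ali", V = "ali", L = "ali", I = "ali", M = "ali", C = "ali",
                F = "aro", W = "aro", Y = "aro", H = "aro",
                S = "pol", T = "pol", N = "pol", Q = "pol",
                K = "pos", R = "pos",
                D = "neg", E = "neg",
                G = "spc", P = "spc")

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA (via \code{bio3d::read.fasta}) and Stockholm
#' (minimal reader: sequence lines only, \code{#} comments and \code{//}
#' terminator ignored, \code{.} gaps normalized to \code{-}).
#'
#' @param file Path to the alignment.
#' @param format \code{"auto"} (by extension/content), \code{"fasta"} or
#'   \code{"stockholm"}.
#' @return An \code{alignment} object: list with \code{ids}, \code{seqs}
#'   (n_seq x n_col character matrix, upper case), \code{gap = "-"}.
#' @export
read_alignment <- function(file, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1L, warn = FALSE)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm"
      else if (grepl("^>", first)) "fasta"
      else if (grepl("\\.(sto|stk|stockholm)$", file, ignore.case = TRUE)) "stockholm"
      else "fasta"
  }
  if (format == "fasta") {
    aln <- bio3d::read.fasta(file)
    seqs <- toupper(aln$ali)
    ids <- aln$id
  } else {
    lines <- readLines(file, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                   nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    ids_raw <- vapply(parts, `[[`, character(1), 1L)
    seq_raw <- vapply(parts, function(p) paste(p[-1L], collapse = ""), character(1))
    # interleaved Stockholm: concatenate blocks per id, keep first-seen order
    ids <- unique(ids_raw)
    seq <- vapply(ids, function(i)
      paste(seq_raw[ids_raw == i], collapse = ""), character(1))
    seqs <- do.call(rbind, strsplit(toupper(seq), ""))
    rownames(seqs) <- NULL
  }
  seqs[seqs %in% c(".", "~")] <- "-"
  if (length(unique(apply(seqs, 1, length))) > 1L ||
      any(is.na(seqs)))
    stop("rows of the alignment have unequal length")
  new_alignment(ids, seqs)
}

#' Construct an alignment object
#' @param ids Sequence identifiers.
#' @param seqs n_seq x n_col character matrix (residues, \code{-} gaps,
#'   \code{X} for unknown).
#' @return An \code{alignment} object.
#' @export
new_alignment <- function(ids, seqs) {
  seqs <- as.matrix(seqs)
  stopifnot(length(ids) == nrow(seqs))
  bad <- setdiff(unique(as.character(seqs)), c(.AA20, "-", "X"))
  if (length(bad))
    stop("unknown letters in alignment: ", paste(bad, collapse = ", "))
  structure(list(ids = ids, seqs = seqs, n_seq = nrow(seqs),
                 n_col = ncol(seqs), gap = "-"),
            class = "alignment")
}

#' Shannon entropy of one alignment column
#'
#' Under the 21-letter alphabet every amino acid and the gap are distinct
#' classes; under the 7-letter alphabet amino acids collapse into six
#' physicochemical groups plus the gap. \code{X} entries are treated as
#' missing and dropped before computing frequencies.
#'
#' @param column Character vector of letters (one alignment column).
#' @param alphabet 21 or 7.
#' @return Entropy S in bits, \code{0 <= S <= log2(alphabet)}.
#' @export
column_entropy <- function(column, alphabet = 21) {
  stopifnot(alphabet %in% c(21, 7))
  column <- toupper(column)
  column <- column[column != "X"]
  if (length(column) == 0L) stop("empty column (only missing letters)")
  bad <- setdiff(unique(column), c(.AA20, "-"))
  if (length(bad))
    stop("unknown letter in column: ", paste(bad, collapse = ", "))
  cls <- if (alphabet == 21) column
    else ifelse(column == "-", "-", .AA7_CLASS[column])
  p <- table(cls) / length(cls)
  -sum(p * log2(p))
}

#' Normalized conservation score
#'
#' \code{C = 1 - S / log2(N)}: fully conserved columns (S = 0) score 1,
#' maximally diverse columns (S = log2 N) score 0.
#'
#' @param S Entropy in bits.
#' @param N Alphabet size (21 or 7).
#' @return Score in [0, 1].
#' @export
normalized_conservation <- function(S, N) {
  smax <- log2(N)
  if (any(S < -1e-12 | S > smax + 1e-9))
    stop("entropy out of range [0, log2(N)]")
  pmin(pmax(1 - S / smax, 0), 1)
}

#' Mask alignment columns with more than 30\% gaps
#'
#' The inequality is strict: a column with exactly 30\% gaps is kept.
#'
#' @param alignment An \code{alignment}.
#' @param max_gap_frac Gap-fraction threshold (default 0.30).
#' @return Logical vector, TRUE = masked.
#' @export
mask_gappy <- function(alignment, max_gap_frac = 0.30) {
  colMeans(alignment$seqs == alignment$gap) > max_gap_frac
}

#' Per-column conservation profile
#'
#' @param alignment An \code{alignment}.
#' @param conserved_cutoff Normalized-score threshold for the conserved call
#'   (default 0.6, strict).
#' @param max_gap_frac Gap mask threshold (default 0.30, strict).
#' @return Data frame with one row per column: \code{col}, \code{entropy21},
#'   \code{entropy7} (bits), \code{C21}, \code{C7}, \code{gap_frac},
#'   \code{masked}, \code{conserved}. n_seq is carried as an attribute.
#' @export
conservation_profile <- function(alignment, conserved_cutoff = 0.6,
                                 max_gap_frac = 0.30) {
  s21 <- apply(alignment$seqs, 2, column_entropy, alphabet = 21)
  s7 <- apply(alignment$seqs, 2, column_entropy, alphabet = 7)
  prof <- data.frame(
    col = seq_len(alignment$n_col),
    entropy21 = s21, entropy7 = s7,
    C21 = normalized_conservation(s21, 21),
    C7 = normalized_conservation(s7, 7),
    gap_frac = colMeans(alignment$seqs == alignment$gap)
  )
  prof$masked <- mask_gappy(alignment, max_gap_frac)
  prof$conserved <- call_conserved(prof, conserved_cutoff)
  attr(prof, "n_seq") <- alignment$n_seq
  prof
}

#' Conserved-position calls
#'
#' A column is conserved when its normalized score under either alphabet
#' exceeds the cutoff and the column is not gap-masked.
#'
#' @param profile Data frame with columns \code{C21}, \code{C7}, \code{masked}.
#' @param cutoff Threshold (default 0.6, strict).
#' @return Logical vector.
#' @export
call_conserved <- function(profile, cutoff = 0.6) {
  (profile$C21 > cutoff | profile$C7 > cutoff) & !profile$masked
}

#' Map alignment columns to structure residues
#'
#' Uses one alignment row as the reference: its ungapped sequence must match
#' the structure's one-letter sequence, allowing truncation at either
#' terminus (the structure may start/end inside the reference, or vice
#' versa).
#'
#' @param alignment An \code{alignment}.
#' @param ref_id Row identifier of the reference sequence.
#' @param structure_seq Character vector, the structure's one-letter sequence.
#' @param structure_labels Residue labels parallel to \code{structure_seq}.
#' @return Data frame with \code{col} (alignment column) and \code{label}
#'   (residue label); gapped reference columns and residues outside the
#'   overlap are absent.
#' @export
map_alignment_to_structure <- function(alignment, ref_id, structure_seq,
                                       structure_labels) {
  stopifnot(length(structure_seq) == length(structure_labels))
  row <- which(alignment$ids == ref_id)
  if (length(row) != 1L) stop("reference id '", ref_id, "' not found")
  ref <- alignment$seqs[row, ]
  cols <- which(ref != alignment$gap)
  ref_seq <- toupper(ref[cols])
  str_seq <- toupper(structure_seq)

  # locate the structure sequence within the reference (or the reference
  # within the structure) allowing terminal truncation only
  find_offset <- function(short, long) {
    for (off in 0:(length(long) - length(short))) {
      if (all(short == long[off + seq_along(short)])) return(off)
    }
    NA_integer_
  }
  if (length(str_seq) <= length(ref_seq)) {
    off <- find_offset(str_seq, ref_seq)
    if (is.na(off)) .mismatch_error(str_seq, ref_seq)
    data.frame(col = cols[off + seq_along(str_seq)],
               label = structure_labels, stringsAsFactors = FALSE)
  } else {
    off <- find_offset(ref_seq, str_seq)
    if (is.na(off)) .mismatch_error(ref_seq, str_seq)
    data.frame(col = cols,
               label = structure_labels[off + seq_along(ref_seq)],
               stringsAsFactors = FALSE)
  }
}

.mismatch_error <- function(a, b) {
  m <- min(length(a), length(b))
  first <- which(a[seq_len(m)] != b[seq_len(m)])[1]
  if (is.na(first)) first <- m + 1L
  stop("reference and structure sequences mismatch beyond the termini ",
       "(first mismatch near position ", first, ")")
}

#' One-letter amino acid code of a structure's polymer residues
#' @param s A \code{structure3d}.
#' @return Character vector over the CA-bearing polymer residues.
#' @export
structure_sequence <- function(s) {
  a <- s$atoms
  ca <- a[a$elety == "CA" & !a$het, , drop = FALSE]
  ca <- ca[!duplicated(paste0(ca$resno, ca$ins)), , drop = FALSE]
  unname(bio3d::aa321(ca$resid))
}
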