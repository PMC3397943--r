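#' Descriptor filter for a compound library
#'
#' Applies the six-descriptor screen conjunctively: molecular weight
#' strictly below 553 Da, at most 14 rotatable bonds, at most 6 hydrogen-bond
#' donors, at least 3 hydrogen-bond acceptors, polar surface area of at least
#' 30 Angstrom^2 and predicted logP of at least -0.5. Records with any
#' missing descriptor are rejected with reason "incomplete". Every violated
#' criterion of a rejected record is counted, so rejection counts can exceed
#' the number of rejected compounds.
#'
#' @param records Data frame with columns \code{id}, \code{mw},
#'   \code{rot_bonds}, \code{hbd}, \code{hba}, \code{psa}, \code{logp}
#'   (and optionally \code{score}).
#' @param mw_max,rot_max,hbd_max,hba_min,psa_min,logp_min Thresholds
#'   (defaults as above; \code{mw_max} is strict, the rest inclusive).
#' @return List with \code{passing} (subset data frame), \code{rejections}
#'   (named counts per criterion, plus \code{incomplete}) and \code{n_pass}.
#' @export
filter_library <- function(records, mw_max = 553, rot_max = 14, hbd_max = 6,
                           hba_min = 3, psa_min = 30, logp_min = -0.5) {
  needed <- c("mw", "rot_bonds", "hbd", "hba", "psa", "logp")
  stopifnot(all(c("id", needed) %in% names(records)))
  complete <- stats::complete.cases(records[, needed])
  crit <- cbind(
    mw = records$mw < mw_max,
    rot_bonds = records$rot_bonds <= rot_max,
    hbd = records$hbd <= hbd_max,
    hba = records$hba >= hba_min,
    psa = records$psa >= psa_min,
    logp = records$logp >= logp_min
  )
  crit[is.na(crit)] <- FALSE
  pass <- complete & rowSums(crit) == ncol(crit)
  rejections <- c(colSums(!crit[complete, , drop = FALSE]),
                  incomplete = sum(!complete))
  list(passing = records[pass, , drop = FALSE],
       rejections = rejections, n_pass = sum(pass))
}

#' Retain and rank compounds by docking score
#'
#' Keeps records scoring at or below the threshold (lower = better; "-8 or
#' lower" is inclusive) and returns them sorted ascending by score, ties
#' broken by id.
#'
#' @param records Data frame with columns \code{id} and \code{score}.
#' @param threshold Score cutoff (default -8, inclusive).
#' @return The retained records, ranked.
#' @export
filter_by_score <- function(records, threshold = -8) {
  stopifnot(all(c("id", "score") %in% names(records)),
            !any(is.na(records$score)))
  keep <- records[records$score <= threshold, , drop = FALSE]
  keep[order(keep$score, keep$id), , drop = FALSE]
}
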