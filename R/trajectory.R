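## Post-simulation accessibility metrics on coarse-grained frames: ATP-site
## lipid contact counts, residue-pair distances, block error estimates.

#' ATP-binding-pocket residues
#'
#' Residue numbers forming the EGFR ATP-binding pocket used for the
#' lipid-contact accessibility metric.
#'
#' @return Integer vector of residue ids.
#' @export
atpSiteResidues <- function() {
  as.integer(c(694:703, 719, 766:769, 772:773, 817, 820, 831))
}

## Pairwise squared distances between two coordinate sets with optional
## minimum-image wrapping in an orthorhombic box.
pairSquaredDistances <- function(a, b, box = NULL) {
  out <- matrix(0, nrow(a), nrow(b))
  for (d in 1:3) {
    dd <- outer(a[, d], b[, d], "-")
    if (!is.null(box)) dd <- dd - box[d] * round(dd / box[d])
    out <- out + dd^2
  }
  out
}

#' Count lipid contacts with the ATP-binding site
#'
#' Number of (lipid bead, ATP-site bead) pairs at a minimum-image distance
#' strictly below the cutoff. The default 16 Angstrom cutoff corresponds to
#' the largest molecular radius of the fluorescent ATP analogue; a high
#' contact count means the bilayer sterically hinders nucleotide binding.
#'
#' @param frame a [TrajectoryFrame-class].
#' @param residues ATP-site residue ids (default [atpSiteResidues()]).
#' @param cutoff contact cutoff in Angstrom (strict `<`).
#' @return Integer contact count.
#' @export
countAtpSiteContacts <- function(frame, residues = atpSiteResidues(),
                                 cutoff = 16) {
  lipid <- frame@kind == "lipid"
  site <- frame@kind == "protein" & !is.na(frame@residueId) &
    frame@residueId %in% residues
  stopifnot2(any(lipid), "frame has no lipid beads")
  if (!any(site)) stop("frame has no beads with the requested residue labels")
  box <- if (frame@periodic) frame@box else NULL
  d2 <- pairSquaredDistances(frame@coords[lipid, , drop = FALSE],
                             frame@coords[site, , drop = FALSE], box)
  sum(d2 < cutoff^2)
}

#' Distance between two residues
#'
#' Minimum-image Euclidean distance between the centroids of the two
#' residues' beads (a single bead is its own centroid), reported in nm.
#'
#' @param frame a [TrajectoryFrame-class].
#' @param resA,resB residue ids (defaults: 721, the residue closest to the
#'   ATP site, and 1186, the C-terminus).
#' @return Distance in nm.
#' @export
residueDistance <- function(frame, resA = 721L, resB = 1186L) {
  pick <- function(res) {
    sel <- frame@kind == "protein" & !is.na(frame@residueId) &
      frame@residueId == res
    if (!any(sel)) stop("residue ", res, " not present in frame")
    colMeans(frame@coords[sel, , drop = FALSE])
  }
  dd <- pick(resA) - pick(resB)
  if (frame@periodic) dd <- dd - frame@box * round(dd / frame@box)
  sqrt(sum(dd^2)) / 10
}

#' Block statistics from equal partitions
#'
#' Splits a series into `nBlocks` contiguous equal parts (remainder to the
#' last), applies the reducer per block, and reports the overall value with
#' the per-block minimum and maximum as the error interval.
#'
#' @param x numeric series (e.g. a per-frame statistic), length `>= nBlocks`.
#' @param nBlocks number of partitions (3 in the standard workflow).
#' @param reducer `"mean"` or `"median"`.
#' @return List (`ReweightedEstimate`): `value`, `blocks`, `min`, `max`.
#' @export
blockStats <- function(x, nBlocks = 3L, reducer = c("mean", "median")) {
  stopifnot2(length(x) >= nBlocks, "series shorter than the number of blocks")
  reducer <- match.arg(reducer)
  f <- if (reducer == "mean") mean else stats::median
  size <- length(x) %/% nBlocks
  starts <- (seq_len(nBlocks) - 1L) * size + 1L
  ends <- c(starts[-1L] - 1L, length(x))
  blocks <- vapply(seq_len(nBlocks), function(i) f(x[starts[i]:ends[i]]),
                   numeric(1))
  list(value = f(x), blocks = blocks, min = min(blocks), max = max(blocks))
}
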