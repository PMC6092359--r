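# groove membership machinery: lipid (P within lipidCutoff of groove
# sidechains) and water (any atom within waterCutoff)

# groove sidechain coordinate rows for one protomer
.grooveSC <- function(traj, gdef, protomer)
  .sidechainIdx(traj@atoms, gdef@grooveResidues, protomer)

#' Lipids in the groove of a protomer at one frame
#'
#' A lipid belongs to the groove when its phosphorus atom lies within the
#' lipid cutoff (default 5 A) of any sidechain heavy atom of the
#' groove-lining residues, under the minimum-image convention. Cutoffs are
#' closed (boundary included).
#'
#' @param traj a [Trajectory-class]
#' @param frame frame index
#' @param gdef a [GrooveDefinition-class]
#' @param protomer chain id; \code{NULL} returns a named list over all
#'   protomers
#' @return character vector of lipid molecule ids (or a named list)
#' @export
grooveLipidIds <- function(traj, frame, gdef = grooveDefinition(),
                           protomer = NULL) {
  if (is.null(protomer)) {
    pr <- protomers(traj)
    out <- lapply(pr, function(ch) grooveLipidIds(traj, frame, gdef, ch))
    names(out) <- pr
    return(out)
  }
  pIdx <- .lipidPIdx(traj@atoms)
  if (!length(pIdx)) stop("no lipid phosphorus atoms in the trajectory")
  sc <- .grooveSC(traj, gdef, protomer)
  if (!length(sc)) stop("no groove residues found on protomer ", protomer)
  co <- frameCoords(traj, frame)
  dd <- .pairDist(co[pIdx, , drop = FALSE], co[sc, , drop = FALSE],
                  boxDims(traj, frame))
  names(pIdx)[apply(dd, 1, min) <= gdef@lipidCutoff]
}

#' Number of waters in the groove of a protomer at one frame
#'
#' A water belongs to the groove when any of its atoms (including
#' hydrogens) lies within the water cutoff (default 3 A) of any sidechain
#' heavy atom of the groove-lining residues.
#'
#' @inheritParams grooveLipidIds
#' @return integer count (or a named list over protomers)
#' @export
grooveWaterCount <- function(traj, frame, gdef = grooveDefinition(),
                             protomer = NULL) {
  if (is.null(protomer)) {
    pr <- protomers(traj)
    out <- lapply(pr, function(ch) grooveWaterCount(traj, frame, gdef, ch))
    names(out) <- pr
    return(out)
  }
  wIdx <- which(traj@atoms$type == "water")
  if (!length(wIdx)) return(0L)
  sc <- .grooveSC(traj, gdef, protomer)
  co <- frameCoords(traj, frame)
  dd <- .pairDist(co[wIdx, , drop = FALSE], co[sc, , drop = FALSE],
                  boxDims(traj, frame))
  inG <- apply(dd, 1, min) <= gdef@waterCutoff
  length(unique(traj@atoms$molid[wIdx][inG]))
}

# z positions of the two compartment boundary planes (C-alpha of the
# boundary residues) for one protomer at one frame, sorted ascending
.compartmentPlanes <- function(traj, frame, gdef, protomer) {
  co <- frameCoords(traj, frame)
  z <- vapply(gdef@boundaryResidues, function(r) {
    .requireResidue(traj@atoms, r, protomer, "boundary residue")
    i <- which(traj@atoms$type == "protein" & traj@atoms$chain == protomer &
                 traj@atoms$resid == r & traj@atoms$elety == "CA")
    if (!length(i)) stop("boundary residue ", r, " has no CA on protomer ",
                         protomer)
    co[i[1], 3]
  }, 0)
  sort(z)
}

#' Per-compartment groove occupancy at one frame
#'
#' Splits the groove lipids of a protomer into three compartments by the
#' z-positions of the C-alpha atoms of the boundary residues (T381, Q436),
#' recomputed per frame: IC below the lower plane, central between the
#' planes (closed interval), EC above the upper plane.
#'
#' @inheritParams grooveLipidIds
#' @return named integer vector \code{c(EC, central, IC)} (or a named list
#'   over protomers)
#' @export
compartmentOccupancy <- function(traj, frame, gdef = grooveDefinition(),
                                 protomer = NULL) {
  if (is.null(protomer)) {
    pr <- protomers(traj)
    out <- lapply(pr, function(ch)
      compartmentOccupancy(traj, frame, gdef, ch))
    names(out) <- pr
    return(out)
  }
  ids <- grooveLipidIds(traj, frame, gdef, protomer)
  planes <- .compartmentPlanes(traj, frame, gdef, protomer)
  if (!length(ids)) return(c(EC = 0L, central = 0L, IC = 0L))
  pIdx <- .lipidPIdx(traj@atoms)
  z <- frameCoords(traj, frame)[pIdx[ids], 3]
  c(EC = sum(z > planes[2]),
    central = sum(z >= planes[1] & z <= planes[2]),
    IC = sum(z < planes[1]))
}

#' Occupancy distribution of a groove region
#'
#' Fraction of trajectory frames in which exactly k lipid headgroups
#' simultaneously occupy the chosen region, averaged over protomers.
#'
#' @param traj a [Trajectory-class]
#' @param gdef a [GrooveDefinition-class]
#' @param region \code{"groove"} (whole groove) or one of \code{"EC"},
#'   \code{"central"}, \code{"IC"}
#' @return named numeric vector: fraction of frames with k = 0, 1, 2, ...
#'   lipids; sums to 1
#' @export
occupancyDistribution <- function(traj, gdef = grooveDefinition(),
                                  region = c("groove", "EC", "central",
                                             "IC")) {
  region <- match.arg(region)
  pr <- protomers(traj)
  nf <- nFrames(traj)
  counts <- matrix(0L, nf, length(pr), dimnames = list(NULL, pr))
  for (f in seq_len(nf)) {
    for (ch in pr) {
      counts[f, ch] <- if (region == "groove")
        length(grooveLipidIds(traj, f, gdef, ch))
      else
        compartmentOccupancy(traj, f, gdef, ch)[[region]]
    }
  }
  kmax <- max(counts)
  ks <- 0:kmax
  hists <- vapply(pr, function(ch)
    vapply(ks, function(k) mean(counts[, ch] == k), 0), numeric(kmax + 1))
  out <- rowMeans(matrix(hists, ncol = length(pr)))
  names(out) <- ks
  out
}

#' Residue-lipid contact frequencies
#'
#' A residue is in contact with a lipid headgroup in a frame when any
#' lipid phosphorus atom lies within the contact cutoff (default 7 A,
#' center-to-center) of any atom of the residue. Frequencies are fractions
#' of frames, averaged over protomers; residues above the hot threshold
#' (default 0.65) are flagged.
#'
#' @param traj a [Trajectory-class]
#' @param residues residue ids; defaults to the groove residues
#' @param gdef a [GrooveDefinition-class]
#' @param hotThreshold frequency above which a residue counts as a
#'   high-contact residue
#' @param protomer chain id; \code{NULL} (default) averages over protomers
#' @return data.frame(resid, frequency, hot), one row per residue
#' @export
residueContactFrequency <- function(traj, residues = NULL,
                                    gdef = grooveDefinition(),
                                    hotThreshold = 0.65, protomer = NULL) {
  if (is.null(residues)) residues <- gdef@grooveResidues
  pr <- if (is.null(protomer)) protomers(traj) else protomer
  nf <- nFrames(traj)
  pIdx <- .lipidPIdx(traj@atoms)
  if (!length(pIdx)) stop("no lipid phosphorus atoms in the trajectory")
  freq <- matrix(0, length(residues), length(pr),
                 dimnames = list(residues, pr))
  for (f in seq_len(nf)) {
    co <- frameCoords(traj, f)
    P <- co[pIdx, , drop = FALSE]
    box <- boxDims(traj, f)
    for (ch in pr) {
      for (i in seq_along(residues)) {
        ri <- .residueIdx(traj@atoms, residues[i], ch)
        if (!length(ri)) next
        if (.minDist(P, co[ri, , drop = FALSE], box) <= gdef@contactCutoff)
          freq[i, ch] <- freq[i, ch] + 1
      }
    }
  }
  fr <- rowMeans(freq) / nf
  data.frame(resid = residues, frequency = fr, hot = fr > hotThreshold,
             row.names = NULL)
}
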