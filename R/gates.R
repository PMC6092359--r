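# coordinate rows of the gate-relevant atom groups on one protomer
.gateAtoms <- function(traj, gdef, protomer) {
  at <- traj@atoms
  gr <- gdef@gateResidues
  pick <- function(resid, elety = NULL) {
    .requireResidue(at, resid, protomer, "gate residue")
    i <- which(at$type == "protein" & at$chain == protomer &
                 at$resid == resid & .isHeavy(at$elety))
    if (!is.null(elety)) i <- i[at$elety[i] %in% elety]
    if (!length(i))
      stop(sprintf("residue %d on protomer %s lacks atoms %s", resid,
                   protomer, paste(elety, collapse = "/")))
    i
  }
  list(
    # gate salt bridges: carbonyl/carboxyl O of Glu vs sidechain N of Arg
    e313O = pick(gr["e313"], c("OE1", "OE2")),
    e318O = pick(gr["e318"], c("OE1", "OE2")),
    r432N = pick(gr["r432"], c("NE", "NH1", "NH2")),
    t333 = pick(gr["t333"]),
    y439 = pick(gr["y439"]),
    q436 = pick(gr["q436"]),
    e313 = pick(gr["e313"]),
    e318 = pick(gr["e318"]),
    r432 = pick(gr["r432"]),
    r432CA = pick(gr["r432"], "CA"))
}

#' Extracellular gate state metrics
#'
#' Per-frame gate distances and derived booleans for each protomer:
#' E313-R432 and E318-R432 (minimum distance between the Glu carbonyl
#' oxygens and the Arg sidechain nitrogens), T333-Y439 and E313-Q436
#' (minimum heavy-atom distances), the bond booleans (distance at or below
#' the gate cutoff, default 3 A), and the number of lipid headgroups
#' (phosphorus atoms) within the near cutoff (5 A) of any atom of E313 or
#' R432.
#'
#' @param traj a [Trajectory-class]
#' @param gdef a [GrooveDefinition-class]
#' @param protomer chain id; \code{NULL} (default) computes all protomers
#' @return data.frame(frame, protomer, d313_432, d318_432, d333_439,
#'   d313_436, bond313_432, bond318_432, nLipidsNear)
#' @export
gateState <- function(traj, gdef = grooveDefinition(), protomer = NULL) {
  pr <- if (is.null(protomer)) protomers(traj) else protomer
  pIdx <- .lipidPIdx(traj@atoms)
  out <- list()
  for (ch in pr) {
    ga <- .gateAtoms(traj, gdef, ch)
    nf <- nFrames(traj)
    res <- data.frame(frame = seq_len(nf), protomer = ch, d313_432 = NA_real_,
                      d318_432 = NA_real_, d333_439 = NA_real_,
                      d313_436 = NA_real_, bond313_432 = NA,
                      bond318_432 = NA, nLipidsNear = NA_integer_)
    for (f in seq_len(nf)) {
      co <- frameCoords(traj, f)
      box <- boxDims(traj, f)
      res$d313_432[f] <- .minDist(co[ga$e313O, , drop = FALSE],
                                  co[ga$r432N, , drop = FALSE], box)
      res$d318_432[f] <- .minDist(co[ga$e318O, , drop = FALSE],
                                  co[ga$r432N, , drop = FALSE], box)
      res$d333_439[f] <- .minDist(co[ga$t333, , drop = FALSE],
                                  co[ga$y439, , drop = FALSE], box)
      res$d313_436[f] <- .minDist(co[ga$e313, , drop = FALSE],
                                  co[ga$q436, , drop = FALSE], box)
      if (length(pIdx)) {
        pair <- co[c(ga$e313, ga$r432), , drop = FALSE]
        dd <- .pairDist(co[pIdx, , drop = FALSE], pair, box)
        res$nLipidsNear[f] <- sum(apply(dd, 1, min) <= gdef@nearCutoff)
      } else res$nLipidsNear[f] <- 0L
    }
    res$bond313_432 <- res$d313_432 <= gdef@gateCutoff
    res$bond318_432 <- res$d318_432 <= gdef@gateCutoff
    out[[ch]] <- res
  }
  do.call(rbind, out)
}

#' Fraction of time in the switched-gate configuration
#'
#' f_int: fraction of frames in which the alternative E318-R432 bond is
#' formed while the E313-R432 interaction is disrupted, per protomer.
#'
#' @inheritParams gateState
#' @param gates optional precomputed [gateState()] table
#' @return named numeric vector, one value per protomer
#' @export
fInt <- function(traj, gdef = grooveDefinition(), gates = NULL) {
  if (is.null(gates)) gates <- gateState(traj, gdef)
  v <- tapply(gates$bond318_432 & !gates$bond313_432, gates$protomer, mean)
  stats::setNames(as.numeric(v), names(v))[sort(names(v))]
}

#' Fraction of time with two or more lipids at the gate pair
#'
#' f_lip: fraction of frames in which at least two lipid headgroups are
#' within the near cutoff of the E313/R432 pair, per protomer.
#'
#' @inheritParams fInt
#' @return named numeric vector, one value per protomer
#' @export
fLip <- function(traj, gdef = grooveDefinition(), gates = NULL) {
  if (is.null(gates)) gates <- gateState(traj, gdef)
  v <- tapply(gates$nLipidsNear >= 2L, gates$protomer, mean)
  stats::setNames(as.numeric(v), names(v))[sort(names(v))]
}

#' TM3-TM6 opening distance
#'
#' Distance between the centers of mass (unit masses) of the C-alpha atoms
#' of the TM3 span (residues 315-318) and the TM6 span (residues 432-435).
#'
#' @inheritParams gateState
#' @param frame frame index; \code{NULL} computes all frames
#' @return data.frame(frame, protomer, opening) or, for a single frame and
#'   protomer, the numeric distance
#' @export
tm3tm6Opening <- function(traj, gdef = grooveDefinition(), protomer = NULL,
                          frame = NULL) {
  pr <- if (is.null(protomer)) protomers(traj) else protomer
  frames <- if (is.null(frame)) seq_len(nFrames(traj)) else frame
  out <- list()
  for (ch in pr) {
    at <- traj@atoms
    ca <- function(resids) {
      i <- which(at$type == "protein" & at$chain == ch &
                   at$resid %in% resids & at$elety == "CA")
      if (length(i) != length(resids))
        stop("missing CA atoms in residue span ",
             paste(range(resids), collapse = "-"), " on protomer ", ch)
      i
    }
    i3 <- ca(gdef@tm3Span); i6 <- ca(gdef@tm6Span)
    op <- vapply(frames, function(f) {
      co <- frameCoords(traj, f)
      sqrt(sum((colMeans(co[i3, , drop = FALSE]) -
                  colMeans(co[i6, , drop = FALSE]))^2))
    }, 0)
    out[[ch]] <- data.frame(frame = frames, protomer = ch, opening = op)
  }
  res <- do.call(rbind, out)
  if (length(frames) == 1L && length(pr) == 1L) res$opening else res
}

#' Lipid tilt angle
#'
#' Angle between the vector from the lipid phosphorus atom to the centroid
#' of its tail carbon atoms and the +z axis (membrane normal), in degrees
#' within [0, 180]. 0 means tails pointing to the extracellular side, 180
#' to the intracellular side.
#'
#' @param traj a [Trajectory-class]
#' @param lipid lipid molecule id
#' @param frame frame index; \code{NULL} computes all frames
#' @return numeric vector of angles (degrees)
#' @export
lipidTilt <- function(traj, lipid, frame = NULL) {
  at <- traj@atoms
  pi_ <- which(at$type == "lipid" & at$molid == lipid & at$elety == "P")
  ti <- which(at$type == "lipid" & at$molid == lipid & at$elety != "P" &
                grepl("^C", at$elety))
  if (!length(pi_)) stop("lipid ", lipid, " has no phosphorus atom")
  if (!length(ti)) stop("lipid ", lipid, " has no tail carbon atoms")
  frames <- if (is.null(frame)) seq_len(nFrames(traj)) else frame
  vapply(frames, function(f) {
    co <- frameCoords(traj, f)
    v <- colMeans(co[ti, , drop = FALSE]) - co[pi_, ]
    acos(max(-1, min(1, v[3] / sqrt(sum(v^2))))) * 180 / pi
  }, 0)
}

#' Detect lipid flip events through the groove
#'
#' A flip event opens when the phosphorus atom of a groove-assigned lipid
#' crosses the membrane mid-point (z = 0); it is completed once the
#' headgroup reaches the completion depth (default 10 A) on the
#' destination side with its tails directed back towards the origin
#' leaflet (tilt beyond 90 degrees in the appropriate direction). A lipid
#' that returns across the mid-point first yields an uncompleted event.
#'
#' @param traj a [Trajectory-class]
#' @param gdef a [GrooveDefinition-class]
#' @param completionZ completion depth beyond the mid-point (A); default 10
#' @return data.frame(lipid, start, end, direction, completed) with
#'   direction \code{"IC->EC"} or \code{"EC->IC"}; zero rows when no event
#' @export
detectFlips <- function(traj, gdef = grooveDefinition(), completionZ = 10) {
  nf <- nFrames(traj)
  pIdx <- .lipidPIdx(traj@atoms)
  pr <- protomers(traj)
  inGroove <- matrix(FALSE, nf, length(pIdx),
                     dimnames = list(NULL, names(pIdx)))
  for (f in seq_len(nf)) {
    ids <- unique(unlist(grooveLipidIds(traj, f, gdef, protomer = NULL),
                         use.names = FALSE))
    inGroove[f, ids] <- TRUE
  }
  zmat <- t(matrix(traj@xyz[pIdx, 3, ], nrow = length(pIdx)))  # nf x nLip
  colnames(zmat) <- names(pIdx)
  events <- list()
  for (lip in names(pIdx)[colSums(inGroove) > 0]) {
    z <- zmat[, lip]
    tilt <- NULL
    f <- 1L
    while (f < nf) {
      crossed <- sign(z[f]) != sign(z[f + 1]) && z[f] != 0 &&
        (inGroove[f, lip] || inGroove[f + 1, lip])
      if (crossed) {
        dirUp <- z[f + 1] > z[f]
        start <- f
        end <- NA_integer_; completed <- FALSE
        for (g in (f + 1):nf) {
          if (sign(z[g]) == sign(z[f])) { end <- g; break }  # returned
          deep <- if (dirUp) z[g] >= completionZ else z[g] <= -completionZ
          if (deep) {
            if (is.null(tilt)) tilt <- lipidTilt(traj, lip)
            tailsBack <- if (dirUp) tilt[g] > 90 else tilt[g] < 90
            if (tailsBack) { end <- g; completed <- TRUE; break }
          }
        }
        if (is.na(end)) end <- nf
        events[[length(events) + 1L]] <- data.frame(
          lipid = lip, start = start, end = end,
          direction = if (dirUp) "IC->EC" else "EC->IC",
          completed = completed)
        f <- end
      } else f <- f + 1L
    }
  }
  if (!length(events))
    return(data.frame(lipid = character(), start = integer(),
                      end = integer(), direction = character(),
                      completed = logical()))
  do.call(rbind, events)
}

#' Flag frames with a lipid-tail groove blockade
#'
#' Annotates the rare mode in which a lipid inserts tail-first into the
#' extracellular side of the groove: three or more tail carbons of one
#' lipid inside the EC compartment z-slab (above the upper boundary plane)
#' and within the lipid cutoff of the groove sidechains, while the lipid's
#' phosphorus atom is not groove-assigned.
#'
#' @inheritParams gateState
#' @return data.frame(frame, protomer, blocked)
#' @export
tailBlockade <- function(traj, gdef = grooveDefinition(), protomer = NULL) {
  pr <- if (is.null(protomer)) protomers(traj) else protomer
  at <- traj@atoms
  nf <- nFrames(traj)
  out <- list()
  for (ch in pr) {
    sc <- .grooveSC(traj, gdef, ch)
    blocked <- logical(nf)
    for (f in seq_len(nf)) {
      co <- frameCoords(traj, f)
      box <- boxDims(traj, f)
      planes <- .compartmentPlanes(traj, f, gdef, ch)
      ids <- grooveLipidIds(traj, f, gdef, ch)
      for (lip in setdiff(unique(at$molid[at$type == "lipid"]), ids)) {
        ti <- which(at$type == "lipid" & at$molid == lip & at$elety != "P" &
                      grepl("^C", at$elety))
        if (length(ti) < 3L) next
        dd <- .pairDist(co[ti, , drop = FALSE], co[sc, , drop = FALSE], box)
        inEC <- co[ti, 3] > planes[2] &
          apply(dd, 1, min) <= gdef@lipidCutoff
        if (sum(inEC) >= 3L) { blocked[f] <- TRUE; break }
      }
    }
    out[[ch]] <- data.frame(frame = seq_len(nf), protomer = ch,
                            blocked = blocked)
  }
  do.call(rbind, out)
}

#' Eight-variable feature series for tICA
#'
#' Extracts, per frame, the fixed-order feature vector describing the
#' translocating lipid and the extracellular gate of one protomer:
#' (1) signed z-distance between the tracked lipid's phosphorus atom and
#' the C-alpha of R432 (extracellular positive); (2) minimum distance
#' T333-Y439; (3) minimum distance Y439-R432; (4) E313-R432 and (5)
#' E318-R432 gate distances (Glu carbonyl O to Arg sidechain N); (6-8)
#' minimum distances between the tracked phosphorus and residues E313,
#' E318 and R432. Distances in Angstrom. Columns 2, 4 and 5 are computed
#' by the same code path as [gateState()].
#'
#' @param traj a [Trajectory-class]
#' @param gdef a [GrooveDefinition-class]
#' @param protomer chain id (default first protomer)
#' @param trackedLipid lipid molecule id; by default the groove lipid with
#'   the greatest z-range while groove-assigned
#' @return numeric matrix nFrames x 8 with an attribute
#'   \code{"trackedLipid"}
#' @export
ticaFeatures <- function(traj, gdef = grooveDefinition(),
                         protomer = protomers(traj)[1],
                         trackedLipid = NULL) {
  nf <- nFrames(traj)
  pIdx <- .lipidPIdx(traj@atoms)
  if (is.null(trackedLipid)) {
    zr <- rep(-Inf, length(pIdx)); names(zr) <- names(pIdx)
    zs <- lapply(names(pIdx), function(x) numeric())
    names(zs) <- names(pIdx)
    for (f in seq_len(nf)) {
      ids <- grooveLipidIds(traj, f, gdef, protomer)
      co <- frameCoords(traj, f)
      for (id in ids) zs[[id]] <- c(zs[[id]], co[pIdx[id], 3])
    }
    rng <- vapply(zs, function(z) if (length(z) > 1) diff(range(z)) else
      if (length(z) == 1) 0 else -Inf, 0)
    if (all(!is.finite(rng)))
      stop("no groove lipid found; supply trackedLipid explicitly")
    trackedLipid <- names(which.max(rng))
  }
  ga <- .gateAtoms(traj, gdef, protomer)
  pi_ <- pIdx[trackedLipid]
  if (is.na(pi_)) stop("unknown lipid id: ", trackedLipid)
  feat <- matrix(NA_real_, nf, 8)
  colnames(feat) <- c("zP_R432CA", "dmin_T333_Y439", "dmin_Y439_R432",
                      "gate_E313_R432", "gate_E318_R432", "dP_E313",
                      "dP_E318", "dP_R432")
  for (f in seq_len(nf)) {
    co <- frameCoords(traj, f)
    box <- boxDims(traj, f)
    P <- co[pi_, , drop = FALSE]
    feat[f, 1] <- co[pi_, 3] - co[ga$r432CA[1], 3]
    feat[f, 2] <- .minDist(co[ga$t333, , drop = FALSE],
                           co[ga$y439, , drop = FALSE], box)
    feat[f, 3] <- .minDist(co[ga$y439, , drop = FALSE],
                           co[ga$r432, , drop = FALSE], box)
    feat[f, 4] <- .minDist(co[ga$e313O, , drop = FALSE],
                           co[ga$r432N, , drop = FALSE], box)
    feat[f, 5] <- .minDist(co[ga$e318O, , drop = FALSE],
                           co[ga$r432N, , drop = FALSE], box)
    feat[f, 6] <- .minDist(P, co[ga$e313, , drop = FALSE], box)
    feat[f, 7] <- .minDist(P, co[ga$e318, , drop = FALSE], box)
    feat[f, 8] <- .minDist(P, co[ga$r432, , drop = FALSE], box)
  }
  attr(feat, "trackedLipid") <- trackedLipid
  feat
}
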