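#' Create a toy-trajectory script
#'
#' Declares, per frame and protomer, the extracellular gate state
#' (\code{"closed"}: E313-R432 bonded; \code{"intermediate"}: E318-R432
#' bonded; \code{"open"}: neither), the central constriction state, the
#' paths of scripted lipids (groove membership, z position of the
#' phosphorus relative to the membrane mid-point, tilt angle, gate
#' proximity) and groove water counts. Scripted z values must keep a 0.6 A
#' margin from the membrane mid-point so crossing semantics survive
#' jitter; jitter is truncated at 2 SD and limited to 0.25 A.
#'
#' @param nFrames number of frames
#' @param gate data.frame(frame, protomer, ecState, centralOpen); defaults
#'   to all-closed for protomers A and B
#' @param lipids data.frame(lipid, protomer, frame, inGroove, z, tiltDeg,
#'   nearGate); \code{lipid} is the slot number (1-based, per protomer).
#'   Frames not listed leave the slot resting in the outer leaflet.
#' @param waters data.frame(frame, protomer, nInGroove); default none
#' @param nDecoysPerLeaflet bulk lipids per leaflet per protomer
#' @param jitter Gaussian coordinate jitter SD (A), truncated at 2 SD
#' @param seed RNG seed for the jitter
#' @return a validated [TrajScript-class]
#' @export
trajScript <- function(nFrames, gate = NULL, lipids = NULL, waters = NULL,
                       nDecoysPerLeaflet = 6, jitter = 0, seed = 1L) {
  nFrames <- as.integer(nFrames)
  if (nFrames < 1L) stop("nFrames must be >= 1")
  if (jitter < 0 || jitter > 0.25)
    stop("jitter must be in [0, 0.25] A to preserve the cutoff margins")
  full <- expand.grid(frame = seq_len(nFrames), protomer = c("A", "B"),
                      stringsAsFactors = FALSE)
  if (is.null(gate)) {
    gate <- data.frame(full, ecState = "closed", centralOpen = FALSE)
  } else {
    gate <- merge(full, gate, by = c("frame", "protomer"), all.x = TRUE)
    gate$ecState[is.na(gate$ecState)] <- "closed"
    gate$centralOpen[is.na(gate$centralOpen)] <- FALSE
  }
  if (!all(gate$ecState %in% c("closed", "intermediate", "open")))
    stop("ecState must be closed, intermediate or open")
  if (is.null(lipids))
    lipids <- data.frame(lipid = integer(), protomer = character(),
                         frame = integer(), inGroove = logical(),
                         z = numeric(), tiltDeg = numeric(),
                         nearGate = logical())
  if (is.null(lipids$tiltDeg)) lipids$tiltDeg <- 90
  if (is.null(lipids$nearGate)) lipids$nearGate <- FALSE
  if (is.null(lipids$inGroove)) lipids$inGroove <- FALSE
  if (nrow(lipids)) {
    if (any(lipids$frame < 1 | lipids$frame > nFrames))
      stop("lipid schedule references frames outside 1..nFrames")
    if (any(abs(lipids$z) < 0.6 & lipids$inGroove))
      stop("scripted in-groove z values must keep a 0.6 A margin from the ",
           "membrane mid-point (z = 0)")
    if (any(lipids$nearGate & lipids$inGroove))
      stop("a scripted lipid is either at the gate (nearGate) or on the ",
           "groove axis (inGroove), not both")
    if (any(duplicated(lipids[c("lipid", "protomer", "frame")])))
      stop("duplicate schedule rows for a lipid/frame")
  }
  if (is.null(waters))
    waters <- data.frame(frame = integer(), protomer = character(),
                         nInGroove = integer())
  new("TrajScript", nFrames = nFrames, gate = gate, lipids = lipids,
      waters = waters, nDecoysPerLeaflet = as.integer(nDecoysPerLeaflet),
      box = .TOY$box, jitter = jitter, seed = as.integer(seed))
}

# expand the sparse lipid schedule into per-frame state for every slot
.scriptLipidState <- function(script) {
  slots <- unique(script@lipids[c("lipid", "protomer")])
  out <- vector("list", script@nFrames)   # assigning NULL must keep the slot
  for (f in seq_len(script@nFrames)) {
    nearCount <- c(A = 0L, B = 0L)
    st <- list()
    if (nrow(slots)) for (i in seq_len(nrow(slots))) {
      sl <- slots$lipid[i]; ch <- slots$protomer[i]
      row <- script@lipids[script@lipids$lipid == sl &
                             script@lipids$protomer == ch &
                             script@lipids$frame == f, ]
      if (nrow(row)) {
        nearIdx <- if (isTRUE(row$nearGate[1])) {
          nearCount[ch] <- nearCount[ch] + 1L
          nearCount[ch] - 1L
        } else 0L
        st[[length(st) + 1L]] <- data.frame(
          lipid = sl, protomer = ch, slot = sl,
          inGroove = row$inGroove[1], z = row$z[1],
          tiltDeg = row$tiltDeg[1], nearGate = row$nearGate[1],
          nearIdx = nearIdx)
      } else {
        st[[length(st) + 1L]] <- data.frame(
          lipid = sl, protomer = ch, slot = sl, inGroove = FALSE,
          z = .TOY$leafletZ, tiltDeg = 180, nearGate = FALSE, nearIdx = 0L)
      }
    }
    if (length(st)) out[[f]] <- do.call(rbind, st)
  }
  out
}

# generator-side brute force (plain double loops, no wrapping: all relevant
# pair distances are far below half the box) used to derive the manifest's
# geometric ground truth from the jitter-free coordinates
.bfManifest <- function(sys, coordsByFrame, gate, waters, gdef) {
  at <- sys$atoms
  pr <- c("A", "B")
  nf <- length(coordsByFrame)
  pIdx <- which(at$type == "lipid" & at$elety == "P")
  pIds <- at$molid[pIdx]
  res <- list()
  scIdx <- lapply(pr, function(ch) .sidechainIdx(at, gdef@grooveResidues, ch))
  names(scIdx) <- pr
  gateIdx <- lapply(pr, function(ch)
    c(.residueIdx(at, 313L, ch), .residueIdx(at, 432L, ch)))
  names(gateIdx) <- pr
  caIdx <- lapply(pr, function(ch) vapply(gdef@boundaryResidues, function(r)
    which(at$chain == ch & at$resid == r & at$elety == "CA")[1], 0L))
  names(caIdx) <- pr
  counts <- list()
  for (ch in pr)
    counts[[ch]] <- data.frame(frame = seq_len(nf), groove = 0L, EC = 0L,
                               central = 0L, IC = 0L, nNear = 0L)
  mind <- function(co, I, J) {
    m <- Inf
    for (i in I) {
      d <- sqrt((co[J, 1] - co[i, 1])^2 + (co[J, 2] - co[i, 2])^2 +
                  (co[J, 3] - co[i, 3])^2)
      m <- min(m, min(d))
    }
    m
  }
  for (f in seq_len(nf)) {
    co <- coordsByFrame[[f]]
    for (ch in pr) {
      planes <- sort(co[caIdx[[ch]], 3])
      for (j in seq_along(pIdx)) {
        dmin <- mind(co, pIdx[j], scIdx[[ch]])
        if (dmin <= gdef@lipidCutoff) {
          counts[[ch]]$groove[f] <- counts[[ch]]$groove[f] + 1L
          z <- co[pIdx[j], 3]
          comp <- if (z > planes[2]) "EC"
                  else if (z >= planes[1]) "central" else "IC"
          counts[[ch]][[comp]][f] <- counts[[ch]][[comp]][f] + 1L
        }
        if (mind(co, pIdx[j], gateIdx[[ch]]) <= gdef@nearCutoff)
          counts[[ch]]$nNear[f] <- counts[[ch]]$nNear[f] + 1L
      }
    }
  }
  fIntTruth <- fLipTruth <- numeric(length(pr)); names(fIntTruth) <- pr
  names(fLipTruth) <- pr
  for (ch in pr) {
    g <- gate[gate$protomer == ch, ]
    g <- g[order(g$frame), ]
    fIntTruth[ch] <- mean(g$ecState == "intermediate")
    fLipTruth[ch] <- mean(counts[[ch]]$nNear >= 2L)
  }
  list(counts = counts, fInt = fIntTruth, fLip = fLipTruth)
}

# flip events implied by a lipid schedule (computed from the script, not
# from coordinates): same completion semantics as detectFlips
.scriptFlips <- function(stateByFrame, nFrames, completionZ = 10) {
  if (!length(stateByFrame) || is.null(stateByFrame[[1]]))
    return(data.frame(lipid = character(), start = integer(),
                      end = integer(), direction = character(),
                      completed = logical()))
  slots <- stateByFrame[[1]][c("lipid", "protomer")]
  events <- list()
  for (i in seq_len(nrow(slots))) {
    z <- vapply(stateByFrame, function(s) s$z[i], 0)
    inG <- vapply(stateByFrame, function(s)
      isTRUE(s$inGroove[i]) || isTRUE(s$nearGate[i]), NA)
    # nearGate placement has z ~ +14.5 regardless of the scripted z column
    z[vapply(stateByFrame, function(s) isTRUE(s$nearGate[i]), NA)] <- 14.5
    tilt <- vapply(stateByFrame, function(s) s$tiltDeg[i], 0)
    f <- 1L
    while (f < nFrames) {
      if (sign(z[f]) != sign(z[f + 1]) && (inG[f] || inG[f + 1])) {
        dirUp <- z[f + 1] > z[f]
        end <- NA_integer_; completed <- FALSE
        for (g in (f + 1):nFrames) {
          if (sign(z[g]) == sign(z[f])) { end <- g; break }
          deep <- if (dirUp) z[g] >= completionZ else z[g] <= -completionZ
          if (deep && (if (dirUp) tilt[g] > 90 else tilt[g] < 90)) {
            end <- g; completed <- TRUE; break
          }
        }
        if (is.na(end)) end <- nFrames
        events[[length(events) + 1L]] <- data.frame(
          lipid = sprintf("S%s%d", slots$protomer[i], slots$lipid[i]),
          start = f, end = end,
          direction = if (dirUp) "IC->EC" else "EC->IC",
          completed = completed)
        f <- end
      } else f <- f + 1L
    }
  }
  if (!length(events)) return(data.frame(lipid = character(),
                                         start = integer(), end = integer(),
                                         direction = character(),
                                         completed = logical()))
  do.call(rbind, events)
}

#' Render a scripted toy trajectory
#'
#' Realizes a [TrajScript-class] as coordinates (exactly, up to the
#' truncated jitter) and computes the ground-truth manifest: per-frame
#' gate booleans (from the schedule), per-frame groove / compartment /
#' near-gate lipid counts (from the jitter-free coordinates via an
#' independent plain-loop distance computation), f_int and f_lip per
#' protomer, scripted flip events, and groove water counts. Optionally
#' writes the topology PDB, multi-model coordinate PDB and manifest JSON.
#'
#' @param script a [TrajScript-class]
#' @param dir optional output directory for topology/coordinates/manifest
#' @param gdef groove definition used for the manifest's geometric truths
#' @return list with \code{trajectory} (a [Trajectory-class]),
#'   \code{manifest} (list) and, when \code{dir} is given, \code{files}
#' @export
renderToyTrajectory <- function(script, dir = NULL,
                                gdef = grooveDefinition()) {
  stopifnot(is(script, "TrajScript"))
  nSlots <- if (nrow(script@lipids)) max(script@lipids$lipid) else 1L
  maxWater <- if (nrow(script@waters)) max(script@waters$nInGroove) else 0L
  sys <- .toySystem(script@nDecoysPerLeaflet, nSlots, max(maxWater + 2L, 4L))
  state <- .scriptLipidState(script)
  waterN <- function(f, ch) {
    w <- script@waters
    i <- which(w$frame == f & w$protomer == ch)
    if (length(i)) w$nInGroove[i[1]] else 0L
  }
  nf <- script@nFrames
  coordsByFrame <- vector("list", nf)
  for (f in seq_len(nf)) {
    g <- script@gate[script@gate$frame == f, ]
    coordsByFrame[[f]] <- .toyFrameCoords(
      sys,
      gateA = g$ecState[g$protomer == "A"],
      gateB = g$ecState[g$protomer == "B"],
      centralA = g$centralOpen[g$protomer == "A"],
      centralB = g$centralOpen[g$protomer == "B"],
      lipidState = state[[f]],
      waterA = waterN(f, "A"), waterB = waterN(f, "B"))
  }
  bf <- .bfManifest(sys, coordsByFrame, script@gate, script@waters, gdef)
  xyz <- array(NA_real_, c(nrow(sys$atoms), 3, nf))
  for (f in seq_len(nf)) xyz[, , f] <- coordsByFrame[[f]]
  if (script@jitter > 0) {
    set.seed(script@seed)
    j <- stats::rnorm(length(xyz), sd = script@jitter)
    j <- pmin(pmax(j, -2 * script@jitter), 2 * script@jitter)
    xyz <- xyz + j
  }
  traj <- trajectory(sys$atoms, xyz, box = script@box, center = TRUE)
  gate <- script@gate[order(script@gate$protomer, script@gate$frame), ]
  manifest <- list(
    nFrames = nf,
    jitter = script@jitter,
    gate = data.frame(gate,
                      bond313_432 = gate$ecState == "closed",
                      bond318_432 = gate$ecState == "intermediate"),
    fInt = bf$fInt,
    fLip = bf$fLip,
    counts = bf$counts,
    waters = script@waters,
    flips = .scriptFlips(state, nf))
  out <- list(trajectory = traj, manifest = manifest)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- writeTrajectoryPDB(traj, file.path(dir, "toy"))
    mpath <- file.path(dir, "manifest.json")
    mj <- manifest
    mj$fInt <- as.list(mj$fInt)   # keep protomer names in the JSON
    mj$fLip <- as.list(mj$fLip)
    jsonlite::write_json(mj, mpath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    out$files <- c(files, manifest = mpath)
  }
  out
}

#' A ready-made demonstration script
#'
#' Sixty frames covering the full mechanistic repertoire: protomer A walks
#' through closed -> intermediate -> open gate states with the central
#' constriction opening in the last third, one lipid performs a completed
#' IC->EC flip through the A groove (with the tilt reversing through the
#' event), two lipids crowd the A gate pair in mid-trajectory, and groove
#' hydration rises when the pathway opens. Protomer B stays closed with a
#' transiently gate-bound lipid, so per-protomer averaging is exercised.
#'
#' @param jitter coordinate jitter SD (A); default 0
#' @param seed jitter seed
#' @return a [TrajScript-class]
#' @export
demoTrajScript <- function(jitter = 0, seed = 1L) {
  nf <- 60L
  gate <- rbind(
    data.frame(frame = 1:20, protomer = "A", ecState = "closed",
               centralOpen = FALSE),
    data.frame(frame = 21:40, protomer = "A", ecState = "intermediate",
               centralOpen = FALSE),
    data.frame(frame = 41:60, protomer = "A", ecState = "open",
               centralOpen = TRUE),
    data.frame(frame = 1:60, protomer = "B", ecState = "closed",
               centralOpen = FALSE))
  # lipid 1 on A: enters the groove from the IC leaflet, crosses the
  # mid-point at frame 30/31, completes the flip at z >= 10 with tails
  # pointing back to the IC side
  zpath <- c(seq(-13, -1.5, length.out = 15), seq(1.5, 13, length.out = 15))
  tilt <- c(rep(20, 15), seq(60, 160, length.out = 15))
  lip1 <- rbind(
    data.frame(lipid = 1L, protomer = "A", frame = 1:15, inGroove = FALSE,
               z = -17, tiltDeg = 20, nearGate = FALSE),  # rests IC side
    data.frame(lipid = 1L, protomer = "A", frame = 16:45, inGroove = TRUE,
               z = zpath, tiltDeg = tilt, nearGate = FALSE))
  # lipids 2 and 3 on A: at the gate pair during the intermediate/open phase
  lip2 <- data.frame(lipid = 2L, protomer = "A", frame = 25:50,
                     inGroove = FALSE, z = NA_real_, tiltDeg = 150,
                     nearGate = TRUE)
  lip3 <- data.frame(lipid = 3L, protomer = "A", frame = 31:50,
                     inGroove = FALSE, z = NA_real_, tiltDeg = 150,
                     nearGate = TRUE)
  # lipid 1 on B: briefly at the gate, never in the groove column
  lipB <- data.frame(lipid = 1L, protomer = "B", frame = 5:24,
                     inGroove = FALSE, z = NA_real_, tiltDeg = 150,
                     nearGate = TRUE)
  lipids <- rbind(lip1, lip2, lip3, lipB)
  lipids$z[is.na(lipids$z)] <- 14.5
  waters <- rbind(data.frame(frame = 1:40, protomer = "A", nInGroove = 1L),
                  data.frame(frame = 41:60, protomer = "A", nInGroove = 3L))
  trajScript(nf, gate = gate, lipids = lipids, waters = waters,
             jitter = jitter, seed = seed)
}
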