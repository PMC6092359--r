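# ---- toy system geometry -------------------------------------------------
#
# Protomer-local layout (A at x = 0, B at x = +70): the groove is a vertical
# column at (0, 0) spanning z in [-15, 15]. Groove sidechain atoms sit on a
# radius-4 ring around the axis so a phosphorus on the axis is always within
# ~4.1 A of a sidechain atom (groove cutoff 5, margin ~0.9), while "far"
# molecules are placed at radius >= 18 (all cutoffs cleared by > 2 A).
# Gate geometry: E313 carboxylate at (4, 0, 12), E318 at (4, 3.5, 12); the
# R432 sidechain nitrogens move between three scripted positions (bonded
# distance 2.4, unbonded >= 5.9; gate cutoff 3, margins >= 0.6).
# The central constriction is T333 (sidechain at (-4, 0, 1)) vs the mobile
# Y439 hydroxyl (closed: min distance ~2.1 A, open: >= 5 A).
# Compartment planes: CA of T381 at z = -4, CA of Q436 at z = +4.
# Decoy lipids sit in two leaflets at z = +/-17; each scripted lipid has a
# far "mirror" twin at -z so the membrane mid-point stays exactly at z = 0.

.TOY <- list(
  protomerOffset = 70,
  grooveRingRadius = 4, caRadius = 7,
  farLipidRadius = 18, mirrorRadius = 24, decoyRadius = 20,
  farWaterRadius = 28,
  leafletZ = 17,
  g313 = c(4, 0, 12), g318 = c(4, 3.5, 12),
  r432N = list(closed = c(4, -2.4, 12), intermediate = c(4, 5.9, 12),
               open = c(4, -8, 12)),
  y439OH = list(closed = c(-4, 2.4, 1), open = c(-4, 6.5, 1)),
  nearGatePos = function(k) c(4, 0.8 * k, 14.5),
  # groove waters cluster 2.2 A from the T333 OG1 sidechain atom (cutoff 3),
  # on the side away from the mobile Y439 hydroxyl
  grooveWaterPos = function(k) c(-4, 0, 1) +
    2.2 * c(cos(3.6 + 0.5 * k), sin(3.6 + 0.5 * k), 0),
  box = c(160, 64, 70))

# known residue identities; everything else in the groove list is ALA and
# residue 344 is GLY (exercising the glycine sidechain degeneracy)
.TOY_RESNAMES <- c("302" = "LEU", "306" = "ILE", "310" = "ASN",
                   "313" = "GLU", "315" = "ALA", "316" = "ALA",
                   "317" = "ASN", "318" = "GLU", "333" = "THR",
                   "336" = "LEU", "337" = "VAL", "340" = "THR",
                   "341" = "ALA", "344" = "GLY", "348" = "ALA",
                   "352" = "ALA", "367" = "ALA", "370" = "ALA",
                   "371" = "ALA", "374" = "ALA", "377" = "ALA",
                   "378" = "ALA", "381" = "THR", "382" = "SER",
                   "385" = "ALA", "432" = "ARG", "433" = "ALA",
                   "434" = "ALA", "435" = "ALA", "436" = "GLN",
                   "439" = "TYR", "440" = "PHE", "444" = "ALA",
                   "447" = "ALA", "451" = "ALA", "455" = "ALA",
                   "499" = "ALA", "501" = "ALA", "505" = "ARG",
                   "509" = "ALA", "513" = "ALA")

# sidechain atom names per toy residue type
.TOY_SIDECHAIN <- list(GLU = c("CB", "CD", "OE1", "OE2"),
                       ARG = c("CB", "CZ", "NE", "NH1", "NH2"),
                       THR = c("CB", "OG1", "CG2"),
                       TYR = c("CB", "CZ", "OH"),
                       GLN = c("CB", "CD", "OE1", "NE2"),
                       GLY = character())

.toySidechainNames <- function(resname) {
  if (resname %in% names(.TOY_SIDECHAIN)) .TOY_SIDECHAIN[[resname]] else "CB"
}

# base (frame-independent) local coordinates of one protomer's protein atoms
.toyProtomerBase <- function() {
  resids <- sort(as.integer(names(.TOY_RESNAMES)))
  # anchor positions: c(x, y, z) of the sidechain tip / CA direction
  anchor <- list()
  generic <- setdiff(resids, c(313L, 315L, 316L, 317L, 318L, 333L, 381L,
                               432L, 433L, 434L, 435L, 436L, 439L))
  zs <- seq(-15, 15, length.out = length(generic))
  for (i in seq_along(generic))
    anchor[[as.character(generic[i])]] <-
      c(cos(2.399 * i), sin(2.399 * i), 0) * c(1, 1, 0) + c(0, 0, zs[i])
  # specials: unit direction in x/y plus fixed z
  anchor[["313"]] <- c(1, 0, 12)
  anchor[["318"]] <- c(cos(0.46), sin(0.46), 12)  # sidechain overridden below
  anchor[["333"]] <- c(-1, 0, 1)
  anchor[["381"]] <- c(0, -1, -4)
  anchor[["436"]] <- c(0, 1, 4)
  anchor[["439"]] <- c(-1, -0.05, 1)              # CA parked away from T333
  anchor[["432"]] <- c(1, -0.28, 12)
  for (r in c(315, 316, 317)) anchor[[as.character(r)]] <- c(-1, 0.14, 0)
  for (r in c(433, 434, 435)) anchor[[as.character(r)]] <- c(1, -0.28, 0)

  rows <- list(); pos <- list()
  add <- function(resid, elety, p) {
    rows[[length(rows) + 1L]] <<- data.frame(elety = elety, resid = resid,
      resname = .TOY_RESNAMES[[as.character(resid)]],
      stringsAsFactors = FALSE)
    pos[[length(pos) + 1L]] <<- p
  }
  caZ <- c("315" = 10, "316" = 11, "317" = 12, "318" = 13,
           "432" = 12, "433" = 13, "434" = 14, "435" = 15,
           "439" = 1, "333" = 1, "381" = -4, "436" = 4, "313" = 12)
  for (r in resids) {
    key <- as.character(r)
    a <- anchor[[key]]
    u <- a[1:2] / max(sqrt(sum(a[1:2]^2)), 1e-9)
    z <- if (key %in% names(caZ)) caZ[[key]] else a[3]
    ca <- c(u * .TOY$caRadius, z)
    if (key == "439") ca <- c(-7, -5, 1)           # keep backbone off T333
    add(r, "N", ca + c(0.5, 0, 0.9))
    add(r, "CA", ca)
    add(r, "C", ca + c(-0.5, 0, -0.9))
    add(r, "O", ca + c(-0.9, 0, -1.5))
    rn <- .TOY_RESNAMES[[key]]
    for (sc in .toySidechainNames(rn)) {
      p <- switch(paste(key, sc),
        "313 CB" = c(5, 0, 12), "313 CD" = c(4.5, 0.6, 12),
        "313 OE1" = .TOY$g313, "313 OE2" = .TOY$g313 + c(0, 0, 0.5),
        "318 CB" = c(5, 3.1, 12.5), "318 CD" = c(4.5, 3.4, 12.2),
        "318 OE1" = .TOY$g318, "318 OE2" = .TOY$g318 + c(0, 0, 0.5),
        "333 CB" = c(-4.6, 0.4, 1), "333 OG1" = c(-4, 0, 1),
        "333 CG2" = c(-4.5, -0.8, 1.2),
        "439 CB" = NULL, "439 CZ" = NULL, "439 OH" = NULL,  # frame-dependent
        "432 CB" = c(6, -2, 12), "432 CZ" = NULL, "432 NE" = NULL,
        "432 NH1" = NULL, "432 NH2" = NULL,                 # frame-dependent
        "436 CB" = c(0, 4, 4), "436 CD" = c(0.3, 4, 4.2),
        "436 OE1" = c(0.5, 4.4, 4), "436 NE2" = c(-0.5, 4.4, 4),
        c(u * .TOY$grooveRingRadius, z))        # generic ring sidechain
      if (!is.null(p)) add(r, sc, p)
      else add(r, sc, c(NA_real_, NA_real_, NA_real_))  # filled per frame
    }
  }
  list(atoms = do.call(rbind, rows), pos = do.call(rbind, pos))
}

#' Build the toy topology
#'
#' A minimal two-protomer pseudo-protein carrying every residue referenced
#' by the default [grooveDefinition()] (4WIS numbering) as small labeled
#' atom groups (backbone N/CA/C/O plus type-appropriate sidechain atoms:
#' Glu carboxyl oxygens, Arg sidechain nitrogens, Thr/Tyr/Gln polar atoms;
#' residue 344 is a glycine whose sidechain degenerates to CA), together
#' with bulk lipids (P plus two tail carbons) and waters. The returned
#' single-frame [Trajectory-class] corresponds to both gates closed and no
#' molecule in the groove; [renderToyTrajectory()] animates the same
#' topology from a [TrajScript-class].
#'
#' @param nDecoysPerLeaflet bulk lipids per leaflet per protomer (default 6)
#' @param nScriptedLipids number of scripted (mobile) lipid slots
#' @param nWaters water pool size per protomer
#' @return a single-frame [Trajectory-class]
#' @export
buildToyTopology <- function(nDecoysPerLeaflet = 6, nScriptedLipids = 3,
                             nWaters = 6) {
  sys <- .toySystem(nDecoysPerLeaflet, nScriptedLipids, nWaters)
  xyz <- array(.toyFrameCoords(sys, gateA = "closed", gateB = "closed",
                               centralA = FALSE, centralB = FALSE,
                               lipidState = NULL, waterA = 0, waterB = 0),
               dim = c(nrow(sys$atoms), 3, 1))
  trajectory(sys$atoms, xyz, box = .TOY$box, center = TRUE)
}

# full system: atoms table + static base coordinates + bookkeeping indices
.toySystem <- function(nDecoysPerLeaflet, nScriptedLipids, nWaters) {
  base <- .toyProtomerBase()
  np <- nrow(base$atoms)
  atoms <- list(); pos <- list()
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else .TOY$protomerOffset
    a <- base$atoms
    a$chain <- ch; a$type <- "protein"; a$molid <- ""
    atoms[[length(atoms) + 1L]] <- a
    p <- base$pos; p[, 1] <- p[, 1] + off
    pos[[length(pos) + 1L]] <- p
  }
  molCounter <- 0L
  addMol <- function(ch, molid, resname, elety, p, type) {
    molCounter <<- molCounter + 1L   # unique resid so PDB IO keeps molecules
    atoms[[length(atoms) + 1L]] <<- data.frame(
      elety = elety, resid = molCounter, resname = resname, chain = ch,
      type = type, molid = molid, stringsAsFactors = FALSE)
    pos[[length(pos) + 1L]] <<- p
  }
  lipAt <- function(P, tiltDeg, phi = 0) {
    u <- c(sin(tiltDeg * pi / 180) * cos(phi),
           sin(tiltDeg * pi / 180) * sin(phi), cos(tiltDeg * pi / 180))
    rbind(P, P + 2 * u, P + 4 * u)
  }
  # bulk decoys: symmetric leaflets, tails towards the membrane core
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else .TOY$protomerOffset
    for (leaf in c(1, -1)) {
      for (k in seq_len(nDecoysPerLeaflet)) {
        ang <- 2 * pi * k / nDecoysPerLeaflet + (leaf + 1) * 0.3
        P <- c(off + .TOY$decoyRadius * cos(ang),
               .TOY$decoyRadius * sin(ang), leaf * .TOY$leafletZ)
        addMol(ch = "L", molid = sprintf("D%s%d%s", ch, k,
                                         if (leaf > 0) "u" else "l"),
               resname = "LIP", elety = c("P", "C21", "C22"),
               p = lipAt(P, if (leaf > 0) 180 else 0), type = "lipid")
      }
    }
  }
  # scripted lipid slots and their mirrors; the resting position is far
  # from the groove in the outer leaflet (overwritten per rendered frame)
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else .TOY$protomerOffset
    for (k in seq_len(nScriptedLipids)) {
      rest <- c(off + .TOY$farLipidRadius * cos(2.1 * k),
                .TOY$farLipidRadius * sin(2.1 * k), .TOY$leafletZ)
      addMol("L", sprintf("S%s%d", ch, k), "LIP", c("P", "C21", "C22"),
             lipAt(rest, 180), "lipid")
      addMol("L", sprintf("M%s%d", ch, k), "LIP", c("P", "C21", "C22"),
             lipAt(c(off + .TOY$mirrorRadius, 2 * k, -.TOY$leafletZ), 0),
             "lipid")
    }
  }
  # water pools per protomer
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else .TOY$protomerOffset
    for (k in seq_len(nWaters)) {
      O <- c(off + .TOY$farWaterRadius, 2 * k, 20)
      addMol("W", sprintf("W%s%d", ch, k), "HOH", c("O", "H1", "H2"),
             rbind(O, O + c(0.6, 0, 0.3), O + c(-0.6, 0, 0.3)), "water")
    }
  }
  atoms <- do.call(rbind, atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  list(atoms = atoms[c("eleno", "elety", "resid", "resname", "chain",
                       "type", "molid")],
       base = do.call(rbind, pos),
       nDecoysPerLeaflet = nDecoysPerLeaflet,
       nScriptedLipids = nScriptedLipids, nWaters = nWaters)
}

# coordinates of one frame (no jitter); lipidState: data.frame(lipid,
# protomer, slot, inGroove, z, tiltDeg, nearGate, nearIdx)
.toyFrameCoords <- function(sys, gateA, gateB, centralA, centralB,
                            lipidState, waterA, waterB) {
  co <- sys$base
  at <- sys$atoms
  setAtoms <- function(chain, resid, elety, p) {
    i <- which(at$chain == chain & at$resid == resid & at$elety %in% elety &
                 at$type == "protein")
    co[i, ] <<- p
  }
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else .TOY$protomerOffset
    gate <- if (ch == "A") gateA else gateB
    central <- if (ch == "A") centralA else centralB
    rN <- .TOY$r432N[[gate]] + c(off, 0, 0)
    setAtoms(ch, 432, "NH1", matrix(rN, 1))
    setAtoms(ch, 432, "NE", matrix(rN + c(0, 0, 0.5), 1))
    setAtoms(ch, 432, "NH2", matrix(rN + c(0, 0, -0.5), 1))
    setAtoms(ch, 432, "CZ", matrix(rN + c(0.7, 0, 0), 1))
    oh <- .TOY$y439OH[[if (central) "open" else "closed"]] + c(off, 0, 0)
    setAtoms(ch, 439, "OH", matrix(oh, 1))
    setAtoms(ch, 439, "CZ", matrix(oh + c(0, 0.5, 0.3), 1))
    setAtoms(ch, 439, "CB", matrix(oh + c(0.6, -2, 0), 1))
  }
  placeLip <- function(molid, P, tiltDeg, phi = 0) {
    i <- which(at$molid == molid)
    u <- c(sin(tiltDeg * pi / 180) * cos(phi),
           sin(tiltDeg * pi / 180) * sin(phi), cos(tiltDeg * pi / 180))
    co[i, ] <<- rbind(P, P + 2 * u, P + 4 * u)
  }
  if (!is.null(lipidState)) {
    for (i in seq_len(nrow(lipidState))) {
      ls <- lipidState[i, ]
      off <- if (ls$protomer == "A") 0 else .TOY$protomerOffset
      P <- if (isTRUE(ls$nearGate))
        .TOY$nearGatePos(ls$nearIdx) + c(off, 0, 0)
      else if (isTRUE(ls$inGroove)) c(off, 0, ls$z)
      else c(off + .TOY$farLipidRadius * cos(2.1 * ls$slot),
             .TOY$farLipidRadius * sin(2.1 * ls$slot), ls$z)
      placeLip(sprintf("S%s%d", ls$protomer, ls$slot), P, ls$tiltDeg)
      placeLip(sprintf("M%s%d", ls$protomer, ls$slot),
               c(off + .TOY$mirrorRadius, 2 * ls$slot, -P[3]), 90)
    }
  }
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else .TOY$protomerOffset
    nIn <- if (ch == "A") waterA else waterB
    for (k in seq_len(sys$nWaters)) {
      i <- which(at$molid == sprintf("W%s%d", ch, k))
      O <- if (k <= nIn) .TOY$grooveWaterPos(k) + c(off, 0, 0)
      else c(off + .TOY$farWaterRadius, 2 * k, 20)
      co[i, ] <- rbind(O, O + c(0.6, 0, 0.3), O + c(-0.6, 0, 0.3))
    }
  }
  co
}
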