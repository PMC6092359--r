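#' Default groove definition
#'
#' Constructs a [GrooveDefinition-class] with the published residue lists
#' (4WIS numbering) and cutoffs; any component can be overridden.
#'
#' @param grooveResidues residues lining the groove
#' @param waterCutoff,lipidCutoff,contactCutoff,gateCutoff,nearCutoff
#'   distance cutoffs in Angstrom (3, 5, 7, 3, 5 by default)
#' @param boundaryResidues the two residues whose C-alpha x/y planes bound
#'   the central compartment (T381, Q436)
#' @param tm3Span,tm6Span C-alpha spans defining the TM3-TM6 opening
#' @return a [GrooveDefinition-class]
#' @examples
#' grooveDefinition()
#' grooveDefinition(lipidCutoff = 6)
#' @export
grooveDefinition <- function(grooveResidues = c(302L, 306L, 310L, 313L, 333L,
                               336L, 337L, 340L, 341L, 344L, 348L, 352L,
                               367L, 370L, 371L, 374L, 377L, 378L, 381L,
                               382L, 385L, 432L, 436L, 439L, 440L, 444L,
                               447L, 451L, 455L, 499L, 501L, 505L, 509L,
                               513L),
                             waterCutoff = 3, lipidCutoff = 5,
                             contactCutoff = 7, gateCutoff = 3,
                             nearCutoff = 5,
                             boundaryResidues = c(381L, 436L),
                             tm3Span = 315:318, tm6Span = 432:435) {
  new("GrooveDefinition", grooveResidues = as.integer(grooveResidues),
      waterCutoff = waterCutoff, lipidCutoff = lipidCutoff,
      contactCutoff = contactCutoff, gateCutoff = gateCutoff,
      nearCutoff = nearCutoff,
      boundaryResidues = as.integer(boundaryResidues),
      tm3Span = as.integer(tm3Span), tm6Span = as.integer(tm6Span),
      gateResidues = c(e313 = 313L, e318 = 318L, t333 = 333L, r432 = 432L,
                       q436 = 436L, y439 = 439L))
}

# residue names recognised as water / lipid in topologies
.WATER_RESNAMES <- c("HOH", "TIP3", "TIP", "WAT", "SOL", "SPC")
.LIPID_RESNAMES <- c("POPC", "POPE", "POPG", "PC", "PE", "PG", "LIP", "DPPC",
                     "DOPC")

#' Construct a trajectory object
#'
#' Assembles a [Trajectory-class] from an atom table and a coordinate
#' array, optionally shifting each frame along z so that the membrane
#' mid-point (mean z of all lipid phosphorus atoms) is at z = 0.
#'
#' @param atoms atom table (see [Trajectory-class])
#' @param xyz numeric array \code{c(nAtoms, 3, nFrames)}
#' @param box nFrames x 3 matrix of orthorhombic box lengths, or a single
#'   length-3 vector recycled over frames, or \code{NA} for no periodicity
#' @param times frame times (ns); defaults to the frame index
#' @param center center the membrane mid-point at z = 0 per frame (default
#'   \code{TRUE})
#' @return a [Trajectory-class]
#' @export
trajectory <- function(atoms, xyz, box = NA, times = NULL, center = TRUE) {
  nf <- dim(xyz)[3]
  if (is.null(dim(box))) box <- matrix(rep(as.numeric(box), length.out = 3),
                                       nrow = nf, ncol = 3, byrow = TRUE)
  if (is.null(times)) times <- seq_len(nf) - 1
  obj <- new("Trajectory", atoms = atoms, xyz = xyz, box = box,
             times = as.numeric(times))
  if (center) {
    pIdx <- .lipidPIdx(atoms)
    if (length(pIdx)) {
      for (f in seq_len(nf)) {
        mid <- mean(obj@xyz[pIdx, 3, f])
        obj@xyz[, 3, f] <- obj@xyz[, 3, f] - mid
      }
    }
  }
  obj
}

#' Read a labeled trajectory from topology and coordinate files
#'
#' The topology is a PDB (4WIS residue numbering, one chain per protomer).
#' Coordinates may come from a DCD file, a multi-model PDB, or be omitted
#' (single-frame analysis of the topology itself). Atoms are classified as
#' water or lipid by residue name; everything else is protein. Frames are
#' centered so the membrane mid-point is at z = 0.
#'
#' @param topology path to a PDB file
#' @param coords optional path to a DCD or multi-model PDB file
#' @param box orthorhombic box lengths (A): length-3 vector or nFrames x 3
#'   matrix; \code{NA} (default) disables periodic wrapping
#' @param times frame times (ns)
#' @param center center the membrane mid-point at z = 0
#' @param waterResnames,lipidResnames residue names classified as water /
#'   lipid
#' @return a [Trajectory-class]
#' @export
readTrajectory <- function(topology, coords = NULL, box = NA, times = NULL,
                           center = TRUE,
                           waterResnames = .WATER_RESNAMES,
                           lipidResnames = .LIPID_RESNAMES) {
  pdb <- bio3d::read.pdb(topology, multi = is.null(coords), verbose = FALSE)
  at <- pdb$atom
  type <- ifelse(at$resid %in% waterResnames, "water",
                 ifelse(at$resid %in% lipidResnames, "lipid", "protein"))
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  atoms <- data.frame(eleno = at$eleno, elety = at$elety, resid = at$resno,
                      resname = at$resid, chain = chain, type = type,
                      molid = ifelse(type == "protein", "",
                                     paste(chain, at$resno, sep = ":")),
                      stringsAsFactors = FALSE)
  xyzmat <- if (is.null(coords)) {
    pdb$xyz
  } else if (grepl("\\.dcd$", coords, ignore.case = TRUE)) {
    bio3d::read.dcd(coords, verbose = FALSE)
  } else {
    bio3d::read.pdb(coords, multi = TRUE, verbose = FALSE)$xyz
  }
  xyzmat <- matrix(xyzmat, ncol = 3 * nrow(atoms))
  nf <- nrow(xyzmat)
  xyz <- array(NA_real_, c(nrow(atoms), 3, nf))
  for (f in seq_len(nf))
    xyz[, , f] <- matrix(xyzmat[f, ], ncol = 3, byrow = TRUE)
  trajectory(atoms, xyz, box = box, times = times, center = center)
}

#' Write a trajectory as topology + multi-model PDB
#'
#' Writes \code{<prefix>_top.pdb} (frame 1, the topology) and
#' \code{<prefix>_traj.pdb} (all frames as PDB MODEL records). Coordinates
#' are quantized to the 0.001 A PDB field precision.
#'
#' @param traj a [Trajectory-class]
#' @param prefix output path prefix
#' @return invisibly, the two file paths
#' @export
writeTrajectoryPDB <- function(traj, prefix) {
  atoms <- traj@atoms
  nf <- dim(traj@xyz)[3]
  resid3 <- substr(ifelse(atoms$resname == "", "UNK", atoms$resname), 1, 4)
  frameFile <- function(file, f, append = FALSE) {
    xyz <- as.numeric(t(traj@xyz[, , f]))
    bio3d::write.pdb(file = file, xyz = xyz, resno = atoms$resid,
                     resid = resid3, elety = atoms$elety,
                     chain = atoms$chain, eleno = atoms$eleno, end = FALSE)
  }
  topPath <- paste0(prefix, "_top.pdb")
  trjPath <- paste0(prefix, "_traj.pdb")
  frameFile(topPath, 1)
  cat("END\n", file = topPath, append = TRUE)
  tmp <- tempfile(fileext = ".pdb")
  cat("", file = trjPath)
  for (f in seq_len(nf)) {
    cat(sprintf("MODEL     %d\n", f), file = trjPath, append = TRUE)
    frameFile(tmp, f)
    file.append(trjPath, tmp)
    cat("ENDMDL\n", file = trjPath, append = TRUE)
  }
  cat("END\n", file = trjPath, append = TRUE)
  unlink(tmp)
  invisible(c(topology = topPath, coords = trjPath))
}
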