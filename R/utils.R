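# ---- internal geometry helpers ------------------------------------------

# Pairwise Euclidean distances between coordinate matrices A (n x 3) and
# B (m x 3) under the minimum-image convention for an orthorhombic box.
# box: length-3 vector of box edges (A) or NA to disable wrapping.
.pairDist <- function(A, B, box = NA) {
  A <- matrix(A, ncol = 3)
  B <- matrix(B, ncol = 3)
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    if (!any(is.na(box)) && is.finite(box[k]) && box[k] > 0)
      dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# Minimum distance between two atom groups.
.minDist <- function(A, B, box = NA) min(.pairDist(A, B, box))

# Heavy (non-hydrogen) atom filter on elety names.
.isHeavy <- function(elety) !grepl("^[0-9]*H", elety)

# Backbone atom names excluded from the sidechain definition.
.BACKBONE <- c("N", "CA", "C", "O", "OXT")

# Row indices of the sidechain heavy atoms of the given protein residues on
# one chain. Glycine has no sidechain heavy atom and degenerates to CA;
# affected residue ids are recorded in the "glycineCA" attribute.
.sidechainIdx <- function(atoms, resids, chain) {
  sel <- which(atoms$type == "protein" & atoms$chain == chain &
                 atoms$resid %in% resids &
                 !(atoms$elety %in% .BACKBONE) & .isHeavy(atoms$elety))
  covered <- unique(atoms$resid[sel])
  missing <- setdiff(resids[resids %in% atoms$resid[atoms$chain == chain]],
                     covered)
  gly <- integer()
  if (length(missing)) {
    ca <- which(atoms$type == "protein" & atoms$chain == chain &
                  atoms$resid %in% missing & atoms$elety == "CA")
    sel <- c(sel, ca)
    gly <- missing
  }
  structure(sel, glycineCA = gly)
}

# Row indices of all atoms (any name) of the given residues on one chain.
.residueIdx <- function(atoms, resids, chain)
  which(atoms$type == "protein" & atoms$chain == chain &
          atoms$resid %in% resids)

# Row indices of lipid phosphorus atoms; names give the molecule ids.
.lipidPIdx <- function(atoms) {
  idx <- which(atoms$type == "lipid" & atoms$elety == "P")
  names(idx) <- atoms$molid[idx]
  idx
}

# check a residue is present on a chain, with a useful error
.requireResidue <- function(atoms, resid, chain, what = "residue") {
  if (!any(atoms$type == "protein" & atoms$chain == chain &
             atoms$resid == resid))
    stop(sprintf("%s %d is missing from protomer %s", what, resid, chain))
}
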