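# groove membership, compartments, contacts, gates: checked against the
# scripted manifest (exact at zero jitter) and an independent brute-force
# distance oracle on randomized frames

demo <- renderToyTrajectory(demoTrajScript())
tr <- demo$trajectory
man <- demo$manifest

test_that("groove lipid membership applies the 5 A sidechain cutoff", {
  # boundary cases approached from below the groove along its axis, where
  # the nearest sidechain atom is computed explicitly from the topology
  topo <- buildToyTopology()
  at <- atoms(topo); co <- frameCoords(topo, 1)
  sc <- scramblr:::.sidechainIdx(at, grooveDefinition()@grooveResidues, "A")
  nearest <- function(P) min(sqrt(colSums((t(co[sc, ]) - P)^2)))
  zGrid <- seq(-25, -15, by = 0.001)
  dGrid <- vapply(zGrid, function(z) nearest(c(0, 0, z)), 0)
  zIn <- zGrid[which.min(abs(dGrid - 4.9))]    # ~4.9 A from the closest
  zOut <- zGrid[which.min(abs(dGrid - 5.1))]   # ~5.1 A from everything
  t1 <- toy_frame_with(lipid_atoms("X1", c(0, 0, zIn)))
  expect_true("X1" %in% grooveLipidIds(t1, 1, protomer = "A"))
  t2 <- toy_frame_with(lipid_atoms("X2", c(0, 0, zOut)))
  expect_false("X2" %in% grooveLipidIds(t2, 1, protomer = "A"))
  expect_length(grooveLipidIds(t1, 1), 2)  # named list over protomers
})

test_that("groove and compartment counts match the manifest exactly", {
  for (f in c(1, 10, 22, 30, 35, 44, 55, 60)) {
    for (ch in c("A", "B")) {
      cnt <- man$counts[[ch]]
      expect_identical(length(grooveLipidIds(tr, f, protomer = ch)),
                       as.integer(cnt$groove[f]))
      occ <- compartmentOccupancy(tr, f, protomer = ch)
      expect_identical(unname(occ),
                       as.integer(c(cnt$EC[f], cnt$central[f], cnt$IC[f])))
    }
  }
})

test_that("occupancy distributions are normalized and protomer-averaged", {
  for (rg in c("groove", "EC", "central", "IC")) {
    h <- occupancyDistribution(tr, region = rg)
    expect_equal(sum(h), 1)
    expect_true(all(h >= 0))
    # protomer averaging equals the hand average of per-protomer histograms
    perCh <- lapply(c("A", "B"), function(ch) {
      counts <- vapply(seq_len(nFrames(tr)), function(f) {
        if (rg == "groove") length(grooveLipidIds(tr, f, protomer = ch))
        else compartmentOccupancy(tr, f, protomer = ch)[[rg]]
      }, 0L)
      vapply(0:(length(h) - 1), function(k) mean(counts == k), 0)
    })
    expect_equal(unname(h), (perCh[[1]] + perCh[[2]]) / 2)
  }
  # all-empty toy: single bin at zero
  empty <- renderToyTrajectory(trajScript(5))$trajectory
  expect_equal(occupancyDistribution(empty), c("0" = 1))
})

test_that("groove water counts follow the scripted hydration schedule", {
  wA <- vapply(seq_len(nFrames(tr)), function(f)
    grooveWaterCount(tr, f, protomer = "A"), 0L)
  expect_equal(wA, c(rep(1L, 40), rep(3L, 20)))
  expect_equal(vapply(1:5, function(f)
    grooveWaterCount(tr, f, protomer = "B"), 0L), rep(0L, 5))
  # any-atom rule: an H inside the cutoff counts even if O is outside
  w <- list(atoms = data.frame(eleno = 0L, elety = c("O", "H1", "H2"),
                               resid = 9500L, resname = "HOH", chain = "W",
                               type = "water", molid = "WX"),
            pos = rbind(c(-4, 0, 1 + 3.1), c(-4, 0, 1 + 2.8),
                        c(-4, 0.6, 1 + 3.4)))
  expect_identical(grooveWaterCount(toy_frame_with(w), 1, protomer = "A"), 1L)
})

test_that("distance operations agree with the brute-force oracle", {
  gdef <- grooveDefinition()
  at <- atoms(tr)
  pIdx <- which(at$type == "lipid" & at$elety == "P")
  set.seed(31)
  for (f in sample(nFrames(tr), 4)) {
    co <- frameCoords(tr, f)
    box <- boxDims(tr, f)
    for (ch in c("A", "B")) {
      scSel <- at$type == "protein" & at$chain == ch &
        at$resid %in% gdef@grooveResidues &
        !(at$elety %in% c("N", "CA", "C", "O", "OXT")) &
        !grepl("^[0-9]*H", at$elety)
      scCo <- co[scSel, , drop = FALSE]
      inG <- vapply(pIdx, function(i)
        oracle_min_dist(co[i, , drop = FALSE], scCo, box) <= 5, NA)
      expect_setequal(grooveLipidIds(tr, f, protomer = ch),
                      at$molid[pIdx][inG])
    }
    # residue contacts (protomer-averaged) for a handful of residues
    one <- trajectory(at, array(co, c(nrow(at), 3, 1)),
                      box = box, center = FALSE)
    for (r in c(313, 381, 432, 505)) {
      hit <- mean(vapply(c("A", "B"), function(ch) {
        resSel <- at$type == "protein" & at$chain == ch & at$resid == r
        any(vapply(pIdx, function(i)
          oracle_min_dist(co[i, , drop = FALSE],
                          co[resSel, , drop = FALSE], box) <= 7, NA))
      }, NA))
      expect_equal(residueContactFrequency(one, r, gdef)$frequency, hit)
    }
  }
})

test_that("gate states reproduce the scripted schedule", {
  gs <- gateState(tr)
  for (ch in c("A", "B")) {
    m <- man$gate[man$gate$protomer == ch, ]
    g <- gs[gs$protomer == ch, ]
    expect_equal(g$bond313_432, m$bond313_432)
    expect_equal(g$bond318_432, m$bond318_432)
    expect_equal(g$nLipidsNear, man$counts[[ch]]$nNear)
  }
  expect_equal(fInt(tr), man$fInt)
  expect_equal(fLip(tr), man$fLip)
  # hand-built boundary case: E318 bonded, E313 not
  g1 <- gs[gs$protomer == "A" & gs$frame == 25, ]
  expect_true(g1$bond318_432); expect_false(g1$bond313_432)
  g2 <- gs[gs$protomer == "A" & gs$frame == 50, ]    # fully open
  expect_false(g2$bond318_432); expect_false(g2$bond313_432)
})

test_that("gate distances match hand-computed toy geometry", {
  # frame 1, protomer A: R432 N cluster at (4, -2.4, 12), E313 O at
  # (4, 0, 12)/(4, 0, 12.5); minimum distance is 2.4 by construction
  gs <- gateState(tr, protomer = "A")
  expect_equal(gs$d313_432[1], 2.4, tolerance = 1e-12)
  expect_equal(gs$d318_432[21], 2.4, tolerance = 1e-12)
  expect_equal(gs$d313_432[21], 5.9, tolerance = 1e-12)
})

test_that("TM3-TM6 opening is the distance of the CA centers of mass", {
  at <- atoms(tr); co <- frameCoords(tr, 1)
  com <- function(resids) colMeans(co[at$type == "protein" &
    at$chain == "A" & at$resid %in% resids & at$elety == "CA", ])
  expect_equal(tm3tm6Opening(tr, protomer = "A", frame = 1),
               sqrt(sum((com(315:318) - com(432:435))^2)))
  # translation invariance
  co2 <- sweep(co, 2, c(3.2, -1.1, 7.7), "+")
  tr2 <- trajectory(atoms(tr), array(co2, c(nrow(at), 3, 1)),
                    box = boxDims(tr, 1), center = FALSE)
  expect_equal(tm3tm6Opening(tr2, protomer = "A", frame = 1),
               tm3tm6Opening(tr, protomer = "A", frame = 1))
})

test_that("rigid in-plane transformations leave the metrics unchanged", {
  at <- atoms(tr); co <- frameCoords(tr, 30)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  co2 <- sweep(co %*% R, 2, c(5, -3, 0), "+")   # keep z structure intact
  mk <- function(cc) trajectory(at, array(cc, c(nrow(at), 3, 1)),
                                box = NA, center = FALSE)
  t1 <- mk(co); t2 <- mk(co2)
  expect_equal(gateState(t2)$d313_432, gateState(t1)$d313_432)
  expect_setequal(grooveLipidIds(t2, 1, protomer = "A"),
                  grooveLipidIds(t1, 1, protomer = "A"))
  expect_equal(tm3tm6Opening(t2, protomer = "A", frame = 1),
               tm3tm6Opening(t1, protomer = "A", frame = 1))
})

test_that("lipid tilt measures the P-to-tail angle against the z axis", {
  t1 <- toy_frame_with(lipid_atoms("T1", c(30, 25, 0), tilt = 180))
  expect_equal(lipidTilt(t1, "T1", frame = 1), 180)
  t2 <- toy_frame_with(lipid_atoms("T2", c(30, 25, 0), tilt = 90))
  expect_equal(lipidTilt(t2, "T2", frame = 1), 90)
  expect_error(lipidTilt(t1, "nope", frame = 1), "phosphorus")
  # the scripted flip shows a monotone tilt reversal through the event
  tracked <- man$flips$lipid[1]
  tilt <- lipidTilt(tr, "SA1")
  expect_lt(tilt[20], 30); expect_gt(tilt[45], 150)
  expect_true(all(diff(tilt[31:45]) > -1e-9))
})

test_that("flip detection recovers the scripted events exactly", {
  fl <- detectFlips(tr)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$direction, "IC->EC")
  expect_true(fl$completed)
  expect_equal(fl$start, man$flips$start)
  expect_equal(fl$end, man$flips$end)
  # a dip below the mid-point that returns is not a completed flip
  dipZ <- c(-13, -8, -3, 2, 6, 8, 6, 2, -3, -8)
  dip <- trajScript(10, lipids = data.frame(
    lipid = 1L, protomer = "A", frame = 1:10, inGroove = TRUE, z = dipZ,
    tiltDeg = 20, nearGate = FALSE))
  fl2 <- detectFlips(renderToyTrajectory(dip)$trajectory)
  expect_true(all(!fl2$completed))
  # two flips on different protomers give two events
  two <- trajScript(12, lipids = rbind(
    data.frame(lipid = 1L, protomer = "A", frame = 1:12, inGroove = TRUE,
               z = seq(-13, 13, length.out = 12),
               tiltDeg = seq(20, 160, length.out = 12), nearGate = FALSE),
    data.frame(lipid = 1L, protomer = "B", frame = 1:12, inGroove = TRUE,
               z = seq(13, -13, length.out = 12),
               tiltDeg = seq(160, 20, length.out = 12), nearGate = FALSE)))
  fl3 <- detectFlips(renderToyTrajectory(two)$trajectory)
  expect_equal(nrow(fl3), 2)
  expect_setequal(fl3$direction, c("IC->EC", "EC->IC"))
  expect_true(all(fl3$completed))
})

test_that("contact frequencies respect the 65% hot-residue threshold", {
  # a lipid parked 6.5 A from T381's OG1 for all frames -> frequency 1, hot
  lp <- lipid_atoms("C1", c(0, -4, -4 - 6.5))
  one <- toy_frame_with(lp)
  fr <- residueContactFrequency(one, 381, protomer = "A")
  expect_equal(fr$frequency, 1)
  expect_true(fr$hot)
  expect_equal(residueContactFrequency(one, 381)$frequency, 0.5)  # averaged
  # per-protomer frequencies of 0.64 / 0.66 straddle the threshold
  mk <- function(nin, ntot) {
    sc <- trajScript(ntot, lipids = data.frame(
      lipid = 1L, protomer = "A",
      frame = seq_len(ntot), inGroove = c(rep(TRUE, nin),
                                          rep(FALSE, ntot - nin)),
      z = 1.5, tiltDeg = 90, nearGate = FALSE))
    renderToyTrajectory(sc)$trajectory
  }
  fr64 <- residueContactFrequency(mk(32, 50), 333, protomer = "A")
  expect_equal(fr64$frequency, 0.64)
  expect_false(fr64$hot)
  fr66 <- residueContactFrequency(mk(33, 50), 333, protomer = "A")
  expect_equal(fr66$frequency, 0.66)
  expect_true(fr66$hot)
})

test_that("the eight tICA features share the gate-state computation", {
  ft <- ticaFeatures(tr, protomer = "A")
  gs <- gateState(tr, protomer = "A")
  expect_identical(ft[, "gate_E313_R432"], gs$d313_432)
  expect_identical(ft[, "gate_E318_R432"], gs$d318_432)
  expect_identical(ft[, "dmin_T333_Y439"], gs$d333_439)
  expect_equal(attr(ft, "trackedLipid"), "SA1")
  # feature 1 sign convention: EC side positive
  at <- atoms(tr)
  pI <- which(at$molid == "SA1" & at$elety == "P")
  caI <- which(at$chain == "A" & at$resid == 432 & at$elety == "CA")
  expect_equal(ft[, 1],
               tr@xyz[pI, 3, ] - tr@xyz[caI, 3, ],
               ignore_attr = TRUE)
  expect_gt(ft[44, 1], 0)   # lipid above R432 near completion
  # piecewise-linear z path while in the groove
  seg <- ft[16:30, 1]
  expect_lt(max(abs(residuals(lm(seg ~ seq_along(seg))))), 1e-9)
})

test_that("glycine sidechains degenerate to CA and are flagged", {
  at <- atoms(tr)
  idx <- scramblr:::.sidechainIdx(at, grooveDefinition()@grooveResidues, "A")
  expect_true(344 %in% attr(idx, "glycineCA"))
  expect_true(any(at$resid[idx] == 344 & at$elety[idx] == "CA"))
})

test_that("metrics stay at their scripted values under 0.2 A jitter", {
  rj <- renderToyTrajectory(demoTrajScript(jitter = 0.2, seed = 11))
  tj <- rj$trajectory
  expect_equal(fInt(tj), man$fInt)
  expect_equal(fLip(tj), man$fLip)
  fl <- detectFlips(tj)
  expect_equal(nrow(fl), 1)
  expect_true(fl$completed)
  expect_equal(occupancyDistribution(tj), occupancyDistribution(tr))
})
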