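# Independent oracles kept deliberately naive: plain double loops and a
# hand-written minimum-image wrap, no shared code with the package internals.

# scalar minimum-image distance
oracle_dist <- function(a, b, box = NA) {
  d <- a - b
  if (!any(is.na(box))) {
    for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
  }
  sqrt(sum(d^2))
}

# minimum distance between two sets of points (matrices n x 3)
oracle_min_dist <- function(A, B, box = NA) {
  m <- Inf
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      m <- min(m, oracle_dist(A[i, ], B[j, ], box))
  m
}

# numerical ODE solution of the scrambling/bleaching two-state system,
# started from the scramblase equilibrium; returns F(t) = Li + Lo
oracle_ode_fscr <- function(t, alpha, beta, gamma) {
  rhs <- function(t, y, p)
    list(c(-p$a * y[1] + p$b * y[2], p$a * y[1] - (p$b + p$g) * y[2]))
  y0 <- c(beta, alpha) / (alpha + beta)
  tt <- sort(unique(c(0, t)))
  out <- deSolve::ode(y0, tt, rhs, list(a = alpha, b = beta, g = gamma),
                      rtol = 1e-12, atol = 1e-14)
  f <- rowSums(out[, 2:3, drop = FALSE])
  f[match(t, tt)]
}

# quick kinetic parameter sets used across tests
pWTslow <- function(leak = 0)
  kineticParams(alpha = 0.001, gamma = 2, f0 = 0.55, liPF = 0.5, leak = leak)

# ad-hoc single-frame trajectory around the toy topology with lipids/waters
# placed at explicit coordinates (no centering so positions stay literal)
toy_frame_with <- function(extra = NULL) {
  topo <- buildToyTopology()
  at <- atoms(topo)
  co <- frameCoords(topo, 1)
  if (!is.null(extra)) {
    at <- rbind(at, extra$atoms[names(at)])
    co <- rbind(co, extra$pos)
  }
  at$eleno <- seq_len(nrow(at))
  xyz <- array(co, dim = c(nrow(at), 3, 1))
  trajectory(at, xyz, box = c(160, 64, 70), center = FALSE)
}

lipid_atoms <- function(molid, P, tilt = 180) {
  u <- c(sin(tilt * pi / 180), 0, cos(tilt * pi / 180))
  list(atoms = data.frame(eleno = 0L, elety = c("P", "C21", "C22"),
                          resid = 9000L + abs(sum(utf8ToInt(molid))),
                          resname = "LIP", chain = "L", type = "lipid",
                          molid = molid),
       pos = rbind(P, P + 2 * u, P + 4 * u))
}
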