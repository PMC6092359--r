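#' Read a run configuration
#'
#' Configurations are YAML mappings with the sections \code{assay}
#' (\code{traces}, \code{flux}, \code{symmetric}, \code{kappa},
#' \code{nLip}, \code{gamma}), \code{trajectory} (\code{topology},
#' \code{coords}, \code{groove} overrides, \code{lag}, \code{k}) and the
#' top-level \code{outputDir} and \code{seed}. Defaults are filled in and
#' referenced input files must exist.
#'
#' @param path YAML file path, or a list with the same structure
#' @return validated configuration list
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$outputDir <- if (is.null(cfg$outputDir)) "." else cfg$outputDir
  if (!is.null(cfg$assay)) {
    a <- cfg$assay
    a$symmetric <- isTRUE(a$symmetric)
    a$kappa <- if (is.null(a$kappa)) 0.1 else a$kappa
    a$nLip <- if (is.null(a$nLip)) 1e5 else a$nLip
    for (f in c("traces", "flux"))
      if (!is.null(a[[f]]) && !file.exists(a[[f]]))
        stop("configured file does not exist: ", a[[f]])
    cfg$assay <- a
  }
  if (!is.null(cfg$trajectory)) {
    tr <- cfg$trajectory
    tr$lag <- if (is.null(tr$lag)) 10L else as.integer(tr$lag)
    tr$k <- if (is.null(tr$k)) 50L else as.integer(tr$k)
    for (f in c("topology", "coords"))
      if (!is.null(tr[[f]]) && !file.exists(tr[[f]]))
        stop("configured file does not exist: ", tr[[f]])
    cfg$trajectory <- tr
  }
  cfg
}

# groove definition from config overrides
.grooveFromConfig <- function(groove) {
  if (is.null(groove)) return(grooveDefinition())
  do.call(grooveDefinition, groove)
}

#' Run the complete scrambling-assay pipeline
#'
#' Per batch: (1) fit every protein-free replicate to calibrate gamma,
#' Li^PF and the leak; (2) fit the WT(+Ca2+) replicates with f0 free to
#' obtain the batch f0; (3) fit every other construct/condition with
#' Li^PF, gamma, leak and f0 fixed (automatic full/linear mode selection
#' and rate-limited flagging); (4) classify every mutant against the WT of
#' the same Ca2+ condition; (5) summarize flux activities. A batch without
#' protein-free or WT(+Ca2+) traces is an error: the constraint protocol
#' requires both.
#'
#' @param config configuration list or YAML path ([readRunConfig()])
#' @return invisibly, a list with \code{fits} (per construct x condition
#'   summary data.frame), \code{calibration} (per batch), \code{flux}
#'   (summary or NULL); writes \code{assay_summary.csv},
#'   \code{assay_summary.json} and \code{assay_log.txt} under
#'   \code{outputDir}
#' @export
runAssayPipeline <- function(config) {
  cfg <- readRunConfig(config)
  a <- cfg$assay
  if (is.null(a) || is.null(a$traces))
    stop("config$assay$traces is required")
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  tab <- utils::read.csv(a$traces, stringsAsFactors = FALSE)
  need <- c("time_s", "fluorescence", "construct", "ca_state", "replicate",
            "batch")
  if (!all(need %in% names(tab)))
    stop("trace table must contain columns: ", paste(need, collapse = ", "))
  log <- c(sprintf("scramblr assay pipeline  [seed %d]", cfg$seed),
           sprintf("defaults: kappa = %g, nLip = %g, symmetric = %s",
                   a$kappa, a$nLip, a$symmetric))
  rows <- list(); calib <- list()
  for (b in unique(tab$batch)) {
    bt <- tab[tab$batch == b, ]
    getTrace <- function(cons, ca, rep) {
      d <- bt[bt$construct == cons & bt$ca_state == ca & bt$replicate == rep, ]
      new("FluorescenceTrace", time = d$time_s,
          fluorescence = d$fluorescence,
          condition = list(construct = cons, ca = ca == "plus",
                           replicate = rep, batch = b))
    }
    combos <- unique(bt[c("construct", "ca_state", "replicate")])
    pfRows <- combos[combos$construct == "protein-free", ]
    if (!nrow(pfRows))
      stop("batch ", b, " has no protein-free traces; cannot calibrate ",
           "gamma/Li^PF/leak")
    pfFits <- lapply(seq_len(nrow(pfRows)), function(i)
      fitProteinFree(getTrace("protein-free", pfRows$ca_state[i],
                              pfRows$replicate[i])))
    gammaB <- mean(vapply(pfFits, gammaRate, 0))
    liB <- mean(vapply(pfFits, function(f) innerFraction(params(f)), 0))
    leakB <- mean(vapply(pfFits, function(f) leakRate(params(f)), 0))
    wtRows <- combos[combos$construct == "WT" & combos$ca_state == "plus", ]
    if (!nrow(wtRows))
      stop("batch ", b, " has no WT(+Ca2+) traces; cannot constrain f0")
    wtFits <- lapply(wtRows$replicate, function(r)
      resolveRateLimited(fitFull(getTrace("WT", "plus", r), liPF = liB,
                                 f0 = NULL, gamma = gammaB, leak = leakB,
                                 symmetric = a$symmetric),
                         gamma = gammaB, kappa = a$kappa))
    f0B <- mean(vapply(wtFits, function(f) emptyFraction(params(f)), 0))
    calib[[b]] <- data.frame(batch = b, gamma = gammaB, liPF = liB,
                             leak = leakB, f0 = f0B)
    log <- c(log, sprintf(
      "batch %s: gamma = %.4g /s, Li^PF = %.3f, leak = %.3g /s, f0 = %.3f",
      b, gammaB, liB, leakB, f0B))
    # per construct x condition fits
    cc <- unique(combos[combos$construct != "protein-free",
                        c("construct", "ca_state")])
    alphaWT <- list()
    bRows <- list()
    for (i in seq_len(nrow(cc))) {
      cons <- cc$construct[i]; ca <- cc$ca_state[i]
      reps <- combos$replicate[combos$construct == cons &
                                 combos$ca_state == ca]
      fits <- if (cons == "WT" && ca == "plus") wtFits
      else lapply(reps, function(r)
        fitScrambling(getTrace(cons, ca, r), liPF = liB, f0 = f0B,
                      gamma = gammaB, leak = leakB,
                      symmetric = a$symmetric, kappa = a$kappa))
      alphas <- vapply(fits, alphaRate, 0)
      lb <- any(vapply(fits, isLowerBound, NA))
      bRows[[i]] <- data.frame(
        batch = b, construct = cons, ca_state = ca, n = length(fits),
        alpha = mean(alphas), alpha_sd = stats::sd(alphas),
        beta = mean(vapply(fits, betaRate, 0)),
        mode = fits[[1]]@mode, lower_bound_only = lb,
        transport_rate = transportRate(mean(alphas), a$nLip))
      if (cons == "WT") alphaWT[[ca]] <- mean(alphas)
    }
    # classification against the same-condition WT
    for (j in seq_along(bRows)) {
      r <- bRows[[j]]
      bRows[[j]]$class <- if (r$construct == "WT") "reference"
      else if (is.null(alphaWT[[r$ca_state]])) NA_character_
      else classifyImpact(alphaWT[[r$ca_state]], r$alpha,
                          mutantLowerBound = r$lower_bound_only)$label
    }
    rows <- c(rows, bRows)
  }
  fits <- do.call(rbind, rows)
  fluxSummary <- NULL
  if (!is.null(a$flux)) {
    fx <- utils::read.csv(a$flux, stringsAsFactors = FALSE)
    fluxSummary <- fluxReport(fx)$summary
  }
  utils::write.csv(fits, file.path(cfg$outputDir, "assay_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = cfg["assay"], calibration = do.call(rbind, calib),
         fits = fits, flux = fluxSummary),
    file.path(cfg$outputDir, "assay_summary.json"), auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
  writeLines(log, file.path(cfg$outputDir, "assay_log.txt"))
  invisible(list(fits = fits, calibration = do.call(rbind, calib),
                 flux = fluxSummary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the complete trajectory analysis pipeline
#'
#' Computes, for a topology + coordinates pair (or an in-memory
#' [Trajectory-class]): occupancy distributions for the groove and its
#' three compartments, residue contact frequencies, per-frame gate states,
#' f_int and f_lip, flip events, the eight-variable tICA feature series,
#' the fitted tICA model and 2-D scores, k-means microstates, and
#' microstate structural profiles (z-distance to the R432 C-alpha, lipid
#' tilt, T333-Y439 distance, TM3-TM6 opening). Per-metric CSVs and a JSON
#' summary are written under \code{outputDir}.
#'
#' @param config configuration list or YAML path; \code{trajectory$traj}
#'   may hold a [Trajectory-class] directly
#' @return invisibly, a list of all computed results
#' @export
runTrajPipeline <- function(config) {
  cfg <- readRunConfig(config)
  tc <- cfg$trajectory
  if (is.null(tc)) stop("config$trajectory is required")
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  traj <- if (!is.null(tc$traj)) tc$traj
  else readTrajectory(tc$topology, tc$coords, box = unlist(tc$box %||% NA))
  gdef <- .grooveFromConfig(tc$groove)
  out <- list()
  out$occupancy <- lapply(c(groove = "groove", EC = "EC",
                            central = "central", IC = "IC"),
                          function(rg) occupancyDistribution(traj, gdef, rg))
  out$contacts <- residueContactFrequency(traj, gdef = gdef)
  out$gates <- gateState(traj, gdef)
  out$fInt <- fInt(traj, gdef, gates = out$gates)
  out$fLip <- fLip(traj, gdef, gates = out$gates)
  out$flips <- detectFlips(traj, gdef)
  out$opening <- tm3tm6Opening(traj, gdef)
  ft <- try(ticaFeatures(traj, gdef), silent = TRUE)
  if (!inherits(ft, "try-error")) {
    out$features <- ft
    nf <- nFrames(traj)
    lag <- min(tc$lag, max(nf - 2L, 1L))
    out$tica <- fitTICA(ft, lag = lag)
    out$scores <- projectTICA(ft, out$tica, n = 2)
    out$explained <- explainedFraction(out$tica, 2)
    k <- min(tc$k, nf)
    out$microstates <- kmeansMicrostates(out$scores, k = k, seed = cfg$seed)
    tracked <- attr(ft, "trackedLipid")
    metrics <- data.frame(
      z_R432 = ft[, "zP_R432CA"],
      tilt = lipidTilt(traj, tracked),
      d333_439 = ft[, "dmin_T333_Y439"],
      tm3tm6 = out$opening$opening[out$opening$protomer ==
                                     protomers(traj)[1]])
    out$profiles <- microstateProfiles(out$microstates, metrics)
  }
  od <- cfg$outputDir
  utils::write.csv(out$gates, file.path(od, "gate_states.csv"),
                   row.names = FALSE)
  utils::write.csv(out$contacts, file.path(od, "contacts.csv"),
                   row.names = FALSE)
  utils::write.csv(out$flips, file.path(od, "flips.csv"), row.names = FALSE)
  utils::write.csv(out$opening, file.path(od, "tm3tm6_opening.csv"),
                   row.names = FALSE)
  if (!is.null(out$scores))
    utils::write.csv(data.frame(frame = seq_len(nrow(out$scores)),
                                tica1 = out$scores[, 1],
                                tica2 = out$scores[, 2],
                                state = out$microstates@labels),
                     file.path(od, "tica_scores.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(occupancy = out$occupancy, fInt = as.list(out$fInt),
         fLip = as.list(out$fLip),
         explained = out$explained %||% NA,
         nFlips = nrow(out$flips)),
    file.path(od, "traj_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}
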