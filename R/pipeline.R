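#' Frame-sampling arithmetic of an MD run
#'
#' Number of saved frames and frames per ns implied by a run length, an
#' integration time step and a save interval (e.g. 50 ns at 2 fs with one
#' frame per 25,000 steps: 1000 frames, 20 per ns).
#'
#' @param total_ns simulated time, ns.
#' @param timestep_fs integration step, fs.
#' @param save_every save one frame every this many steps.
#' @return list: `n_frames`, `frames_per_ns`, `frame_interval_ns`.
#' @export
samplingSchedule <- function(total_ns, timestep_fs, save_every) {
  stopifnot(total_ns > 0, timestep_fs > 0, save_every >= 1)
  steps <- total_ns * 1e6 / timestep_fs
  n <- steps / save_every
  list(n_frames = n, frames_per_ns = n / total_ns,
       frame_interval_ns = total_ns / n)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param input a [syntheticSpec()] (the system is generated) or a path to
#'   a multi-model PDB file.
#' @param analyses character subset of
#'   `c("interactions", "msd", "rheology", "entropy", "profiles")`.
#' @param params an [interactionParams()] object.
#' @param temperature temperature, K.
#' @param fit_range MSD fit range, ns (`NULL`: default of [fitPowerLaw()]).
#' @param omega frequency grid for the moduli (`NULL`: default grid).
#' @param interaction_stride analyse every k-th frame for interactions.
#' @param entropy_points number of evaluation points of the entropy curve.
#' @param out_dir output directory.
#' @param seed integer seed controlling all randomness.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(input,
                      analyses = c("interactions", "msd", "rheology",
                                   "entropy", "profiles"),
                      params = interactionParams(),
                      temperature = 310,
                      fit_range = NULL, omega = NULL,
                      interaction_stride = 1L,
                      entropy_points = 20L,
                      out_dir = tempfile("memdyn_run_"),
                      seed = 1L) {
  if (!length(analyses)) stop("at least one analysis must be enabled")
  analyses <- match.arg(analyses, several.ok = TRUE)
  stopifnot(temperature > 0, interaction_stride >= 1)
  structure(list(input = input, analyses = analyses, params = params,
                 temperature = temperature, fit_range = fit_range,
                 omega = omega, interaction_stride = as.integer(interaction_stride),
                 entropy_points = as.integer(entropy_points),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full analysis pipeline
#'
#' Loads or generates the system, repairs jump artefacts
#' ([levelJumps()]), assigns leaflets, then executes the enabled analyses
#' in dependency order and writes their outputs (CSV/JSON) to the output
#' directory. Deterministic under the config seed.
#'
#' @param config a [runConfig()].
#' @return A `RunReport` list: `manifest` (output files), `headline`
#'   (named key numbers), `config`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  if (inherits(config$input, "SyntheticSpec")) {
    spec <- config$input
    spec$rng_seed <- config$seed
    topo <- generateTopology(spec)
    traj <- generateTrajectory(topo, spec)
  } else {
    sys <- readMultimodelPDB(config$input)
    topo <- sys$topology
    traj <- sys$trajectory
  }
  if (!is.null(traj$box)) traj <- levelJumps(traj, topo)
  topo <- assignLeaflets(topo, traj)

  manifest <- character(0)
  headline <- list()
  emit <- function(name, obj, writer) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    manifest <<- c(manifest, path)
  }
  wcsv <- function(obj, path) utils::write.csv(obj, path, row.names = FALSE)
  wjson <- function(obj, path) jsonlite::write_json(obj, path,
                                                    auto_unbox = TRUE,
                                                    digits = NA, pretty = TRUE)

  fits <- NULL
  if (any(c("msd", "rheology") %in% config$analyses)) {
    lm_ <- leafletMSD(traj, topo, fit_range = config$fit_range)
    fits <- lm_
    msd_tab <- do.call(rbind, lapply(names(lm_), function(g)
      data.frame(leaflet = g, t = lm_[[g]]$msd$t, msd = lm_[[g]]$msd$msd)))
    emit("msd.csv", msd_tab, wcsv)
    fit_tab <- lapply(lm_, function(z)
      list(alpha = z$fit$alpha, D_alpha_A2ns = z$fit$D,
           D_alpha_cm2s = z$fit$D_cm2s, std_alpha = z$fit$std_alpha,
           std_D = z$fit$std_D))
    emit("msd_fits.json", fit_tab, wjson)
    for (g in names(lm_)) {
      headline[[paste0("alpha_", g)]] <- lm_[[g]]$fit$alpha
      headline[[paste0("D_", g)]] <- lm_[[g]]$fit$D
    }
  }

  if ("rheology" %in% config$analyses) {
    Rg <- radiusOfGyration(traj, topo, "lipid",
                           frames = unique(round(seq(1, nFrames(traj),
                                                     length.out = min(20, nFrames(traj))))))
    headline$Rg_lipid <- Rg
    mod <- lapply(fits, function(z)
      gserModuli(z$fit, Rg = Rg, temperature = config$temperature,
                 omega = config$omega))
    mod_tab <- do.call(rbind, lapply(names(mod), function(g)
      cbind(leaflet = g, mod[[g]])))
    emit("moduli.csv", mod_tab, wcsv)
    for (g in names(mod)) {
      mid <- ceiling(nrow(mod[[g]]) / 2)
      headline[[paste0("Gprime_mid_", g)]] <- mod[[g]]$Gprime_kPa[mid]
      headline[[paste0("Gdoubleprime_mid_", g)]] <- mod[[g]]$Gdoubleprime_kPa[mid]
    }
  }

  if ("interactions" %in% config$analyses) {
    frames <- seq(1, nFrames(traj), by = config$interaction_stride)
    ts <- interactionTimeSeries(traj, topo, config$params,
                                scope = NULL, frames = frames)
    emit("interaction_series.csv", ts$series, wcsv)
    if (!is.null(ts$records) && nrow(ts$records)) {
      emit("interaction_records.tsv", ts$records,
           function(obj, path) utils::write.table(obj, path, sep = "\t",
                                                  row.names = FALSE, quote = FALSE))
      pl <- ts$records[ts$records$scope == "lipid-protein" &
                         ts$records$kind == "hbond", , drop = FALSE]
      if (nrow(pl))
        emit("hbond_map.csv",
             as.data.frame.matrix(buildInteractionMap(pl, "protein_residue")),
             function(obj, path) utils::write.csv(obj, path))
    }
    last <- ts$series[nrow(ts$series), ]
    headline$n_hbond_final <- last$n_hbond
    headline$n_hp_final <- last$n_hp
    headline$n_ionic_final <- last$n_ionic
    headline$n_water_bridge_final <- last$n_water_bridge
    headline$n_lipids_final <- last$n_lipids
  }

  if ("entropy" %in% config$analyses) {
    nf <- nFrames(traj)
    ev <- unique(round(seq(3, nf, length.out = min(config$entropy_points, nf - 2))))
    leaf <- if (any(!is.na(topo$atoms$leaflet) &
                      topo$atoms$leaflet == "contact")) "contact" else NA
    ent <- entropyTimeCurve(traj, topo, config$temperature,
                            leaflet = leaf, eval_frames = ev)
    emit("entropy.csv", as.data.frame(ent), wcsv)
    headline$S_plateau_kcal_molK <- ent$S_mean_kcal_molK[nrow(ent)]
  }

  if ("profiles" %in% config$analyses) {
    prof <- electronDensityProfile(traj, topo)
    emit("density_profile.csv", as.data.frame(prof), wcsv)
    th <- tryCatch(bilayerThickness(prof), error = function(e) NA_real_)
    headline$thickness_A <- as.numeric(th)
    if (any(topo$atoms$kind == "protein")) {
      pen <- penetrationDepth(traj, topo)
      emit("penetration.csv", as.data.frame(pen), wcsv)
      headline$depth_A <- pen$depth[nrow(pen)]
    }
    wat <- interiorWaterCount(traj, topo)
    emit("interior_waters.csv", wat, wcsv)
    headline$interior_waters_final <- wat$n_interior_waters[nrow(wat)]
  }

  report <- list(config = list(analyses = config$analyses,
                               temperature = config$temperature,
                               seed = config$seed),
                 manifest = manifest, headline = headline)
  rp <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$manifest <- c(report$manifest, rp)
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Pipeline run:", length(x$manifest), "output files\n")
  for (k in names(x$headline))
    cat(sprintf("  %s = %s\n", k, format(x$headline[[k]], digits = 6)))
  invisible(x)
}

#' Compare headline numbers of two pipeline runs
#'
#' @param report_a,report_b `RunReport` objects from [runPipeline()].
#' @return data.frame: `key`, `a`, `b`, `ratio` (a/b); keys present in
#'   only one report are skipped with a warning.
#' @export
compareRuns <- function(report_a, report_b) {
  ka <- names(report_a$headline)
  kb <- names(report_b$headline)
  shared <- intersect(ka, kb)
  miss <- setdiff(union(ka, kb), shared)
  if (length(miss))
    warning("key(s) present in only one run skipped: ",
            paste(miss, collapse = ", "))
  if (!length(shared)) {
    warning("no overlapping headline keys")
    return(data.frame(key = character(0), a = numeric(0), b = numeric(0),
                      ratio = numeric(0)))
  }
  a <- vapply(report_a$headline[shared], as.numeric, numeric(1))
  b <- vapply(report_b$headline[shared], as.numeric, numeric(1))
  data.frame(key = shared, a = a, b = b, ratio = a / b, row.names = NULL)
}
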