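# Configuration-driven entry points wiring the stages together:
# run_simulate() writes a synthetic trajectory with known ground truth;
# run_analyze() runs the analysis stages over a trajectory (and optional
# control) and writes per-stage outputs plus a one-row global summary.

.default_config <- function() {
  list(
    environment = "f2", watson_base = "A", crick_base = "T",
    n_frames = 100L, seed = 1L,
    mean = list(rise = 3.38, twist = 36, chi = -117, propeller = 0),
    sds = list(intra = c(0.1, 0.1, 0.1, 4, 4, 3),
               inter = c(0.25, 0.25, 0.15, 2.5, 3.5, 3.5),
               chi = 8),
    planted_breathing = NULL,
    ion = NULL,                       # e.g. list(molarity=0.15, r_max=16, z_half=10)
    stages = c("params", "pairing", "grooves", "ions", "ensemble", "transfer"),
    control_path = NULL,
    hbond = list(d_max = 3.5, theta_min = 135),
    breathing = list(threshold = 45, min_frames = 2L, frame_dt = 1),
    groove_offsets = 2:3,
    ion_bins = list(r_max = 16, dr = 0.5, dtheta = 10, z_half = 1.7),
    alpha = 0.05, alpha_t = 0.01,
    cluster_cutoff = 1.0,
    temperature = 298,
    outdir = "mmduplex_out")
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- .default_config()
  base[names(config)] <- config
  base
}

.spec_from_config <- function(cfg) {
  seq <- sequence_for(cfg$environment, cfg$watson_base, cfg$crick_base)
  inter <- c(0, 0, cfg$mean$rise, 0, 0, cfg$mean$twist)
  intra <- c(0, 0, 0, 0, cfg$mean$propeller, 0)
  table <- parameter_table(seq$n_pairs, intra = intra, inter = inter,
                           chi = cfg$mean$chi)
  pb <- cfg$planted_breathing
  if (!is.null(pb) && !is.data.frame(pb))
    pb <- do.call(rbind, lapply(pb, as.data.frame))
  ion <- NULL
  if (!is.null(cfg$ion))
    ion <- c(list(type = "uniform"), cfg$ion)
  ensemble_spec(seq, table = table, sds = cfg$sds,
                n_frames = cfg$n_frames, seed = cfg$seed,
                planted_breathing = pb, ion_spec = ion)
}

#' Simulate a synthetic duplex trajectory to disk
#'
#' Builds an \code{ensemble_spec} from the config, samples the trajectory,
#' and writes a multi-model PDB, the ground-truth mean parameter tables
#' (CSV) and a manifest JSON carrying the seed, the echoed config and the
#' md5 of the trajectory file. Identical configs produce byte-identical
#' outputs.
#'
#' @param config a list or path to a YAML file; see the package vignette
#'   for the schema. Unset fields take package defaults.
#' @return invisibly, the named vector of written paths.
#' @export
run_simulate <- function(config = list()) {
  cfg <- .load_config(config)
  if (cfg$n_frames < 1L) stop("n_frames must be >= 1")
  spec <- .spec_from_config(cfg)
  traj <- sample_trajectory(spec)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trajectory = file.path(cfg$outdir, "trajectory.pdb"),
             truth_intra = file.path(cfg$outdir, "truth_intra.csv"),
             truth_inter = file.path(cfg$outdir, "truth_inter.csv"),
             manifest = file.path(cfg$outdir, "manifest.json"))
  write_trajectory_pdb(traj, paths[["trajectory"]])
  utils::write.csv(data.frame(pair = seq_len(spec$seq$n_pairs),
                              spec$table$intra),
                   paths[["truth_intra"]], row.names = FALSE)
  utils::write.csv(data.frame(step = seq_len(spec$seq$n_pairs - 1L),
                              spec$table$inter),
                   paths[["truth_inter"]], row.names = FALSE)
  manifest <- list(seed = cfg$seed,
                   sequence = list(watson = spec$seq$watson,
                                   crick = spec$seq$crick,
                                   mm_position = spec$seq$mm_position),
                   n_frames = cfg$n_frames,
                   resampled_frames = traj$resampled,
                   trajectory_md5 = unname(tools::md5sum(paths[["trajectory"]])),
                   config = cfg)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Analyse a duplex trajectory end to end
#'
#' Runs the enabled stages in order (params, pairing, grooves, ions,
#' ensemble, transfer), writing per-stage CSV/JSON outputs into
#' \code{outdir}, plus a one-row global summary (mean helical bend,
#' breathing occupancy at the lesion, mean minor groove width, mean total
#' twist). A failing stage aborts with an error naming the stage; outputs of
#' completed stages remain on disk.
#'
#' @param config list or YAML path. \code{trajectory_path} (or an in-memory
#'   \code{trajectory}) is required; \code{control_path} is required when
#'   the transfer stage is enabled. The ions stage is skipped silently when
#'   the trajectory carries no ion records.
#' @return invisibly, a list with the stage results and written paths.
#' @export
run_analyze <- function(config = list()) {
  cfg <- .load_config(config)
  traj <- if (!is.null(cfg[["trajectory"]])) cfg[["trajectory"]]
  else if (!is.null(cfg$trajectory_path)) read_trajectory_pdb(cfg$trajectory_path)
  else stop("config needs trajectory or trajectory_path")
  stages <- cfg$stages
  if ("transfer" %in% stages && is.null(cfg$control_path) &&
      is.null(cfg[["control"]])) {
    stop("transfer stage enabled but no control trajectory supplied ",
         "(set control_path, or drop 'transfer' from stages)")
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list(paths = character(0L))
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  emit <- function(df, file) {
    p <- file.path(cfg$outdir, file)
    utils::write.csv(df, p, row.names = FALSE)
    out$paths <<- c(out$paths, p)
  }
  emit_json <- function(x, file) {
    p <- file.path(cfg$outdir, file)
    jsonlite::write_json(x, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$paths <<- c(out$paths, p)
  }
  an <- run_stage("params", function() analyze_trajectory(traj))
  out$analysis <- an
  if ("params" %in% stages) {
    emit(an$intra, "params_intra.csv"); emit(an$inter, "params_inter.csv")
    emit(an$chi, "chi.csv"); emit(an$globals, "globals.csv")
    emit_json(list(intra = an$summary$intra, inter = an$summary$inter),
              "params_summary.json")
  }
  mm_rel <- 0L
  opening <- an$intra$value[an$intra$position == mm_rel &
                              an$intra$parameter == "opening"]
  br <- NULL
  if ("pairing" %in% stages) {
    pb <- pair_bases(traj$seq)
    catalog <- run_stage("pairing", function()
      read_scheme_catalog(if (!is.null(cfg[["catalog"]])) cfg[["catalog"]]
                          else paste0(pb[1L], pb[2L])))
    occ <- run_stage("pairing", function()
      scheme_occupancies(traj, catalog = catalog,
                         d_max = cfg$hbond$d_max,
                         theta_min = cfg$hbond$theta_min))
    out$occupancies <- occ
    emit(data.frame(scheme = names(occ$fractions),
                    fraction = as.numeric(occ$fractions)),
         "scheme_occupancies.csv")
    br <- run_stage("pairing", function()
      breathing_analysis(opening, frame_dt = cfg$breathing$frame_dt,
                         threshold = cfg$breathing$threshold,
                         min_frames = cfg$breathing$min_frames))
    out$breathing <- br
    emit_json(br$summary, "breathing.json")
  }
  grooves <- NULL
  if ("grooves" %in% stages) {
    grooves <- run_stage("grooves", function() {
      prof <- lapply(seq_len(nrow(traj$xyz)), function(f)
        groove_width_profile(.traj_frame(traj, f), offsets = cfg$groove_offsets))
      minor <- sapply(prof, `[[`, "minor")
      major <- sapply(prof, `[[`, "major")
      data.frame(position = prof[[1L]]$position,
                 minor_mean = rowMeans(minor), minor_sd = apply(minor, 1L, stats::sd),
                 major_mean = rowMeans(major), major_sd = apply(major, 1L, stats::sd))
    })
    out$grooves <- grooves
    emit(grooves, "grooves.csv")
  }
  if ("ions" %in% stages && any(vapply(traj$ions, nrow, 0L) > 0L)) {
    map <- run_stage("ions", function()
      ion_density_map(traj, r_max = cfg$ion_bins$r_max, dr = cfg$ion_bins$dr,
                      dtheta = cfg$ion_bins$dtheta,
                      z_half = cfg$ion_bins$z_half))
    out$ion_map <- map
    emit(as.data.frame(map$molarity), "ion_map.csv")
    emit_json(list(r_edges = map$r_edges, theta_edges = map$theta_edges,
                   z_half = map$z_half, n_frames = map$n_frames,
                   mean_count = map_mean_count(map)), "ion_map_meta.json")
  }
  if ("ensemble" %in% stages) {
    ens <- run_stage("ensemble", function() rmsd_and_average(traj))
    out$ensemble <- ens
    emit(data.frame(frame = seq_along(ens$rmsd), rmsd = ens$rmsd), "rmsd.csv")
    rep_ <- run_stage("ensemble", function()
      cluster_representative(traj, cutoff = cfg$cluster_cutoff))
    out$representative <- rep_
    p <- file.path(cfg$outdir, "representative.pdb")
    write_snapshot_pdb(traj, rep_$representative, p)
    out$paths <- c(out$paths, p)
    minw_series <- if (!is.null(grooves)) NULL else NULL
    stiff <- run_stage("ensemble", function()
      stiffness_constants(bend = an$globals$helical_bend, opening = opening,
                          temperature = cfg$temperature))
    out$stiffness <- stiff
    emit_json(list(k_bend = stiff$k_bend, k_opening = stiff$k_opening,
                   temperature = stiff$temperature), "stiffness.json")
  }
  if ("transfer" %in% stages) {
    control <- if (!is.null(cfg[["control"]])) cfg[["control"]]
    else read_trajectory_pdb(cfg$control_path)
    an_c <- run_stage("transfer", function() analyze_trajectory(control))
    prof <- run_stage("transfer", function()
      deviation_profile(an$inter, an_c$inter))
    tr <- run_stage("transfer", function()
      transfer_range(prof, alpha = cfg$alpha, alpha_t = cfg$alpha_t))
    out$transfer <- tr
    emit(tr$profile, "transfer_profile.csv")
    emit_json(list(range = tr$range,
                   flagged = tr$flagged_cells), "transfer_range.json")
  }
  summary_row <- data.frame(
    helical_bend = mean(an$globals$helical_bend),
    breathing_pct = if (!is.null(br)) br$summary$occupancy_pct else NA_real_,
    minW = if (!is.null(grooves)) mean(grooves$minor_mean, na.rm = TRUE) else NA_real_,
    total_twist = mean(an$globals$total_twist))
  out$summary <- summary_row
  emit(summary_row, "summary.csv")
  invisible(out)
}
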