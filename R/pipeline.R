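## Run configuration and report generation.
##
## A run is driven by a single serializable config (YAML or JSON, or an R
## list of the same shape) naming the stages to execute, the inputs, the
## thresholds and the seeds.  Every run emits a machine-readable manifest
## (inputs, package version, seeds, output checksums) and a config snapshot
## beside its outputs, so any output file is traceable to the exact
## configuration that produced it.

#' Load and validate a run configuration
#'
#' @param config path to a YAML/JSON config file, or a list.
#' @return validated config list (class `lipidsite_config`).
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  validate_config(config)
}

validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list or a YAML/JSON file")
  if (is.null(cfg$stages) || !length(cfg$stages))
    stop("config field 'stages' is missing or empty")
  known <- c("synth", "contacts", "density", "sitegeom", "dose")
  bad <- setdiff(cfg$stages, known)
  if (length(bad))
    stop("config field 'stages' names unknown stage(s): ",
         paste(bad, collapse = ", "))
  if (is.null(cfg$output_dir)) stop("config field 'output_dir' is missing")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  traj_stages <- intersect(cfg$stages, c("contacts", "density", "sitegeom"))
  if (length(traj_stages) && !("synth" %in% cfg$stages)) {
    for (f in c("topology", "trajectory"))
      if (is.null(cfg$input[[f]]))
        stop("config field 'input$", f, "' is required for stage(s) ",
             paste(traj_stages, collapse = ", "), " without 'synth'")
  }
  if ("dose" %in% cfg$stages && is.null(cfg$dose$csv) &&
      is.null(cfg$dose$generate))
    stop("config field 'dose$csv' (or 'dose$generate') is required ",
         "for the dose stage")
  for (st in c("contacts", "density")) {
    cl <- cfg[[st]]$lipid_class
    if (!is.null(cl) && !all(cl %in% LIPID_CLASSES))
      stop("config field '", st, "$lipid_class' must be among ",
           paste(LIPID_CLASSES, collapse = ", "))
  }
  class(cfg) <- c("lipidsite_config", "list")
  cfg
}

#' Default desk-scale demonstration configuration
#'
#' Generates a small synthetic membrane (deep zwitterionic/cationic outer
#' wells, no anionic outer well) and runs every trajectory stage plus a
#' dose-response fit on generated data, in well under a minute.
#'
#' @param output_dir where outputs go.
#' @param seed master seed.
#' @export
demo_config <- function(output_dir, seed = 1) {
  list(
    stages = c("synth", "contacts", "density", "sitegeom", "dose"),
    output_dir = output_dir, seed = seed,
    synth = list(n_lipids_per_leaflet = 150,
                 class_fractions = c(lipid_PC = 0.8, lipid_PG = 0.2,
                                     lipid_TAP = 0),
                 n_frames = 150, save_stride = 10,
                 site_lipid_class = "lipid_PC"),
    contacts = list(mode = "cg", lipid_class = c("lipid_PC", "lipid_PG"),
                    hot_cutoff = 0.33),
    density = list(lipid_class = c("lipid_PC", "lipid_PG"), spacing = 2,
                   level = 20),
    sitegeom = list(),
    dose = list(generate = list(pEC50 = 2.96, nH = 2.2)))
}

#' Execute a configured analysis run
#'
#' Runs the requested stages in dependency order, writing CSV/JSON/DX
#' outputs, a config snapshot, a machine-readable `manifest.json` and a
#' human-readable `summary.txt` into `output_dir`.  Any stage error aborts
#' the run naming the stage.
#'
#' @param config config list, path, or [demo_config()] output.
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- load_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[lipidsite] ", ...)
  outputs <- character(0)
  summary_lines <- character(0)
  note <- function(...) summary_lines <<- c(summary_lines, sprintf(...))
  stage <- "config"
  emit <- function(path) outputs <<- c(outputs, path)

  res <- tryCatch({
    cfg_path <- file.path(cfg$output_dir, "config_snapshot.yaml")
    yaml::write_yaml(unclass(cfg), cfg_path)
    emit(cfg_path)

    top <- NULL; traj <- NULL; system <- NULL; params <- NULL
    if ("synth" %in% cfg$stages) {
      stage <- "synth"
      say("generating synthetic membrane")
      sy <- cfg$synth
      spec <- membrane_spec(
        box_xy = sy$box_xy %||% c(300, 300),
        n_lipids_per_leaflet = sy$n_lipids_per_leaflet %||% 200,
        class_fractions = unlist(sy$class_fractions %||%
          c(lipid_PC = 0.8, lipid_PG = 0.2, lipid_TAP = 0)))
      params <- sim_params(
        n_frames = sy$n_frames %||% 400,
        save_stride = sy$save_stride %||% 10,
        well_width = sy$well_width %||% 3,
        seed = cfg$seed,
        site_lipid_class = sy$site_lipid_class)
      system <- build_membrane_system(spec, protein_placeholder(), params)
      top <- system$topology
      traj <- simulate_membrane(system, params)
      p_top <- file.path(cfg$output_dir, "system.pdb")
      p_gro <- file.path(cfg$output_dir, "system.gro")
      p_trj <- file.path(cfg$output_dir, "trajectory.trj")
      p_gt <- file.path(cfg$output_dir, "ground_truth.json")
      write_pdb(top, p_top); write_gro(top, p_gro)
      write_traj_text(traj, p_trj)
      write_ground_truth(system, params, p_gt)
      emit(p_top); emit(p_gro); emit(p_trj); emit(p_gt)
      note("synth: %d lipids/leaflet, %d frames, seed %d",
           spec$n_lipids_per_leaflet, n_frames(traj), cfg$seed)
    } else if (!is.null(cfg$input$topology)) {
      stage <- "input"
      top <- load_topology(cfg$input$topology)
      traj <- load_trajectory(top, cfg$input$trajectory)
    }

    if ("contacts" %in% cfg$stages) {
      stage <- "contacts"
      say("contact profiles")
      cc <- cfg$contacts
      map <- symmetry_map(top)
      for (cl in (cc$lipid_class %||% "lipid_PC")) {
        pars <- contact_params(mode = cc$mode %||% "cg",
                               threshold = cc$threshold,
                               lipid_class = cl)
        prof <- compute_contact_profile(traj, top, pars)
        path <- file.path(cfg$output_dir,
                          paste0("contacts_", cl, ".csv"))
        write_contacts_csv(prof, map, path,
                           cutoff = cc$hot_cutoff %||% 0.33)
        emit(path)
        avg <- average_over_subunits(prof, map)
        hot <- classify_hot_residues(avg, cc$hot_cutoff %||% 0.33)
        note("contacts[%s]: %d residues above %.2f: %s", cl, length(hot),
             cc$hot_cutoff %||% 0.33,
             paste(utils::head(hot, 12), collapse = " "))
      }
    }

    if ("density" %in% cfg$stages) {
      stage <- "density"
      say("occupancy densities")
      dd <- cfg$density
      for (cl in (dd$lipid_class %||% "lipid_PC")) {
        sel <- headgroup_selection(cl, "cg")
        grid <- compute_density_grid(traj, top, sel,
                                     spacing = dd$spacing %||% 2)
        path <- file.path(cfg$output_dir, paste0("density_", cl, ".dx"))
        write_opendx(grid, path)
        emit(path)
        if (!is.null(dd$level)) {
          mk <- threshold_mask(grid, dd$level)
          note("density[%s]: %d component(s) at %.2f molecules/nm^3", cl,
               mk$n_components, dd$level)
        }
      }
    }

    if ("sitegeom" %in% cfg$stages) {
      stage <- "sitegeom"
      say("site geometry")
      map <- symmetry_map(top)
      lids <- if (!is.null(system)) system$site_lipid_ids else NULL
      rmsd_list <- list(); cat_list <- list()
      for (s in 1:5) {
        sd <- site_definition(s, map,
                              lipid_id = if (!is.null(lids)) lids[s],
                              ring_names = c("CG", "CD1", "NE1", "CE2",
                                             "CD2", "CE3"))
        rmsd_list[[s]] <- site_rmsd_series(traj, top, sd)
        cat_list[[s]] <- cation_pi_series(traj, top, sd)
      }
      rs <- pool_and_summarize(rmsd_list)
      cs <- pool_and_summarize(cat_list)
      path <- file.path(cfg$output_dir, "sitegeom.json")
      jsonlite::write_json(list(
        rmsd = rs[c("median", "q1", "q3", "whisker_lo", "whisker_hi", "n")],
        cation_centroid = cs[c("median", "q1", "q3", "whisker_lo",
                               "whisker_hi", "n")],
        frac_le_4.5 = mean(vapply(cat_list, attr, 0, "frac_le_4.5")),
        frac_le_6 = mean(vapply(cat_list, attr, 0, "frac_le_6"))),
        path, auto_unbox = TRUE, digits = NA)
      emit(path)
      note("sitegeom: cation-centroid median %.2f A (frac <= 4.5 A: %.2f)",
           cs$median, mean(vapply(cat_list, attr, 0, "frac_le_4.5")))
    }

    if ("dose" %in% cfg$stages) {
      stage <- "dose"
      say("dose-response fits")
      dz <- cfg$dose
      dat <- if (!is.null(dz$csv)) read_dose_csv(dz$csv)
             else do.call(simulate_dose_response, dz$generate)
      labs <- if ("label" %in% names(dat)) unique(dat$label) else "dataset"
      fits <- lapply(labs, function(lb) {
        dd <- if ("label" %in% names(dat)) dat[dat$label == lb, ] else dat
        fit <- fit_hill(dd)
        c(as.list(coef(fit)), list(EC50_M = fit$EC50,
                                   r.squared = fit$r.squared))
      })
      names(fits) <- labs
      path <- file.path(cfg$output_dir, "dose_fits.json")
      jsonlite::write_json(fits, path, auto_unbox = TRUE, digits = NA)
      emit(path)
      for (lb in labs)
        note("dose[%s]: EC50 %.4g M, nH %.3g", lb, fits[[lb]]$EC50_M,
             fits[[lb]]$nH)
    }

    stage <- "manifest"
    manifest <- list(
      package = "lipidsite",
      version = as.character(packageVersion("lipidsite")),
      seed = cfg$seed,
      stages = cfg$stages,
      inputs = cfg$input,
      outputs = lapply(setNames(outputs, basename(outputs)), function(f)
        list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))))
    mpath <- file.path(cfg$output_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
    writeLines(c("lipidsite run summary", "=====================",
                 summary_lines),
               file.path(cfg$output_dir, "summary.txt"))
    say("done: ", length(outputs), " output file(s)")
    manifest
  }, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
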