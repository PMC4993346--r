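# Delimited-text IO for trajectories and count tables, JSON run manifests,
# and the pipeline commands tying the modules together. Embryonic time is
# decimal days everywhere (E14.5 -> 14.5); hours appear only inside
# phase-duration parameters.

#' Write a trajectory to CSV
#'
#' Columns: `time`, the derived observables, and (optionally) the full state
#' columns under the documented naming scheme.
#'
#' @param trajectory A `niche_trajectory`.
#' @param path Output CSV path.
#' @param full_state Also include every state column.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(trajectory, path, full_state = FALSE) {
  if (!inherits(trajectory, "niche_trajectory")) abort_usage("not a niche_trajectory")
  tab <- trajectory$observables
  if (full_state) tab <- dplyr::bind_cols(tab, state_as_tibble(trajectory$states))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("no such file: %s", path))
  tibble::as_tibble(utils::read.csv(path))
}

#' Write / read stereology count tables
#'
#' Delimited text with columns `section_index`, `site_index` (constant 1 for
#' Cavalieri tables) and `count`.
#'
#' @param counts A data frame with those columns (`site_index` optional).
#' @param path CSV path.
#' @return The path (write) or a tibble (read).
#' @export
write_counts <- function(counts, path) {
  counts <- tibble::as_tibble(counts)
  if (!"site_index" %in% names(counts)) counts$site_index <- 1L
  need <- c("section_index", "site_index", "count")
  if (!all(need %in% names(counts))) {
    abort_usage("counts must have columns section_index, site_index, count")
  }
  utils::write.csv(counts[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("no such file: %s", path))
  tab <- tibble::as_tibble(utils::read.csv(path))
  need <- c("section_index", "site_index", "count")
  if (!all(need %in% names(tab))) {
    abort_usage("counts file must have columns section_index, site_index, count")
  }
  tab
}

#' Write a run manifest
#'
#' Every pipeline command records a JSON manifest listing the command, the
#' configuration fingerprint, seeds, package version, timestamp, status and
#' all output files, so any artifact can be traced to the run that made it.
#'
#' @param out_dir Directory the manifest (`manifest.json`) is written into.
#' @param command Command name.
#' @param outputs Character vector of output paths.
#' @param seeds Named or unnamed integer seeds used.
#' @param fingerprint Config fingerprint, if applicable.
#' @param status `"ok"` or an error message.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(out_dir, command, outputs = character(0),
                               seeds = integer(0), fingerprint = NA_character_,
                               status = "ok") {
  manifest <- list(command = command,
                   package = "nichegrowth",
                   version = as.character(utils::packageVersion("nichegrowth")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config_fingerprint = fingerprint,
                   seeds = seeds,
                   status = status,
                   outputs = as.list(outputs))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

with_manifest <- function(out_dir, command, seeds, fingerprint, body) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  res <- tryCatch(body(), error = function(e) {
    write_run_manifest(out_dir, command, outputs, seeds, fingerprint,
                       status = conditionMessage(e))
    rlang::abort(conditionMessage(e), class = class(e)[1L])
  })
  write_run_manifest(out_dir, command, res$outputs, seeds, fingerprint, "ok")
  invisible(res)
}

#' Run a simulation and write its artifacts
#'
#' Simulates one genotype (or both, with `compare = TRUE`, writing a joined
#' long table of both genotypes' observables) and records a manifest.
#'
#' @param out_dir Output directory (created if missing).
#' @param config_path Optional YAML configuration; defaults to the packaged
#'   default configuration.
#' @param genotype `"control"` or `"ccna2null"`.
#' @param compare Run both genotypes, calibrated to their E14.5 targets, and
#'   write `comparison.csv`.
#' @param calibrate Calibrate initial volume before simulating.
#' @param targets,target_time Calibration targets (see
#'   [simulate_comparison()]).
#' @return Invisibly, a list with `outputs` and the result object(s).
#' @export
run_simulate <- function(out_dir, config_path = NULL,
                         genotype = c("control", "ccna2null"),
                         compare = FALSE, calibrate = TRUE,
                         targets = c(control = 4, mutant = 1),
                         target_time = 14.5) {
  genotype <- match.arg(genotype)
  base <- if (is.null(config_path)) {
    load_config(system.file("extdata", "default_config.yaml",
                            package = "nichegrowth"))
  } else load_config(config_path)
  mods <- attr(base, "modifiers")
  mutant_cfg <- if (!is.null(mods$ccna2null)) apply_genotype(base, mods$ccna2null)
    else apply_genotype(base, genotype_modifier())
  fp <- config_fingerprint(base)

  with_manifest(out_dir, "simulate", integer(0), fp, function() {
    if (compare) {
      tab <- simulate_comparison(base, mutant_cfg, calibrate = calibrate,
                                 targets = targets, target_time = target_time)
      path <- file.path(out_dir, "comparison.csv")
      utils::write.csv(tab, path, row.names = FALSE)
      list(outputs = path, comparison = tab)
    } else {
      cfg <- if (genotype == "control") base else mutant_cfg
      if (calibrate) {
        tgt <- if (genotype == "control") targets[[1L]] else targets[[2L]]
        cfg <- calibrate_initial_volume(cfg, tgt, target_time)$config
      }
      traj <- simulate_niche(cfg)
      path <- file.path(out_dir, sprintf("trajectory_%s.csv", genotype))
      write_trajectory(traj, path)
      list(outputs = path, trajectory = traj)
    }
  })
}

#' Run the hypothesis-exclusion engine and write verdicts
#'
#' @param out_dir Output directory.
#' @param constraints A [constraint_set()].
#' @return Invisibly, a list with `outputs` and the verdict tibble.
#' @export
run_hypotheses <- function(out_dir, constraints = constraint_set()) {
  with_manifest(out_dir, "hypotheses", integer(0), NA_character_, function() {
    verdicts <- evaluate_hypotheses(constraints)
    path <- file.path(out_dir, "verdicts.json")
    jsonlite::write_json(verdicts, path, auto_unbox = TRUE, pretty = TRUE)
    list(outputs = path, verdicts = verdicts)
  })
}

#' Run a stereology estimator on a count table
#'
#' @param out_dir Output directory.
#' @param method `"cavalieri"` or `"fractionator"`.
#' @param counts_path CSV with columns `section_index, site_index, count`.
#' @param preset A [stereology_preset()] name, or a design object.
#' @return Invisibly, a list with `outputs` and the single-number `estimate`.
#' @export
run_stereology <- function(out_dir, method = c("cavalieri", "fractionator"),
                           counts_path, preset = NULL) {
  method <- match.arg(method)
  counts <- read_counts(counts_path)
  design <- if (is.null(preset)) {
    if (method == "cavalieri") stereology_preset("cavalieri_vzsvz")
    else stereology_preset("fractionator_caspase3")
  } else if (is.character(preset)) stereology_preset(preset) else preset
  with_manifest(out_dir, paste0("stereology_", method), integer(0),
                NA_character_, function() {
    est <- if (method == "cavalieri") cavalieri_volume(counts$count, design)
      else fractionator_count(counts$count, design)
    path <- file.path(out_dir, sprintf("%s_estimate.json", method))
    jsonlite::write_json(list(method = method, estimate = est,
                              n_rows = nrow(counts)),
                         path, auto_unbox = TRUE, digits = NA)
    list(outputs = path, estimate = est)
  })
}

#' Generate synthetic specimen files
#'
#' Writes `n` control and `n` mutant specimens (Cavalieri and fractionator
#' count tables per specimen) derived from calibrated trajectories of both
#' genotypes.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; per-specimen seeds are derived from it.
#' @param n Specimens per genotype.
#' @param age Embryonic day of the virtual specimens.
#' @return Invisibly, a list with `outputs` and the specimen lists.
#' @export
run_synth <- function(out_dir, seed = 1L, n = 10L, age = 14.5) {
  with_manifest(out_dir, "synth", c(seed = seed), NA_character_, function() {
    cal_c <- calibrate_initial_volume(default_config("control"), 4, 14.5)
    cal_m <- calibrate_initial_volume(default_config("mutant"), 1, 14.5)
    trajs <- list(control = simulate_niche(cal_c$config),
                  mutant = simulate_niche(cal_m$config))
    outputs <- character(0)
    specimens <- list(control = list(), mutant = list())
    for (g in names(trajs)) {
      for (i in seq_len(n)) {
        sp <- specimen_spec(g, age = age, trajectory = trajs[[g]],
                            seed = seed * 10000L + (g == "mutant") * 1000L + i)
        meas <- generate_specimen(sp)
        specimens[[g]][[i]] <- meas
        p1 <- file.path(out_dir, sprintf("%s_%02d_cavalieri.csv", g, i))
        write_counts(meas$cavalieri, p1)
        p2 <- file.path(out_dir, sprintf("%s_%02d_fractionator.csv", g, i))
        write_counts(meas$fractionator, p2)
        outputs <- c(outputs, p1, p2)
      }
    }
    list(outputs = outputs, specimens = specimens)
  })
}
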