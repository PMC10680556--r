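# End-to-end orchestration: simulate -> track -> count -> periodicity, with
# per-stage sub-seeds, on-disk artifacts and a run manifest.

#' Derive a per-stage sub-seed from the run seed
#'
#' Fixed documented rule so every stage is independently reproducible:
#' `(seed * 48271 + 7919 * index) mod (2^31 - 1)`, kept below 2^31.
#' @param seed integer run seed.
#' @param index stage or acquisition index (>= 1).
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %%
               2147483647)
}

default_pipeline_config <- function() {
  list(seed = 42L,
       n_acquisitions = 30L,
       simulate = list(),     # slimfield_config overrides
       tracking = list(),     # tracking_params overrides
       counting = list(min_steps = 20L),
       periodicity = list(kernel_width = 0.7, bootstrap = 1000L,
                          adjacent_only = FALSE))
}

merge_config <- function(defaults, overrides) {
  for (k in names(overrides)) defaults[[k]] <- overrides[[k]]
  defaults
}

load_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
    if (!is.null(config$simulate)) {
      config$simulate <- as.list(config$simulate)
      if (!is.null(config$simulate$multiple_weights))
        config$simulate$multiple_weights <-
          unlist(config$simulate$multiple_weights)
      if (!is.null(config$simulate$roi))
        config$simulate$roi <- as.list(config$simulate$roi)
    }
    if (!is.null(config$tracking)) config$tracking <- as.list(config$tracking)
  }
  full <- default_pipeline_config()
  bad <- setdiff(names(config), names(full))
  if (length(bad))
    stop_config("unknown pipeline config key(s): ", paste(bad, collapse = ", "))
  merge_config(full, config)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> track -> count -> periodicity in order, writing
#' every stage's artifact under `out_dir` and a manifest recording the
#' config hash, seed, per-stage outputs with row counts, and the package
#' version.  A stage failure aborts with the failing stage named.
#' Identical config and seed reproduce identical outputs.
#'
#' @param config pipeline config: a JSON path or a list with any of `seed`,
#'   `n_acquisitions`, `simulate` (slimfield overrides), `tracking`,
#'   `counting`, `periodicity`.
#' @param out_dir output directory (created).
#' @param quiet suppress stage log lines.
#' @return the manifest, invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir, quiet = FALSE) {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("stacks", "masks", "truth", "tracks"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "pipeline_config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  stages <- list()
  log <- function(...) if (!quiet) message(...)
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  # -- stage 1: simulate --------------------------------------------------
  n_acq <- cfg$n_acquisitions
  sims <- vector("list", n_acq)
  tryCatch({
    for (a in seq_len(n_acq)) {
      sc <- do.call(slimfield_config,
                    merge_config(cfg$simulate,
                                 list(seed = derive_seed(cfg$seed, a))))
      sims[[a]] <- simulate_image_stack(sc)
      write_stack(sims[[a]]$stack,
                  file.path(out_dir, "stacks", sprintf("acq_%03d.tif", a)))
      write_mask(sims[[a]]$mask,
                 file.path(out_dir, "masks", sprintf("acq_%03d_mask.tif", a)))
      utils::write.csv(sims[[a]]$truth$trajectories,
                       file.path(out_dir, "truth",
                                 sprintf("acq_%03d_truth.csv", a)),
                       row.names = FALSE)
    }
  }, error = function(e) fail("simulate", e))
  log("simulate: ", n_acq, " acquisitions")
  stages$simulate <- list(outputs = file.path(out_dir, "stacks"),
                          n = n_acq)

  # -- stage 2: track -----------------------------------------------------
  params <- do.call(tracking_params, cfg$tracking)
  all_tracks <- NULL
  frame_interval <- NA_real_
  tryCatch({
    rows <- 0L
    for (a in seq_len(n_acq)) {
      stack <- read_stack(file.path(out_dir, "stacks",
                                    sprintf("acq_%03d.tif", a)))
      mask <- read_mask(file.path(out_dir, "masks",
                                  sprintf("acq_%03d_mask.tif", a)), stack)
      frame_interval <- stack$frame_interval
      tr <- track_stack(stack, mask, params)
      write_tracks(tr, file.path(out_dir, "tracks",
                                 sprintf("acq_%03d_tracks.csv", a)))
      if (nrow(tr)) tr$acquisition_id <- a
      all_tracks <- rbind(all_tracks,
                          if (nrow(tr)) tr else NULL)
      rows <- rows + nrow(tr)
    }
  }, error = function(e) fail("track", e))
  if (is.null(all_tracks))
    all_tracks <- data.frame(track_id = integer(0), frame = integer(0),
                             row = numeric(0), col = numeric(0),
                             summed_intensity = numeric(0),
                             background_mean = numeric(0),
                             background_sd = numeric(0),
                             roi_label = integer(0), extended = logical(0),
                             acquisition_id = integer(0))
  log("track: ", nrow(all_tracks), " spot rows")
  stages$track <- list(outputs = file.path(out_dir, "tracks"),
                       n = nrow(all_tracks))

  # -- stage 3: count -----------------------------------------------------
  counted <- if (nrow(all_tracks) == 0L) {
    # an empty acquisition set is a valid (if useless) run, not an error
    list(samples = data.frame(track_id = integer(0),
                              acquisition_id = integer(0),
                              initial_intensity = numeric(0),
                              stoichiometry = numeric(0)),
         calibration = list(brightness = NA_real_, uncertainty = NA_real_,
                            n_steps = 0L),
         step_heights = numeric(0))
  } else tryCatch(
    count_tracks(all_tracks, frame_interval = frame_interval,
                 min_steps = cfg$counting$min_steps),
    error = function(e) fail("count", e))
  stoich_path <- file.path(out_dir, "stoichiometries.csv")
  write_stoichiometries(counted$samples, stoich_path)
  cal <- counted$calibration
  jsonlite::write_json(list(brightness = cal$brightness,
                            uncertainty = cal$uncertainty,
                            n_steps = cal$n_steps),
                       file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  log(sprintf("count: %d stoichiometry samples, brightness %.1f +/- %.1f",
              nrow(counted$samples), cal$brightness, cal$uncertainty))
  stages$count <- list(outputs = stoich_path, n = nrow(counted$samples))

  # -- stage 4: periodicity -----------------------------------------------
  per <- tryCatch(
    estimate_periodicity(counted$samples,
                         kernel_width = cfg$periodicity$kernel_width,
                         adjacent_only = isTRUE(cfg$periodicity$adjacent_only),
                         bootstrap = cfg$periodicity$bootstrap,
                         seed = derive_seed(cfg$seed, 999L)),
    error = function(e) fail("periodicity", e))
  result_path <- file.path(out_dir, "periodicity.json")
  res <- per$periodicity
  jsonlite::write_json(list(periodicity = res$periodicity,
                            ci95 = res$ci95,
                            n_intervals = res$n_intervals,
                            n_tracks = per$n_tracks,
                            kernel_width = cfg$periodicity$kernel_width,
                            interval_kernel_width = res$interval_kernel_width,
                            status = res$status),
                       result_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  log("periodicity: ", res$status,
      if (is.finite(res$periodicity))
        sprintf(" (%.2f molecules)", res$periodicity) else "")
  stages$periodicity <- list(outputs = result_path, n = res$n_intervals)

  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed,
                   tool_version = as.character(utils::packageVersion("slimcount")),
                   stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
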