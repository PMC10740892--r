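# Reproducible experiment runner and serialization glue: a single JSON config
# is the source of truth; outputs are CSV/JSON files plus a manifest with
# content hashes so a re-run from the saved config can be verified
# bit-for-bit.

#' Build a run configuration
#'
#' @param seed integer seed for every stochastic component.
#' @param out_dir output directory (created if missing).
#' @param n_per_crista fibers per crista.
#' @param facial add a facial-nerve branch for upper-limit detection.
#' @param shapes,slopes,polarity,phase_us,amp_uA sweep factors / pulse
#'   parameters.
#' @param amplitudes_uA amplitude grid.
#' @param model_tier `"surrogate"` (fast) or `"hh"` for recruitment; eCAP
#'   columns always use the HH tier and are skipped when `ecap = FALSE`.
#' @param ecap compute eCAP threshold columns.
#' @param log_level `"info"` or `"quiet"`.
#' @return validated list of class `vest_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("vestibsim_run_"),
                       n_per_crista = 100, facial = TRUE,
                       shapes = c("rect", "ramp_up"),
                       slopes = c(15, 30, 45, 60),
                       polarity = "cathodic_first", phase_us = 200,
                       amp_uA = 240, amplitudes_uA = default_amp_grid(),
                       model_tier = c("surrogate", "hh"), ecap = TRUE,
                       log_level = c("info", "quiet")) {
  model_tier <- match.arg(model_tier)
  log_level <- match.arg(log_level)
  cfg <- list(seed = seed, out_dir = out_dir, n_per_crista = n_per_crista,
              facial = facial, shapes = shapes, slopes = slopes,
              polarity = polarity, phase_us = phase_us, amp_uA = amp_uA,
              amplitudes_uA = amplitudes_uA, model_tier = model_tier,
              ecap = ecap, log_level = log_level)
  validate_config(cfg)
  structure(cfg, class = "vest_config")
}

validate_config <- function(cfg) {
  bad <- character(0)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) bad <- c(bad, "seed")
  if (!is.numeric(cfg$n_per_crista) || cfg$n_per_crista < 3) {
    bad <- c(bad, "n_per_crista")
  }
  if (!length(cfg$shapes)) bad <- c(bad, "shapes")
  if (!length(cfg$slopes)) bad <- c(bad, "slopes")
  if (!is.numeric(cfg$amplitudes_uA) || !length(cfg$amplitudes_uA)) {
    bad <- c(bad, "amplitudes_uA")
  }
  if (!is.numeric(cfg$phase_us) || cfg$phase_us <= 0) bad <- c(bad, "phase_us")
  if (length(bad)) {
    stop_invalid(paste("invalid config fields:", paste(bad, collapse = ", ")),
                 class = "vestibsim_schema")
  }
  invisible(cfg)
}

#' Write / read a run configuration as JSON
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "vest_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Run a full sweep experiment from a configuration
#'
#' Builds the anatomy, runs the pulse-shape sweep, and writes the anatomy
#' JSON, sweep CSV/JSON, recruitment CSV for the first spec, the resolved
#' config, and a manifest listing every output with its MD5 content hash.
#' Deterministic tiers reproduce identical hashes when re-run from the saved
#' config.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the `anatomy`, the `sweep` tibble, and the
#'   `manifest` tibble.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "vest_config"))
  validate_config(config)
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) {
    if (config$log_level == "info") message(sprintf(...))
  }
  say("vestibsim %s | seed %d | out %s",
      as.character(utils::packageVersion("vestibsim")),
      as.integer(config$seed), config$out_dir)

  anat <- build_default_labyrinth(config$n_per_crista, seed = config$seed)
  if (isTRUE(config$facial)) anat <- add_facial_branch(anat)
  write_anatomy_json(anat, file.path(config$out_dir, "anatomy.json"))

  model <- if (config$model_tier == "hh") hh_node_model() else
    surrogate_model()
  sweep <- slope_sweep(
    anat, slopes = config$slopes, shapes = config$shapes,
    polarity = config$polarity, phase_us = config$phase_us,
    amp_uA = config$amp_uA, model = model,
    ecap_model = if (isTRUE(config$ecap)) hh_node_model() else NULL,
    amplitudes_uA = config$amplitudes_uA)
  utils::write.csv(as.data.frame(sweep),
                   file.path(config$out_dir, "sweep.csv"), row.names = FALSE)
  jsonlite::write_json(as.data.frame(sweep),
                       file.path(config$out_dir, "sweep.json"),
                       digits = I(17), na = "null")

  spec1 <- waveform_spec(config$shapes[[1]], config$phase_us, config$amp_uA,
                         slope_deg = config$slopes[[1]],
                         polarity = config$polarity)
  curve <- recruitment_curve(anat, spec1, config$amplitudes_uA, model = model)
  utils::write.csv(as.data.frame(curve),
                   file.path(config$out_dir, "recruitment.csv"),
                   row.names = FALSE)
  write_config_json(config, file.path(config$out_dir, "config.json"))

  files <- c("anatomy.json", "sweep.csv", "sweep.json", "recruitment.csv",
             "config.json")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files)))
  )
  utils::write.csv(as.data.frame(manifest),
                   file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  say("done in %.1f s (%d sweep rows)",
      as.numeric(difftime(Sys.time(), t0, units = "secs")), nrow(sweep))
  invisible(list(anatomy = anat, sweep = sweep, manifest = manifest))
}

#' Check that a file written by this package round-trips exactly
#'
#' Dispatches on content: anatomy JSON, waveform spec JSON, run-config JSON,
#' or waveform CSV. The file is read, re-written, and re-read; structures
#' must match exactly.
#'
#' @param path file written by this package.
#' @return `TRUE` on success; raises an incompatibility error for files this
#'   package cannot parse.
#' @export
validate_io_roundtrip <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(paste("no such file:", path), class = "vestibsim_schema")
  }
  tmp <- tempfile(fileext = paste0(".", tools::file_ext(path)))
  on.exit(unlink(tmp))
  if (grepl("\\.json$", path)) {
    head <- jsonlite::read_json(path)
    if (identical(head$format, "vestibsim-anatomy-1")) {
      a1 <- read_anatomy_json(path)
      write_anatomy_json(a1, tmp)
      a2 <- read_anatomy_json(tmp)
      return(isTRUE(all.equal(a1, a2, tolerance = 0)))
    }
    if (all(c("shape", "phase_us", "amp_uA") %in% names(head))) {
      s1 <- read_spec_json(path)
      write_spec_json(s1, tmp)
      return(identical(s1, read_spec_json(tmp)))
    }
    if (all(c("seed", "out_dir", "shapes") %in% names(head))) {
      c1 <- read_config_json(path)
      write_config_json(c1, tmp)
      return(identical(unclass(c1), unclass(read_config_json(tmp))))
    }
    stop_invalid("unrecognized vestibsim JSON file",
                 class = "vestibsim_incompatible")
  }
  if (grepl("\\.csv$", path)) {
    w1 <- read_waveform_csv(path)
    write_waveform_csv(w1, tmp)
    w2 <- read_waveform_csv(tmp)
    return(isTRUE(all.equal(as.data.frame(w1), as.data.frame(w2))))
  }
  stop_invalid("unsupported file type", class = "vestibsim_incompatible")
}
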