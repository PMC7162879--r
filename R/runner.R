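# Scenario configuration and orchestration: build the scene and implant,
# run the scattering and/or ray-tracing operators, write field maps, echo
# waveforms and metric tables, and a machine-readable run manifest.

.default_scenario <- function() {
  list(
    scene = list(kind = "layered_breast", params = list()),
    implant = list(shape = "lens", materials = c("PZT-5A", "LiNbO3"),
                   thickness_mm = c(1, 2), position = c(0.042, 0.03, 0.03),
                   axis = c(-1, 0, 0)),
    source = list(radius = 0.005, frequency = 5e6, regime = "pulse"),
    solver = list(max_iter = 100, tol = 0.10),
    raytrace = list(n_rays = 128, max_wavelengths = 1000,
                    min_amplitude = 1e-5, max_generation = 6,
                    cone_half_angle = pi / 6),
    detection = list(threshold = 1e-5, cap = 1200),
    sweep = list(frequencies = NULL, apertures = 0.03),
    stages = c("scattering", "raytrace"),
    seed = 1L,
    out_dir = "usforward-run")
}

#' Read and validate a scenario configuration
#'
#' Scenario files are YAML; every omitted entry takes the framework
#' default (5 mm source radius, 100-iteration / 10% CG stopping rule,
#' 1000-wavelength ray limit, 10 uV detection threshold, 1200-record
#' cap). Validation happens before any computation.
#'
#' @param file Path to a YAML scenario file, or `NULL` for pure defaults.
#' @param overrides Named list merged over the file contents.
#' @return A validated `us_scenario` list.
#' @export
read_scenario <- function(file = NULL, overrides = list()) {
  cfg <- .default_scenario()
  if (!is.null(file)) {
    user <- yaml::read_yaml(file)
    cfg <- utils::modifyList(cfg, user)
  }
  if (length(overrides) > 0L) cfg <- utils::modifyList(cfg, overrides)
  validate_scenario(cfg)
}

#' Validate a scenario configuration list
#'
#' @param cfg Scenario list (see [read_scenario()]).
#' @return The list, classed `us_scenario`, or an error naming the
#'   offending entry.
#' @export
validate_scenario <- function(cfg) {
  f <- cfg$source$frequency
  if (!is.numeric(f) || f < 1e6 || f > 10e6) {
    stop("source$frequency must lie in the 1-10 MHz band (got ", f, ")")
  }
  sw_f <- cfg$sweep$frequencies
  if (!is.null(sw_f) && (any(sw_f < 1e6) || any(sw_f > 10e6))) {
    stop("sweep$frequencies must lie within [1, 10] MHz")
  }
  ap <- cfg$sweep$apertures
  if (any(ap < 0.01 - 1e-12) || any(ap > 0.07 + 1e-12)) {
    stop("sweep$apertures must lie within [0.01, 0.07] m")
  }
  if (is.null(cfg$seed)) stop("a seed is mandatory for stochastic stages")
  bad <- setdiff(cfg$stages, c("scattering", "raytrace"))
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!cfg$source$regime %in% c("pulse", "harmonic")) {
    stop("source$regime must be 'pulse' or 'harmonic'")
  }
  class(cfg) <- "us_scenario"
  cfg
}

#' Run a simulation scenario
#'
#' Builds the configured scene (and implant), runs the requested
#' operator stages, and writes per-stage outputs under `cfg$out_dir`:
#' field CSVs and the CG convergence trace for the scattering stage;
#' echo-metric tables (one row per frequency/aperture pair), example
#' waveforms and magnitude-map images for the ray-tracing stage; plus
#' `manifest.json` recording the configuration, seed, package version
#' and completed stages.
#'
#' @param cfg A `us_scenario` (from [read_scenario()]) or a plain list,
#'   which is validated first.
#' @return Invisibly, a results list with the scene, solution and metric
#'   tables.
#' @export
run_scenario <- function(cfg) {
  if (!inherits(cfg, "us_scenario")) cfg <- validate_scenario(
    utils::modifyList(.default_scenario(), cfg))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  completed <- character(0)
  results <- list(config = cfg)
  t_start <- Sys.time()

  scn <- synthetic_scene(cfg$scene$kind, cfg$scene$params, seed = cfg$seed)
  scene <- scn$scene
  if (!is.null(cfg$implant)) {
    spec <- implant_spec(cfg$implant$shape, cfg$implant$materials,
                         cfg$implant$thickness_mm,
                         position = cfg$implant$position,
                         axis = cfg$implant$axis)
    scene <- embed_implant(scene, build_implant(spec))
  }
  results$scene <- scene
  src <- source_transducer(center = scene$source_center,
                           normal = scene$source_normal,
                           radius = cfg$source$radius)
  completed <- c(completed, "scene")

  if ("scattering" %in% cfg$stages) {
    sol <- cg_solve(scene, src, cfg$source$frequency,
                    max_iter = cfg$solver$max_iter, tol = cfg$solver$tol)
    write_field(sol$incident, scene$grid, file.path(out, "field_incident.csv"))
    write_field(sol$total, scene$grid, file.path(out, "field_total.csv"))
    write_field(sol$scattered, scene$grid,
                file.path(out, "field_scattered.csv"))
    utils::write.csv(sol$history, file.path(out, "cg_history.csv"),
                     row.names = FALSE)
    .try_field_image(sol$scattered, scene$grid,
                     file.path(out, "field_scattered.png"))
    results$solution <- sol
    completed <- c(completed, "scattering")
  }

  if ("raytrace" %in% cfg$stages) {
    freqs <- cfg$sweep$frequencies
    if (is.null(freqs)) freqs <- cfg$source$frequency
    rows <- list()
    example_written <- FALSE
    for (f in freqs) {
      rays <- trace_rays(scene, src, f,
                         n_rays = cfg$raytrace$n_rays,
                         cone_half_angle = cfg$raytrace$cone_half_angle,
                         limits = list(
                           max_wavelengths = cfg$raytrace$max_wavelengths,
                           min_amplitude = cfg$raytrace$min_amplitude,
                           max_generation = cfg$raytrace$max_generation),
                         seed = cfg$seed)
      template <- if (cfg$source$regime == "pulse") {
        gaussian_pulse(f)
      } else {
        harmonic_excitation(f)
      }
      for (ap in cfg$sweep$apertures) {
        rec <- collect_echo(rays, src$center, ap, f,
                            detector_normal = src$normal,
                            threshold = cfg$detection$threshold,
                            cap = cfg$detection$cap)
        echo <- synthesize_echo(rec, template)
        met <- echo_metrics(echo, records = rec,
                            threshold = cfg$detection$threshold,
                            cap = cfg$detection$cap)
        rows[[length(rows) + 1]] <- data.frame(
          frequency = f, aperture = ap, n_interactions = met$n_interactions,
          energy = met$energy, peak = met$peak)
        if (!example_written && nrow(rec) > 0L) {
          write_waveform(echo, file.path(out, "echo_example.csv"),
                         file.path(out, "echo_example_spectrum.csv"))
          example_written <- TRUE
        }
      }
    }
    metrics <- do.call(rbind, rows)
    utils::write.csv(metrics, file.path(out, "echo_metrics.csv"),
                     row.names = FALSE)
    results$metrics <- metrics
    completed <- c(completed, "raytrace")
  }

  manifest <- list(
    package = "usforward",
    version = as.character(utils::packageVersion("usforward")),
    r_version = R.version.string,
    seed = cfg$seed,
    stages_completed = completed,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(results)
}

# Magnitude-map image of a field on the mid-z plane, logarithmic colour
# scale; silently skipped where no PNG device is available.
.try_field_image <- function(field, grid, file) {
  tryCatch({
    ext <- grid$extent
    n1 <- max(16L, grid$n_base[1] * 4L)
    n2 <- max(16L, grid$n_base[2] * 4L)
    xs <- grid$origin[1] + (seq_len(n1) - 0.5) * ext[1] / n1
    ys <- grid$origin[2] + (seq_len(n2) - 0.5) * ext[2] / n2
    zmid <- grid$origin[3] + ext[3] / 2
    pts <- cbind(rep(xs, times = n2), rep(ys, each = n1), zmid)
    cells <- locate_cells(grid, pts)
    m <- matrix(log10(pmax(Mod(field$p[cells]), 1e-12)), n1, n2)
    grDevices::png(file, width = 480, height = 480)
    graphics::image(xs, ys, m, col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "x (m)", ylab = "y (m)",
                    main = paste0("log10 |p| (", field$variant, ")"))
    grDevices::dev.off()
    invisible(TRUE)
  }, error = function(e) invisible(FALSE))
}
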