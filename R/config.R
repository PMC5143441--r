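# Run configuration: YAML with explicit keys, resolved against package
# defaults.  Every CLI run writes the fully resolved configuration next to
# its outputs so any run is reproducible from that file plus its seed.

cfg_error <- function(msg) {
  stop(structure(class = c("hasim_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Default run configuration
#'
#' The array defaults describe the reference clinical geometry used
#' throughout the package: 256 elements, 14.5 cm circular aperture,
#' 13 cm focal length, 1 MHz.
#'
#' @return nested named list of defaults.
#' @export
default_config <- function() {
  list(
    frequency = 1e6,
    seed = 1L,
    grid = list(dims = c(64L, 64L, 80L),
                spacing = c(7.5e-4, 7.5e-4, 7.5e-4),
                origin = NULL),
    medium = list(kind = "water", c = 1500, a = 0, rho = 1000,
                  base_thickness = 7.5e-3, max_relief = 4e-3,
                  feature_scale = 5e-3, plate_speed = 2492,
                  plate_attenuation = 4.72, plate_density = 1180,
                  plate_z = NULL,
                  mean_thickness = 6e-3, thickness_variation = 1.5e-3,
                  thickness_scale = 25e-3, hu_mean = 1400,
                  texture_amplitude = 300, texture_scale = 2e-3),
    array = list(n_elements = 256L, aperture_diameter = 0.145,
                 focal_length = 0.13, layout = "spiral",
                 layout_file = NULL),
    solver = list(dz = NULL, evanescent = "zero", pad_factor = 2,
                  taper = 10, reflection = FALSE),
    region = NULL,
    targets = NULL,
    analysis = list(n_lattice = 5L, lattice_spacing = 1e-3,
                    sigma = 0, aperture_radius = NULL),
    output_dir = "hasim_out"
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(user[[k]])))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Resolve a run configuration against the defaults
#'
#' @param config path to a YAML file, a named list, or `NULL` (defaults).
#' @param overrides named list applied on top (e.g. CLI flags).
#' @return the fully resolved configuration list.
#' @export
resolve_config <- function(config = NULL, overrides = list()) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) {
    if (!file.exists(config)) cfg_error(sprintf("config file not found: %s", config))
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else cfg_error("config must be a file path or a named list")
  cfg <- merge_config(default_config(), user)
  cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  req <- function(val, key) if (is.null(val) || (is.atomic(val) && anyNA(val)))
    cfg_error(sprintf("missing required config key: %s", key))
  req(cfg$frequency, "frequency")
  if (!is.numeric(cfg$frequency) || cfg$frequency <= 0)
    cfg_error("invalid config key: frequency (must be a positive Hz value)")
  req(cfg$grid$dims, "grid.dims"); req(cfg$grid$spacing, "grid.spacing")
  if (length(cfg$grid$dims) != 3L || any(cfg$grid$dims < 1))
    cfg_error("invalid config key: grid.dims")
  if (length(cfg$grid$spacing) != 3L || any(cfg$grid$spacing <= 0))
    cfg_error("invalid config key: grid.spacing")
  req(cfg$medium$kind, "medium.kind")
  if (!cfg$medium$kind %in% c("water", "aberrator", "hu"))
    cfg_error("invalid config key: medium.kind (water | aberrator | hu)")
  req(cfg$array$n_elements, "array.n_elements")
  if (cfg$array$aperture_diameter >= 2 * cfg$array$focal_length)
    cfg_error("invalid config key: array.aperture_diameter (aperture too large)")
  invisible(cfg)
}

cfg_grid <- function(cfg) {
  voxel_grid(cfg$grid$dims, cfg$grid$spacing, cfg$grid$origin)
}

cfg_array <- function(cfg) {
  build_spherical_array(n_elements = cfg$array$n_elements,
                        aperture_diameter = cfg$array$aperture_diameter,
                        focal_length = cfg$array$focal_length,
                        frequency = cfg$frequency,
                        layout_kind = cfg$array$layout,
                        layout_file = cfg$array$layout_file)
}

cfg_solver <- function(cfg) {
  solver_config(dz = cfg$solver$dz, evanescent = cfg$solver$evanescent,
                pad_factor = cfg$solver$pad_factor, taper = cfg$solver$taper,
                reflection = cfg$solver$reflection)
}

cfg_medium_model <- function(cfg) {
  g <- cfg_grid(cfg)
  m <- cfg$medium
  switch(m$kind,
    water = make_water_model(g$dims, g$spacing, c_water = m$c, a_water = m$a,
                             rho_water = m$rho, origin = g$origin),
    aberrator = generate_aberrator(cfg$seed, g,
                                   base_thickness = m$base_thickness,
                                   max_relief = m$max_relief,
                                   feature_scale = m$feature_scale,
                                   plate_speed = m$plate_speed,
                                   plate_attenuation = m$plate_attenuation,
                                   plate_density = m$plate_density,
                                   plate_z = m$plate_z,
                                   c_water = m$c, a_water = m$a,
                                   rho_water = m$rho)$model,
    hu = cfg_error("medium.kind 'hu' requires the map-ct stage (a model file)"))
}

write_resolved_config <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  drop_null <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, drop_null)
    x[!vapply(x, is.null, logical(1))]
  }
  yaml::write_yaml(drop_null(cfg), file.path(dir, "resolved_config.yaml"))
}
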