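# File formats: NIfTI (via RNifti) and MetaImage MHD/RAW for property and
# HU volumes, CSV/JSON for element layouts and phase solutions, CSV/STL
# for aberrator height maps.  Geometry is SI (meters) in memory; NIfTI and
# MHD headers carry millimeters, the convention of medical-image viewers.
# A JSON sidecar written next to NIfTI volumes is the authoritative
# (lossless) record of spacing and origin in meters.

grid_meta_list <- function(grid) {
  list(dims = as.integer(grid$dims), spacing = grid$spacing,
       origin = grid$origin, units = "m")
}

write_grid_sidecar <- function(grid, path, extra = list()) {
  jsonlite::write_json(c(grid_meta_list(grid), extra), path,
                       auto_unbox = TRUE, digits = NA)
}

read_grid_sidecar <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  voxel_grid(m$dims, m$spacing, m$origin)
}

write_volume_nifti <- function(vol, grid, file) {
  img <- RNifti::asNifti(vol)
  img <- RNifti::`pixdim<-`(img, grid$spacing * 1e3)
  RNifti::writeNifti(img, file)
  write_grid_sidecar(grid, sidecar_path(file))
  invisible(file)
}

sidecar_path <- function(file) {
  sub("\\.nii(\\.gz)?$", "_meta.json", file)
}

read_volume_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  sc <- sidecar_path(file)
  grid <- if (file.exists(sc)) read_grid_sidecar(sc)
  else voxel_grid(dim(img), RNifti::pixdim(img) * 1e-3)
  list(data = array(as.numeric(img), dim(img)), grid = grid)
}

#' Write / read an acoustic model as NIfTI volumes
#'
#' Writes three volumes `<prefix>_speed.nii.gz`, `<prefix>_attenuation.nii.gz`
#' and `<prefix>_density.nii.gz` plus a JSON sidecar per volume holding the
#' exact grid geometry in meters and a `<prefix>_background.json` with the
#' immersion-medium properties.
#'
#' @param model an [acoustic_model()].
#' @param prefix path prefix for the output files.
#' @return (invisibly) the vector of files written.
#' @export
write_model_nifti <- function(model, prefix) {
  stopifnot(inherits(model, "acoustic_model"))
  files <- c(speed = paste0(prefix, "_speed.nii.gz"),
             attenuation = paste0(prefix, "_attenuation.nii.gz"),
             density = paste0(prefix, "_density.nii.gz"))
  write_volume_nifti(model$speed, model$grid, files["speed"])
  write_volume_nifti(model$attenuation, model$grid, files["attenuation"])
  write_volume_nifti(model$density, model$grid, files["density"])
  jsonlite::write_json(model$background, paste0(prefix, "_background.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' @rdname write_model_nifti
#' @export
read_model_nifti <- function(prefix) {
  sp <- read_volume_nifti(paste0(prefix, "_speed.nii.gz"))
  at <- read_volume_nifti(paste0(prefix, "_attenuation.nii.gz"))
  de <- read_volume_nifti(paste0(prefix, "_density.nii.gz"))
  bgf <- paste0(prefix, "_background.json")
  bg <- if (file.exists(bgf)) jsonlite::read_json(bgf, simplifyVector = TRUE)
  else list(speed = 1500, attenuation = 0, density = 1000)
  acoustic_model(sp$grid, sp$data, at$data, de$data, background = bg)
}

#' Write / read a Hounsfield-unit volume as NIfTI
#'
#' @param hu an [hu_volume()].
#' @param file output `.nii`/`.nii.gz` path.
#' @return (invisibly) the file path.
#' @export
write_hu_nifti <- function(hu, file) {
  stopifnot(inherits(hu, "hu_volume"))
  write_volume_nifti(hu$hu, hu$grid, file)
  invisible(file)
}

#' @rdname write_hu_nifti
#' @export
read_hu_nifti <- function(file) {
  v <- read_volume_nifti(file)
  hu_volume(v$grid, v$data)
}

#' Export a pressure volume's magnitude as NIfTI
#'
#' Complex fields persist losslessly as `.rds`; this export is the
#' magnitude-only view for image viewers.
#'
#' @param p a [pressure_volume()].
#' @param file output path.
#' @export
write_pressure_nifti <- function(p, file) {
  stopifnot(inherits(p, "pressure_volume"))
  write_volume_nifti(Mod(p$field), p$grid, file)
  invisible(file)
}

#' Write / read a volume in MetaImage MHD/RAW format
#'
#' Minimal MetaImage support: an `.mhd` text header (`DimSize`,
#' `ElementSpacing`/`Offset` in mm, `MET_DOUBLE` data) next to a raw
#' little-endian block.
#'
#' @param vol numeric 3D array.
#' @param grid a [voxel_grid()].
#' @param file output `.mhd` path (the `.raw` is written beside it).
#' @return (invisibly) the header path.
#' @export
write_mhd <- function(vol, grid, file) {
  stopifnot(length(dim(vol)) == 3L, inherits(grid, "voxel_grid"))
  raw_file <- sub("\\.mhd$", ".raw", file)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(vol), collapse = " ")),
           paste("ElementSpacing =",
                 paste(format(grid$spacing * 1e3, digits = 17), collapse = " ")),
           paste("Offset =",
                 paste(format(grid$origin * 1e3, digits = 17), collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", basename(raw_file)))
  writeLines(hdr, file)
  con <- file(raw_file, "wb")
  on.exit(close(con))
  writeBin(as.vector(vol), con, size = 8, endian = "little")
  invisible(file)
}

#' @rdname write_mhd
#' @export
read_mhd <- function(file) {
  lines <- readLines(file)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  val <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop(sprintf("MHD header missing key '%s'", k), call. = FALSE)
    kv[[i]][2]
  }
  dims <- as.integer(strsplit(val("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(val("ElementSpacing"), "\\s+")[[1]]) * 1e-3
  origin <- as.numeric(strsplit(val("Offset"), "\\s+")[[1]]) * 1e-3
  raw_file <- file.path(dirname(file), val("ElementDataFile"))
  con <- file(raw_file, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = prod(dims), size = 8, endian = "little")
  list(data = array(v, dims), grid = voxel_grid(dims, spacing, origin))
}

#' Write / read a transducer element layout CSV
#'
#' Columns `x,y,z,nx,ny,nz,area` in SI units; a header row is required.
#' Malformed rows raise a parse error naming the offending line.
#'
#' @param array a [build_spherical_array()] (for writing).
#' @param file CSV path.
#' @export
write_layout_csv <- function(array, file) {
  stopifnot(inherits(array, "transducer_array"))
  df <- data.frame(x = array$centers[, 1], y = array$centers[, 2],
                   z = array$centers[, 3],
                   nx = array$normals[, 1], ny = array$normals[, 2],
                   nz = array$normals[, 3], area = array$areas)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 2L)
    stop("layout CSV needs a header and at least one element", call. = FALSE)
  hdr <- gsub('"', "", strsplit(lines[1], ",")[[1]])
  need <- c("x", "y", "z", "nx", "ny", "nz", "area")
  if (!all(need %in% trimws(hdr)))
    stop("layout CSV header must contain columns x,y,z,nx,ny,nz,area",
         call. = FALSE)
  df <- tryCatch(utils::read.csv(file), error = function(e)
    stop(sprintf("cannot parse layout CSV: %s", conditionMessage(e)),
         call. = FALSE))
  for (i in seq_len(nrow(df))) {
    row <- df[i, need]
    if (any(is.na(suppressWarnings(as.numeric(unlist(row))))))
      stop(sprintf("malformed layout CSV at line %d", i + 1L), call. = FALSE)
  }
  if (any(df$area <= 0))
    stop("element areas must be positive", call. = FALSE)
  df
}

#' Export a phase solution
#'
#' CSV (`element_index, phase_rad`) is the driver-facing artifact; the
#' JSON companion carries the target location and provenance.
#'
#' @param solution a [correction_phases()] solution.
#' @param csv_file,json_file output paths (either may be `NULL`).
#' @export
write_phase_solution <- function(solution, csv_file = NULL, json_file = NULL) {
  stopifnot(inherits(solution, "phase_solution"))
  if (!is.null(csv_file)) {
    utils::write.csv(data.frame(element_index = seq_along(solution$phases),
                                phase_rad = solution$phases),
                     csv_file, row.names = FALSE)
  }
  if (!is.null(json_file)) {
    jsonlite::write_json(list(target_m = solution$target,
                              target_voxel = solution$target_voxel,
                              frequency_hz = solution$frequency,
                              n_elements = solution$n_elements,
                              phases_rad = solution$phases),
                         json_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(solution)
}

#' @rdname write_phase_solution
#' @param file a CSV or JSON file written by [write_phase_solution()].
#' @export
read_phase_solution <- function(file) {
  if (grepl("\\.json$", file)) {
    m <- jsonlite::read_json(file, simplifyVector = TRUE)
    structure(list(phases = m$phases_rad, target = m$target_m,
                   target_voxel = m$target_voxel,
                   p_target = NULL, frequency = m$frequency_hz,
                   n_elements = m$n_elements),
              class = "phase_solution")
  } else {
    df <- utils::read.csv(file)
    structure(list(phases = df$phase_rad, target = rep(NA_real_, 3),
                   target_voxel = rep(NA_integer_, 3), p_target = NULL,
                   frequency = NA_real_, n_elements = nrow(df)),
              class = "phase_solution")
  }
}

#' Export an aberrator height map
#'
#' `write_heightmap_csv` writes the relief lattice (meters) as a plain CSV
#' grid.  `write_heightmap_stl` writes a watertight ASCII STL solid (flat
#' base + relief top + side walls) suitable for 3D printing the physical
#' aberrator plate.
#'
#' @param hm a `height_map` from [generate_aberrator()].
#' @param file output path.
#' @export
write_heightmap_csv <- function(hm, file) {
  stopifnot(inherits(hm, "height_map"))
  utils::write.table(hm$heights, file, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname write_heightmap_csv
#' @export
write_heightmap_stl <- function(hm, file) {
  stopifnot(inherits(hm, "height_map"))
  nx <- nrow(hm$heights); ny <- ncol(hm$heights)
  dx <- hm$spacing[1] * 1e3; dy <- hm$spacing[2] * 1e3  # STL in mm
  zt <- (hm$base + hm$heights) * 1e3
  xs <- (seq_len(nx) - 1) * dx
  ys <- (seq_len(ny) - 1) * dy
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("solid aberrator", con)
  tri <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    c(sprintf(" facet normal %g %g %g", n[1], n[2], n[3]),
      "  outer loop",
      sprintf("   vertex %g %g %g", p1[1], p1[2], p1[3]),
      sprintf("   vertex %g %g %g", p2[1], p2[2], p2[3]),
      sprintf("   vertex %g %g %g", p3[1], p3[2], p3[3]),
      "  endloop", " endfacet")
  }
  out <- character(0)
  for (i in seq_len(nx - 1)) {
    for (j in seq_len(ny - 1)) {
      a <- c(xs[i], ys[j], zt[i, j]);       b <- c(xs[i + 1], ys[j], zt[i + 1, j])
      cc <- c(xs[i + 1], ys[j + 1], zt[i + 1, j + 1]); d <- c(xs[i], ys[j + 1], zt[i, j + 1])
      out <- c(out, tri(a, b, cc), tri(a, cc, d))
      a0 <- c(xs[i], ys[j], 0);       b0 <- c(xs[i + 1], ys[j], 0)
      c0 <- c(xs[i + 1], ys[j + 1], 0); d0 <- c(xs[i], ys[j + 1], 0)
      out <- c(out, tri(a0, c0, b0), tri(a0, d0, c0))
    }
  }
  # side walls
  wall <- function(p_lo1, p_lo2, z1, z2) {
    c(tri(c(p_lo1, 0), c(p_lo2, 0), c(p_lo2, z2)),
      tri(c(p_lo1, 0), c(p_lo2, z2), c(p_lo1, z1)))
  }
  for (i in seq_len(nx - 1)) {
    out <- c(out, wall(c(xs[i], ys[1]), c(xs[i + 1], ys[1]),
                       zt[i, 1], zt[i + 1, 1]))
    out <- c(out, wall(c(xs[i + 1], ys[ny]), c(xs[i], ys[ny]),
                       zt[i + 1, ny], zt[i, ny]))
  }
  for (j in seq_len(ny - 1)) {
    out <- c(out, wall(c(xs[1], ys[j + 1]), c(xs[1], ys[j]),
                       zt[1, j + 1], zt[1, j]))
    out <- c(out, wall(c(xs[nx], ys[j]), c(xs[nx], ys[j + 1]),
                       zt[nx, j], zt[nx, j + 1]))
  }
  writeLines(out, con)
  writeLines("endsolid aberrator", con)
  invisible(file)
}

#' Export a ratio map or correlation result
#'
#' CSV lattice plus a JSON summary (peak, contour areas where present).
#'
#' @param x a `ratio_map` or `correlation_result`.
#' @param csv_file,json_file output paths (either may be `NULL`).
#' @export
write_analysis <- function(x, csv_file = NULL, json_file = NULL) {
  if (inherits(x, "ratio_map")) {
    if (!is.null(csv_file)) {
      df <- expand.grid(x = x$x, y = x$y)
      df$value <- as.vector(x$values)
      utils::write.csv(df, csv_file, row.names = FALSE)
    }
    if (!is.null(json_file))
      jsonlite::write_json(list(kind = x$kind, reference = x$reference,
                                min = min(x$values), max = max(x$values)),
                           json_file, auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "correlation_result")) {
    if (!is.null(csv_file)) {
      df <- expand.grid(lag_x = x$lag_x, lag_y = x$lag_y)
      df$value <- as.vector(x$corr)
      utils::write.csv(df, csv_file, row.names = FALSE)
    }
    if (!is.null(json_file))
      jsonlite::write_json(list(peak = max(x$corr),
                                aperture_radius_m = x$aperture_radius,
                                contour_areas_mm2 = as.list(x$areas_mm2)),
                           json_file, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported analysis object", call. = FALSE)
  invisible(x)
}
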