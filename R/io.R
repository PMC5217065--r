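# File formats and the end-to-end pipeline. CSV dialect: UTF-8, comma
# separated, mandatory header, '.' decimal separator; angles in degrees,
# lengths in mm, areas in m^2. Scene and statistics serialise to JSON.

LANDMARK_COLS <- c("specimen_id", "taxon", "Ax", "Ay", "Az",
                   "Bx", "By", "Bz", "Cx", "Cy", "Cz", "slice_count")

#' Read and write landmark tables
#'
#' The landmark CSV schema has columns `specimen_id`, `taxon`,
#' `Ax,Ay,Az,Bx,By,Bz,Cx,Cy,Cz` (mm; C columns NA for two-landmark
#' specimens) and `slice_count`. `read_landmarks()` validates the schema and
#' reports the offending row and column on failure.
#'
#' @param path File path.
#' @return `read_landmarks()`: the validated data frame.
#' @export
read_landmarks <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(LANDMARK_COLS, names(x))
  if (length(missing_cols))
    stop("landmark file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  x <- x[, LANDMARK_COLS]
  for (col in c("Ax", "Ay", "Az", "Bx", "By", "Bz")) {
    bad <- which(!is.finite(x[[col]]))
    if (length(bad))
      stop(sprintf("landmark file %s: non-finite value at row %d, column %s",
                   path, bad[1], col))
  }
  bad_taxon <- which(!x$taxon %in% c("ammonoid", "gastropod"))
  if (length(bad_taxon))
    stop(sprintf("landmark file %s: unknown taxon at row %d, column taxon",
                 path, bad_taxon[1]))
  x
}

#' @param lm_table Landmark data frame in the schema above.
#' @rdname read_landmarks
#' @export
write_landmarks <- function(lm_table, path) {
  utils::write.csv(lm_table[, LANDMARK_COLS], path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and write orientation tables
#'
#' The orientation CSV is the output schema of [measure_orientations()].
#'
#' @param path File path.
#' @param or_table Orientation data frame.
#' @export
read_orientations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_orientations
#' @export
write_orientations <- function(or_table, path) {
  utils::write.csv(or_table, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Serialise and restore scenes as JSON
#'
#' Full-precision JSON round trip of a [generate_scene()] scene: shell table
#' (ids, mm units, unit-vector poles), block dimensions, seed and fabric
#' configuration.
#'
#' @param scene A scene.
#' @param path Output (input) file path.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene"))
  payload <- list(block_dims_mm = scene$block_dims_mm,
                  seed = scene$seed,
                  config = unclass(scene$config),
                  shells = scene$shells)
  # 17 significant digits: exact binary round trip for doubles
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  cfg$packing <- match.arg(cfg$packing, c("shell_supported", "matrix_supported"))
  config <- do.call(fabric_config, cfg)
  shells <- as.data.frame(payload$shells, stringsAsFactors = FALSE)
  if (nrow(shells) == 0) shells <- empty_shell_table(0)
  structure(list(shells = shells,
                 block_dims_mm = as.numeric(payload$block_dims_mm),
                 seed = as.integer(payload$seed),
                 config = config),
            class = "scene")
}

#' Fabric statistics report for an orientation table
#'
#' Computes the full statistical read-out of one orientation table: the
#' ammonoid aperture rose diagram (directed, with the axial vector mean also
#' reported), Fisher statistics of the eligible ammonoid lineations and
#' sagittal-plane poles, the gastropod aperture rose and lineation statistics,
#' and the abundance extrapolations.
#'
#' @param orientations Orientation table from [measure_orientations()].
#' @param bin_width_deg Rose-diagram class width (default 20).
#' @param significance Fisher cone significance (default 0.05).
#' @param footprint_block_m2,extension_m2 Abundance extrapolation inputs;
#'   the defaults are the reference-block bedding-plane face 0.150 x 0.140 m
#'   and the 5 km^2 mapped extension.
#' @return A nested list (class `fabric_report`) ready for JSON export.
#' @export
fabric_report <- function(orientations, bin_width_deg = 20,
                          significance = 0.05,
                          footprint_block_m2 = 0.150 * 0.140,
                          extension_m2 = 5e6) {
  o <- orientations
  amm <- o[o$taxon == "ammonoid", , drop = FALSE]
  gas <- o[o$taxon == "gastropod", , drop = FALSE]

  rose_block <- function(az) {
    az <- az[!is.na(az)]
    if (!length(az)) return(NULL)
    r <- rose_histogram(az, bin_width_deg, mode = "directed")
    ax <- circular_vector_mean(az, mode = "axial")
    list(n = r$n,
         bin_width_deg = r$bin_width_deg,
         bin_edges_deg = r$bin_edges_deg,
         percentages = r$percentages,
         vector_mean_deg = r$vector_mean_deg,
         mean_resultant_length = r$mean_resultant_length,
         axial_mean_deg = ax$mean_deg,
         axial_resultant_length = ax$resultant_length,
         max_class = r$max_class)
  }
  fisher_block <- function(tab, trend_col, plunge_col) {
    tab <- tab[!is.na(tab[[trend_col]]) & !is.na(tab[[plunge_col]]), , drop = FALSE]
    if (nrow(tab) < 1) return(NULL)
    f <- fisher_statistics(tab[[trend_col]], tab[[plunge_col]], significance)
    unclass(f)
  }

  lin <- amm[amm$lineation_eligible, , drop = FALSE]
  pla <- amm[amm$plane_eligible, , drop = FALSE]
  gel <- gas[gas$gastropod_eligible, , drop = FALSE]

  plane_poles <- fisher_block(pla, "pole_trend_deg", "pole_plunge_deg")
  if (!is.null(plane_poles)) {
    # express the mean pole as the mean sagittal plane it represents
    mean_plane <- plane_from_normal(as.numeric(trend_plunge_to_cartesian(
      plane_poles$mean_trend_deg, plane_poles$mean_plunge_deg)))
    plane_poles$mean_plane_dip_deg <- mean_plane$dip_deg
    plane_poles$mean_plane_dip_direction_deg <- mean_plane$dip_direction_deg
  }

  counts <- list(total = nrow(o),
                 ammonoids = nrow(amm),
                 gastropods = nrow(gas),
                 lineation_eligible = nrow(lin),
                 plane_eligible = nrow(pla),
                 gastropod_eligible = nrow(gel))

  extr <- list()
  if (nrow(amm) > 0)
    extr$ammonoids <- unclass(extrapolate_abundance(nrow(amm),
                                                    footprint_block_m2,
                                                    extension_m2))
  if (nrow(gas) > 0)
    extr$gastropods <- unclass(extrapolate_abundance(nrow(gas),
                                                     footprint_block_m2,
                                                     extension_m2))

  structure(list(
    counts = counts,
    ammonoid_apertures = rose_block(amm$aperture_azimuth_deg[amm$lineation_eligible]),
    ammonoid_lineations = fisher_block(lin, "trend_deg", "plunge_deg"),
    ammonoid_plane_poles = plane_poles,
    gastropod_apertures = rose_block(gel$aperture_azimuth_deg),
    gastropod_lineations = fisher_block(gel, "trend_deg", "plunge_deg"),
    abundance = extr,
    parameters = list(bin_width_deg = bin_width_deg,
                      significance = significance,
                      footprint_block_m2 = footprint_block_m2,
                      extension_m2 = extension_m2)),
    class = "fabric_report")
}

#' @rdname fabric_report
#' @param report A `fabric_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the whole pipeline: simulate, slice, reconstruct, measure, summarise
#'
#' Orchestrates the stages end to end and writes all artifacts into
#' `out_dir`: `scene.json`, `ground_truth.csv`, `landmarks.csv`,
#' `orientations.csv`, `statistics.json`, SVG plots (aperture rose and
#' plane-pole stereonet, when any specimen is eligible) and `run_log.txt`.
#' Rerunning with the same configuration and seed reproduces the data outputs
#' byte for byte.
#'
#' @param config A [fabric_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param block_dims_mm Block dimensions, mm (x East, y North, z up; default
#'   is the reference block in bed coordinates, 45 mm thickness vertical).
#' @param interval_mm Slice interval, mm.
#' @param slice_axis Grinding axis passed to [slice_scene()]; the default
#'   `"y"` cuts vertical sections across the bedding, the physical protocol.
#' @param thresholds Eligibility thresholds, see [eligibility_filter()].
#' @param projection Stereonet projection for plots.
#' @param bin_width_deg Rose class width.
#' @param significance Fisher cone significance.
#' @param footprint_block_m2,extension_m2 Abundance extrapolation inputs; the
#'   footprint defaults to the block's horizontal (bedding-plane) area in m^2.
#' @param make_plots Write SVG figures (default TRUE).
#' @return Invisibly, a list with the scene, stack, specimens, landmark and
#'   orientation tables, the report, and the output paths.
#' @export
run_pipeline <- function(config = fabric_config(),
                         out_dir,
                         seed = 1L,
                         block_dims_mm = c(150, 140, 45),
                         interval_mm = 2.0,
                         slice_axis = c("y", "z", "x"),
                         thresholds = list(lineation = 6L, plane = 3L,
                                           gastropod = 2L),
                         projection = c("equal_area", "equal_angle"),
                         bin_width_deg = 20,
                         significance = 0.05,
                         footprint_block_m2 = NULL,
                         extension_m2 = 5e6,
                         make_plots = TRUE) {
  projection <- match.arg(projection)
  slice_axis <- match.arg(slice_axis)
  if (is.null(footprint_block_m2))
    footprint_block_m2 <- block_dims_mm[1] * block_dims_mm[2] * 1e-6
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(scene = file.path(out_dir, "scene.json"),
                ground_truth = file.path(out_dir, "ground_truth.csv"),
                landmarks = file.path(out_dir, "landmarks.csv"),
                orientations = file.path(out_dir, "orientations.csv"),
                statistics = file.path(out_dir, "statistics.json"),
                rose = file.path(out_dir, "rose_apertures.svg"),
                stereonet = file.path(out_dir, "stereonet_plane_poles.svg"),
                log = file.path(out_dir, "run_log.txt"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # each stage re-reads the artifact the previous stage wrote, so a run here
  # is byte-identical to the same stages composed by hand through the files
  scene <- stage("simulate", {
    s <- generate_scene(config, block_dims_mm, seed)
    write_scene(s, paths$scene)
    utils::write.csv(ground_truth_table(s), paths$ground_truth,
                     row.names = FALSE, quote = FALSE, na = "NA")
    read_scene(paths$scene)
  })
  stack <- stage("slice", slice_scene(scene, interval_mm, axis = slice_axis))
  specimens <- stage("reconstruct", reconstruct_specimens(stack))
  lm_table <- stage("landmarks", {
    write_landmarks(landmark_table(specimens, stack), paths$landmarks)
    read_landmarks(paths$landmarks)
  })
  orientations <- stage("measure", {
    o <- measure_orientations(lm_table, thresholds)
    write_orientations(o, paths$orientations)
    read_orientations(paths$orientations)
  })
  report <- stage("stats", {
    r <- fabric_report(orientations, bin_width_deg, significance,
                       footprint_block_m2, extension_m2)
    write_report(r, paths$statistics)
    r
  })
  if (make_plots) {
    stage("plot", {
      az <- orientations$aperture_azimuth_deg[orientations$taxon == "ammonoid"]
      az <- az[!is.na(az)]
      if (length(az)) {
        grDevices::svg(paths$rose, width = 6, height = 6)
        plot(rose_histogram(az, bin_width_deg, "directed"))
        grDevices::dev.off()
      }
      pla <- orientations[orientations$plane_eligible &
                            !is.na(orientations$pole_trend_deg), , drop = FALSE]
      if (nrow(pla)) {
        grDevices::svg(paths$stereonet, width = 6, height = 6)
        plot_stereonet(pla$pole_trend_deg, pla$pole_plunge_deg,
                       method = projection,
                       main = "Sagittal-plane poles (lower hemisphere)")
        grDevices::dev.off()
      }
    })
  }
  elig <- eligibility_filter(specimens, thresholds)
  writeLines(c(
    sprintf("coquina %s", as.character(utils::packageVersion("coquina"))),
    sprintf("R %s", R.version.string),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("block_dims_mm: %s", paste(block_dims_mm, collapse = " x ")),
    sprintf("interval_mm: %g (grinding axis %s)", interval_mm, slice_axis),
    sprintf("shells generated: %d", nrow(scene$shells)),
    sprintf("specimens reconstructed: %d", length(specimens)),
    sprintf("lineation eligible (>= %d slices): %d",
            thresholds$lineation, length(elig$lineation_eligible)),
    sprintf("plane eligible (>= %d slices): %d",
            thresholds$plane, length(elig$plane_eligible)),
    sprintf("gastropod eligible (>= %d slices): %d",
            thresholds$gastropod, length(elig$gastropod_eligible))),
    paths$log)
  invisible(list(scene = scene, stack = stack, specimens = specimens,
                 landmarks = lm_table, orientations = orientations,
                 report = report, paths = paths))
}
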