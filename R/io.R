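#' Read a grayscale image
#'
#' Supports 8/16-bit grayscale TIFF and PNG. Intensities are returned as
#' floats in `[0, 1]` (the tiff and png readers already normalize by the bit
#' depth, so a 16-bit value of 65535 reads as 1.0). RGB or multi-channel
#' images are rejected rather than silently converted.
#'
#' @param path Image file path.
#' @return Numeric matrix (height x width) in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext,
                     " (expected TIFF or PNG)"))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) img <- img[, , 1]
    else stop("RGB/multi-channel images are not supported: ", path)
  }
  img
}

#' Write a grayscale image
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output path (`.tiff` or `.png`).
#' @param bits_per_sample Bit depth for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits_per_sample = 16L) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(img, path,
                                        bits.per.sample = bits_per_sample),
         png = png::writePNG(img, path),
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Write a results table as CSV
#'
#' All tables carry a header row and a fixed column order; numbers are
#' written at full precision so that a write/read round trip is exact to
#' about 1e-15 relative.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param columns Optional required column order; an error is raised if a
#'   column is missing.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(df, path, columns = NULL) {
  if (!is.null(columns)) {
    missing <- setdiff(columns, names(df))
    if (length(missing))
      stop("missing columns: ", paste(missing, collapse = ", "))
    df <- df[, columns, drop = FALSE]
  }
  old <- options(digits = 15)
  on.exit(options(old))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results CSV with basic validation
#'
#' @param path CSV path.
#' @param columns Optional required columns.
#' @return Data frame. Malformed rows (wrong field count) raise an error
#'   naming the line number.
#' @export
read_results_csv <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("CSV file does not exist: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty CSV: ", path)
  nfield <- lengths(strsplit(lines, ",", fixed = TRUE))
  bad <- which(nfield != nfield[1])
  if (length(bad))
    stop("malformed CSV row at line ", bad[1], " of ", path,
         ": expected ", nfield[1], " fields, found ", nfield[bad[1]])
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    missing <- setdiff(columns, names(df))
    if (length(missing))
      stop("missing columns in ", path, ": ",
           paste(missing, collapse = ", "))
  }
  df
}

#' Load and validate a run configuration
#'
#' One YAML file describes a complete run: seed, speckle, specimen,
#' protocol, slip, rig, dic, strain and analysis blocks. Defaults are filled
#' in for omitted fields; unknown top-level blocks and schema violations
#' raise errors naming the field.
#'
#' @param path YAML file path.
#' @return An object of class `run_config` (a named list).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "output_dir", "speckle", "specimen", "protocol", "slip",
             "rig", "dic", "strain", "analysis")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config block(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$seed)) stop("config field 'seed' is mandatory")
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("config field 'seed' must be an integer")
  build <- function(fun, block) {
    args <- cfg[[block]]
    if (is.null(args)) args <- list()
    ok <- names(args) %in% names(formals(fun))
    if (!all(ok))
      stop("unknown field(s) in config block '", block, "': ",
           paste(names(args)[!ok], collapse = ", "))
    do.call(fun, args)
  }
  rig <- cfg$rig
  if (is.null(rig)) rig <- list()
  rig_defaults <- list(scale_mm_per_px = 0.05, working_distance_mm = 500,
                       baseline_mm = 140, plate_width_mm = 24,
                       plate_height_mm = 6)
  bad <- setdiff(names(rig), names(rig_defaults))
  if (length(bad))
    stop("unknown field(s) in config block 'rig': ",
         paste(bad, collapse = ", "))
  rig <- utils::modifyList(rig_defaults, rig)
  analysis <- cfg$analysis
  if (is.null(analysis)) analysis <- list()
  ana_defaults <- list(central_disc_diameter_mm = 4.0, grid_mm = 1.0,
                       damage_threshold_pct = 5.0)
  bad <- setdiff(names(analysis), names(ana_defaults))
  if (length(bad))
    stop("unknown field(s) in config block 'analysis': ",
         paste(bad, collapse = ", "))
  analysis <- utils::modifyList(ana_defaults, analysis)
  structure(list(seed = as.integer(cfg$seed),
                 output_dir = if (is.null(cfg$output_dir)) "." else
                   cfg$output_dir,
                 speckle = build(speckle_params, "speckle"),
                 specimen = build(specimen_model, "specimen"),
                 protocol = build(load_protocol, "protocol"),
                 slip = build(grip_slip_model, "slip"),
                 rig = rig,
                 dic = build(dic_config, "dic"),
                 strain = build(strain_config, "strain"),
                 analysis = analysis),
            class = "run_config")
}

#' Append a stage record to the run manifest
#'
#' The manifest records, per pipeline stage, the configuration hash and the
#' MD5 checksums of input and output files, so that re-running a
#' deterministic stage with an identical configuration reproduces identical
#' checksums.
#'
#' @param manifest_path Path of the manifest JSON (created if absent).
#' @param stage Stage name.
#' @param config_hash Hash of the run configuration (see
#'   [config_hash()]).
#' @param inputs,outputs Character vectors of file paths to checksum.
#' @return The updated manifest list, invisibly.
#' @export
manifest_append <- function(manifest_path, stage, config_hash,
                            inputs = character(0), outputs = character(0)) {
  man <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE) else list()
  sums <- function(ps) {
    ps <- ps[file.exists(ps)]
    as.list(tools::md5sum(ps))
  }
  man[[stage]] <- list(config_hash = config_hash,
                       package_version =
                         as.character(utils::packageVersion("tendondic")),
                       r_version = paste(R.version$major, R.version$minor,
                                         sep = "."),
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                       inputs = sums(inputs), outputs = sums(outputs))
  jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

#' Hash of a run configuration
#'
#' @param config A `run_config`.
#' @return MD5 hex string of the serialized configuration.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass_all(config)), tmp)
  unname(tools::md5sum(tmp))
}

unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_all) else x
}
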