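# Persistent formats. Datasets live in a single HDF5 container; complex
# arrays are stored as paired `re`/`im` double datasets under a group
# (HDF5 has no native complex type), and the layout is self-describing via
# root attributes. All arrays round-trip bit-exactly.

FORMAT_VERSION <- "1.0"

h5_write_complex <- function(x, path, group) {
  rhdf5::h5createGroup(path, group)
  rhdf5::h5write(Re(x), path, paste0(group, "/re"))
  rhdf5::h5write(Im(x), path, paste0(group, "/im"))
}

h5_read_complex <- function(path, group) {
  re <- rhdf5::h5read(path, paste0(group, "/re"))
  im <- rhdf5::h5read(path, paste0(group, "/im"))
  out <- complex(real = re, imaginary = im)
  dim(out) <- dim(re)
  out
}

#' Write a ptychography dataset to an HDF5 container
#'
#' Layout: `/data` (S, S, n double intensities), `/probe/{re,im}`,
#' `/positions` (n x 2 integer, 0-based row/col), optional
#' `/ground_truth/{re,im}`; root attributes `H`, `W`, `format_version` and a
#' JSON serialization of the simulation spec. Arrays round-trip bit-exactly.
#'
#' @param dataset a `pty_dataset`.
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
pty_write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pty_dataset"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(dataset$data, path, "data")
  h5_write_complex(dataset$probe, path, "probe")
  rhdf5::h5write(dataset$positions, path, "positions")
  if (!is.null(dataset$ground_truth))
    h5_write_complex(dataset$ground_truth, path, "ground_truth")
  fid <- rhdf5::H5Fopen(path)
  root <- rhdf5::H5Gopen(fid, "/")
  rhdf5::h5writeAttribute(as.integer(dataset$shape[1]), root, "H")
  rhdf5::h5writeAttribute(as.integer(dataset$shape[2]), root, "W")
  rhdf5::h5writeAttribute(FORMAT_VERSION, root, "format_version")
  rhdf5::h5writeAttribute(
    "positions are 0-based (row, col) top-left footprint corners; complex arrays stored as re/im pairs",
    root, "layout")
  if (!is.null(dataset$spec))
    rhdf5::h5writeAttribute(
      as.character(jsonlite::toJSON(dataset$spec, auto_unbox = TRUE, null = "null")),
      root, "spec")
  rhdf5::H5Gclose(root)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a ptychography dataset from an HDF5 container
#'
#' Validates the format version and member shapes; missing members or
#' inconsistent shapes raise a format error naming the field.
#'
#' @param path file written by [pty_write_dataset()].
#' @return a `pty_dataset`.
#' @export
pty_read_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such dataset file: %s", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  members <- rhdf5::h5ls(path)
  have <- file.path(members$group, members$name)
  have <- sub("^//", "/", have)
  for (need in c("/data", "/probe", "/positions"))
    if (!need %in% have)
      stop(sprintf("dataset file %s is missing required member %s", path, need))
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (is.null(attrs$format_version))
    stop("dataset file has no format_version attribute")
  if (!identical(as.character(attrs$format_version), FORMAT_VERSION))
    stop(sprintf("unsupported dataset format_version '%s' (expected '%s')",
                 attrs$format_version, FORMAT_VERSION))
  data <- rhdf5::h5read(path, "data")
  probe <- h5_read_complex(path, "probe")
  positions <- rhdf5::h5read(path, "positions")
  gt <- if ("/ground_truth" %in% have) h5_read_complex(path, "ground_truth")
  spec <- if (!is.null(attrs$spec)) jsonlite::fromJSON(attrs$spec)
  pty_dataset(data, probe, positions, c(attrs$H, attrs$W),
              ground_truth = gt, spec = spec)
}

#' Write / read a reconstructed object as HDF5
#'
#' Stores the complex object as `/object/{re,im}` with a `format_version`
#' attribute; the companion reader restores it bit-exactly.
#'
#' @param obj complex matrix.
#' @param path file path.
#' @return `path` (write) or the complex matrix (read).
#' @export
pty_write_object <- function(obj, path) {
  obj <- as_complex_matrix(obj)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5_write_complex(obj, path, "object")
  fid <- rhdf5::H5Fopen(path)
  root <- rhdf5::H5Gopen(fid, "/")
  rhdf5::h5writeAttribute(FORMAT_VERSION, root, "format_version")
  rhdf5::H5Gclose(root); rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname pty_write_object
#' @export
pty_read_object <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such object file: %s", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5_read_complex(path, "object")
}

#' Export amplitude and phase images of an object
#'
#' Writes `<prefix>_amplitude.<ext>` (amplitude scaled by its maximum into
#' [0, 1]), `<prefix>_phase.<ext>` (phase wrapped to (-pi, pi], mapped
#' linearly to [0, 1]), and `<prefix>_meta.json` recording the scale factors
#' so the images can be mapped back to physical values. TIFF output is
#' 32-bit float (lossless up to float32 quantization); PNG is 16-bit.
#'
#' @param obj complex matrix with finite entries.
#' @param prefix output path prefix.
#' @param format `"tiff"` or `"png"`.
#' @return named character vector of the written paths, invisibly.
#' @export
pty_export_images <- function(obj, prefix, format = c("tiff", "png")) {
  format <- match.arg(format)
  obj <- as_complex_matrix(obj)
  if (!all(is.finite(Re(obj))) || !all(is.finite(Im(obj))))
    stop("cannot export images: object contains non-finite values")
  amp <- Mod(obj)
  amp_max <- max(amp)
  amp_img <- if (amp_max > 0) amp / amp_max else amp
  phase <- Arg(obj)                      # (-pi, pi]
  phase_img <- (phase + pi) / (2 * pi)
  ext <- if (format == "tiff") "tif" else "png"
  paths <- c(amplitude = sprintf("%s_amplitude.%s", prefix, ext),
             phase = sprintf("%s_phase.%s", prefix, ext),
             meta = sprintf("%s_meta.json", prefix))
  if (format == "tiff") {
    tiff::writeTIFF(amp_img, paths[["amplitude"]], bits.per.sample = 32L)
    tiff::writeTIFF(phase_img, paths[["phase"]], bits.per.sample = 32L)
  } else {
    png::writePNG(amp_img, paths[["amplitude"]], dpi = NULL)
    png::writePNG(phase_img, paths[["phase"]], dpi = NULL)
  }
  jsonlite::write_json(
    list(amplitude_scale = amp_max,
         amplitude_encoding = "pixel = amplitude / amplitude_scale",
         phase_encoding = "pixel = (phase + pi) / (2*pi), phase in (-pi, pi]",
         format = format,
         quantization = if (format == "tiff") "float32" else "uint16"),
    paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write / read a resolved run configuration as YAML
#'
#' Configurations round-trip losslessly so any run can be reproduced from
#' its logged config and seed.
#'
#' @param cfg a [pty_config()] (or plain named list).
#' @param path YAML file path.
#' @return `path` (write) or a `pty_config` (read).
#' @export
pty_write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 17L)
  invisible(path)
}

#' @rdname pty_write_config
#' @export
pty_read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pty_config, vals[names(vals) %in% names(formals(pty_config))])
}
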