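#' Acquisition container I/O
#'
#' The package stores acquisitions in an HDF5 dialect modelled on the
#' data-exchange layout used by tomography beamlines:
#'
#' * `/exchange/data`        — projections, unsigned 16-bit, file shape
#'   `(n, rows, cols)` (C order; R sees the transposed `[rows, cols, n]`)
#' * `/exchange/data_white`  — flat fields, same layout
#' * `/exchange/data_dark`   — dark fields, same layout
#' * `/exchange/theta`       — rotation angles in degrees
#' * `/measurement/*`        — scalar scan metadata (pixel size, energy,
#'   distances, COR offset, tiling layout, free-form keys)
#' * `/provenance/fill_*`    — per-frame fill masks recording which slots of
#'   the pre-sized datasets have been written
#'
#' Frames are stored uncompressed. Angles are stored in degrees and converted
#' to radians only at computation boundaries.
#'
#' @name acquisition-container
NULL

H5_U16 <- "H5T_STD_U16LE"

#' Create an acquisition file skeleton
#'
#' Creates the full structure of an acquisition file — pre-sized (unfilled)
#' projection/flat/dark datasets, the angle vector and fixed metadata —
#' before any image data exist, so that frames can be filled in during and
#' after an acquisition without resizing any dataset.
#'
#' @param path Destination file path.
#' @param geometry A [scan_geometry()].
#' @param n_flats,n_darks Number of flat-field and dark-field frames to
#'   reserve.
#' @param metadata Named list of additional scalar metadata.
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @return An acquisition handle (list with `path` and `geometry`),
#'   invisibly classed `acq_handle`.
#' @export
create_skeleton <- function(path, geometry, n_flats = 1L, n_darks = 1L,
                            metadata = list(), overwrite = FALSE) {
  validate_geometry(geometry)
  stopifnot(n_flats >= 1L, n_darks >= 1L)
  if (file.exists(path)) {
    if (!overwrite) stop("file exists and overwrite = FALSE: ", path)
    unlink(path)
  }
  rhdf5::h5createFile(path)
  for (grp in c("exchange", "measurement", "provenance"))
    rhdf5::h5createGroup(path, grp)
  rows <- geometry$detector_rows; cols <- geometry$detector_cols
  n <- geometry$n_projections
  mk16 <- function(name, k) {
    rhdf5::h5createDataset(path, name, dims = c(rows, cols, k),
                           H5type = H5_U16,
                           chunk = c(rows, cols, 1L), level = 0L)
  }
  mk16("exchange/data", n)
  mk16("exchange/data_white", n_flats)
  mk16("exchange/data_dark", n_darks)
  rhdf5::h5write(geometry$angles_deg, path, "exchange/theta")
  for (nm in c("fill_data", "fill_white", "fill_dark")) {
    k <- switch(nm, fill_data = n, fill_white = n_flats, fill_dark = n_darks)
    rhdf5::h5write(integer(k), path, paste0("provenance/", nm))
  }
  scal <- c(geometry[c("pixel_size_um", "energy_keV",
                       "propagation_distance_mm", "cor_offset_px",
                       "angular_range_deg")],
            list(source_sample_mm =
                   if (is.infinite(geometry$source_sample_mm)) -1
                   else geometry$source_sample_mm,
                 detector_rows = geometry$detector_rows,
                 detector_cols = geometry$detector_cols,
                 n_projections = geometry$n_projections))
  if (!is.null(geometry$tiling)) {
    scal$tiling_n_h <- geometry$tiling$n_h
    scal$tiling_n_v <- geometry$tiling$n_v
    scal$tiling_step_h_px <- geometry$tiling$step_h_px
    scal$tiling_step_v_px <- geometry$tiling$step_v_px
  }
  for (nm in names(scal))
    rhdf5::h5write(scal[[nm]], path, paste0("measurement/", nm))
  if (length(metadata)) {
    rhdf5::h5createGroup(path, "measurement/metadata")
    for (nm in names(metadata))
      rhdf5::h5write(metadata[[nm]], path, paste0("measurement/metadata/", nm))
  }
  rhdf5::h5closeAll()
  invisible(structure(list(path = path, geometry = geometry), class = "acq_handle"))
}

stack_name <- function(what) switch(match.arg(what, c("data", "white", "dark")),
  data = "exchange/data", white = "exchange/data_white",
  dark = "exchange/data_dark")

#' Fill frames into a pre-sized acquisition skeleton
#'
#' Writes 16-bit frames into slots of an existing skeleton. Writing never
#' resizes a dataset; indices outside the pre-declared extent are an error.
#'
#' @param path Acquisition file created by [create_skeleton()].
#' @param frames A `[rows, cols]` matrix or `[rows, cols, k]` array of
#'   integer counts in `[0, 65535]`.
#' @param indices 1-based frame slots to write (length `k`).
#' @param what One of `"data"`, `"white"`, `"dark"`.
#' @return Invisibly, the updated fill mask.
#' @export
fill_frames <- function(path, frames, indices, what = "data") {
  ds <- stack_name(what)
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(length(indices) == dim(frames)[3])
  if (any(frames < 0 | frames > 65535))
    stop("frame values outside unsigned 16-bit range")
  dims <- extract_dims(path, ds)
  if (any(indices < 1L | indices > dims[3]))
    stop("frame index outside pre-declared extent (", dims[3], " slots)")
  storage.mode(frames) <- "integer"
  rhdf5::h5write(frames, path, ds, index = list(NULL, NULL, indices))
  mask_ds <- paste0("provenance/fill_",
                    switch(what, data = "data", white = "white", dark = "dark"))
  mask <- as.integer(rhdf5::h5read(path, mask_ds))
  mask[indices] <- 1L
  rhdf5::h5write(mask, path, mask_ds)
  rhdf5::h5closeAll()
  invisible(mask)
}

extract_dims <- function(path, ds) {
  info <- rhdf5::h5ls(path)
  row <- info[paste0(ifelse(info$group == "/", "/", paste0(info$group, "/")),
                     info$name) == paste0("/", ds), ]
  if (nrow(row) != 1L) stop("dataset not found: ", ds)
  as.integer(strsplit(row$dim, " x ")[[1]])
}

#' Validate skeleton completeness
#'
#' Reports how many frame slots of each stack are still unwritten.
#'
#' @param path Acquisition file.
#' @return Named list with `missing_data`, `missing_white`, `missing_dark`
#'   counts and a logical `complete`.
#' @export
validate_skeleton <- function(path) {
  miss <- vapply(c("data", "white", "dark"), function(w) {
    m <- as.integer(rhdf5::h5read(path, paste0("provenance/fill_", w)))
    sum(m == 0L)
  }, integer(1))
  rhdf5::h5closeAll()
  list(missing_data = miss[["data"]], missing_white = miss[["white"]],
       missing_dark = miss[["dark"]], complete = all(miss == 0L))
}

#' Read an acquisition file
#'
#' @param path Acquisition file in the package dialect (see
#'   [acquisition-container]).
#' @return An `acquisition` object: list with integer stacks `projections`,
#'   `flats`, `darks` (`[rows, cols, n]` arrays), the `scan_geometry`, and a
#'   `metadata` list.
#' @export
read_acquisition <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rd <- function(ds) rhdf5::h5read(path, ds)
  proj <- rd("exchange/data"); storage.mode(proj) <- "integer"
  flats <- rd("exchange/data_white"); storage.mode(flats) <- "integer"
  darks <- rd("exchange/data_dark"); storage.mode(darks) <- "integer"
  theta <- as.numeric(rd("exchange/theta"))
  m <- function(nm) as.numeric(rd(paste0("measurement/", nm)))
  ssd <- m("source_sample_mm"); if (ssd < 0) ssd <- Inf
  tiling <- NULL
  ls_meas <- rhdf5::h5ls(path)
  meas_names <- ls_meas$name[ls_meas$group == "/measurement"]
  if ("tiling_n_h" %in% meas_names) {
    tiling <- list(n_h = as.integer(m("tiling_n_h")),
                   n_v = as.integer(m("tiling_n_v")),
                   step_h_px = m("tiling_step_h_px"),
                   step_v_px = m("tiling_step_v_px"))
  }
  geometry <- scan_geometry(
    n_projections = length(theta), angles_deg = theta,
    detector_rows = dim(proj)[1], detector_cols = dim(proj)[2],
    pixel_size_um = m("pixel_size_um"), energy_keV = m("energy_keV"),
    propagation_distance_mm = m("propagation_distance_mm"),
    source_sample_mm = ssd, cor_offset_px = m("cor_offset_px"),
    tiling = tiling, angular_range_deg = m("angular_range_deg"))
  metadata <- list()
  meta_rows <- ls_meas[ls_meas$group == "/measurement/metadata", "name"]
  for (nm in meta_rows)
    metadata[[nm]] <- rd(paste0("measurement/metadata/", nm))
  rhdf5::h5closeAll()
  acquisition(proj, flats, darks, geometry, metadata)
}

#' Construct an in-memory acquisition dataset
#'
#' @param projections,flats,darks `[rows, cols, n]` integer arrays of 16-bit
#'   counts (matrices are promoted to single-frame stacks).
#' @param geometry A [scan_geometry()].
#' @param metadata Named list.
#' @return An object of class `acquisition`.
#' @export
acquisition <- function(projections, flats, darks, geometry,
                        metadata = list()) {
  as_stack <- function(x) if (length(dim(x)) == 2L)
    array(x, c(dim(x), 1L)) else x
  projections <- as_stack(projections); flats <- as_stack(flats)
  darks <- as_stack(darks)
  stopifnot(all(dim(flats)[1:2] == dim(projections)[1:2]),
            all(dim(darks)[1:2] == dim(projections)[1:2]),
            dim(flats)[3] >= 1L, dim(darks)[3] >= 1L)
  if (dim(projections)[3] != geometry$n_projections)
    stop("projection count does not match geometry")
  structure(list(projections = projections, flats = flats, darks = darks,
                 geometry = geometry, metadata = metadata),
            class = "acquisition")
}

#' Write an acquisition dataset to a container file
#'
#' Convenience wrapper: creates the skeleton and fills every frame.
#'
#' @param acq An `acquisition`.
#' @param path Destination path.
#' @param overwrite Overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_acquisition <- function(acq, path, overwrite = FALSE) {
  stopifnot(inherits(acq, "acquisition"))
  create_skeleton(path, acq$geometry,
                  n_flats = dim(acq$flats)[3], n_darks = dim(acq$darks)[3],
                  metadata = acq$metadata, overwrite = overwrite)
  fill_frames(path, acq$projections, seq_len(dim(acq$projections)[3]), "data")
  fill_frames(path, acq$flats, seq_len(dim(acq$flats)[3]), "white")
  fill_frames(path, acq$darks, seq_len(dim(acq$darks)[3]), "dark")
  invisible(path)
}

#' @export
print.acquisition <- function(x, ...) {
  d <- dim(x$projections)
  cat(sprintf("<acquisition> %d projections of %d x %d, %d flats, %d darks\n",
              d[3], d[1], d[2], dim(x$flats)[3], dim(x$darks)[3]))
  print(x$geometry)
  invisible(x)
}
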