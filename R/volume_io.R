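#' Reconstructed volume container
#'
#' A 32-bit floating-point volume plus its voxel size and a provenance list
#' recording every pipeline stage (with parameters) that produced it.
#' Data are held as an R array indexed `[y, x, z]` (slice row, slice column,
#' slice index).
#'
#' @param data 3-D numeric array (a matrix is promoted to one slice).
#' @param voxel_size_um Isotropic voxel size in micrometres.
#' @param provenance List of stage records; see [reconstruct_pipeline()].
#' @return An object of class `recon_volume`.
#' @export
recon_volume <- function(data, voxel_size_um = 1, provenance = list()) {
  if (length(dim(data)) == 2L) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L, all(dim(data) >= 1L))
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 provenance = provenance), class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<recon_volume> %d x %d x %d float32 voxels @ %g um, %d stage(s)\n",
              d[1], d[2], d[3], x$voxel_size_um, length(x$provenance)))
  invisible(x)
}

VOLUME_FORMATS <- c("hdf5", "tiff_stack", "nifti", "nrrd")

#' Write a reconstructed volume
#'
#' Supported formats: `"hdf5"` (dataset `/exchange/recon` as 32-bit float,
#' voxel size under `/measurement/voxel_size_um`, provenance as YAML text
#' under `/provenance/pipeline`), `"tiff_stack"` (one 32-bit float TIFF per
#' slice, zero-padded numeric suffixes, into a directory), `"nifti"` and
#' `"nrrd"` (both with voxel spacing; NIfTI stores spacing in millimetres).
#'
#' Values are committed to 32-bit float precision on write; a write/read
#' round trip reproduces the data to within a single float32 rounding.
#'
#' @param vol A [recon_volume()].
#' @param path Output file (or directory for `tiff_stack`).
#' @param format One of `"hdf5"`, `"tiff_stack"`, `"nifti"`, `"nrrd"`.
#' @param overwrite Overwrite existing output.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = "hdf5", overwrite = FALSE) {
  stopifnot(inherits(vol, "recon_volume"))
  if (!format %in% VOLUME_FORMATS)
    stop("unsupported format '", format, "'; supported: ",
         paste(VOLUME_FORMATS, collapse = ", "))
  if (file.exists(path) && !overwrite)
    stop("output exists and overwrite = FALSE: ", path)
  switch(format,
    hdf5 = write_volume_hdf5(vol, path),
    tiff_stack = write_volume_tiff_stack(vol, path),
    nifti = write_volume_nifti(vol, path),
    nrrd = write_volume_nrrd(vol, path))
  invisible(path)
}

#' Read a reconstructed volume written by [write_volume()]
#'
#' @param path File or directory produced by [write_volume()].
#' @param format Same options as [write_volume()].
#' @return A [recon_volume()] (provenance restored for hdf5 only).
#' @export
read_volume <- function(path, format = "hdf5") {
  if (!format %in% VOLUME_FORMATS)
    stop("unsupported format '", format, "'; supported: ",
         paste(VOLUME_FORMATS, collapse = ", "))
  switch(format,
    hdf5 = read_volume_hdf5(path),
    tiff_stack = read_volume_tiff_stack(path),
    nifti = read_volume_nifti(path),
    nrrd = read_volume_nrrd(path))
}

as_float32 <- function(x) {
  # round-trip through a raw float32 buffer to realise 32-bit precision
  array(readBin(writeBin(as.numeric(x), raw(), size = 4L),
                numeric(), n = length(x), size = 4L), dim(x))
}

write_volume_hdf5 <- function(vol, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "exchange")
  rhdf5::h5createGroup(path, "measurement")
  rhdf5::h5createGroup(path, "provenance")
  d <- dim(vol$data)
  rhdf5::h5createDataset(path, "exchange/recon", dims = d,
                         H5type = "H5T_IEEE_F32LE",
                         chunk = c(d[1], d[2], 1L), level = 0L)
  rhdf5::h5write(vol$data, path, "exchange/recon")
  rhdf5::h5write(vol$voxel_size_um, path, "measurement/voxel_size_um")
  rhdf5::h5write(yaml::as.yaml(vol$provenance), path, "provenance/pipeline")
  rhdf5::h5closeAll()
}

read_volume_hdf5 <- function(path) {
  data <- rhdf5::h5read(path, "exchange/recon")
  vx <- as.numeric(rhdf5::h5read(path, "measurement/voxel_size_um"))
  prov <- yaml::yaml.load(as.character(rhdf5::h5read(path, "provenance/pipeline")))
  rhdf5::h5closeAll()
  recon_volume(data, vx, if (is.null(prov)) list() else prov)
}

write_volume_tiff_stack <- function(vol, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(vol$data)[3]
  width <- max(4L, nchar(as.character(nz)))
  for (k in seq_len(nz)) {
    f <- file.path(path, sprintf(paste0("slice_%0", width, "d.tif"), k - 1L))
    write_float_tiff(vol$data[, , k], f)
  }
  writeLines(yaml::as.yaml(list(voxel_size_um = vol$voxel_size_um)),
             file.path(path, "spacing.yaml"))
}

read_volume_tiff_stack <- function(path) {
  files <- sort(list.files(path, pattern = "^slice_\\d+\\.tif$",
                           full.names = TRUE))
  if (!length(files)) stop("no slice_*.tif files under ", path)
  slices <- lapply(files, tiff::readTIFF)
  vx <- 1
  sp <- file.path(path, "spacing.yaml")
  if (file.exists(sp)) vx <- yaml::read_yaml(sp)$voxel_size_um
  recon_volume(array(unlist(slices), c(dim(slices[[1]]), length(slices))), vx)
}

# Minimal single-strip little-endian 32-bit float TIFF writer (grayscale,
# SampleFormat = IEEE float). libtiff-based readers (tiff::readTIFF) read it.
write_float_tiff <- function(img, path) {
  stopifnot(is.matrix(img))
  h <- nrow(img); w <- ncol(img)
  pix <- writeBin(as.numeric(t(img)), raw(), size = 4L, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con); wr2(42L); wr4(8L)    # header, IFD at byte 8
  entries <- list(
    # tag, type (3 = SHORT, 4 = LONG), count, value
    c(256L, 4L, 1L, w),            # ImageWidth
    c(257L, 4L, 1L, h),            # ImageLength
    c(258L, 3L, 1L, 32L),          # BitsPerSample
    c(259L, 3L, 1L, 1L),           # Compression: none
    c(262L, 3L, 1L, 1L),           # Photometric: BlackIsZero
    c(273L, 4L, 1L, 0L),           # StripOffsets (patched below)
    c(277L, 3L, 1L, 1L),           # SamplesPerPixel
    c(278L, 4L, 1L, h),            # RowsPerStrip: one strip
    c(279L, 4L, 1L, length(pix)),  # StripByteCounts
    c(339L, 3L, 1L, 3L))           # SampleFormat: IEEE float
  n <- length(entries)
  data_offset <- 8L + 2L + n * 12L + 4L
  entries[[6]][4] <- data_offset
  wr2(n)
  for (e in entries) {
    wr2(e[1]); wr2(e[2]); wr4(e[3])
    if (e[2] == 3L) { wr2(e[4]); wr2(0L) } else wr4(e[4])
  }
  wr4(0L)                                             # no next IFD
  writeBin(pix, con)
}

write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(as_float32(vol$data))
  # NIfTI spacing is conventionally millimetres
  RNifti::pixdim(img) <- rep(vol$voxel_size_um * 1e-3, 3L)
  RNifti::writeNifti(img, path, datatype = "float")
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  recon_volume(array(as.numeric(img), dim(img)),
               voxel_size_um = RNifti::pixdim(img)[1] * 1e3)
}

# Minimal NRRD: text header + raw little-endian float32 payload.
write_volume_nrrd <- function(vol, path) {
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "type: float",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.10g %.10g %.10g", vol$voxel_size_um,
                   vol$voxel_size_um, vol$voxel_size_um),
           "endian: little",
           "encoding: raw",
           "")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
}

read_volume_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || line == "") break
    hdr <- c(hdr, line)
  }
  get <- function(key) sub(paste0("^", key, ": *"), "",
                           grep(paste0("^", key, ":"), hdr, value = TRUE))
  sizes <- as.integer(strsplit(get("sizes"), " +")[[1]])
  spac <- as.numeric(strsplit(get("spacings"), " +")[[1]])
  data <- readBin(con, numeric(), n = prod(sizes), size = 4L,
                  endian = "little")
  recon_volume(array(data, sizes), voxel_size_um = spac[1])
}
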