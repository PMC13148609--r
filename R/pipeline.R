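#' Default pipeline configuration
#'
#' Returns the complete default configuration for
#' [reconstruct_pipeline()]: every stage toggle and parameter of the three
#' sections (raw correction, pre-processing, reconstruction), plus I/O and
#' logging options. See `inst/schema/pipeline-config.yaml` for the full
#' schema with types and permitted values; [validate_config()] checks a
#' user configuration against it and rejects unknown keys.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    input = NULL,
    output = NULL,
    output_format = "hdf5",
    memory_budget_bytes = NULL,
    log_level = "info",
    seed = 1L,
    raw_correction = list(
      flat_dark = TRUE,
      bad_pixel = TRUE,
      bad_pixel_k = 5,
      threshold_median = FALSE,
      threshold_median_threshold = 0.1,
      threshold_median_window = 3L,
      projection_stride = 1L,
      tiling_method = "none"
    ),
    preprocess = list(
      phase_retrieval = FALSE,
      gamma = 100,
      pad_mode = "edge",
      beam_hardening = FALSE,
      c2 = 0,
      bh_domain = "attenuation"
    ),
    reconstruction = list(
      cor_mode = "auto",
      cor_value = NULL,
      rac_sort = FALSE,
      rac_sort_filter_size = 9L,
      rac_large = FALSE,
      rac_large_snr = 3,
      rac_large_filter_size = 21L,
      filter = "ramlak",
      cutoff_frac = 1.0,
      circle_mask = TRUE,
      circle_ratio = 0.98,
      angle_min_deg = NULL,
      angle_max_deg = NULL
    )
  )
}

config_schema <- function() {
  path <- system.file("schema", "pipeline-config.yaml", package = "ctpipe")
  if (path == "") path <- file.path("inst", "schema", "pipeline-config.yaml")
  yaml::read_yaml(path)
}

#' Validate a pipeline configuration
#'
#' Checks `config` against the shipped schema: unknown keys are rejected,
#' types and enumerated values enforced, and cross-key consistency rules
#' applied (`cor_mode = "manual"` requires `cor_value`; `cor_mode = "auto"`
#' with a `cor_value` set is contradictory; correlation tiling requires an
#' overlap). Missing keys take their defaults.
#'
#' @param config Nested list (e.g. from `yaml::read_yaml()`); may be
#'   partial.
#' @return The fully merged configuration, or stop() with a message listing
#'   every violation with its key path.
#' @export
validate_config <- function(config = list()) {
  schema <- config_schema()
  issues <- character()
  check_node <- function(cfg, sch, path) {
    for (key in names(cfg)) {
      if (!key %in% names(sch)) {
        issues <<- c(issues, paste0(path, key, ": unknown key"))
        next
      }
      rule <- sch[[key]]
      val <- cfg[[key]]
      if (identical(rule$type, "section")) {
        if (!is.list(val)) {
          issues <<- c(issues, paste0(path, key, ": must be a mapping"))
        } else {
          check_node(val, rule$keys, paste0(path, key, "."))
        }
        next
      }
      if (is.null(val)) {
        if (!isTRUE(rule$nullable))
          issues <<- c(issues, paste0(path, key, ": may not be null"))
        next
      }
      ok <- switch(rule$type,
        logical = is.logical(val) && length(val) == 1L,
        number = is.numeric(val) && length(val) == 1L,
        integer = is.numeric(val) && length(val) == 1L &&
          val == round(val),
        string = is.character(val) && length(val) == 1L,
        TRUE)
      if (!ok) {
        issues <<- c(issues, paste0(path, key, ": expected ", rule$type))
        next
      }
      if (!is.null(rule$enum) && !val %in% rule$enum)
        issues <<- c(issues, paste0(path, key, ": '", val,
                                    "' not one of ",
                                    paste(rule$enum, collapse = ", ")))
      if (!is.null(rule$min) && is.numeric(val) && val < rule$min)
        issues <<- c(issues, paste0(path, key, ": below minimum ", rule$min))
    }
  }
  check_node(config, schema, "")
  merged <- utils::modifyList(default_config(), config,
                              keep.null = TRUE)
  rc <- merged$reconstruction
  if (identical(rc$cor_mode, "manual") && is.null(rc$cor_value))
    issues <- c(issues,
                "reconstruction.cor_mode: 'manual' requires reconstruction.cor_value")
  if (identical(rc$cor_mode, "auto") && !is.null(rc$cor_value))
    issues <- c(issues, paste0(
      "reconstruction.cor_mode: 'auto' contradicts an explicit ",
      "reconstruction.cor_value; set cor_mode to 'manual' or drop cor_value"))
  if (!is.null(rc$angle_min_deg) != !is.null(rc$angle_max_deg))
    issues <- c(issues, paste0(
      "reconstruction.angle_min_deg/angle_max_deg must be set together"))
  if (length(issues))
    stop("invalid pipeline configuration:\n  ",
         paste(issues, collapse = "\n  "))
  merged
}

#' Pre-flight validation of a configuration against a dataset
#'
#' @param acq An `acquisition`.
#' @param config Merged configuration from [validate_config()].
#' @return `config`, invisibly; stops with a list of issues otherwise.
#' @export
preflight_check <- function(acq, config) {
  issues <- character()
  if (config$raw_correction$tiling_method == "correlation") {
    tl <- acq$geometry$tiling
    if (is.null(tl))
      issues <- c(issues, "correlation tiling requested but dataset not tiled")
    else if (!is.null(tl$overlap_px) && tl$overlap_px < 1)
      issues <- c(issues, "correlation tiling requires >= 1 px overlap")
  }
  rc <- config$reconstruction
  if (!is.null(rc$angle_min_deg)) {
    keep <- acq$geometry$angles_deg >= rc$angle_min_deg &
      acq$geometry$angles_deg <= rc$angle_max_deg
    if (sum(keep) < 2L)
      issues <- c(issues, "limited-angle range keeps fewer than 2 projections")
  }
  if (length(issues))
    stop("pre-flight validation failed:\n  ", paste(issues, collapse = "\n  "))
  invisible(config)
}

# Stages 1 + 2 + negative log + COR; returns list(proj_log, geometry,
# provenance, cor) with proj_log the COR-aligned line-integral stack.
pipeline_front_end <- function(acq, config) {
  prov <- list()
  g <- acq$geometry
  rc <- config$raw_correction
  refs <- reference_images(acq$darks, acq$flats)

  if (rc$flat_dark) {
    proj <- flat_dark_correct(acq$projections, refs)
    prov <- c(prov, list(list(stage = "flat_dark_correct",
                              n_clamped = attr(proj, "n_clamped"))))
  } else {
    proj <- acq$projections * 1.0
  }

  if (rc$bad_pixel && dim(acq$darks)[3] >= 2L && dim(acq$flats)[3] >= 2L) {
    mask <- detect_bad_pixels(acq$darks, acq$flats, k = rc$bad_pixel_k)
    if (any(mask))
      for (k in seq_len(dim(proj)[3]))
        proj[, , k] <- repair_pixels(proj[, , k], mask)
    prov <- c(prov, list(list(stage = "bad_pixel", k = rc$bad_pixel_k,
                              n_flagged = sum(mask))))
  }

  if (rc$threshold_median) {
    for (k in seq_len(dim(proj)[3]))
      proj[, , k] <- threshold_median_filter(
        proj[, , k], rc$threshold_median_threshold,
        rc$threshold_median_window)
    prov <- c(prov, list(list(stage = "threshold_median",
                              threshold = rc$threshold_median_threshold,
                              window = rc$threshold_median_window)))
  }

  angles <- g$angles_deg
  if (rc$projection_stride > 1L) {
    keep <- seq(1L, dim(proj)[3], by = rc$projection_stride)
    proj <- proj[, , keep, drop = FALSE]
    angles <- angles[keep]
    prov <- c(prov, list(list(stage = "trim",
                              projection_stride = rc$projection_stride)))
  }

  pp <- config$preprocess
  if (pp$phase_retrieval) {
    params <- phase_params(gamma = pp$gamma,
                           z_mm = g$propagation_distance_mm,
                           energy_keV = g$energy_keV,
                           pixel_size_um = g$pixel_size_um,
                           pad_mode = pp$pad_mode)
    proj <- phase_retrieve(proj, params)
    prov <- c(prov, list(list(stage = "phase_retrieval", gamma = pp$gamma,
                              z_mm = g$propagation_distance_mm,
                              energy_keV = g$energy_keV)))
  }

  p <- negative_log(proj)
  prov <- c(prov, list(list(stage = "negative_log",
                            n_clamped = attr(p, "n_clamped"))))

  if (pp$beam_hardening) {
    p <- beam_hardening_correct(p, bh_params(pp$c2, pp$bh_domain))
    prov <- c(prov, list(list(stage = "beam_hardening", c2 = pp$c2,
                              domain = pp$bh_domain)))
  }

  rcfg <- config$reconstruction
  if (!is.null(rcfg$angle_min_deg)) {
    keep <- angles >= rcfg$angle_min_deg & angles <= rcfg$angle_max_deg
    p <- p[, , keep, drop = FALSE]
    angles <- angles[keep]
    prov <- c(prov, list(list(stage = "limited_angle",
                              angle_min_deg = rcfg$angle_min_deg,
                              angle_max_deg = rcfg$angle_max_deg,
                              n_kept = sum(keep))))
  }

  cor_offset <- 0
  if (rcfg$cor_mode == "manual") {
    cor_offset <- rcfg$cor_value
  } else if (rcfg$cor_mode == "auto") {
    pair <- which.min(abs((angles - angles[1]) - 180))
    if (abs(angles[pair] - angles[1] - 180) > 5)
      warning("no projection pair separated by ~180 degrees; COR from a ",
              sprintf("%.1f-degree pair", angles[pair] - angles[1]))
    est <- find_cor(p[, , 1], p[, , pair])
    if (!est$usable)
      warning("COR estimate confidence below floor; using it anyway — ",
              "consider tuning the correlation window or manual COR")
    cor_offset <- est$offset_px
  }
  if (cor_offset != 0) p <- apply_cor(p, cor_offset)
  prov <- c(prov, list(list(stage = "cor", mode = rcfg$cor_mode,
                            offset_px = cor_offset)))

  list(proj_log = p, angles = angles, geometry = g, provenance = prov,
       cor_offset = cor_offset)
}

# Reconstruct output slices z0..z1 (detector rows) from the front-end
# product. Deterministic and per-slice independent, so any slab split
# yields bit-identical results.
recon_slab <- function(fe, config, z0, z1) {
  rcfg <- config$reconstruction
  spec <- filter_spec(rcfg$filter, rcfg$cutoff_frac)
  p <- fe$proj_log
  nrow_det <- dim(p)[1]; nc <- dim(p)[2]
  stopifnot(z0 >= 1L, z1 <= nrow_det)
  if (rcfg$rac_sort || rcfg$rac_large) {
    for (r in seq_len(nrow_det)) {
      s <- extract_sinogram(p, fe$angles, r)
      s <- rac_apply(s, rcfg$rac_sort, rcfg$rac_large,
                     rcfg$rac_sort_filter_size, rcfg$rac_large_snr,
                     rcfg$rac_large_filter_size)
      p[r, , ] <- t(s$values)
    }
  }
  g <- fe$geometry
  if (is.infinite(g$source_sample_mm)) {
    out <- array(0, c(nc, nc, z1 - z0 + 1L))
    for (r in z0:z1) {
      s <- sinogram(t(p[r, , ]), fe$angles, r)
      sl <- fbp_slice(s, spec)
      if (rcfg$circle_mask) sl <- circle_mask(sl, rcfg$circle_ratio)
      out[, , r - z0 + 1L] <- sl
    }
    out
  } else {
    geom <- g
    geom$angles_deg <- fe$angles
    geom$n_projections <- length(fe$angles)
    vol <- fdk_volume(p, geom, spec, z_range = c(z0, z1))$data
    if (rcfg$circle_mask) vol <- circle_mask(vol, rcfg$circle_ratio)
    vol
  }
}

#' Run the full processing pipeline
#'
#' Executes the three sections in order — raw correction (dark/flat
#' normalisation, bad-pixel repair, optional threshold median filter,
#' trimming), pre-processing (optional TIE-Hom phase retrieval and
#' beam-hardening correction), then reconstruction (negative log, COR
#' estimation/correction, optional sequential ring-artefact correction,
#' filtered back-projection per detector row — or FDK for a finite source
#' distance — and circle masking). Every enabled stage and its parameters
#' are recorded in the returned volume's provenance.
#'
#' @param acq An `acquisition` (see [read_acquisition()],
#'   [simulate_acquisition()]).
#' @param config Configuration list; merged over [default_config()] and
#'   validated.
#' @return A [recon_volume()] of shape `[cols, cols, rows]`.
#' @export
reconstruct_pipeline <- function(acq, config = list()) {
  stopifnot(inherits(acq, "acquisition"))
  config <- validate_config(config)
  preflight_check(acq, config)
  fe <- pipeline_front_end(acq, config)
  nr <- dim(fe$proj_log)[1]
  vol <- recon_slab(fe, config, 1L, nr)
  prov <- c(fe$provenance,
            list(list(stage = "reconstruct",
                      algorithm = if (is.infinite(acq$geometry$source_sample_mm))
                        "fbp" else "fdk",
                      filter = config$reconstruction$filter,
                      cutoff_frac = config$reconstruction$cutoff_frac,
                      circle_mask = config$reconstruction$circle_mask,
                      circle_ratio = config$reconstruction$circle_ratio,
                      rac_sort = config$reconstruction$rac_sort,
                      rac_large = config$reconstruction$rac_large,
                      n_angles = length(fe$angles))),
            list(list(stage = "config", config = config)))
  recon_volume(vol, voxel_size_um = acq$geometry$pixel_size_um,
               provenance = prov)
}

#' Streaming slab reconstruction
#'
#' Reconstructs the volume in vertical slabs sized to a memory budget and
#' writes each slab to the HDF5 output incrementally, so volumes larger
#' than memory can be produced. Slices are computed exactly as in
#' [reconstruct_pipeline()] (same floating-point path), so the concatenated
#' slab output is bit-identical to the single-pass volume. In streaming
#' mode no secondary (rescaled or binned) output can be produced, because
#' that would require the entire volume in memory; requesting one is
#' refused.
#'
#' @param acq An `acquisition`.
#' @param config Configuration list (as [reconstruct_pipeline()]).
#' @param max_memory_bytes Memory budget for the output slab buffer.
#' @param path Output HDF5 file.
#' @param secondary_output Must be `NULL`; any other value is refused in
#'   streaming mode.
#' @param overwrite Overwrite an existing output file.
#' @return Invisibly, a list with `path`, `n_slabs`, `slab_height`.
#' @export
reconstruct_streaming <- function(acq, config = list(), max_memory_bytes,
                                  path, secondary_output = NULL,
                                  overwrite = FALSE) {
  if (!is.null(secondary_output))
    stop("streaming mode cannot generate a secondary output file: ",
         "rescaling/binning requires the full volume in memory")
  stopifnot(inherits(acq, "acquisition"))
  config <- validate_config(config)
  preflight_check(acq, config)
  fe <- pipeline_front_end(acq, config)
  nr <- dim(fe$proj_log)[1]; nc <- dim(fe$proj_log)[2]
  bytes_per_slice <- nc * nc * 8
  slab_height <- min(nr, floor(max_memory_bytes / bytes_per_slice))
  if (slab_height < 1L)
    stop("max_memory_bytes below the one-slice minimum of ",
         bytes_per_slice, " bytes")
  if (file.exists(path)) {
    if (!overwrite) stop("output exists and overwrite = FALSE: ", path)
    unlink(path)
  }
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "exchange")
  rhdf5::h5createGroup(path, "measurement")
  rhdf5::h5createDataset(path, "exchange/recon", dims = c(nc, nc, nr),
                         H5type = "H5T_IEEE_F32LE",
                         chunk = c(nc, nc, 1L), level = 0L)
  starts <- seq(1L, nr, by = slab_height)
  for (z0 in starts) {
    z1 <- min(z0 + slab_height - 1L, nr)
    slab <- recon_slab(fe, config, z0, z1)
    rhdf5::h5write(slab, path, "exchange/recon",
                   index = list(NULL, NULL, z0:z1))
  }
  rhdf5::h5write(acq$geometry$pixel_size_um, path,
                 "measurement/voxel_size_um")
  rhdf5::h5createGroup(path, "provenance")
  rhdf5::h5write(yaml::as.yaml(c(fe$provenance,
                                 list(list(stage = "streaming",
                                           n_slabs = length(starts),
                                           slab_height = slab_height)))),
                 path, "provenance/pipeline")
  rhdf5::h5closeAll()
  invisible(list(path = path, n_slabs = length(starts),
                 slab_height = slab_height))
}
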