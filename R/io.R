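#' Read a multi-frame TIFF stack
#'
#' Reads a 16-bit integer or 32-bit float multi-frame TIFF into a 3-d
#' array, preserving frame order and pixel values bit-exactly (integer
#' samples are returned as stored, not rescaled to `[0, 1]`).
#'
#' @param path TIFF file path.
#' @return 3-d array `[rows, cols, frames]`.
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop("cannot read movie: ", path)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                     error = function(e)
                       stop("failed to read TIFF '", path, "': ",
                            conditionMessage(e)))
  if (!is.list(frames)) frames <- list(frames)
  fmt <- attr(frames[[1]], "sample.format")
  if (!is.null(fmt) && fmt != "float") {
    # integer samples: reread unscaled so pixel values survive bit-exactly
    frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(frames)) frames <- list(frames)
  }
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f[, , 1] else f
  })
  d <- dim(frames[[1]])
  out <- array(0, dim = c(d[1], d[2], length(frames)))
  for (i in seq_along(frames)) {
    if (!all(dim(frames[[i]]) == d))
      stop("inconsistent frame dimensions in '", path, "'")
    out[, , i] <- frames[[i]]
  }
  out
}

#' Write a multi-frame TIFF stack
#'
#' Writes frames as 32-bit IEEE-float samples (uncompressed, little-endian,
#' one strip per frame) so concentrations and angle maps of any range
#' round-trip without quantization. The installed TIFF writers only emit
#' integer sample formats, so the (baseline) float TIFF structure is
#' assembled directly; the result is readable by any standard TIFF reader,
#' including [read_movie()].
#'
#' @param stack Matrix or 3-d array `[rows, cols, frames]`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_movie <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nt <- dim(stack)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wb(c(73L, 73L), 1L)          # "II": little-endian byte order
  wb(42L, 2L)                  # TIFF magic
  data_bytes <- 4L * nr * nc
  n_entries <- 10L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  frame_bytes <- data_bytes + ifd_bytes
  wb(8L + data_bytes, 4L)      # offset of the first IFD
  entry <- function(tag, type, value) {  # type 3 = SHORT, 4 = LONG
    wb(as.integer(tag), 2L)
    wb(as.integer(type), 2L)
    wb(1L, 4L)
    if (type == 3L) { wb(as.integer(value), 2L); wb(0L, 2L) }
    else wb(as.integer(value), 4L)
  }
  for (i in seq_len(nt)) {
    off <- 8L + (i - 1L) * frame_bytes
    # samples in TIFF row order
    wb(as.vector(t(stack[, , i])), 4L)
    wb(n_entries, 2L)
    entry(256, 4, nc)          # ImageWidth
    entry(257, 4, nr)          # ImageLength
    entry(258, 3, 32)          # BitsPerSample
    entry(259, 3, 1)           # Compression: none
    entry(262, 3, 1)           # Photometric: black is zero
    entry(273, 4, off)         # StripOffsets
    entry(277, 3, 1)           # SamplesPerPixel
    entry(278, 4, nr)          # RowsPerStrip
    entry(279, 4, data_bytes)  # StripByteCounts
    entry(339, 3, 3)           # SampleFormat: IEEE float
    wb(if (i < nt) off + frame_bytes + data_bytes else 0L, 4L)
  }
  invisible(path)
}

#' Export a simulation to disk
#'
#' Writes one 32-bit float TIFF stack per stored field plus the audit table
#' (time, total mass, per-field min/max) as CSV, and a provenance record.
#'
#' @param sim An `rd_sim` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "rd_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in c("A", "I", "F"))
    if (!is.null(sim[[f]]))
      write_movie(sim[[f]], file.path(dir, paste0(f, ".tif")))
  utils::write.csv(sim$audit, file.path(dir, "audit.csv"),
                   row.names = FALSE)
  write_movie(sim$grid$mask * 1, file.path(dir, "mask.tif"))
  write_provenance(dir, list(params = unclass(sim$params),
                             grid = list(h = sim$grid$h, dt = sim$grid$dt,
                                         save_every = sim$grid$save_every,
                                         mask_dim = dim(sim$grid$mask)),
                             seed = sim$seed))
  invisible(dir)
}

#' Write a provenance record
#'
#' JSON echo of the configuration, seed and package version next to the
#' outputs of a run.
#'
#' @param dir Output directory.
#' @param config Named list to echo.
#' @return Invisibly, the file path.
#' @export
write_provenance <- function(dir, config) {
  rec <- list(package = "cortexwaves",
              version = as.character(utils::packageVersion("cortexwaves")),
              written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              config = config)
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

config_defaults <- function() {
  list(model = unclass(model_params()),
       grid = list(mask_kind = "square", mask_size = 202, h = 0.02,
                   dt = 0.001, save_every = 1000),
       scaling = unclass(scaling_factors()),
       wavefield = unclass(wave_params()),
       domains = unclass(domain_params())[c("C_cr", "theta_m", "l_cr",
                                            "r_max", "std_cap")],
       init = "homogeneous",
       duration = 4000,
       seed = 1)
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration; unspecified fields take the
#' reference defaults, unknown keys are rejected, and every
#' parameter is validated through its constructor (a negative rate, for
#' example, raises an error naming the field).
#'
#' @param path Configuration file.
#' @return List of class `run_config` with elements `model` (`cw_params`),
#'   `grid` (`cw_grid`), `scaling`, `wavefield`, `domains`, `init`,
#'   `duration`, `seed`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defs <- config_defaults()
  bad <- setdiff(names(raw), names(defs))
  if (length(bad) > 0)
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  for (sec in c("model", "grid", "scaling", "wavefield", "domains")) {
    extra <- setdiff(names(raw[[sec]]), names(defs[[sec]]))
    if (length(extra) > 0)
      stop("unknown key(s) in '", sec, "': ", paste(extra, collapse = ", "))
  }
  merged <- modifyList(defs, raw)
  mask <- make_mask(merged$grid$mask_kind, merged$grid$mask_size)
  structure(list(
    model = do.call(model_params, merged$model),
    grid = grid_spec(mask, h = merged$grid$h, dt = merged$grid$dt,
                     save_every = merged$grid$save_every),
    scaling = do.call(scaling_factors, merged$scaling),
    wavefield = do.call(wave_params, merged$wavefield),
    domains = do.call(domain_params, merged$domains),
    init = merged$init,
    duration = merged$duration,
    seed = merged$seed), class = "run_config")
}

#' Save a run configuration
#'
#' @param config A `run_config` object (or plain nested list).
#' @param path Output YAML path.
#' @return Invisibly, the path.
#' @export
save_config <- function(config, path) {
  if (inherits(config, "run_config")) {
    config <- list(model = unclass(config$model),
                   grid = list(mask_kind = "square",
                               mask_size = nrow(config$grid$mask),
                               h = config$grid$h, dt = config$grid$dt,
                               save_every = config$grid$save_every),
                   scaling = unclass(config$scaling),
                   wavefield = unclass(config$wavefield),
                   domains = unclass(config$domains)[c("C_cr", "theta_m",
                                                       "l_cr", "r_max",
                                                       "std_cap")],
                   init = config$init,
                   duration = config$duration,
                   seed = config$seed)
  }
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}
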