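# Minimal NIfTI-1 single-file (.nii) reader/writer, float64 data, sform
# affine. Written against the published 348-byte header layout; no R NIfTI
# package is assumed. Supports 3D volumes and 4D volumes with echo (or any
# series) as the 4th dimension, plus a JSON sidecar declaring the echo
# dialect and acquisition metadata.

#' Write a volume as NIfTI-1
#'
#' Writes uncompressed single-file NIfTI-1 (magic `n+1`, float64), with the
#' affine stored in the sform (`sform_code = 2`) and a free-text
#' description. A JSON sidecar (same path, `.json`) records the dialect
#' (`"4d"` or `"per-echo"`), units and any extra metadata.
#'
#' @param data 3D or 4D numeric array (NA written as NaN).
#' @param path output path ending in `.nii`.
#' @param voxel_size isotropic voxel size (mm) or length-3 vector.
#' @param origin physical coordinate of the center of voxel `[1,1,1]`.
#' @param description up to 79 characters stored in the header.
#' @param sidecar named list written as JSON sidecar (`NULL` for none).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size = 1, origin = c(0, 0, 0),
                        description = "", sidecar = NULL) {
  dm <- dim(data)
  stopifnot(length(dm) %in% c(3, 4))
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  ndim <- length(dm)
  dim_field <- rep(1L, 8)
  dim_field[1] <- ndim
  dim_field[seq_len(ndim) + 1] <- dm
  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wC <- function(s, n) {
    raw <- charToRaw(s)
    if (length(raw) > n) raw <- raw[seq_len(n)]
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wI(348, 4)                       # sizeof_hdr
  wC("", 10); wC("", 18)           # data_type, db_name (unused)
  wI(0, 4); wI(0, 2); wC("", 1); wC("r", 1) # extents, session_error, regular, dim_info
  wI(dim_field, 2)                 # dim[8]
  wF(c(0, 0, 0))                   # intent_p1..p3
  wI(0, 2)                         # intent_code
  wI(64, 2)                        # datatype: float64
  wI(64, 2)                        # bitpix
  wI(0, 2)                         # slice_start
  wF(c(1, voxel_size, 1, 1, 1, 1)[1:8]) # pixdim[8] (qfac = 1)
  wF(352)                          # vox_offset
  wF(1); wF(0)                     # scl_slope, scl_inter
  wI(0, 2); wC("", 1); wC("", 1)   # slice_end, slice_code, xyzt_units
  wF(0); wF(0)                     # cal_max, cal_min
  wF(0); wI(0, 4); wI(0, 4)        # slice_duration, toffset, glmax
  wI(0, 4)                         # glmin
  wC(description, 80)
  wC("", 24)                       # aux_file
  wI(0, 2); wI(2, 2)               # qform_code = 0, sform_code = 2
  wF(rep(0, 6))                    # quaternions b,c,d + qoffsets x,y,z
  wF(c(voxel_size[1], 0, 0, origin[1]))   # srow_x
  wF(c(0, voxel_size[2], 0, origin[2]))   # srow_y
  wF(c(0, 0, voxel_size[3], origin[3]))   # srow_z
  wC("", 16)                       # intent_name
  wC("n+1", 4)                     # magic (nul-padded)
  writeBin(as.raw(c(0, 0, 0, 0)), con) # extension flag
  writeBin(as.numeric(data), con, size = 8, endian = "little")
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, sub("\\.nii$", ".json", path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package (or any conformant
#' single-file float/int NIfTI-1)
#'
#' @param path `.nii` file path.
#' @return list `data` (array), `voxel_size`, `origin`, `affine` (4x4),
#'   `description`, `sidecar` (parsed JSON list or `NULL`).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 352) stop("not a NIfTI-1 file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rI <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rF <- function(n) readBin(con, "numeric", n = n, size = 4,
                            endian = "little")
  hdr_len <- rI(1, 4)
  if (!identical(hdr_len, 348L)) stop("malformed NIfTI header in ", path)
  invisible(readBin(con, "raw", n = 36))
  dim_field <- rI(8, 2)
  invisible(rF(3)); invisible(rI(1, 2))
  datatype <- rI(1, 2)
  bitpix <- rI(1, 2)
  invisible(rI(1, 2))
  pixdim <- rF(8)
  vox_offset <- rF(1)
  scl_slope <- rF(1); scl_inter <- rF(1)
  invisible(readBin(con, "raw", n = 2 + 1 + 1))
  invisible(rF(2)); invisible(rF(1)); invisible(rI(2, 4)); invisible(rI(1, 4))
  description <- rawToChar(readBin(con, "raw", n = 80))
  description <- sub("\\x00.*$", "", description)
  invisible(readBin(con, "raw", n = 24))
  invisible(rI(1, 2)); sform_code <- rI(1, 2)
  invisible(rF(6))
  srow <- matrix(rF(12), 3, 4, byrow = TRUE)
  invisible(readBin(con, "raw", n = 16))
  magic <- rawToChar(readBin(con, "raw", n = 4))
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1"))
    stop("malformed NIfTI magic in ", path)
  ndim <- dim_field[1]
  if (ndim < 1 || ndim > 7) stop("malformed NIfTI dim field in ", path)
  dm <- dim_field[seq_len(ndim) + 1]
  n <- prod(dm)
  seek(con, where = vox_offset, origin = "start")
  data <- switch(as.character(datatype),
                 "2" = readBin(con, "integer", n = n, size = 1, signed = FALSE),
                 "4" = readBin(con, "integer", n = n, size = 2,
                               endian = "little"),
                 "8" = readBin(con, "integer", n = n, size = 4,
                               endian = "little"),
                 "16" = readBin(con, "numeric", n = n, size = 4,
                                endian = "little"),
                 "64" = readBin(con, "numeric", n = n, size = 8,
                                endian = "little"),
                 stop("unsupported NIfTI datatype ", datatype, " in ", path))
  if (length(data) < n) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  affine <- rbind(srow, c(0, 0, 0, 1))
  voxel_size <- pixdim[2:4]
  origin <- if (sform_code > 0) srow[, 4] else c(0, 0, 0)
  sidecar_path <- sub("\\.nii$", ".json", path)
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  list(data = array(data, dm), voxel_size = voxel_size, origin = origin,
       affine = affine, description = description, sidecar = sidecar)
}

#' Write a weighted volume set to a directory
#'
#' One NIfTI per weighting. Dialect `"4d"` stores the echo train as the
#' 4th dimension of a single file per weighting; `"per-echo"` writes one 3D
#' file per echo (`<w>_echo-<i>.nii`). A sidecar declares the dialect, TE
#' list, TR, flip angle and MT-pulse flag.
#'
#' @param volumes a `weighted_volumes`.
#' @param dir output directory (created if needed).
#' @param dialect `"4d"` or `"per-echo"`.
#' @return character vector of files written.
#' @export
write_weighted_volumes <- function(volumes, dir, dialect = c("4d", "per-echo")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- volumes$grid_meta
  files <- character(0)
  for (w in names(volumes$signals)) {
    ww <- volumes$protocol$weightings[[w]]
    side <- list(dialect = dialect, weighting = w, TE_ms = ww$TE,
                 TR_ms = ww$TR, flip_deg = ww$flip_deg,
                 mt_pulse = ww$mt_pulse,
                 cohort_id = volumes$protocol$cohort_id,
                 noise_sd = volumes$noise_sd, seed = volumes$seed)
    if (dialect == "4d") {
      f <- file.path(dir, paste0(w, ".nii"))
      write_nifti(volumes$signals[[w]], f, meta$voxel_size, meta$origin,
                  description = paste0(w, " multi-echo FLASH (a.u.)"),
                  sidecar = side)
      files <- c(files, f)
    } else {
      nte <- dim(volumes$signals[[w]])[4]
      for (i in seq_len(nte)) {
        f <- file.path(dir, sprintf("%s_echo-%d.nii", w, i))
        write_nifti(volumes$signals[[w]][, , , i], f, meta$voxel_size,
                    meta$origin,
                    description = sprintf("%s echo %d TE %.2f ms", w, i,
                                          ww$TE[i]),
                    sidecar = if (i == 1) side else NULL)
        files <- c(files, f)
      }
    }
  }
  for (nm in c("f_T", "g_R")) {
    f <- file.path(dir, paste0(nm, ".nii"))
    write_nifti(volumes$fields[[nm]], f, meta$voxel_size, meta$origin,
                description = paste(nm, "field (dimensionless)"))
    files <- c(files, f)
  }
  f <- file.path(dir, "tissue.nii")
  write_nifti(volumes$tissue + 0, f, meta$voxel_size, meta$origin,
              description = "tissue labels 0=bg 1=WM 2=GM 3=CSF")
  c(files, f)
}

#' Read a weighted volume set written by [write_weighted_volumes()]
#'
#' Both dialects load to an identical in-memory representation.
#'
#' @param dir directory containing the volumes.
#' @param protocol optional `mpm_protocol`; reconstructed from the sidecars
#'   when `NULL`.
#' @return a `weighted_volumes` object.
#' @export
read_weighted_volumes <- function(dir, protocol = NULL) {
  wts <- c("PDw", "T1w", "MTw")
  signals <- list()
  sides <- list()
  meta <- NULL
  for (w in wts) {
    f4 <- file.path(dir, paste0(w, ".nii"))
    if (file.exists(f4)) {
      nii <- read_nifti(f4)
      signals[[w]] <- nii$data
      sides[[w]] <- nii$sidecar
    } else {
      fs <- sort(list.files(dir, sprintf("^%s_echo-\\d+\\.nii$", w),
                            full.names = TRUE))
      fs <- fs[order(as.integer(sub(".*_echo-(\\d+)\\.nii$", "\\1", fs)))]
      if (!length(fs)) stop("no volumes for weighting ", w, " in ", dir)
      vols <- lapply(fs, read_nifti)
      dm <- dim(vols[[1]]$data)
      signals[[w]] <- array(unlist(lapply(vols, `[[`, "data")),
                            c(dm, length(vols)))
      sides[[w]] <- vols[[1]]$sidecar
      nii <- vols[[1]]
    }
    if (is.null(meta))
      meta <- list(dim = dim(signals[[w]])[1:3], origin = nii$origin,
                   voxel_size = nii$voxel_size[1])
  }
  if (is.null(protocol)) {
    wspec <- lapply(wts, function(w) {
      s <- sides[[w]]
      if (is.null(s)) stop("missing sidecar metadata for ", w)
      list(flip_deg = s$flip_deg, TR = s$TR_ms, TE = as.numeric(s$TE_ms),
           mt_pulse = isTRUE(s$mt_pulse))
    })
    names(wspec) <- wts
    protocol <- new_mpm_protocol(wspec, sides[[1]]$cohort_id %||% 1L)
  }
  fields <- list(
    f_T = if (file.exists(file.path(dir, "f_T.nii")))
      read_nifti(file.path(dir, "f_T.nii"))$data else array(1, meta$dim),
    g_R = if (file.exists(file.path(dir, "g_R.nii")))
      read_nifti(file.path(dir, "g_R.nii"))$data else array(1, meta$dim))
  tissue <- if (file.exists(file.path(dir, "tissue.nii")))
    array(as.integer(read_nifti(file.path(dir, "tissue.nii"))$data),
          meta$dim)
  else array(2L, meta$dim)
  structure(list(signals = signals, protocol = protocol, fields = fields,
                 tissue = tissue, grid_meta = meta,
                 noise_sd = sides[[1]]$noise_sd %||% NA_real_,
                 forward_model = "unknown", noise_model = "unknown",
                 seed = sides[[1]]$seed %||% NA_integer_),
            class = "weighted_volumes")
}

#' Write parameter maps as NIfTI with units in the header
#'
#' @param maps a `parameter_maps`.
#' @param dir output directory.
#' @return files written.
#' @export
write_parameter_maps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  units <- c(R1 = "1/s", R2star = "1/s", MTsat = "pu", PDstar = "pu",
             A = "a.u.")
  files <- character(0)
  for (p in names(units)) {
    f <- file.path(dir, paste0(p, ".nii"))
    write_nifti(maps[[p]], f, maps$grid_meta$voxel_size,
                maps$grid_meta$origin,
                description = paste0(p, " [", units[[p]], "]"),
                sidecar = list(parameter = p, units = units[[p]]))
    files <- c(files, f)
  }
  f <- file.path(dir, "valid.nii")
  write_nifti(maps$valid + 0, f, maps$grid_meta$voxel_size,
              maps$grid_meta$origin, description = "validity mask")
  c(files, f)
}
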