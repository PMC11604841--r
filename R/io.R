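#' Minimal NIfTI-1 volume I/O
#'
#' Reads and writes single-file NIfTI-1 (`.nii` / `.nii.gz`) volumes: 3D or
#' 4D arrays, float32/float64/int16/uint8 on read, float32 (or float64) on
#' write, with the voxel size recorded in `pixdim` and a diagonal sform
#' matching the package axis convention (x right-to-left, y
#' anterior-to-posterior, z inferior-to-superior).  No R NIfTI package is
#' available in this toolchain, so the 348-byte header is handled directly;
#' round-trips are covered by tests (and were checked against nibabel).
#'
#' @param vol 3D/4D numeric or logical array.
#' @param path output path; `.gz` suffix selects gzip compression.
#' @param voxel_size_mm voxel size (scalar or length-3).
#' @param datatype `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, voxel_size_mm = 1,
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  dm <- dim(vol)
  stopifnot(length(dm) %in% c(3, 4))
  vs <- rep(voxel_size_mm, length.out = 3)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size = 4) writeBin(as.integer(x), con, size = size,
                                       endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348)                                   # sizeof_hdr
  writeBin(raw(36), con)                    # unused
  wi(c(length(dm), dm, rep(1, 7 - length(dm))), size = 2)  # dim[8]
  wf(c(0, 0, 0))                            # intent_p1..p3
  wi(0, 2)                                  # intent_code
  wi(if (datatype == "float32") 16 else 64, 2)  # datatype
  wi(if (datatype == "float32") 32 else 64, 2)  # bitpix
  wi(0, 2)                                  # slice_start
  wf(c(1, vs, rep(1, 4)))                   # pixdim[8]
  wf(352)                                   # vox_offset
  wf(c(1, 0))                               # scl_slope, scl_inter
  wi(0, 2); writeBin(raw(1), con); writeBin(raw(1), con)  # slice_end..xyzt
  wf(c(0, 0, 0))                            # cal_max, cal_min, slice_dur
  wf(0)                                     # toffset
  wi(c(0, 0))                               # glmax, glmin
  writeBin(charToRaw(formatC("", width = 80)), con)   # descrip
  writeBin(charToRaw(formatC("", width = 24)), con)   # aux_file
  wi(c(1, 1), 2)                            # qform_code, sform_code
  wf(rep(0, 6))                             # quatern b,c,d + offsets x,y,z
  wf(c(vs[1], 0, 0, 0))                     # srow_x
  wf(c(0, vs[2], 0, 0))                     # srow_y
  wf(c(0, 0, vs[3], 0))                     # srow_z
  writeBin(charToRaw(formatC("", width = 16)), con)   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)       # magic
  writeBin(raw(4), con)                     # extension flag
  writeBin(as.numeric(vol), con, size = if (datatype == "float32") 4 else 8,
           endian = "little")
  invisible(path)
}

#' @rdname write_nifti
#' @return `read_nifti()`: the array, with attributes `voxel_size_mm`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size = 4) readBin(con, "integer", n, size = size,
                                      endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  hdr_size <- ri(1)
  if (hdr_size != 348) stop("not a NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", 36))
  dm8 <- ri(8, 2)
  nd <- dm8[1]
  dm <- dm8[2:(1 + nd)]
  rf(3); ri(1, 2)
  dtype <- ri(1, 2); ri(1, 2); ri(1, 2)
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl <- rf(2)
  invisible(readBin(con, "raw", 348 - 120 + 4))   # rest of header + ext
  nv <- prod(dm)
  data <- switch(as.character(dtype),
                 "2" = as.numeric(readBin(con, "integer", nv, 1,
                                          signed = FALSE)),
                 "4" = as.numeric(readBin(con, "integer", nv, 2,
                                          endian = "little")),
                 "8" = as.numeric(ri(nv)),
                 "16" = rf(nv),
                 "64" = readBin(con, "numeric", nv, 8, endian = "little"),
                 stop("unsupported NIfTI datatype ", dtype))
  if (!is.na(scl[1]) && scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    data <- data * scl[1] + scl[2]
  out <- array(data, dm)
  attr(out, "voxel_size_mm") <- pixdim[2:4]
  out
}

#' Persist / load a radial acquisition
#'
#' Uses HDF5 (`rhdf5`) when available, with datasets `/kdata_re`,
#' `/kdata_im`, `/traj/directions`, `/traj/radii`, `/time`, `/coilmaps_re`,
#' `/coilmaps_im` and a `/meta` attribute group; otherwise falls back to an
#' RDS file with the same contents (same extension, detected on read).
#'
#' @param acq a `radial_acquisition`.
#' @param path output file path (`.h5`).
#' @return `path`, invisibly.
#' @export
write_acquisition <- function(acq, path) {
  if (requireNamespace("rhdf5", quietly = TRUE)) {
    if (file.exists(path)) unlink(path)
    h5q <- function(expr) suppressMessages(invisible(expr))
    rhdf5::h5createFile(path)
    h5q(rhdf5::h5write(Re(acq$kdata), path, "kdata_re"))
    h5q(rhdf5::h5write(Im(acq$kdata), path, "kdata_im"))
    rhdf5::h5write(acq$traj$directions, path, "traj_directions")
    rhdf5::h5write(acq$traj$radii, path, "traj_radii")
    rhdf5::h5write(acq$traj$ramp_fraction, path, "traj_ramp_fraction")
    rhdf5::h5write(acq$timestamp_s, path, "time")
    rhdf5::h5write(Re(acq$coil_maps), path, "coilmaps_re")
    rhdf5::h5write(Im(acq$coil_maps), path, "coilmaps_im")
    rhdf5::h5write(as.integer(acq$meta$grid_shape), path, "meta_grid_shape")
    rhdf5::h5write(acq$meta$voxel_size_mm, path, "meta_voxel_size_mm")
    rhdf5::h5write(acq$meta$seed, path, "meta_seed")
    rhdf5::h5write(acq$meta$TR_s, path, "meta_TR_s")
    if (!is.null(acq$truth))
      rhdf5::h5write(acq$truth$phase_of_spoke, path, "truth_phase_of_spoke")
    rhdf5::h5closeAll()
  } else {
    saveRDS(acq, path)
  }
  invisible(path)
}

#' @rdname write_acquisition
#' @export
read_acquisition <- function(path) {
  is_h5 <- requireNamespace("rhdf5", quietly = TRUE) &&
    tryCatch(rhdf5::H5Fis_hdf5(path), error = function(e) FALSE)
  if (!is_h5) return(readRDS(path))
  g <- function(n) rhdf5::h5read(path, n)
  kdata <- g("kdata_re") + 1i * g("kdata_im")
  dirs <- g("traj_directions")
  radii <- as.numeric(g("traj_radii"))
  traj <- structure(list(directions = dirs, radii = radii,
                         ramp_fraction = as.numeric(g("traj_ramp_fraction")),
                         dcf = density_compensation(radii),
                         n_spokes = nrow(dirs),
                         n_readout = length(radii)),
                    class = "radial_trajectory")
  truth_phase <- tryCatch(as.numeric(g("truth_phase_of_spoke")),
                          error = function(e) NULL)
  out <- structure(list(
    kdata = kdata, traj = traj, timestamp_s = as.numeric(g("time")),
    coil_maps = g("coilmaps_re") + 1i * g("coilmaps_im"),
    meta = list(grid_shape = as.integer(g("meta_grid_shape")),
                voxel_size_mm = as.numeric(g("meta_voxel_size_mm")),
                seed = as.integer(g("meta_seed")),
                TR_s = as.numeric(g("meta_TR_s")),
                n_spokes = nrow(dirs)),
    truth = if (!is.null(truth_phase)) list(phase_of_spoke = truth_phase)),
    class = "radial_acquisition")
  rhdf5::h5closeAll()
  out
}
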