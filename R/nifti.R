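# Minimal single-file NIfTI-1 (.nii, uncompressed) I/O.
#
# No NIfTI-capable R package is available in this stack, so the fixed
# 348-byte NIfTI-1 header is read and written directly. Scope: 3D/4D
# float32 (datatype 16) and uint8 (datatype 2) images with an RAS
# diagonal affine built from the isotropic voxel size. That is all the
# toolkit's masks, runs and component maps need.

#' Write a 3D/4D array as an uncompressed NIfTI-1 file
#'
#' @param arr numeric or logical array with 3 or 4 dimensions.
#' @param path output file path (`.nii`).
#' @param voxel_size_mm isotropic voxel edge in mm (pixdim).
#' @param tr_s time step in seconds stored in `pixdim[4]` for 4D images.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(arr, path, voxel_size_mm = 2, tr_s = 1.2) {
  stopifnot(is.array(arr), length(dim(arr)) %in% c(3L, 4L))
  is_mask <- is.logical(arr)
  dims <- dim(arr)
  ndim <- length(dims)
  dim_field <- rep(1L, 8)
  dim_field[1] <- ndim
  dim_field[seq_len(ndim) + 1] <- dims

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wpad <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                      # sizeof_hdr
  wpad(35)                         # data_type[10], db_name[18], extents, session_error, regular
  writeBin(as.raw(0L), con)        # dim_info
  wi(dim_field, 2)                 # dim[8]
  wf(c(0, 0, 0))                   # intent_p1..p3
  wi(0L, 2)                        # intent_code
  wi(if (is_mask) 2L else 16L, 2)  # datatype: uint8 / float32
  wi(if (is_mask) 8L else 32L, 2)  # bitpix
  wi(0L, 2)                        # slice_start
  wf(c(0, rep(voxel_size_mm, 3), tr_s, 0, 0, 0))  # pixdim[8]
  wf(352)                          # vox_offset
  wf(c(1, 0))                      # scl_slope, scl_inter
  wi(0L, 2)                        # slice_end
  writeBin(as.raw(c(0L, 0L)), con) # slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wpad(80 + 24)                    # descrip, aux_file
  wi(c(0L, 1L), 2)                 # qform_code 0, sform_code 1
  wf(rep(0, 6))                    # quatern_b/c/d, qoffset_x/y/z
  wf(c(voxel_size_mm, 0, 0, 0))    # srow_x
  wf(c(0, voxel_size_mm, 0, 0))    # srow_y
  wf(c(0, 0, voxel_size_mm, 0))    # srow_z
  wpad(16)                         # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(as.raw(0L), con)
  wpad(4)                          # extension flag

  if (is_mask) {
    writeBin(as.integer(arr), con, size = 1, endian = "little")
  } else {
    writeBin(as.numeric(arr), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file written at this scope
#'
#' @param path `.nii` file path.
#' @return list with `data` (array), `voxel_size_mm`, `tr_s`, `datatype`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")

  sizeof <- ri(1, 4)
  if (!identical(sizeof, 348L)) stop_npda("not a NIfTI-1 file", "npda_io_error")
  invisible(readBin(con, "raw", n = 36))           # through dim_info
  dim_field <- ri(8, 2)
  invisible(rf(3)); invisible(ri(1, 2))            # intent
  datatype <- ri(1, 2)
  invisible(ri(1, 2)); invisible(ri(1, 2))         # bitpix, slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  invisible(readBin(con, "raw", n = 352 - 112))    # rest of header + ext
  ndim <- dim_field[1]
  dims <- dim_field[2:(1 + ndim)]
  n <- prod(dims)
  seek(con, where = vox_offset, origin = "start")
  data <- switch(
    as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE,
                             endian = "little")),
    "16" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    stop_npda(paste("unsupported NIfTI datatype", datatype), "npda_io_error")
  )
  list(
    data = array(data, dim = dims),
    voxel_size_mm = pixdim[2],
    tr_s = pixdim[5],
    datatype = datatype
  )
}

#' Write a run, its motion trace and ground truth to a directory
#'
#' The 4D series goes to `<stem>.nii`, motion to `<stem>_motion.tsv`
#' (columns trans_x..rot_z, one row per volume), ground-truth latents (if
#' present) to `<stem>_truth.tsv`.
#'
#' @param run an `npda_run`.
#' @param dir output directory (created if needed).
#' @param stem file stem.
#' @return named list of written paths, invisibly.
#' @export
write_run <- function(run, dir, stem = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nii <- file.path(dir, paste0(stem, ".nii"))
  write_nifti(run$data, nii, voxel_size_mm = run$voxel_size_mm,
              tr_s = run$params$tr_ms / 1000)
  mot <- file.path(dir, paste0(stem, "_motion.tsv"))
  utils::write.table(
    run$motion[, c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")],
    mot, sep = "\t", quote = FALSE, row.names = FALSE
  )
  paths <- list(nifti = nii, motion = mot)
  if (!is.null(run$ground_truth)) {
    gt <- file.path(dir, paste0(stem, "_truth.tsv"))
    utils::write.table(run$ground_truth, gt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$truth <- gt
  }
  invisible(paths)
}

#' Write a network mask as binary NIfTI
#'
#' @param mask an `npda_mask`.
#' @param path output `.nii` path.
#' @param voxel_size_mm voxel edge in mm.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, voxel_size_mm = 2) {
  write_nifti(mask$voxels, path, voxel_size_mm = voxel_size_mm)
}
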