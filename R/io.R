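# Minimal NRRD and NIfTI-1 volume I/O.
#
# No NRRD/NIfTI reader is available in the dependency set, so the two
# formats are implemented here directly: enough of each standard to
# round-trip a 3D scalar volume with voxel-spacing metadata exactly.
# Spacing is never silently assumed: a file without spacing metadata is an
# error on read.

.nrrd_write <- function(arr, spacing, path, type = c("double", "uint8")) {
  type <- match.arg(type)
  d <- as_dim3(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.17g %.17g %.17g", spacing[1], spacing[2], spacing[3]),
    "encoding: raw",
    "endian: little",
    ""
  )
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (type == "uint8") {
    writeBin(as.raw(as.integer(arr != 0)), con)
  } else {
    writeBin(as.numeric(arr), con, size = 8, endian = "little")
  }
  invisible(path)
}

.nrrd_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !nzchar(line)) break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3D NRRD volumes are supported")
  spacing <- NULL
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- sapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
    spacing <- sqrt(colSums(m^2))
  }
  if (is.null(spacing) || length(spacing) != 3 || any(!is.finite(spacing)))
    stop("NRRD file has no spacing metadata ('spacings' or 'space directions'): ",
         path)
  n <- prod(sizes)
  type <- fields$type
  enc <- fields$encoding
  vals <- if (identical(enc, "raw")) {
    switch(type,
      "double" = readBin(con, "double", n = n, size = 8, endian = "little"),
      "float"  = readBin(con, "double", n = n, size = 4, endian = "little"),
      "uint8"  = ,
      "uchar"  = as.numeric(readBin(con, "integer", n = n, size = 1,
                                    signed = FALSE)),
      "short"  = as.numeric(readBin(con, "integer", n = n, size = 2,
                                    endian = "little")),
      "int"    = as.numeric(readBin(con, "integer", n = n, size = 4,
                                    endian = "little")),
      stop("unsupported NRRD type: ", type))
  } else if (identical(enc, "text") || identical(enc, "ascii")) {
    scan(con, what = double(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("truncated NRRD data in ", path)
  list(data = array(vals, dim = sizes), spacing = spacing)
}

.nifti_write <- function(arr, spacing, path) {
  d <- as_dim3(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    r <- charToRaw(s)
    writeBin(c(r, raw(len - length(r))), con)
  }
  wi(348, 4)                         # sizeof_hdr
  wc("", 10); wc("", 18)             # data_type, db_name
  wi(0, 4); wi(0, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(c(3, d, 1, 1, 1, 1), 2)         # dim[8]
  wf(c(0, 0, 0))                     # intent_p1..3
  wi(0, 2)                           # intent_code
  wi(64, 2); wi(64, 2)               # datatype float64, bitpix
  wi(0, 2)                           # slice_start
  wf(c(1, spacing, 0, 0, 0, 0))      # pixdim[8]
  wf(352)                            # vox_offset
  wf(1); wf(0)                       # scl_slope, scl_inter
  wi(0, 2); wc("", 1)                # slice_end, slice_code
  wc(rawToChar(as.raw(2)), 1)        # xyzt_units = mm
  wf(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                     # glmax, glmin
  wc("radrot volume", 80); wc("", 24)  # descrip, aux_file
  wi(0, 2); wi(0, 2)                 # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))            # quatern_b/c/d, qoffset x/y/z
  wf(rep(0, 12))                     # srow_x/y/z
  wc("", 16)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)              # extension flag
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
  invisible(path)
}

.nifti_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  rdi <- function(off, size, n = 1, signed = TRUE)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = signed)
  rdf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (rdi(0, 4) != 348) stop("not a NIfTI-1 file: ", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: ", path)
  dims <- rdi(40, 2, 8)
  if (dims[1] != 3) stop("only 3D NIfTI volumes are supported")
  d <- dims[2:4]
  datatype <- rdi(70, 2)
  pixdim <- rdf(76, 8)
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI file has no usable spacing metadata (pixdim): ", path)
  vox_offset <- rdf(108)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(d)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n = n, size = 2, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n = n, size = 4, endian = "little")),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype: ", datatype))
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  list(data = array(vals, dim = d), spacing = spacing)
}

#' Write a volume/mask pair to disk
#'
#' Writes `<patient_id>_image` and `<patient_id>_mask` files in NRRD or
#' NIfTI-1 format (mask values in {0, 1}); round-trips through
#' [read_volume()] preserve array values exactly and spacing to <= 1e-6 mm.
#'
#' @param pair a [volume_pair()].
#' @param dir output directory (created if needed).
#' @param format `"nrrd"` or `"nifti"`.
#' @return invisibly, a named list with `image` and `mask` paths.
#' @export
write_volume <- function(pair, dir, format = c("nrrd", "nifti")) {
  stopifnot(inherits(pair, "volume_pair"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "nrrd") "nrrd" else "nii"
  ip <- file.path(dir, sprintf("%s_image.%s", pair$patient_id, ext))
  mp <- file.path(dir, sprintf("%s_mask.%s", pair$patient_id, ext))
  if (format == "nrrd") {
    .nrrd_write(pair$image, pair$spacing, ip, "double")
    .nrrd_write(pair$mask, pair$spacing, mp, "uint8")
  } else {
    .nifti_write(pair$image, pair$spacing, ip)
    .nifti_write(pair$mask + 0, pair$spacing, mp)
  }
  invisible(list(image = ip, mask = mp))
}

#' Read a volume/mask pair from disk
#'
#' Format is inferred from the file extension (`.nrrd` vs `.nii`). Reading a
#' file without spacing metadata is an error; 1 mm is never silently assumed.
#'
#' @param image_path,mask_path file paths.
#' @param patient_id,class_label metadata for the resulting pair.
#' @return a [volume_pair()].
#' @export
read_volume <- function(image_path, mask_path, patient_id = NULL,
                        class_label = NA_integer_) {
  readfun <- function(p) {
    if (grepl("\\.nrrd$", p, ignore.case = TRUE)) .nrrd_read(p)
    else if (grepl("\\.nii$", p, ignore.case = TRUE)) .nifti_read(p)
    else stop("unknown volume format (expected .nrrd or .nii): ", p)
  }
  img <- readfun(image_path)
  msk <- readfun(mask_path)
  if (max(abs(img$spacing - msk$spacing)) > 1e-6)
    stop("image and mask spacing disagree")
  if (is.null(patient_id))
    patient_id <- sub("_image\\.(nrrd|nii)$", "", basename(image_path))
  volume_pair(img$data, msk$data, img$spacing, patient_id, class_label)
}

#' Write a cohort plus manifest CSV
#'
#' @param cohort list of [volume_pair()].
#' @param dir output directory.
#' @param format `"nrrd"` or `"nifti"`.
#' @return invisibly, the manifest `data.frame` (also written to
#'   `manifest.csv`: patient_id, image_path, mask_path, class_label).
#' @export
write_cohort <- function(cohort, dir, format = c("nrrd", "nifti")) {
  format <- match.arg(format)
  rows <- lapply(cohort, function(p) {
    paths <- write_volume(p, dir, format)
    data.frame(patient_id = p$patient_id, image_path = paths$image,
               mask_path = paths$mask, class_label = p$class_label,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest CSV
#'
#' @param manifest_path path to a manifest written by [write_cohort()].
#' @return list of [volume_pair()].
#' @export
read_cohort <- function(manifest_path) {
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    ip <- manifest$image_path[i]
    mp <- manifest$mask_path[i]
    if (!file.exists(ip)) ip <- file.path(base, basename(ip))
    if (!file.exists(mp)) mp <- file.path(base, basename(mp))
    if (!file.exists(ip) || !file.exists(mp))
      stop("missing volume files for patient ", manifest$patient_id[i])
    read_volume(ip, mp, manifest$patient_id[i], manifest$class_label[i])
  })
}
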