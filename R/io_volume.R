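#' Read a binary label volume
#'
#' NIfTI (`.nii`, `.nii.gz`) via RNifti, or MetaImage (`.mhd`, `.mha`).
#' Voxels `>= 1` are foreground. The volume must be axis-aligned: any
#' orientation other than the identity (up to spacing scaling) is rejected at
#' load time rather than silently reinterpreted.
#'
#' @param path volume file.
#' @return a `seg_mask` carrying the file's [image_geometry()].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("volume file not found: %s", path))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") read_label_nifti(path)
  else if (ext %in% c("mhd", "mha")) read_label_metaimage(path)
  else stop(sprintf("unsupported volume format '.%s' (use .nii[.gz], .mhd or .mha)",
                    tools::file_ext(path)))
}

#' Read only the geometry of a volume
#'
#' @param path volume file (NIfTI or MetaImage).
#' @return an [image_geometry()].
#' @export
read_image_geometry <- function(path) read_label_volume(path)$geometry

read_label_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3L) stop("expected a 3-D volume")
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  dirs <- sweep(rot, 2, spacing, `/`)
  # NIfTI xforms are RAS; data written by this package (and ITK-style
  # axis-aligned LPS data) appear with -x/-y diagonal signs. Accept any
  # diagonal direction matrix and fold signs into the geometry.
  if (max(abs(abs(dirs) - diag(3))) > 1e-4)
    stop("non-axis-aligned NIfTI orientation is not supported")
  sgn <- sign(diag(dirs))
  origin <- xf[1:3, 4]
  geom_origin <- ifelse(sgn > 0, origin,
                        origin + sgn * spacing * (dim(arr)[1:3] - 1))
  arr_fixed <- arr
  for (ax in which(sgn < 0)) {
    idx <- rev(seq_len(dim(arr)[ax]))
    arr_fixed <- switch(ax,
                        arr_fixed[idx, , , drop = FALSE],
                        arr_fixed[, idx, , drop = FALSE],
                        arr_fixed[, , idx, drop = FALSE])
  }
  g <- image_geometry(dim(arr)[1:3], spacing, geom_origin)
  seg_mask(arr_fixed >= 1, g)
}

#' Write a mask as NIfTI
#'
#' Writes foreground as 1, background as 0 (uint8), with the geometry's
#' spacing and origin in the sform/qform.
#'
#' @param mask a `seg_mask`.
#' @param path output `.nii` or `.nii.gz` path.
#' @export
write_mask_nifti <- function(mask, path) {
  arr <- array(as.integer(mask$data), dim = mask$geometry$shape)
  xf <- diag(4)
  diag(xf)[1:3] <- mask$geometry$spacing
  xf[1:3, 4] <- mask$geometry$origin
  attr(arr, "pixdim") <- mask$geometry$spacing
  img <- RNifti::asNifti(arr, datatype = "uint8")
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_label_metaimage <- function(path) {
  is_mhd <- tolower(tools::file_ext(path)) == "mhd"
  data_bytes <- NULL
  if (is_mhd) {
    hdr_lines <- readLines(path, warn = FALSE)
  } else {
    # .mha: text header terminated by the ElementDataFile line, then raw data
    all_bytes <- readBin(path, "raw", file.info(path)$size)
    nl <- which(all_bytes == as.raw(10L))
    hdr_end <- NA_integer_
    prev <- 0L
    for (p in nl) {
      line <- rawToChar(all_bytes[(prev + 1L):(p - 1L)])
      if (grepl("^ElementDataFile", line)) { hdr_end <- p; break }
      prev <- p
    }
    if (is.na(hdr_end)) stop("malformed MetaImage header")
    hdr_lines <- strsplit(rawToChar(all_bytes[seq_len(hdr_end - 1L)]), "\n")[[1]]
    data_bytes <- all_bytes[(hdr_end + 1L):length(all_bytes)]
  }
  kv <- strsplit(hdr_lines, "\\s*=\\s*")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  getv <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  ndims <- as.integer(getv("NDims", "3"))
  if (ndims != 3L) stop("expected a 3-D MetaImage volume")
  dims <- as.integer(strsplit(getv("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(getv("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(getv("Offset", "0 0 0"), "\\s+")[[1]])
  tm <- getv("TransformMatrix", "1 0 0 0 1 0 0 0 1")
  if (max(abs(as.numeric(strsplit(tm, "\\s+")[[1]]) - as.numeric(diag(3)))) > 1e-6)
    stop("non-identity MetaImage orientation is not supported")
  etype <- getv("ElementType", "MET_UCHAR")
  if (!identical(getv("CompressedData", "False"), "False"))
    stop("compressed MetaImage data is not supported")
  n <- prod(dims)
  reader <- switch(etype,
                   MET_UCHAR = function(con) readBin(con, "integer", n, size = 1L, signed = FALSE),
                   MET_CHAR = function(con) readBin(con, "integer", n, size = 1L, signed = TRUE),
                   MET_SHORT = function(con) readBin(con, "integer", n, size = 2L, endian = "little"),
                   MET_USHORT = function(con) readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "little"),
                   MET_FLOAT = function(con) readBin(con, "double", n, size = 4L, endian = "little"),
                   MET_DOUBLE = function(con) readBin(con, "double", n, size = 8L, endian = "little"),
                   stop(sprintf("unsupported MetaImage ElementType %s", etype)))
  datafile <- trimws(getv("ElementDataFile"))
  if (is_mhd) {
    if (identical(datafile, "LOCAL")) stop("mhd header points to LOCAL data")
    raw_path <- file.path(dirname(path), datafile)
    con2 <- file(raw_path, "rb")
    on.exit(close(con2), add = TRUE)
    vox <- reader(con2)
  } else {
    if (!identical(datafile, "LOCAL")) stop("mha file must use ElementDataFile = LOCAL")
    con2 <- rawConnection(data_bytes)
    on.exit(close(con2), add = TRUE)
    vox <- reader(con2)
  }
  arr <- array(vox, dim = dims)
  seg_mask(arr >= 1, image_geometry(dims, spacing, origin))
}

#' Write a mask as MetaImage
#'
#' Single-file `.mha` (uncompressed uint8, identity orientation) or `.mhd`
#' header with a sibling `.raw` file.
#'
#' @param mask a `seg_mask`.
#' @param path output `.mha` or `.mhd` path.
#' @export
write_mask_metaimage <- function(mask, path) {
  g <- mask$geometry
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("mha", "mhd")) stop("path must end in .mha or .mhd")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           sprintf("Offset = %.17g %.17g %.17g", g$origin[1], g$origin[2], g$origin[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g",
                   g$spacing[1], g$spacing[2], g$spacing[3]),
           sprintf("DimSize = %d %d %d", g$shape[1], g$shape[2], g$shape[3]),
           "ElementType = MET_UCHAR")
  bytes <- as.raw(as.integer(mask$data))
  if (ext == "mha") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(bytes, con)
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path))
    writeLines(c(hdr, sprintf("ElementDataFile = %s", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
    writeBin(bytes, con)
  }
  invisible(path)
}
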