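#' Read a binary structure mask from a volumetric file
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and single-file NRRD (`.nrrd`, raw
#' or gzip encoding). The voxel data are binarized: any nonzero value is
#' occupied. Spacing is taken from the file header; patient axis roles are
#' NOT inferred from orientation codes — they are supplied by the caller
#' (normally from the cohort manifest) with the package default axis order
#' RL, AP, CC.
#'
#' @param path file to read.
#' @param label structure label to attach (see [dirqa_structures()]).
#' @param axis_roles patient-direction roles of the three array axes.
#' @return A [structure_mask()].
#' @export
read_mask <- function(path, label = "other",
                      axis_roles = c("RL", "AP", "CC")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    vol <- read_nrrd(path)
  } else {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
      stop("expected a 3D volume, got ", length(dim(img)), " dimensions")
    sp <- RNifti::pixdim(img)
    if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
      stop("volume carries no usable spacing metadata")
    xf <- RNifti::xform(img)
    vol <- list(data = as.array(img), spacing = as.numeric(sp[1:3]),
                origin = as.numeric(xf[1:3, 4]))
  }
  grid <- voxel_grid(dim(vol$data), vol$spacing, vol$origin, axis_roles)
  structure_mask(vol$data, grid, label)
}

#' Write a structure mask to a NIfTI-1 file
#'
#' Occupancy is stored as uint8 {0,1}; spacing and origin go into the
#' header (sform with a diagonal direction matrix). Axis roles are a
#' manifest-level concept and are not encoded in the file.
#'
#' @param mask a [structure_mask()].
#' @param path destination; `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  g <- mask$grid
  img <- RNifti::asNifti(array(as.integer(mask$occupancy), dim = g$shape))
  RNifti::pixdim(img) <- g$spacing
  aff <- diag(c(g$spacing, 1))
  aff[1:3, 4] <- g$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

# Minimal single-file NRRD reader: ASCII header terminated by a blank line,
# then the voxel block. Handles 3D volumes, raw/gzip encoding, little-endian,
# spacing from "spacings" or a diagonal "space directions".
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.na(ndim) || ndim != 3L) stop("expected a 3D NRRD volume")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- vapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    }, numeric(3))
    spacing <- sqrt(colSums(m^2))
  }
  if (is.null(spacing) || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NRRD header carries no usable spacing metadata")
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]])
  n <- prod(sizes)
  rtype <- switch(type,
    "unsigned char" = , "uint8" = , "uchar" = list(what = "integer", size = 1, signed = FALSE),
    "short" = , "int16" = list(what = "integer", size = 2, signed = TRUE),
    "unsigned short" = , "uint16" = list(what = "integer", size = 2, signed = FALSE),
    "int" = , "int32" = list(what = "integer", size = 4, signed = TRUE),
    "float" = list(what = "numeric", size = 4, signed = TRUE),
    "double" = list(what = "numeric", size = 8, signed = TRUE),
    stop("unsupported NRRD type: ", type))
  payload <- readBin(con, "raw", n = n * rtype$size * 4 + 1024)
  if (identical(enc, "gzip") || identical(enc, "gz"))
    payload <- memDecompress(payload, type = "gzip")
  else if (!identical(enc, "raw"))
    stop("unsupported NRRD encoding: ", enc)
  vals <- readBin(payload, rtype$what, n = n, size = rtype$size,
                  signed = rtype$signed, endian = "little")
  if (length(vals) < n) stop("NRRD voxel block truncated")
  list(data = array(vals, dim = sizes), spacing = spacing, origin = origin)
}
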