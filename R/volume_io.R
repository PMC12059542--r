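#' Read a 3D scalar volume from NIfTI or NRRD
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) through RNifti and NRRD (`.nrrd`,
#' raw/gzip/ascii encodings) through a built-in reader.  On-disk axis order
#' and orientation are normalized to the internal `(x, y, z)` convention:
#' files whose direction matrix is an axis-aligned permutation/flip are
#' reordered accordingly; oblique volumes are rejected.  Trailing singleton
#' dimensions are dropped; anything else non-3D is a format error.
#'
#' @param path path to an existing `.nii`, `.nii.gz`, or `.nrrd` file.
#' @return A [volume()] with spacing and origin taken from the header.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "histocal_format_error")
  ext <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", ext)) {
    read_nifti_volume(path)
  } else if (grepl("\\.nrrd$", ext)) {
    read_nrrd_volume(path)
  } else {
    abort(sprintf("unsupported volume format: %s (expected .nii/.nii.gz/.nrrd)",
                  basename(path)), class = "histocal_format_error")
  }
}

#' Write a volume to NIfTI or NRRD
#'
#' The format is chosen from the file extension.  NRRD is written with
#' `double` raw encoding and full-precision header geometry so the
#' read/write round trip is exact; NIfTI headers store geometry in single
#' precision (a format property), so spacing/origin round-trip to ~1e-6 mm.
#'
#' @param volume a [volume()].
#' @param path output path ending in `.nii`, `.nii.gz`, or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot_volume(volume)
  if (!dir.exists(dirname(path)))
    abort(sprintf("parent directory does not exist: %s", dirname(path)))
  ext <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", ext)) {
    write_nifti_volume(volume, path)
  } else if (grepl("\\.nrrd$", ext)) {
    write_nrrd_volume(volume, path)
  } else {
    abort(sprintf("unsupported volume format: %s", basename(path)),
          class = "histocal_format_error")
  }
  invisible(path)
}

drop_singletons <- function(arr) {
  d <- dim(arr)
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(arr) <- d
  }
  arr
}

# Decompose an affine voxel->world matrix (3x4) into permutation/flip +
# spacing + origin; errors when the grid is oblique.
normalize_axes <- function(arr, affine) {
  rot <- affine[1:3, 1:3, drop = FALSE]
  off <- affine[1:3, 4]
  d <- dim(arr)
  perm <- integer(3)   # perm[i]: file axis feeding world axis i
  sign <- numeric(3)
  for (i in 1:3) {
    j <- which.max(abs(rot[i, ]))
    cn <- sqrt(sum(rot[, j]^2))
    if (abs(rot[i, j]) < (1 - 1e-4) * cn)
      abort("volume orientation is oblique; only axis-aligned volumes are supported.",
            class = "histocal_format_error")
    perm[i] <- j
    sign[i] <- base::sign(rot[i, j])
  }
  if (length(unique(perm)) != 3L)
    abort("degenerate direction matrix.", class = "histocal_format_error")
  spacing <- numeric(3); origin <- numeric(3)
  idx <- vector("list", 3)
  for (i in 1:3) {
    j <- perm[i]
    spacing[i] <- abs(rot[i, j])
    if (sign[i] > 0) {
      origin[i] <- off[i]
      idx[[i]] <- seq_len(d[j])
    } else {
      origin[i] <- off[i] + rot[i, j] * (d[j] - 1)
      idx[[i]] <- rev(seq_len(d[j]))
    }
  }
  arr <- aperm(arr, perm)
  arr <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  volume(arr, spacing = spacing, origin = origin)
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(
                    sprintf("unreadable NIfTI file %s: %s", path, conditionMessage(e)),
                    class = "histocal_format_error"))
  arr <- drop_singletons(as.array(img))
  if (length(dim(arr)) != 3L)
    abort(sprintf("image in %s is %dD, expected a 3D scalar volume.",
                  basename(path), length(dim(arr))),
          class = "histocal_format_error")
  if (!is.numeric(arr))
    abort("non-scalar voxel type.", class = "histocal_format_error")
  xf <- RNifti::xform(img)
  normalize_axes(arr, cbind(xf[1:3, 1:3], xf[1:3, 4]))
}

write_nifti_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  # pixdim must be set before the xform or RNifti renormalizes the
  # rotation block to unit spacing
  RNifti::pixdim(img) <- volume$spacing
  m <- diag(4)
  diag(m)[1:3] <- volume$spacing
  m[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
}

nrrd_type_map <- list(
  double = list(what = "double", size = 8),
  float = list(what = "double", size = 4),
  short = list(what = "integer", size = 2),
  ushort = list(what = "integer", size = 2, signed = FALSE),
  int = list(what = "integer", size = 4),
  uchar = list(what = "integer", size = 1, signed = FALSE),
  uint8 = list(what = "integer", size = 1, signed = FALSE)
)

read_nrrd_volume <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  sep <- NULL
  for (i in seq_len(length(bytes) - 1L)) {
    if (bytes[i] == as.raw(10) && bytes[i + 1] == as.raw(10)) { sep <- i; break }
  }
  if (is.null(sep))
    abort("malformed NRRD: no end-of-header blank line.",
          class = "histocal_format_error")
  header <- strsplit(rawToChar(bytes[1:sep]), "\n", fixed = TRUE)[[1]]
  if (!grepl("^NRRD", header[1]))
    abort("not a NRRD file (missing magic).", class = "histocal_format_error")
  fields <- list()
  for (line in header[-1]) {
    if (grepl("^\\s*#", line) || !grepl(":", line, fixed = TRUE)) next
    kv <- regmatches(line, regexpr(":", line, fixed = TRUE), invert = TRUE)[[1]]
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.na(ndim) || ndim != 3L)
    abort(sprintf("NRRD image is %sD, expected a 3D scalar volume.",
                  fields[["dimension"]]), class = "histocal_format_error")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- tolower(fields[["type"]])
  alias <- c("signed char" = "uchar", "unsigned char" = "uchar",
             "float64" = "double", "float32" = "float")[type]
  if (!is.na(alias)) type <- unname(alias)
  tm <- nrrd_type_map[[type]]
  if (is.null(tm))
    abort(sprintf("unsupported NRRD voxel type '%s'.", fields[["type"]]),
          class = "histocal_format_error")
  payload <- bytes[(sep + 2L):length(bytes)]
  enc <- tolower(fields[["encoding"]] %||% "raw")
  n <- prod(sizes)
  if (enc %in% c("gzip", "gz")) payload <- memDecompress(payload, type = "gzip")
  if (enc %in% c("raw", "gzip", "gz")) {
    vals <- readBin(payload, what = tm$what, n = n, size = tm$size,
                    signed = tm$signed %||% TRUE,
                    endian = fields[["endian"]] %||% "little")
  } else if (enc %in% c("ascii", "text", "txt")) {
    vals <- as.numeric(strsplit(trimws(rawToChar(payload)), "\\s+")[[1]])
  } else {
    abort(sprintf("unsupported NRRD encoding '%s'.", enc),
          class = "histocal_format_error")
  }
  if (length(vals) < n)
    abort("truncated NRRD payload.", class = "histocal_format_error")
  arr <- array(as.double(vals[seq_len(n)]), dim = sizes)
  affine <- cbind(diag(3), c(0, 0, 0))
  if (!is.null(fields[["space directions"]])) {
    vecs <- parse_nrrd_vectors(fields[["space directions"]])
    affine[1:3, 1:3] <- do.call(cbind, vecs)
  } else if (!is.null(fields[["spacings"]])) {
    diag(affine[1:3, 1:3]) <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]]))
    affine[1:3, 4] <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  normalize_axes(arr, affine)
}

parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_nrrd_volume <- function(volume, path) {
  d <- dim(volume$data)
  fmt <- function(x) sprintf("%.17g", x)
  header <- c(
    "NRRD0004",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "encoding: raw",
    "endian: little",
    "space: right-anterior-superior",
    sprintf("space directions: (%s,0,0) (0,%s,0) (0,0,%s)",
            fmt(volume$spacing[1]), fmt(volume$spacing[2]), fmt(volume$spacing[3])),
    sprintf("space origin: (%s,%s,%s)",
            fmt(volume$origin[1]), fmt(volume$origin[2]), fmt(volume$origin[3])),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(as.vector(volume$data), con, size = 8, endian = "little")
  invisible(path)
}
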