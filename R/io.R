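#' Read a streamline tractogram (TRK or TCK)
#'
#' Streamlines are returned in world RAS millimetres regardless of the
#' on-disk convention. TRK files store points in the TrackVis "voxel-mm"
#' dialect (voxel indices scaled by voxel size, corner-origin); these are
#' converted through the header affine on read. TCK files store world RAS mm
#' directly but carry no reference grid, so one may be supplied.
#'
#' @param path path to a `.trk` or `.tck` file.
#' @param reference optional `volume` or `bundle_mask` providing the
#'   reference grid for TCK files (ignored for TRK, which carries its own).
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  t <- switch(ext,
    trk = read_trk(path),
    tck = read_tck(path, reference),
    stop("unsupported tractogram format: .", ext, " (need .trk or .tck)"))
  if (t$n_streamlines == 0L)
    stop("empty tractogram: ", path, " contains zero streamlines")
  t
}

#' Write a streamline tractogram (TRK or TCK)
#'
#' @param t a [tractogram()].
#' @param path output path; format chosen by extension (`.trk` or `.tck`).
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(t, path) {
  stopifnot(inherits(t, "tractogram"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    trk = write_trk(t, path),
    tck = write_tck(t, path),
    stop("unsupported tractogram format: .", ext))
  invisible(path)
}

# ---- TRK (TrackVis, version 2, little-endian) -------------------------------

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6)
  if (!identical(rawToChar(magic[1:5]), "TRACK"))
    stop("not a TRK file (bad magic bytes): ", path)
  dim3 <- readBin(con, "integer", n = 3, size = 2, endian = "little")
  vsize <- readBin(con, "double", n = 3, size = 4, endian = "little")
  readBin(con, "double", n = 3, size = 4, endian = "little")  # origin, unused
  n_scalars <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  readBin(con, "raw", n = 200)
  n_props <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  readBin(con, "raw", n = 200)
  vox2ras <- matrix(readBin(con, "double", n = 16, size = 4, endian = "little"),
                    4, 4, byrow = TRUE)
  readBin(con, "raw", n = 444 + 4 + 4 + 24 + 2 + 6)
  n_count <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  version <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (!identical(hdr_size, 1000L))
    stop("corrupt TRK header (hdr_size != 1000): ", path)
  if (vox2ras[4, 4] == 0)
    stop("TRK file has no valid vox_to_ras affine: ", path)
  streamlines <- vector("list", max(n_count, 0L))
  i <- 0L
  repeat {
    n_pts <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (length(n_pts) == 0L) break
    vals <- readBin(con, "double", n = n_pts * (3L + n_scalars), size = 4,
                    endian = "little")
    if (n_props > 0L)
      readBin(con, "double", n = n_props, size = 4, endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # voxel-mm -> voxel (corner origin) -> world RAS
    vox <- sweep(m, 2, vsize, "/") - 0.5
    i <- i + 1L
    streamlines[[i]] <- voxel_to_world(vox, vox2ras)
  }
  length(streamlines) <- i
  tractogram(streamlines, affine = vox2ras, shape = dim3)
}

write_trk <- function(t, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  vsize <- voxel_sizes(t$affine)
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(t$shape), con, size = 2, endian = "little")
  writeBin(as.numeric(vsize), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")        # origin
  writeBin(0L, con, size = 2, endian = "little")                # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")                # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(t$affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)
  writeBin(c(charToRaw("RAS"), as.raw(0)), con)                 # voxel_order
  writeBin(raw(4), con)
  writeBin(numeric(6), con, size = 4, endian = "little")        # orientation
  writeBin(raw(2 + 6), con)
  writeBin(as.integer(t$n_streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")                # version
  writeBin(1000L, con, size = 4, endian = "little")
  inv <- solve(t$affine)
  for (s in t$streamlines) {
    vox <- world_to_voxel(s, t$affine)
    pts <- sweep(vox + 0.5, 2, vsize, "*")
    writeBin(nrow(pts), con, size = 4, endian = "little")
    writeBin(as.numeric(t(pts)), con, size = 4, endian = "little")
  }
  invisible(path)
}

# ---- TCK (MRtrix, Float32LE) ------------------------------------------------

read_tck <- function(path, reference = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (!identical(trimws(first), "mrtrix tracks"))
    stop("not a TCK file (bad magic line): ", path)
  offset <- NA_integer_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop("corrupt TCK header (no END): ", path)
    if (identical(trimws(line), "END")) break
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (key == "file") offset <- as.integer(strsplit(val, "\\s+")[[1]][2])
    if (key == "datatype") datatype <- val
  }
  if (!identical(datatype, "Float32LE"))
    stop("unsupported TCK datatype: ", datatype)
  if (is.na(offset)) stop("corrupt TCK header (no file offset): ", path)
  seek(con, offset)
  raw_vals <- readBin(con, "double", n = file.size(path), size = 4,
                      endian = "little")
  m <- matrix(raw_vals, ncol = 3, byrow = TRUE)
  breaks <- which(is.nan(m[, 1]) | is.infinite(m[, 1]))
  streamlines <- list()
  start <- 1L
  for (b in breaks) {
    if (b > start) streamlines[[length(streamlines) + 1L]] <-
        m[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
    if (is.infinite(m[b, 1])) break
  }
  aff <- if (!is.null(reference)) reference$affine else diag(4)
  shp <- if (!is.null(reference)) {
    if (inherits(reference, "bundle_mask")) dim(reference$mask)
    else dim(reference$data)
  } else c(0L, 0L, 0L)
  tractogram(streamlines, affine = aff, shape = shp)
}

write_tck <- function(t, path) {
  base <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                 t$n_streamlines, "\nfile: . ")
  # the 'file: . <offset>' line states its own end position; fixed point
  off <- nchar(base) + nchar("\nEND\n") + 1L
  repeat {
    total <- nchar(base) + nchar(as.character(off)) + nchar("\nEND\n")
    if (total <= off) break
    off <- total
  }
  hdr <- paste0(base, off, "\nEND\n")
  stopifnot(nchar(hdr) <= off)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  if (nchar(hdr) < off) writeBin(raw(off - nchar(hdr)), con)
  for (s in t$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

# ---- NIfTI volumes ----------------------------------------------------------

#' Read a 3-D NIfTI volume
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return A [volume()]; voxel sizes are derived from the affine columns.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) d <- d[1:3]
    else stop("expected a 3-D volume, got ", length(d), "-D with dims ",
              paste(d, collapse = "x"), ": ", path)
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume(array(as.numeric(img), dim = d), affine = aff)
}

#' Read a 4-D NIfTI series (e.g. diffusion-weighted volumes)
#'
#' @param path NIfTI-1 file.
#' @return list with `data` (4-D array) and `affine`.
#' @export
read_volume4d <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4-D volume: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(data = array(as.numeric(img), dim = d), affine = aff)
}

#' Write a volume, mask, or 4-D array as NIfTI
#'
#' @param x a [volume()], [bundle_mask()], or a list with `data` and `affine`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  data <- if (inherits(x, "bundle_mask")) x$mask + 0L
          else x$data
  aff <- x$affine
  img <- RNifti::asNifti(data)
  pd <- voxel_sizes(aff)
  if (length(dim(data)) == 4L) pd <- c(pd, 1)
  RNifti::pixdim(img) <- pd
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a bundle mask from NIfTI
#'
#' @param path NIfTI file holding a binary (0/1) volume.
#' @return A [bundle_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  bundle_mask(v$data != 0, v$affine)
}

# ---- FSL-style gradient scheme ----------------------------------------------

#' Read an FSL-style bval/bvec gradient scheme
#'
#' @param bval_path whitespace-separated b-values (s/mm^2), one row.
#' @param bvec_path 3 rows of whitespace-separated unit gradient components.
#' @param b0_threshold b-values at or below this count as non-diffusion-weighted.
#' @return An object of class `dwi_scheme` with `bvals`, `bvecs` (n x 3),
#'   `n_volumes`, `b0_threshold`.
#' @export
read_scheme <- function(bval_path, bvec_path, b0_threshold = 50) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- t(matrix(scan(bvec_path, quiet = TRUE), nrow = 3, byrow = TRUE))
  dwi_scheme(bvals, bvecs, b0_threshold)
}

#' Construct and validate a gradient scheme
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs n x 3 matrix of gradient directions (unit norm where b > b0
#'   threshold).
#' @param b0_threshold see [read_scheme()].
#' @return A `dwi_scheme`.
#' @export
dwi_scheme <- function(bvals, bvecs, b0_threshold = 50) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L || nrow(bvecs) != length(bvals))
    stop("bvecs must be n x 3 matching length(bvals)")
  dw <- bvals > b0_threshold
  if (sum(!dw) < 1L) stop("scheme needs at least one b0 volume")
  if (sum(dw) < 6L) stop("scheme needs at least 6 diffusion-weighted volumes")
  norms <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-3))
    stop("diffusion-weighted bvecs must have unit norm (tolerance 1e-3)")
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs,
                 n_volumes = length(bvals), b0_threshold = b0_threshold),
            class = "dwi_scheme")
}

#' Write a gradient scheme as FSL bval/bvec text files
#' @param scheme a `dwi_scheme`.
#' @param bval_path,bvec_path output paths.
#' @return invisibly, `c(bval_path, bvec_path)`.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(scheme$bvecs), 1, paste, collapse = " "), bvec_path)
  invisible(c(bval_path, bvec_path))
}

# ---- study manifest ---------------------------------------------------------

#' Confound contrast identifiers used in multi-scanner bundle studies
#'
#' RESCAN (same scanner, repeat session), SCAN1/SCAN2 (cross-scanner, same
#' vendor), VEN1/VEN2 (cross-vendor), RES1/RES2 (acquisition resolution),
#' DIR1/DIR2 (number of diffusion directions), BVAL (diffusion sensitization).
#' User-defined identifiers are also accepted.
#' @export
KNOWN_CONFOUNDS <- c("RESCAN", "SCAN1", "SCAN2", "VEN1", "VEN2",
                     "RES1", "RES2", "DIR1", "DIR2", "BVAL")

#' Read a study manifest
#'
#' A manifest is a flat YAML file declaring subjects, pathways, datasets,
#' the reference dataset, path templates (placeholders `{subject}`,
#' `{dataset}`, `{pathway}`), and the confound contrasts: pairs of datasets
#' from the same subject differing in exactly one factor.
#'
#' @param path YAML manifest file. Relative path templates are resolved
#'   against the manifest's directory.
#' @return An object of class `study_manifest`: a list with `subjects`,
#'   `pathways`, `datasets`, `reference_dataset`, `templates`, `root`, and
#'   `contrasts` (a tibble with columns confound, a, b).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- yaml::read_yaml(path)
  required <- c("subjects", "datasets", "reference_dataset", "contrasts")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("manifest missing required fields: ", paste(missing, collapse = ", "))
  datasets <- unlist(m$datasets)
  contrasts <- dplyr::bind_rows(lapply(m$contrasts, function(ct) {
    tibble::tibble(confound = as.character(ct$confound),
                   a = as.character(ct$a), b = as.character(ct$b))
  }))
  bad <- setdiff(unique(c(contrasts$a, contrasts$b)), datasets)
  if (length(bad))
    stop("manifest contrasts reference undeclared dataset(s): ",
         paste(bad, collapse = ", "))
  if (!m$reference_dataset %in% datasets)
    stop("reference_dataset '", m$reference_dataset, "' is not declared")
  structure(
    list(subjects = as.character(unlist(m$subjects)),
         pathways = as.character(unlist(m$pathways)),
         datasets = as.character(datasets),
         reference_dataset = as.character(m$reference_dataset),
         templates = m$templates,
         contrasts = contrasts,
         dwi = isTRUE(m$dwi),
         root = normalizePath(dirname(path))),
    class = "study_manifest")
}

#' @export
print.study_manifest <- function(x, ...) {
  cat(sprintf(
    "<study_manifest> %d subjects, %d pathways, %d datasets (ref: %s), %d contrasts\n",
    length(x$subjects), length(x$pathways), length(x$datasets),
    x$reference_dataset, nrow(x$contrasts)))
  invisible(x)
}

#' Resolve a manifest path template
#' @param m a `study_manifest`.
#' @param what template name (`bundle`, `grid`, `dwi`, `bval`, `bvec`).
#' @param subject,dataset,pathway placeholder values.
#' @return absolute file path (not checked for existence).
#' @export
manifest_path <- function(m, what, subject = "", dataset = "", pathway = "") {
  tpl <- m$templates[[what]]
  if (is.null(tpl)) stop("manifest has no '", what, "' template")
  p <- gsub("{subject}", subject, tpl, fixed = TRUE)
  p <- gsub("{dataset}", dataset, p, fixed = TRUE)
  p <- gsub("{pathway}", pathway, p, fixed = TRUE)
  file.path(m$root, p)
}
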