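# Volume readers/writers and result serialisation.
#
# NIfTI is the canonical interchange format (via RNifti); DICOM series are
# read-only through a minimal explicit-VR little-endian parser (uncompressed
# pixel data, axial axis-aligned series). Internally everything is (z, y, x)
# with z increasing caudally.

# labelmap integer codes (myocardium = WH voxels outside every chamber)
LABELMAP_CODES <- c(`WH-only` = 1L, LV = 2L, RV = 3L, LA = 4L, RA = 5L)

#' Read a CT volume
#'
#' NIfTI files (`.nii`, `.nii.gz`) or a directory containing a DICOM series.
#' DICOM stored values are rescaled to HU via slope/intercept; slices are
#' ordered cranio-caudally. Oblique acquisitions are rejected.
#'
#' @param path File or directory.
#' @return A `ct_volume` with (z, y, x) intensities and spacing in mm.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D volume, got ", length(d), "D")
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0)) {
    stop("volume is missing valid voxel spacing")
  }
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (!inherits(xf, "try-error") && is.matrix(xf)) {
    rot <- abs(xf[1:3, 1:3])
    offdiag <- rot; diag(offdiag) <- 0
    if (any(offdiag > 1e-3 * max(rot))) {
      stop("oblique acquisition: only axis-aligned volumes are supported")
    }
  }
  # NIfTI arrays are (x, y, z); normalize to (z, y, x)
  arr <- aperm(as.array(img), c(3L, 2L, 1L))
  new_ct_volume(arr, rev(pd[1:3]),
                identifier = sub("\\.nii(\\.gz)?$", "", basename(path)))
}

#' Write a CT volume or 3D array as NIfTI
#'
#' @param volume A `ct_volume`, or a 3D (z, y, x) array (then `spacing`
#'   is required).
#' @param path Output `.nii` or `.nii.gz` path.
#' @param spacing (z, y, x) spacing when `volume` is a bare array.
#' @export
write_volume <- function(volume, path, spacing = NULL) {
  if (inherits(volume, "ct_volume")) {
    arr <- volume$intensities; spacing <- volume$spacing
  } else {
    arr <- volume
    if (is.null(spacing)) stop("spacing required for a bare array")
  }
  img <- RNifti::asNifti(aperm(arr, c(3L, 2L, 1L)))
  RNifti::pixdim(img) <- rev(spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Encode five structure masks as an integer labelmap
#'
#' Codes: 1 = WH outside every chamber (myocardium), 2 = LV, 3 = RV,
#' 4 = LA, 5 = RA, 0 = background.
#'
#' @param labels A `label_volume` or named list of binary masks.
#' @return Integer 3D array.
#' @export
encode_labelmap <- function(labels) {
  masks <- if (inherits(labels, "label_volume")) labels$masks else labels
  lab <- array(0L, dim = dim(masks$WH))
  lab[masks$WH != 0] <- LABELMAP_CODES[["WH-only"]]
  for (s in c("LV", "RV", "LA", "RA")) {
    lab[masks[[s]] != 0] <- LABELMAP_CODES[[s]]
  }
  lab
}

#' Decode an integer labelmap into the five binary masks
#'
#' @param lab Integer 3D array with the [encode_labelmap()] code table.
#' @return Named list of logical masks (`WH` is the union of codes 1-5).
#' @export
decode_labelmap <- function(lab) {
  masks <- list(WH = lab >= 1L & lab <= 5L)
  for (s in c("LV", "RV", "LA", "RA")) {
    masks[[s]] <- lab == LABELMAP_CODES[[s]]
  }
  masks
}

#' Write a segmentation result to a directory
#'
#' Emits one binary NIfTI mask per structure, an integer labelmap NIfTI,
#' and a JSON report (volumes in ml, thresholds, provenance, labelmap code
#' table). Re-reading the masks reproduces them exactly.
#'
#' @param result A `segmentation_result`.
#' @param out_dir Output directory (created if needed).
#' @return Path of the JSON report (the manifest).
#' @export
write_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(result$masks)) {
    write_volume(array(as.integer(result$masks[[s]]),
                       dim = dim(result$masks[[s]])),
                 file.path(out_dir, paste0(s, ".nii.gz")),
                 spacing = result$spacing)
  }
  write_volume(encode_labelmap(result$masks),
               file.path(out_dir, "labelmap.nii.gz"),
               spacing = result$spacing)
  prov <- result$provenance
  prov$slab <- if (!is.null(prov$slab)) {
    list(z_start = prov$slab$z_start, z_end = prov$slab$z_end,
         empty = prov$slab$empty)
  }
  report <- list(volumes_ml = as.list(result$volumes_ml),
                 spacing_mm = result$spacing,
                 threshold = result$threshold,
                 empty_slab = isTRUE(prov$empty_slab),
                 labelmap_codes = as.list(LABELMAP_CODES),
                 provenance = prov)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Write a phantom dataset to disk
#'
#' One NIfTI volume and one labelmap per phantom plus a JSON manifest
#' (identifiers, seeds, spacing, partition, labelmap code table).
#'
#' @param dataset A `phantom_dataset` from [generate_dataset()].
#' @param out_dir Output directory.
#' @return The manifest path.
#' @export
write_phantom_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$phantoms)) {
    ph <- dataset$phantoms[[id]]
    write_volume(ph$volume, file.path(out_dir, paste0(id, ".nii.gz")))
    write_volume(encode_labelmap(ph$labels),
                 file.path(out_dir, paste0(id, "_labels.nii.gz")),
                 spacing = ph$labels$spacing)
  }
  manifest <- list(volumes = dataset$manifest,
                   labelmap_codes = as.list(LABELMAP_CODES),
                   grid_shape = dataset$config$grid_shape,
                   in_plane_spacing = dataset$config$in_plane_spacing,
                   seed = dataset$config$seed)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Load a phantom dataset directory written by [write_phantom_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `phantom_dataset` (volumes and labels in memory).
#' @export
load_phantom_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  manifest <- as.data.frame(mf$volumes)
  phantoms <- lapply(manifest$id, function(id) {
    vol <- read_volume(file.path(dir, paste0(id, ".nii.gz")))
    vol$identifier <- id
    lab <- read_volume(file.path(dir, paste0(id, "_labels.nii.gz")))
    masks <- decode_labelmap(round(lab$intensities))
    list(volume = vol,
         labels = new_label_volume(masks, vol$spacing, id))
  })
  names(phantoms) <- manifest$id
  structure(list(phantoms = phantoms, manifest = manifest, config = NULL),
            class = "phantom_dataset")
}

## ---- minimal DICOM series reader ----------------------------------------

read_uint <- function(raw) sum(as.integer(raw) * 256^(seq_along(raw) - 1L))

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path)
  }
  pos <- 133L
  n <- length(raw)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  fields <- list()
  while (pos + 7L <= n) {
    group <- read_uint(raw[pos:(pos + 1L)])
    elem <- read_uint(raw[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("implicit-VR or corrupt DICOM not supported: ", path)
    }
    if (vr %in% long_vrs) {
      len <- read_uint(raw[(pos + 8L):(pos + 11L)])
      vstart <- pos + 12L
    } else {
      len <- read_uint(raw[(pos + 6L):(pos + 7L)])
      vstart <- pos + 8L
    }
    key <- sprintf("%04x%04x", group, elem)
    val <- raw[vstart:(vstart + len - 1L)]
    if (len == 0L) val <- raw(0)
    fields[[key]] <- list(vr = vr, value = val)
    pos <- vstart + len
  }
  fields
}

dicom_str <- function(fields, key) {
  f <- fields[[key]]
  if (is.null(f)) return(NULL)
  trimws(rawToChar(f$value))
}

dicom_num <- function(fields, key, default = NULL) {
  s <- dicom_str(fields, key)
  if (is.null(s) || s == "") return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_us <- function(fields, key) {
  f <- fields[[key]]
  if (is.null(f)) return(NULL)
  read_uint(f$value[1:2])
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("empty DICOM directory: ", dir)
  parsed <- lapply(files, parse_dicom_file)
  rows <- dicom_us(parsed[[1L]], "00280010")
  cols <- dicom_us(parsed[[1L]], "00280011")
  ps <- dicom_num(parsed[[1L]], "00280030")
  thick <- dicom_num(parsed[[1L]], "00180050")
  if (is.null(rows) || is.null(cols) || is.null(ps)) {
    stop("DICOM series is missing Rows/Columns/PixelSpacing")
  }
  zpos <- vapply(parsed, function(f) {
    ipp <- dicom_num(f, "00200032")
    if (is.null(ipp) || length(ipp) < 3L) NA_real_ else ipp[3L]
  }, 0)
  if (anyNA(zpos)) stop("DICOM series is missing ImagePositionPatient")
  # patient z increases cranially; our axial index increases caudally
  ord <- order(zpos, decreasing = TRUE)
  parsed <- parsed[ord]; zpos <- zpos[ord]
  dz <- if (length(zpos) > 1L) {
    steps <- abs(diff(zpos))
    if (max(steps) - min(steps) > 0.01) {
      stop("non-uniform DICOM slice spacing")
    }
    mean(steps)
  } else if (!is.null(thick)) thick else {
    stop("cannot determine slice spacing from a single slice without ",
         "SliceThickness")
  }
  nz <- length(parsed)
  arr <- array(0, dim = c(nz, rows, cols))
  for (i in seq_len(nz)) {
    f <- parsed[[i]]
    bits <- dicom_us(f, "00280100")
    if (!identical(bits, 16)) stop("only 16-bit DICOM pixel data supported")
    signed <- identical(dicom_us(f, "00280103"), 1)
    slope <- dicom_num(f, "00281053", default = 1)
    intercept <- dicom_num(f, "00281052", default = 0)
    px <- f[["7fe00010"]]
    if (is.null(px)) stop("DICOM file has no pixel data")
    vals <- readBin(px$value, integer(), n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
    # row-major pixel order: columns vary fastest
    arr[i, , ] <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE) *
      slope + intercept
  }
  new_ct_volume(arr, c(dz, ps[1L], ps[2L]), identifier = basename(dir))
}
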