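#' Construct a paired Tag/Control image series
#'
#' @param ti Numeric vector of inversion times in ms, ascending.
#' @param tag,control Lists of same-shape numeric matrices (2-D slices)
#'   or 3-D arrays, one per TI, non-negative intensities.
#' @param m0 Either a matrix/array congruent with the images, or the
#'   string `"derived"`: use the control image at the longest TI as the
#'   equilibrium M0 reference (longitudinal recovery nearly complete
#'   there).
#' @return An object of class `image_series`.
#' @export
image_series <- function(ti, tag, control, m0 = "derived") {
  stopifnot(is.numeric(ti), length(ti) >= 1, all(diff(ti) > 0),
            is.list(tag), is.list(control),
            length(tag) == length(ti), length(control) == length(ti))
  dims <- dim(as.array(tag[[1]]))
  chk <- function(x) identical(dim(as.array(x)), dims)
  if (!all(vapply(tag, chk, logical(1))) ||
      !all(vapply(control, chk, logical(1))))
    stop("all tag/control volumes must share the same dimensions")
  if (!identical(m0, "derived") && !chk(m0))
    stop("m0 volume dimensions must match the series")
  structure(list(ti = as.numeric(ti), tag = tag, control = control, m0 = m0),
            class = "image_series")
}

#' Construct an ROI mask
#'
#' @param mask Logical (or 0/1 numeric) matrix or array congruent with
#'   the image grid; at least one voxel must be TRUE.
#' @param label Text label for the region (e.g. `"eSSS"`, `"SSS"`,
#'   `"LU mLV"`).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "ROI") {
  m <- array(as.logical(mask), dim = dim(as.array(mask)))
  if (!any(m)) stop("ROI mask has no voxels")
  structure(list(mask = m, label = label), class = "roi_mask")
}

#' 3x3 median filter for a 2-D image
#'
#' Each output pixel is the exact median of its 3x3 neighborhood, the
#' standard despeckling step applied to Tag and Control images before
#' subtraction. Borders are handled by edge replication by default
#' (zero padding available).
#'
#' @param image Numeric matrix, at least 3x3.
#' @param border `"replicate"` (default) or `"zero"`.
#' @return Filtered matrix of the same shape.
#' @export
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 100
#' median_filter_2d(m)[3, 3]  # impulse removed
median_filter_2d <- function(image, border = c("replicate", "zero")) {
  border <- match.arg(border)
  stopifnot(is.matrix(image), is.numeric(image))
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) stop("image must be at least 3x3 for a 3x3 kernel")
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- image
  if (border == "replicate") {
    pad[1, 2:(nc + 1)] <- image[1, ]
    pad[nr + 2, 2:(nc + 1)] <- image[nr, ]
    pad[, 1] <- pad[, 2]
    pad[, nc + 2] <- pad[, nc + 1]
  }
  # stack the 9 shifted neighborhoods and take the row-wise median
  neigh <- matrix(0, nr * nc, 9L)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    neigh[, k] <- as.vector(pad[di + seq_len(nr), dj + seq_len(nc)])
  }
  ord <- apply(neigh, 1L, function(v) sort.int(v, method = "quick")[5L])
  matrix(ord, nr, nc)
}

# apply a function slice-by-slice for 3-D arrays, directly for matrices
apply_2d <- function(x, fn) {
  if (is.matrix(x)) return(fn(x))
  a <- as.array(x)
  if (length(dim(a)) == 2L) return(fn(matrix(a, dim(a)[1], dim(a)[2])))
  for (k in seq_len(dim(a)[3])) a[, , k] <- fn(a[, , k])
  a
}

#' Compute voxelwise SIR maps for a Tag/Control series
#'
#' For each TI computes `(Tag - Control) / M0` voxelwise, optionally
#' after 3x3 median filtering of both Tag and Control images (applied
#' slice-by-slice for 3-D volumes). Voxels with M0 below a floor
#' (`m0_floor_frac` of the M0 volume's 99th-percentile intensity,
#' background air) are set to `NA` to avoid division blow-up.
#'
#' @param series An [image_series()].
#' @param apply_filter Apply the 3x3 median filter first (default TRUE).
#' @param m0_floor_frac M0 floor as a fraction of the 99th percentile
#'   (default 0.01).
#' @param border Border policy for the median filter.
#' @return A list of class `sir_series`: `ti`, `sir` (list of SIR grids
#'   with `NA` at masked-out voxels), `n_floor` (count of voxels under
#'   the M0 floor), `m0` (the M0 grid used).
#' @export
compute_sir_series <- function(series, apply_filter = TRUE,
                               m0_floor_frac = 0.01,
                               border = "replicate") {
  stopifnot(inherits(series, "image_series"))
  filt <- if (apply_filter)
    function(x) apply_2d(x, function(m) median_filter_2d(m, border))
  else identity
  tag <- lapply(series$tag, filt)
  control <- lapply(series$control, filt)
  m0 <- if (identical(series$m0, "derived"))
    control[[length(control)]] else filt(series$m0)
  m0a <- as.array(m0)
  floor_val <- m0_floor_frac * stats::quantile(m0a, 0.99, names = FALSE)
  bad <- m0a < floor_val | m0a <= 0
  sir <- lapply(seq_along(series$ti), function(k) {
    s <- (as.array(tag[[k]]) - as.array(control[[k]])) / m0a
    s[bad] <- NA_real_
    s
  })
  structure(list(ti = series$ti, sir = sir, n_floor = sum(bad), m0 = m0a),
            class = "sir_series")
}

#' Extract the ROI-mean SIR curve from an SIR series
#'
#' @param sir_series A [compute_sir_series()] result.
#' @param mask An [roi_mask()] congruent with the image grid.
#' @return An [sir_curve()]: per TI, the mean SIR over non-missing mask
#'   voxels, labeled with the ROI label and voxel count.
#' @export
extract_roi_curve <- function(sir_series, mask) {
  stopifnot(inherits(sir_series, "sir_series"), inherits(mask, "roi_mask"))
  if (!identical(dim(mask$mask), dim(as.array(sir_series$sir[[1]]))))
    stop("mask dimensions do not match the SIR grids")
  idx <- which(mask$mask)
  vals <- vapply(seq_along(sir_series$ti), function(k) {
    v <- as.array(sir_series$sir[[k]])[idx]
    v <- v[!is.na(v)]
    if (length(v) == 0)
      stop("empty effective ROI at TI = ", sir_series$ti[k], " ms")
    mean(v)
  }, numeric(1))
  sir_curve(sir_series$ti, vals, label = mask$label, n_voxels = length(idx))
}

#' Read a Time-SLIP image series from NIfTI files and a JSON sidecar
#'
#' The sidecar lists the acquisition:
#' `{"ti_ms": [...], "tag": [paths], "control": [paths],
#'   "m0": path or "derived"}`. Relative paths are resolved against the
#' sidecar's directory. Volumes must be pre-registered; no registration
#' is performed here.
#'
#' @param sidecar Path to the JSON sidecar.
#' @return An [image_series()].
#' @export
read_image_series <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("ti_ms", "tag", "control")
  if (!all(need %in% names(meta)))
    stop("sidecar must contain fields: ", paste(need, collapse = ", "))
  root <- dirname(normalizePath(sidecar))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(root, p)
  rd <- function(p) {
    a <- RNifti::readNifti(resolve(p))
    array(as.numeric(a), dim = dim(a))
  }
  tag <- lapply(meta$tag, rd)
  control <- lapply(meta$control, rd)
  m0 <- if (is.null(meta$m0) || identical(meta$m0, "derived")) "derived"
        else rd(meta$m0)
  image_series(meta$ti_ms, tag, control, m0)
}

#' Write an image series to NIfTI files plus a JSON sidecar
#'
#' Inverse of [read_image_series()]; file names are
#' `tag_<TI>ms.nii.gz` / `control_<TI>ms.nii.gz` under `dir`.
#'
#' @param series An [image_series()].
#' @param dir Output directory (created if needed).
#' @param voxel_mm Voxel size recorded in the NIfTI headers (default 1).
#' @return Path of the written sidecar, invisibly.
#' @export
write_image_series <- function(series, dir, voxel_mm = 1) {
  stopifnot(inherits(series, "image_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(img, name) {
    path <- file.path(dir, name)
    RNifti::writeNifti(RNifti::asNifti(as.array(img), pixdim = rep(voxel_mm, 3)),
                       path)
    name
  }
  tagf <- vapply(seq_along(series$ti), function(k)
    wr(series$tag[[k]], sprintf("tag_%04.0fms.nii.gz", series$ti[k])),
    character(1))
  ctlf <- vapply(seq_along(series$ti), function(k)
    wr(series$control[[k]], sprintf("control_%04.0fms.nii.gz", series$ti[k])),
    character(1))
  meta <- list(ti_ms = series$ti, tag = tagf, control = ctlf,
               m0 = if (identical(series$m0, "derived")) "derived"
                    else wr(series$m0, "m0.nii.gz"))
  sidecar <- file.path(dir, "series.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Write an ROI mask to NIfTI
#'
#' @param mask An [roi_mask()].
#' @param path Output .nii/.nii.gz path.
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask$mask),
                                           dim = dim(mask$mask))), path)
  invisible(path)
}

#' Read an ROI mask from NIfTI
#'
#' Voxels greater than 0.5 are in the region.
#'
#' @param path A .nii/.nii.gz mask volume.
#' @param label ROI label to attach.
#' @return An [roi_mask()].
#' @export
read_roi_mask <- function(path, label = "ROI") {
  a <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(a) > 0.5, dim = dim(a)), label = label)
}
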