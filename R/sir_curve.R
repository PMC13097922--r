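#' Construct a sampled SIR curve
#'
#' A signal increase ratio (SIR) curve: dimensionless
#' `(Tag - Control) / M0` values sampled at a strictly increasing sequence
#' of inversion times.
#'
#' @param ti Numeric vector of inversion times in ms, strictly increasing.
#' @param sir Numeric vector of SIR values, same length as `ti`. Negative
#'   samples are allowed (noise); the models, not the data, are
#'   non-negative.
#' @param label Optional character label (e.g. an ROI name).
#' @param n_voxels Optional integer, number of voxels averaged per sample.
#' @return An object of class `sir_curve`.
#' @export
#' @examples
#' sir_curve(ti = c(500, 1000, 2000, 3000), sir = c(0.05, 0.4, 0.3, 0.1))
sir_curve <- function(ti, sir, label = NULL, n_voxels = NULL) {
  stopifnot(is.numeric(ti), is.numeric(sir))
  if (length(ti) != length(sir))
    stop("ti and sir must have the same length")
  if (any(!is.finite(ti)) || any(!is.finite(sir)))
    stop("ti and sir must be finite")
  if (length(ti) > 1 && any(diff(ti) <= 0))
    stop("ti must be strictly increasing")
  structure(list(ti = as.numeric(ti), sir = as.numeric(sir),
                 label = label, n_voxels = n_voxels),
            class = "sir_curve")
}

#' @export
print.sir_curve <- function(x, ...) {
  cat("SIR curve", if (!is.null(x$label)) paste0("[", x$label, "]"),
      sprintf("- %d samples, TI %g-%g ms, max SIR %.4g\n",
              length(x$ti), min(x$ti), max(x$ti), max(x$sir)))
  invisible(x)
}

#' @export
as.data.frame.sir_curve <- function(x, ...) {
  data.frame(ti_ms = x$ti, sir = x$sir,
             n_voxels = if (is.null(x$n_voxels)) NA_integer_ else x$n_voxels,
             roi_label = if (is.null(x$label)) NA_character_ else x$label,
             stringsAsFactors = FALSE)
}

#' Read an SIR curve from CSV or JSON
#'
#' CSV files must have columns `ti_ms` and `sir` (optional `roi_label`,
#' `n_voxels`); JSON files an object with fields `ti_ms` and `sir`.
#'
#' @param path File path; format chosen by extension (.csv or .json).
#' @return An `sir_curve` object.
#' @export
read_sir_curve <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("ti_ms", "sir") %in% names(d)))
      stop("CSV must contain columns ti_ms and sir: ", path)
    lab <- if ("roi_label" %in% names(d) && !all(is.na(d$roi_label)))
      d$roi_label[1] else NULL
    nv <- if ("n_voxels" %in% names(d) && !all(is.na(d$n_voxels)))
      d$n_voxels[1] else NULL
    sir_curve(d$ti_ms, d$sir, label = lab, n_voxels = nv)
  } else if (ext == "json") {
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!all(c("ti_ms", "sir") %in% names(d)))
      stop("JSON must contain fields ti_ms and sir: ", path)
    sir_curve(d$ti_ms, d$sir, label = d$roi_label, n_voxels = d$n_voxels)
  } else stop("unsupported curve format: ", path)
}

#' Write an SIR curve to CSV or JSON
#'
#' @param curve An `sir_curve` object.
#' @param path Output path; format chosen by extension (.csv or .json).
#' @return `path`, invisibly.
#' @export
write_sir_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sir_curve"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  } else if (ext == "json") {
    obj <- list(ti_ms = curve$ti, sir = curve$sir)
    if (!is.null(curve$label)) obj$roi_label <- curve$label
    if (!is.null(curve$n_voxels)) obj$n_voxels <- curve$n_voxels
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported curve format: ", path)
  invisible(path)
}
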