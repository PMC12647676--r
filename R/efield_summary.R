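#' Peak E-field strength of a voxel field
#'
#' The peak is defined as the 95th percentile of the E-field magnitude over
#' grey-matter voxels, which avoids the partial-volume sensitivity of the
#' single hottest voxel. Percentiles use the linear-interpolation
#' convention between order statistics (type 7).
#'
#' @param field a voxel field: list with `values` (3-D numeric array, V/m),
#'   `gm_mask` (logical array, same dims) and `voxel_volume` (mm^3).
#' @param probs percentile to extract (default 0.95).
#' @return peak E-field strength in V/m.
#' @export
peak_efield <- function(field, probs = 0.95) {
  v <- masked_values(field)
  unname(stats::quantile(v, probs = probs, type = 7))
}

masked_values <- function(field) {
  stopifnot(is.list(field), !is.null(field$values), !is.null(field$gm_mask))
  if (!all(dim(field$values) == dim(field$gm_mask)))
    stop("values and gm_mask dimensions differ", call. = FALSE)
  v <- field$values[field$gm_mask]
  if (length(v) == 0L)
    stop("degenerate input: grey-matter mask is empty", call. = FALSE)
  v
}

#' Reject extreme per-montage peak E-field outliers
#'
#' Values outside the Tukey-style fences `[Q1 - k*IQR, Q3 + k*IQR]` are
#' rejected; the dataset QC rule uses `k = 3` per montage. Quartiles use
#' the same linear-interpolation convention as [peak_efield()]. An
#' alternative reading of the fence, median +/- k*IQR, is selectable.
#'
#' @param values numeric vector of peak E-field strengths for one montage.
#' @param k IQR multiplier (default 3).
#' @param method `"tukey"` (quartile fences, default) or `"median"`.
#' @return list with integer vectors `kept` and `rejected` (indices into
#'   `values`) plus the fence `bounds`.
#' @export
reject_outliers <- function(values, k = 3, method = c("tukey", "median")) {
  method <- match.arg(method)
  if (length(values) < 4L)
    stop("insufficient data: need at least 4 values for quartiles",
         call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  bounds <- if (method == "tukey") {
    c(q[1L] - k * iqr, q[3L] + k * iqr)
  } else {
    c(q[2L] - k * iqr, q[2L] + k * iqr)
  }
  keep <- values >= bounds[1L] & values <= bounds[2L]
  list(kept = which(keep), rejected = which(!keep), bounds = bounds)
}

#' Apply the per-montage outlier rule to a peak E-field table
#'
#' @param efields data frame with `participant_id`, `montage_id`, `peak_e`.
#' @param k IQR multiplier.
#' @param method fence convention, see [reject_outliers()].
#' @return `efields` with a logical `qc_keep` column.
#' @export
qc_efield_table <- function(efields, k = 3, method = c("tukey", "median")) {
  method <- match.arg(method)
  efields$qc_keep <- TRUE
  for (m in unique(efields$montage_id)) {
    idx <- which(efields$montage_id == m)
    res <- reject_outliers(efields$peak_e[idx], k = k, method = method)
    efields$qc_keep[idx[res$rejected]] <- FALSE
  }
  efields
}

#' Focality of a voxel field
#'
#' Grey-matter volume whose E-field strength equals or exceeds 75% of the
#' 99.9th percentile of the masked E-field distribution. The threshold is
#' relative, so focality is invariant under positive rescaling of the
#' field.
#'
#' @inheritParams peak_efield
#' @return focal volume in mm^3.
#' @export
focality <- function(field) {
  v <- masked_values(field)
  vol <- if (is.null(field$voxel_volume)) 1 else field$voxel_volume
  thr <- 0.75 * stats::quantile(v, 0.999, type = 7, names = FALSE)
  vol * sum(v >= thr)
}
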