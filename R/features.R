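#' Apply the inverse of an affine transform to points
#'
#' Maps points given in MNI152 coordinates back to a participant's native
#' space by applying the inverse of the native-to-MNI affine in homogeneous
#' coordinates. Points are row vectors in mm, RAS axis convention.
#'
#' @param points numeric matrix, n x 3, one point per row (mm).
#' @param transform 4 x 4 homogeneous affine mapping native -> MNI152.
#' @return n x 3 matrix of native-space points (mm).
#' @export
apply_inverse_affine <- function(points, transform) {
  points <- as_points3(points)
  check_affine(transform)
  inv <- tryCatch(solve(transform),
                  error = function(e) stop("affine transform is singular: ",
                                           conditionMessage(e), call. = FALSE))
  hom <- cbind(points, 1)
  out <- hom %*% t(inv)
  out[, 1:3, drop = FALSE]
}

as_points3 <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop("points must be n x 3", call. = FALSE)
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3", call. = FALSE)
  storage.mode(points) <- "double"
  points
}

check_affine <- function(transform) {
  if (!is.matrix(transform) || !all(dim(transform) == c(4L, 4L)))
    stop("transform must be a 4 x 4 matrix", call. = FALSE)
  if (!isTRUE(all.equal(transform[4, ], c(0, 0, 0, 1))))
    stop("transform bottom row must be (0, 0, 0, 1)", call. = FALSE)
  invisible(transform)
}

#' Head circumference from template contour points
#'
#' The circumference is measured by placing an ordered set of points around
#' the measurement plane of the MNI152 template, mapping them to native
#' space with the inverse of the participant's affine, and summing the
#' Euclidean distances around the closed polygon (the closing segment from
#' the last point back to the first is included).
#'
#' @param template_points ordered contour points in MNI152 space, n x 3 mm.
#' @param transform 4 x 4 native -> MNI152 affine.
#' @return circumference in mm.
#' @export
head_circumference <- function(template_points, transform = diag(4)) {
  pts <- as_points3(template_points)
  if (nrow(pts) < 3L)
    stop("degenerate contour: need at least 3 points", call. = FALSE)
  native <- apply_inverse_affine(pts, transform)
  closed <- rbind(native, native[1L, , drop = FALSE])
  seg <- diff(closed)
  sum(sqrt(rowSums(seg^2)))
}

#' Head length and width from a planar outline
#'
#' Length is the extent of the outline along the anterior-posterior axis;
#' width is the maximum extent along the in-plane perpendicular axis. The
#' axis is supplied as metadata (the measurement plane is fixed on the
#' template), so no axis re-estimation is performed.
#'
#' @param outline n x 2 matrix of in-plane points (mm), n >= 4.
#' @param ap_axis length-2 unit vector giving the anterior-posterior axis
#'   within the plane (default the second in-plane coordinate).
#' @return named numeric vector `c(length = , width = )` in mm.
#' @export
head_length_width <- function(outline, ap_axis = c(0, 1)) {
  outline <- as.matrix(outline)
  if (ncol(outline) != 2L || nrow(outline) < 4L)
    stop("outline must be an n x 2 matrix with n >= 4", call. = FALSE)
  ap <- ap_axis / sqrt(sum(ap_axis^2))
  perp <- c(-ap[2L], ap[1L])
  centered <- sweep(outline, 2L, colMeans(outline))
  sv <- svd(centered, nu = 0, nv = 0)$d
  if (sv[2L] < 1e-9 * max(sv[1L], 1))
    stop("degenerate contour: points are collinear", call. = FALSE)
  proj_ap <- outline %*% ap
  proj_pp <- outline %*% perp
  c(length = max(proj_ap) - min(proj_ap),
    width = max(proj_pp) - min(proj_pp))
}

#' Cephalic index
#'
#' Head width divided by head length, multiplied by 100.
#'
#' @param width head width in mm.
#' @param length head length in mm.
#' @return dimensionless index.
#' @export
cephalic_index <- function(width, length) {
  if (any(width <= 0) || any(length <= 0))
    stop("width and length must be positive", call. = FALSE)
  100 * width / length
}

#' Inter-electrode distance for a montage geometry
#'
#' For a conventional montage (one cathode) this is the Euclidean distance
#' between the anode and cathode midpoints. For a high-definition (HD)
#' montage (four return electrodes) it is the arithmetic mean of the four
#' anode-return distances. Invariant under rigid transforms of all
#' midpoints.
#'
#' @param geometry list with `anode_midpoint` (length-3) and
#'   `cathode_midpoints` (k x 3 matrix, k = 1 conventional or 4 HD), mm.
#' @return distance in mm.
#' @export
inter_electrode_distance <- function(geometry) {
  anode <- as_points3(geometry$anode_midpoint)
  cath <- as_points3(geometry$cathode_midpoints)
  if (!nrow(cath) %in% c(1L, 4L))
    stop("montage shape error: expected 1 (conventional) or 4 (HD) cathode midpoints, got ",
         nrow(cath), call. = FALSE)
  d <- sqrt(rowSums(sweep(cath, 2L, anode[1L, ])^2))
  mean(d)
}

#' Impute missing BMI values with a reference median
#'
#' @param values numeric BMI values (kg/m^2), possibly containing `NA`.
#' @param reference_median imputation value (kg/m^2); the cohort median of
#'   the calculable BMIs is the conventional choice.
#' @return complete numeric vector.
#' @export
impute_bmi <- function(values, reference_median) {
  if (!is.numeric(reference_median) || length(reference_median) != 1L ||
      reference_median <= 0)
    stop("reference_median must be a positive scalar", call. = FALSE)
  values[is.na(values)] <- reference_median
  values
}

#' Fit standardization parameters on training data
#'
#' Each predictor is standardized by the rule matching its distribution:
#' min-max scaling for the (uniform) age, z-scoring for head circumference,
#' cephalic index and per-montage peak E-field strength, and median/IQR
#' scaling for the right-skewed BMI. Inter-electrode distance, when
#' supplied, is z-scored. All parameters are computed from the training
#' rows only and carried with every fitted model.
#'
#' @param cohort data frame with columns `age`, `head_circumference`,
#'   `cephalic_index`, `bmi` (complete, i.e. already imputed) and `gender`.
#' @param efields optional data frame with `montage_id` and `peak_e`
#'   (V/m at 1 mA) used for the per-montage outcome standardization.
#' @param ed optional numeric vector of raw inter-electrode distances (mm).
#' @param fitted_on identifier of the training fold (bookkeeping).
#' @return object of class `tes_standardizer`.
#' @export
fit_standardizer <- function(cohort, efields = NULL, ed = NULL,
                             fitted_on = "all") {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0L)
  need <- c("age", "head_circumference", "cephalic_index", "bmi")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(cohort$bmi))
    stop("bmi must be complete (impute first)", call. = FALSE)

  zcheck <- function(x, name) {
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0)
      stop("degenerate feature: zero variance in ", name, call. = FALSE)
    s
  }
  p <- list(
    age_min = min(cohort$age), age_max = max(cohort$age),
    hc_mean = mean(cohort$head_circumference),
    hc_sd = zcheck(cohort$head_circumference, "head_circumference"),
    ci_mean = mean(cohort$cephalic_index),
    ci_sd = zcheck(cohort$cephalic_index, "cephalic_index"),
    bmi_median = stats::median(cohort$bmi),
    bmi_iqr = stats::IQR(cohort$bmi, type = 7),
    fitted_on = fitted_on
  )
  if (p$age_max <= p$age_min)
    stop("degenerate feature: zero range in age", call. = FALSE)
  if (p$bmi_iqr <= 0)
    stop("degenerate feature: zero IQR in bmi", call. = FALSE)
  if (!is.null(efields)) {
    sp <- split(efields$peak_e, efields$montage_id)
    p$peak_e <- lapply(sp, function(v) {
      s <- zcheck(v, "peak_e")
      list(mean = mean(v), sd = s)
    })
  }
  if (!is.null(ed)) {
    p$ed_mean <- mean(ed)
    p$ed_sd <- zcheck(ed, "inter-electrode distance")
  }
  structure(p, class = "tes_standardizer")
}

#' Standardize cohort features
#'
#' Applies the fitted per-feature standardization rules and encodes gender
#' as 1 (male) / 0 (female). Ages outside the training range extrapolate
#' linearly; no clipping is applied.
#'
#' @param cohort data frame as in [fit_standardizer()]; `gender` must be
#'   `"male"` or `"female"`.
#' @param params a `tes_standardizer`.
#' @param ed optional raw inter-electrode distances (mm) to standardize
#'   alongside (requires ED statistics in `params`).
#' @return data frame with columns `x_age`, `x_hc`, `x_ci`, `x_bmi`,
#'   `x_gender` and, when `ed` is given, `x_ed` (standardized) and
#'   `ed_raw` (mm).
#' @export
standardize_features <- function(cohort, params, ed = NULL) {
  stopifnot(inherits(params, "tes_standardizer"))
  g <- as.character(cohort$gender)
  bad <- setdiff(unique(g), c("male", "female"))
  if (length(bad))
    stop("encoding error: unknown gender label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyNA(cohort$bmi))
    stop("bmi must be complete (impute first)", call. = FALSE)
  out <- data.frame(
    x_age = (cohort$age - params$age_min) / (params$age_max - params$age_min),
    x_hc = (cohort$head_circumference - params$hc_mean) / params$hc_sd,
    x_ci = (cohort$cephalic_index - params$ci_mean) / params$ci_sd,
    x_bmi = (cohort$bmi - params$bmi_median) / params$bmi_iqr,
    x_gender = as.numeric(g == "male")
  )
  if (!is.null(ed)) {
    if (is.null(params$ed_mean))
      stop("params carry no inter-electrode distance statistics", call. = FALSE)
    out$x_ed <- (ed - params$ed_mean) / params$ed_sd
    out$ed_raw <- ed
  }
  out
}

#' Standardize / back-transform peak E-field strengths per montage
#'
#' @param e peak E-field values (V/m) or standardized values for the
#'   inverse direction.
#' @param params a `tes_standardizer` fitted with outcome statistics.
#' @param montage_id montage whose statistics to use.
#' @return standardized values (`standardize_outcome`) or V/m
#'   (`unstandardize_outcome`).
#' @export
standardize_outcome <- function(e, params, montage_id) {
  st <- outcome_stats(params, montage_id)
  (e - st$mean) / st$sd
}

#' @rdname standardize_outcome
#' @export
unstandardize_outcome <- function(e, params, montage_id) {
  st <- outcome_stats(params, montage_id)
  e * st$sd + st$mean
}

outcome_stats <- function(params, montage_id) {
  stopifnot(inherits(params, "tes_standardizer"))
  if (is.null(params$peak_e) || is.null(params$peak_e[[montage_id]]))
    stop("no outcome statistics for montage ", montage_id, call. = FALSE)
  params$peak_e[[montage_id]]
}

#' Regular contour of template points for circumference measurement
#'
#' Generates `n` ordered points on a circle of radius `radius` mm in the
#' z = `z` transverse plane, emulating the template measurement contour.
#'
#' @param n number of points (default 60).
#' @param radius circle radius in mm.
#' @param z plane height in mm.
#' @return n x 3 matrix.
#' @export
template_contour <- function(n = 60L, radius = 100, z = 0) {
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(radius * cos(theta), radius * sin(theta), z)
}
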