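# Left atrial shape statistics from six center-of-mass radial measurements.
#
# The atrium is measured along its three principal axes; each axis is split by
# the center of mass into two radii, giving A1, B1 (transverse), A2, B2
# (superior-inferior) and A3, B3 (anteroposterior), all in mm. All shape
# statistics below are functions of those six radii.

RADII_COLS <- c("a1", "b1", "a2", "b2", "a3", "b3")

#' Assemble and validate a matrix of LA radial measurements
#'
#' Accepts a single patient's six radii, an n-by-6 matrix, or a data frame
#' with columns `a1, b1, a2, b2, a3, b3` (mm), and returns a validated
#' numeric matrix with those columns.
#'
#' @param r numeric vector of length 6 (ordered a1, b1, a2, b2, a3, b3),
#'   an n-by-6 matrix, or a data frame carrying the six radius columns.
#' @param check_windows if `TRUE`, additionally require each derived diameter
#'   (a1+b1, a2+b2, a3+b3) to fall in the anatomical plausibility window
#'   `window` (mm). Off by default so synthetic stress tests can explore
#'   arbitrary positive radii.
#' @param window length-2 numeric, the diameter plausibility window in mm.
#' @return an n-by-6 numeric matrix with columns `a1, b1, a2, b2, a3, b3`.
#' @export
#' @examples
#' as_radii(c(30, 30, 30, 30, 30, 30))
as_radii <- function(r, check_windows = FALSE, window = c(20, 150)) {
  if (is.data.frame(r)) {
    missing <- setdiff(RADII_COLS, names(r))
    if (length(missing)) {
      stop("missing radius column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    r <- as.matrix(r[RADII_COLS])
  } else if (is.null(dim(r))) {
    if (length(r) != 6L) {
      stop("a single measurement set must have exactly 6 radii", call. = FALSE)
    }
    r <- matrix(as.numeric(r), nrow = 1L, dimnames = list(NULL, RADII_COLS))
  } else {
    if (ncol(r) != 6L) stop("radius matrix must have 6 columns", call. = FALSE)
    r <- as.matrix(r)
    colnames(r) <- RADII_COLS
  }
  storage.mode(r) <- "double"
  if (anyNA(r) || any(!is.finite(r))) {
    stop("radii must be finite and non-missing", call. = FALSE)
  }
  if (any(r <= 0)) {
    stop("all six radii must be strictly positive", call. = FALSE)
  }
  if (check_windows) {
    d <- derive_diameters(r)
    bad <- which(d < window[1] | d > window[2], arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "diameter outside plausibility window [%g, %g] mm (first offender: row %d, %s)",
        window[1], window[2], bad[1, 1], colnames(d)[bad[1, 2]]
      ), call. = FALSE)
    }
  }
  r
}

#' Average radius of the left atrium
#'
#' The arithmetic mean of the six radii; the radius of the sphere best
#' fitting the atrium.
#'
#' @inheritParams as_radii
#' @return numeric vector (mm), one value per measurement set.
#' @export
#' @examples
#' average_radius(c(40, 32, 35, 29, 27, 23)) # 31
average_radius <- function(r, check_windows = FALSE) {
  r <- as_radii(r, check_windows)
  rowMeans(r)
}

# row-wise SD of the six radii under either divisor convention
radial_sd <- function(r, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  m <- rowMeans(r)
  ss <- rowSums((r - m)^2)
  denom <- if (sd_mode == "sample") 5 else 6
  sqrt(ss / denom)
}

#' Left atrial sphericity
#'
#' Sphericity is `(1 - CVS) * 100` where `CVS = SDR / AR` is the coefficient
#' of variation of the six radii (SDR their standard deviation, AR their
#' mean). 100 means a perfect sphere (all six radii equal); more dispersed
#' radii give lower values. The divisor in the SD is configurable because
#' published sphericity values do not state which convention was used;
#' the default is the sample SD (n - 1), matching common statistical
#' software. Population-SD sphericities are about 9% closer to 100 in
#' relative distance (sd ratio sqrt(5/6)).
#'
#' @inheritParams as_radii
#' @param sd_mode `"sample"` (n - 1 divisor, default) or `"population"` (n).
#' @return numeric vector of sphericities in percent (<= 100).
#' @export
#' @examples
#' sphericity(c(30, 30, 30, 30, 30, 30)) # 100
sphericity <- function(r, sd_mode = c("sample", "population"),
                       check_windows = FALSE) {
  r <- as_radii(r, check_windows)
  (1 - radial_sd(r, sd_mode) / rowMeans(r)) * 100
}

#' Volume coefficient of the left atrium
#'
#' The sum of the cubes of the six radii (mm^3). Its interpretation as a
#' volume estimate: `(2 * pi / 9) * VC` equals the mean of the volumes of
#' the six spheres with radii a1, b1, a2, b2, a3, b3, since
#' mean(4/3 * pi * r^3) = (4 * pi / 18) * sum(r^3).
#'
#' @inheritParams as_radii
#' @return numeric vector (mm^3).
#' @export
#' @examples
#' volume_coefficient(rep(30, 6)) # 6 * 30^3 = 162000
volume_coefficient <- function(r, check_windows = FALSE) {
  r <- as_radii(r, check_windows)
  rowSums(r^3)
}

#' Principal-axis diameters from the radii
#'
#' @inheritParams as_radii
#' @return an n-by-3 matrix with columns `d_transverse` (a1+b1),
#'   `d_supinf` (a2+b2) and `d_anteropost` (a3+b3), in mm.
#' @export
derive_diameters <- function(r, check_windows = FALSE) {
  r <- as_radii(r, check_windows)
  cbind(
    d_transverse = r[, "a1"] + r[, "b1"],
    d_supinf     = r[, "a2"] + r[, "b2"],
    d_anteropost = r[, "a3"] + r[, "b3"]
  )
}

#' All LA shape metrics for one or more measurement sets
#'
#' Bundles [average_radius()], the radial SD, the coefficient of variation,
#' [sphericity()], [volume_coefficient()] and [derive_diameters()] into one
#' data frame, one row per measurement set.
#'
#' @inheritParams sphericity
#' @return a data frame with columns `ar`, `sdr`, `cvs`, `lasp`, `vc`,
#'   `d_transverse`, `d_supinf`, `d_anteropost`.
#' @export
#' @examples
#' shape_metrics(c(40, 32, 35, 29, 27, 23))
shape_metrics <- function(r, sd_mode = c("sample", "population"),
                          check_windows = FALSE) {
  r <- as_radii(r, check_windows)
  ar <- rowMeans(r)
  sdr <- radial_sd(r, sd_mode)
  cvs <- sdr / ar
  d <- derive_diameters(r)
  data.frame(
    ar = ar, sdr = sdr, cvs = cvs, lasp = (1 - cvs) * 100,
    vc = rowSums(r^3),
    d_transverse = d[, "d_transverse"],
    d_supinf = d[, "d_supinf"],
    d_anteropost = d[, "d_anteropost"]
  )
}

#' Append shape-metric columns to a cohort table
#'
#' Convenience wrapper for cohort CSVs: computes [shape_metrics()] from the
#' radius columns and binds the results (plus `vc_scaled = vc / 10000`, the
#' unit the discriminant uses, and `la_volume_cm3 = (2 pi / 9) vc / 1000`,
#' the sphere-volume interpretation of VC) onto the input.
#'
#' @param cohort data frame with columns `a1, b1, a2, b2, a3, b3` (mm).
#' @inheritParams sphericity
#' @return `cohort` with the shape-metric columns appended.
#' @export
add_shape_metrics <- function(cohort, sd_mode = c("sample", "population"),
                              check_windows = FALSE) {
  sm <- shape_metrics(cohort, sd_mode, check_windows)
  sm$vc_scaled <- sm$vc / 10000
  sm$la_volume_cm3 <- (2 * pi / 9) * sm$vc / 1000
  clash <- intersect(names(sm), names(cohort))
  if (length(clash)) cohort <- cohort[setdiff(names(cohort), clash)]
  cbind(cohort, sm)
}
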