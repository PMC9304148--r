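#' Size-exclusion chromatography calibration line
#'
#' Log-linear calibration of a Superdex200-class analytical column:
#' log10(Mr) = intercept - slope * Ve, with Mr in daltons and the elution
#' volume Ve in ml. Defaults are the column calibration constants used for
#' the apparent-mass estimates (intercept 8.1537, slope 0.2316 per ml).
#'
#' @param intercept,slope Calibration constants.
#' @param ve_range Elution-volume range over which the calibration is
#'   trusted (ml); queries outside it warn.
#' @return Object of class \code{sec_calibration}.
#' @export
sec_calibration <- function(intercept = 8.1537, slope = 0.2316,
                            ve_range = c(8, 20)) {
  if (slope <= 0) stop("slope must be positive (Mr decreases with Ve)")
  structure(list(intercept = intercept, slope = slope, ve_range = ve_range),
            class = "sec_calibration")
}

#' Apparent molecular mass from an elution volume
#'
#' @param ve Elution volume in ml (positive).
#' @param calib A \code{sec_calibration}.
#' @return Apparent Mr in kDa.
#' @export
sec_apparent_mr <- function(ve, calib = sec_calibration()) {
  if (any(ve <= 0)) stop("elution volume must be positive")
  out <- any(ve < calib$ve_range[1] | ve > calib$ve_range[2])
  if (out) warning("elution volume outside calibrated range (",
                   calib$ve_range[1], "-", calib$ve_range[2], " ml)")
  10^(calib$intercept - calib$slope * ve) / 1000
}

#' Elution volume at which a given mass would elute
#'
#' Algebraic inverse of \code{sec_apparent_mr}.
#'
#' @param mr_kda Molecular mass in kDa (positive).
#' @param calib A \code{sec_calibration}.
#' @return Elution volume in ml.
#' @export
sec_elution_volume <- function(mr_kda, calib = sec_calibration()) {
  if (any(mr_kda <= 0)) stop("mass must be positive")
  (calib$intercept - log10(mr_kda * 1000)) / calib$slope
}

#' Call the oligomeric state from apparent and protomer masses
#'
#' @param apparent_mr Apparent Mr from SEC, in kDa.
#' @param protomer_mr Protomer Mr (sequence or mass-spectrometry), kDa.
#' @param tol Relative tolerance for the call (default 0.25).
#' @return list with \code{n} (nearest positive integer of the ratio),
#'   \code{apparent_mr}, \code{protomer_mr}, \code{deviation} (relative)
#'   and \code{within_tolerance}.
#' @export
call_oligomer <- function(apparent_mr, protomer_mr, tol = 0.25) {
  if (apparent_mr <= 0 || protomer_mr <= 0) stop("masses must be positive")
  n <- max(1L, as.integer(round(apparent_mr / protomer_mr)))
  dev <- abs(apparent_mr - n * protomer_mr) / (n * protomer_mr)
  list(n = n, apparent_mr = apparent_mr, protomer_mr = protomer_mr,
       deviation = dev, within_tolerance = dev <= tol)
}

#' Pick elution peaks from a SEC trace
#'
#' Local-maximum peak picking (via pracma) on an absorbance trace,
#' returning elution volumes and apparent masses.
#'
#' @param ve Elution-volume grid (ml).
#' @param absorbance Absorbance values on the grid.
#' @param min_height Minimum peak height relative to the trace maximum
#'   (default 0.2).
#' @param min_separation Minimum separation between reported peaks in ml
#'   (default 0.5); of nearby local maxima only the highest is kept, so
#'   noise bumps on a peak flank are not called twice.
#' @param calib A \code{sec_calibration}.
#' @return data frame with \code{ve}, \code{height}, \code{apparent_mr}
#'   (kDa), ordered by elution volume.
#' @export
sec_pick_peaks <- function(ve, absorbance, min_height = 0.2,
                           min_separation = 0.5,
                           calib = sec_calibration()) {
  step <- stats::median(diff(ve))
  pk <- pracma::findpeaks(absorbance,
                          minpeakheight = min_height * max(absorbance),
                          minpeakdistance = max(1L, round(min_separation / step)))
  if (is.null(pk)) {
    return(data.frame(ve = numeric(), height = numeric(),
                      apparent_mr = numeric()))
  }
  out <- data.frame(ve = ve[pk[, 2]], height = pk[, 1])
  out <- out[order(out$ve), , drop = FALSE]
  out$apparent_mr <- sec_apparent_mr(out$ve, calib)
  rownames(out) <- NULL
  out
}
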