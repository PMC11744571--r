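#' Packaged nine-ROI channel montage
#'
#' Channel-to-region assignment for the 49 analysis channels grouped into nine
#' regions of interest (medial frontal; left/right superior frontal, middle
#' frontal, precentral, parietal), with 760/850 nm wavelengths and a ~3 cm
#' inter-optode distance. Channels not listed in the montage are unassigned
#' and excluded from ROI averaging.
#'
#' @return List of class `fnirs_montage` with `assignment` (data frame:
#'   `channel`, `roi`, `roi_label`), `wavelengths_nm`, `distance_cm`, `fs_hz`.
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage_9roi.csv", package = "brainbreaks")
  assignment <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(
    list(
      assignment = assignment,
      wavelengths_nm = c(760, 850),
      distance_cm = 3,
      fs_hz = 10.2
    ),
    class = "fnirs_montage"
  )
}

#' Modified Beer-Lambert law parameters
#'
#' Extinction coefficients (1/(mM cm)) for HbO/HbR at the montage wavelengths,
#' the inter-optode distance, and the differential pathlength factor (default
#' 6). The packaged coefficients derive from standard tabulated hemoglobin
#' spectra (Gratzer/Prahl compilation); both are overridable.
#'
#' @param dpf Differential pathlength factor (> 0).
#' @param distance_cm Inter-optode distance in cm.
#' @param extinction 2x2 matrix, rows = wavelengths (760, 850 nm), columns =
#'   `c("hbo", "hbr")`; default read from the packaged table.
#' @return List of class `mbll_params`.
#' @export
mbll_params <- function(dpf = 6, distance_cm = 3, extinction = NULL) {
  check_positive(dpf, "dpf")
  check_positive(distance_cm, "distance_cm")
  if (is.null(extinction)) {
    path <- system.file("extdata", "extinction_coefficients.csv",
                        package = "brainbreaks")
    tab <- read.csv(path, comment.char = "#")
    extinction <- as.matrix(tab[, c("e_hbo", "e_hbr")])
    dimnames(extinction) <- list(paste0("nm", tab$wavelength_nm), c("hbo", "hbr"))
  }
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2L, 2L))) {
    stop_config("extinction matrix must be 2 wavelengths x 2 chromophores")
  }
  if (kappa(extinction) >= 100) {
    stop_config("extinction matrix is ill-conditioned (condition number >= 100)")
  }
  structure(list(dpf = dpf, distance_cm = distance_cm, extinction = extinction),
            class = "mbll_params")
}

#' Convert raw light intensities to optical density
#'
#' OD(t) = -log10(I(t) / mean(I)) per channel, so each channel's OD series is
#' approximately zero-mean and dimensionless.
#'
#' @param intensity Numeric matrix, time in rows, channels in columns.
#' @return Matrix of the same shape.
#' @export
intensity_to_od <- function(intensity) {
  intensity <- as.matrix(intensity)
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    bad <- which(!is.finite(intensity) | intensity <= 0, arr.ind = TRUE)[1L, ]
    stop_config("non-positive intensity at sample %d, channel %d", bad[1L], bad[2L])
  }
  -log10(sweep(intensity, 2L, colMeans(intensity), "/"))
}

#' Coefficient-of-variation channel quality check
#'
#' Computes CV = sd/mean per channel per wavelength and excludes a channel
#' when its CV is equal to or higher than the cutoff (default 15%) at either
#' wavelength.
#'
#' @param intensity Matrix (time x channels) of raw intensities for one
#'   wavelength, or a list of such matrices (one per wavelength) sharing
#'   column names.
#' @param cv_cutoff Exclusion threshold on the coefficient of variation.
#' @return List with `retained`, `excluded` (channel names) and `cv` (matrix
#'   wavelength x channel).
#' @export
channel_quality_check <- function(intensity, cv_cutoff = 0.15) {
  if (is.matrix(intensity) || is.data.frame(intensity)) intensity <- list(as.matrix(intensity))
  cv <- t(vapply(intensity, function(m) {
    m <- as.matrix(m)
    apply(m, 2L, sd) / colMeans(m)
  }, numeric(ncol(as.matrix(intensity[[1L]])))))
  channels <- colnames(as.matrix(intensity[[1L]]))
  if (is.null(channels)) channels <- paste0("C", seq_len(ncol(cv)))
  colnames(cv) <- channels
  bad <- apply(cv >= cv_cutoff, 2L, any)
  list(retained = channels[!bad], excluded = channels[bad], cv = cv)
}

#' Convert optical-density changes to hemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert law per sample:
#' `c(t) = solve(E) %*% od(t) / (d * DPF)`, where `E` is the extinction
#' matrix, `d` the inter-optode distance and DPF the differential pathlength
#' factor. Linear in the OD input. Concentrations are in mM under the packaged
#' extinction units.
#'
#' @param od_list List of two OD matrices (time x channels), ordered as the
#'   rows of the extinction matrix (760 nm, 850 nm).
#' @param params An [mbll_params()] object.
#' @return List with matrices `hbo` and `hbr` (time x channels).
#' @export
od_to_hemoglobin <- function(od_list, params = mbll_params()) {
  if (length(od_list) != 2L) stop_config("two wavelengths are required")
  od1 <- as.matrix(od_list[[1L]]); od2 <- as.matrix(od_list[[2L]])
  if (!all(dim(od1) == dim(od2))) stop_config("OD matrices must share dimensions")
  einv <- solve(params$extinction)
  scale <- params$distance_cm * params$dpf
  hbo <- (einv[1L, 1L] * od1 + einv[1L, 2L] * od2) / scale
  hbr <- (einv[2L, 1L] * od1 + einv[2L, 2L] * od2) / scale
  dimnames(hbo) <- dimnames(od1); dimnames(hbr) <- dimnames(od1)
  list(hbo = hbo, hbr = hbr)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 3rd-order Butterworth applied forward-backward (`signal::filtfilt`), so the
#' filter is zero-phase and does not introduce lag distortion into downstream
#' lagged-regression (Granger) analyses. Default band 0.01-0.08 Hz isolates
#' the slow hemodynamic fluctuations from cardiac, respiratory and Mayer-wave
#' physiology.
#'
#' @param x Numeric vector or matrix (time in rows).
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges, Hz (`fs > 2 * high` required).
#' @param order Butterworth order.
#' @return Filtered series, same shape as `x`.
#' @export
bandpass <- function(x, fs = 10.2, low = 0.01, high = 0.08, order = 3L) {
  check_positive(fs, "fs")
  if (high <= low) stop_config("'high' must exceed 'low'")
  if (fs <= 2 * high) stop_config("sampling rate too low for the requested band")
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n < ceiling(9 * fs / low / 100) || n < 12L * order) {
    stop_config("series too short for stable zero-phase filtering")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  apply_fun <- function(v) signal::filtfilt(bf, v)
  if (is.matrix(x)) {
    out <- apply(x, 2L, apply_fun)
    dimnames(out) <- dimnames(x)
    out
  } else {
    apply_fun(x)
  }
}

#' Regress out leading spatial principal components
#'
#' Removes the stated number of leading spatial components (channel-space
#' singular vectors of the centered data) from every channel, suppressing
#' global systemic physiology shared across the array. The cleaned data are
#' orthogonal to the removed components.
#'
#' @param x Matrix (time x channels).
#' @param n_components Number of leading components to remove (0 = identity).
#' @param variance_fraction Alternative to `n_components`: remove the smallest
#'   number of leading components explaining at least this fraction of
#'   variance.
#' @return Matrix of the same shape.
#' @export
pca_denoise <- function(x, n_components = 1L, variance_fraction = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop_config("at least 2 channels are required")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc)
  if (!is.null(variance_fraction)) {
    frac <- cumsum(sv$d^2) / sum(sv$d^2)
    n_components <- which(frac >= variance_fraction)[1L]
  }
  n_components <- as.integer(n_components)
  if (n_components < 0L || n_components >= ncol(x)) {
    stop_config("'n_components' must be in [0, n_channels - 1]")
  }
  if (n_components == 0L) return(x)
  v <- sv$v[, seq_len(n_components), drop = FALSE]
  cleaned <- xc - xc %*% v %*% t(v)
  out <- sweep(cleaned, 2L, mu, "+")
  dimnames(out) <- dimnames(x)
  out
}

#' Average retained channels into ROI time series
#'
#' Unweighted mean of the retained member channels of each ROI. ROIs whose
#' channels were all excluded by quality control are dropped with a warning
#' flag in the output.
#'
#' @param x Matrix (time x channels) with channel names as column names.
#' @param montage A [default_montage()]-style montage.
#' @param retained Character vector of retained channel names (default: all
#'   columns of `x`).
#' @return List with `series` (time x ROI matrix, columns `roi1`..), `n_channels`
#'   (retained member count per ROI) and `dropped_rois`.
#' @export
roi_average <- function(x, montage = default_montage(), retained = colnames(x)) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop_config("'x' must have channel names as column names")
  assignment <- montage$assignment
  rois <- sort(unique(assignment$roi))
  series <- matrix(NA_real_, nrow(x), length(rois),
                   dimnames = list(NULL, paste0("roi", rois)))
  n_channels <- setNames(integer(length(rois)), paste0("roi", rois))
  for (i in seq_along(rois)) {
    members <- assignment$channel[assignment$roi == rois[i]]
    use <- intersect(intersect(members, retained), colnames(x))
    n_channels[i] <- length(use)
    if (length(use)) series[, i] <- rowMeans(x[, use, drop = FALSE])
  }
  dropped <- names(n_channels)[n_channels == 0L]
  if (length(dropped)) {
    warning(sprintf("ROI(s) with no retained channels dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    series <- series[, n_channels > 0L, drop = FALSE]
  }
  list(series = series, n_channels = n_channels, dropped_rois = dropped)
}

#' Full preprocessing chain: intensities to ROI hemoglobin series
#'
#' Runs quality control, OD conversion, band-pass filtering, MBLL inversion,
#' spatial PCA denoising and ROI averaging in the order used for the
#' connectivity analyses. Filtering and MBLL are linear so their order is
#' immaterial; PCA is applied to channel-space hemoglobin before averaging.
#'
#' @param intensity_list List of two intensity matrices (time x channels), one
#'   per wavelength (760, 850 nm).
#' @param montage Channel montage.
#' @param params MBLL parameters.
#' @param cv_cutoff Channel-exclusion CV threshold.
#' @param filter_band Band edges in Hz, or `NULL` to skip filtering.
#' @param pca_components Leading spatial components to remove (0 to skip).
#' @return List with `hbo`, `hbr` (time x ROI), `qc` (channel QC report) and
#'   `n_channels` per ROI.
#' @export
preprocess_recording <- function(intensity_list, montage = default_montage(),
                                 params = mbll_params(), cv_cutoff = 0.15,
                                 filter_band = c(0.01, 0.08),
                                 pca_components = 1L) {
  qc <- channel_quality_check(intensity_list, cv_cutoff = cv_cutoff)
  od <- lapply(intensity_list, intensity_to_od)
  if (!is.null(filter_band)) {
    od <- lapply(od, bandpass, fs = montage$fs_hz,
                 low = filter_band[1L], high = filter_band[2L])
  }
  hb <- od_to_hemoglobin(od, params)
  if (pca_components > 0L) {
    hb$hbo <- pca_denoise(hb$hbo, pca_components)
    hb$hbr <- pca_denoise(hb$hbr, pca_components)
  }
  roi_hbo <- roi_average(hb$hbo, montage, retained = qc$retained)
  roi_hbr <- roi_average(hb$hbr, montage, retained = qc$retained)
  list(hbo = roi_hbo$series, hbr = roi_hbr$series, qc = qc,
       n_channels = roi_hbo$n_channels)
}
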