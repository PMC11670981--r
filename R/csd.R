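# CSD estimation: delta inverse-CSD with a disc forward model, the
# traditional second-derivative estimator, and the channel-sum diagnostic.

#' Disc forward matrix of the delta inverse-CSD method
#'
#' The delta-iCSD method models the CSD as infinitely thin current discs of
#' radius `R` centred at each channel depth. The potential a unit planar
#' density disc at depth `z_i` generates at depth `z_j` is
#' `F[j, i] = (1 / (2 sigma)) * (sqrt(R^2 + (z_j - z_i)^2) - |z_j - z_i|)`,
#' so LFP = F CSD per time bin and the CSD estimate is the inverse map.
#'
#' @param geom a [probe_geometry()] (conductivity and disc radius are taken
#'   from it).
#' @return an N_ch x N_ch forward matrix.
#' @export
csd_forward_matrix <- function(geom) {
  stopifnot(inherits(geom, "probe_geometry"))
  z <- geom$depths_um
  d <- abs(outer(z, z, "-"))
  (sqrt(geom$disc_radius_um^2 + d^2) - d) / (2 * geom$sigma_s_per_m)
}

#' Delta inverse-CSD estimate
#'
#' Inverts the disc forward model per time bin: `CSD = F^{-1} LFP`. The
#' estimate is linear in the LFP and is the exact inverse of
#' [forward_lfp_from_csd()] on the same geometry. Output units are planar
#' source density (current per disc area), consistent up to scaling.
#' Sign convention: sinks negative, sources positive.
#'
#' @param lfp a [recording_matrix()] of kind `"lfp"`.
#' @param geom a [probe_geometry()] matching the LFP channel count.
#' @return a [recording_matrix()] of kind `"csd"`.
#' @export
delta_icsd <- function(lfp, geom) {
  stopifnot(inherits(lfp, "recording_matrix"))
  if (rec_kind(lfp) != "lfp") {
    lp_abort("`delta_icsd()` expects an LFP recording.", "parameter_error")
  }
  check_channel_count(nrow(lfp), geom)
  f <- csd_forward_matrix(geom)
  kappa <- condition_number(f)
  if (!is.finite(kappa) || kappa > 1e12) {
    lp_abort(sprintf("disc forward matrix is ill-conditioned (condition number %.3g).",
                     kappa), "numeric_error")
  }
  csd <- solve(f, unclass(lfp))
  recording_matrix(csd, rec_dt(lfp), rec_t0(lfp), "csd",
                   depths_um = geom$depths_um)
}

#' Forward LFP from a CSD
#'
#' Applies the disc forward model `LFP = F CSD`; the exact inverse of
#' [delta_icsd()]. Used by the synthetic generator to produce LFP from a
#' planted CSD.
#'
#' @param csd a [recording_matrix()] of kind `"csd"`.
#' @param geom a [probe_geometry()] matching the channel count.
#' @return a [recording_matrix()] of kind `"lfp"`.
#' @export
forward_lfp_from_csd <- function(csd, geom) {
  stopifnot(inherits(csd, "recording_matrix"))
  if (rec_kind(csd) != "csd") {
    lp_abort("`forward_lfp_from_csd()` expects a CSD matrix.", "parameter_error")
  }
  check_channel_count(nrow(csd), geom)
  f <- csd_forward_matrix(geom)
  recording_matrix(f %*% unclass(csd), rec_dt(csd), rec_t0(csd), "lfp",
                   depths_um = geom$depths_um)
}

#' Traditional (double spatial derivative) CSD estimate
#'
#' Interior channels get `C_i = -sigma (phi_{i+1} - 2 phi_i + phi_{i-1}) /
#' dz^2`; the two boundary channels are excluded, so the output has two fewer
#' channels. Requires uniform channel spacing.
#'
#' @param lfp a [recording_matrix()] of kind `"lfp"`, >= 3 channels.
#' @param geom a [probe_geometry()] with uniformly spaced depths.
#' @return a [recording_matrix()] of kind `"csd"` with N_ch - 2 rows.
#' @export
traditional_csd <- function(lfp, geom) {
  stopifnot(inherits(lfp, "recording_matrix"))
  if (rec_kind(lfp) != "lfp") {
    lp_abort("`traditional_csd()` expects an LFP recording.", "parameter_error")
  }
  check_channel_count(nrow(lfp), geom)
  if (nrow(lfp) < 3) lp_abort("need at least 3 channels.", "parameter_error")
  dz <- diff(geom$depths_um)
  if (max(abs(dz - dz[1])) > 1e-9 * dz[1]) {
    lp_abort("channel spacing is non-uniform; use delta_icsd() instead.",
             "parameter_error")
  }
  n <- nrow(lfp)
  phi <- unclass(lfp)
  d2 <- phi[3:n, , drop = FALSE] - 2 * phi[2:(n - 1), , drop = FALSE] +
    phi[1:(n - 2), , drop = FALSE]
  recording_matrix(-geom$sigma_s_per_m * d2 / dz[1]^2,
                   rec_dt(lfp), rec_t0(lfp), "csd",
                   depths_um = geom$depths_um[2:(n - 1)])
}

#' Channel-sum deviation of a CSD
#'
#' Charge balance diagnostic: the time-averaged absolute sum of the CSD across
#' channels, normalized by the peak absolute CSD value,
#' `(1/B) sum_j |sum_i C(z_i, t_j)| / max_{ij} |C|`. It is 0 for a CSD whose
#' sinks and sources balance in every time bin, and 1 for a single-channel
#' monopole. An all-zero CSD is defined to have deviation 0.
#'
#' @param csd a [recording_matrix()] of kind `"csd"`, or a plain matrix.
#' @return a non-negative scalar.
#' @export
channel_sum_deviation <- function(csd) {
  if (inherits(csd, "recording_matrix") && rec_kind(csd) != "csd") {
    lp_abort("`channel_sum_deviation()` expects a CSD matrix.", "parameter_error")
  }
  m <- unclass(as.matrix(csd))
  peak <- max(abs(m))
  if (peak == 0) return(0)
  mean(abs(colSums(m))) / peak
}
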