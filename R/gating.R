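# Retrospective intrinsic cardiac gating, with no ECG input: the difference
# between the measured projections and reprojections of an ungated
# reconstruction isolates motion; its per-view reduction carries the cardiac
# signal, whose dominant in-band spectral peak gives the heart rate and whose
# filtered peaks delimit the R-R intervals used for phase binning.

#' Difference sinogram
#'
#' Elementwise difference between measured projections and the time-average
#' reprojections; static structures cancel, leaving the motion signal.
#'
#' @param measured,reprojected `ndet x views` matrices (log domain).
#' @return residual matrix of the same shape.
#' @export
difference_sinogram <- function(measured, reprojected) {
  if (!all(dim(measured) == dim(reprojected))) stopf("shape mismatch between measured and reprojected sinograms")
  measured - reprojected
}

# per-view scalar reduction of the residual
reduce_residual <- function(residual, reduction = c("sum", "rms", "com")) {
  reduction <- match.arg(reduction)
  switch(reduction,
    sum = colMeans(residual),
    rms = sqrt(colMeans(residual^2)),
    com = {
      u <- seq_len(nrow(residual))
      w <- abs(residual)
      colSums(u * w) / pmax(colSums(w), .Machine$double.eps)
    })
}

#' Extract the cardiac signal and heart rate from a motion residual
#'
#' Reduces the difference sinogram to one scalar per view, locates the
#' dominant amplitude-spectrum peak inside the expected heart-rate band
#' (default 300-600 bpm), refines it by quadratic interpolation of the
#' log-amplitude around the peak, and returns a zero-phase band-filtered
#' trace for phase assignment.
#'
#' @param residual `ndet x views` residual matrix, or an already-reduced
#'   per-view vector.
#' @param sampling_rate view rate in Hz.
#' @param band heart-rate search band in bpm.
#' @param reduction per-view reduction: `"sum"` (signed detector mean, the
#'   default LV-volume proxy), `"rms"`, or `"com"` (center of mass).
#' @return list with `signal` (band-filtered per-view trace), `heart_rate`
#'   (bpm), `spectrum` (data.frame of frequency in Hz and amplitude) and
#'   `band`.
#' @export
extract_cardiac_signal <- function(residual, sampling_rate, band = c(300, 600),
                                   reduction = "sum") {
  f_band <- band / 60
  if (sampling_rate <= 2 * f_band[2])
    stopf("sampling rate %g Hz aliases the %g bpm band edge", sampling_rate, band[2])
  trace <- if (is.matrix(residual)) reduce_residual(residual, reduction) else residual
  nv <- length(trace)
  t_idx <- seq_len(nv)
  trace_d <- stats::residuals(stats::lm(trace ~ t_idx)) # remove mean and drift
  w <- 0.5 - 0.5 * cos(2 * pi * (t_idx - 1) / (nv - 1))  # Hann
  amp <- Mod(stats::fft(trace_d * w))[seq_len(floor(nv / 2))]
  freq <- (seq_len(floor(nv / 2)) - 1) * sampling_rate / nv
  in_band <- which(freq >= f_band[1] & freq <= f_band[2])
  if (length(in_band) < 3) stopf("scan too short to resolve the heart-rate band")
  pk <- in_band[which.max(amp[in_band])]
  floor_amp <- stats::median(amp[in_band])
  if (floor_amp <= 0 || amp[pk] < 4 * floor_amp) {
    stop(structure(class = c("no_cardiac_signal", "error", "condition"),
                   list(message = sprintf(
                     "no cardiac signal: in-band spectral peak (%.3g) below noise floor (4 x %.3g)",
                     amp[pk], floor_amp), call = NULL)))
  }
  # quadratic interpolation of log-amplitude around the peak bin
  delta <- 0
  if (pk > 1 && pk < length(amp)) {
    la <- log(pmax(amp[(pk - 1):(pk + 1)], .Machine$double.xmin))
    den <- la[1] - 2 * la[2] + la[3]
    if (den < 0) delta <- clamp(0.5 * (la[1] - la[3]) / den, -0.5, 0.5)
  }
  heart_rate <- 60 * (freq[pk] + delta * sampling_rate / nv)

  bf <- signal::butter(2, f_band / (sampling_rate / 2), type = "pass")
  filtered <- as.numeric(signal::filtfilt(bf, trace_d))
  list(signal = filtered, heart_rate = heart_rate,
       spectrum = data.frame(freq_hz = freq, amplitude = amp), band = band)
}

# local maxima with a minimum separation (greedy by height)
find_peaks <- function(x, min_sep) {
  n <- length(x)
  cand <- which(x > c(-Inf, x[-n]) & x >= c(x[-1], -Inf))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand) {
    if (all(abs(p - keep) >= min_sep)) keep <- c(keep, p)
  }
  sort(keep)
}

#' Assign cardiac phase bins to views
#'
#' Peaks of the filtered cardiac signal delimit the cardiac cycles (the R-R
#' intervals); each view's phase is the fraction of its cycle elapsed,
#' binned into `n_phases` equal bins. Views before the first and after the
#' last detected peak are handled by extrapolating with the mean period.
#'
#' @param sig filtered per-view signal (from [extract_cardiac_signal()]).
#' @param heart_rate bpm estimate.
#' @param sampling_rate view rate, Hz.
#' @param n_phases number of phase bins.
#' @return integer vector of phase bins in `0:(n_phases-1)`, one per view.
#' @export
assign_phases <- function(sig, heart_rate, sampling_rate, n_phases = 10) {
  nv <- length(sig)
  period <- 60 / heart_rate * sampling_rate # samples per cycle
  if (n_phases == 1) return(rep(0L, nv))
  peaks <- find_peaks(sig, min_sep = 0.8 * period)
  if (length(peaks) < 2) stopf("fewer than 2 cardiac cycle peaks detected")
  mean_period <- mean(diff(peaks))
  # anchor cycles half a bin before each peak so that bin 0 is centered on
  # the peak (end-diastole) and the opposite extreme falls at a bin center
  peaks <- peaks - mean_period / (2 * n_phases)
  # extend the peak train to cover all views
  while (peaks[1] > 1) peaks <- c(peaks[1] - mean_period, peaks)
  while (peaks[length(peaks)] < nv) peaks <- c(peaks, peaks[length(peaks)] + mean_period)
  cyc <- findInterval(seq_len(nv), peaks, rightmost.closed = FALSE)
  cyc <- clamp(cyc, 1, length(peaks) - 1)
  frac <- (seq_len(nv) - peaks[cyc]) / (peaks[cyc + 1] - peaks[cyc])
  as.integer(clamp(floor(n_phases * frac), 0, n_phases - 1))
}

#' Intrinsic gating of a photon-counting sinogram
#'
#' Full projection-domain gating chain: ungated FBP of the cumulative
#' lowest-threshold channel, reprojection, difference sinogram, cardiac
#' signal extraction, heart-rate estimation and phase binning. No ECG input
#' exists anywhere in the chain.
#'
#' @param sino counts-mode sinogram from [acquire()].
#' @param band heart-rate band, bpm.
#' @param n_phases number of cardiac phase bins.
#' @param reduction see [extract_cardiac_signal()].
#' @param proj optional [projector()].
#' @return object of class `gating_result`: `heart_rate` (bpm),
#'   `per_view_phase` (0-based bins), `phase_subsets` (1-based view indices
#'   per bin, a partition of the views), `cardiac_signal`, `spectrum`,
#'   `band`.
#' @export
intrinsic_gating <- function(sino, band = c(300, 600), n_phases = 10,
                             reduction = "sum", proj = NULL) {
  if (sino$mode != "counts") stopf("intrinsic_gating expects the counts-mode sinogram")
  if (is.null(proj)) proj <- projector(sino$n, sino$voxel_mm)
  ch <- sino_channel(sino, "sum")
  measured <- -log(pmax(ch$data, 0.5) / ch$air)
  ungated <- fbp(sino, bin = "sum", proj = proj)
  repro <- vapply(sino$angles,
                  function(a) as.vector(proj_matrix(proj, a) %*% as.vector(ungated)) *
                    1, numeric(proj$ndet))
  resid <- difference_sinogram(measured, repro)
  cs <- extract_cardiac_signal(resid, sampling_rate = sino$view_rate,
                               band = band, reduction = reduction)
  phases <- assign_phases(cs$signal, cs$heart_rate, sino$view_rate, n_phases)
  subsets <- lapply(seq_len(n_phases) - 1, function(p) which(phases == p))
  structure(list(heart_rate = cs$heart_rate, per_view_phase = phases,
                 phase_subsets = subsets, cardiac_signal = cs$signal,
                 spectrum = cs$spectrum, band = band, n_phases = n_phases),
            class = "gating_result")
}
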