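# Pulsatile waveform analysis: outlier removal, anti-aliased resampling to
# a uniform grid, heart-rate estimation, heart-rate band-pass in the
# frequency domain, and the mean peak-to-valley amplitude (delta-t).

#' Waveform-analysis tuning parameters
#'
#' Defaults pin the published processing constants: outliers beyond 3
#' (scaled) median absolute deviations are discarded and the band-pass
#' retains 0.5 to 3 times the heart rate.
#'
#' @param nMads outlier threshold in scaled MADs.
#' @param loMult,hiMult band-pass edges as multiples of the heart rate.
#' @param targetRateHz resampling rate; `NULL` chooses
#'   `max(4 * hiMult * hrMaxHz, median input rate)`.
#' @param hrBandHz search interval for the spectral heart-rate estimate.
#' @param minProminenceFrac peak-detection prominence threshold as a
#'   fraction of the filtered signal's standard deviation.
#' @param tukeyAlpha taper fraction of the optional Tukey window applied
#'   before the discrete Fourier transform; 0 (the default) applies the
#'   ideal mask to the unwindowed series, which keeps the filter exactly
#'   transparent in the pass band.
#' @return A named list of class `waveformControl`.
#' @export
waveformControl <- function(nMads = 3, loMult = 0.5, hiMult = 3.0,
                            targetRateHz = NULL, hrBandHz = c(0.7, 2.0),
                            minProminenceFrac = 0.25, tukeyAlpha = 0) {
  stopifnot(nMads > 0, loMult > 0, hiMult > loMult,
            length(hrBandHz) == 2, hrBandHz[1] > 0,
            hrBandHz[2] > hrBandHz[1],
            minProminenceFrac >= 0, tukeyAlpha >= 0, tukeyAlpha <= 1)
  structure(list(nMads = nMads, loMult = loMult, hiMult = hiMult,
                 targetRateHz = targetRateHz, hrBandHz = hrBandHz,
                 minProminenceFrac = minProminenceFrac,
                 tukeyAlpha = tukeyAlpha),
            class = c("waveformControl", "list"))
}

.wavNext <- function(parent, stage, times, cht, sampleRate = NA_real_,
                     heartRate = NA_real_, params = list()) {
  new("ThicknessWaveform", stage = stage, times = as.numeric(times),
      cht = as.numeric(cht), sampleRate = sampleRate,
      heartRate = heartRate, deltaT = NA_real_, params = params,
      history = c(parent@history, list(parent)))
}

#' Discard MAD outliers from a thickness series
#'
#' Points whose absolute deviation from the series median exceeds
#' `nMads` scaled MADs (scaled MAD = 1.4826 x median absolute deviation,
#' the Gaussian-consistent estimate) are removed together with their
#' timestamps. A zero-MAD series (e.g. constant) is returned unchanged.
#'
#' @param wave a [ThicknessWaveform-class] (raw stage).
#' @param nMads threshold in scaled MADs (default 3).
#' @return A cleaned-stage [ThicknessWaveform-class].
#' @examples
#' w <- thicknessWaveform(0:5, c(10, 10, 11, 9, 10, 50))
#' chtSeries(removeOutliersMAD(w))
#' @export
removeOutliersMAD <- function(wave, nMads = 3) {
  stopifnot(is(wave, "ThicknessWaveform"))
  x <- wave@cht
  if (length(x) < 5L) stop("at least 5 points required")
  med <- stats::median(x)
  smad <- stats::mad(x)              # 1.4826-scaled by default
  keep <- if (smad == 0) rep(TRUE, length(x))
          else abs(x - med) <= nMads * smad
  if (!any(keep)) stop("all points removed as outliers")
  .wavNext(wave, "cleaned", wave@times[keep], x[keep],
           params = list(nMads = nMads, nRemoved = sum(!keep)))
}

#' Resample an irregular series to a uniform grid
#'
#' Linear-time interpolation onto a uniform grid spanning the original
#' time range, followed by a zero-phase (forward-backward) FIR
#' anti-aliasing low-pass, so the net group delay is zero. The default
#' target rate is `max(4 * hiMult * hrMaxHz, median input rate)`.
#'
#' @param wave a raw- or cleaned-stage [ThicknessWaveform-class].
#' @param targetRateHz uniform sampling rate in Hz (`NULL` = automatic).
#' @param hrMaxHz upper bound of plausible heart rates; the target rate
#'   must exceed twice `3 * hrMaxHz` so the analysis band stays
#'   alias-free.
#' @param hiMult band-pass upper multiple (used by the automatic rate).
#' @return A uniform-stage [ThicknessWaveform-class].
#' @export
resampleUniform <- function(wave, targetRateHz = NULL, hrMaxHz = 2.0,
                            hiMult = 3.0) {
  stopifnot(is(wave, "ThicknessWaveform"))
  t <- wave@times; x <- wave@cht
  if (length(t) < 2L) stop("at least 2 points required")
  medRate <- 1 / stats::median(diff(t))
  rate <- if (is.null(targetRateHz)) max(4 * hiMult * hrMaxHz, medRate)
          else targetRateHz
  if (rate <= 2 * (3 * hrMaxHz))
    stop("target rate below the Nyquist requirement for the analysis band")
  span <- t[length(t)] - t[1]
  m <- floor(span * rate) + 1L
  grid <- t[1] + (seq_len(m) - 1L) / rate
  y <- stats::approx(t, x, xout = grid)$y
  # zero-phase FIR anti-aliasing low-pass; cutoff guards against content
  # beyond the original series' effective bandwidth
  wc <- min(0.9, 0.9 * medRate / rate)
  ord <- max(4L, min(64L, 2L * ((m - 1L) %/% 8L)))
  if (ord %% 2L == 1L) ord <- ord - 1L
  if (m > 3L * (ord + 1L)) {
    b <- as.numeric(signal::fir1(ord, wc))
    # zero-phase filtering around the mean with odd-reflection padding,
    # so record edges carry no filter transient
    mu <- mean(y)
    yc <- y - mu
    L <- ord + 1L
    yp <- c(2 * yc[1] - rev(yc[2:(L + 1L)]), yc,
            2 * yc[m] - rev(yc[(m - L):(m - 1L)]))
    yp <- as.numeric(signal::filtfilt(b, 1, yp))
    y <- yp[(L + 1L):(L + m)] + mu
  }
  # record input gaps wider than 3x the median spacing: grid samples in
  # there carry interpolated, not observed, signal (tracker pauses,
  # removed outliers); the peak-to-valley stage decides which gaps are
  # long enough relative to the cardiac period to disqualify a cycle
  medGap <- stats::median(diff(t))
  wide <- which(diff(t) > 3 * medGap)
  gaps <- if (length(wide))
    cbind(start = t[wide], end = t[wide + 1L])
  else cbind(start = numeric(0), end = numeric(0))
  .wavNext(wave, "uniform", grid, y, sampleRate = rate,
           params = list(targetRateHz = rate, medianInputRateHz = medRate,
                         gapIntervals = gaps))
}

#' Spectral heart-rate estimate
#'
#' Frequency of the maximal discrete-Fourier magnitude within the search
#' band after removing the mean and a linear trend. Fails with an
#' instructive error when no dominant peak exists (peak below twice the
#' in-band median), in which case the heart rate should be supplied
#' explicitly.
#'
#' @param wave a uniform-stage [ThicknessWaveform-class].
#' @param searchBandHz frequency interval searched, Hz.
#' @return Heart rate in Hz.
#' @export
estimateHeartRate <- function(wave, searchBandHz = c(0.7, 2.0)) {
  stopifnot(is(wave, "ThicknessWaveform"), !is.na(wave@sampleRate))
  t <- wave@times; y <- wave@cht
  if (diff(range(t)) < 2 / searchBandHz[1])
    stop("series shorter than two cycles of the slowest searched rate")
  y <- stats::residuals(stats::lm(y ~ t))
  n <- length(y)
  fs <- wave@sampleRate
  # Hann-windowed, zero-padded periodogram: the window confines spectral
  # leakage of off-bin tones to the main lobe and the padding interpolates
  # the spectrum so the peak frequency is not quantized to the raw bins
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  np <- 8L * stats::nextn(n, 2)
  mag <- Mod(stats::fft(c(w * y, rep(0, np - n))))[seq_len(np %/% 2)]
  freq <- (seq_len(np %/% 2) - 1L) * fs / np
  inband <- which(freq >= searchBandHz[1] & freq <= searchBandHz[2])
  if (!length(inband)) stop("no spectral bins inside the search band")
  peak <- inband[which.max(mag[inband])]
  fHat <- freq[peak]
  # flatness guard: harmonic F-test of the best-fitting sinusoid at the
  # estimated frequency against the white-noise null, Bonferroni-adjusted
  # for having searched the band's independent frequencies; unlike a
  # raw-periodogram peak/median rule this stays calibrated when the tone
  # falls between Fourier bins
  X <- cbind(sin(2 * pi * fHat * t), cos(2 * pi * fHat * t))
  rss1 <- sum(stats::lsfit(X, y, intercept = FALSE)$residuals^2)
  rss0 <- sum(y^2)
  fStat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
  mEff <- max(1, floor(diff(searchBandHz) * n / fs))
  if (stats::pf(fStat, 2, n - 3, lower.tail = FALSE) * mEff > 0.05)
    stop(paste("no dominant spectral peak in the heart-rate band;",
               "supply the heart rate explicitly"))
  fHat
}

# Tukey (tapered-cosine) window of length n with taper fraction alpha.
.tukeyWindow <- function(n, alpha) {
  if (alpha <= 0) return(rep(1, n))
  if (alpha >= 1) return(0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))))
  x <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Heart-rate band-pass via the discrete Fourier transform
#'
#' The detrended (mean and linear trend removed), Tukey-windowed series is
#' transformed, every Fourier coefficient outside
#' `[loMult x HR, hiMult x HR]` (both frequency signs) is zeroed, and the
#' inverse transform is taken. The taper is compensated afterwards
#' (division by the window, floored at 0.1 so the extreme edges attenuate
#' gracefully instead of amplifying). The result is real-valued with zero
#' mean.
#'
#' @param wave a uniform-stage [ThicknessWaveform-class].
#' @param heartRateHz heart rate in Hz.
#' @param loMult,hiMult band edges as multiples of the heart rate
#'   (defaults 0.5 and 3).
#' @param tukeyAlpha Tukey taper fraction (0, the default, disables the
#'   window and keeps the mask exactly transparent in the pass band).
#' @return A filtered-stage [ThicknessWaveform-class].
#' @export
bandpassFilter <- function(wave, heartRateHz, loMult = 0.5, hiMult = 3.0,
                           tukeyAlpha = 0) {
  stopifnot(is(wave, "ThicknessWaveform"), !is.na(wave@sampleRate),
            heartRateHz > 0, loMult > 0, hiMult > loMult)
  fs <- wave@sampleRate
  loF <- loMult * heartRateHz
  hiF <- hiMult * heartRateHz
  if (hiF >= fs / 2)
    stop("band upper edge at or above Nyquist; resample faster")
  t <- wave@times
  y <- wave@cht
  n <- length(y)
  w <- .tukeyWindow(n, tukeyAlpha)
  Y <- stats::fft(w * (y - mean(y)))
  freq <- (seq_len(n) - 1L) * fs / n
  fEff <- pmin(freq, fs - freq)            # fold negative frequencies
  mask <- fEff >= loF & fEff <= hiF
  if (!any(mask)) stop("band empty after discretization")
  Y[!mask] <- 0
  yf <- Re(stats::fft(Y, inverse = TRUE)) / n
  yf <- yf / pmax(w, 0.1)
  .wavNext(wave, "filtered", t, yf, sampleRate = fs,
           heartRate = heartRateHz,
           params = list(loMult = loMult, hiMult = hiMult,
                         tukeyAlpha = tukeyAlpha))
}

# Alternating local extrema of y; plateaus collapse to their first index.
.localExtrema <- function(y) {
  d <- diff(y)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(NULL)
  s <- sign(d[nz])
  turn <- which(diff(s) != 0)
  if (!length(turn)) return(NULL)
  idx <- nz[turn] + 1L
  kind <- ifelse(s[turn] > 0, "peak", "valley")
  list(idx = idx, kind = kind)
}

#' Mean peak-to-valley amplitude of a filtered waveform
#'
#' Local maxima and the valleys following them are detected after
#' iteratively merging oscillations smaller than the prominence threshold;
#' the amplitude is the mean of (peak minus following valley) over
#' complete cycles (a trailing peak without a following valley is
#' excluded).
#'
#' @param wave a filtered-stage [ThicknessWaveform-class] or a numeric
#'   vector.
#' @param minProminenceUm prominence threshold in micrometres; the default
#'   is 25% of the signal's standard deviation.
#' @param excludeMask optional logical vector marking samples whose value
#'   is interpolated rather than observed (see [resampleUniform()]);
#'   peak-valley pairs overlapping masked samples are excluded from the
#'   average.
#' @return Mean peak-to-valley amplitude (micrometres).
#' @export
meanPeakToValley <- function(wave, minProminenceUm = NULL,
                             excludeMask = NULL) {
  y <- if (is(wave, "ThicknessWaveform")) wave@cht else as.numeric(wave)
  if (is.null(minProminenceUm)) minProminenceUm <- 0.25 * stats::sd(y)
  ex <- .localExtrema(y)
  if (is.null(ex)) stop("no peak-valley pair found")
  idx <- ex$idx
  # merge sub-threshold oscillations: repeatedly delete the adjacent
  # extremum pair with the smallest swing below the prominence threshold
  repeat {
    if (length(idx) < 2L) break
    swings <- abs(diff(y[idx]))
    k <- which.min(swings)
    if (swings[k] >= minProminenceUm) break
    idx <- idx[-c(k, k + 1L)]
  }
  if (length(idx) < 2L) stop("no peak-valley pair found")
  kind <- character(length(idx))
  for (i in seq_len(length(idx) - 1L))
    kind[i] <- if (y[idx[i]] > y[idx[i + 1L]]) "peak" else "valley"
  kind[length(idx)] <-
    if (kind[length(idx) - 1L] == "peak") "valley" else "peak"
  amps <- c()
  for (i in seq_len(length(idx) - 1L))
    if (kind[i] == "peak" && kind[i + 1L] == "valley") {
      if (!is.null(excludeMask) &&
          any(excludeMask[idx[i]:idx[i + 1L]])) next
      amps <- c(amps, y[idx[i]] - y[idx[i + 1L]])
    }
  if (!length(amps)) stop("no peak-valley pair found")
  mean(amps)
}

#' Extract the pulsatile thickness change from a raw waveform
#'
#' Composes the full published processing chain: 3-MAD outlier removal,
#' anti-aliased resampling to a uniform grid, heart-rate estimation (unless
#' supplied), 0.5-3x heart-rate band-pass and mean peak-to-valley
#' amplitude. All intermediate stages are retained in the result's
#' `history` for audit.
#'
#' @param wave a raw-stage [ThicknessWaveform-class].
#' @param heartRateHz known heart rate in Hz, or `NULL` to estimate it
#'   from the series spectrum.
#' @param control a [waveformControl()].
#' @return A filtered-stage [ThicknessWaveform-class] with slot `deltaT`
#'   set (micrometres).
#' @examples
#' t <- seq(0, 6, by = 0.02)
#' w <- thicknessWaveform(t, 300 + 5 * sin(2 * pi * 1.2 * t))
#' deltaT(extractDeltaT(w, heartRateHz = 1.2))
#' @export
extractDeltaT <- function(wave, heartRateHz = NULL,
                          control = waveformControl()) {
  stopifnot(is(wave, "ThicknessWaveform"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cleaned <- stage("outlier-removal",
                   removeOutliersMAD(wave, control$nMads))
  uniform <- stage("resampling",
                   resampleUniform(cleaned, control$targetRateHz,
                                   hrMaxHz = control$hrBandHz[2],
                                   hiMult = control$hiMult))
  hr <- if (is.null(heartRateHz))
    stage("heart-rate", estimateHeartRate(uniform, control$hrBandHz))
  else heartRateHz
  filtered <- stage("band-pass",
                    bandpassFilter(uniform, hr, control$loMult,
                                   control$hiMult, control$tukeyAlpha))
  prom <- control$minProminenceFrac * stats::sd(filtered@cht)
  # unreliable samples: data gaps longer than a quarter cardiac period
  # (dilated by half a period, the scale of the ideal-mask filter's
  # ringing) and the Tukey taper zones at the record edges
  n <- length(filtered@cht)
  fs <- uniform@sampleRate
  tt <- filtered@times
  mask <- rep(FALSE, n)
  gaps <- uniform@params$gapIntervals
  if (!is.null(gaps) && nrow(gaps)) {
    half <- 0.5 / hr
    for (g in seq_len(nrow(gaps))) {
      if (gaps[g, "end"] - gaps[g, "start"] <= 0.25 / hr) next
      mask[tt > gaps[g, "start"] - half & tt < gaps[g, "end"] + half] <-
        TRUE
    }
  }
  edgeMask <- rep(FALSE, n)
  ntap <- ceiling(control$tukeyAlpha / 2 * n) + round(0.25 * fs / hr)
  if (ntap >= 1 && 2 * ntap < n) {
    edgeMask[seq_len(ntap)] <- TRUE
    edgeMask[(n - ntap + 1L):n] <- TRUE
  }
  # prefer cycles untouched by gaps and edges; if exclusion leaves no
  # complete cycle (short records with several pauses), degrade
  # gracefully and record how much exclusion was applied
  tryMask <- list(gaps_and_edges = mask | edgeMask,
                  edges_only = edgeMask,
                  none = NULL)
  dt <- NULL
  for (nm in names(tryMask)) {
    dt <- tryCatch(meanPeakToValley(filtered, prom,
                                    excludeMask = tryMask[[nm]]),
                   error = function(e) NULL)
    if (!is.null(dt)) {
      filtered@params$cycleExclusion <- nm
      break
    }
  }
  if (is.null(dt))
    dt <- stage("peak-to-valley",
                meanPeakToValley(filtered, prom, excludeMask = NULL))
  filtered@deltaT <- dt
  filtered@params$minProminenceUm <- prom
  validObject(filtered)
  filtered
}
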