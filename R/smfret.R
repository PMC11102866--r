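# Single-molecule FRET kinetics: photobleach change points, trace QC,
# corrected efficiency, two-state threshold segmentation, exponential dwell
# fits and a discrete-sampling correction for frame-quantized kinetics.

#' Channel correction factors for FRET efficiency
#'
#' @param alpha Donor-to-acceptor spectral leakage fraction, `0 <= alpha < 1`.
#' @param gamma Ratio of detection efficiency times quantum yield between the
#'   two channels, `> 0`.
#'
#' Both factors are instrument properties and must be measured for each
#' setup; there are deliberately no defaults.
#' @return A `CorrectionFactors` list.
#' @export
correction_factors <- function(alpha, gamma) {
  stopifnot(is.numeric(alpha), is.numeric(gamma),
            alpha >= 0, alpha < 1, gamma > 0)
  structure(list(alpha = alpha, gamma = gamma), class = "CorrectionFactors")
}

#' Largest change point of an intensity series
#'
#' Finds the split index maximizing the reduction in total squared error of a
#' two-mean piecewise-constant fit (equivalent to the largest standardized
#' mean step). Returns `NULL` when the best step is smaller than
#' `min_effect`; by default that threshold is twice the robust noise s.d.
#' estimated from the median absolute deviation of first differences.
#'
#' @param signal Numeric series, length >= 4.
#' @param min_effect Minimum absolute mean step to accept; `NULL` for the
#'   MAD-based default.
#' @return `NULL`, or a list with `index` (last frame of the pre-change
#'   segment), `step` (post mean minus pre mean) and `sse_reduction`.
#' @export
largest_change_point <- function(signal, min_effect = NULL) {
  n <- length(signal)
  if (n < 4L) stop("series too short for change-point detection (need >= 4)")
  if (is.null(min_effect)) {
    sigma <- mad(diff(signal)) / sqrt(2)
    min_effect <- 2 * sigma
  }
  cs <- cumsum(signal)
  tot <- cs[n]
  k <- seq_len(n - 1L)
  m1 <- cs[k] / k
  m2 <- (tot - cs[k]) / (n - k)
  red <- k * (n - k) / n * (m1 - m2)^2
  best <- which.max(red)
  step <- m2[best] - m1[best]
  if (abs(step) <= min_effect) return(NULL)  # <=: a constant series (both 0) is "none"
  list(index = best, step = step, sse_reduction = red[best])
}

# QC helper: a partial (multi-step) photobleach shows up as a block of
# frames displaced from the otherwise constant corrected total intensity --
# a dip, which a single change-point split dilutes. Flag segments with at
# least `min_frames` frames beyond `k` robust s.d. from the median.
.has_level_outliers <- function(signal, noise, k = 3, min_frames = 3L) {
  dev <- (signal - median(signal)) / max(noise, 1e-12)
  sum(dev < -k) >= min_frames || sum(dev > k) >= min_frames
}

#' Corrected FRET efficiency series
#'
#' `E = (IA - alpha ID) / (gamma ID + IA - alpha ID)`. Frames with a
#' non-positive denominator are flagged invalid (`NA`); values are never
#' clipped for fitting.
#'
#' @param donor,acceptor Intensity series of equal length (pre-bleach window).
#' @param factors A [correction_factors()].
#' @return Numeric efficiency series with `NA` at invalid frames.
#' @examples
#' fret_efficiency(50, 50, correction_factors(0, 1))  # 0.5
#' @export
fret_efficiency <- function(donor, acceptor, factors) {
  stopifnot(inherits(factors, "CorrectionFactors"),
            length(donor) == length(acceptor))
  fa <- acceptor - factors$alpha * donor
  den <- factors$gamma * donor + fa
  ifelse(den > 0, fa / den, NA_real_)
}

#' Quality control of a single two-channel trace
#'
#' Acceptance mirrors the standard smFRET criteria: the molecule must show
#' acceptor signal at the start (no donor-only molecules), exactly one
#' photobleaching step per fluorophore, at least `min_prebleach` frames of
#' FRET before the first bleach, and donor fluorescence recovery
#' (anticorrelation) after the acceptor bleach. Extra bleaching steps are
#' detected on the leakage-corrected total intensity, which is constant
#' through FRET switching and through a clean acceptor bleach, so two-state
#' dynamics never trigger the multiple-bleach rejection.
#'
#' @param trace data.frame for one molecule with columns `time_s`, `donor`,
#'   `acceptor` (rows in frame order).
#' @param factors A [correction_factors()].
#' @param min_prebleach Minimum frames of FRET before the acceptor bleach.
#' @return A `FretTrace` list: `qc_status` (`"accepted"` or
#'   `"rejected:<reason>"`), `acceptor_bleach_frame`, `donor_bleach_frame`
#'   (last pre-bleach frames, `NA` when undetected), `efficiency` (series on
#'   the pre-bleach window, `NULL` if rejected), `dt`, and the raw channels.
#' @export
qc_trace <- function(trace, factors, min_prebleach = 5L) {
  donor <- trace$donor
  acceptor <- trace$acceptor
  n <- length(donor)
  dt <- if (n > 1L) median(diff(trace$time_s)) else NA_real_
  out <- list(donor = donor, acceptor = acceptor, time = trace$time_s,
              dt = dt, acceptor_bleach_frame = NA_integer_,
              donor_bleach_frame = NA_integer_, efficiency = NULL,
              qc_status = "accepted")
  reject <- function(reason) {
    out$qc_status <- paste0("rejected:", reason)
    structure(out, class = "FretTrace")
  }
  if (n < max(8L, 2L * min_prebleach)) return(reject("too_short"))
  noise_d <- mad(diff(donor)) / sqrt(2)
  noise_a <- mad(diff(acceptor)) / sqrt(2)

  # 1. acceptor signal must be present at the start
  aa <- acceptor - factors$alpha * donor  # leakage-corrected acceptor
  if (mean(aa[seq_len(min_prebleach)]) < 3 * max(noise_a, 1e-12))
    return(reject("no_acceptor"))

  # 2. donor bleach: single down step on the corrected total intensity,
  # which is constant through FRET switching and a clean acceptor bleach
  s <- donor + aa
  noise_s <- mad(diff(s)) / sqrt(2)
  cp_s <- largest_change_point(s, min_effect = 2 * max(noise_s, 1e-12))
  if (is.null(cp_s) || cp_s$step > 0) return(reject("no_donor_bleach"))
  k_d <- cp_s$index
  if (.has_level_outliers(s[seq_len(k_d)], noise_s))
    return(reject("multiple_bleach"))
  if (n - k_d >= 4L && .has_level_outliers(s[seq.int(k_d + 1L, n)], noise_s))
    return(reject("multiple_bleach"))

  # 3. acceptor bleach: single down step to background before the donor bleach
  if (k_d < 4L) return(reject("short_prebleach"))
  cp_a <- largest_change_point(aa[seq_len(k_d)],
                               min_effect = 2 * max(noise_a, 1e-12))
  if (is.null(cp_a) || cp_a$step > 0) return(reject("no_acceptor_bleach"))
  k_a <- cp_a$index
  # the SSE-optimal split can land early, at a FRET switch preceding the
  # bleach (the low-state acceptor level has less contrast against the
  # background); refine to the last frame significantly above the
  # post-bleach background, re-estimating the background each pass
  for (pass in 1:3) {
    if (k_d - k_a < 2L) break
    bg <- aa[seq.int(k_a + 1L, k_d)]
    thr <- median(bg) + 4 * max(mad(bg), noise_a, 1e-12)
    above <- which(aa[seq_len(k_d - 1L)] > thr)
    if (!length(above) || max(above) <= k_a) break
    k_a <- max(above)
  }
  post <- aa[seq.int(k_a + 1L, k_d)]
  pre <- aa[seq_len(k_a)]
  if (mean(post) > 0.25 * mean(pre)) return(reject("ambiguous_acceptor_bleach"))
  if (k_a < min_prebleach) return(reject("short_prebleach"))
  if (k_d - k_a < 2L) return(reject("no_recovery_window"))

  # 4. donor must recover (anticorrelation at the acceptor bleach)
  rec <- mean(donor[seq.int(k_a + 1L, k_d)]) - mean(donor[seq_len(k_a)])
  if (rec <= 2 * noise_d) return(reject("no_donor_recovery"))

  out$acceptor_bleach_frame <- k_a
  out$donor_bleach_frame <- k_d
  out$efficiency <- fret_efficiency(donor[seq_len(k_a)],
                                    acceptor[seq_len(k_a)], factors)
  structure(out, class = "FretTrace")
}

#' @export
print.FretTrace <- function(x, ...) {
  cat(sprintf("FretTrace: %d frames, dt %.3g s, %s\n", length(x$donor),
              x$dt, x$qc_status))
  invisible(x)
}

#' Threshold segmentation of an efficiency series into dwells
#'
#' Frames with `E >= threshold` are the high-FRET (wrapped) state, others the
#' low-FRET (unwrapped, factor-bound) state. Consecutive runs become dwells
#' of duration run length x frame interval; the first and last runs are
#' flagged censored (their true start/end was not observed). Runs shorter
#' than `min_dwell_frames` are merged into their longer neighbor.
#'
#' @param E Efficiency series (from an accepted trace; `NA` frames inherit
#'   the preceding state).
#' @param threshold Efficiency separating the states (default 0.48).
#' @param dt Frame interval in seconds.
#' @param min_dwell_frames Minimum run length kept as a dwell (default 1, no
#'   merging).
#' @return List with `dwells` (data.frame `state`, `n_frames`, `duration_s`,
#'   `censored`) and `states` (per-frame classification).
#' @export
segment_states <- function(E, threshold = 0.48, dt = 1,
                           min_dwell_frames = 1L) {
  stopifnot(threshold > 0, threshold < 1, dt > 0)
  hi <- E >= threshold
  if (anyNA(hi)) {   # carry last valid classification forward
    for (i in seq_along(hi)) {
      if (is.na(hi[i])) hi[i] <- if (i > 1L) hi[i - 1L] else TRUE
    }
  }
  r <- rle(hi)
  while (min_dwell_frames > 1L && length(r$lengths) > 1L &&
         any(r$lengths < min_dwell_frames)) {
    i <- which.min(r$lengths)
    r$values[i] <- !r$values[i]  # absorb into neighboring state
    r <- rle(inverse.rle(r))
  }
  dwells <- data.frame(
    state = ifelse(r$values, "high_fret_wrapped", "low_fret_unwrapped"),
    n_frames = r$lengths,
    duration_s = r$lengths * dt,
    censored = seq_along(r$lengths) %in% c(1L, length(r$lengths))
  )
  list(dwells = dwells, states = inverse.rle(r))
}

#' Maximum-likelihood exponential fit of dwell times
#'
#' With `censoring = "drop"` (default) the MLE is the plain mean of the
#' uncensored dwells; with `censoring = "include"` the right-censored MLE is
#' the sum of all durations divided by the number of uncensored dwells.
#'
#' @param dwells Either the `dwells` data.frame from [segment_states()]
#'   (optionally filtered to one state) or a numeric vector of durations.
#' @param censoring `"drop"` or `"include"`.
#' @param censored Logical vector when `dwells` is numeric (default all
#'   uncensored).
#' @param min_dwells Minimum number of uncensored dwells required.
#' @return A `DwellFit` list: `tau` (exponential mean, s), `half_life`
#'   (`tau * ln 2`), `rate` (`1 / half_life`, following the convention of
#'   inverting half-lives), `n_dwells`, `censoring`.
#' @export
fit_exponential <- function(dwells, censoring = c("drop", "include"),
                            censored = NULL, min_dwells = 10L) {
  censoring <- match.arg(censoring)
  if (is.data.frame(dwells)) {
    durations <- dwells$duration_s
    censored <- dwells$censored
  } else {
    durations <- as.numeric(dwells)
    if (is.null(censored)) censored <- rep(FALSE, length(durations))
  }
  stopifnot(all(durations > 0))
  n_unc <- sum(!censored)
  if (n_unc < min_dwells)
    stop("too few uncensored dwells (", n_unc, " < ", min_dwells, ")")
  tau <- if (censoring == "drop") mean(durations[!censored])
         else sum(durations) / n_unc
  dwell_fit(tau, n_unc, censoring)
}

dwell_fit <- function(tau, n_dwells, method) {
  half_life <- tau * log(2)
  structure(list(tau = tau, half_life = half_life, rate = 1 / half_life,
                 n_dwells = n_dwells, method = method),
            class = "DwellFit")
}

#' @export
print.DwellFit <- function(x, ...) {
  cat(sprintf("DwellFit (%s): tau %.3f s, half-life %.3f s, rate %.4f /s, n=%d\n",
              x$method, x$tau, x$half_life, x$rate, x$n_dwells))
  invisible(x)
}

#' Two-state dwell kinetics with discrete-sampling correction
#'
#' Frame-quantized dwell times are biased estimates of the underlying
#' exponential means: conditioning on a dwell being observed inflates run
#' lengths geometrically, and sub-frame dwells of the opposite state merge
#' adjacent runs. For a two-state process sampled at interval `dt`, observed
#' run lengths are geometric with persistence `p_state = pi + (1 - pi)
#' exp(-(k_low + k_high) dt)`; `correction = "markov"` (default) inverts this
#' relation jointly for both states, which is exact for instantaneous frame
#' sampling. `"half_frame"` subtracts half a frame from the mean run duration
#' (adequate only when `dt << tau`); `"none"` uses the raw exponential MLE.
#'
#' @param dwells Pooled `dwells` data.frame from [segment_states()] across
#'   molecules (columns `state`, `n_frames`, `duration_s`, `censored`).
#' @param dt Frame interval in seconds.
#' @param correction `"markov"`, `"half_frame"` or `"none"`.
#' @param min_dwells Minimum uncensored dwells per state.
#' @return List with `low` and `high` `DwellFit`s and `n_low`, `n_high`.
#' @export
dwell_kinetics <- function(dwells, dt, correction = c("markov", "half_frame",
                                                      "none"),
                           min_dwells = 10L) {
  correction <- match.arg(correction)
  u <- dwells[!dwells$censored, , drop = FALSE]
  lo <- u$n_frames[u$state == "low_fret_unwrapped"]
  hi <- u$n_frames[u$state == "high_fret_wrapped"]
  if (length(lo) < min_dwells || length(hi) < min_dwells)
    stop("too few uncensored dwells (low ", length(lo), ", high ", length(hi),
         ", need ", min_dwells, " each)")
  if (correction == "markov") {
    # persistence of each observed state, estimated by transition counting
    # over all runs (the Markov-chain MLE): a run of n frames contributes
    # n - 1 stay transitions, and every run followed by another run in the
    # same molecule contributes one leave transition. Censored runs keep
    # their internal transitions, so short observation windows do not
    # length-bias the estimate.
    grp <- if (!is.null(dwells$molecule_id)) dwells$molecule_id
           else rep("all", nrow(dwells))
    last_of_grp <- !duplicated(grp, fromLast = TRUE)
    is_low <- dwells$state == "low_fret_unwrapped"
    stay_lo <- sum(dwells$n_frames[is_low] - 1L)
    leave_lo <- sum(is_low & !last_of_grp)
    stay_hi <- sum(dwells$n_frames[!is_low] - 1L)
    leave_hi <- sum(!is_low & !last_of_grp)
    pa <- stay_lo / (stay_lo + leave_lo)
    pb <- stay_hi / (stay_hi + leave_hi)
    lam <- pa + pb - 1           # exp(-(k_low + k_high) dt)
    if (lam <= 0 || lam >= 1) {
      warning("discrete-sampling inversion out of range; falling back to ",
              "uncorrected means")
      return(dwell_kinetics(dwells, dt, correction = "none",
                            min_dwells = min_dwells))
    }
    pi_low <- (pa - lam) / (1 - lam)
    k_sum <- -log(lam) / dt
    tau_low <- 1 / ((1 - pi_low) * k_sum)
    tau_high <- 1 / (pi_low * k_sum)
    fit_lo <- dwell_fit(tau_low, length(lo), "markov")
    fit_hi <- dwell_fit(tau_high, length(hi), "markov")
  } else if (correction == "half_frame") {
    fit_lo <- dwell_fit(mean(lo) * dt - dt / 2, length(lo), "half_frame")
    fit_hi <- dwell_fit(mean(hi) * dt - dt / 2, length(hi), "half_frame")
  } else {
    fit_lo <- dwell_fit(mean(lo) * dt, length(lo), "none")
    fit_hi <- dwell_fit(mean(hi) * dt, length(hi), "none")
  }
  list(low = fit_lo, high = fit_hi, n_low = length(lo), n_high = length(hi))
}

#' Full per-experiment dwell-time pipeline
#'
#' Runs [qc_trace()] on every molecule of a trace table, computes corrected
#' efficiencies, segments two states at `threshold` and fits both dwell-time
#' means with the discrete-sampling correction.
#'
#' @param traces A trace table (see [read_traces()]).
#' @param factors A [correction_factors()].
#' @param threshold Efficiency threshold (default 0.48).
#' @param correction Passed to [dwell_kinetics()].
#' @param min_prebleach,min_dwell_frames,min_dwells Tuning parameters, see
#'   the respective functions.
#' @return List with `fits` (from [dwell_kinetics()]), `dwells` (pooled
#'   data.frame with `molecule_id`), `qc` (per-molecule status data.frame)
#'   and `dt`.
#' @export
fret_dwell_pipeline <- function(traces, factors, threshold = 0.48,
                                correction = "markov", min_prebleach = 5L,
                                min_dwell_frames = 1L, min_dwells = 10L) {
  ids <- unique(traces$molecule_id)
  qc <- data.frame(molecule_id = ids, status = NA_character_,
                   prebleach_frames = NA_integer_)
  pooled <- list()
  dts <- numeric()
  for (i in seq_along(ids)) {
    tr <- traces[traces$molecule_id == ids[i], , drop = FALSE]
    ft <- qc_trace(tr, factors, min_prebleach = min_prebleach)
    qc$status[i] <- ft$qc_status
    qc$prebleach_frames[i] <- ft$acceptor_bleach_frame
    if (ft$qc_status != "accepted") next
    seg <- segment_states(ft$efficiency, threshold = threshold, dt = ft$dt,
                          min_dwell_frames = min_dwell_frames)
    if (nrow(seg$dwells)) {
      seg$dwells$molecule_id <- ids[i]
      pooled[[length(pooled) + 1L]] <- seg$dwells
    }
    dts <- c(dts, ft$dt)
  }
  if (!length(pooled)) stop("no accepted traces with dwells")
  dwells <- do.call(rbind, pooled)
  dt <- median(dts)
  fits <- dwell_kinetics(dwells, dt, correction = correction,
                         min_dwells = min_dwells)
  list(fits = fits, dwells = dwells, qc = qc, dt = dt)
}

#' Unpaired two-sided Student's t-test on replicate-level values
#'
#' Classical pooled-variance t-test comparing replicate means between two
#' groups (e.g. per-replicate dwell-time fits for two protein variants).
#'
#' @param fits_a,fits_b Numeric vectors of replicate-level values (length
#'   >= 2 each).
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_replicates <- function(fits_a, fits_b) {
  na <- length(fits_a); nb <- length(fits_b)
  if (na < 2L || nb < 2L) stop("need >= 2 replicate values per group")
  ma <- mean(fits_a); mb <- mean(fits_b)
  sp2 <- ((na - 1) * var(fits_a) + (nb - 1) * var(fits_b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- if (se == 0) {
    if (ma == mb) 0 else sign(ma - mb) * Inf
  } else (ma - mb) / se
  df <- na + nb - 2
  p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df)
  list(t = tstat, df = df, p_value = p, mean_a = ma, mean_b = mb)
}
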