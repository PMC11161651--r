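#' Synthetic single-lead ECG generator
#'
#' Generates labelled 10-s, 500-Hz single-lead ECG-like records in which the
#' two diagnostic domains of atrial fibrillation (AF) are independently
#' controllable:
#' \itemize{
#'   \item \emph{morphology}: non-AF records carry a P wave before every QRS
#'     complex; AF records replace it with a band-limited fibrillatory
#'     oscillation (F waves) between QRS complexes;
#'   \item \emph{rhythm}: RR intervals are drawn from a log-normal
#'     distribution whose coefficient of variation (CV) is low for non-AF
#'     and high for AF.
#' }
#' Every record carries ground-truth annotations (R-peak indices, P-wave
#' indices, RR series) so that attribution methods can be scored against
#' known class-feature locations. The waveform model is deliberately
#' parametric (sums of Gaussian bumps), not physiological: it provides
#' analytic ground truth, not realism.
#'
#' @param fs Sampling frequency in Hz.
#' @param duration Record duration in seconds.
#' @param heart_rate_range Range (bpm) from which each record's mean heart
#'   rate is drawn uniformly.
#' @param rr_cv_nonAF,rr_cv_AF Target coefficient of variation of the RR
#'   interval series for the two classes. `rr_cv_AF` must exceed
#'   `rr_cv_nonAF` unless `morphology_only` is set.
#' @param f_wave_amplitude Peak amplitude of the fibrillatory oscillation,
#'   relative to the unit R-peak amplitude.
#' @param f_wave_freq_range Frequency band (Hz) of the fibrillatory
#'   oscillation.
#' @param p_amplitude P-wave amplitude relative to the unit R peak.
#' @param pr_offset_s Time (s) from P-wave centre to R peak.
#' @param noise_sd Standard deviation of additive white Gaussian noise.
#' @param morphology_only If `TRUE`, both classes share the non-AF RR
#'   dispersion so that only morphology separates them.
#' @param rhythm_only If `TRUE`, both classes share the non-AF morphology
#'   (P waves, no F waves) so that only the RR series separates them.
#' @return An object of class `ecg_generator_config`.
#' @export
ecg_generator_config <- function(fs = 500, duration = 10,
                                 heart_rate_range = c(55, 100),
                                 rr_cv_nonAF = 0.05, rr_cv_AF = 0.2,
                                 f_wave_amplitude = 0.1,
                                 f_wave_freq_range = c(4, 9),
                                 p_amplitude = 0.15,
                                 pr_offset_s = 0.16,
                                 noise_sd = 0.03,
                                 morphology_only = FALSE,
                                 rhythm_only = FALSE) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  amps <- c(f_wave_amplitude, p_amplitude, noise_sd)
  if (any(amps < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  if (rr_cv_nonAF < 0 || rr_cv_AF < 0)
    stop("RR coefficients of variation must be non-negative", call. = FALSE)
  if (!morphology_only && rr_cv_AF <= rr_cv_nonAF)
    stop("rr_cv_AF must exceed rr_cv_nonAF unless morphology_only is set",
         call. = FALSE)
  if (morphology_only && rhythm_only)
    stop("morphology_only and rhythm_only are mutually exclusive", call. = FALSE)
  if (diff(heart_rate_range) < 0 || any(heart_rate_range <= 0))
    stop("invalid heart_rate_range", call. = FALSE)
  structure(list(fs = fs, duration = duration,
                 heart_rate_range = heart_rate_range,
                 rr_cv_nonAF = rr_cv_nonAF, rr_cv_AF = rr_cv_AF,
                 f_wave_amplitude = f_wave_amplitude,
                 f_wave_freq_range = f_wave_freq_range,
                 p_amplitude = p_amplitude, pr_offset_s = pr_offset_s,
                 noise_sd = noise_sd,
                 morphology_only = morphology_only, rhythm_only = rhythm_only),
            class = "ecg_generator_config")
}

#' Run code with a private RNG seed, restoring global RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

gaussian_bump <- function(t, centre, sd, amp) {
  amp * exp(-((t - centre)^2) / (2 * sd^2))
}

#' Generate one synthetic ECG record
#'
#' Beats are built from Gaussian bumps (Q, R, S, T and optionally P), placed
#' at R-peak times whose RR intervals follow a log-normal distribution with
#' the class's target coefficient of variation. AF records additionally
#' receive an amplitude-modulated sinusoidal F-wave component gated away
#' from QRS complexes. Fully reproducible from `(config, label, seed)`.
#'
#' @param config An [ecg_generator_config()].
#' @param label `"AF"` or `"non-AF"`.
#' @param seed Integer seed for this record.
#' @return An object of class `ecg_record` with fields `samples`, `fs`,
#'   `label`, `r_peaks`, `p_waves`, `rr_intervals` (samples), `record_id`
#'   and `seed`. Annotation indices are 1-based.
#' @export
generate_record <- function(config, label = c("non-AF", "AF"), seed) {
  stopifnot(inherits(config, "ecg_generator_config"))
  label <- match.arg(label)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  with_seed(seed, {
    fs <- config$fs
    n <- round(fs * config$duration)
    t <- (seq_len(n) - 1) / fs

    # rhythm: log-normal RR series at the class's target CV
    cv <- if (label == "AF" && !config$morphology_only) config$rr_cv_AF
          else config$rr_cv_nonAF
    hr <- stats::runif(1, config$heart_rate_range[1], config$heart_rate_range[2])
    mean_rr <- 60 / hr
    sdlog <- sqrt(log(1 + cv^2))
    mulog <- log(mean_rr) - sdlog^2 / 2
    n_draw <- ceiling(config$duration / mean_rr * 2) + 8
    rr <- stats::rlnorm(n_draw, mulog, sdlog)
    first <- stats::runif(1, 0.25, 0.25 + mean_rr / 2)
    r_times <- first + c(0, cumsum(rr))
    r_times <- r_times[r_times < config$duration - 0.05]

    # morphology: AF records lose the P wave unless rhythm_only equalizes it
    has_p <- label == "non-AF" || config$rhythm_only
    has_f <- label == "AF" && !config$rhythm_only

    x <- numeric(n)
    for (rt in r_times) {
      r_amp <- stats::rnorm(1, 1, 0.05)
      x <- x + gaussian_bump(t, rt, 0.012, r_amp)
      x <- x + gaussian_bump(t, rt - 0.035, 0.009, -0.08)
      x <- x + gaussian_bump(t, rt + 0.035, 0.009, -0.10)
      x <- x + gaussian_bump(t, rt + 0.28, 0.05, 0.25)
      if (has_p)
        x <- x + gaussian_bump(t, rt - config$pr_offset_s, 0.02,
                               config$p_amplitude * stats::rnorm(1, 1, 0.1))
    }
    if (has_f && config$f_wave_amplitude > 0) {
      f0 <- stats::runif(1, config$f_wave_freq_range[1], config$f_wave_freq_range[2])
      phase <- stats::runif(1, 0, 2 * pi)
      fm <- stats::runif(1, 0.1, 0.5)
      envelope <- 0.7 + 0.3 * sin(2 * pi * fm * t + stats::runif(1, 0, 2 * pi))
      fwave <- config$f_wave_amplitude * envelope * sin(2 * pi * f0 * t + phase)
      # gate F waves away from the QRS complexes
      gate <- rep(1, n)
      for (rt in r_times) gate <- gate - exp(-((t - rt)^2) / (2 * 0.03^2))
      fwave <- fwave * pmin(pmax(gate, 0), 1)
      x <- x + fwave
    }
    if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)

    r_peaks <- round(r_times * fs) + 1L
    r_peaks <- r_peaks[r_peaks >= 1 & r_peaks <= n]
    p_waves <- if (has_p) {
      p <- r_peaks - round(config$pr_offset_s * fs)
      as.integer(p[p >= 1])
    } else integer(0)
    if (has_p && length(p_waves) < length(r_peaks))
      r_peaks <- r_peaks[r_peaks - round(config$pr_offset_s * fs) >= 1]

    structure(list(samples = x, fs = fs, label = label,
                   r_peaks = as.integer(r_peaks),
                   p_waves = as.integer(p_waves),
                   rr_intervals = as.integer(diff(r_peaks)),
                   record_id = sprintf("%s-%d", gsub("-", "", label), seed),
                   seed = as.integer(seed %% .Machine$integer.max)),
              class = "ecg_record")
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> %s, %d samples @ %g Hz, %d R peaks, %d P waves\n",
              x$record_id, x$label, length(x$samples), x$fs,
              length(x$r_peaks), length(x$p_waves)))
  invisible(x)
}

#' Generate a balanced labelled dataset
#'
#' Produces exactly `n_per_class` records per class. Per-record seeds are
#' derived deterministically from the master seed, so two calls with the
#' same arguments yield identical datasets.
#'
#' @param config An [ecg_generator_config()].
#' @param n_per_class Records per class (>= 1).
#' @param seed Master seed.
#' @return A list of `ecg_record` objects (non-AF block first).
#' @export
generate_dataset <- function(config, n_per_class, seed) {
  stopifnot(n_per_class >= 1)
  labels <- rep(c("non-AF", "AF"), each = n_per_class)
  seeds <- (as.double(seed) + seq_along(labels) * 7919) %% .Machine$integer.max
  mapply(function(lab, s) generate_record(config, lab, s),
         labels, seeds, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

record_labels <- function(records) {
  vapply(records, function(r) r$label, character(1))
}

#' Stratified test split and cross-validation folds
#'
#' Splits records into a held-out test set of the given fraction and
#' partitions the remainder into label-stratified folds, reproducibly from
#' the seed.
#'
#' @param records List of `ecg_record`s.
#' @param test_fraction Fraction held out for testing (0 < f < 1).
#' @param n_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed.
#' @return A list with `folds` (list of `n_folds` lists of records) and
#'   `test` (list of records). The union of all parts is the input and the
#'   parts are pairwise disjoint.
#' @export
train_test_split_records <- function(records, test_fraction = 0.1,
                                     n_folds = 5, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1, n_folds >= 2)
  labs <- record_labels(records)
  classes <- unique(labs)
  counts <- table(labs)
  if (any(counts < n_folds + 1))
    stop("too few records per class for stratified folds", call. = FALSE)
  with_seed(seed, {
    test_idx <- integer(0)
    fold_of <- rep(NA_integer_, length(records))
    for (cl in classes) {
      idx <- which(labs == cl)
      n_test <- round(length(idx) * test_fraction)
      shuffled <- sample(idx)
      test_idx <- c(test_idx, shuffled[seq_len(n_test)])
      rest <- shuffled[-seq_len(n_test)]
      fold_of[rest] <- rep_len(seq_len(n_folds), length(rest))
    }
    folds <- lapply(seq_len(n_folds), function(f) records[which(fold_of == f)])
    list(folds = folds, test = records[test_idx])
  })
}

#' Write / read a dataset as plain-text files
#'
#' Signals are stored as a CSV matrix (one column per record) alongside a
#' JSON sidecar with labels, seeds and annotations.
#'
#' @param records List of `ecg_record`s.
#' @param path Base path; `<path>.csv` and `<path>.json` are written.
#' @return `write_records`: the base path, invisibly. `read_records`: the
#'   reconstructed list of records.
#' @export
write_records <- function(records, path) {
  sig <- vapply(records, function(r) r$samples, numeric(length(records[[1]]$samples)))
  utils::write.csv(sig, paste0(path, ".csv"), row.names = FALSE)
  meta <- lapply(records, function(r)
    list(record_id = r$record_id, label = r$label, fs = r$fs, seed = r$seed,
         r_peaks = r$r_peaks, p_waves = r$p_waves,
         rr_intervals = r$rr_intervals))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  sig <- as.matrix(utils::read.csv(paste0(path, ".csv")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  lapply(seq_along(meta), function(i) {
    m <- meta[[i]]
    structure(list(samples = unname(sig[, i]), fs = m$fs, label = m$label,
                   r_peaks = as.integer(unlist(m$r_peaks)),
                   p_waves = as.integer(unlist(m$p_waves)),
                   rr_intervals = as.integer(unlist(m$rr_intervals)),
                   record_id = m$record_id, seed = m$seed),
              class = "ecg_record")
  })
}
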