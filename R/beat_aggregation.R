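#' Segment a record into R-peak-centred beat windows
#'
#' Cuts fixed-length windows centred on each annotated R peak; beats whose
#' window would exceed the signal bounds are dropped. A relevance map is
#' segmented identically so that per-beat relevance statistics align with
#' the beat waveform.
#'
#' @param record An `ecg_record` with R-peak annotations.
#' @param relevance Optional [relevance_map()] (or numeric vector) for the
#'   same record.
#' @param window Window length in samples (centred on the R peak; the
#'   actual segment length is `2 * floor(window / 2) + 1`). The default of
#'   300 samples (0.6 s at 500 Hz) spans one beat at up to 100 bpm.
#' @return List with `beats` (matrix, one row per beat), `relevance`
#'   (matching matrix or `NULL`) and `centers` (R-peak indices used).
#' @export
segment_beats <- function(record, relevance = NULL, window = 300) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$r_peaks) == 0)
    stop("record has no R-peak annotations", call. = FALSE)
  half <- floor(window / 2)
  n <- length(record$samples)
  centers <- record$r_peaks[record$r_peaks - half >= 1 &
                            record$r_peaks + half <= n]
  if (length(centers) == 0)
    stop("no beat window fits within the signal bounds", call. = FALSE)
  cut_rows <- function(x) t(vapply(centers, function(c0)
    x[(c0 - half):(c0 + half)], numeric(2 * half + 1)))
  rel <- NULL
  if (!is.null(relevance)) {
    v <- if (inherits(relevance, "relevance_map")) relevance$values else relevance
    stopifnot(length(v) == n)
    rel <- cut_rows(v)
  }
  list(beats = cut_rows(record$samples), relevance = rel, centers = centers)
}

#' Template beat: per-sample mean across beat segments
#'
#' @param beats Matrix of aligned beat segments (one row per beat).
#' @return Numeric vector (the averaged beat).
#' @export
template_beat <- function(beats) {
  if (is.null(dim(beats))) beats <- matrix(beats, nrow = 1)
  if (nrow(beats) < 1) stop("at least one beat segment required", call. = FALSE)
  colMeans(beats)
}

#' Per-template-sample relevance mean and intra-ECG variation coefficient
#'
#' For each template sample, the mean and (population) standard deviation
#' of the relevance across the record's beats are computed; the variation
#' coefficient is their ratio. Where the mean relevance is at most `tol`
#' the coefficient is set to 0 and flagged (attribute `cv_undefined`).
#'
#' @param rel_segments Matrix of aligned relevance segments (>= 2 rows).
#' @param tol Mean-relevance tolerance below which the cv is undefined.
#' @param force Allow a single beat (cv all zero) instead of erroring.
#' @return List with `mean`, `sd` and `cv` per template sample.
#' @export
relevance_beat_stats <- function(rel_segments, tol = 1e-12, force = FALSE) {
  if (is.null(dim(rel_segments))) rel_segments <- matrix(rel_segments, nrow = 1)
  if (nrow(rel_segments) < 2 && !force)
    stop("at least two beats are required for a defined standard deviation",
         call. = FALSE)
  m <- colMeans(rel_segments)
  s <- sqrt(colMeans(rel_segments^2) - m^2)
  s <- ifelse(s < 0, 0, s)          # numerical guard
  defined <- abs(m) > tol
  cv <- ifelse(defined, s / m, 0)
  out <- list(mean = m, sd = s, cv = cv)
  attr(out, "cv_undefined") <- which(!defined)
  out
}

#' Per-record template-beat summary
#'
#' Convenience wrapper: segments the record, averages the beats and
#' computes the relevance statistics.
#'
#' @inheritParams segment_beats
#' @return List with `template`, `mean_relevance`, `cv`, `n_beats`,
#'   `label`.
#' @export
record_beat_summary <- function(record, relevance, window = 300) {
  seg <- segment_beats(record, relevance, window)
  st <- relevance_beat_stats(seg$relevance, force = nrow(seg$relevance) < 2)
  list(template = template_beat(seg$beats), mean_relevance = st$mean,
       cv = st$cv, n_beats = nrow(seg$beats), label = record$label)
}

#' Class-level template-beat aggregate
#'
#' Averages per-record templates, mean relevance and intra-ECG variation
#' coefficients across all records of one class. Stored values are never
#' display-scaled; the conventional 1/10 scaling of the cv band is applied
#' only when plotting.
#'
#' @param summaries List of [record_beat_summary()] results.
#' @param class `"AF"` or `"non-AF"`.
#' @return Object of class `template_beat_summary` with fields `template`,
#'   `mean_relevance`, `intra_ecg_cv`, `label`, `n_records`,
#'   `display_scale` (0.1).
#' @export
class_aggregate <- function(summaries, class) {
  sel <- Filter(function(s) s$label == class, summaries)
  if (length(sel) == 0) stop("no records of the requested class", call. = FALSE)
  avg <- function(field) rowMeans(vapply(sel, function(s) s[[field]],
                                         numeric(length(sel[[1]]$template))))
  structure(list(template = avg("template"),
                 mean_relevance = avg("mean_relevance"),
                 intra_ecg_cv = avg("cv"),
                 label = class, n_records = length(sel),
                 display_scale = 0.1),
            class = "template_beat_summary")
}

#' @export
print.template_beat_summary <- function(x, ...) {
  cat(sprintf("<template_beat_summary> class %s, %d records, %d samples/beat\n",
              x$label, x$n_records, length(x$template)))
  invisible(x)
}

#' Plot a class template beat with projected relevance
#'
#' Draws the averaged beat, overlays the mean relevance and shades the
#' intra-ECG variation coefficient band scaled by `display_scale` (0.1);
#' the stored values remain unscaled.
#'
#' @param x A `template_beat_summary`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.template_beat_summary <- function(x, ...) {
  idx <- seq_along(x$template)
  graphics::plot(idx, x$template, type = "l", xlab = "template sample",
                 ylab = "amplitude / relevance",
                 main = sprintf("%s template beat (n = %d)", x$label,
                                x$n_records), ...)
  rel <- x$mean_relevance
  if (max(abs(rel)) > 0) rel <- rel / max(abs(rel)) * max(abs(x$template))
  band <- x$display_scale * x$intra_ecg_cv
  graphics::polygon(c(idx, rev(idx)), c(rel + band, rev(rel - band)),
                    border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::lines(idx, rel, col = "steelblue")
  invisible(x)
}

#' Write a template-beat summary as CSV
#'
#' @param x A `template_beat_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_beat_summary <- function(x, path) {
  utils::write.csv(data.frame(sample = seq_along(x$template),
                              template = x$template,
                              mean_relevance = x$mean_relevance,
                              intra_ecg_cv = x$intra_ecg_cv),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beat_summary
#' @param class Class label stored in the reconstructed summary.
#' @param n_records Number of records the summary was computed from.
#' @export
read_beat_summary <- function(path, class, n_records = NA_integer_) {
  d <- utils::read.csv(path)
  structure(list(template = d$template, mean_relevance = d$mean_relevance,
                 intra_ecg_cv = d$intra_ecg_cv, label = class,
                 n_records = n_records, display_scale = 0.1),
            class = "template_beat_summary")
}
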