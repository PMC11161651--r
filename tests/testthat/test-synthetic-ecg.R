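test_that("record generation is deterministic and respects class invariants", {
  cfg <- ecg_generator_config()
  a <- generate_record(cfg, "non-AF", seed = 11)
  b <- generate_record(cfg, "non-AF", seed = 11)
  expect_identical(a$samples, b$samples)
  expect_identical(a$r_peaks, b$r_peaks)

  expect_length(a$samples, cfg$fs * cfg$duration)
  expect_true(all(diff(a$r_peaks) > 0))
  expect_true(all(a$r_peaks >= 1 & a$r_peaks <= length(a$samples)))
  expect_equal(length(a$p_waves), length(a$r_peaks))
  pr <- round(cfg$pr_offset_s * cfg$fs)
  expect_true(all(a$r_peaks - a$p_waves == pr))

  af <- generate_record(cfg, "AF", seed = 11)
  expect_length(af$p_waves, 0)
  expect_false(identical(af$samples, a$samples))
  expect_equal(af$rr_intervals, diff(af$r_peaks))
})

test_that("generator rejects invalid configurations", {
  expect_error(ecg_generator_config(duration = 0), "duration")
  expect_error(ecg_generator_config(f_wave_amplitude = -1), "amplitude")
  expect_error(ecg_generator_config(rr_cv_AF = 0.01), "rr_cv_AF")
  expect_error(ecg_generator_config(morphology_only = TRUE, rhythm_only = TRUE),
               "exclusive")
  cfg <- ecg_generator_config()
  expect_error(generate_record(cfg, "AF"), "seed")
})

test_that("RR dispersion matches the configured coefficient of variation", {
  cfg <- ecg_generator_config(rr_cv_AF = 0.2)
  cvs <- vapply(1:200, function(s) {
    r <- generate_record(cfg, "AF", seed = s)
    stats::sd(r$rr_intervals) / mean(r$rr_intervals)
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 0.2), 0.03)
})

test_that("datasets are balanced, seeded and class-signal switches work", {
  cfg <- ecg_generator_config()
  ds <- generate_dataset(cfg, 10, seed = 3)
  expect_length(ds, 20)
  expect_equal(sum(vapply(ds, function(r) r$label, character(1)) == "AF"), 10)
  ds2 <- generate_dataset(cfg, 10, seed = 3)
  expect_identical(lapply(ds, `[[`, "samples"), lapply(ds2, `[[`, "samples"))

  # morphology_only: RR dispersion statistically indistinguishable
  cfgm <- ecg_generator_config(morphology_only = TRUE)
  dsm <- generate_dataset(cfgm, 200, seed = 5)
  cvs <- vapply(dsm, function(r)
    stats::sd(r$rr_intervals) / mean(r$rr_intervals), numeric(1))
  labs <- vapply(dsm, function(r) r$label, character(1))
  p <- stats::ks.test(cvs[labs == "AF"], cvs[labs == "non-AF"])$p.value
  expect_gt(p, 0.01)
})

test_that("rhythm_only equalizes beat morphology between the classes", {
  cfg <- ecg_generator_config(rhythm_only = TRUE)
  ds <- generate_dataset(cfg, 200, seed = 9)
  labs <- vapply(ds, function(r) r$label, character(1))
  templ <- function(recs) {
    segs <- do.call(rbind, lapply(recs, function(r)
      segment_beats(r, window = 300)$beats))
    template_beat(segs)
  }
  t_af <- templ(ds[labs == "AF"])
  t_non <- templ(ds[labs == "non-AF"])
  # compare the central half of the window (edges see neighbouring beats,
  # whose spacing legitimately differs between the rhythm classes)
  mid <- 76:226
  expect_lt(sqrt(mean((t_af[mid] - t_non[mid])^2)), 0.02)
})

test_that("stratified split partitions records with balanced folds", {
  cfg <- ecg_generator_config()
  ds <- generate_dataset(cfg, 50, seed = 2)          # 100 records
  sp <- train_test_split_records(ds, test_fraction = 0.1, n_folds = 5, seed = 4)
  expect_length(sp$test, 10)
  expect_true(all(lengths(sp$folds) == 18))
  ids <- function(recs) sort(vapply(recs, function(r) r$record_id, character(1)))
  all_ids <- ids(c(do.call(c, sp$folds), sp$test))
  expect_identical(all_ids, ids(ds))
  expect_equal(anyDuplicated(all_ids), 0L)
  # per-fold label balance within one record of the global ratio
  for (f in sp$folds) {
    n_af <- sum(vapply(f, function(r) r$label, character(1)) == "AF")
    expect_lte(abs(n_af - length(f) / 2), 1)
  }
  sp2 <- train_test_split_records(ds, 0.1, 5, seed = 4)
  expect_identical(ids(sp$test), ids(sp2$test))
  expect_error(train_test_split_records(ds[c(1:3, 51:53)], 0.1, 5), "too few")
})

test_that("records survive a plain-text write/read round trip", {
  cfg <- ecg_generator_config()
  ds <- generate_dataset(cfg, 2, seed = 8)
  path <- file.path(tempdir(), "ecg-roundtrip")
  write_records(ds, path)
  back <- read_records(path)
  expect_equal(lapply(back, `[[`, "samples"), lapply(ds, `[[`, "samples"),
               tolerance = 1e-12)
  expect_identical(lapply(back, `[[`, "r_peaks"), lapply(ds, `[[`, "r_peaks"))
  expect_identical(vapply(back, `[[`, "", "label"),
                   vapply(ds, `[[`, "", "label"))
})
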