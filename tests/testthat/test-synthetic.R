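test_that("double-gamma HRF starts at zero, peaks near 6 s and decays", {
  expect_identical(hemodynamic_response(0), 0)
  tt <- seq(0, 30, by = 0.01)
  h <- hemodynamic_response(tt)
  peak_t <- tt[which.max(h)]
  expect_gte(peak_t, 5)
  expect_lte(peak_t, 7)
  expect_lt(abs(hemodynamic_response(30)), 0.01 * max(h))
  expect_error(hemodynamic_response(-1), "t must be >= 0")
})

test_that("all-zero configuration yields constant-zero channels", {
  cfg <- quiet_config(n_participants = 1, amplitude_1back = 0,
                      amplitude_2back = 0, rest_duration = 10,
                      block_duration = 10, blocks_per_task = 1)
  rec <- generate_recording(cfg, "P01", seed = 3)
  expect_true(all(rec$channels == 0))
})

test_that("noise-free recordings show the planted 2-back > 1-back ordering", {
  cfg <- quiet_config(n_participants = 1, block_duration = 30)
  rec <- generate_recording(cfg, "P01", seed = 5)
  for (ch in colnames(rec$channels)) {
    x <- rec$channels[, ch]
    block_mean <- function(label) {
      b <- rec$task_blocks[rec$task_blocks$label == label, ]
      mean(unlist(lapply(seq_len(nrow(b)), function(i) {
        x[(b$start[i] + 1):b$end[i]]
      })))
    }
    expect_gt(block_mean("2-back"), block_mean("1-back"))
  }
  # misleading participants invert the ordering
  rec_m <- generate_recording(cfg, "P01", seed = 5, misleading = TRUE)
  x <- rec_m$channels[, "Left1"]
  b <- rec_m$task_blocks
  m1 <- mean(x[(b$start[1] + 1):b$end[1]])
  m2 <- mean(x[(b$start[2] + 1):b$end[2]])
  expect_gt(m1, m2)  # first block is 1-back, now the larger response
})

test_that("the planted effect grows monotonically with the amplitude gap", {
  diffs <- vapply(c(0.5, 1, 2, 4), function(a2) {
    cfg <- quiet_config(n_participants = 1, amplitude_1back = 0.5,
                        amplitude_2back = a2, block_duration = 30)
    rec <- generate_recording(cfg, "P01", seed = 1)
    x <- rec$channels[, "Left3"]
    b <- rec$task_blocks
    mean(x[(b$start[2] + 1):b$end[2]]) - mean(x[(b$start[1] + 1):b$end[1]])
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})

test_that("lateralization gain and nonlinearity shape channel amplitudes", {
  cfg <- quiet_config(n_participants = 1, left_lateralization_gain = 2,
                      block_duration = 30)
  rec <- generate_recording(cfg, "P01", seed = 1)
  expect_equal(rec$channels[, "Left1"], 2 * rec$channels[, "Right1"],
               tolerance = 1e-12)
  # quadratic distortion: a + k a^2 with k = 0.5, a = 1 doubles the 1-back level
  cfg_nl <- quiet_config(n_participants = 1, nonlinearity_strength = 0.5,
                         left_lateralization_gain = 1, block_duration = 30)
  rec_nl <- generate_recording(cfg_nl, "P01", seed = 1)
  b <- rec_nl$task_blocks
  base <- generate_recording(quiet_config(n_participants = 1,
                                          left_lateralization_gain = 1,
                                          block_duration = 30), "P01", seed = 1)
  i1 <- (b$start[1] + 1):b$end[1]
  expect_equal(mean(rec_nl$channels[i1, "Right1"]),
               1.5 * mean(base$channels[i1, "Right1"]), tolerance = 1e-10)
})

test_that("cohorts are reproducible and sized correctly", {
  cfg <- simulation_config(n_participants = 28, seed = 11)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 28)
  cohort2 <- generate_cohort(cfg)
  expect_identical(cohort, cohort2)
  rec_a <- generate_recording(cfg, "X", seed = 7)
  rec_b <- generate_recording(cfg, "X", seed = 7)
  expect_identical(rec_a, rec_b)
})

test_that("exactly round(misleading_fraction * n) participants are misleading", {
  for (frac in c(0, 0.25, 0.5)) {
    cfg <- simulation_config(n_participants = 10, misleading_fraction = frac,
                             seed = 2)
    cohort <- generate_cohort(cfg)
    n_mis <- sum(vapply(cohort, function(r) isTRUE(r$misleading), logical(1)))
    expect_identical(n_mis, as.integer(floor(frac * 10 + 0.5)))
  }
})

test_that("misleading_fraction = 0 keeps 2-back norms above 1-back per participant", {
  cfg <- quiet_config(n_participants = 5, block_duration = 30)
  cohort <- generate_cohort(cfg)
  for (rec in cohort) {
    x <- rec$channels[, "Left1"]
    b <- rec$task_blocks
    norms <- vapply(seq_len(nrow(b)), function(i) {
      sqrt(sum(x[(b$start[i] + 1):b$end[i]]^2))
    }, numeric(1))
    expect_gt(min(norms[b$label == "2-back"]), max(norms[b$label == "1-back"]))
  }
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(misleading_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(channel_names = c("A", "B", "C")), "4 channel")
  expect_error(simulation_config(sampling_rate = 0), "sampling_rate")
  expect_error(simulation_config(rest_duration = -1), "rest_duration")
})

test_that("recording CSV round-trips and rejects malformed files", {
  cfg <- quiet_config(n_participants = 1, rest_duration = 1,
                      block_duration = 1, blocks_per_task = 1,
                      noise_sd = 0.5)
  rec <- generate_recording(cfg, "P01", seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$channels, rec$channels, tolerance = 1e-12)
  expect_identical(back$task_blocks, rec$task_blocks)
  expect_identical(back$rest_interval, rec$rest_interval)
  expect_identical(back$participant_id, rec$participant_id)
  expect_identical(back$sampling_rate, rec$sampling_rate)

  # three channels only
  bad <- withr::local_tempfile(fileext = ".csv")
  tab <- utils::read.csv(path, skip = 1, check.names = FALSE)
  writeLines(c(readLines(path, n = 1), utils::capture.output(
    utils::write.csv(tab[, 1:4], row.names = FALSE))), bad)
  file.copy(sub("\\.csv$", "_events.csv", path), sub("\\.csv$", "_events.csv", bad))
  expect_error(read_recording(bad), "expected 4 channels")

  # block interval out of the series range
  ev <- utils::read.csv(sub("\\.csv$", "_events.csv", path))
  ev$end[nrow(ev)] <- 10 * nrow(tab)
  utils::write.csv(ev, sub("\\.csv$", "_events.csv", path), row.names = FALSE)
  expect_error(read_recording(path), "out of series range")
})

test_that("cohort directories round-trip through the manifest", {
  cfg <- quiet_config(n_participants = 3, rest_duration = 2,
                      block_duration = 2, blocks_per_task = 1, noise_sd = 0.2)
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_length(back, 3)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$channels, cohort[[i]]$channels, tolerance = 1e-12)
  }
  expect_error(read_cohort(withr::local_tempdir()), "cohort.yaml")
})
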