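test_that("degenerate background process is exactly constant", {
  cfg <- synthetic_config(
    background = list(log_level = log(100), ar_coef = 0.9,
                      innovation_sd = 0, drift_per_hour = 0),
    calibrate = FALSE
  )
  frame <- withr::with_seed(1, generate_background(cfg, 700))
  counts <- as.matrix(frame[, -1])
  expect_true(all(apply(counts, 2, function(col) length(unique(col)) == 1)))
  expect_error(generate_background(cfg, 30), "10 sampling intervals")
})

test_that("background draws are seed-reproducible", {
  cfg <- synthetic_config(calibrate = FALSE)
  a <- withr::with_seed(5, generate_background(cfg, 1400))
  b <- withr::with_seed(5, generate_background(cfg, 1400))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("log background autocorrelation tracks the configured coefficient", {
  cfg <- synthetic_config(calibrate = FALSE)
  frame <- withr::with_seed(8, generate_background(cfg, 70000))
  lt <- log(rowSums(as.matrix(frame[, -1])))
  ac <- stats::acf(lt, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac - cfg$background$ar_coef), 0.05)
})

test_that("event injection composes amplitudes exactly before rounding", {
  cfg <- synthetic_config(event_decay_intervals = 1, calibrate = FALSE)
  frame <- withr::with_seed(3, generate_background(cfg, 1400))
  before <- aggregate_size_fractions(frame)
  inj <- inject_event(frame, time_s = 700, label = "burp", config = cfg,
                      amplitude = c(aerosol = 100, droplet = 0))
  after <- aggregate_size_fractions(inj$frame)
  i <- which(before$time_s >= 700)[1]
  # exact on the latent intensity; counts differ only by per-channel rounding
  dlam <- rowSums(attr(inj$frame, "lambda")) -
    rowSums(attr(frame, "lambda"))
  expect_equal(dlam[i], 100)
  expect_equal(dlam[-i], rep(0, length(dlam) - 1))
  expect_lt(abs(after$aerosol[i] - before$aerosol[i] - 100), 3)
  expect_equal(after$aerosol[-i], before$aerosol[-i])
  expect_equal(after$droplet, before$droplet)
  expect_equal(inj$truth$aerosol_amp, 100)

  # zero amplitude leaves the series untouched
  zero <- inject_event(frame, 700, "burp", cfg,
                       amplitude = c(aerosol = 0, droplet = 0))
  expect_identical(as.data.frame(zero$frame), as.data.frame(frame))
})

test_that("multi-interval decay spreads the amplitude with geometric weights", {
  cfg <- synthetic_config(event_decay = 0.5, event_decay_intervals = 3,
                          calibrate = FALSE)
  frame <- withr::with_seed(4, generate_background(cfg, 1400))
  lam0 <- attr(frame, "lambda")
  inj <- inject_event(frame, time_s = 700, label = "burp", config = cfg,
                      amplitude = c(aerosol = 70, droplet = 0))
  dlam <- rowSums(attr(inj$frame, "lambda")) - rowSums(lam0)
  i <- which(frame$time_s >= 700)[1]
  expect_equal(dlam[i + 0:2], 70 * c(4, 2, 1) / 7)
  expect_equal(sum(dlam), 70)
})

test_that("throat spray boosts aerosols more than droplets relative to null", {
  cfg <- synthetic_config(event_sd_log = 0, calibrate = TRUE)
  frame <- withr::with_seed(6, generate_background(cfg, 1400))
  inj <- withr::with_seed(7, inject_event(frame, 700, "throat_spray", cfg,
                                          arm = "Cytosponge"))
  rel_aero <- inj$truth$aerosol_amp / cfg$null_excess[["aerosol"]]
  rel_drop <- inj$truth$droplet_amp / cfg$null_excess[["droplet"]]
  expect_gt(rel_aero, rel_drop)
  # mean amplitude is (ratio - 1) x null level
  expect_equal(rel_aero, 138.1 - 1, tolerance = 1e-6)
  expect_equal(rel_drop, 16.2 - 1, tolerance = 1e-6)
})

test_that("a generated study is complete, parseable and deterministic", {
  cfg <- tiny_config(seed = 11)
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  study_a <- generate_study(cfg, dir = dir_a)
  study_b <- generate_study(cfg, dir = dir_b)

  expect_length(study_a$procedures, 8)
  expect_equal(sort(list.files(dir_a)), sort(list.files(dir_b)))
  # byte-identical outputs under the same config and seed
  for (f in list.files(dir_a)) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)),
                     label = f)
  }

  # every emitted file round-trips through the readers
  loaded <- read_study(dir_a)
  expect_length(loaded, 8)
  for (i in seq_along(loaded)) {
    orig <- study_a$procedures[[i]]
    expected <- as.data.frame(orig$frame)
    attr(expected, "lambda") <- NULL  # in-memory latent intensity only
    expect_equal(as.data.frame(loaded[[i]]$frame), expected)
    expect_equal(loaded[[i]]$record$arm, orig$record$arm)
    expect_equal(as.data.frame(loaded[[i]]$record$annotations),
                 as.data.frame(orig$record$annotations))
  }
  # emitted counts equal the rounded latent intensity (truth consistency)
  for (pr in study_a$procedures) {
    expect_equal(unname(as.matrix(pr$frame[, -1])),
                 unname(round(attr(pr$frame, "lambda"))))
  }
})

test_that("every procedure retains a clean 5-minute reference window", {
  study <- generate_study(tiny_config(seed = 13))
  for (pr in study$procedures) {
    win <- reference_window(pr$record)
    expect_true(win$valid)
    expect_equal(win$end_s - win$start_s, 300)
  }
})

test_that("generated burp rates converge to the configured means", {
  cfg <- synthetic_config(calibrate = FALSE)
  withr::with_seed(17, {
    for (arm in c("EGD", "Cytosponge")) {
      rates <- vapply(1:500, function(i) {
        dur <- aerosolwatch:::sample_duration_min(cfg, arm)
        ann <- aerosolwatch:::schedule_events(cfg, arm, 360,
                                              360 + dur * 60, "none")
        sum(ann$label == "burp") * 20 / dur
      }, numeric(1))
      target <- cfg$burp_rate_per_20min[[arm]]
      expect_lt(abs(mean(rates) - target) / target, 0.1)
    }
  })
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_egd = 1), ">= 2")
  expect_error(synthetic_config(
    background = list(log_level = 4, ar_coef = 1.2, innovation_sd = 0.05,
                      drift_per_hour = 0)), "ar_coef")
  expect_error(synthetic_config(pre_roll_min = 3), "reference window")
  expect_error(synthetic_config(channel_weights = rep(1, 5)),
               "one per channel")
})
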