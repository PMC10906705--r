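test_that("event excess subtracts the local baseline expectation", {
  const <- make_series(rep(7, 30), rep(3, 30))
  ex <- extract_event_excess(const, time_s = 140)
  expect_equal(ex$aerosol, 0)
  expect_equal(ex$droplet, 0)

  # baseline 5/interval for 10 intervals, event intervals [5, 50, 5]
  aero <- c(rep(5, 10), 5, 50, 5, rep(5, 5))
  s <- make_series(aero)
  ex2 <- extract_event_excess(s, time_s = 70)
  expect_equal(ex2$aerosol, 60 - 5 * 3)

  expect_error(extract_event_excess(s, time_s = 35), "too close")
})

test_that("event excess is invariant to constant series offsets", {
  withr::with_seed(5, {
    for (i in 1:8) {
      x <- rpois(40, 20)
      s0 <- make_series(x)
      s1 <- make_series(x + 500)
      t_ev <- 7 * sample(12:30, 1)
      expect_equal(extract_event_excess(s1, t_ev)$aerosol,
                   extract_event_excess(s0, t_ev)$aerosol)
    }
  })
})

test_that("null-reference sampling respects gaps and is reproducible", {
  s <- make_series(rpois(200, 30))
  none <- tibble::tibble(time_s = numeric(), label = character())
  nulls <- sample_null_events(s, none, n_events = 5, seed = 42)
  expect_equal(nrow(nulls), 5)
  expect_true(all(nulls$label == "null_reference"))
  expect_true(all(diff(sort(nulls$time_s)) >= 60))

  again <- sample_null_events(s, none, n_events = 5, seed = 42)
  expect_identical(nulls$time_s, again$time_s)

  other <- sample_null_events(s, none, n_events = 5, seed = 43)
  expect_false(identical(nulls$time_s, other$time_s))

  # annotations everywhere leave no eligible stretch
  busy <- tibble::tibble(time_s = seq(0, 1400, by = 30),
                         label = "burp")
  expect_error(sample_null_events(s, busy, n_events = 2),
               "Insufficient annotation-free time")
})

test_that("null sampling avoids boundary times whose windows they straddle", {
  s <- make_series(rpois(200, 30))
  none <- tibble::tibble(time_s = numeric(), label = character())
  nulls <- sample_null_events(s, none, n_events = 8, seed = 1,
                              avoid_times_s = 700)
  # 700 must not fall inside any null's [t - 70, t + 21) span
  expect_true(all(700 <= nulls$time_s - 70 | 700 >= nulls$time_s + 21))
})

test_that("bootstrap ratios are exchangeable and well-behaved under self-comparison", {
  withr::with_seed(9, {
    ev <- tibble::tibble(procedure_id = "p", label = "removal",
                         time_s = seq_len(17) * 100,
                         aerosol = rlnorm(17, 3, 1),
                         droplet = rlnorm(17, 2, 1))
    self <- bootstrap_ratio(ev, ev, "aerosol", n_boot = 2000, seed = 1)
    expect_equal(self$ratio, 1)
    expect_gt(self$p_value, 0.5)

    scaled <- dplyr::mutate(ev, aerosol = aerosol * 10)
    up <- bootstrap_ratio(scaled, ev, "aerosol", n_boot = 2000, seed = 2)
    expect_equal(up$ratio, 10)
    expect_lt(up$p_value, 0.05)

    down <- bootstrap_ratio(ev, scaled, "aerosol", n_boot = 2000, seed = 2)
    expect_equal(down$ratio, 1 / up$ratio, tolerance = 1e-12)

    expect_error(bootstrap_ratio(ev, ev, "aerosol", n_boot = 10),
                 "at least 1000")
    expect_error(bootstrap_ratio(ev[0, ], ev, "aerosol"), "non-empty")
  })
})

test_that("well-separated groups reject consistently across seeds", {
  withr::with_seed(33, {
    ev <- tibble::tibble(procedure_id = "p", label = "removal",
                         time_s = seq_len(17) * 100,
                         aerosol = rlnorm(17, 3, 0.8),
                         droplet = 0)
    scaled <- dplyr::mutate(ev, aerosol = aerosol * 10)
    rejections <- vapply(1:20, function(s) {
      bootstrap_ratio(scaled, ev, "aerosol", n_boot = 1000,
                      seed = s)$p_value < 0.05
    }, logical(1))
    expect_gte(mean(rejections), 0.95)
  })
})

test_that("event-vs-null wrapper labels comparisons and checks inputs", {
  withr::with_seed(2, {
    ev <- tibble::tibble(procedure_id = "p", label = "removal",
                         time_s = 1:10 * 100,
                         aerosol = rlnorm(10, 4, 0.5), droplet = 0)
    nulls <- tibble::tibble(procedure_id = "p", label = "null_reference",
                            time_s = 1:30 * 50,
                            aerosol = rnorm(30, 0, 2), droplet = 0)
    est <- event_vs_null(ev, nulls, "aerosol", n_boot = 1000, seed = 4)
    expect_equal(est$comparison, "removal_vs_null")
    expect_equal(est$n_a, 10)
    expect_error(event_vs_null(ev, nulls[0, ], "aerosol"), "non-empty")
  })
})
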