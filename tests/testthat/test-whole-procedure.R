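test_that("log-ratio test recovers exact geometric-mean ratios", {
  same <- log_ratio_test(c(10, 20, 40), c(10, 20, 40), pseudocount = 0)
  expect_equal(same$ratio, 1)
  expect_equal(same$p_value, 1)

  doubled <- log_ratio_test(c(20, 40, 80), c(10, 20, 40), pseudocount = 0)
  expect_equal(doubled$ratio, 2)

  expect_error(log_ratio_test(5, c(1, 2)), "at least 2")
  expect_error(log_ratio_test(c(-2, 3), c(1, 2), pseudocount = 0),
               "Non-finite")
})

test_that("log-ratio p-values match the closed-form Welch t on logs", {
  a <- c(10, 20, 40); b <- c(11, 19, 42)
  est <- log_ratio_test(a, b, pseudocount = 0)
  oracle <- welch_oracle(log(a), log(b))
  expect_equal(est$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(est$ratio, exp(mean(log(a)) - mean(log(b))),
               tolerance = 1e-12)
})

test_that("arm comparison is scale-equivariant and exchangeable", {
  withr::with_seed(3, {
    a <- rlnorm(12, 5, 0.6)
    b <- rlnorm(9, 5, 0.8)
    base <- log_ratio_test(a, b, pseudocount = 0)
    scaled <- log_ratio_test(a * 3, b, pseudocount = 0)
    expect_equal(scaled$ratio, base$ratio * 3, tolerance = 1e-12)
    # joint rescaling is a nuisance transformation: nothing changes
    both <- log_ratio_test(a * 3, b * 3, pseudocount = 0)
    expect_equal(both$ratio, base$ratio, tolerance = 1e-12)
    expect_equal(both$p_value, base$p_value, tolerance = 1e-12)

    swapped <- log_ratio_test(b, a, pseudocount = 0)
    expect_equal(swapped$ratio, 1 / base$ratio, tolerance = 1e-12)
    expect_equal(swapped$ci_low, 1 / base$ci_high, tolerance = 1e-12)
    expect_equal(swapped$ci_high, 1 / base$ci_low, tolerance = 1e-12)
    expect_equal(swapped$p_value, base$p_value, tolerance = 1e-12)
  })
})

test_that("procedure summaries rescale raw counts and zero out constant spikes", {
  # 5-s sampling so the 10-min procedure and 5-min reference tile exactly:
  # constant 10 aerosol counts per interval
  n <- 240  # 20 minutes of recording
  s <- make_series(rep(10, n), rep(2, n), period = 5)
  rec <- procedure_record("p", "Cytosponge", 300, 900)
  summ <- summarize_procedure(s, rec)
  aero <- summ[summ$fraction == "aerosol", ]
  # 120 intervals x 10 counts over 10 min -> x2 for the 20-min equivalent
  expect_equal(aero$proc_raw, 120 * 10 * 2)
  expect_equal(aero$proc_spike, 0)  # constant series has no spikes
  expect_equal(aero$ref_raw, 60 * 10 * 4)
  expect_true(aero$reference_ok)
  # identical constant levels: procedure/reference ratio is exactly 1
  expect_equal(aero$proc_raw / aero$ref_raw, 1)
})

test_that("procedure-vs-reference pairing recovers exact fold changes", {
  summaries <- dplyr::bind_rows(lapply(1:6, function(i) {
    ref <- 100 * i
    tibble::tibble(
      procedure_id = paste0("p", i), arm = "Cytosponge",
      sedation = "none", fraction = "aerosol", duration_min = 10,
      proc_raw = 3 * ref, proc_spike = 3 * ref,
      ref_raw = ref, ref_spike = ref, reference_ok = TRUE
    )
  }))
  est <- procedure_vs_reference(summaries, "aerosol", "raw",
                                pseudocount = 0)
  expect_equal(est$ratio, 3)

  ident <- dplyr::mutate(summaries, proc_raw = ref_raw)
  est0 <- procedure_vs_reference(ident, "aerosol", "raw", pseudocount = 0)
  expect_equal(est0$ratio, 1)
  expect_equal(est0$p_value, 1)
})

test_that("arm comparison enforces preconditions and recovers exact scaling", {
  mk <- function(arm, vals, sedation = "none") {
    dplyr::bind_rows(lapply(seq_along(vals), function(i) {
      tibble::tibble(
        procedure_id = paste0(arm, i), arm = arm, sedation = sedation,
        fraction = "aerosol", duration_min = 10,
        proc_raw = vals[i], proc_spike = vals[i] / 2,
        ref_raw = NA_real_, ref_spike = NA_real_, reference_ok = FALSE
      )
    }))
  }
  a <- c(120, 340, 560, 210)
  summaries <- dplyr::bind_rows(mk("EGD", 2 * a), mk("Cytosponge", a))
  est <- compare_arms(summaries, "aerosol", "raw", pseudocount = 0)
  expect_equal(est$ratio, 2, tolerance = 1e-12)

  single <- dplyr::bind_rows(mk("EGD", 2 * a), mk("Cytosponge", 100))
  expect_error(compare_arms(single, "aerosol", "raw"), ">= 2 procedures")
})

test_that("arm comparison under a simulated null is unremarkable", {
  withr::with_seed(19, {
    vals <- function() rlnorm(20, 6, 0.5)
    mk <- function(arm) {
      v <- vals()
      dplyr::bind_rows(lapply(seq_along(v), function(i) {
        tibble::tibble(
          procedure_id = paste0(arm, i), arm = arm, sedation = "none",
          fraction = "aerosol", duration_min = 10,
          proc_raw = v[i], proc_spike = v[i], ref_raw = NA_real_,
          ref_spike = NA_real_, reference_ok = FALSE
        )
      }))
    }
    est <- compare_arms(dplyr::bind_rows(mk("EGD"), mk("Cytosponge")),
                        "aerosol", "raw")
    expect_gt(est$ratio, 0.5)
    expect_lt(est$ratio, 2)
    expect_gt(est$p_value, 0.001)
  })
})

test_that("throat-spray exclusion restricts the capsule-sponge arm only", {
  mk <- function(arm, vals, sedation) {
    dplyr::bind_rows(lapply(seq_along(vals), function(i) {
      tibble::tibble(
        procedure_id = paste0(arm, sedation, i), arm = arm,
        sedation = sedation, fraction = "aerosol", duration_min = 10,
        proc_raw = vals[i], proc_spike = vals[i], ref_raw = NA_real_,
        ref_spike = NA_real_, reference_ok = FALSE
      )
    }))
  }
  summaries <- dplyr::bind_rows(
    mk("EGD", c(200, 300, 400), "throat_spray_only"),
    mk("Cytosponge", c(100, 150), "none"),
    mk("Cytosponge", c(9000, 9500), "throat_spray_only")
  )
  all_in <- compare_arms(summaries, "aerosol", "raw")
  no_spray <- compare_arms(summaries, "aerosol", "raw",
                           exclude_throat_spray = TRUE)
  expect_equal(no_spray$n_a, 3)  # EGD procedures all retained
  expect_equal(no_spray$n_b, 2)  # spray-free Cytosponge only
  expect_gt(no_spray$ratio, all_in$ratio)
})
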