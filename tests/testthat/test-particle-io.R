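test_that("particle CSVs parse and round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "time_s,c0.5_0.7,c0.7_1.0,c1.0_3.0,c3.0_5.0,c5.0_10.0,c10.0_25.0",
    "0,10,5,3,2,1,0",
    "7,11,4,3,2,0,1",
    "14,9,6,2,3,1,0"
  ), path)
  frame <- read_particle_csv(path)
  expect_s3_class(frame, "particle_frame")
  expect_equal(nrow(frame), 3)
  expect_equal(ncol(frame), 7)  # time + 6 channels
  expect_equal(frame$c0.5_0.7, c(10, 11, 9))

  out <- withr::local_tempfile(fileext = ".csv")
  write_particle_csv(frame, out)
  back <- read_particle_csv(out)
  expect_equal(as.data.frame(back), as.data.frame(frame))
})

test_that("malformed particle CSVs are rejected with located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "time_s,c0.5_0.7,c0.7_1.0,c1.0_3.0,c3.0_5.0,c5.0_10.0,c10.0_25.0",
    "0,10,5,3,2,1,0",
    "7,11,-4,3,2,0,1"
  ), path)
  expect_error(read_particle_csv(path), "row.*2", ignore.case = TRUE)

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,c0.5_0.7", "0,10"), path2)
  expect_error(read_particle_csv(path2), "missing column")

  expect_error(read_particle_csv(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("cumulative instrument exports are differenced on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  # cumulative >= lower-bound counts: 21,11,6,3,1,1 -> diffs 10,5,3,2,0,1
  writeLines(c(
    "time_s,c0.5_0.7,c0.7_1.0,c1.0_3.0,c3.0_5.0,c5.0_10.0,c10.0_25.0",
    "0,21,11,6,3,1,1"
  ), path)
  frame <- read_particle_csv(path, cumulative = TRUE)
  expect_equal(unname(unlist(frame[1, -1])), c(10, 5, 3, 2, 0, 1))
})

test_that("frame validation enforces the count and timestamp invariants", {
  expect_error(make_frame(matrix(-1, 1, 6)), "non-negative")
  expect_error(make_frame(matrix(1.5, 2, 6)), "integer")
  expect_error(
    particle_frame(c(0, 7, 20), matrix(1L, 3, 6)),
    "spaced"
  )
  expect_error(particle_frame(0, matrix(1L, 1, 5)), "channels")
})

test_that("annotation logs validate the vocabulary and sort by time", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,label", "300,removal", "150,burp"), path)
  ann <- read_annotations(path)
  expect_equal(ann$label, c("burp", "removal"))
  expect_equal(ann$time_s, c(150, 300))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_s,label", empty)
  expect_equal(nrow(read_annotations(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".csv")
  # coughs are recorded as burp; "cough" is not a label
  writeLines(c("time_s,label", "10,cough"), bad)
  expect_error(read_annotations(bad), "burp")
  expect_error(read_annotations(bad), "cough")
})

test_that("annotations round-trip through CSV", {
  ann <- tibble::tibble(time_s = c(10, 250.5), label = c("burp", "removal"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  expect_equal(as.data.frame(read_annotations(path)), as.data.frame(ann))
})

test_that("procedure records round-trip through JSON", {
  rec <- procedure_record(
    "p1", "Cytosponge", 360, 840, sedation = "throat_spray_only",
    demographics = list(age = 61, sex = "male", bmi = 27.0, smoker = FALSE),
    annotations = tibble::tibble(time_s = c(500, 400),
                                 label = c("removal", "insertion")),
    recording_end_s = 900
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_procedure_record(rec, path)
  back <- read_procedure_record(path)
  expect_equal(back$procedure_id, "p1")
  expect_equal(back$arm, "Cytosponge")
  expect_equal(back$annotations$label, c("insertion", "removal"))
  expect_equal(back$demographics$age, 61)
  expect_true(back$reference_ok)
})

test_that("records flag a missing pre-procedure reference period", {
  rec <- procedure_record("p2", "EGD", 200, 700)
  expect_false(rec$reference_ok)
})

test_that("result tables round-trip numerics to 12 significant digits", {
  est <- ratio_estimate(2.1634567891234, 1.4812345678901, 3.1298765432109,
                        0.000123456789012, 37, 18, "log_t",
                        comparison = "EGD_vs_Cytosponge",
                        fraction = "aerosol", variant = "raw")
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(list(est), path)
  back <- read_results(path)
  expect_equal(nrow(back), 1)
  expect_equal(names(back)[1:4],
               c("comparison", "fraction", "variant", "ratio"))
  for (col in c("ratio", "ci_low", "ci_high", "p_value")) {
    expect_equal(back[[col]], tidy(est)[[col]], tolerance = 1e-12)
  }

  empty <- withr::local_tempfile(fileext = ".csv")
  write_results(list(), empty)
  expect_equal(nrow(read_results(empty)), 0)
})

test_that("channel banks are contiguous and partition under the cutoff", {
  bank <- channel_bank()
  expect_equal(nrow(bank), 6)
  expect_equal(bank$lower_um[1], 0.5)
  expect_equal(bank$upper_um[6], 25)
  cl <- classify_channels(bank, 5)
  expect_setequal(levels(cl$fraction), c("aerosol", "droplet"))
  expect_false(any(is.na(cl$fraction)))  # partition-complete
  expect_equal(sum(cl$fraction == "aerosol"), 4)
  expect_error(classify_channels(bank, 4), "straddle")
  expect_error(channel_bank(c(0.5, 2), c(1, 3)), "contiguous")
  expect_error(channel_bank(2, 1), "lower_um < upper_um")
})
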