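test_that("TIC normalization rescales to unit sum and preserves proportions", {
  sp <- toy_spectra(list(s1 = c(`57` = 1, `73` = 3)))
  out <- tic_normalize(sp)
  m <- spectra_matrix(out)
  expect_equal(unname(m[1, "mz_57"]), 0.25)
  expect_equal(unname(m[1, "mz_73"]), 0.75)
  expect_equal(unname(rowSums(m)), 1, tolerance = 1e-12)
  expect_identical(normalization_state(out), "tic")

  scaled <- toy_spectra(list(s1 = c(`57` = 10, `73` = 30)))
  expect_equal(spectra_matrix(tic_normalize(scaled)), m)
})

test_that("mean normalization gives unit channel mean and is idempotent", {
  sp <- as_spectra(toy_spectrum(setNames(rep(7, 421), 30:450)))
  out <- mean_normalize(sp)
  m <- spectra_matrix(out)
  expect_equal(unname(m[1, ]), rep(1, 421))

  sp2 <- toy_spectra(list(s1 = c(`40` = 2, `41` = 4, `42` = 6)))
  m1 <- spectra_matrix(mean_normalize(sp2))
  expect_equal(unname(m1[1, "mz_41"]), 4 / (12 / 421))
  m2 <- spectra_matrix(mean_normalize(mean_normalize(sp2)))
  expect_equal(m1, m2)
})

test_that("all-zero spectra are rejected by both normalizations", {
  sp <- toy_spectra(list(s1 = c(`57` = 0)))
  expect_error(tic_normalize(sp), class = "pymbms_error_invalid_spectrum")
  expect_error(mean_normalize(sp), class = "pymbms_error_invalid_spectrum")
})

test_that("replicate averaging is the channel-wise mean with counts recorded", {
  sp <- as_spectra(dplyr::bind_rows(
    toy_spectrum(c(`57` = 0, `73` = 2), "a", "r1"),
    toy_spectrum(c(`57` = 2, `73` = 0), "a", "r2"),
    toy_spectrum(c(`98` = 5), "b", "r1")
  ))
  avg <- average_replicates(sp)
  m <- spectra_matrix(avg)
  expect_equal(unname(m["a", c("mz_57", "mz_73")]), c(1, 1))
  expect_equal(avg$n_replicates[avg$sample_id == "a"], 2L)
  expect_equal(avg$n_replicates[avg$sample_id == "b"], 1L)
  expect_equal(unname(m["b", "mz_98"]), 5)

  twin <- as_spectra(dplyr::bind_rows(
    toy_spectrum(c(`126` = 3), "a", "r1"),
    toy_spectrum(c(`126` = 3), "a", "r2")
  ))
  expect_equal(unname(spectra_matrix(average_replicates(twin))["a", "mz_126"]), 3)
})

test_that("TIC normalization commutes with averaging when replicate TICs are equal", {
  sp <- as_spectra(dplyr::bind_rows(
    toy_spectrum(c(`57` = 1, `73` = 3), "a", "r1"),
    toy_spectrum(c(`57` = 3, `73` = 1), "a", "r2")
  ))
  a <- spectra_matrix(average_replicates(tic_normalize(sp)))
  b <- spectra_matrix(tic_normalize(average_replicates(sp)))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("binding spectra refuses mixed normalization states", {
  raw <- toy_spectra(list(s1 = c(`57` = 1)))
  ticd <- tic_normalize(toy_spectra(list(s2 = c(`57` = 1))))
  expect_error(bind_spectra(raw, ticd),
               class = "pymbms_error_inconsistent_normalization")
  ok <- bind_spectra(raw, toy_spectra(list(s3 = c(`60` = 1))))
  expect_equal(nrow(ok), 2)
})

test_that("spectra files round-trip losslessly and bad input is rejected", {
  withr::with_tempdir({
    truth <- sample_compositions(5, seed = 11)
    sp <- compose_spectra(truth, seed = 12)
    write_spectra(sp, "spectra.csv")
    back <- read_spectra("spectra.csv", normalization = "tic")
    expect_equal(as.matrix(back[mz_cols_test()]),
                 as.matrix(sp[mz_cols_test()]), tolerance = 0)
    expect_identical(back$sample_id, sp$sample_id)
    expect_identical(back$replicate_id, sp$replicate_id)

    # negative intensity
    bad <- sp
    bad$mz_57[1] <- -1
    readr::write_csv(bad, "bad.csv")
    expect_error(read_spectra("bad.csv"), class = "pymbms_error_parse")

    # missing channel column
    dropped <- sp[setdiff(names(sp), "mz_200")]
    readr::write_csv(dropped, "miss.csv")
    expect_error(read_spectra("miss.csv"), class = "pymbms_error_parse")

    # duplicate (sample_id, replicate_id)
    dup <- dplyr::bind_rows(sp[1, ], sp[1, ])
    readr::write_csv(dup, "dup.csv")
    expect_error(read_spectra("dup.csv"), class = "pymbms_error_parse")
  })
})

test_that("fractional m/z columns are rejected rather than rounded", {
  sp <- toy_spectrum(c(`57` = 1))
  sp$mz_57.5 <- 0.1
  expect_error(as_spectra(sp), class = "pymbms_error_parse")
})

test_that("metadata validation enforces pedigree parents", {
  md <- tibble::tibble(
    sample_id = c("a", "b"), genotype_id = c("a", "b"),
    population = c("natural", "pedigree"),
    mother_id = c(NA, "m1"), father_id = c(NA, NA)
  )
  expect_error(pymbms:::validate_sample_metadata(md),
               class = "pymbms_error_parse")
  md$father_id[2] <- "f1"
  expect_silent(pymbms:::validate_sample_metadata(md))
})
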