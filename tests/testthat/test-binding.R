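test_that("occupancy enumeration matches hand counts on small arrays", {
  # 4 intact repeats, full placements only: a unique two-dimer tiling
  cfgs4 <- enumerate_occupancy(repeat_array("IIII"), max_dimers = 2)
  two <- Filter(function(cf) nrow(cf) == 2L, cfgs4)
  expect_length(two, 1L)
  expect_identical(sort(two[[1]]$start), c(1L, 3L))

  # 5 intact repeats: exactly 3 two-full-dimer configurations
  cfgs5 <- enumerate_occupancy(repeat_array("IIIII"), max_dimers = 2)
  two5 <- Filter(function(cf) nrow(cf) == 2L, cfgs5)
  expect_length(two5, 3L)
  starts <- sort(vapply(two5, function(cf) paste(sort(cf$start), collapse = ","),
                        ""))
  expect_identical(starts, c("1,3", "1,4", "2,4"))

  # 3 intact repeats: never more than one full dimer
  cfgs3 <- enumerate_occupancy(repeat_array("III"), max_dimers = 3)
  expect_true(all(vapply(cfgs3, nrow, 0L) <= 1L))

  # placements never engage mutated repeats
  cfgsM <- enumerate_occupancy(repeat_array("IMII"), max_dimers = 3,
                               allow_partial = TRUE)
  for (cf in cfgsM) {
    engaged <- unlist(lapply(seq_len(nrow(cf)), function(i)
      cf$start[i]:(cf$start[i] + cf$size[i] - 1L)))
    expect_false(2L %in% engaged)
  }
})

test_that("band categories reproduce the mutational probe panel", {
  panel <- list(
    IIII  = "double",                  # four tandem repeats, two dimers
    IIIII = "double",                  # all five repeats
    III   = "single_plus_weak_upper",  # three repeats
    MII   = "single",                  # outlying repeat mutated
    IIM   = "single",
    IMI   = "none"                     # central repeat mutated: no tandem pair
  )
  for (probe in names(panel)) {
    expect_identical(predict_bands(repeat_array(probe))$category,
                     panel[[probe]],
                     label = paste("probe", probe))
  }
})

test_that("a stable double band needs at least four repeats", {
  for (len in 1:8) {
    b <- predict_bands(repeat_array(strrep("I", len)))
    expect_identical(b$category == "double", len >= 4L,
                     label = paste("length", len))
    expect_identical(b$max_full_dimers, as.integer(len %/% 2))
  }
})

test_that("footprint geometry follows the engaged repeats", {
  arr <- repeat_array("IIII")
  cfgs <- enumerate_occupancy(arr, max_dimers = 2)
  full2 <- Filter(function(cf) nrow(cf) == 2L, cfgs)[[1]]
  fp <- predict_footprints(arr, full2)
  # two dimers x two DBDs: four tracts per strand, centres 11 nt apart
  sense <- fp$oh_tracts[fp$oh_tracts$strand == "sense", ]
  expect_identical(nrow(sense), 4L)
  expect_true(all(diff(sense$center) == 11L))
  expect_identical(nrow(fp$oh_tracts), 8L)
  expect_true(all(sense$end - sense$start + 1L == 3L))
  # DNase span covers the 44 bp of engaged repeats plus the 4 nt margins
  expect_identical(fp$dnase_span, c(-3L, 48L))
  expect_identical(diff(fp$dnase_span) + 1L, 52L)
  # exonuclease III arrests just outside the engaged block
  expect_identical(fp$exo3_sense_stop, 44L + 4L)
  expect_identical(fp$exo3_antisense_stop, 1L - 3L)

  one <- data.frame(start = 1L, size = 2L)
  fp1 <- predict_footprints(arr, one)
  expect_identical(nrow(fp1$oh_tracts[fp1$oh_tracts$strand == "sense", ]), 2L)

  # every tract lies inside the DNase span
  expect_true(all(fp$oh_tracts$start >= fp$dnase_span[1] &
                    fp$oh_tracts$end <= fp$dnase_span[2]))

  bad <- data.frame(start = 2L, size = 2L)
  expect_error(predict_footprints(repeat_array("IMII"), bad), "mutated")
})

test_that("fraction bound derives from free-DNA depletion", {
  expect_equal(fraction_bound_from_intensities(100, 100), 0)
  expect_equal(fraction_bound_from_intensities(0, 100), 1)
  expect_equal(fraction_bound_from_intensities(25, 100), 0.75)
  expect_error(fraction_bound_from_intensities(10, 0), "positive")
  cv <- fraction_bound_from_intensities(c(100, 50, 0), 100,
                                        concentrations = c(1, 10, 100))
  expect_s3_class(cv, "binding_curve")
  expect_equal(cv$fraction_bound, c(0, 0.5, 1))
})

test_that("the Hill fit recovers noise-free ground truth", {
  curve <- gen_emsa_curve(A = 1, kd = 35, h = 2)
  fit <- fit_hill(curve)
  expect_true(fit$converged)
  expect_equal(fit$kd, 35, tolerance = 0.5 / 35)
  expect_equal(fit$amplitude, 1, tolerance = 1e-3)
  expect_equal(fit$hill_h, 2, tolerance = 1e-3)
  # definitional: the fitted model passes through A/2 at [P] = KD
  expect_equal(predict(fit, fit$kd), fit$amplitude / 2, tolerance = 1e-9)
})

test_that("hill_fit behaves like a classed model object", {
  fit <- fit_hill(gen_emsa_curve(A = 0.9, kd = 10, h = 1.5))
  expect_s3_class(fit, "hill_fit")
  expect_named(coef(fit), c("amplitude", "kd", "hill_h"))
  expect_equal(unname(coef(fit)["kd"]), 10, tolerance = 1e-6)
  expect_length(residuals(fit), 7L)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-8)
  expect_output(print(fit), "apparent KD")
  expect_output(print(summary(fit)), "Parameter table")
  sims <- simulate(fit, nsim = 2, seed = 1)
  sims2 <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(sims, sims2)
  expect_s3_class(sims[[1]], "binding_curve")
})

test_that("degenerate binding curves are rejected", {
  expect_error(fit_hill(binding_curve(c(1, 2, 3), c(0.1, 0.2, 0.3))),
               "at least 4")
  expect_error(fit_hill(binding_curve(c(1, 2, 3, 4), rep(0.5, 4))),
               "all equal")
  expect_error(binding_curve(c(0, 1, 2, 3), rep(0.2, 4)), "positive")
  expect_error(binding_curve(1:4, c(0.1, 0.2, 0.3, 1.4)), "\\[0, 1\\]")
})

test_that("median KD error stays below 10% on noisy replicates", {
  kds <- vapply(1:200, function(s) {
    fit_hill(gen_emsa_curve(A = 1, kd = 35, h = 2, noise_sigma = 0.03,
                            seed = s))$kd
  }, 0)
  expect_lt(abs(stats::median(kds) - 35) / 35, 0.10)
})
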