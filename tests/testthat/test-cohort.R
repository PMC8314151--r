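make_organ_masks <- function(seed, organs = c("Brainstem", "Mandible")) {
  set.seed(seed)
  out <- list()
  for (o in organs) {
    r <- stats::runif(1, 3, 6)
    out[[o]] <- make_phantom(phantom_spec("sphere", radius_mm = r,
                                          shape = c(20, 20, 20)))
  }
  out
}

test_that("case evaluation produces one consistent record per organ", {
  truth <- make_organ_masks(1)
  tols <- tolerance_set(c(Brainstem = 2, Mandible = 1))

  rec <- evaluate_case(truth, truth, tols, case_id = "c1", role = "model")
  expect_equal(nrow(rec), 2)
  expect_true(all(rec$surface_dsc == 1))
  expect_true(all(rec$volumetric_dsc == 1))

  # perturbed predictions match direct metric calls
  pred <- lapply(truth, function(m) {
    binary_mask(surfdice:::shift_grid(m$grid, c(1, 0, 0)), m$spacing)
  })
  rec2 <- evaluate_case(pred, truth, tols, case_id = "c1", role = "model")
  for (i in seq_len(nrow(rec2))) {
    o <- rec2$organ[i]
    direct <- surface_dsc(pred[[o]], truth[[o]], tols$tolerances[[o]])
    expect_equal(rec2$surface_dsc[i], direct$value)
    expect_equal(rec2$volumetric_dsc[i],
                 volumetric_dsc(pred[[o]], truth[[o]]))
  }

  # an organ absent on both sides propagates undefined, others unaffected
  tols3 <- tolerance_set(c(Brainstem = 2, Mandible = 1, Brain = 2))
  empty <- binary_mask(array(FALSE, c(20, 20, 20)))
  rec3 <- evaluate_case(c(truth, list(Brain = empty)),
                        c(truth, list(Brain = empty)), tols3)
  expect_false(rec3$surface_dsc_defined[rec3$organ == "Brain"])
  expect_true(all(rec3$surface_dsc[rec3$organ != "Brain"] == 1))

  expect_error(evaluate_case(truth, truth, tolerance_set(c(Brainstem = 2))),
               "Mandible")
})

test_that("cohort summaries reproduce direct order statistics", {
  vals <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  rec <- data.frame(case_id = paste0("c", 1:5), organ = "Brainstem",
                    role = "model", tolerance_mm = 2,
                    surface_dsc = vals, volumetric_dsc = vals,
                    surface_dsc_defined = TRUE,
                    volumetric_dsc_defined = TRUE)
  s <- summarize_cohort(rec)
  expect_equal(s$median, 0.6)
  expect_equal(s$q1, 0.4)
  expect_equal(s$q3, 0.8)
  expect_equal(s$n, 5)
  expect_equal(s$notch, 1.57 * 0.4 / sqrt(5))

  # single record: median is the value, IQR 0
  s1 <- summarize_cohort(rec[1, ])
  expect_equal(s1$median, 0.2)
  expect_equal(s1$q3 - s1$q1, 0)

  # permutation invariance
  s2 <- summarize_cohort(rec[sample(5), ])
  expect_equal(s2, s)
})

test_that("whiskers and outliers cover every defined value", {
  set.seed(9)
  vals <- c(stats::runif(20, 0.8, 1), 0.2)  # one far outlier
  rec <- data.frame(case_id = paste0("c", seq_along(vals)),
                    organ = "Mandible", role = "model", tolerance_mm = 1,
                    surface_dsc = vals, volumetric_dsc = vals,
                    surface_dsc_defined = TRUE,
                    volumetric_dsc_defined = TRUE)
  s <- summarize_cohort(rec)
  outs <- as.numeric(strsplit(s$outliers, ";")[[1]])
  expect_true(0.2 %in% round(outs, 6))
  inside <- vals[vals >= s$whisker_low & vals <= s$whisker_high]
  expect_equal(sort(c(inside, outs)), sort(vals), tolerance = 1e-6)
})

test_that("paired differences use (case, organ) pairing with exclusion tally", {
  rec <- rbind(
    data.frame(case_id = c("c1", "c2", "c3"), organ = "Brainstem",
               role = "model", tolerance_mm = 2,
               surface_dsc = c(0.9, 0.8, 0.95), volumetric_dsc = 0.9,
               surface_dsc_defined = TRUE, volumetric_dsc_defined = TRUE),
    data.frame(case_id = c("c1", "c2"), organ = "Brainstem",
               role = "radiographer", tolerance_mm = 2,
               surface_dsc = c(0.9, 0.8), volumetric_dsc = 0.9,
               surface_dsc_defined = TRUE, volumetric_dsc_defined = TRUE))
  s <- summarize_cohort(rec, pair_with = "radiographer")
  expect_equal(s$n_pairs, 2)
  expect_equal(s$n_unpaired, 1)  # c3 has no comparator
  expect_equal(s$mean_diff_pp, 0)
  expect_equal(s$diff_class, "nonsubstantial")

  rec$surface_dsc[rec$role == "model"] <-
    rec$surface_dsc[rec$role == "model"] + 0.07
  s2 <- summarize_cohort(rec, pair_with = "radiographer")
  expect_equal(s2$mean_diff_pp, 7, tolerance = 1e-9)
  expect_equal(s2$diff_class, "better")

  expect_error(summarize_cohort(rec, pair_with = "oncologist"),
               "not present")
})

test_that("undefined metric values are excluded and counted", {
  rec <- data.frame(case_id = c("c1", "c2", "c3"), organ = "Lens-left",
                    role = "model", tolerance_mm = 1,
                    surface_dsc = c(0.9, NA, 0.7),
                    volumetric_dsc = c(0.9, NA, 0.7),
                    surface_dsc_defined = c(TRUE, FALSE, TRUE),
                    volumetric_dsc_defined = c(TRUE, FALSE, TRUE))
  s <- summarize_cohort(rec)
  expect_equal(s$n, 2)
  expect_equal(s$n_undefined, 1)
  expect_equal(s$median, 0.8)

  rec$surface_dsc_defined <- FALSE
  s0 <- summarize_cohort(rec)
  expect_equal(s0$n, 0)
  expect_true(is.na(s0$median))
})
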