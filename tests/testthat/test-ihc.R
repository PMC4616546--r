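rec <- function(case, type, marker, intensity, proportion) {
  data.frame(case_id = case, tumor_type = type, marker = marker,
             intensity = intensity, proportion = proportion,
             stringsAsFactors = FALSE)
}

# deterministic grading cohort mirroring the published renal validation
# series: 23 chromophobe strong-diffuse, 153 clear cell (8 weakly positive
# for ATP6V1G3), 10 papillary (1 weak), 14 oncocytoma (13 positive)
reference_records <- function(seed = 1) {
  simulate_ihc(sim_config(seed, ihc = ihc_reference_config()))
}
RCC_TYPES <- c("chromophobe", "clear_cell", "papillary")

test_that("positivity calls follow the accepted-grade set", {
  strict <- positivity_rule("strict")
  lenient <- positivity_rule("lenient")
  expect_true(call_positivity(rec("c1", "t", "m", "strong", "diffuse"), strict))
  expect_false(call_positivity(rec("c1", "t", "m", "weak", "partial"), strict))
  expect_true(call_positivity(rec("c1", "t", "m", "weak", "partial"), lenient))
  expect_true(call_positivity(rec("c1", "t", "m", "weak", "diffuse"), lenient))
  expect_false(call_positivity(rec("c1", "t", "m", "negative", "none"), strict))
  expect_false(call_positivity(rec("c1", "t", "m", "negative", "none"), lenient))
  expect_false(call_positivity(rec("c1", "t", "m", "strong", "partial"), lenient))
})

test_that("invalid grades and rules are rejected with the allowed values", {
  expect_error(validate_ihc_records(rec("c1", "t", "m", "faint", "diffuse")),
               "negative, weak, strong")
  expect_error(validate_ihc_records(rec("c1", "t", "m", "strong", "most")),
               "none, partial, diffuse")
  expect_error(validate_ihc_records(rec("c1", "t", "m", "negative", "diffuse")),
               "must co-occur")
  expect_error(validate_ihc_records(rec("c1", "t", "m", "weak", "none")),
               "must co-occur")
  expect_error(positivity_rule("custom",
                               data.frame(intensity = "negative",
                                          proportion = "none")),
               "cannot accept")
  expect_error(positivity_rule("majority"), "no preset")
})

test_that("tabulation reproduces the published per-type counts", {
  records <- reference_records()
  strict <- positivity_rule("strict")
  lenient <- positivity_rule("lenient")

  cc <- tabulate_ihc(records, "BSND", "chromophobe", strict,
                     types = RCC_TYPES)
  expect_identical(c(cc$tp, cc$fn, cc$fp, cc$tn), c(23L, 0L, 0L, 163L))

  cc <- tabulate_ihc(records, "ATP6V1G3", "chromophobe", lenient,
                     types = RCC_TYPES)
  expect_identical(c(cc$tp, cc$fn, cc$fp, cc$tn), c(23L, 0L, 9L, 154L))

  empty <- tabulate_ihc(records[0, ], "BSND", "chromophobe", strict)
  expect_identical(c(empty$tp, empty$fn, empty$fp, empty$tn),
                   c(0L, 0L, 0L, 0L))

  dup <- rbind(records, records[1, ])
  expect_error(tabulate_ihc(dup, records$marker[1], "chromophobe", strict),
               "duplicate")
})

test_that("metrics give exact ratios, printed percentages, and Wilson CIs", {
  m <- diagnostic_metrics(confusion_counts(tp = 23, fn = 0, fp = 0, tn = 163))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$sens_pct, 100.0)
  expect_equal(m$spec_pct, 100.0)

  m <- diagnostic_metrics(confusion_counts(tp = 23, fn = 0, fp = 9, tn = 154))
  expect_equal(m$specificity, 154 / 163)
  expect_equal(m$spec_pct, 94.5)

  # CI bounds bracket the estimate and stay inside [0, 1], even at 100%
  expect_true(m$sens_lo <= m$sensitivity && m$sensitivity <= m$sens_hi)
  expect_true(m$spec_lo <= m$specificity && m$specificity <= m$spec_hi)
  expect_true(m$sens_hi <= 1 && m$sens_lo >= 0)
  expect_lt(m$sens_lo, 1)  # Wilson lower bound is informative at 23/23

  expect_error(diagnostic_metrics(confusion_counts(0, 0, 1, 5)),
               "sensitivity undefined")
  expect_error(diagnostic_metrics(confusion_counts(3, 1, 0, 0)),
               "specificity undefined")
})

test_that("single-type positivity rates cover non-contrast tumor types", {
  records <- reference_records()
  strict <- positivity_rule("strict")
  onco <- positivity_rate(records, "BSND", "oncocytoma", strict)
  expect_identical(onco$positive, 13L)
  expect_equal(onco$rate_pct, 92.9)
  cc <- positivity_rate(records, "ATP6V1G3", "clear_cell",
                        positivity_rule("lenient"))
  expect_equal(cc$rate_pct, 5.2)
  expect_error(positivity_rate(records, "BSND", "lung_adeno", strict),
               "no records")
})

test_that("half-up rounding reproduces every printed validation percentage", {
  expect_equal(round_half_up(100 * 23 / 23), 100.0)
  expect_equal(round_half_up(100 * 0 / 153), 0.0)
  expect_equal(round_half_up(100 * 8 / 153), 5.2)
  expect_equal(round_half_up(100 * 1 / 10), 10.0)
  expect_equal(round_half_up(100 * 13 / 14), 92.9)
  expect_equal(round_half_up(100 * 154 / 163), 94.5)
  # half-up, not banker's: 92.85 prints as 92.9
  expect_equal(round_half_up(92.85), 92.9)
})

test_that("enlarging a rule never lowers sensitivity or raises specificity", {
  strict <- positivity_rule("strict")
  wider <- list(
    positivity_rule("lenient"),
    positivity_rule("any_stain",
                    expand.grid(intensity = c("weak", "strong"),
                                proportion = c("partial", "diffuse"),
                                stringsAsFactors = FALSE)))
  grades <- expand.grid(intensity = c("weak", "strong"),
                        proportion = c("partial", "diffuse"),
                        stringsAsFactors = FALSE)
  set.seed(31)
  for (i in 1:10) {
    n <- 60
    stained <- runif(n) < 0.6
    g <- grades[sample(nrow(grades), n, replace = TRUE), ]
    records <- data.frame(
      case_id = sprintf("c%03d", seq_len(n)),
      tumor_type = sample(c("target", "other"), n, replace = TRUE),
      marker = "MK",
      intensity = ifelse(stained, g$intensity, "negative"),
      proportion = ifelse(stained, g$proportion, "none"),
      stringsAsFactors = FALSE)
    if (!all(c("target", "other") %in% records$tumor_type)) next
    m0 <- diagnostic_metrics(tabulate_ihc(records, "MK", "target", strict))
    for (rule in wider) {
      m1 <- diagnostic_metrics(tabulate_ihc(records, "MK", "target", rule))
      expect_gte(m1$sensitivity, m0$sensitivity)
      expect_lte(m1$specificity, m0$specificity)
    }
  }
})
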