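mk_record <- function(course, gap, spread = 58, base = as.Date("2020-03-01")) {
  data.frame(injection_date_1 = base,
             injection_date_2 = base + round(spread / 2),
             injection_date_3 = base + (course - gap),
             final_date = base + course)
}

test_that("protocol classification follows the day windows", {
  expect_identical(classify_protocol(mk_record(117, 58)), "standard")
  expect_identical(classify_protocol(mk_record(91, 32, spread = 50)), "short")
  expect_identical(classify_protocol(mk_record(140, 58)), "excluded")
  # boundary cases
  expect_identical(classify_protocol(mk_record(105, 49)), "standard")
  expect_identical(classify_protocol(mk_record(135, 70)), "standard")
  expect_identical(classify_protocol(mk_record(75, 48, spread = 20)), "short")
  expect_identical(classify_protocol(mk_record(104, 21, spread = 70)), "short")
  # course in the standard window but gap in neither window
  expect_identical(classify_protocol(mk_record(117, 40, spread = 70)),
                   "excluded")
})

test_that("invalid dates raise a validation error", {
  bad <- mk_record(117, 58)
  bad$injection_date_2 <- bad$injection_date_3 + 5
  expect_error(classify_protocol(bad), "unordered")
  bad2 <- mk_record(117, 58)
  bad2$final_date <- NA
  expect_error(classify_protocol(bad2), "missing")
})

test_that("exclusion filtering drops records with reasons and counts", {
  ch <- generate_synthetic_cohort(cohort_config(30, seed = 8))
  ex0 <- apply_exclusions(ch)
  expect_equal(nrow(ex0$kept), nrow(ch))
  expect_equal(nrow(ex0$dropped), 0)

  ch$outcome[1] <- NA
  ch$has_imaging[2] <- FALSE
  ch$final_date[3] <- ch$injection_date_2[3]           # unordered
  ch$final_date[4] <- ch$injection_date_1[4] + 200     # out of both windows
  ex <- apply_exclusions(ch)
  expect_equal(nrow(ex$kept), nrow(ch) - 4)
  expect_setequal(ex$dropped$reason,
                  c("no outcome", "no imaging", "invalid dates",
                    "protocol excluded"))
  expect_equal(unname(ex$counts["no outcome"]), 1L)
  # enumerated toy input: 5 records, 2 violating date windows -> 3 survive
  toy <- rbind(mk_record(117, 58), mk_record(91, 32, spread = 50),
               mk_record(140, 58), mk_record(60, 10, spread = 40),
               mk_record(110, 52))
  toy$eye_id <- paste0("T", 1:5)
  toy$outcome <- 1L
  toy$has_imaging <- TRUE
  ext <- apply_exclusions(toy)
  expect_equal(nrow(ext$kept), 3)
  expect_true(all(ext$dropped$reason == "protocol excluded"))
})

test_that("splitting is patient-grouped, stratified, and sized 20/16/64", {
  # 100 single-eye standard patients in one stratum: 20 test, 16 val, 64 train
  ch <- generate_synthetic_cohort(
    cohort_config(100, second_eye_prob = 0, short_protocol_prob = 0, seed = 2))
  ch$protocol <- classify_protocol(ch)
  ch$outcome <- 0L            # single stratum
  ch$n_scans <- 25L
  sp <- suppressWarnings(split_cohort(ch, seed = 4))
  expect_equal(as.integer(table(sp$partition)[c("test", "validation", "train")]),
               c(20L, 16L, 64L))

  # patients never straddle partitions, even with eyes in different strata
  ch2 <- generate_synthetic_cohort(
    cohort_config(400, second_eye_prob = 0.5, seed = 6))
  ch2$protocol <- classify_protocol(ch2)
  sp2 <- split_cohort(ch2, seed = 9)
  per_patient <- tapply(sp2$partition, sp2$patient_id,
                        function(x) length(unique(x)))
  expect_true(all(per_patient == 1))
  # short-protocol eyes are only ever train or test (merged hold-out)
  expect_true(all(sp2$partition[sp2$protocol == "short"] != "validation"))

  # per-partition outcome prevalence close to overall on a large cohort
  ch3 <- generate_synthetic_cohort(cohort_config(1000, seed = 10))
  ch3$protocol <- classify_protocol(ch3)
  sp3 <- split_cohort(ch3, seed = 11)
  std <- merge(sp3[sp3$protocol == "standard", ], ch3[, c("eye_id", "outcome")])
  overall <- mean(std$outcome)
  by_part <- tapply(std$outcome, std$partition, mean)
  expect_true(all(abs(by_part - overall) < 0.05))
})

test_that("splits are reproducible and degrade stratification when sparse", {
  ch <- generate_synthetic_cohort(cohort_config(60, seed = 12))
  ch$protocol <- classify_protocol(ch)
  s1 <- suppressWarnings(split_cohort(ch, seed = 5))
  s2 <- suppressWarnings(split_cohort(ch, seed = 5))
  expect_identical(s1, s2)
  expect_warning(split_cohort(ch, seed = 5), "degrading")
})

test_that("fold assignment is patient-grouped and balanced per stratum", {
  # 50 patients, one clinic, balanced outcome -> folds of 10
  ch <- generate_synthetic_cohort(
    cohort_config(50, second_eye_prob = 0, seed = 14))
  ch$clinic <- "C01"
  ch$outcome <- rep(c(0L, 1L), 25)
  ch$protocol <- "standard"
  fl <- assign_folds(ch, seed = 3)
  expect_equal(as.integer(table(fl$fold)), rep(10L, 5))

  # two-eye patients share folds; per-stratum sizes match round-robin
  ch2 <- generate_synthetic_cohort(
    cohort_config(120, second_eye_prob = 0.4, seed = 15))
  ch2$protocol <- "standard"
  fl2 <- assign_folds(ch2, seed = 8)
  per_patient <- tapply(fl2$fold, fl2$patient_id,
                        function(x) length(unique(x)))
  expect_true(all(per_patient == 1))
  pt <- ch2[!duplicated(ch2$patient_id), ]
  pt <- merge(pt, fl2[!duplicated(fl2$patient_id), c("patient_id", "fold")])
  for (k in unique(paste(pt$clinic, pt$outcome))) {
    sub <- pt[paste(pt$clinic, pt$outcome) == k, ]
    counts <- sort(unname(table(factor(sub$fold, levels = 1:5))),
                   decreasing = TRUE)
    expect_equal(as.integer(counts), round_robin_counts(nrow(sub)))
  }
})
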