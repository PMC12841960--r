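test_that("worked reporting cases give the documented outcomes", {
  # restricted icteric sample without prior clinician contact
  d <- decide_with(i_index = 5, tbil = 120, fhb = 300)
  expect_identical(d$status, "CLINICIAN_REQUEST_ONLY")
  expect_identical(d$annotations, "ICTERIC_INTERFERENCE")
  # everything benign
  expect_identical(decide_with()$status, "REPORT")
  expect_length(decide_with()$annotations, 0)
  # unavoidable lipemia with low fHb
  d <- decide_with(lipemia_present = TRUE, parenteral_nutrition = TRUE,
                   nutrition_discontinuable = FALSE, fhb = 30)
  expect_identical(d$status, "REPORT_WITH_ANNOTATION")
  expect_identical(d$annotations, "LIPEMIC_SAMPLE")
  # unverified venipuncture with high hemolysis index
  d <- decide_with(h_index = 15, venipuncture_verified = FALSE)
  expect_identical(d$status, "VERIFY_PREANALYTICS")
  # severe hemolysis with unremarkable bilirubin
  d <- decide_with(fhb = 250, tbil = 50, venipuncture_verified = FALSE)
  expect_identical(d$status, "VERIFY_PREANALYTICS")
  expect_identical(d$annotations, "REVIEW_SAMPLING")
  # icterus trigger with unmeasured bilirubin demands the reflex test
  expect_identical(decide_with(i_index = 5, tbil = NA, dbil = NA)$status,
                   "NEEDS_TBIL")
  # prior clinician request keeps an icteric result reportable, annotated
  d <- decide_with(i_index = 5, tbil = 120, clinician_requested = TRUE,
                   fhb = 150)
  expect_identical(d$status, "REPORT_WITH_ANNOTATION")
  expect_identical(d$annotations, "ICTERIC_INTERFERENCE")
})

test_that("every decision returns exactly one valid status (totality)", {
  statuses <- c("REPORT", "REPORT_WITH_ANNOTATION", "CLINICIAN_REQUEST_ONLY",
                "REQUEST_NEW_SAMPLE", "VERIFY_PREANALYTICS", "NEEDS_TBIL")
  set.seed(202)
  for (k in 1:300) {
    d <- do.call(decide_sample, random_record())
    expect_length(d$status, 1)
    expect_true(d$status %in% statuses)
  }
})

test_that("raising bilirubin never un-restricts an icteric sample", {
  prev_restricted <- FALSE
  for (tb in seq(10, 300, by = 5)) {
    st <- decide_with(i_index = 5, tbil = tb, dbil = NA, fhb = 100)$status
    restricted <- st == "CLINICIAN_REQUEST_ONLY"
    if (prev_restricted) expect_true(restricted)
    prev_restricted <- restricted
  }
})

test_that("threshold scans switch exactly once, at the configured value", {
  single_switch <- function(statuses) {
    expect_equal(sum(statuses[-1] != statuses[-length(statuses)]), 1)
  }
  # icterus trigger: strict > 4
  st <- vapply(seq(0, 8, by = 0.25),
               function(i) decide_with(i_index = i, tbil = 120, fhb = 100)$status,
               character(1))
  single_switch(st)
  expect_identical(decide_with(i_index = 4, tbil = 120, fhb = 100)$status, "REPORT")
  expect_identical(decide_with(i_index = 4.25, tbil = 120, fhb = 100)$status,
                   "CLINICIAN_REQUEST_ONLY")
  # bilirubin restriction: >= 75
  st <- vapply(seq(50, 100, by = 2.5),
               function(tb) decide_with(i_index = 5, tbil = tb, dbil = NA, fhb = 100)$status,
               character(1))
  single_switch(st)
  expect_identical(decide_with(i_index = 5, tbil = 74.9, dbil = NA, fhb = 100)$status,
                   "REPORT")
  expect_identical(decide_with(i_index = 5, tbil = 75, dbil = NA, fhb = 100)$status,
                   "CLINICIAN_REQUEST_ONLY")
  # hemolysis verification trigger: strict > 10
  st <- vapply(seq(0, 20, by = 1),
               function(h) decide_with(h_index = h)$status, character(1))
  single_switch(st)
  expect_identical(decide_with(h_index = 10)$status, "REPORT")
  expect_identical(decide_with(h_index = 11)$status, "VERIFY_PREANALYTICS")
  # fHb review: strict > 200 (at unremarkable bilirubin)
  st <- vapply(seq(100, 300, by = 10),
               function(f) decide_with(fhb = f, tbil = 50)$status, character(1))
  single_switch(st)
  expect_identical(decide_with(fhb = 200, tbil = 50)$status, "REPORT")
  expect_identical(decide_with(fhb = 210, tbil = 50)$status, "VERIFY_PREANALYTICS")
  # lipemic reportability: strict < 50
  lip <- function(f) decide_with(lipemia_present = TRUE, parenteral_nutrition = TRUE,
                                 fhb = f)$status
  st <- vapply(seq(10, 90, by = 5), lip, character(1))
  single_switch(st)
  expect_identical(lip(49.9), "REPORT_WITH_ANNOTATION")
  expect_identical(lip(50), "CLINICIAN_REQUEST_ONLY")
})

test_that("thresholds are configurable, not baked in", {
  cfg <- threshold_config(tbil_restrict = 150)
  expect_identical(decide_with(i_index = 5, tbil = 120, fhb = 100)$status,
                   "CLINICIAN_REQUEST_ONLY")
  d <- do.call(decide_sample,
               c(benign_record(i_index = 5, tbil = 120, fhb = 100),
                 list(config = cfg)))
  expect_identical(d$status, "REPORT")
})

test_that("rule traces cover every evaluated rule and replay to the status", {
  set.seed(77)
  for (k in 1:200) {
    d <- do.call(decide_sample, random_record())
    tr <- d$rule_trace
    expect_gt(nrow(tr), 0)
    # evaluation follows the fixed step order
    order_ref <- c("icterus_needs_tbil", "icterus_restrict", "hemolysis_verify",
                   "lipemia_resample", "lipemia_report", "lipemia_clinician",
                   "fhb_review")
    expect_true(all(diff(match(tr$rule, order_ref)) > 0))
    # replay: the last decided outcome in the trace is the status,
    # or no rule decided and the status is a (possibly annotated) report
    decided <- tr$outcome[!is.na(tr$outcome)]
    if (length(decided)) {
      expect_identical(decided[length(decided)], d$status)
    } else {
      expect_true(d$status %in% c("REPORT", "REPORT_WITH_ANNOTATION"))
    }
    # nothing after a terminal outcome
    if (length(decided)) {
      expect_identical(which(!is.na(tr$outcome)), nrow(tr))
    }
  }
})

test_that("missing fhb when a rule needs it raises a named input error", {
  expect_error(decide_with(lipemia_present = TRUE, fhb = NA),
               "lipemia_report", class = "freehb_input_error")
  expect_error(decide_with(fhb = NA), "fhb_review", class = "freehb_input_error")
})

test_that("record invariants are enforced", {
  expect_error(decide_with(dbil = 50, tbil = 20), "dbil",
               class = "freehb_input_error")
  expect_error(decide_with(h_index = -1), class = "freehb_input_error")
  expect_error(decide_with(lipemia_present = NA), class = "freehb_input_error")
})

test_that("batch decisions equal element-wise decisions and preserve order", {
  fb <- fixture_batch()
  dec <- decide_reports(fb, quiet = TRUE)
  expect_identical(dec$sample_id, fb$sample_id)
  for (r in seq_len(nrow(fb))) {
    single <- do.call(decide_sample, as.list(fb[r, ]))
    expect_identical(dec$status[r], single$status)
    expect_identical(dec$annotations[[r]], single$annotations)
  }
  expect_error(decide_reports(fb[0, ]), "empty", class = "freehb_input_error")
  expect_message(decide_reports(fb[1, ]), "decided 1 sample")
  # per-record failures carry the sample id
  bad <- fb
  bad$fhb[11] <- NA
  expect_error(decide_reports(bad, quiet = TRUE), "F11",
               class = "freehb_input_error")
})
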