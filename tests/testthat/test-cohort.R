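make_csvs <- function(labs_txt, adm_txt) {
    d <- withr::local_tempdir(.local_envir = parent.frame())
    lp <- file.path(d, "labs.csv"); ap <- file.path(d, "admissions.csv")
    writeLines(labs_txt, lp); writeLines(adm_txt, ap)
    list(labs = lp, adm = ap)
}

adm_header <- paste("admission_id,patient_id,admit_time,discharge_time,",
                    "age_years,sex,diagnosis_codes,procedure_codes", sep = "")
lab_header <- "admission_id,patient_id,analyte,value,unit,timestamp"

test_that("readCohort parses valid rows and records malformed ones", {
    p <- make_csvs(
        c(lab_header,
          "A1,P1,creatinine_serum,80,umol/L,2012-03-01T08:00:00",
          "A1,P1,sodium,140,mmol/L,2012-03-02T08:00:00",
          "A1,P1,potassium,NA,mmol/L,2012-03-02T08:00:00",
          "A1,P1,urea,7,mmol/L,not-a-time",
          "A1,P1,urea,7,mmol/L,2012-03-20T08:00:00"),
        c(adm_header,
          "A1,P1,2012-03-01T00:00:00,2012-03-05T00:00:00,60,female,,"))
    co <- readCohort(p$labs, p$adm)
    expect_equal(nrow(co$labs), 2L)
    expect_s3_class(co$labs$timestamp, "POSIXct")
    expect_setequal(co$rejected$reason,
                    c("non_finite_value", "unparseable_timestamp",
                      "outside_admission_window"))
    expect_equal(nrow(co$rejected), 3L)
    # timestamps keep their time of day through the ISO round trip
    expect_equal(format(co$labs$timestamp[1], "%H"), "08")
})

test_that("readCohort enforces referential integrity and required columns", {
    p <- make_csvs(
        c(lab_header,
          "A9,P1,sodium,140,mmol/L,2012-03-01T08:00:00"),
        c(adm_header,
          "A1,P1,2012-03-01T00:00:00,2012-03-05T00:00:00,60,female,,"))
    expect_error(readCohort(p$labs, p$adm), "A9")

    p2 <- make_csvs(
        c("admission_id,patient_id,analyte,value,unit",
          "A1,P1,sodium,140,mmol/L"),
        c(adm_header,
          "A1,P1,2012-03-01T00:00:00,2012-03-05T00:00:00,60,female,,"))
    expect_error(readCohort(p2$labs, p2$adm), "timestamp")
})

test_that("computeEGFR matches an independently coded CKD-EPI 2009 oracle", {
    # worked example: creatinine 61.9 umol/L (~0.70 mg/dL), age 60, female
    v <- computeEGFR(61.9, 60, "female")
    expect_equal(v, oracle_egfr(61.9, 60, "female"), tolerance = 1e-10)
    expect_gt(v, 90); expect_lt(v, 96)
    # sex coefficient direction and monotonicity in creatinine
    expect_gt(computeEGFR(61.9, 60, "male"), v)
    expect_lt(computeEGFR(123.8, 60, "female"), v)
    # 1000 random draws agree within 0.1
    set.seed(31)
    scr <- runif(1000, 30, 500); age <- runif(1000, 5, 95)
    sex <- sample(c("male", "female"), 1000, replace = TRUE)
    got <- computeEGFR(scr, age, sex)
    want <- vapply(1:1000, function(i) oracle_egfr(scr[i], age[i], sex[i]),
                   0)
    expect_lt(max(abs(got - want)), 0.1)
    expect_error(computeEGFR(-1, 60, "male"), "positive")
    expect_error(computeEGFR(80, 0, "male"), "positive")
})

test_that("exclusion cascade applies rules in order with one reason each", {
    base <- as.POSIXct("2012-03-01 00:00:00", tz = "UTC")
    adm <- data.frame(
        admission_id = c("S", "C", "K", "R", "N", "OK", "SK"),
        patient_id = paste0("P", 1:7),
        admit_time = rep(base, 7),
        discharge_time = base + c(36, 96, 96, 96, 96, 96, 36) * 3600,
        age_years = 60, sex = "female", stringsAsFactors = FALSE)
    adm$diagnosis_codes <- list(character(), character(), character(),
                                character(), character(), character(),
                                character())
    adm$procedure_codes <- list(character(), character(), character(),
                                "chronic hemodialysis", character(),
                                character(), character())
    mk_lab <- function(id, value, hours = 2)
        data.frame(admission_id = id, patient_id = "x",
                   analyte = "creatinine_serum", value = value, unit = "u",
                   timestamp = base + hours * 3600)
    labs <- rbind(mk_lab("S", 70), mk_lab("C", 70), mk_lab("K", 600),
                  mk_lab("R", 250), mk_lab("OK", 70), mk_lab("SK", 600))
    episodes <- data.frame(admission_id = "C",
                           onset_time = as.numeric(base) + 24 * 3600)
    ex <- applyExclusions(adm, labs, episodes)
    want <- c(S = "short_stay", C = "community_aki", K = "ckd5",
              R = "prior_rrt_no_recovery", N = "no_labs")
    got <- setNames(ex$excluded$reason, ex$excluded$admission_id)
    expect_equal(got[names(want)], want)
    expect_equal(ex$kept, "OK")
    # first-matching rule wins: short stay + stage-5 eGFR records short_stay
    expect_equal(got[["SK"]], "short_stay")
    # partition property
    expect_equal(length(ex$kept) + nrow(ex$excluded), nrow(adm))
    expect_equal(sum(ex$counts), nrow(ex$excluded))
})

test_that("empty cohorts and missing admission creatinine are handled", {
    ex <- applyExclusions(data.frame(), data.frame(), NULL)
    expect_length(ex$kept, 0)
    # no creatinine within 48 h: eGFR clauses cannot fire
    base <- as.POSIXct("2012-03-01 00:00:00", tz = "UTC")
    adm <- data.frame(admission_id = "A", patient_id = "P",
                      admit_time = base,
                      discharge_time = base + 96 * 3600,
                      age_years = 60, sex = "male",
                      stringsAsFactors = FALSE)
    adm$diagnosis_codes <- list(character())
    adm$procedure_codes <- list("chronic hemodialysis")
    labs <- data.frame(admission_id = "A", patient_id = "P",
                       analyte = "sodium", value = 140, unit = "u",
                       timestamp = base + 3600)
    ex2 <- applyExclusions(adm, labs, NULL)
    expect_equal(ex2$kept, "A")
})

test_that("planted exclusion reasons are recovered exactly on a cohort", {
    tc <- tiny_cohort()
    truth <- tc$sim$truth
    got <- merge(truth[, c("admission_id", "exclusion_reason")],
                 tc$ex$excluded, by = "admission_id", all = TRUE)
    expect_equal(is.na(got$reason), is.na(got$exclusion_reason))
    both <- !is.na(got$reason)
    expect_equal(got$reason[both], got$exclusion_reason[both])
    planted <- table(truth$exclusion_reason)
    expect_equal(ex <- tc$ex$counts[names(planted)],
                 setNames(as.integer(planted), names(planted)))
})
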