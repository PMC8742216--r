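#' @importFrom data.table fread fwrite data.table as.data.table setDT := .N .SD setorder rbindlist dcast CJ
NULL

.LAB_COLS <- c("admission_id", "patient_id", "analyte", "value", "unit",
               "timestamp")
.ADM_COLS <- c("admission_id", "patient_id", "admit_time", "discharge_time",
               "age_years", "sex", "diagnosis_codes", "procedure_codes")

#' Read an admissions/labs cohort from CSV
#'
#' Parses the long-format laboratory event table and the admissions table.
#' Timestamps are normalized to a single timezone-naive (UTC) convention.
#' Malformed laboratory rows (non-finite value, unparseable timestamp, or a
#' timestamp outside \code{[admit - pre_admit_tolerance_h, discharge]}) are
#' never dropped silently: they are removed from the returned events and
#' recorded row-by-row with a reason in the \code{rejected} element.
#'
#' @param lab_csv path to the lab events CSV (columns \code{admission_id},
#'   \code{patient_id}, \code{analyte}, \code{value}, \code{unit},
#'   \code{timestamp} in ISO-8601).
#' @param admissions_csv path to the admissions CSV (columns
#'   \code{admission_id}, \code{patient_id}, \code{admit_time},
#'   \code{discharge_time}, \code{age_years}, \code{sex},
#'   \code{diagnosis_codes}, \code{procedure_codes}; code lists
#'   semicolon-delimited).
#' @param pre_admit_tolerance_h hours before admission within which lab
#'   draws are still accepted (default 24).
#' @return list with \code{admissions} (data.frame; code lists as
#'   character-vector list columns), \code{labs} (data.frame of valid
#'   events) and \code{rejected} (data.frame of row index + reason).
#' @examples
#' sim <- simulateCohort(simConfig(n_admissions = 30, seed = 1))
#' d <- tempfile(); dir.create(d)
#' writeCohortCSV(sim, d)
#' cohort <- readCohort(file.path(d, "labs.csv"), file.path(d, "admissions.csv"))
#' nrow(cohort$admissions)
#' @export
readCohort <- function(lab_csv, admissions_csv, pre_admit_tolerance_h = 24) {
    if (!file.exists(lab_csv)) .stopf("lab file not found: %s", lab_csv)
    if (!file.exists(admissions_csv))
        .stopf("admissions file not found: %s", admissions_csv)

    adm <- fread(admissions_csv, colClasses = list(character = "admission_id"))
    miss <- setdiff(.ADM_COLS, names(adm))
    if (length(miss))
        .stopf("admissions.csv is missing required column(s): %s",
               paste(miss, collapse = ", "))
    labs <- fread(lab_csv, colClasses = list(character = "admission_id"))
    miss <- setdiff(.LAB_COLS, names(labs))
    if (length(miss))
        .stopf("labs.csv is missing required column(s): %s",
               paste(miss, collapse = ", "))

    adm <- as.data.frame(adm)
    adm$admission_id <- as.character(adm$admission_id)
    adm$patient_id <- as.character(adm$patient_id)
    adm$admit_time <- .parse_time(adm$admit_time)
    adm$discharge_time <- .parse_time(adm$discharge_time)
    if (anyNA(adm$admit_time) || anyNA(adm$discharge_time))
        .stopf("unparseable admit/discharge timestamps in admissions.csv")
    if (any(adm$discharge_time <= adm$admit_time))
        .stopf("discharge_time must be after admit_time for every admission")
    adm$diagnosis_codes <- .split_codes(adm$diagnosis_codes)
    adm$procedure_codes <- .split_codes(adm$procedure_codes)

    labs <- as.data.frame(labs)
    labs$admission_id <- as.character(labs$admission_id)
    labs$analyte <- as.character(labs$analyte)
    labs$value <- suppressWarnings(as.numeric(labs$value))
    ts <- suppressWarnings(.parse_time(labs$timestamp))

    orphan <- setdiff(unique(labs$admission_id), adm$admission_id)
    if (length(orphan))
        .stopf("lab events reference admission_id(s) absent from the admissions table: %s",
               paste(utils::head(orphan, 10), collapse = ", "))

    idx <- match(labs$admission_id, adm$admission_id)
    lo <- as.numeric(adm$admit_time)[idx] - pre_admit_tolerance_h * .HOUR
    hi <- as.numeric(adm$discharge_time)[idx]
    reason <- rep(NA_character_, nrow(labs))
    reason[!nzchar(labs$analyte) | is.na(labs$analyte)] <- "empty_analyte"
    reason[!is.finite(labs$value)] <- "non_finite_value"
    reason[is.na(ts)] <- "unparseable_timestamp"
    tsn <- as.numeric(ts)
    out_win <- is.na(reason) & (tsn < lo | tsn > hi)
    reason[out_win] <- "outside_admission_window"

    rejected <- data.frame(row = which(!is.na(reason)),
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE)
    keep <- is.na(reason)
    labs <- labs[keep, .LAB_COLS]
    labs$timestamp <- ts[keep]
    rownames(labs) <- NULL
    list(admissions = adm, labs = labs, rejected = rejected)
}

.split_codes <- function(x) {
    x <- as.character(x)
    lapply(x, function(s) {
        if (is.na(s) || !nzchar(s)) character() else
            trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    })
}

#' CKD-EPI 2009 estimated glomerular filtration rate
#'
#' Computes eGFR (mL/min/1.73 m^2) from serum creatinine in µmol/L using
#' the 2009 CKD-EPI creatinine equation.  Creatinine is converted to mg/dL
#' by dividing by 88.4.  The race coefficient is omitted by default and can
#' be enabled for fidelity studies.
#'
#' @param creatinine_umol_l serum creatinine, µmol/L (> 0); vectorized.
#' @param age_years age in years (> 0).
#' @param sex \code{"male"} or \code{"female"}.
#' @param black logical; apply the 1.159 race coefficient (default FALSE).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' computeEGFR(61.9, 60, "female")
#' @export
computeEGFR <- function(creatinine_umol_l, age_years, sex, black = FALSE) {
    if (any(!is.finite(creatinine_umol_l)) || any(creatinine_umol_l <= 0))
        .stopf("creatinine must be positive and finite")
    if (any(!is.finite(age_years)) || any(age_years <= 0))
        .stopf("age must be positive")
    sex <- match.arg(tolower(as.character(sex)), c("male", "female"),
                     several.ok = TRUE)
    n <- max(length(creatinine_umol_l), length(age_years), length(sex))
    scr <- rep_len(creatinine_umol_l, n) / 88.4
    age <- rep_len(age_years, n)
    female <- rep_len(sex, n) == "female"
    kappa <- ifelse(female, 0.7, 0.9)
    alpha <- ifelse(female, -0.329, -0.411)
    egfr <- 141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^-1.209 *
        0.993^age * ifelse(female, 1.018, 1)
    if (isTRUE(black)) egfr <- egfr * 1.159
    egfr
}

# Inverse of the CKD-EPI 2009 equation in its scr/kappa > 1 branch; used by
# the synthetic generator to plant admissions at an exact target eGFR.
.creatinine_for_egfr <- function(egfr_target, age_years, sex) {
    female <- sex == "female"
    kappa <- ifelse(female, 0.7, 0.9)
    base <- 141 * 0.993^age_years * ifelse(female, 1.018, 1)
    scr <- kappa * (egfr_target / base)^(-1 / 1.209)
    pmax(scr, kappa * 1.0001) * 88.4
}

#' Exclusion-cascade configuration
#'
#' Thresholds and code-pattern lists for \code{\link{applyExclusions}}.
#' Code matching is case-insensitive substring matching on code
#' descriptions, since the KDIGO-oriented exclusion rules are phrased as
#' text patterns rather than terminology code lists.
#'
#' @param short_stay_h minimum length of stay, hours (default 48).
#' @param community_aki_h AKI onsets earlier than this after admission are
#'   community-acquired (default 48).
#' @param egfr_ckd5 admission eGFR below which stage-5 CKD is inferred
#'   (default 15).
#' @param egfr_recovery admission eGFR below which a prior-RRT patient has
#'   not recovered (default 30).
#' @param eskd_dx_patterns diagnosis-code patterns for end-stage kidney
#'   disease.
#' @param access_proc_patterns procedure patterns for dialysis-access
#'   creation (stage-5 CKD rule).
#' @param rrt_proc_patterns procedure patterns for prior renal replacement
#'   therapy (dialysis/filtration/diafiltration rule).
#' @param creatinine_analyte analyte token used for admission eGFR.
#' @param admission_egfr_window_h window after admission in which the first
#'   creatinine defines the admission eGFR (default 48).
#' @return named list of settings.
#' @export
exclusionConfig <- function(short_stay_h = 48, community_aki_h = 48,
                            egfr_ckd5 = 15, egfr_recovery = 30,
                            eskd_dx_patterns = c("end-stage kidney",
                                                 "end-stage renal",
                                                 "eskd", "esrd"),
                            access_proc_patterns = c(
                                "peritoneal dialysis catheter",
                                "arteriovenous", "fistuloplasty"),
                            rrt_proc_patterns = c("dialysis", "filtration",
                                                  "diafiltration"),
                            creatinine_analyte = "creatinine_serum",
                            admission_egfr_window_h = 48) {
    list(short_stay_h = short_stay_h, community_aki_h = community_aki_h,
         egfr_ckd5 = egfr_ckd5, egfr_recovery = egfr_recovery,
         eskd_dx_patterns = eskd_dx_patterns,
         access_proc_patterns = access_proc_patterns,
         rrt_proc_patterns = rrt_proc_patterns,
         creatinine_analyte = creatinine_analyte,
         admission_egfr_window_h = admission_egfr_window_h)
}

.match_any <- function(codes, patterns) {
    if (!length(codes) || !length(patterns)) return(FALSE)
    codes <- tolower(codes)
    any(vapply(patterns, function(p) any(grepl(p, codes, fixed = TRUE)),
               TRUE))
}

#' Apply the five-rule admission exclusion cascade
#'
#' Produces the analyzable cohort by applying, in order: (1)
#' \code{short_stay} — discharged within 48 h of admission; (2)
#' \code{community_aki} — earliest AKI onset within 48 h of admission; (3)
#' \code{ckd5} — end-stage kidney disease diagnosis code, admission eGFR
#' < 15, or a dialysis-access procedure code; (4)
#' \code{prior_rrt_no_recovery} — a dialysis/filtration/diafiltration
#' procedure code with admission eGFR < 30; (5) \code{no_labs} — no
#' laboratory events at all.  The first matching rule is the recorded
#' reason.  Admission eGFR uses the first creatinine within 48 h of
#' admission; if none was measured the eGFR-based clauses cannot fire.
#' Exclusions operate per admission, never per patient.
#'
#' @param admissions data.frame as returned by \code{\link{readCohort}}.
#' @param labs lab events data.frame.
#' @param episodes AKI episode table from \code{\link{detectAkiEpisodes}}
#'   (may be empty).
#' @param config list from \code{\link{exclusionConfig}}.
#' @return list with \code{kept} (admission ids), \code{excluded}
#'   (data.frame admission_id/reason), \code{counts} (named integer vector
#'   over the five reasons) and \code{pediatric} (kept admission ids with
#'   age < 18, flagged because the adult CKD-EPI equation was applied).
#' @export
applyExclusions <- function(admissions, labs, episodes,
                            config = exclusionConfig()) {
    adm <- admissions
    n <- nrow(adm)
    reasons <- c("short_stay", "community_aki", "ckd5",
                 "prior_rrt_no_recovery", "no_labs")
    if (n == 0L)
        return(list(kept = character(),
                    excluded = data.frame(admission_id = character(),
                                          reason = character()),
                    counts = stats::setNames(integer(5), reasons),
                    pediatric = character()))

    labs_dt <- as.data.table(labs)
    n_labs <- labs_dt[, .N, by = admission_id]
    lab_count <- stats::setNames(rep(0L, n), adm$admission_id)
    lab_count[n_labs$admission_id] <- n_labs$N

    # admission eGFR from the first creatinine within the admission window
    cre <- labs_dt[analyte == config$creatinine_analyte]
    egfr <- rep(NA_real_, n)
    if (nrow(cre)) {
        cre <- merge(cre,
                     data.table(admission_id = adm$admission_id,
                                .admit = as.numeric(adm$admit_time)),
                     by = "admission_id")
        cre <- cre[as.numeric(timestamp) <=
                       .admit + config$admission_egfr_window_h * .HOUR]
        setorder(cre, admission_id, timestamp)
        first <- cre[, .SD[1L], by = admission_id]
        idx <- match(first$admission_id, adm$admission_id)
        egfr[idx] <- computeEGFR(first$value, adm$age_years[idx],
                                 adm$sex[idx])
    }

    first_onset <- rep(NA_real_, n)
    if (!is.null(episodes) && nrow(episodes)) {
        eo <- as.data.table(episodes)[, .(onset = min(as.numeric(onset_time))),
                                      by = admission_id]
        first_onset[match(eo$admission_id, adm$admission_id)] <- eo$onset
    }

    los_h <- as.numeric(adm$discharge_time) - as.numeric(adm$admit_time)
    los_h <- los_h / .HOUR
    admit_n <- as.numeric(adm$admit_time)

    eskd_dx <- vapply(adm$diagnosis_codes, .match_any, TRUE,
                      patterns = tolower(config$eskd_dx_patterns))
    access_proc <- vapply(adm$procedure_codes, .match_any, TRUE,
                          patterns = tolower(config$access_proc_patterns))
    rrt_proc <- vapply(adm$procedure_codes, .match_any, TRUE,
                       patterns = tolower(config$rrt_proc_patterns))

    reason <- rep(NA_character_, n)
    r1 <- los_h < config$short_stay_h
    r2 <- !is.na(first_onset) &
        first_onset < admit_n + config$community_aki_h * .HOUR
    r3 <- eskd_dx | (!is.na(egfr) & egfr < config$egfr_ckd5) | access_proc
    r4 <- rrt_proc & !is.na(egfr) & egfr < config$egfr_recovery
    r5 <- lab_count == 0L
    reason[r5] <- "no_labs"
    reason[r4] <- "prior_rrt_no_recovery"
    reason[r3] <- "ckd5"
    reason[r2] <- "community_aki"
    reason[r1] <- "short_stay"

    kept <- adm$admission_id[is.na(reason)]
    excluded <- data.frame(admission_id = adm$admission_id[!is.na(reason)],
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE)
    counts <- stats::setNames(
        vapply(reasons, function(r) sum(excluded$reason == r), 0L), reasons)
    list(kept = kept, excluded = excluded, counts = counts,
         pediatric = adm$admission_id[is.na(reason) & adm$age_years < 18])
}

#' Write the exclusion report and kept cohort
#'
#' Serializes an \code{\link{applyExclusions}} result to
#' \code{cohort.json} (per-reason counts, a study-flow-diagram analogue)
#' plus a kept-cohort CSV.
#'
#' @param exclusion result of \code{\link{applyExclusions}}.
#' @param admissions the admissions data.frame.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohortReport <- function(exclusion, admissions, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jp <- file.path(dir, "cohort.json")
    jsonlite::write_json(list(
        n_input = nrow(admissions),
        n_kept = length(exclusion$kept),
        excluded_counts = as.list(exclusion$counts),
        n_pediatric_kept = length(exclusion$pediatric)),
        jp, auto_unbox = TRUE, pretty = TRUE)
    kp <- file.path(dir, "kept_cohort.csv")
    keep <- admissions[admissions$admission_id %in% exclusion$kept, ]
    keep$diagnosis_codes <- vapply(keep$diagnosis_codes, paste, "",
                                   collapse = ";")
    keep$procedure_codes <- vapply(keep$procedure_codes, paste, "",
                                   collapse = ";")
    keep$admit_time <- .fmt_time(keep$admit_time)
    keep$discharge_time <- .fmt_time(keep$discharge_time)
    fwrite(as.data.table(keep), kp)
    invisible(c(jp, kp))
}
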