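#' Default analyte catalog for the synthetic EHR generator
#'
#' Roughly thirty routinely ordered analytes with log-normal value models
#' (in native units) and per-day ordering probabilities mirroring the
#' typical hospital test-prevalence hierarchy: complete blood count most
#' common, then electrolytes/urea/creatinine, liver panel, coagulation and
#' inflammatory markers, with blood gas, lactate and drug levels rare.
#'
#' @return data.frame with \code{analyte}, \code{meanlog}, \code{sdlog},
#'   \code{order_prob}, \code{unit}.
#' @export
defaultAnalyteCatalog <- function() {
    m <- function(analyte, typical, sdlog, p, unit)
        data.frame(analyte = analyte, meanlog = log(typical), sdlog = sdlog,
                   order_prob = p, unit = unit, stringsAsFactors = FALSE)
    rbind(
        m("hemoglobin", 13, 0.10, 0.85, "g/dL"),
        m("wbc", 8, 0.35, 0.85, "10^9/L"),
        m("neutrophils", 5, 0.40, 0.85, "10^9/L"),
        m("lymphocytes", 1.8, 0.35, 0.85, "10^9/L"),
        m("platelets", 250, 0.25, 0.85, "10^9/L"),
        m("hematocrit", 40, 0.08, 0.85, "%"),
        m("sodium", 138, 0.02, 0.80, "mmol/L"),
        m("potassium", 4.1, 0.08, 0.80, "mmol/L"),
        m("chloride", 103, 0.03, 0.80, "mmol/L"),
        m("bicarbonate", 24, 0.10, 0.80, "mmol/L"),
        m("urea", 6, 0.40, 0.80, "mmol/L"),
        m("creatinine_serum", 70, 0.05, 0.80, "umol/L"),
        m("glucose", 6.5, 0.30, 0.60, "mmol/L"),
        m("calcium", 2.25, 0.06, 0.50, "mmol/L"),
        m("phosphate", 1.15, 0.20, 0.40, "mmol/L"),
        m("magnesium", 0.85, 0.12, 0.35, "mmol/L"),
        m("albumin", 38, 0.12, 0.45, "g/L"),
        m("bilirubin_total", 12, 0.45, 0.45, "umol/L"),
        m("alt", 28, 0.50, 0.45, "U/L"),
        m("ast", 28, 0.50, 0.45, "U/L"),
        m("alp", 80, 0.35, 0.45, "U/L"),
        m("ggt", 45, 0.55, 0.30, "U/L"),
        m("inr", 1.1, 0.12, 0.35, "ratio"),
        m("aptt", 30, 0.15, 0.35, "s"),
        m("crp", 18, 0.80, 0.30, "mg/L"),
        m("procalcitonin", 0.2, 0.90, 0.08, "ng/mL"),
        m("troponin_i", 0.02, 0.90, 0.25, "ng/mL"),
        m("ck", 110, 0.60, 0.20, "U/L"),
        m("lactate", 1.3, 0.35, 0.15, "mmol/L"),
        m("ph_arterial", 7.4, 0.005, 0.10, "pH"),
        m("pco2", 5.3, 0.12, 0.10, "kPa"),
        m("po2", 11, 0.20, 0.10, "kPa"),
        m("vancomycin_level", 12, 0.35, 0.25, "mg/L"),
        m("uric_acid", 350, 0.30, 0.20, "umol/L"),
        m("urine_wbc", 5, 0.80, 0.25, "/uL"),
        m("urine_rbc", 3, 0.80, 0.25, "/uL"))
}

#' Default prodromal archetypes
#'
#' Each AKI case is assigned one clinical archetype whose signal analytes
#' drift upward ahead of the prediction window: inflammatory (C-reactive
#' protein, neutrophils), cardiac (troponin-I), nephrotoxic (vancomycin
#' level) and hepatic/multiorgan (lactate, transaminases, bilirubin).
#'
#' @return named list of character vectors of signal analytes.
#' @export
defaultArchetypes <- function() {
    list(sepsis = c("crp", "neutrophils", "wbc"),
         cardiac = c("troponin_i", "ck"),
         nephrotoxic = "vancomycin_level",
         multiorgan = c("lactate", "alt", "ast", "bilirubin_total", "inr"))
}

# clinical mix of the archetypes among AKI cases: sepsis is the dominant
# cause of hospital-acquired AKI, nephrotoxicity the least common
.DEFAULT_ARCHETYPE_WEIGHTS <- c(sepsis = 0.40, cardiac = 0.20,
                                nephrotoxic = 0.15, multiorgan = 0.25)

#' Configuration of the synthetic cohort generator
#'
#' The defaults encode the emulated study conditions: ~4.4% admission-level
#' AKI prevalence, AKI onset log-normal with median 6 days (IQR roughly
#' 3-10) from admission, length of stay log-normal with median 5 days (at
#' least 48 h unless a short stay is planted), archetype signals drifting
#' up by 2 SD (log scale) over the 5 days ending at the prediction-window
#' boundary, and small planted fractions of each exclusion reason.
#'
#' @param n_admissions number of admissions to generate.
#' @param aki_prevalence probability that a non-planted admission develops
#'   hospital-acquired AKI.
#' @param catalog analyte catalog (see \code{\link{defaultAnalyteCatalog}}).
#' @param archetypes named list of signal-analyte sets.
#' @param archetype_weights sampling weights over the archetypes (default:
#'   sepsis most common, nephrotoxic least).
#' @param shared_signal analytes drifting in every impending-AKI case
#'   regardless of archetype (default urea: pre-renal azotemia precedes
#'   the creatinine rise).
#' @param effect_size archetype drift at full ramp, in per-analyte log-SD
#'   units.
#' @param ramp_days days over which the drift ramps from 0 to full; the
#'   ramp starts at the feature-window start (\code{span_h + lead_h}
#'   before onset) and the drift persists at full effect through onset.
#' @param span_h feature-window length the signal geometry assumes.
#' @param exclusion_fractions named fractions of admissions planted per
#'   exclusion reason.
#' @param los_meanlog,los_sdlog log-normal length-of-stay (days).
#' @param onset_meanlog,onset_sdlog log-normal AKI onset (days from
#'   admission).
#' @param lead_h prediction-window length the signals must respect.
#' @param signal_in_prediction_window_only if TRUE the archetype drift is
#'   confined to the 48-h prediction window (leakage canary: a clean
#'   featurization must then see no signal).
#' @param informative_ordering couple signal-analyte ordering intensity to
#'   deterioration (off by default).
#' @param seed integer; fixes everything.
#' @return named list (class \code{akitv_sim_config}).
#' @export
simConfig <- function(n_admissions = 5000, aki_prevalence = 0.044,
                      catalog = defaultAnalyteCatalog(),
                      archetypes = defaultArchetypes(),
                      archetype_weights = .DEFAULT_ARCHETYPE_WEIGHTS,
                      shared_signal = "urea",
                      effect_size = 2, ramp_days = 5, span_h = 168,
                      exclusion_fractions = c(short_stay = 0.04,
                                              community_aki = 0.01,
                                              ckd5 = 0.01,
                                              prior_rrt_no_recovery = 0.005,
                                              no_labs = 0.005),
                      los_meanlog = log(5), los_sdlog = 0.6,
                      onset_meanlog = log(6), onset_sdlog = 0.8,
                      lead_h = 48,
                      signal_in_prediction_window_only = FALSE,
                      informative_ordering = FALSE, seed = 1) {
    stopifnot(aki_prevalence >= 0, aki_prevalence <= 1, effect_size >= 0,
              all(exclusion_fractions >= 0), n_admissions >= 1)
    if (aki_prevalence == 0 && length(archetypes) && effect_size > 0)
        .stopf("archetype signals requested but AKI prevalence is 0")
    if (length(archetypes)) {
        archetype_weights <- archetype_weights[names(archetypes)]
        stopifnot(!anyNA(archetype_weights))
    }
    structure(list(n_admissions = as.integer(n_admissions),
                   aki_prevalence = aki_prevalence, catalog = catalog,
                   archetypes = archetypes,
                   archetype_weights = archetype_weights,
                   shared_signal = shared_signal,
                   effect_size = effect_size,
                   ramp_days = ramp_days, span_h = span_h,
                   exclusion_fractions = exclusion_fractions,
                   los_meanlog = los_meanlog, los_sdlog = los_sdlog,
                   onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
                   lead_h = lead_h,
                   signal_in_prediction_window_only =
                       isTRUE(signal_in_prediction_window_only),
                   informative_ordering = isTRUE(informative_ordering),
                   seed = as.integer(seed)),
              class = "akitv_sim_config")
}

# noise ratio bound keeping a flat creatinine series below both KDIGO
# criteria: ratio within [1-r, 1+r] with 2*r*b < 26.5 and (1+r)/(1-r) < 1.5
.cre_noise_clip <- function(b) pmin(0.07, 12 / b)

#' Generate a synthetic cohort of admissions and lab streams
#'
#' Emulates irregular multi-analyte hospital laboratory time series with
#' planted hospital-acquired AKI episodes, planted exclusion cases and
#' archetype-specific prodromal signals.  AKI cases carry a creatinine
#' course that is flat at baseline until 48 h before the planted onset and
#' then rises to 1.6x baseline exactly at onset (so detection under the
#' KDIGO criteria is guaranteed at, and only near, the onset); control
#' creatinine noise is ratio-clipped so neither KDIGO criterion can fire
#' spuriously.  Archetype signal analytes drift upward by
#' \code{effect_size} log-SD over \code{ramp_days}, reaching full effect at
#' the prediction-window boundary (or, in leakage-canary mode, drifting
#' only inside the prediction window).
#'
#' @param config an \code{\link{simConfig}}.
#' @return list with \code{admissions} (data.frame, code lists as list
#'   columns), \code{labs} (data.frame of events), \code{truth}
#'   (data.frame: planted label, archetype, onset time, signal analytes,
#'   exclusion reason) and \code{config}.
#' @export
simulateCohort <- function(config = simConfig()) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(.child_seed(config$seed, "simulate"))

    n <- config$n_admissions
    id <- sprintf("A%06d", seq_len(n))
    patient <- sprintf("P%06d",
                       sample.int(max(2L, ceiling(n * 0.85)), n,
                                  replace = TRUE))
    age <- pmin(pmax(stats::rnorm(n, 53, 25), 0.5), 100)
    sex <- ifelse(stats::runif(n) < 0.522, "male", "female")
    admit <- as.numeric(.parse_time("2012-01-01")) +
        round(stats::runif(n, 0, 364) * .DAY / 60) * 60

    # planted exclusions (disjoint, assigned to a random subset)
    reason <- rep(NA_character_, n)
    pool <- sample.int(n)
    for (r in names(config$exclusion_fractions)) {
        k <- round(config$exclusion_fractions[[r]] * n)
        if (k > 0) {
            reason[pool[seq_len(k)]] <- r
            pool <- pool[-seq_len(k)]
        }
    }

    is_aki <- is.na(reason) & stats::rbinom(n, 1, config$aki_prevalence) == 1
    has_aki_course <- is_aki | (!is.na(reason) & reason == "community_aki")

    onset_h <- rep(NA_real_, n)
    onset_h[is_aki] <- pmin(pmax(stats::rlnorm(sum(is_aki),
                                               config$onset_meanlog,
                                               config$onset_sdlog), 2.6), 28) *
        24
    onset_h[!is.na(reason) & reason == "community_aki"] <- 24

    # kept controls get a pseudo-onset from the same distribution: their
    # creatinine monitoring stops there, so the admission-to-reference gap
    # is label-independent and the prediction-window canary holds
    is_ctrl <- is.na(reason) & !is_aki
    final_cre_h <- rep(NA_real_, n)
    final_cre_h[is_ctrl] <- pmin(pmax(stats::rlnorm(sum(is_ctrl),
                                                    config$onset_meanlog,
                                                    config$onset_sdlog),
                                      2.6), 28) * 24

    los_d <- pmax(stats::rlnorm(n, config$los_meanlog, config$los_sdlog),
                  2.25)
    los_d[is_aki] <- pmax(los_d[is_aki], onset_h[is_aki] / 24 + 0.75)
    los_d[is_ctrl] <- pmax(los_d[is_ctrl], final_cre_h[is_ctrl] / 24 + 0.3)
    short <- !is.na(reason) & reason == "short_stay"
    los_d[short] <- stats::runif(sum(short), 0.5, 1.9)
    comm <- !is.na(reason) & reason == "community_aki"
    los_d[comm] <- pmax(los_d[comm], 3)
    discharge <- admit + round(los_d * .DAY / 60) * 60
    onset_time <- admit + round(onset_h * .HOUR / 60) * 60

    # creatinine baseline; exclusion-planted admissions sit at an exact
    # target eGFR (ckd5 < 15, prior RRT between 15 and 30)
    cat_df <- config$catalog
    cre_row <- cat_df[cat_df$analyte == "creatinine_serum", ]
    b <- pmin(pmax(stats::rlnorm(n, cre_row$meanlog, 0.25), 40), 150)
    b[has_aki_course] <- pmin(b[has_aki_course], 110)
    ckd5 <- !is.na(reason) & reason == "ckd5"
    rrt <- !is.na(reason) & reason == "prior_rrt_no_recovery"
    b[ckd5] <- .creatinine_for_egfr(10, age[ckd5], sex[ckd5])
    b[rrt] <- .creatinine_for_egfr(22, age[rrt], sex[rrt])

    # archetypes for every AKI course
    arch_names <- names(config$archetypes)
    archetype <- rep(NA_character_, n)
    if (length(arch_names) && any(has_aki_course))
        archetype[has_aki_course] <- sample(arch_names,
                                            sum(has_aki_course),
                                            replace = TRUE,
                                            prob = config$archetype_weights)

    dx <- replicate(n, c("I10 essential hypertension",
                         "E11 type 2 diabetes")[stats::runif(2) < 0.3],
                    simplify = FALSE)
    proc <- replicate(n, character(), simplify = FALSE)
    eskd_half <- ckd5 & stats::runif(n) < 0.5
    dx[eskd_half] <- lapply(dx[eskd_half], c, "end-stage renal disease")
    proc[rrt] <- lapply(proc[rrt], c, "intermittent hemodialysis session")

    admissions <- data.frame(admission_id = id, patient_id = patient,
                             admit_time = as.POSIXct(admit,
                                                     origin = "1970-01-01",
                                                     tz = "UTC"),
                             discharge_time = as.POSIXct(discharge,
                                                         origin = "1970-01-01",
                                                         tz = "UTC"),
                             age_years = round(age, 1), sex = sex,
                             stringsAsFactors = FALSE)
    admissions$diagnosis_codes <- dx
    admissions$procedure_codes <- proc

    # ---- scheduled daily draws ------------------------------------------
    n_days <- pmax(ceiling(los_d), 1L)
    day_adm <- rep(seq_len(n), n_days)
    day_no <- unlist(lapply(n_days, function(k) seq_len(k) - 1L))
    ev <- vector("list", nrow(cat_df))
    for (a in seq_len(nrow(cat_df))) {
        p <- rep(cat_df$order_prob[a], length(day_adm))
        hit <- stats::runif(length(day_adm)) < p
        ai <- day_adm[hit]
        t_ev <- admit[ai] + day_no[hit] * .DAY +
            round(stats::runif(sum(hit), 6, 10) * .HOUR / 60) * 60
        val <- stats::rlnorm(sum(hit), cat_df$meanlog[a], cat_df$sdlog[a])
        ev[[a]] <- data.table(admission_id = id[ai], adm = ai,
                              analyte = cat_df$analyte[a], value = val,
                              timestamp = t_ev, anchor = 0L)
    }
    labs <- rbindlist(ev)
    labs <- labs[timestamp <= discharge[adm]]
    # control creatinine stops at the pseudo-onset (the draw there is
    # planted below as the final creatinine)
    cre_stop <- admit + final_cre_h * .HOUR
    labs <- labs[!(analyte == "creatinine_serum" &
                   !is.na(cre_stop[adm]) & timestamp >= cre_stop[adm])]

    # guaranteed anchor points: admission creatinine for everyone, and for
    # AKI courses a flat baseline draw plus the onset-defining creatinine
    anchor <- list(data.table(admission_id = id, adm = seq_len(n),
                              analyte = "creatinine_serum", value = b,
                              timestamp = admit + 2 * .HOUR, anchor = 1L))
    # both arms get the same guaranteed pre-reference draw 72 h before the
    # (pseudo-)onset, with identically clipped noise, so neither the
    # observation pattern nor the value distribution differs by label
    pre_noise <- function(k) pmin(pmax(exp(stats::rnorm(k, 0, 0.03)),
                                       0.95), 1.05)
    ctl <- which(is_ctrl)
    if (length(ctl)) {
        r_ctl <- .cre_noise_clip(b[ctl])
        nz <- pmin(pmax(exp(stats::rnorm(length(ctl), 0, 0.05)),
                        1 - r_ctl), 1 + r_ctl)
        ctl_pre <- ctl[cre_stop[ctl] - 72 * .HOUR >= admit[ctl] - 20 * .HOUR]
        anchor <- c(anchor, list(
            data.table(admission_id = id[ctl], adm = ctl,
                       analyte = "creatinine_serum", value = b[ctl] * nz,
                       timestamp = round(cre_stop[ctl] / 60) * 60,
                       anchor = 1L),
            data.table(admission_id = id[ctl_pre], adm = ctl_pre,
                       analyte = "creatinine_serum",
                       value = b[ctl_pre] * pre_noise(length(ctl_pre)),
                       timestamp = round((cre_stop[ctl_pre] - 72 * .HOUR) /
                                         60) * 60,
                       anchor = 1L)))
    }
    ak <- which(has_aki_course)
    if (length(ak)) {
        pre_ok <- ak[onset_time[ak] - 72 * .HOUR >= admit[ak] - 20 * .HOUR]
        anchor <- c(anchor, list(
            data.table(admission_id = id[pre_ok], adm = pre_ok,
                       analyte = "creatinine_serum",
                       value = b[pre_ok] * pre_noise(length(pre_ok)),
                       timestamp = onset_time[pre_ok] - 72 * .HOUR,
                       anchor = 1L),
            data.table(admission_id = id[ak], adm = ak,
                       analyte = "creatinine_serum", value = 1.6 * b[ak],
                       timestamp = onset_time[ak], anchor = 1L)))
    }
    labs <- rbindlist(c(list(labs), anchor))

    # creatinine course: clipped flat noise, quadratic rise inside the
    # prediction window, clipped plateau after onset
    cre <- labs$analyte == "creatinine_serum" & labs$anchor == 0L
    bb <- b[labs$adm]
    r_clip <- .cre_noise_clip(bb)
    noise <- pmin(pmax(exp(stats::rnorm(nrow(labs), 0, 0.05)),
                       1 - r_clip), 1 + r_clip)
    vals <- labs$value
    vals[cre] <- (bb * noise)[cre]
    on_t <- onset_time[labs$adm]
    in_rise <- cre & has_aki_course[labs$adm] &
        labs$timestamp > on_t - config$lead_h * .HOUR & labs$timestamp <= on_t
    frac <- (labs$timestamp - (on_t - config$lead_h * .HOUR)) /
        (config$lead_h * .HOUR)
    vals[in_rise] <- (bb * (1 + 0.6 * frac^2))[in_rise]
    post <- cre & has_aki_course[labs$adm] & labs$timestamp > on_t
    plateau_noise <- pmin(pmax(noise, 0.97), 1.03)
    vals[post] <- (1.6 * bb * plateau_noise)[post]
    labs$value <- vals

    # archetype prodromal drift on signal analytes
    if (length(arch_names) && config$effect_size > 0 && length(ak)) {
        sig_pairs <- unlist(lapply(arch_names, function(a)
            paste(a, config$archetypes[[a]])))
        is_sig <- has_aki_course[labs$adm] &
            (paste(archetype[labs$adm], labs$analyte) %in% sig_pairs |
             labs$analyte %in% config$shared_signal)
        if (any(is_sig)) {
            lead_s <- config$lead_h * .HOUR
            ramp_s <- config$ramp_days * .DAY
            t_ev <- labs$timestamp[is_sig]
            o_ev <- onset_time[labs$adm[is_sig]]
            fr <- if (config$signal_in_prediction_window_only)
                pmin(pmax((t_ev - (o_ev - lead_s)) / lead_s, 0), 1)
            else pmin(pmax(
                (t_ev - (o_ev - lead_s - config$span_h * .HOUR)) / ramp_s,
                0), 1)
            sdl <- cat_df$sdlog[match(labs$analyte[is_sig], cat_df$analyte)]
            labs$value[is_sig] <- labs$value[is_sig] *
                exp(config$effect_size * sdl * fr)
        }
    }

    no_labs <- !is.na(reason) & reason == "no_labs"
    labs <- labs[!no_labs[adm]]
    labs[, unit := cat_df$unit[match(analyte, cat_df$analyte)]]
    labs[, patient_id := patient[adm]]
    setorder(labs, admission_id, timestamp, analyte)

    truth <- data.frame(admission_id = id, patient_id = patient,
                        label = as.integer(is_aki),
                        archetype = archetype,
                        onset_time = as.POSIXct(onset_time,
                                                origin = "1970-01-01",
                                                tz = "UTC"),
                        signal_analytes = vapply(archetype, function(a)
                            if (is.na(a)) "" else
                                paste(unique(c(config$archetypes[[a]],
                                               config$shared_signal)),
                                      collapse = ";"), ""),
                        exclusion_reason = reason,
                        baseline_creatinine = b,
                        stringsAsFactors = FALSE)

    labs_out <- data.frame(admission_id = labs$admission_id,
                           patient_id = labs$patient_id,
                           analyte = labs$analyte,
                           value = labs$value, unit = labs$unit,
                           timestamp = as.POSIXct(labs$timestamp,
                                                  origin = "1970-01-01",
                                                  tz = "UTC"),
                           stringsAsFactors = FALSE)
    list(admissions = admissions, labs = labs_out, truth = truth,
         config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits \code{labs.csv} and \code{admissions.csv} in exactly the schemas
#' \code{\link{readCohort}} reads, plus \code{truth.json} (ground truth
#' for tests, not an input to any analysis step).
#'
#' @param sim output of \code{\link{simulateCohort}}.
#' @param dir output directory.
#' @return invisibly, the paths.
#' @export
writeCohortCSV <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    adm <- sim$admissions
    out_adm <- data.table(
        admission_id = adm$admission_id, patient_id = adm$patient_id,
        admit_time = .fmt_time(adm$admit_time),
        discharge_time = .fmt_time(adm$discharge_time),
        age_years = adm$age_years, sex = adm$sex,
        diagnosis_codes = vapply(adm$diagnosis_codes, paste, "",
                                 collapse = ";"),
        procedure_codes = vapply(adm$procedure_codes, paste, "",
                                 collapse = ";"))
    fwrite(out_adm, file.path(dir, "admissions.csv"))
    labs <- as.data.table(sim$labs)
    labs[, timestamp := .fmt_time(sim$labs$timestamp)]
    fwrite(labs, file.path(dir, "labs.csv"))
    tr <- sim$truth
    tr$onset_time <- ifelse(is.na(tr$onset_time), NA, .fmt_time(tr$onset_time))
    jsonlite::write_json(tr, file.path(dir, "truth.json"), digits = NA,
                         na = "null")
    invisible(file.path(dir, c("labs.csv", "admissions.csv", "truth.json")))
}

#' Achievable-AUROC oracle for a simulated cohort
#'
#' Fits a logistic model on the true signal summaries (per-admission mean
#' log value of every archetype signal analyte inside the feature window,
#' with an unmeasured analyte imputed at its catalog mean) and reports the
#' test-split AUROC.  This bounds what any model can realistically extract
#' from the planted signal and calibrates model-quality expectations: the
#' TITV model is expected to come within 0.05 of it.
#'
#' @param sim a \code{\link{simulateCohort}} result; if NULL, generated
#'   from \code{config}.
#' @param config an \code{\link{simConfig}} (used when \code{sim} is NULL).
#' @param spec a \code{\link{windowSpec}}.
#' @param split_seed seed for the 80/10/10 split.
#' @return list with \code{auroc} (test split), \code{n_test},
#'   \code{n_signal_features}.
#' @export
effectSizeOracle <- function(sim = NULL, config = simConfig(),
                             spec = windowSpec(), split_seed = 1) {
    if (is.null(sim)) sim <- simulateCohort(config)
    cfg <- sim$config
    truth <- sim$truth
    keep <- is.na(truth$exclusion_reason)
    ids <- truth$admission_id[keep]
    y <- truth$label[keep]
    labs <- as.data.table(sim$labs)

    # reference anchor: planted onset for cases, last creatinine otherwise
    ref <- as.numeric(truth$onset_time[keep])
    lc <- labs[analyte == "creatinine_serum",
               .(lc = max(as.numeric(timestamp))), by = admission_id]
    ref[y == 0] <- lc$lc[match(ids[y == 0], lc$admission_id)]
    ok <- !is.na(ref)
    ids <- ids[ok]; y <- y[ok]; ref <- ref[ok]

    sig <- unique(c(unlist(cfg$archetypes), cfg$shared_signal))
    refs <- data.table(admission_id = ids, .ref = ref)
    ev <- labs[analyte %in% sig][refs, on = "admission_id", nomatch = NULL]
    off <- (ev$.ref - as.numeric(ev$timestamp)) / .HOUR - spec$lead_h
    ev <- ev[off > 0 & off <= spec$span_h]
    su <- ev[, .(mlog = mean(log(value))), by = .(admission_id, analyte)]

    Xs <- matrix(rep(cfg$catalog$meanlog[match(sig, cfg$catalog$analyte)],
                     each = length(ids)), length(ids), length(sig),
                 dimnames = list(ids, sig))
    if (nrow(su))
        Xs[cbind(match(su$admission_id, ids), match(su$analyte, sig))] <-
            su$mlog

    split <- splitCohort(ids, seed = split_seed)
    df <- data.frame(y = y, Xs)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df[split == "train", ],
                                       family = stats::binomial()))
    pred <- stats::predict(fit, newdata = df[split == "test", ],
                           type = "response")
    list(auroc = aurocScore(pred, y[split == "test"]),
         n_test = sum(split == "test"), n_signal_features = length(sig))
}
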