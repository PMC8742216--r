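H <- 3600

test_that("daily bins are anchored to the reference and leak-free", {
    spec <- windowSpec()
    ref <- as.numeric(as.POSIXct("2012-06-10 12:00:00", tz = "UTC"))
    ev <- function(hours_before, value, analyte = "sodium")
        data.frame(analyte = analyte, value = value,
                   timestamp = ref - hours_before * H)
    # 49 h before reference: one hour before the prediction window, so the
    # most recent bin (7)
    b <- binEvents(ev(49, 140), ref, spec, c("sodium", "urea"))
    expect_equal(unname(b$M[7, "sodium"]), 1)
    expect_equal(unname(b$X[7, "sodium"]), 140)
    expect_equal(sum(b$M), 1)
    # two values in one bin average
    b2 <- binEvents(rbind(ev(50, 10), ev(60, 20)), ref, spec,
                    c("sodium", "urea"))
    expect_equal(unname(b2$X[7, "sodium"]), 15)
    # inside the prediction window: never used
    b3 <- binEvents(ev(47, 140), ref, spec, c("sodium", "urea"))
    expect_equal(sum(b3$M), 0)
    # exactly on the boundary is inside the prediction window (half-open)
    b4 <- binEvents(ev(48, 140), ref, spec, c("sodium", "urea"))
    expect_equal(sum(b4$M), 0)
    # older than the feature window: dropped
    b5 <- binEvents(ev(48 + 168 + 1, 140), ref, spec, c("sodium", "urea"))
    expect_equal(sum(b5$M), 0)
})

test_that("binning agrees with brute-force interval filtering", {
    spec <- windowSpec()
    set.seed(12)
    ref <- 1e9
    for (r in 1:30) {
        n <- 60
        ev <- data.frame(analyte = sample(c("a", "b", "c"), n, TRUE),
                         value = runif(n, 1, 100),
                         timestamp = ref - runif(n, 0, 300) * H)
        got <- binEvents(ev, ref, spec, c("a", "b", "c"))
        for (k in 1:7) for (f in c("a", "b", "c")) {
            lo <- ref - (48 + (7 - k + 1) * 24) * H
            hi <- ref - (48 + (7 - k) * 24) * H
            sel <- ev$analyte == f & ev$timestamp >= lo & ev$timestamp < hi
            if (any(sel)) {
                expect_equal(unname(got$X[k, f]), mean(ev$value[sel]))
                expect_equal(unname(got$M[k, f]), 1)
            } else {
                expect_equal(unname(got$M[k, f]), 0)
            }
        }
    }
})

test_that("min-max normalization clips and handles degenerate ranges", {
    expect_equal(minmaxNormalize(5, 0, 10), 0.5)
    expect_equal(minmaxNormalize(0, 0, 10), 0)
    expect_equal(minmaxNormalize(10, 0, 10), 1)
    expect_equal(minmaxNormalize(12, 0, 10), 1)
    expect_equal(minmaxNormalize(-3, 0, 10), 0)
    expect_equal(minmaxNormalize(7, 7, 7), 0)
})

test_that("zero imputation touches only masked cells", {
    X <- matrix(runif(12), 3); M <- matrix(rbinom(12, 1, 0.5), 3)
    out <- imputeMissing(X, M)
    expect_true(all(out[M == 0] == 0))
    expect_identical(out[M == 1], X[M == 1])
    expect_identical(imputeMissing(X, matrix(1, 3, 4)), X)
    expect_true(all(imputeMissing(X, matrix(0, 3, 4)) == 0))
})

test_that("cohort split sizes, determinism and grouping", {
    s <- splitCohort(20732, seed = 9)
    expect_equal(as.integer(table(s)[c("train", "valid", "test")]),
                 c(16585L, 2073L, 2074L))
    expect_identical(splitCohort(100, seed = 4), splitCohort(100, seed = 4))
    expect_false(identical(splitCohort(100, seed = 4),
                           splitCohort(100, seed = 5)))
    expect_error(splitCohort(2, seed = 1), "at least 3")
    # grouped mode keeps a patient's admissions together
    ids <- paste0("a", 1:60)
    grp <- rep(paste0("p", 1:20), each = 3)
    sg <- splitCohort(ids, seed = 2, groups = grp)
    per_group <- tapply(as.character(sg), grp, function(x)
        length(unique(x)))
    expect_true(all(per_group == 1))
})

test_that("reference time selection anchors cases and controls", {
    ep <- data.frame(onset_time = 500)
    expect_equal(selectReferenceTime(ep, c(100, 200)),
                 list(reference_time = 500, y = 1L, dropped = FALSE))
    expect_equal(selectReferenceTime(NULL, c(100, 900, 200)),
                 list(reference_time = 900, y = 0L, dropped = FALSE))
    out <- selectReferenceTime(NULL, numeric())
    expect_true(out$dropped)
})

test_that("buildFeatureSet output satisfies the sample contract", {
    tc <- tiny_cohort()
    fs <- tc$fs
    expect_s4_class(fs, "AkiFeatureSet")
    X <- SummarizedExperiment::assay(fs, "X")
    M <- SummarizedExperiment::assay(fs, "M")
    expect_true(all(X >= 0 & X <= 1))
    expect_true(all(X[M == 0] == 0))
    # one sample per kept admission except dropped creatinine-less controls
    md <- S4Vectors::metadata(fs)
    expect_equal(ncol(fs) + md$dropped$n, length(tc$ex$kept))
    # normalization stats come from the training split only: training
    # cells never exceed their stored min/max, other splits may clip to 1
    vocab <- md$vocabulary
    tr <- splitSubset(fs, "train")
    arr <- featureArray(tr); msk <- maskArray(tr)
    spec <- md$windowSpec
    for (f in sample(seq_len(nrow(vocab)), 5)) {
        vals <- arr[, , f][msk[, , f] == 1]
        if (length(vals)) expect_true(all(vals >= 0 & vals <= 1))
    }
    # vocabulary ordered by descending training prevalence
    expect_true(all(diff(vocab$prevalence) <= 1e-12))
})

test_that("no event inside the prediction window reaches the features", {
    tc <- tiny_cohort()
    fs <- tc$fs
    labs <- tc$sim$labs
    spec <- S4Vectors::metadata(fs)$windowSpec
    cd <- SummarizedExperiment::colData(fs)
    msk <- maskArray(fs)
    vocab <- S4Vectors::metadata(fs)$vocabulary$analyte
    set.seed(88)
    ids <- sample(colnames(fs), 40)
    for (id in ids) {
        j <- match(id, colnames(fs))
        ref <- as.numeric(cd$reference_time[j])
        ev <- labs[labs$admission_id == id, ]
        # reconstruct the expected mask from the raw events by explicit
        # inequalities: bin k covers [ref-48-(8-k)*24, ref-48-(7-k)*24) h
        want <- matrix(0, spec$T, length(vocab))
        tn <- as.numeric(ev$timestamp)
        for (k in seq_len(spec$T)) {
            lo <- ref - (spec$lead_h + (spec$T - k + 1) * spec$bin_h) * H
            hi <- ref - (spec$lead_h + (spec$T - k) * spec$bin_h) * H
            sel <- tn >= lo & tn < hi
            want[k, ] <- as.integer(vocab %in% ev$analyte[sel])
        }
        expect_equal(matrix(msk[j, , ], spec$T), want,
                     ignore_attr = TRUE)
    }
})

test_that("featurization is bit-identical across reruns", {
    tc <- tiny_cohort()
    fs2 <- buildFeatureSet(tc$kept, tc$sim$labs, tc$eps, seed = 402)
    expect_identical(SummarizedExperiment::assay(tc$fs, "X"),
                     SummarizedExperiment::assay(fs2, "X"))
    expect_identical(SummarizedExperiment::assay(tc$fs, "M"),
                     SummarizedExperiment::assay(fs2, "M"))
    expect_identical(as.character(splitOf(tc$fs)),
                     as.character(splitOf(fs2)))
})
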