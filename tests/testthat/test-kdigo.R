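H <- 3600

test_that("detectAki reproduces the canonical creatinine-pair cases", {
    # relative criterion within 7 days, absolute window not met
    e <- detectAki(c(0, 100) * H, c(60, 95))
    expect_equal(nrow(e), 1L)
    expect_equal(e$criterion, "relative")
    expect_equal(e$baseline_creatinine, 60)
    expect_equal(e$onset_time, 100 * H)
    expect_equal(e$stage, 1L)

    # absolute criterion: delta 28 > 26.5 within 48 h, ratio below 1.5
    e2 <- detectAki(c(0, 24) * H, c(60, 88))
    expect_equal(e2$criterion, "absolute")
    expect_equal(e2$stage, 1L)

    # both windows exceeded
    expect_equal(nrow(detectAki(c(0, 200) * H, c(60, 95))), 0L)

    # stage 2 by ratio
    e3 <- detectAki(c(0, 72) * H, c(60, 125))
    expect_equal(e3$criterion, "relative")
    expect_equal(e3$stage, 2L)

    # single point: no episode, no error
    expect_equal(nrow(detectAki(0, 60)), 0L)
    expect_error(detectAki(c(0, 10) * H, c(60, -1)), "positive")
})

test_that("staging follows the ratio and absolute stage-3 rules", {
    expect_equal(stageEpisode(60, 95), 1L)
    expect_equal(stageEpisode(60, 125), 2L)
    expect_equal(stageEpisode(60, 190), 3L)   # ratio 3.17
    expect_equal(stageEpisode(330, 360), 3L)  # >= 353.6 with delta > 26.5
    expect_error(stageEpisode(60, 70), "qualify")
})

test_that("detector equals the brute-force pair-enumeration oracle", {
    vals <- c(50, 70, 90, 120, 200)
    gaps <- c(12, 48, 96, 168)
    check <- function(t_h, v) {
        got <- detectAki(t_h * H, v)
        want <- oracle_detect(t_h, v)
        expect_equal(nrow(got), nrow(want))
        if (nrow(got)) {
            expect_equal(got$onset_time / H, want$onset)
            expect_equal(got$baseline_creatinine, want$base)
            expect_equal(got$defining_creatinine, want$def)
        }
    }
    # exhaustive up to length 3
    for (L in 2:3) {
        vg <- do.call(expand.grid, rep(list(vals), L))
        gg <- do.call(expand.grid, rep(list(gaps), L - 1))
        for (i in seq_len(nrow(vg))) for (j in seq_len(nrow(gg))) {
            t_h <- cumsum(c(0, as.numeric(gg[j, ])))
            check(t_h, as.numeric(vg[i, ]))
        }
    }
    # random longer series
    set.seed(77)
    for (r in 1:400) {
        L <- sample(4:6, 1)
        t_h <- cumsum(c(0, sample(gaps, L - 1, replace = TRUE)))
        v <- sample(vals, L, replace = TRUE)
        check(t_h, v)
    }
    # random-walk series with continuous values
    for (r in 1:100) {
        L <- sample(3:8, 1)
        t_h <- cumsum(c(0, runif(L - 1, 6, 100)))
        v <- pmax(30, 70 * cumprod(c(1, exp(rnorm(L - 1, 0, 0.3)))))
        check(t_h, v)
    }
})

test_that("relative-criterion episodes are invariant to rescaling", {
    # with every inter-draw gap beyond 48 h only the ratio criterion can
    # fire, so episode onsets must be exactly preserved under any k > 0
    set.seed(5)
    for (r in 1:60) {
        L <- sample(3:6, 1)
        t_h <- cumsum(c(0, runif(L - 1, 49, 160)))
        v <- 80 * exp(cumsum(rnorm(L, 0, 0.35)))
        for (k in c(0.25, 3, 11)) {
            e1 <- detectAki(t_h * H, v)
            e2 <- detectAki(t_h * H, v * k)
            expect_equal(e1$onset_time, e2$onset_time)
            expect_equal(e1$baseline_time, e2$baseline_time)
        }
    }
})

test_that("consecutive qualifying points merge into one episode", {
    # a rise followed by further elevated points within 7 days is a single
    # episode; a separate rise after recovery opens a second one
    t_h <- c(0, 100, 120, 150, 500, 600)
    v <- c(60, 95, 100, 98, 60, 95)
    e <- detectAki(t_h * H, v)
    expect_equal(nrow(e), 2L)
    expect_equal(e$onset_time / H, c(100, 600))
})

test_that("first analyzed episode and community flag", {
    eps <- data.frame(onset_time = c(9, 3) * 86400,
                      baseline_creatinine = c(60, 60),
                      defining_creatinine = c(95, 95))
    out <- firstAnalyzedEpisode(eps, admit_time = 0)
    expect_equal(out$episode$onset_time, 3 * 86400)
    expect_false(out$community_acquired)
    out2 <- firstAnalyzedEpisode(data.frame(onset_time = 24 * H), 0)
    expect_true(out2$community_acquired)
    out3 <- firstAnalyzedEpisode(NULL, 0)
    expect_null(out3$episode)
    expect_false(out3$community_acquired)
})

test_that("per-admission wrapper matches single-series detection", {
    tc <- tiny_cohort()
    eps <- tc$eps
    labs <- tc$sim$labs
    one <- unique(eps$admission_id)[1]
    s <- labs[labs$admission_id == one &
              labs$analyte == "creatinine_serum", ]
    s <- s[order(s$timestamp), ]
    direct <- detectAki(s$timestamp, s$value)
    expect_equal(as.numeric(eps$onset_time[eps$admission_id == one]),
                 direct$onset_time)
})
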