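# Independent oracles used across the suite.  Each is written from the
# underlying definition, not by calling package internals.

# CKD-EPI 2009 equation, coded directly from the published piecewise form
oracle_egfr <- function(scr_umol, age, sex) {
    scr <- scr_umol / 88.4
    if (sex == "female") {
        if (scr <= 0.7) 141 * 1.018 * (scr / 0.7)^-0.329 * 0.993^age
        else            141 * 1.018 * (scr / 0.7)^-1.209 * 0.993^age
    } else {
        if (scr <= 0.9) 141 * (scr / 0.9)^-0.411 * 0.993^age
        else            141 * (scr / 0.9)^-1.209 * 0.993^age
    }
}

# Brute-force KDIGO detector: the qualifying-pair relation is evaluated by
# literal enumeration of every (i, j) pair; episode grouping follows the
# same published convention as the detector (absorb within 168 h of onset,
# a later episode needs a pair whose reference is at/after the previous
# episode's last qualifying point).
oracle_detect <- function(t_h, v) {
    n <- length(v)
    if (n < 2) return(data.frame(onset = numeric(), base = numeric(),
                                 def = numeric()))
    qual_pair <- function(i, j) {
        dt <- t_h[j] - t_h[i]
        (dt <= 168 && v[j] >= 1.5 * v[i]) || (dt <= 48 && v[j] - v[i] > 26.5)
    }
    q <- rep(FALSE, n); any_rel <- rep(FALSE, n)
    for (j in 2:n) for (i in 1:(j - 1)) {
        if (qual_pair(i, j)) q[j] <- TRUE
        if (t_h[j] - t_h[i] <= 168 && v[j] >= 1.5 * v[i])
            any_rel[j] <- TRUE
    }
    out <- list(); onset <- -Inf; lastq <- -Inf
    for (j in which(q)) {
        if (is.finite(onset) && t_h[j] - onset <= 168) { lastq <- t_h[j]; next }
        if (is.finite(onset)) {
            fresh <- FALSE
            for (i in seq_len(j - 1))
                if (t_h[i] >= lastq && qual_pair(i, j)) { fresh <- TRUE; break }
            if (!fresh) { lastq <- max(lastq, t_h[j]); next }
        }
        win <- if (any_rel[j]) 168 else 48
        cand <- which(t_h < t_h[j] & t_h >= t_h[j] - win)
        bidx <- cand[which.min(v[cand])]
        out[[length(out) + 1]] <- data.frame(onset = t_h[j],
                                             base = v[bidx], def = v[j])
        onset <- t_h[j]; lastq <- t_h[j]
    }
    if (!length(out)) return(data.frame(onset = numeric(), base = numeric(),
                                        def = numeric()))
    do.call(rbind, out)
}

# AUROC by explicit positive-negative pair counting (ties count 1/2)
oracle_auroc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

# small simulated cohort shared across tests (built once per run)
tiny_cohort <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            sim <- simulateCohort(simConfig(n_admissions = 800, seed = 402))
            eps <- detectAkiEpisodes(sim$labs)
            ex <- applyExclusions(sim$admissions, sim$labs, eps)
            kept <- sim$admissions[sim$admissions$admission_id %in% ex$kept, ]
            fs <- buildFeatureSet(kept, sim$labs, eps, seed = 402)
            cache <<- list(sim = sim, eps = eps, ex = ex, kept = kept,
                           fs = fs)
        }
        cache
    }
})
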