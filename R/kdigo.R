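# KDIGO 2012 creatinine criteria (oliguria criterion intentionally absent):
#   relative: creatinine >= 1.5 x a reference value measured within the
#             preceding 168 h;
#   absolute: creatinine rise > 26.5 umol/L over a reference within 48 h.
.KDIGO_REL_WINDOW_H <- 168
.KDIGO_ABS_WINDOW_H <- 48
.KDIGO_REL_RATIO <- 1.5
.KDIGO_ABS_DELTA <- 26.5
.KDIGO_STAGE3_ABS <- 353.6

#' Stage a qualifying creatinine rise
#'
#' KDIGO initial staging from the baseline and AKI-defining creatinine:
#' stage 3 if defining/baseline >= 3.0 or (defining >= 353.6 µmol/L with a
#' rise > 26.5 µmol/L); else stage 2 if the ratio >= 2.0; else stage 1.
#'
#' @param baseline baseline creatinine, µmol/L.
#' @param defining AKI-defining creatinine, µmol/L.
#' @return integer stage 1, 2 or 3.
#' @examples
#' stageEpisode(60, 125)  # 2
#' @export
stageEpisode <- function(baseline, defining) {
    if (defining / baseline < .KDIGO_REL_RATIO &&
        defining - baseline <= .KDIGO_ABS_DELTA)
        .stopf("creatinine pair (%.1f -> %.1f) does not qualify as AKI",
               baseline, defining)
    ratio <- defining / baseline
    if (ratio >= 3 || (defining >= .KDIGO_STAGE3_ABS &&
                       defining - baseline > .KDIGO_ABS_DELTA)) return(3L)
    if (ratio >= 2) return(2L)
    1L
}

# Qualifying-pair relation for one series: q[j] TRUE iff some earlier point
# i makes j AKI-defining; also records whether a relative-window pair
# exists (drives the baseline look-back width).
.kdigo_qualifies <- function(t_h, v) {
    n <- length(v)
    q <- logical(n); rel <- logical(n)
    for (j in seq_len(n)[-1]) {
        dt <- t_h[j] - t_h[seq_len(j - 1)]
        vi <- v[seq_len(j - 1)]
        rel_j <- dt <= .KDIGO_REL_WINDOW_H & v[j] >= .KDIGO_REL_RATIO * vi
        abs_j <- dt <= .KDIGO_ABS_WINDOW_H & v[j] - vi > .KDIGO_ABS_DELTA
        q[j] <- any(rel_j) || any(abs_j)
        rel[j] <- any(rel_j)
    }
    list(q = q, rel = rel)
}

#' Detect KDIGO AKI episodes in a creatinine series
#'
#' Scans a time-ordered serum creatinine series and returns the AKI
#' episodes defined by the KDIGO 2012 creatinine criteria.  A point j is
#' AKI-defining iff some earlier point i satisfies the relative criterion
#' (within 168 h, ratio >= 1.5) or the absolute criterion (within 48 h,
#' rise > 26.5 µmol/L).  The baseline is the minimum creatinine inside the
#' widest qualifying look-back window (168 h when a relative pair exists,
#' else 48 h), the earliest such point on ties.  Qualifying points within
#' 168 h of an episode's onset are absorbed into that episode; a new
#' episode afterwards requires a qualifying pair whose reference lies at or
#' after the prior episode's last qualifying point.
#'
#' @param timestamps POSIXct (or numeric hours) in non-decreasing order.
#' @param values creatinine, µmol/L, all > 0.
#' @return data.frame with one row per episode: \code{onset_time},
#'   \code{defining_creatinine}, \code{baseline_creatinine},
#'   \code{baseline_time}, \code{criterion} (relative/absolute/both),
#'   \code{stage}.
#' @examples
#' detectAki(c(0, 100) * 3600, c(60, 95))
#' @export
detectAki <- function(timestamps, values) {
    stopifnot(length(timestamps) == length(values))
    empty <- data.frame(onset_time = numeric(), defining_creatinine = numeric(),
                        baseline_creatinine = numeric(),
                        baseline_time = numeric(), criterion = character(),
                        stage = integer())
    if (length(values) < 2L) return(empty)
    if (any(values <= 0)) .stopf("creatinine values must be positive")
    t_raw <- as.numeric(timestamps)
    if (is.unsorted(t_raw)) .stopf("timestamps must be non-decreasing")
    t_h <- t_raw / .HOUR

    rel_q <- .kdigo_qualifies(t_h, values)
    q <- rel_q$q

    out <- list()
    onset <- -Inf; last_q <- -Inf
    for (j in which(q)) {
        if (t_h[j] - onset <= .KDIGO_REL_WINDOW_H && is.finite(onset)) {
            last_q <- t_h[j]            # absorbed into the open episode
            next
        }
        if (is.finite(onset)) {
            # beyond 168 h of the prior onset: require a fresh pair whose
            # reference is at or after the prior episode's last qualifying
            # point, else j is residue of the old rise
            ok <- FALSE
            for (i in seq_len(j - 1)) {
                if (t_h[i] < last_q) next
                dt <- t_h[j] - t_h[i]
                if ((dt <= .KDIGO_REL_WINDOW_H &&
                     values[j] >= .KDIGO_REL_RATIO * values[i]) ||
                    (dt <= .KDIGO_ABS_WINDOW_H &&
                     values[j] - values[i] > .KDIGO_ABS_DELTA)) { ok <- TRUE; break }
            }
            if (!ok) { last_q <- max(last_q, t_h[j]); next }
        }
        win_h <- if (rel_q$rel[j]) .KDIGO_REL_WINDOW_H else .KDIGO_ABS_WINDOW_H
        in_win <- which(t_h < t_h[j] & t_h >= t_h[j] - win_h)
        b <- in_win[which.min(values[in_win])]   # earliest min on ties
        base <- values[b]
        is_rel <- values[j] >= .KDIGO_REL_RATIO * base &&
            t_h[j] - t_h[b] <= .KDIGO_REL_WINDOW_H
        is_abs <- values[j] - base > .KDIGO_ABS_DELTA &&
            t_h[j] - t_h[b] <= .KDIGO_ABS_WINDOW_H
        out[[length(out) + 1L]] <- data.frame(
            onset_time = t_raw[j], defining_creatinine = values[j],
            baseline_creatinine = base, baseline_time = t_raw[b],
            criterion = if (is_rel && is_abs) "both" else
                if (is_rel) "relative" else "absolute",
            stage = stageEpisode(base, values[j]))
        onset <- t_h[j]; last_q <- t_h[j]
    }
    if (!length(out)) return(empty)
    do.call(rbind, out)
}

#' Detect AKI episodes for every admission in a lab table
#'
#' Convenience wrapper running \code{\link{detectAki}} on each admission's
#' serum creatinine series.
#'
#' @param labs lab events data.frame (as from \code{\link{readCohort}}).
#' @param creatinine_analyte analyte token (default
#'   \code{"creatinine_serum"}).
#' @return data.frame of episodes with an \code{admission_id} column;
#'   \code{onset_time}/\code{baseline_time} are POSIXct when the input
#'   timestamps were.
#' @export
detectAkiEpisodes <- function(labs, creatinine_analyte = "creatinine_serum") {
    dt <- as.data.table(labs)[analyte == creatinine_analyte]
    if (!nrow(dt))
        return(data.frame(admission_id = character(), onset_time = numeric(),
                          defining_creatinine = numeric(),
                          baseline_creatinine = numeric(),
                          baseline_time = numeric(), criterion = character(),
                          stage = integer()))
    is_posix <- inherits(labs$timestamp, "POSIXct")
    setorder(dt, admission_id, timestamp)
    eps <- dt[, {
        e <- detectAki(timestamp, value)
        if (nrow(e)) e else NULL
    }, by = admission_id]
    eps <- as.data.frame(eps)
    if (nrow(eps) && is_posix) {
        eps$onset_time <- as.POSIXct(eps$onset_time, origin = "1970-01-01",
                                     tz = "UTC")
        eps$baseline_time <- as.POSIXct(eps$baseline_time,
                                        origin = "1970-01-01", tz = "UTC")
    }
    eps
}

#' First analyzed episode of an admission
#'
#' Returns the earliest AKI episode (the one analyzed per admission)
#' together with the community-acquired flag: onset within 48 h of
#' admission (such admissions are excluded upstream).
#'
#' @param episodes episode data.frame for one admission (may have 0 rows).
#' @param admit_time admission time (POSIXct or numeric, same scale as
#'   \code{onset_time}).
#' @param community_aki_h community-acquisition window, hours (default 48).
#' @return list with \code{episode} (one-row data.frame or NULL) and
#'   \code{community_acquired} flag.
#' @export
firstAnalyzedEpisode <- function(episodes, admit_time, community_aki_h = 48) {
    if (is.null(episodes) || nrow(episodes) == 0L)
        return(list(episode = NULL, community_acquired = FALSE))
    first <- episodes[which.min(as.numeric(episodes$onset_time)), , drop = FALSE]
    flag <- as.numeric(first$onset_time) <
        as.numeric(admit_time) + community_aki_h * .HOUR
    list(episode = first, community_acquired = flag)
}

#' Write the episode table
#'
#' @param episodes episode data.frame from \code{\link{detectAkiEpisodes}}.
#' @param path CSV output path.
#' @return invisibly, \code{path}.
#' @export
writeEpisodesCSV <- function(episodes, path) {
    out <- as.data.table(episodes)
    if (nrow(out) && inherits(episodes$onset_time, "POSIXct")) {
        out$onset_time <- .fmt_time(episodes$onset_time)
        out$baseline_time <- .fmt_time(episodes$baseline_time)
    }
    fwrite(out, path)
    invisible(path)
}
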