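#' Feature/prediction window geometry
#'
#' The sample geometry places a prediction window of \code{lead_h} hours
#' (default 48) immediately before the reference time point; events inside
#' it are never used, which guarantees the prediction lead time.  The
#' feature window spans the \code{span_h} hours (default 168 = 7 days)
#' before the prediction window and is sectioned into \code{T} =
#' \code{span_h / bin_h} daily bins.
#'
#' @param lead_h prediction-window (lead-time) length in hours.
#' @param span_h feature-window length in hours.
#' @param bin_h bin width in hours; must divide \code{span_h}.
#' @return list with \code{lead_h}, \code{span_h}, \code{bin_h}, \code{T}.
#' @export
windowSpec <- function(lead_h = 48, span_h = 168, bin_h = 24) {
    stopifnot(lead_h > 0, span_h > 0, bin_h > 0)
    if (span_h %% bin_h != 0)
        .stopf("feature span (%g h) must be divisible by bin width (%g h)",
               span_h, bin_h)
    list(lead_h = lead_h, span_h = span_h, bin_h = bin_h,
         T = as.integer(span_h / bin_h))
}

#' Select the reference time point and label for one admission
#'
#' AKI admissions are anchored at the onset (the AKI-defining creatinine)
#' of the first episode with label 1; admissions without AKI are anchored
#' at their final in-hospital serum creatinine with label 0.  A non-AKI
#' admission with no creatinine at all has no anchor and is reported as
#' dropped.
#'
#' @param first_episode one-row episode data.frame or NULL.
#' @param creatinine_times timestamps of the admission's creatinine draws.
#' @return list with \code{reference_time}, \code{y}, \code{dropped}.
#' @export
selectReferenceTime <- function(first_episode, creatinine_times) {
    if (!is.null(first_episode) && nrow(first_episode))
        return(list(reference_time = as.numeric(first_episode$onset_time),
                    y = 1L, dropped = FALSE))
    if (!length(creatinine_times))
        return(list(reference_time = NA_real_, y = 0L, dropped = TRUE))
    list(reference_time = max(as.numeric(creatinine_times)), y = 0L,
         dropped = FALSE)
}

#' Bin one admission's events against a reference time
#'
#' Bin \code{k} (1 = oldest, T = most recent) covers the half-open interval
#' \code{[ref - lead - (T-k+1)*bin, ref - lead - (T-k)*bin)}.  Cell (k, f)
#' is the arithmetic mean of analyte f's values in bin k; the mask is 1 iff
#' at least one value fell in the bin.  Events inside the prediction window
#' (less than \code{lead_h} before the reference) or before the feature
#' window never contribute.
#'
#' @param events data.frame with \code{analyte}, \code{value},
#'   \code{timestamp} for one admission.
#' @param reference_time the sample's reference time point.
#' @param spec a \code{\link{windowSpec}}.
#' @param analytes character vector fixing the feature order (columns).
#' @return list with \code{X} (raw T x F matrix of per-bin means, NA where
#'   unobserved) and \code{M} (binary mask).
#' @export
binEvents <- function(events, reference_time, spec, analytes) {
    T_ <- spec$T; F_ <- length(analytes)
    X <- matrix(NA_real_, T_, F_, dimnames = list(NULL, analytes))
    M <- matrix(0, T_, F_, dimnames = list(NULL, analytes))
    if (!nrow(events)) return(list(X = X, M = M))
    off_h <- (as.numeric(reference_time) - as.numeric(events$timestamp)) /
        .HOUR - spec$lead_h
    k <- T_ - ceiling(off_h / spec$bin_h) + 1L   # valid when off_h in (0, span]
    ok <- off_h > 0 & off_h <= spec$span_h & events$analyte %in% analytes
    if (!any(ok)) return(list(X = X, M = M))
    dt <- data.table(k = k[ok], analyte = events$analyte[ok],
                     value = events$value[ok])
    agg <- dt[, .(m = mean(value)), by = .(k, analyte)]
    idx <- cbind(agg$k, match(agg$analyte, analytes))
    X[idx] <- agg$m
    M[idx] <- 1
    list(X = X, M = M)
}

#' Min-max normalization with clipping
#'
#' \code{(x - feat_min) / (feat_max - feat_min)}, clipped to [0, 1] so that
#' values outside the training range saturate; a degenerate feature
#' (\code{feat_min == feat_max}) maps to 0.
#'
#' @param x numeric values.
#' @param feat_min,feat_max training-split minimum and maximum.
#' @return values in [0, 1].
#' @examples
#' minmaxNormalize(5, 0, 10)
#' @export
minmaxNormalize <- function(x, feat_min, feat_max) {
    stopifnot(all(feat_min <= feat_max))
    rng <- feat_max - feat_min
    z <- ifelse(rng > 0, (x - feat_min) / rng, 0)
    pmin(pmax(z, 0), 1)
}

#' Zero imputation
#'
#' Sets cells with mask 0 exactly to 0 and leaves observed cells untouched.
#'
#' @param X normalized matrix (NA allowed where unobserved).
#' @param M binary mask of the same shape.
#' @return imputed matrix.
#' @export
imputeMissing <- function(X, M) {
    stopifnot(all(dim(X) == dim(M)))
    X[M == 0] <- 0
    X
}

#' Random 80/10/10 split of the cohort
#'
#' Deterministic (seeded) random shuffle of the samples into
#' train/validation/test partitions.  Sizes are \code{floor(n * f)} for the
#' first two fractions with the remainder going to the last, so the split
#' is exhaustive and disjoint.  In grouped mode all samples sharing a group
#' (e.g. all admissions of one patient) land in the same partition, at the
#' cost of only approximately matching the fractions.
#'
#' @param ids sample identifiers (or an integer n).
#' @param fractions length-3 positive fractions summing to 1.
#' @param seed integer seed.
#' @param groups optional grouping vector parallel to \code{ids}.
#' @return factor with levels train/valid/test, named by \code{ids}.
#' @examples
#' table(splitCohort(100, seed = 1))
#' @export
splitCohort <- function(ids, fractions = c(0.8, 0.1, 0.1), seed = 1,
                        groups = NULL) {
    if (length(ids) == 1L && is.numeric(ids)) ids <- as.character(seq_len(ids))
    n <- length(ids)
    if (n < 3L) .stopf("need at least 3 samples to split, got %d", n)
    if (length(fractions) != 3L || any(fractions <= 0) ||
        abs(sum(fractions) - 1) > 1e-8)
        .stopf("fractions must be 3 positive numbers summing to 1")
    n_train <- floor(n * fractions[1]); n_valid <- floor(n * fractions[2])
    lv <- c("train", "valid", "test")
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(.child_seed(seed, "split"))
    if (is.null(groups)) {
        perm <- sample.int(n)
        lab <- rep("test", n)
        lab[perm[seq_len(n_train)]] <- "train"
        lab[perm[n_train + seq_len(n_valid)]] <- "valid"
    } else {
        stopifnot(length(groups) == n)
        g <- as.character(groups)
        gu <- sample(unique(g))
        sizes <- table(g)[gu]
        cum <- cumsum(as.integer(sizes))
        g_lab <- ifelse(cum <= n_train, "train",
                        ifelse(cum <= n_train + n_valid, "valid", "test"))
        names(g_lab) <- gu
        lab <- unname(g_lab[g])
    }
    stats::setNames(factor(lab, levels = lv), ids)
}

#' Build the supervised feature set for a cohort
#'
#' End-to-end featurization: selects each kept admission's reference time
#' point and label, assigns the 80/10/10 split, fits the feature vocabulary
#' (analyte order by descending training-split prevalence; per-feature
#' min/max over training-split binned means), bins all admissions into the
#' T x F window matrix, min-max-normalizes with the training statistics
#' (clipping out-of-range values) and zero-imputes.  Non-AKI admissions
#' without any creatinine cannot be anchored and are dropped with a count
#' kept in \code{metadata()$dropped}.
#'
#' @param admissions kept admissions data.frame (after exclusions).
#' @param labs lab events data.frame.
#' @param episodes AKI episode table (from \code{\link{detectAkiEpisodes}}).
#' @param spec a \code{\link{windowSpec}}.
#' @param fractions split fractions (default 0.8/0.1/0.1).
#' @param seed split seed.
#' @param grouped logical: patient-grouped split.
#' @param creatinine_analyte analyte anchoring non-AKI admissions.
#' @return an \code{\linkS4class{AkiFeatureSet}}.
#' @export
buildFeatureSet <- function(admissions, labs, episodes, spec = windowSpec(),
                            fractions = c(0.8, 0.1, 0.1), seed = 1,
                            grouped = FALSE,
                            creatinine_analyte = "creatinine_serum") {
    labs_dt <- as.data.table(labs)
    labs_dt <- labs_dt[admission_id %in% admissions$admission_id]

    eps <- if (!is.null(episodes) && nrow(episodes))
        as.data.table(episodes)[, .(onset = min(as.numeric(onset_time))),
                                by = admission_id] else
        data.table(admission_id = character(), onset = numeric())
    last_cre <- labs_dt[analyte == creatinine_analyte,
                        .(last_cre = max(as.numeric(timestamp))),
                        by = admission_id]

    ids <- admissions$admission_id
    onset <- eps$onset[match(ids, eps$admission_id)]
    lcre <- last_cre$last_cre[match(ids, last_cre$admission_id)]
    y <- as.integer(!is.na(onset))
    ref <- ifelse(y == 1L, onset, lcre)
    dropped <- y == 0L & is.na(ref)

    keep <- !dropped
    samples <- data.frame(admission_id = ids[keep],
                          patient_id = admissions$patient_id[keep],
                          y = y[keep], reference_time = ref[keep],
                          stringsAsFactors = FALSE)

    split <- splitCohort(samples$admission_id, fractions, seed,
                         groups = if (grouped) samples$patient_id else NULL)
    samples$split <- as.character(split)

    # vocabulary: analytes ordered by descending prevalence among training
    # admissions (ties broken alphabetically for determinism)
    train_ids <- samples$admission_id[samples$split == "train"]
    tr <- labs_dt[admission_id %in% train_ids]
    prev <- tr[, .(prevalence = length(unique(admission_id))), by = analyte]
    prev[, prevalence := prevalence / length(train_ids)]
    setorder(prev, -prevalence, analyte)
    analytes <- prev$analyte
    if (!length(analytes)) .stopf("training split contains no lab events")

    refs <- data.table(admission_id = samples$admission_id,
                       .ref = samples$reference_time)
    binned <- .bin_all_simple(labs_dt, refs, spec, analytes)

    tr_cells <- binned[admission_id %in% train_ids]
    mm <- tr_cells[, .(min = min(m), max = max(m)), by = analyte]
    vocab <- data.frame(analyte = analytes,
                        min = mm$min[match(analytes, mm$analyte)],
                        max = mm$max[match(analytes, mm$analyte)],
                        prevalence = prev$prevalence,
                        stringsAsFactors = FALSE)
    # analytes never observed in a training feature window: degenerate range
    vocab$min[is.na(vocab$min)] <- 0
    vocab$max[is.na(vocab$max)] <- 0

    T_ <- spec$T; F_ <- length(analytes); n <- nrow(samples)
    X <- matrix(0, T_ * F_, n)
    M <- matrix(0, T_ * F_, n)
    if (nrow(binned)) {
        ri <- (match(binned$analyte, analytes) - 1L) * T_ + binned$window
        ci <- match(binned$admission_id, samples$admission_id)
        fmin <- vocab$min[match(binned$analyte, analytes)]
        fmax <- vocab$max[match(binned$analyte, analytes)]
        X[cbind(ri, ci)] <- minmaxNormalize(binned$m, fmin, fmax)
        M[cbind(ri, ci)] <- 1
    }

    rd <- DataFrame(window = rep(seq_len(T_), times = F_),
                    analyte = rep(analytes, each = T_))
    cd <- DataFrame(admission_id = samples$admission_id,
                    patient_id = samples$patient_id,
                    y = samples$y,
                    reference_time = as.POSIXct(samples$reference_time,
                                                origin = "1970-01-01",
                                                tz = "UTC"),
                    split = samples$split)
    se <- SummarizedExperiment(assays = list(X = X, M = M),
                               rowData = rd, colData = cd)
    colnames(se) <- samples$admission_id
    metadata(se)$windowSpec <- spec
    metadata(se)$vocabulary <- vocab
    metadata(se)$dropped <- list(n = sum(dropped),
                                 admission_ids = ids[dropped])
    metadata(se)$split_seed <- seed
    new("AkiFeatureSet", se)
}

# straightforward vectorized binner used by buildFeatureSet
.bin_all_simple <- function(labs_dt, refs, spec, analytes) {
    dt <- labs_dt[refs, on = "admission_id", nomatch = NULL]
    dt[, off_h := (.ref - as.numeric(timestamp)) / 3600 - spec$lead_h]
    dt <- dt[off_h > 0 & off_h <= spec$span_h & analyte %in% analytes]
    dt[, window := spec$T - as.integer(ceiling(off_h / spec$bin_h)) + 1L]
    dt[, .(m = mean(value)), by = .(admission_id, window, analyte)]
}

#' Dense arrays and labels from an AkiFeatureSet
#'
#' \code{featureArray} and \code{maskArray} return the n x T x F arrays of
#' normalized values and observation masks; \code{sampleLabels} the 0/1
#' label vector; \code{splitOf} the split factor; \code{featureMatrix} one
#' admission's T x F matrix.
#'
#' @param fs an \code{AkiFeatureSet}.
#' @param which assay, \code{"X"} or \code{"M"}.
#' @return array, vector or matrix as described.
#' @export
featureArray <- function(fs, which = "X") {
    spec <- metadata(fs)$windowSpec
    T_ <- spec$T; F_ <- nrow(fs) / T_
    a <- assay(fs, which)
    arr <- aperm(array(a, dim = c(T_, F_, ncol(fs))), c(3, 1, 2))
    dimnames(arr) <- list(colnames(fs), NULL,
                          metadata(fs)$vocabulary$analyte)
    arr
}

#' @rdname featureArray
#' @export
maskArray <- function(fs) featureArray(fs, "M")

#' @rdname featureArray
#' @export
sampleLabels <- function(fs) stats::setNames(colData(fs)$y, colnames(fs))

#' @rdname featureArray
#' @export
splitOf <- function(fs) stats::setNames(
    factor(colData(fs)$split, levels = c("train", "valid", "test")),
    colnames(fs))

#' @rdname featureArray
#' @param admission_id one admission identifier.
#' @export
featureMatrix <- function(fs, admission_id, which = "X") {
    spec <- metadata(fs)$windowSpec
    j <- match(admission_id, colnames(fs))
    if (is.na(j)) .stopf("admission '%s' not in feature set", admission_id)
    m <- matrix(assay(fs, which)[, j], nrow = spec$T)
    colnames(m) <- metadata(fs)$vocabulary$analyte
    m
}

#' Subset an AkiFeatureSet to one split
#'
#' @param fs an \code{AkiFeatureSet}.
#' @param split one of "train", "valid", "test".
#' @return the subset \code{AkiFeatureSet}.
#' @export
splitSubset <- function(fs, split) {
    fs[, colData(fs)$split == split]
}

#' Write the fitted vocabulary to JSON
#'
#' @param fs an \code{AkiFeatureSet}.
#' @param path output path (vocabulary.json).
#' @return invisibly, \code{path}.
#' @export
writeVocabularyJSON <- function(fs, path) {
    jsonlite::write_json(metadata(fs)$vocabulary, path, digits = NA)
    invisible(path)
}
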