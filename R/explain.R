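#' Per-case feature-importance explanation
#'
#' Ranks the (window, analyte) cells of one sample by their importance to
#' the model's risk score, by default \code{alpha_tf * beta_f} (the product
#' of time-variant and time-invariant importance), optionally by the
#' magnitude of the exact additive logit contribution.  The full table can
#' be reshaped into per-feature importance trajectories across the 7 daily
#' windows for case-report heatmaps.
#'
#' @param model a fitted \code{\linkS4class{TitvModel}} of kind "titv".
#' @param fs an \code{\linkS4class{AkiFeatureSet}}.
#' @param admission_id the sample to explain.
#' @param top_k number of cells to return (capped at T*F).
#' @param by rank by \code{"importance"} (alpha*beta) or
#'   \code{"contribution"} (|additive logit contribution|).
#' @return data.frame ranked by decreasing score with columns
#'   \code{analyte}, \code{window}, \code{importance},
#'   \code{contribution}, \code{risk} (the sample's risk, repeated).
#' @export
titvExplain <- function(model, fs, admission_id, top_k = 10,
                        by = c("importance", "contribution")) {
    by <- match.arg(by)
    if (modelKind(model) != "titv")
        .stopf("explanations are only defined for the TITV model")
    X <- featureMatrix(fs, admission_id, "X")
    M <- featureMatrix(fs, admission_id, "M")
    out <- titvForward(model, X, M)
    T_ <- nrow(X); F_ <- ncol(X)
    analytes <- metadata(fs)$vocabulary$analyte
    imp <- sweep(out$alpha, 2L, out$beta, "*")
    imp <- imp / sum(imp)                  # relative importance, mass 1
    tab <- data.frame(analyte = rep(analytes, each = T_),
                      window = rep(seq_len(T_), times = F_),
                      importance = as.vector(imp),
                      contribution = as.vector(out$contributions),
                      risk = out$risk)
    score <- if (by == "importance") tab$importance else
        abs(tab$contribution)
    tab <- tab[order(-score), ]
    rownames(tab) <- NULL
    utils::head(tab, min(top_k, T_ * F_))
}

#' Mean importance profile over a set of cases
#'
#' Averages \code{alpha * beta} importance over the given admissions,
#' returning one row per (analyte, window): the cohort-level analogue of
#' the per-case heatmaps, used e.g. to check that a planted prodromal
#' analyte is recovered.
#'
#' @param model fitted TITV model.
#' @param fs an \code{AkiFeatureSet}.
#' @param admission_ids admissions to average over (default: all positives).
#' @return data.frame with \code{analyte}, \code{window},
#'   \code{importance} (grand mean over cases), plus a per-analyte
#'   aggregate attribute.
#' @export
meanImportance <- function(model, fs, admission_ids = NULL) {
    if (is.null(admission_ids))
        admission_ids <- colnames(fs)[colData(fs)$y == 1]
    sub <- fs[, admission_ids]
    a <- .fs_arrays(sub)
    out <- .titv_forward_plain(modelParams(model), a$X3, a$M3,
                               isTRUE(modelConfig(model)$use_mask))
    n <- dim(a$X3)[1]; T_ <- dim(a$X3)[2]; F_ <- dim(a$X3)[3]
    imp <- out$alpha        # n x T x F; beta (n x F) broadcasts over T
    # per-case alpha*beta, renormalized to unit mass before averaging

    for (t in seq_len(T_)) imp[, t, ] <- imp[, t, ] * out$beta
    tot <- apply(imp, 1, sum)
    imp <- imp / tot
    m <- apply(imp, c(2, 3), mean)
    analytes <- metadata(fs)$vocabulary$analyte
    df <- data.frame(analyte = rep(analytes, each = T_),
                     window = rep(seq_len(T_), times = F_),
                     importance = as.vector(m))
    attr(df, "by_analyte") <- stats::setNames(colSums(m), analytes)
    df
}
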