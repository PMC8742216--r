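#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' AkiFeatureSet: supervised samples for AKI risk modelling
#'
#' An \code{AkiFeatureSet} holds one supervised sample per analyzable
#' admission: the T x F matrix of daily-binned, min-max-normalized,
#' zero-imputed laboratory values covering the 7-day feature window, the
#' matching observation mask, and the binary AKI label.  It extends
#' \linkS4class{SummarizedExperiment}: the two assays \code{"X"} and
#' \code{"M"} are stored flattened as (T*F) x n matrices, with one row per
#' (time window, analyte) cell and one column per admission.
#'
#' \code{rowData} carries \code{window} (1 = oldest daily bin, T = the bin
#' ending at the prediction-window boundary) and \code{analyte};
#' \code{colData} carries \code{admission_id}, \code{patient_id}, \code{y}
#' (1 = AKI), \code{reference_time} and \code{split} (train/valid/test).
#' \code{metadata()} stores the \code{\link{windowSpec}} and the fitted
#' feature vocabulary (analyte order, training-split min/max, prevalence).
#'
#' @seealso \code{\link{buildFeatureSet}}, \code{\link{featureArray}},
#'   \code{\link{sampleLabels}}
#' @export
setClass("AkiFeatureSet", contains = "SummarizedExperiment")

setValidity("AkiFeatureSet", function(object) {
    msg <- character()
    if (!all(c("X", "M") %in% names(assays(object))))
        msg <- c(msg, "assays must contain 'X' and 'M'")
    else {
        X <- assay(object, "X"); M <- assay(object, "M")
        if (length(X) && (min(X) < 0 || max(X) > 1))
            msg <- c(msg, "X entries must lie in [0, 1]")
        if (length(X) && any(X[M == 0] != 0))
            msg <- c(msg, "X must be 0 wherever M is 0")
        if (!all(M %in% c(0, 1)))
            msg <- c(msg, "M must be binary")
    }
    rd <- rowData(object)
    if (!all(c("window", "analyte") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'window' and 'analyte'")
    cd <- colData(object)
    need <- c("admission_id", "y", "reference_time", "split")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, paste("colData must contain",
                            paste(need, collapse = ", ")))
    else if (!all(cd$y %in% c(0L, 1L)))
        msg <- c(msg, "labels y must be 0/1")
    spec <- metadata(object)$windowSpec
    if (is.null(spec))
        msg <- c(msg, "metadata must contain the windowSpec")
    if (length(msg)) msg else TRUE
})

#' TitvModel: a fitted AKI risk model
#'
#' Container for a fitted model of any of the four supported kinds:
#' \code{"titv"} (the interpretable time-invariant/time-variant recurrent
#' model), \code{"logistic"}, \code{"gru"} or \code{"bgru"}.  Slots hold
#' the raw parameter list, the training configuration, the feature
#' vocabulary the model was fitted against (risk scores are only valid for
#' samples featurized with the same vocabulary), and the per-epoch training
#' history with the best-validation epoch.
#'
#' @slot kind character, one of titv/logistic/gru/bgru.
#' @slot params named list of numeric parameter matrices/vectors.
#' @slot config the \code{\link{titvConfig}} list used for fitting.
#' @slot vocabulary data.frame (analyte, min, max, prevalence).
#' @slot history data.frame with one row per epoch (loss, validation AUROC).
#' @slot best_epoch integer epoch whose parameters are stored.
#'
#' @seealso \code{\link{fitTitv}}, \code{\link{fitBaseline}},
#'   \code{\link{predictRisk}}, \code{\link{titvExplain}}
#' @export
setClass("TitvModel",
    representation(kind = "character", params = "list", config = "list",
                   vocabulary = "data.frame", history = "data.frame",
                   best_epoch = "integer"))

setValidity("TitvModel", function(object) {
    if (!object@kind %in% c("titv", "logistic", "gru", "bgru"))
        return("kind must be one of titv/logistic/gru/bgru")
    if (any(!vapply(object@params, function(p) all(is.finite(p)), TRUE)))
        return("parameters contain non-finite values")
    TRUE
})

#' @describeIn TitvModel compact summary
#' @param object a \code{TitvModel}
#' @export
setMethod("show", "TitvModel", function(object) {
    np <- sum(vapply(object@params, length, 0L))
    cat(sprintf("TitvModel of kind '%s' — %d parameters, F = %d features\n",
                object@kind, np, nrow(object@vocabulary)))
    if (nrow(object@history)) {
        b <- object@best_epoch
        cat(sprintf("  fitted %d epochs; best epoch %d (validation AUROC %.3f)\n",
                    nrow(object@history), b, object@history$val_auroc[b]))
    }
    invisible(NULL)
})

#' @describeIn AkiFeatureSet compact summary
#' @param object an \code{AkiFeatureSet}
#' @export
setMethod("show", "AkiFeatureSet", function(object) {
    spec <- metadata(object)$windowSpec
    cd <- colData(object)
    cat(sprintf(
        "AkiFeatureSet: %d admissions, T = %d windows x F = %d analytes\n",
        ncol(object), spec$T, nrow(object) / spec$T))
    cat(sprintf("  positives: %d (%.1f%%); splits: %s\n",
        sum(cd$y), 100 * mean(cd$y),
        paste(sprintf("%s=%d", names(table(cd$split)), table(cd$split)),
              collapse = ", ")))
    invisible(NULL)
})

#' Model accessors
#'
#' \code{modelKind}, \code{modelParams}, \code{modelConfig},
#' \code{trainingHistory} and \code{modelVocabulary} read the corresponding
#' slots of a \code{\linkS4class{TitvModel}} without touching slots
#' directly.
#'
#' @param model a \code{TitvModel}
#' @return the slot contents.
#' @export
modelKind <- function(model) model@kind

#' @rdname modelKind
#' @export
modelParams <- function(model) model@params

#' @rdname modelKind
#' @export
modelConfig <- function(model) model@config

#' @rdname modelKind
#' @export
trainingHistory <- function(model) model@history

#' @rdname modelKind
#' @export
modelVocabulary <- function(model) model@vocabulary
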