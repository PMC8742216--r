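#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a uniformly drawn positive sample outranks a
#' uniformly drawn negative one, with ties counted 1/2; computed from
#' midranks.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in [0, 1].
#' @examples
#' aurocScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
aurocScore <- function(scores, labels) {
    labels <- as.integer(labels)
    n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
    if (n_pos == 0L || n_neg == 0L)
        .stopf("AUROC requires both classes (got %d positives, %d negatives)",
               n_pos, n_neg)
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Bootstrap confidence interval for the AUROC
#'
#' Percentile bootstrap: samples are resampled with replacement
#' \code{n_boot} times; degenerate resamples containing a single class are
#' redrawn (their count is reported).  Deterministic given \code{seed}.
#'
#' @inheritParams aurocScore
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return list with \code{lo}, \code{hi}, \code{auroc} (point estimate)
#'   and \code{n_redrawn}.
#' @export
aurocCI <- function(scores, labels, n_boot = 2000, seed = 1, level = 0.95) {
    n <- length(scores)
    stopifnot(length(labels) == n, n >= 10)
    point <- aurocScore(scores, labels)
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(.child_seed(seed, "auroc_ci"))
    stat <- numeric(n_boot); redrawn <- 0L
    for (b in seq_len(n_boot)) {
        repeat {
            idx <- sample.int(n, n, replace = TRUE)
            if (length(unique(labels[idx])) == 2L) break
            redrawn <- redrawn + 1L
        }
        stat[b] <- aurocScore(scores[idx], labels[idx])
    }
    a <- (1 - level) / 2
    qs <- stats::quantile(stat, c(a, 1 - a), names = FALSE, type = 7)
    list(lo = qs[1], hi = qs[2], auroc = point, n_redrawn = redrawn)
}

#' Area under the precision-recall curve
#'
#' Step-wise (rectangular) integration of precision over recall across all
#' distinct score thresholds.
#'
#' @inheritParams aurocScore
#' @return AUPRC in [0, 1].
#' @export
auprcScore <- function(scores, labels) {
    labels <- as.integer(labels)
    o <- order(scores, decreasing = TRUE)
    y <- labels[o]; s <- scores[o]
    tp <- cumsum(y); fp <- cumsum(1 - y)
    keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
    tp <- tp[keep]; fp <- fp[keep]
    prec <- tp / (tp + fp); rec <- tp / sum(y)
    sum(diff(c(0, rec)) * prec)
}

#' Confusion matrix at a probability threshold
#'
#' A sample is predicted positive iff its score is greater than or equal
#' to the threshold (a score exactly at the threshold raises an alert).
#'
#' @inheritParams aurocScore
#' @param threshold probability threshold in [0, 1].
#' @return list with \code{tp}, \code{fp}, \code{fn}, \code{tn}.
#' @export
confusionAtThreshold <- function(scores, labels, threshold) {
    stopifnot(threshold >= 0, threshold <= 1)
    labels <- as.integer(labels)
    pred <- scores >= threshold
    list(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
         fn = sum(!pred & labels == 1), tn = sum(!pred & labels == 0))
}

#' F1 score from precision and recall
#'
#' \code{2 * precision * recall / (precision + recall)}; 0 when both are 0.
#'
#' @param precision,recall values in [0, 1].
#' @return the harmonic mean.
#' @examples
#' f1Score(0.397, 0.256)
#' @export
f1Score <- function(precision, recall) {
    stopifnot(all(precision >= 0 & precision <= 1),
              all(recall >= 0 & recall <= 1))
    ifelse(precision + recall == 0, 0,
           2 * precision * recall / (precision + recall))
}

#' Precision/recall/F1 row from confusion counts
#'
#' Arithmetic used throughout the threshold sweep; exposed so printed
#' confusion counts can be turned into metric rows directly.  Precision is
#' reported as 0 with \code{precision_defined = FALSE} when there are no
#' predicted positives.
#'
#' @param tp,fp,fn,tn confusion counts.
#' @return one-row data.frame with \code{precision}, \code{recall},
#'   \code{f1}, \code{n_predicted_positive}, \code{n_true_positive},
#'   \code{precision_defined}.
#' @export
metricsFromCounts <- function(tp, fp, fn, tn) {
    npp <- tp + fp
    prec_def <- npp > 0
    precision <- if (prec_def) tp / npp else 0
    pos <- tp + fn
    recall <- if (pos > 0) tp / pos else 0
    data.frame(precision = precision, recall = recall,
               f1 = f1Score(precision, recall),
               n_predicted_positive = npp, n_true_positive = tp,
               precision_defined = prec_def)
}

#' Threshold sweep with best-F1 selection
#'
#' One metric row per probability threshold (default 5% to 30% in 5%
#' steps); the operating threshold is selected as the argmax of F1, the
#' lowest threshold on ties.
#'
#' @inheritParams aurocScore
#' @param thresholds probability thresholds.
#' @return list with \code{rows} (data.frame, one per threshold, including
#'   the confusion counts) and \code{best_f1_threshold}.
#' @export
thresholdSweep <- function(scores, labels,
                           thresholds = seq(0.05, 0.30, by = 0.05)) {
    if (length(unique(as.integer(labels))) < 2L)
        .stopf("threshold sweep requires both classes")
    rows <- do.call(rbind, lapply(thresholds, function(th) {
        cm <- confusionAtThreshold(scores, labels, th)
        cbind(data.frame(threshold = th),
              metricsFromCounts(cm$tp, cm$fp, cm$fn, cm$tn),
              data.frame(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn))
    }))
    rownames(rows) <- NULL
    list(rows = rows,
         best_f1_threshold = rows$threshold[which.max(rows$f1)])
}

#' Full evaluation report
#'
#' AUROC with bootstrap confidence interval, AUPRC, the threshold sweep
#' with per-threshold confusion matrices, and the best-F1 operating
#' threshold.
#'
#' @inheritParams thresholdSweep
#' @param n_boot bootstrap replicates for the AUROC interval.
#' @param seed bootstrap seed.
#' @param ci_method \code{"bootstrap"} (default) or \code{"delong"}
#'   (requires the pROC package).
#' @return list (class \code{akitv_eval_report}) with \code{auroc},
#'   \code{auroc_ci}, \code{auprc}, \code{rows}, \code{matrices},
#'   \code{best_f1_threshold}, \code{n}.
#' @export
evalReport <- function(scores, labels,
                       thresholds = seq(0.05, 0.30, by = 0.05),
                       n_boot = 2000, seed = 1,
                       ci_method = c("bootstrap", "delong")) {
    ci_method <- match.arg(ci_method)
    sweep_ <- thresholdSweep(scores, labels, thresholds)
    if (ci_method == "delong") {
        if (!requireNamespace("pROC", quietly = TRUE))
            .stopf("ci_method='delong' requires the pROC package")
        r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
        ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
        auroc_ci <- list(lo = ci[1], hi = ci[3], auroc = ci[2],
                         n_redrawn = 0L)
    } else {
        auroc_ci <- aurocCI(scores, labels, n_boot = n_boot, seed = seed)
    }
    matrices <- lapply(seq_len(nrow(sweep_$rows)), function(i)
        as.list(sweep_$rows[i, c("tp", "fp", "fn", "tn")]))
    names(matrices) <- sprintf("%g", sweep_$rows$threshold)
    structure(list(auroc = aurocScore(scores, labels),
                   auroc_ci = auroc_ci[c("lo", "hi")],
                   auprc = auprcScore(scores, labels),
                   rows = sweep_$rows, matrices = matrices,
                   best_f1_threshold = sweep_$best_f1_threshold,
                   n = length(scores)),
              class = "akitv_eval_report")
}

#' Write / read an evaluation report
#'
#' \code{writeEvalReport} serializes a report to \code{eval_report.json}
#' plus \code{threshold_table.csv} (one row per threshold) and per-
#' threshold \code{confusion_<thr>.csv} files; \code{readEvalReport}
#' restores the JSON losslessly.
#'
#' @param report an \code{akitv_eval_report}.
#' @param dir output directory.
#' @return invisibly, the JSON path; \code{readEvalReport}: the report.
#' @export
writeEvalReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jp <- file.path(dir, "eval_report.json")
    jsonlite::write_json(unclass(report), jp, auto_unbox = TRUE, digits = NA)
    fwrite(as.data.table(report$rows), file.path(dir, "threshold_table.csv"))
    for (nm in names(report$matrices)) {
        cm <- report$matrices[[nm]]
        fwrite(data.table(truth = c("positive", "positive", "negative",
                                    "negative"),
                          predicted = c("positive", "negative", "positive",
                                        "negative"),
                          n = c(cm$tp, cm$fn, cm$fp, cm$tn)),
               file.path(dir, sprintf("confusion_%s.csv", nm)))
    }
    invisible(jp)
}

#' @rdname writeEvalReport
#' @param path path to \code{eval_report.json}.
#' @export
readEvalReport <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    j$rows <- as.data.frame(j$rows)
    j$matrices <- lapply(j$matrices, as.list)
    structure(j, class = "akitv_eval_report")
}
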