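# Shared minibatch training machinery for the TITV model and its
# logistic / GRU / BGRU comparison baselines: class-weighted binary
# cross-entropy minimized with Adam, early stopping on validation AUROC,
# best-validation checkpoint returned.  All stochastic operations
# (initialization, shuffling, dropout) derive from the config seed.

.fs_arrays <- function(fs) {
    if (is.list(fs) && !is(fs, "AkiFeatureSet"))
        return(fs)                      # already list(X3, M3, y)
    list(X3 = featureArray(fs, "X"), M3 = featureArray(fs, "M"),
         y = unname(sampleLabels(fs)))
}

.tlist <- function(A3, idx) {
    n <- length(idx); T_ <- dim(A3)[2]; F_ <- dim(A3)[3]
    lapply(seq_len(T_), function(t) matrix(A3[idx, t, ], n, F_))
}

# one loss + gradient evaluation on a tape (also used by gradient tests)
.loss_and_grads <- function(kind, params, X3, M3, y, w, use_mask = FALSE,
                            drop = NULL, shift_decay = 0, head_decay = 0,
                            beta_entropy = 0) {
    tape <- .ad_tape()
    pn <- lapply(params, function(p) .ad_const(tape, p))
    idx <- seq_len(dim(X3)[1])
    Xl <- .tlist(X3, idx); Ml <- .tlist(M3, idx)
    delta <- NULL
    if (kind == "titv") {
        fwd <- .titv_forward_tape(tape, pn, Xl, Ml, use_mask, drop)
        logit <- fwd$logit; delta <- fwd$delta
    } else {
        logit <- .baseline_forward_tape(kind, tape, pn, Xl, Ml, use_mask,
                                        drop)
    }
    loss <- .ad_bce_logits(tape, logit, y, w)
    if (kind == "titv" && shift_decay > 0)
        loss <- .ad_scalar_axpy(tape, loss, .ad_meansq(tape, delta),
                                shift_decay)
    if (kind == "titv" && head_decay > 0)
        loss <- .ad_scalar_axpy(tape, loss, .ad_meansq(tape, pn$w),
                                head_decay)
    if (kind == "titv" && beta_entropy > 0)
        loss <- .ad_scalar_axpy(tape, loss,
                                .ad_row_entropy(tape, fwd$beta),
                                beta_entropy)
    .ad_backward(tape, loss)
    grads <- lapply(pn, function(nd)
        if (is.null(nd$grad)) NULL else {
            g <- nd$grad
            if (is.matrix(nd$value)) matrix(g, nrow(nd$value)) else
                as.vector(g)
        })
    list(loss = loss$value, grads = grads)
}

.fit_net <- function(kind, train, valid, config) {
    tr <- .fs_arrays(train); va <- .fs_arrays(valid)
    y <- tr$y
    if (length(unique(y)) < 2L)
        .stopf("training set must contain both classes")
    n <- length(y); T_ <- dim(tr$X3)[2]; F_ <- dim(tr$X3)[3]

    pcw <- config$positive_class_weight
    if (identical(pcw, "auto")) pcw <- sum(y == 0) / sum(y == 1)
    w <- ifelse(y == 1, pcw, 1)

    old_seed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(.child_seed(config$seed, paste0("fit_", kind)))

    params <- if (kind == "titv") .init_titv_params(F_, config) else
        .init_baseline_params(kind, T_, F_, config)
    state <- .adam_state(params)

    best <- list(auroc = -Inf, params = params, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_auroc = numeric())
    wait <- 0L
    H2 <- if (kind == "titv") 2L * config$hidden_size else NA_integer_

    for (epoch in seq_len(config$max_epochs)) {
        perm <- sample.int(n)
        starts <- seq(1L, n, by = config$batch_size)
        losses <- numeric(length(starts))
        for (bi in seq_along(starts)) {
            idx <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
            nb <- length(idx)
            drop <- NULL
            if (config$dropout > 0 && kind == "titv") {
                keep <- 1 - config$dropout
                drop <- list(
                    film = matrix(stats::rbinom(nb * F_ * config$film_hidden,
                                                1, keep) / keep,
                                  nb * F_, config$film_hidden),
                    hidden = lapply(seq_len(T_), function(t)
                        matrix(stats::rbinom(nb * H2, 1, keep) / keep,
                               nb, H2)))
            }
            X3b <- tr$X3[idx, , , drop = FALSE]
            M3b <- tr$M3[idx, , , drop = FALSE]
            lg <- .loss_and_grads(kind, params, X3b, M3b, y[idx], w[idx],
                                  config$use_mask, drop,
                                  shift_decay = config$shift_decay,
                                  head_decay = config$head_decay,
                                  beta_entropy = config$beta_entropy)
            losses[bi] <- lg$loss
            if (kind == "titv" && epoch <= config$attn_warmup)
                for (nm in c("Wa", "ba", "va", "Wb", "sb", "bb",
                             grep("^[fb]_", names(params), value = TRUE)))
                    lg$grads[[nm]] <- NULL
            upd <- .adam_step(params, lg$grads, state, config$learning_rate)
            params <- upd$params; state <- upd$state
        }
        val_risk <- if (kind == "titv")
            .titv_forward_plain(params, va$X3, va$M3, config$use_mask)$risk
        else .baseline_forward_plain(kind, params, va$X3, va$M3,
                                     config$use_mask)$risk
        val_auc <- if (length(unique(va$y)) < 2L) NA_real_ else
            aurocScore(val_risk, va$y)
        hist <- rbind(hist, data.frame(epoch = epoch,
                                       train_loss = mean(losses),
                                       val_auroc = val_auc))
        if (!is.na(val_auc) && val_auc > best$auroc + 1e-6) {
            best <- list(auroc = val_auc, params = params, epoch = epoch)
            wait <- 0L
        } else {
            wait <- wait + 1L
            if (wait >= config$early_stop_patience) break
        }
    }
    if (!is.finite(best$auroc))
        best <- list(auroc = NA_real_, params = params, epoch = nrow(hist))
    # undo the class-weight prior shift so risks are calibrated to the
    # cohort prevalence scale (rank order, and hence AUROC, unchanged)
    best$params$b0 <- best$params$b0 - log(pcw)
    list(params = best$params, history = hist, best_epoch = best$epoch)
}

#' Fit the TITV model
#'
#' Trains the time-invariant/time-variant interpretable recurrent model by
#' minibatch Adam on class-weighted binary cross-entropy, with early
#' stopping on validation AUROC and the best-validation checkpoint
#' returned.  Fully reproducible given \code{config$seed}.
#'
#' @param train,valid \code{\linkS4class{AkiFeatureSet}}s (or lists with
#'   \code{X3}, \code{M3}, \code{y} arrays).
#' @param config a \code{\link{titvConfig}}.
#' @return a fitted \code{\linkS4class{TitvModel}} of kind \code{"titv"}.
#' @export
fitTitv <- function(train, valid, config = titvConfig()) {
    fit <- .fit_net("titv", train, valid, config)
    vocab <- if (is(train, "AkiFeatureSet")) metadata(train)$vocabulary else
        data.frame(analyte = paste0("f", seq_len(dim(.fs_arrays(train)$X3)[3])))
    new("TitvModel", kind = "titv", params = fit$params, config = config,
        vocabulary = vocab, history = fit$history,
        best_epoch = as.integer(fit$best_epoch))
}

#' Fit a comparison baseline
#'
#' \code{"logistic"} operates on the flattened T*F vector; \code{"gru"}
#' and \code{"bgru"} feed the last (both-direction) hidden state(s) through
#' a linear output layer.  All share the TITV loss, optimizer and
#' early-stopping protocol.
#'
#' @param kind one of \code{"logistic"}, \code{"gru"}, \code{"bgru"}.
#' @inheritParams fitTitv
#' @return a fitted \code{\linkS4class{TitvModel}} of the requested kind.
#' @export
fitBaseline <- function(kind = c("logistic", "gru", "bgru"), train, valid,
                        config = titvConfig()) {
    kind <- match.arg(kind)
    fit <- .fit_net(kind, train, valid, config)
    vocab <- if (is(train, "AkiFeatureSet")) metadata(train)$vocabulary else
        data.frame(analyte = paste0("f", seq_len(dim(.fs_arrays(train)$X3)[3])))
    new("TitvModel", kind = kind, params = fit$params, config = config,
        vocabulary = vocab, history = fit$history,
        best_epoch = as.integer(fit$best_epoch))
}

#' Predicted AKI risk for a feature set
#'
#' @param model a fitted \code{\linkS4class{TitvModel}}.
#' @param fs an \code{\linkS4class{AkiFeatureSet}} (or list with
#'   \code{X3}/\code{M3} arrays) featurized with the model's vocabulary.
#' @return named numeric vector of risk probabilities.
#' @export
predictRisk <- function(model, fs) {
    a <- .fs_arrays(fs)
    use_mask <- isTRUE(modelConfig(model)$use_mask)
    r <- if (modelKind(model) == "titv")
        .titv_forward_plain(modelParams(model), a$X3, a$M3, use_mask)$risk
    else .baseline_forward_plain(modelKind(model), modelParams(model),
                                 a$X3, a$M3, use_mask)$risk
    if (is(fs, "AkiFeatureSet")) names(r) <- colnames(fs)
    r
}

#' Serialize / restore a fitted model
#'
#' Versioned plain-JSON checkpoint holding the parameters, the exact
#' training configuration, the vocabulary and the training history.
#'
#' @param model a \code{TitvModel}.
#' @param path output path.
#' @return \code{writeModelJSON}: invisibly, \code{path};
#'   \code{readModelJSON}: the restored \code{TitvModel}.
#' @export
writeModelJSON <- function(model, path) {
    payload <- list(format_version = 1L, kind = modelKind(model),
                    config = modelConfig(model),
                    vocabulary = modelVocabulary(model),
                    history = trainingHistory(model),
                    best_epoch = model@best_epoch,
                    params = lapply(modelParams(model), function(p)
                        list(dim = if (is.matrix(p)) dim(p) else length(p),
                             data = as.vector(p))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    params <- lapply(j$params, function(p) {
        if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2]) else
            as.numeric(p$data)
    })
    cfg <- j$config
    cfg$use_mask <- isTRUE(cfg$use_mask)
    new("TitvModel", kind = j$kind, params = params, config = cfg,
        vocabulary = as.data.frame(j$vocabulary),
        history = as.data.frame(j$history),
        best_epoch = as.integer(j$best_epoch))
}
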