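#' Training configuration for TITV and baseline models
#'
#' @param hidden_size GRU hidden units per direction (default 24; the model
#'   is deliberately small since F is tens of features and T = 7).
#' @param film_hidden hidden units of the feature-wise-modulation network.
#' @param attn_size hidden units of the attention scorer.
#' @param dropout dropout probability in [0, 1) applied to the modulation
#'   and recurrent hidden layers during training.
#' @param learning_rate Adam step size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation-AUROC improvement
#'   before stopping.
#' @param batch_size minibatch size.
#' @param positive_class_weight weight of positive samples in the
#'   cross-entropy, or \code{"auto"} for n_negative / n_positive.
#' @param shift_decay L2 penalty on the feature-wise modulation shift
#'   delta.  Without it the pooled-summary network can smuggle the whole
#'   prediction through the shift, leaving the importance outputs
#'   uninformative; the penalty forces the risk through the
#'   modulated-input/attention pathway that the attributions report.
#' @param head_decay light L2 penalty on the per-feature head weights,
#'   pushing feature selection into the (reported) modulation scales.
#' @param beta_entropy sparsity prior on the time-invariant importance:
#'   penalty weight on the mean Shannon entropy of beta.  Encourages each
#'   case's importance mass to concentrate on the few analytes whose
#'   pooled window summary actually departs from baseline.
#' @param attn_warmup epochs during which the attention and recurrent
#'   parameters stay frozen at their initialization.  During warm-up the
#'   risk is a feature-wise-modulated near-linear model, so the modulation
#'   scales (the reported time-invariant importance) must align with the
#'   informative analytes before the higher-capacity time-variant module
#'   is allowed to move.
#' @param seed integer; fixes initialization, shuffling and dropout.
#' @param use_mask logical; feed the observation mask to the recurrent
#'   module alongside the zero-imputed values.
#' @return named list of settings.
#' @export
titvConfig <- function(hidden_size = 24, film_hidden = 16, attn_size = 8,
                       dropout = 0, learning_rate = 0.015, max_epochs = 100,
                       early_stop_patience = 15, batch_size = 256,
                       positive_class_weight = "auto", shift_decay = 1,
                       head_decay = 0.001, beta_entropy = 0,
                       attn_warmup = 10, seed = 1, use_mask = FALSE) {
    stopifnot(hidden_size > 0, film_hidden > 0, attn_size > 0,
              dropout >= 0, dropout < 1, learning_rate > 0,
              max_epochs >= 1, batch_size >= 1)
    if (!identical(positive_class_weight, "auto"))
        stopifnot(positive_class_weight > 0)
    list(hidden_size = as.integer(hidden_size),
         film_hidden = as.integer(film_hidden),
         attn_size = as.integer(attn_size), dropout = dropout,
         learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         batch_size = as.integer(batch_size),
         positive_class_weight = positive_class_weight,
         shift_decay = shift_decay, head_decay = head_decay,
         beta_entropy = beta_entropy,
         attn_warmup = as.integer(attn_warmup),
         seed = as.integer(seed), use_mask = isTRUE(use_mask))
}

.runif_mat <- function(nr, nc, scale) {
    matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

.init_gru_block <- function(f_in, H) {
    s_in <- sqrt(6 / (f_in + H)); s_h <- sqrt(6 / (2 * H))
    list(Wz = .runif_mat(f_in, H, s_in), Uz = .runif_mat(H, H, s_h),
         bz = numeric(H),
         Wr = .runif_mat(f_in, H, s_in), Ur = .runif_mat(H, H, s_h),
         br = numeric(H),
         Wn = .runif_mat(f_in, H, s_in), Un = .runif_mat(H, H, s_h),
         bn = numeric(H))
}

.init_titv_params <- function(F_, config) {
    H <- config$hidden_size; H1 <- config$film_hidden; A <- config$attn_size
    f_in <- F_ * (1L + config$use_mask)
    # feature-wise modulation: a shared scalar two-layer map of each
    # feature's pooled mean, with per-feature gain and bias
    p <- list(W1 = .runif_mat(1, H1, 1), b1 = numeric(H1),
              Wg = .runif_mat(H1, 1, sqrt(6 / (H1 + 1))),
              Wd = .runif_mat(H1, 1, sqrt(6 / (H1 + 1))),
              sg = rep(0.5, F_), bg = rep(1, F_),
              sd = rep(0.5, F_), bd = numeric(F_))
    fw <- .init_gru_block(f_in, H); bw <- .init_gru_block(f_in, H)
    names(fw) <- paste0("f_", names(fw)); names(bw) <- paste0("b_", names(bw))
    sa <- sqrt(6 / (2 * H + A))
    c(p, fw, bw,
      list(Wa = .runif_mat(2 * H, A, sa), ba = numeric(A),
           va = .runif_mat(A, 1, sqrt(6 / (A + 1))),
           Wb = .runif_mat(2 * H, F_, sqrt(6 / (2 * H + F_))),
           sb = rep(1, F_), bb = numeric(F_),
           w = rep(1, F_), b0 = 0))
}

.init_baseline_params <- function(kind, T_, F_, config) {
    H <- config$hidden_size
    f_in <- F_ * (1L + config$use_mask)
    switch(kind,
        logistic = list(w = .runif_mat(T_ * F_, 1, 0.01), b0 = 0),
        gru = {
            fw <- .init_gru_block(f_in, H); names(fw) <- paste0("f_", names(fw))
            c(fw, list(w_out = .runif_mat(H, 1, sqrt(6 / (H + 1))), b0 = 0))
        },
        bgru = {
            fw <- .init_gru_block(f_in, H); names(fw) <- paste0("f_", names(fw))
            bw <- .init_gru_block(f_in, H); names(bw) <- paste0("b_", names(bw))
            c(fw, bw,
              list(w_out = .runif_mat(2 * H, 1, sqrt(6 / (2 * H + 1))),
                   b0 = 0))
        },
        .stopf("unknown baseline kind '%s'", kind))
}

# ---- plain (prediction-time) forward pass --------------------------------

.sigm <- function(z) 1 / (1 + exp(-z))

.gru_step_plain <- function(p, pre, x, h) {
    z <- .sigm(sweep(x %*% p[[paste0(pre, "Wz")]] +
                     h %*% p[[paste0(pre, "Uz")]], 2,
                     p[[paste0(pre, "bz")]], "+"))
    r <- .sigm(sweep(x %*% p[[paste0(pre, "Wr")]] +
                     h %*% p[[paste0(pre, "Ur")]], 2,
                     p[[paste0(pre, "br")]], "+"))
    cc <- tanh(sweep(x %*% p[[paste0(pre, "Wn")]] +
                     (r * h) %*% p[[paste0(pre, "Un")]], 2,
                     p[[paste0(pre, "bn")]], "+"))
    (1 - z) * cc + z * h
}

# X3, M3: n x T x F arrays.  Returns all interpretation outputs.
.titv_forward_plain <- function(params, X3, M3, use_mask = FALSE) {
    n <- dim(X3)[1]; T_ <- dim(X3)[2]; F_ <- dim(X3)[3]
    H <- ncol(params$f_Uz)
    Xl <- lapply(seq_len(T_), function(t) matrix(X3[, t, ], n, F_))
    Ml <- lapply(seq_len(T_), function(t) matrix(M3[, t, ], n, F_))

    Msum <- Reduce(`+`, Ml)
    u <- Reduce(`+`, Map(`*`, Ml, Xl)) / pmax(1, Msum)
    uv <- matrix(u, n * F_, 1)
    hm <- tanh(sweep(uv %*% params$W1, 2, params$b1, "+"))
    gamma <- sweep(matrix(hm %*% params$Wg, n, F_), 2, params$sg, "*")
    gamma <- sweep(gamma, 2, params$bg, "+")
    delta <- sweep(matrix(hm %*% params$Wd, n, F_), 2, params$sd, "*")
    delta <- sweep(delta, 2, params$bd, "+")
    Xt <- lapply(Xl, function(x) gamma * x + delta)
    beta <- abs(gamma) / rowSums(abs(gamma))

    inp <- if (use_mask) Map(cbind, Xt, Ml) else Xt
    hfw <- matrix(0, n, H); hbw <- matrix(0, n, H)
    Hfw <- vector("list", T_); Hbw <- vector("list", T_)
    for (t in seq_len(T_)) {
        hfw <- .gru_step_plain(params, "f_", inp[[t]], hfw)
        Hfw[[t]] <- hfw
    }
    for (t in rev(seq_len(T_))) {
        hbw <- .gru_step_plain(params, "b_", inp[[t]], hbw)
        Hbw[[t]] <- hbw
    }
    Ht <- Map(cbind, Hfw, Hbw)

    E <- vapply(Ht, function(h)
        as.vector(tanh(sweep(h %*% params$Wa, 2, params$ba, "+")) %*%
                  params$va), numeric(n))
    E <- matrix(E, n, T_)
    a <- exp(E - apply(E, 1, max)); a <- a / rowSums(a)

    alpha <- array(0, c(n, T_, F_))
    contrib <- array(0, c(n, T_, F_))
    for (t in seq_len(T_)) {
        Bt <- sweep(Ht[[t]] %*% params$Wb +
                    sweep(Xt[[t]], 2, params$sb, "*"), 2, params$bb, "+")
        Bt <- exp(Bt - apply(Bt, 1, max)); Bt <- Bt / rowSums(Bt)
        al <- Bt * a[, t]
        alpha[, t, ] <- al
        contrib[, t, ] <- sweep(al * Xt[[t]] * beta, 2, params$w, "*")
    }
    logit <- apply(contrib, 1, sum) + params$b0
    list(risk = .sigm(logit), logit = logit, beta = beta, alpha = alpha,
         contributions = contrib, logit_bias = params$b0,
         window_attention = a)
}

.baseline_forward_plain <- function(kind, params, X3, M3, use_mask = FALSE) {
    n <- dim(X3)[1]; T_ <- dim(X3)[2]; F_ <- dim(X3)[3]
    if (kind == "logistic") {
        flat <- matrix(X3, n, T_ * F_)
        logit <- as.vector(flat %*% params$w) + params$b0
        return(list(risk = .sigm(logit), logit = logit))
    }
    Xl <- lapply(seq_len(T_), function(t) matrix(X3[, t, ], n, F_))
    Ml <- lapply(seq_len(T_), function(t) matrix(M3[, t, ], n, F_))
    inp <- if (use_mask) Map(cbind, Xl, Ml) else Xl
    H <- ncol(params$f_Uz)
    h <- matrix(0, n, H)
    for (t in seq_len(T_)) h <- .gru_step_plain(params, "f_", inp[[t]], h)
    last <- h
    if (kind == "bgru") {
        hb <- matrix(0, n, H)
        for (t in rev(seq_len(T_)))
            hb <- .gru_step_plain(params, "b_", inp[[t]], hb)
        last <- cbind(h, hb)
    }
    logit <- as.vector(last %*% params$w_out) + params$b0
    list(risk = .sigm(logit), logit = logit)
}

#' TITV forward pass for one sample
#'
#' Runs the fitted (or any) TITV parameter set on a single T x F sample
#' and returns the risk together with every interpretation output.
#'
#' The three modules are: (1) the time-invariant module pools each
#' feature's masked mean over the feature window and maps it through a
#' two-layer network to a per-feature scale \code{gamma} and shift
#' \code{delta}; the input is feature-wise linearly modulated,
#' \code{Xmod_t = gamma * X_t + delta}, and the time-invariant importance
#' is \code{beta = |gamma| / sum|gamma|}.  (2) The time-variant module
#' runs a bidirectional GRU over the modulated windows; window attention
#' \code{a_t = softmax_t(v' tanh(Wa h_t))} and within-window feature
#' weights \code{b_tf = softmax_f(Wb h_t + sb * Xmod_t)} (a recurrent key
#' plus a direct salience term on the modulated value itself) factorize
#' into the time-variant importance \code{alpha_tf = a_t * b_tf}.  (3) The prediction head
#' aggregates both importances bilinearly:
#' \code{logit = sum_tf w_f * beta_f * alpha_tf * Xmod_tf + bias}, so the
#' per-cell contributions are exact additive attributions of the logit.
#'
#' @param model a fitted \code{\linkS4class{TitvModel}} of kind "titv", or
#'   a raw parameter list.
#' @param X T x F matrix of normalized, zero-imputed values.
#' @param M T x F observation mask (defaults to all-observed).
#' @return list with \code{risk}, \code{logit}, \code{beta} (length F,
#'   sums to 1), \code{alpha} (T x F, sums to 1), \code{contributions}
#'   (T x F, summing with \code{logit_bias} to the logit),
#'   \code{logit_bias} and \code{window_attention} (length T).
#' @export
titvForward <- function(model, X, M = NULL) {
    params <- if (is(model, "TitvModel")) modelParams(model) else model
    use_mask <- if (is(model, "TitvModel"))
        isTRUE(modelConfig(model)$use_mask) else FALSE
    X <- as.matrix(X)
    if (is.null(M)) M <- matrix(1, nrow(X), ncol(X))
    if (any(!is.finite(unlist(params, use.names = FALSE))))
        .stopf("model parameters contain non-finite values")
    F_ <- length(params$sg)
    if (ncol(X) != F_)
        .stopf("sample has %d features but the model expects %d",
               ncol(X), F_)
    X3 <- array(0, c(1, nrow(X), ncol(X))); X3[1, , ] <- X
    M3 <- array(0, c(1, nrow(X), ncol(X))); M3[1, , ] <- as.matrix(M)
    out <- .titv_forward_plain(params, X3, M3, use_mask)
    list(risk = out$risk[1], logit = out$logit[1],
         beta = as.vector(out$beta[1, ]),
         alpha = matrix(out$alpha[1, , ], nrow(X)),
         contributions = matrix(out$contributions[1, , ], nrow(X)),
         logit_bias = out$logit_bias,
         window_attention = as.vector(out$window_attention[1, ]))
}

# ---- tape (training-time) forward passes ---------------------------------

# builds the TITV logit node on a tape; pn = list of parameter nodes,
# Xl/Ml = lists of constant n x F matrices, drop = optional list of
# pre-drawn dropout mask matrices (already inverted-scaled)
.titv_forward_tape <- function(tape, pn, Xl, Ml, use_mask, drop = NULL) {
    T_ <- length(Xl); n <- nrow(Xl[[1]])
    F_ <- ncol(Xl[[1]])
    Msum <- Reduce(`+`, Ml)
    u <- Reduce(`+`, Map(`*`, Ml, Xl)) / pmax(1, Msum)
    uv <- .ad_const(tape, matrix(u, n * F_, 1))
    hf <- .ad_tanh(tape, .ad_addbias(tape, .ad_matmul(tape, uv, pn$W1),
                                     pn$b1))
    if (!is.null(drop))
        hf <- .ad_mul(tape, hf, .ad_const(tape, drop$film))
    gamma <- .ad_addbias(tape, .ad_scale_cols(tape,
        .ad_reshape(tape, .ad_matmul(tape, hf, pn$Wg), n, F_), pn$sg),
        pn$bg)
    delta <- .ad_addbias(tape, .ad_scale_cols(tape,
        .ad_reshape(tape, .ad_matmul(tape, hf, pn$Wd), n, F_), pn$sd),
        pn$bd)
    ag <- .ad_abs(tape, gamma)
    beta <- .ad_div_rows(tape, ag, .ad_rowsums(tape, ag))

    Xt <- lapply(Xl, function(x)
        .ad_add(tape, .ad_mul(tape, gamma, .ad_const(tape, x)), delta))
    inp <- if (use_mask)
        Map(function(xt, m) .ad_concat_cols(tape, xt, .ad_const(tape, m)),
            Xt, Ml) else Xt

    H <- ncol(pn$f_Uz$value)
    gru_dir <- function(pre, order) {
        h <- .ad_const(tape, matrix(0, n, H))
        out <- vector("list", T_)
        for (t in order) {
            h <- .gru_step_tape(tape, pn, pre, inp[[t]], h)
            out[[t]] <- h
        }
        out
    }
    Hfw <- gru_dir("f_", seq_len(T_))
    Hbw <- gru_dir("b_", rev(seq_len(T_)))
    Ht <- Map(function(a, b) .ad_concat_cols(tape, a, b), Hfw, Hbw)
    if (!is.null(drop))
        Ht <- Map(function(h, m) .ad_mul(tape, h, .ad_const(tape, m)),
                  Ht, drop$hidden)

    Et <- lapply(Ht, function(h)
        .ad_matmul(tape, .ad_tanh(tape,
            .ad_addbias(tape, .ad_matmul(tape, h, pn$Wa), pn$ba)), pn$va))
    E <- Reduce(function(a, b) .ad_concat_cols(tape, a, b), Et)
    a_att <- .ad_softmax_rows(tape, E)

    total <- NULL
    for (t in seq_len(T_)) {
        Bt <- .ad_softmax_rows(tape, .ad_addbias(tape,
            .ad_add(tape, .ad_matmul(tape, Ht[[t]], pn$Wb),
                    .ad_scale_cols(tape, Xt[[t]], pn$sb)), pn$bb))
        al <- .ad_scale_rows(tape, Bt, .ad_getcol(tape, a_att, t))
        ct <- .ad_scale_cols(tape,
            .ad_mul(tape, .ad_mul(tape, al, Xt[[t]]), beta), pn$w)
        rs <- .ad_rowsums(tape, ct)
        total <- if (is.null(total)) rs else .ad_add(tape, total, rs)
    }
    list(logit = .ad_addscalar(tape, total, pn$b0), delta = delta,
         beta = beta)
}

.gru_step_tape <- function(tape, pn, pre, x, h) {
    g <- function(nm) pn[[paste0(pre, nm)]]
    lin <- function(W, U, b)
        .ad_addbias(tape, .ad_add(tape, .ad_matmul(tape, x, W),
                                  .ad_matmul(tape, h, U)), b)
    z <- .ad_sigmoid(tape, lin(g("Wz"), g("Uz"), g("bz")))
    r <- .ad_sigmoid(tape, lin(g("Wr"), g("Ur"), g("br")))
    cc <- .ad_tanh(tape, .ad_addbias(tape, .ad_add(tape,
        .ad_matmul(tape, x, g("Wn")),
        .ad_matmul(tape, .ad_mul(tape, r, h), g("Un"))), g("bn")))
    .ad_add(tape, .ad_mul(tape, .ad_oneminus(tape, z), cc),
            .ad_mul(tape, z, h))
}

.baseline_forward_tape <- function(kind, tape, pn, Xl, Ml, use_mask,
                                   drop = NULL) {
    T_ <- length(Xl); n <- nrow(Xl[[1]])
    if (kind == "logistic") {
        # column order must match .baseline_forward_plain's matrix(X3, ...)
        flat <- matrix(unlist(lapply(seq_len(ncol(Xl[[1]])), function(f)
            vapply(seq_len(T_), function(t) Xl[[t]][, f],
                   numeric(n)))), n)
        fl <- .ad_const(tape, flat)
        return(.ad_addscalar(tape, .ad_matmul(tape, fl, pn$w), pn$b0))
    }
    inp <- lapply(seq_len(T_), function(t) {
        x <- if (use_mask) cbind(Xl[[t]], Ml[[t]]) else Xl[[t]]
        .ad_const(tape, x)
    })
    H <- ncol(pn$f_Uz$value)
    h <- .ad_const(tape, matrix(0, n, H))
    for (t in seq_len(T_)) h <- .gru_step_tape(tape, pn, "f_", inp[[t]], h)
    last <- h
    if (kind == "bgru") {
        hb <- .ad_const(tape, matrix(0, n, H))
        for (t in rev(seq_len(T_)))
            hb <- .gru_step_tape(tape, pn, "b_", inp[[t]], hb)
        last <- .ad_concat_cols(tape, h, hb)
    }
    if (!is.null(drop))
        last <- .ad_mul(tape, last, .ad_const(tape, drop$hidden[[1]]))
    .ad_addscalar(tape, .ad_matmul(tape, last, pn$w_out), pn$b0)
}
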