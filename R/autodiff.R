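# Minimal reverse-mode automatic differentiation over dense matrices.
# Internal machinery for fitting the recurrent risk models; the operation
# set is exactly what the TITV forward pass and the GRU baselines need.
# Gradient correctness is pinned down by finite-difference tests.
#
# A tape is an environment accumulating nodes in creation order; each node
# is an environment with $value, $grad (accumulated lazily), $backfn.

.ad_tape <- function() {
    tape <- new.env(parent = emptyenv())
    tape$nodes <- vector("list", 256L)
    tape$n <- 0L
    tape
}

.ad_node <- function(tape, value, backfn = NULL) {
    node <- new.env(parent = emptyenv())
    node$value <- value
    node$grad <- NULL
    node$backfn <- backfn
    if (tape$n == length(tape$nodes))
        tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- node
    node
}

.ad_const <- function(tape, value) .ad_node(tape, value)

.ad_acc <- function(node, g) {
    node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# run backward from a scalar loss node
.ad_backward <- function(tape, loss) {
    loss$grad <- 1
    for (i in rev(seq_len(tape$n))) {
        nd <- tape$nodes[[i]]
        if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
    }
}

.ad_matmul <- function(tape, a, b) {
    .ad_node(tape, a$value %*% b$value, function(g) {
        .ad_acc(a, g %*% t(b$value))
        .ad_acc(b, t(a$value) %*% g)
    })
}

.ad_add <- function(tape, a, b) {
    .ad_node(tape, a$value + b$value, function(g) {
        .ad_acc(a, g); .ad_acc(b, g)
    })
}

# mat (n x k) + bias (length k), broadcast over rows
.ad_addbias <- function(tape, a, bias) {
    .ad_node(tape, sweep(a$value, 2L, bias$value, "+"), function(g) {
        .ad_acc(a, g); .ad_acc(bias, colSums(g))
    })
}

.ad_mul <- function(tape, a, b) {
    .ad_node(tape, a$value * b$value, function(g) {
        .ad_acc(a, g * b$value); .ad_acc(b, g * a$value)
    })
}

.ad_oneminus <- function(tape, a) {
    .ad_node(tape, 1 - a$value, function(g) .ad_acc(a, -g))
}

.ad_sigmoid <- function(tape, a) {
    s <- 1 / (1 + exp(-a$value))
    .ad_node(tape, s, function(g) .ad_acc(a, g * s * (1 - s)))
}

.ad_tanh <- function(tape, a) {
    th <- tanh(a$value)
    .ad_node(tape, th, function(g) .ad_acc(a, g * (1 - th^2)))
}

.ad_abs <- function(tape, a) {
    sg <- sign(a$value)
    .ad_node(tape, abs(a$value), function(g) .ad_acc(a, g * sg))
}

# row-wise softmax of an n x k matrix
.ad_softmax_rows <- function(tape, a) {
    z <- a$value - apply(a$value, 1L, max)
    e <- exp(z)
    p <- e / rowSums(e)
    .ad_node(tape, p, function(g) {
        .ad_acc(a, p * (g - rowSums(g * p)))
    })
}

# multiply each row i of mat (n x k) by col[i] (n x 1)
.ad_scale_rows <- function(tape, a, col) {
    cv <- as.vector(col$value)
    .ad_node(tape, a$value * cv, function(g) {
        .ad_acc(a, g * cv)
        .ad_acc(col, matrix(rowSums(g * a$value), ncol = 1L))
    })
}

# divide each row i of mat by col[i]
.ad_div_rows <- function(tape, a, col) {
    cv <- as.vector(col$value)
    .ad_node(tape, a$value / cv, function(g) {
        .ad_acc(a, g / cv)
        .ad_acc(col, matrix(-rowSums(g * a$value) / cv^2, ncol = 1L))
    })
}

# multiply each column f of mat (n x k) by w[f] (length k)
.ad_scale_cols <- function(tape, a, w) {
    wv <- as.vector(w$value)
    .ad_node(tape, sweep(a$value, 2L, wv, "*"), function(g) {
        .ad_acc(a, sweep(g, 2L, wv, "*"))
        .ad_acc(w, colSums(g * a$value))
    })
}

.ad_rowsums <- function(tape, a) {
    k <- ncol(a$value)
    .ad_node(tape, matrix(rowSums(a$value), ncol = 1L), function(g) {
        .ad_acc(a, matrix(as.vector(g), nrow(a$value), k))
    })
}

.ad_concat_cols <- function(tape, a, b) {
    ka <- ncol(a$value)
    .ad_node(tape, cbind(a$value, b$value), function(g) {
        .ad_acc(a, g[, seq_len(ka), drop = FALSE])
        .ad_acc(b, g[, -seq_len(ka), drop = FALSE])
    })
}

.ad_getcol <- function(tape, a, j) {
    .ad_node(tape, a$value[, j, drop = FALSE], function(g) {
        gm <- matrix(0, nrow(a$value), ncol(a$value))
        gm[, j] <- g
        .ad_acc(a, gm)
    })
}

# add a scalar bias node to an n x 1 column
.ad_addscalar <- function(tape, a, s) {
    .ad_node(tape, a$value + s$value, function(g) {
        .ad_acc(a, g); .ad_acc(s, sum(g))
    })
}

# mean of per-sample weighted binary cross-entropy from logits (stable)
.ad_bce_logits <- function(tape, logits, y, w) {
    z <- as.vector(logits$value)
    sp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))  # softplus
    loss <- sum(w * (sp - y * z)) / sum(w)
    .ad_node(tape, loss, function(g) {
        p <- 1 / (1 + exp(-z))
        .ad_acc(logits, matrix(g * w * (p - y) / sum(w), ncol = 1L))
    })
}

# reshape (gradient reshapes back)
.ad_reshape <- function(tape, a, nr, nc) {
    .ad_node(tape, matrix(a$value, nr, nc), function(g)
        .ad_acc(a, matrix(g, nrow(a$value), ncol(a$value))))
}

# mean over rows of the Shannon entropy of a row-stochastic matrix
.ad_row_entropy <- function(tape, p) {
    n <- nrow(p$value)
    v <- pmax(p$value, 1e-12)
    .ad_node(tape, -sum(v * log(v)) / n, function(g)
        .ad_acc(p, g * (-(log(v) + 1)) / n))
}

# mean of squared entries (regularization penalty)
.ad_meansq <- function(tape, a) {
    n <- length(a$value)
    .ad_node(tape, sum(a$value^2) / n, function(g)
        .ad_acc(a, g * 2 * a$value / n))
}

# weighted sum of scalar nodes: value = a + k * b
.ad_scalar_axpy <- function(tape, a, b, k) {
    .ad_node(tape, a$value + k * b$value, function(g) {
        .ad_acc(a, g); .ad_acc(b, k * g)
    })
}

# ---- Adam optimizer over a named list of parameter arrays ----------------

.adam_state <- function(params) {
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
    state$t <- state$t + 1L
    for (nm in names(params)) {
        g <- grads[[nm]]
        if (is.null(g)) next
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
        mhat <- state$m[[nm]] / (1 - beta1^state$t)
        vhat <- state$v[[nm]] / (1 - beta2^state$t)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(params = params, state = state)
}
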