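rand_sample <- function(T_ = 4, F_ = 5, n = 1, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    X3 <- array(runif(n * T_ * F_), c(n, T_, F_))
    M3 <- array(rbinom(n * T_ * F_, 1, 0.7), c(n, T_, F_))
    X3[M3 == 0] <- 0
    list(X3 = X3, M3 = M3)
}

toy_separable <- function(n = 240, T_ = 3, F_ = 4, seed = 21) {
    set.seed(seed)
    y <- rep(c(1L, 0L), length.out = n)
    X3 <- array(runif(n * T_ * F_, 0, 0.3), c(n, T_, F_))
    X3[y == 1, , 1] <- runif(sum(y == 1) * T_, 0.7, 1)
    M3 <- array(1, c(n, T_, F_))
    list(X3 = X3, M3 = M3, y = y)
}

test_that("forward-pass importance outputs are normalized attributions", {
    set.seed(101)
    cfg <- titvConfig(hidden_size = 6, film_hidden = 5, attn_size = 3)
    for (r in 1:20) {
        params <- akitv:::.init_titv_params(5L, cfg)
        s <- rand_sample(4, 5)
        out <- titvForward(params, matrix(s$X3[1, , ], 4),
                           matrix(s$M3[1, , ], 4))
        expect_equal(sum(out$beta), 1, tolerance = 1e-6)
        expect_true(all(out$beta >= 0))
        expect_equal(sum(out$alpha), 1, tolerance = 1e-6)
        expect_true(all(out$alpha >= 0))
        expect_equal(sum(out$window_attention), 1, tolerance = 1e-6)
        expect_equal(sum(out$contributions) + out$logit_bias, out$logit,
                     tolerance = 1e-5)
        expect_equal(out$risk, 1 / (1 + exp(-out$logit)))
    }
})

test_that("attribution identity holds on batches of random inputs", {
    set.seed(55)
    cfg <- titvConfig(hidden_size = 8, film_hidden = 6, attn_size = 4)
    params <- akitv:::.init_titv_params(7L, cfg)
    s <- rand_sample(5, 7, n = 100)
    out <- akitv:::.titv_forward_plain(params, s$X3, s$M3)
    resid <- apply(out$contributions, 1, sum) + out$logit_bias - out$logit
    expect_lt(max(abs(resid)), 1e-5)
    a_sum <- apply(out$alpha, 1, sum)
    expect_lt(max(abs(a_sum - 1)), 1e-6)
    expect_lt(max(abs(rowSums(out$beta) - 1)), 1e-6)
})

test_that("all-zero input with zero shift reduces to the bias risk", {
    set.seed(7)
    cfg <- titvConfig(hidden_size = 4, film_hidden = 3, attn_size = 2)
    params <- akitv:::.init_titv_params(4L, cfg)
    params$sd[] <- 0; params$bd[] <- 0      # delta == 0
    params$b0 <- 0.7
    out <- titvForward(params, matrix(0, 3, 4), matrix(0, 3, 4))
    expect_equal(max(abs(out$contributions)), 0)
    expect_equal(out$risk, 1 / (1 + exp(-0.7)))
})

test_that("risk is invariant under joint feature permutation", {
    set.seed(17)
    cfg <- titvConfig(hidden_size = 5, film_hidden = 4, attn_size = 3)
    F_ <- 6
    params <- akitv:::.init_titv_params(F_, cfg)
    s <- rand_sample(4, F_)
    X <- matrix(s$X3[1, , ], 4); M <- matrix(s$M3[1, , ], 4)
    perm <- sample(F_)
    p2 <- params
    for (nm in c("sg", "bg", "sd", "bd", "sb", "bb", "w"))
        p2[[nm]] <- params[[nm]][perm]
    for (nm in c("f_Wz", "f_Wr", "f_Wn", "b_Wz", "b_Wr", "b_Wn"))
        p2[[nm]] <- params[[nm]][perm, , drop = FALSE]
    p2$Wb <- params$Wb[, perm, drop = FALSE]
    o1 <- titvForward(params, X, M)
    o2 <- titvForward(p2, X[, perm], M[, perm])
    expect_equal(o2$risk, o1$risk, tolerance = 1e-12)
    expect_equal(o2$beta, o1$beta[perm], tolerance = 1e-12)
    expect_equal(o2$alpha, o1$alpha[, perm], tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences", {
    set.seed(42)
    cfg <- titvConfig(hidden_size = 4, film_hidden = 3, attn_size = 2)
    s <- rand_sample(2, 3, n = 5)
    y <- c(1, 0, 1, 0, 1); w <- rep(1, 5)
    for (kind in c("titv", "logistic", "gru", "bgru")) {
        params <- if (kind == "titv")
            akitv:::.init_titv_params(3L, cfg) else
            akitv:::.init_baseline_params(kind, 2L, 3L, cfg)
        lg <- akitv:::.loss_and_grads(kind, params, s$X3, s$M3, y, w,
                                      shift_decay = 0.5, head_decay = 0.01)
        eps <- 1e-6
        for (nm in names(params)) {
            for (i in seq_len(min(length(params[[nm]]), 4))) {
                p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
                p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
                fd <- (akitv:::.loss_and_grads(kind, p1, s$X3, s$M3, y, w,
                           shift_decay = 0.5, head_decay = 0.01)$loss -
                       akitv:::.loss_and_grads(kind, p2, s$X3, s$M3, y, w,
                           shift_decay = 0.5, head_decay = 0.01)$loss) /
                      (2 * eps)
                g <- if (is.null(lg$grads[[nm]])) 0 else lg$grads[[nm]][i]
                expect_lt(abs(fd - g), 1e-4)
            }
        }
    }
})

test_that("training separates a linearly separable toy problem", {
    toy <- toy_separable()
    tr <- list(X3 = toy$X3[1:160, , , drop = FALSE],
               M3 = toy$M3[1:160, , , drop = FALSE], y = toy$y[1:160])
    va <- list(X3 = toy$X3[161:240, , , drop = FALSE],
               M3 = toy$M3[161:240, , , drop = FALSE], y = toy$y[161:240])
    cfg <- titvConfig(hidden_size = 4, film_hidden = 4, attn_size = 2,
                      max_epochs = 50, early_stop_patience = 50,
                      attn_warmup = 5, batch_size = 64, seed = 2)
    m <- fitTitv(tr, va, cfg)
    expect_gte(aurocScore(predictRisk(m, tr), tr$y), 0.99)
    ml <- fitBaseline("logistic", tr, va, cfg)
    expect_gte(aurocScore(predictRisk(ml, tr), tr$y), 0.999)
})

test_that("fitting is deterministic given the seed", {
    toy <- toy_separable(n = 120)
    tr <- list(X3 = toy$X3[1:80, , , drop = FALSE],
               M3 = toy$M3[1:80, , , drop = FALSE], y = toy$y[1:80])
    va <- list(X3 = toy$X3[81:120, , , drop = FALSE],
               M3 = toy$M3[81:120, , , drop = FALSE], y = toy$y[81:120])
    cfg <- titvConfig(hidden_size = 3, film_hidden = 3, attn_size = 2,
                      max_epochs = 6, early_stop_patience = 6,
                      batch_size = 40, seed = 77)
    m1 <- fitTitv(tr, va, cfg); m2 <- fitTitv(tr, va, cfg)
    expect_identical(modelParams(m1), modelParams(m2))
    expect_identical(trainingHistory(m1), trainingHistory(m2))
    expect_error(fitTitv(list(X3 = tr$X3, M3 = tr$M3,
                              y = rep(1L, 80)), va, cfg), "both classes")
})

test_that("bidirectional baseline has more parameters than one-directional", {
    cfg <- titvConfig(hidden_size = 5)
    pg <- akitv:::.init_baseline_params("gru", 3L, 4L, cfg)
    pb <- akitv:::.init_baseline_params("bgru", 3L, 4L, cfg)
    expect_gt(sum(vapply(pb, length, 0L)), sum(vapply(pg, length, 0L)))
})

test_that("logistic baseline agrees with a glm cross-check", {
    toy <- toy_separable(n = 300, seed = 9)
    # soften the problem so neither fit is degenerate
    set.seed(10)
    toy$X3[, , 1] <- pmin(1, pmax(0, toy$X3[, , 1] +
                                  rnorm(length(toy$X3[, , 1]), 0, 0.35)))
    idx <- 1:200
    tr <- list(X3 = toy$X3[idx, , , drop = FALSE],
               M3 = toy$M3[idx, , , drop = FALSE], y = toy$y[idx])
    te <- list(X3 = toy$X3[-idx, , , drop = FALSE],
               M3 = toy$M3[-idx, , , drop = FALSE], y = toy$y[-idx])
    cfg <- titvConfig(max_epochs = 80, early_stop_patience = 80,
                      learning_rate = 0.05, batch_size = 64, seed = 3,
                      positive_class_weight = 1)
    ml <- fitBaseline("logistic", tr, te, cfg)
    auc_pkg <- aurocScore(predictRisk(ml, te), te$y)
    flat_tr <- matrix(tr$X3, nrow(tr$X3))
    flat_te <- matrix(te$X3, nrow(te$X3))
    g <- suppressWarnings(glm.fit(cbind(1, flat_tr), tr$y,
                                  family = binomial()))
    pred <- 1 / (1 + exp(-(cbind(1, flat_te) %*% g$coefficients)))
    auc_glm <- aurocScore(as.vector(pred), te$y)
    expect_lt(abs(auc_pkg - auc_glm), 0.05)
})

test_that("explanations rank cells and cap top_k", {
    tc <- tiny_cohort()
    fs <- tc$fs
    cfg <- titvConfig(hidden_size = 4, film_hidden = 4, attn_size = 2,
                      max_epochs = 3, early_stop_patience = 3, seed = 5)
    m <- fitTitv(splitSubset(fs, "train"), splitSubset(fs, "valid"), cfg)
    id <- colnames(fs)[1]
    ex <- titvExplain(m, fs, id, top_k = 10)
    expect_equal(nrow(ex), 10L)
    expect_true(all(diff(ex$importance) <= 1e-12))
    spec <- S4Vectors::metadata(fs)$windowSpec
    full <- titvExplain(m, fs, id, top_k = 1e6)
    expect_equal(nrow(full), spec$T * nrow(modelVocabulary(m)))
    expect_equal(sum(full$importance), 1, tolerance = 1e-6)
    # untrained/random model still yields valid normalization
    p0 <- akitv:::.init_titv_params(nrow(modelVocabulary(m)), cfg)
    o <- titvForward(p0, featureMatrix(fs, id), featureMatrix(fs, id, "M"))
    expect_equal(sum(o$alpha), 1, tolerance = 1e-6)
})

test_that("model checkpoints round-trip through JSON", {
    toy <- toy_separable(n = 120)
    tr <- list(X3 = toy$X3[1:80, , , drop = FALSE],
               M3 = toy$M3[1:80, , , drop = FALSE], y = toy$y[1:80])
    va <- list(X3 = toy$X3[81:120, , , drop = FALSE],
               M3 = toy$M3[81:120, , , drop = FALSE], y = toy$y[81:120])
    cfg <- titvConfig(hidden_size = 3, film_hidden = 3, attn_size = 2,
                      max_epochs = 2, early_stop_patience = 2, seed = 1)
    m <- fitTitv(tr, va, cfg)
    f <- withr::local_tempfile(fileext = ".json")
    writeModelJSON(m, f)
    m2 <- readModelJSON(f)
    expect_equal(modelParams(m2), modelParams(m), tolerance = 1e-12)
    expect_equal(predictRisk(m2, va), predictRisk(m, va),
                 tolerance = 1e-12)
})
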