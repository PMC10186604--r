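# Internal engine of the ratio network: parameter initialization, forward and
# backward passes (ratio layer, batch normalization, dropout), and Adam.
# All math is vectorized base R; matrices are samples x units.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

.ratioPairs <- function(n) {
    cmb <- utils::combn(n, 2L)
    list(I = cmb[1L, ], J = cmb[2L, ])
}

# Stabilized denominator: sign(d) * max(|d|, eps); zeros treated as +eps.
.stabilize <- function(d, eps) {
    if (eps <= 0) return(d)
    small <- abs(d) < eps
    if (!any(small)) return(d)
    d[small] <- eps * ((d[small] >= 0) * 2 - 1)
    d
}

.ratioForward <- function(Z, I, J, eps) {
    A <- Z[, I, drop = FALSE]
    D <- Z[, J, drop = FALSE]
    S <- .stabilize(D, eps)
    list(R = A / S, A = A, D = D, S = S)
}

.ratioBackward <- function(G, cache, Pi, Pj, eps) {
    dA <- G / cache$S
    dD <- -G * cache$A / cache$S^2
    if (eps > 0)
        dD[abs(cache$D) < eps] <- 0   # clamped region: flat in the denominator
    dA %*% Pi + dD %*% Pj
}

.bnForwardTrain <- function(Z, g, be, stats) {
    n <- nrow(Z)
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
    v[v < 0] <- 0
    sdv <- sqrt(v + .BN_EPS)
    Zc <- Z - rep(mu, each = n)
    Xhat <- Zc / rep(sdv, each = n)
    Y <- Xhat * rep(g, each = n) + rep(be, each = n)
    stats$mean <- (1 - .BN_MOMENTUM) * stats$mean + .BN_MOMENTUM * mu
    stats$var <- (1 - .BN_MOMENTUM) * stats$var + .BN_MOMENTUM * v
    list(Y = Y, cache = list(Xhat = Xhat, Zc = Zc, sdv = sdv, g = g),
         stats = stats)
}

# Eval-mode BN folds into one affine map y = a*z + c per unit; recycling via
# rep(..., each = n) keeps it to two temporaries.
.bnForwardEval <- function(Z, g, be, stats) {
    a <- g / sqrt(stats$var + .BN_EPS)
    cc <- be - stats$mean * a
    n <- nrow(Z)
    Z * rep(a, each = n) + rep(cc, each = n)
}

.bnBackward <- function(dY, cache) {
    n <- nrow(dY)
    dg <- colSums(dY * cache$Xhat)
    dbe <- colSums(dY)
    dXhat <- dY * rep(cache$g, each = n)
    dvar <- colSums(dXhat * cache$Zc) * (-0.5) / cache$sdv^3
    dmu <- -colSums(dXhat) / cache$sdv
    dZ <- dXhat / rep(cache$sdv, each = n) +
        cache$Zc * rep(2 * dvar / n, each = n) +
        rep(dmu / n, each = n)
    list(dZ = dZ, dg = dg, dbe = dbe)
}

.dropoutMask <- function(dim1, dim2, p) {
    if (p <= 0) return(NULL)
    matrix((runif(dim1 * dim2) >= p) / (1 - p), dim1, dim2)
}

.initRatioParams <- function(config, n_features) {
    C <- config@n_compress
    R <- C * (C - 1L) / 2L
    H <- config@hidden_sizes
    glorot <- function(fin, fout)
        matrix(runif(fin * fout, -1, 1) * sqrt(6 / (fin + fout)), fin, fout)
    he <- function(fin, fout)
        matrix(rnorm(fin * fout, 0, sqrt(2 / fin)), fin, fout)
    p <- list(W1 = glorot(n_features, C))
    if (config@use_bias) p$b1 <- numeric(C)
    if (!config@ratio_layer) {
        p$Wr <- he(C, R)
        p$br <- numeric(R)
    }
    p$g0 <- rep(1, R); p$be0 <- numeric(R)
    prev <- R
    for (h in seq_along(H)) {
        p[[paste0("W_h", h)]] <- he(prev, H[h])
        p[[paste0("b_h", h)]] <- numeric(H[h])
        p[[paste0("g_h", h)]] <- rep(1, H[h])
        p[[paste0("be_h", h)]] <- numeric(H[h])
        prev <- H[h]
    }
    p$Wo <- glorot(prev, 1L)
    p$bo <- 0
    p
}

.initBnStats <- function(config) {
    C <- config@n_compress
    R <- C * (C - 1L) / 2L
    s <- list(bn0 = list(mean = numeric(R), var = rep(1, R)))
    for (h in seq_along(config@hidden_sizes)) {
        w <- config@hidden_sizes[h]
        s[[paste0("bn_h", h)]] <- list(mean = numeric(w), var = rep(1, w))
    }
    s
}

# Weight decay per parameter: compression, hidden layers, output; the ratio
# layer (and its dense stand-in) carries none, nor do offsets or BN params.
.decayMap <- function(config, params) {
    wd <- config@weight_decays
    H <- length(config@hidden_sizes)
    map <- setNames(rep(0, length(params)), names(params))
    map["W1"] <- wd[1L]
    for (h in seq_len(H)) map[paste0("W_h", h)] <- wd[1L + h]
    map["Wo"] <- wd[H + 2L]
    map
}

.rnForward <- function(params, arch, config, X, training, bnStats) {
    cache <- list()
    eps <- config@ratio_epsilon
    p <- config@dropout
    if (training && p > 0) {
        cache$mX <- .dropoutMask(nrow(X), ncol(X), p)
        X <- X * cache$mX
    }
    cache$X <- X
    Z1 <- X %*% params$W1
    if (!is.null(params$b1)) Z1 <- Z1 + rep(params$b1, each = nrow(Z1))
    cache$Z1 <- Z1
    if (arch$ratio) {
        rc <- .ratioForward(Z1, arch$I, arch$J, eps)
        A <- rc$R
        cache$ratio <- rc
    } else {
        A <- Z1 %*% params$Wr + rep(params$br, each = nrow(Z1))
    }
    cache$Araw <- A
    if (training) {
        bf <- .bnForwardTrain(A, params$g0, params$be0, bnStats$bn0)
        bnStats$bn0 <- bf$stats
        cache$bn0 <- bf$cache
        A <- bf$Y
    } else {
        A <- .bnForwardEval(A, params$g0, params$be0, bnStats$bn0)
    }
    cache$relu0 <- A > 0
    Hcur <- A * cache$relu0
    cache$H0 <- Hcur
    nH <- length(arch$hidden)
    for (h in seq_len(nH)) {
        Zk <- Hcur %*% params[[paste0("W_h", h)]] +
            rep(params[[paste0("b_h", h)]], each = nrow(Hcur))
        cache[[paste0("Zin_h", h)]] <- Hcur
        if (training) {
            bf <- .bnForwardTrain(Zk, params[[paste0("g_h", h)]],
                                  params[[paste0("be_h", h)]],
                                  bnStats[[paste0("bn_h", h)]])
            bnStats[[paste0("bn_h", h)]] <- bf$stats
            cache[[paste0("bn_h", h)]] <- bf$cache
            Zk <- bf$Y
        } else {
            Zk <- .bnForwardEval(Zk, params[[paste0("g_h", h)]],
                                 params[[paste0("be_h", h)]],
                                 bnStats[[paste0("bn_h", h)]])
        }
        cache[[paste0("relu_h", h)]] <- Zk > 0
        Hcur <- Zk * (Zk > 0)
        if (training && p > 0) {
            m <- .dropoutMask(nrow(Hcur), ncol(Hcur), p)
            cache[[paste0("mask_h", h)]] <- m
            Hcur <- Hcur * m
        }
        cache[[paste0("H_h", h)]] <- Hcur
    }
    yhat <- drop(Hcur %*% params$Wo + params$bo)
    list(yhat = yhat, cache = cache, bnStats = bnStats, lastH = Hcur)
}

.rnBackward <- function(params, arch, config, fw, dy) {
    cache <- fw$cache
    g <- list()
    nH <- length(arch$hidden)
    lastH <- if (nH > 0) cache[[paste0("H_h", nH)]] else cache$H0
    g$Wo <- crossprod(lastH, dy)
    g$bo <- sum(dy)
    dH <- dy %*% t(params$Wo)
    for (h in rev(seq_len(nH))) {
        m <- cache[[paste0("mask_h", h)]]
        if (!is.null(m)) dH <- dH * m
        dZ <- dH * cache[[paste0("relu_h", h)]]
        bb <- .bnBackward(dZ, cache[[paste0("bn_h", h)]])
        g[[paste0("g_h", h)]] <- bb$dg
        g[[paste0("be_h", h)]] <- bb$dbe
        Hin <- cache[[paste0("Zin_h", h)]]
        g[[paste0("W_h", h)]] <- crossprod(Hin, bb$dZ)
        g[[paste0("b_h", h)]] <- colSums(bb$dZ)
        dH <- bb$dZ %*% t(params[[paste0("W_h", h)]])
    }
    dA <- dH * cache$relu0
    bb <- .bnBackward(dA, cache$bn0)
    g$g0 <- bb$dg
    g$be0 <- bb$dbe
    if (arch$ratio) {
        dZ1 <- .ratioBackward(bb$dZ, cache$ratio, arch$Pi, arch$Pj,
                              config@ratio_epsilon)
    } else {
        g$Wr <- crossprod(cache$Z1, bb$dZ)
        g$br <- colSums(bb$dZ)
        dZ1 <- bb$dZ %*% t(params$Wr)
    }
    g$W1 <- crossprod(cache$X, dZ1)
    if (!is.null(params$b1)) g$b1 <- colSums(dZ1)
    g
}

.adamInit <- function(params) {
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    state$t <- state$t + 1L
    c1 <- 1 - beta1^state$t
    c2 <- 1 - beta2^state$t
    for (nm in names(grads)) {
        gr <- grads[[nm]]
        if (decay[nm] > 0) gr <- gr + decay[nm] * params[[nm]]
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
        params[[nm]] <- params[[nm]] -
            lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    }
    list(params = params, state = state)
}

.evalMse <- function(params, arch, config, bnStats, X, y) {
    fw <- .rnForward(params, arch, config, X, training = FALSE, bnStats)
    mean((fw$yhat - y)^2)
}

# Fast evaluation path: activations kept units x samples so per-unit affine
# maps recycle natively; batch normalization is folded into one scale/shift
# per unit. Produces the same predictions as the training-mode graph in
# evaluation mode, at a fraction of the memory traffic.
.foldEval <- function(params, arch, config, bnStats) {
    fold <- function(g, be, stats, b = NULL) {
        a <- g / sqrt(stats$var + .BN_EPS)
        cc <- be - stats$mean * a
        if (!is.null(b)) cc <- cc + a * b   # absorb the linear offset
        list(a = a, c = cc)
    }
    pre <- list(W1 = params$W1, b1 = params$b1,
                bn0 = fold(params$g0, params$be0, bnStats$bn0))
    if (!arch$ratio) {
        pre$tWr <- t(params$Wr)
        pre$br <- params$br
    }
    for (h in seq_along(arch$hidden)) {
        pre[[paste0("tW_h", h)]] <- t(params[[paste0("W_h", h)]])
        pre[[paste0("bn_h", h)]] <- fold(params[[paste0("g_h", h)]],
                                         params[[paste0("be_h", h)]],
                                         bnStats[[paste0("bn_h", h)]],
                                         params[[paste0("b_h", h)]])
    }
    pre$wo <- drop(params$Wo)
    pre$bo <- params$bo
    pre
}

.rnEvalFast <- function(pre, arch, config, X) {
    Zt <- t(X %*% pre$W1)                     # compress: 12 x n
    if (!is.null(pre$b1)) Zt <- Zt + pre$b1
    if (arch$ratio) {
        A <- Zt[arch$I, , drop = FALSE] /
            .stabilize(Zt[arch$J, , drop = FALSE], config@ratio_epsilon)
    } else {
        A <- pre$tWr %*% Zt + pre$br
    }
    H <- A * pre$bn0$a + pre$bn0$c
    H[H < 0] <- 0
    for (h in seq_along(arch$hidden)) {
        bn <- pre[[paste0("bn_h", h)]]
        H <- pre[[paste0("tW_h", h)]] %*% H * bn$a + bn$c
        H[H < 0] <- 0
    }
    drop(crossprod(H, pre$wo)) + pre$bo
}
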