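# Independent brute-force oracles.  These deliberately share no code with
# the package implementation: explicit loops, closed forms, or refits.

bruteDegree <- function(w) {
    n <- nrow(w)
    d <- integer(n)
    for (i in seq_len(n))
        for (j in seq_len(n))
            if (j != i && w[i, j] > 0) d[i] <- d[i] + 1L
    names(d) <- rownames(w)
    d
}

bruteStrength <- function(w) {
    n <- nrow(w)
    s <- numeric(n)
    for (i in seq_len(n))
        for (j in seq_len(n))
            if (j != i) s[i] <- s[i] + w[i, j]
    names(s) <- rownames(w)
    s
}

# Onnela geometric-mean clustering on max-normalised weights, by explicit
# triple enumeration
bruteClustering <- function(w) {
    n <- nrow(w)
    cc <- numeric(n)
    names(cc) <- rownames(w)
    mx <- max(w)
    if (mx == 0) return(cc)
    wh <- w / mx
    for (i in seq_len(n)) {
        k <- sum(w[i, -i] > 0)
        if (k < 2) next
        acc <- 0
        others <- setdiff(seq_len(n), i)
        for (a in seq_along(others))
            for (b in seq_along(others))
                if (b > a) {
                    j <- others[a]; h <- others[b]
                    acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
                }
        cc[i] <- 2 * acc / (k * (k - 1))
    }
    cc
}

# partial correlation from the inverse of the sample correlation matrix
partialCorrInv <- function(x, y, covariates) {
    m <- cbind(x, y, covariates)
    pinv <- solve(cor(m))
    -pinv[1, 2] / sqrt(pinv[1, 1] * pinv[2, 2])
}

# Cook's distance by the leave-one-out refit definition:
# D_i = sum_j (yhat_j - yhat_j(-i))^2 / (p * s^2)
cooksLOO <- function(y, X) {
    X <- as.matrix(X)
    n <- nrow(X)
    p <- ncol(X)
    full <- stats::lm.fit(X, y)
    yhat <- X %*% full$coefficients
    s2 <- sum(full$residuals^2) / (n - p)
    vapply(seq_len(n), function(i) {
        fit <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])
        sum((yhat - X %*% fit$coefficients)^2) / (p * s2)
    }, numeric(1))
}

# hand step-up BH
bhHand <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- ps * m / seq_len(m)
    for (i in (m - 1):1)
        if (m > 1) q[i] <- min(q[i], q[i + 1])
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}
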