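# Brute-force oracle: a literal, loop-based transcription of the
# nearest-shrunken-centroid formulas, kept deliberately independent of the
# package implementation so the two can be compared to 1e-12.

oracleFitNSC <- function(X, y, delta) {
    classes <- c("HDACi", "non-HDACi")
    n <- ncol(X); K <- length(classes); G <- nrow(X)
    xbar <- numeric(G)
    for (i in seq_len(G)) xbar[i] <- mean(X[i, ])
    cent <- matrix(0, G, K)
    nk <- numeric(K)
    for (k in seq_len(K)) {
        idx <- which(y == classes[k])
        nk[k] <- length(idx)
        for (i in seq_len(G)) cent[i, k] <- mean(X[i, idx])
    }
    s <- numeric(G)
    for (i in seq_len(G)) {
        ss <- 0
        for (k in seq_len(K))
            for (j in which(y == classes[k]))
                ss <- ss + (X[i, j] - cent[i, k])^2
        s[i] <- sqrt(ss / (n - K))
    }
    s0 <- median(s)
    mk <- sqrt(1 / nk - 1 / n)
    d <- matrix(0, G, K); dshr <- d
    for (i in seq_len(G)) for (k in seq_len(K)) {
        d[i, k] <- (cent[i, k] - xbar[i]) / (mk[k] * (s[i] + s0))
        dshr[i, k] <- sign(d[i, k]) * max(abs(d[i, k]) - delta, 0)
    }
    list(classes = classes, xbar = xbar, cent = cent, s = s, s0 = s0,
         nk = nk, mk = mk, d = d, dshr = dshr)
}

oracleProbs <- function(fit, x, priors = c(0.5, 0.5)) {
    surv <- which(apply(fit$dshr, 1, function(r) any(r != 0)))
    disc <- numeric(2)
    for (k in 1:2) {
        dk <- -2 * log(priors[k])
        for (i in surv) {
            shrcent <- fit$xbar[i] +
                fit$mk[k] * (fit$s[i] + fit$s0) * fit$dshr[i, k]
            dk <- dk + (x[i] - shrcent)^2 / (fit$s[i] + fit$s0)^2
        }
        disc[k] <- dk
    }
    w <- exp(-(disc - min(disc)) / 2)
    w / sum(w)
}

# Literal two-term discriminant of a frozen panel applied to one profile.
oracleAssetProbs <- function(centroids, sds, priors, x) {
    disc <- numeric(2)
    for (k in 1:2) {
        dk <- -2 * log(priors[k])
        for (i in seq_along(sds))
            dk <- dk + (x[i] - centroids[i, k])^2 / sds[i]^2
        disc[k] <- dk
    }
    w <- exp(-(disc - min(disc)) / 2)
    w / sum(w)
}

# Quick labeled ProfileSet from a matrix.
makePS <- function(X, labels, compounds = colnames(X)) {
    if (is.null(colnames(X)))
        colnames(X) <- sprintf("cpd%02d", seq_len(ncol(X)))
    if (is.null(rownames(X)))
        rownames(X) <- sprintf("G%d", seq_len(nrow(X)))
    ProfileSet(X, compound = if (is.null(compounds)) colnames(X) else
               compounds, class_label = labels)
}

# Well-separated two-class profiles from the packaged panel structure.
makePanelSim <- function(seed, nRef = c(10, 10), nVal = c(0, 0), ...) {
    simulateProfiles(simConfig(seed = seed, nReference = nRef,
                               nValidation = nVal, ...))
}
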