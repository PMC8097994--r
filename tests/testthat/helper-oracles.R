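# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check.

oracleRevComp <- function(s) {
    if (nchar(s) == 0) return("")
    paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]),
          collapse = "")
}

# sliding-window seed-match scan over every width-7 window
oracleScan <- function(utrseq, seed) {
    m <- oracleRevComp(seed)
    L <- nchar(utrseq)
    rows <- list()
    i <- 1
    while (i + 6 <= L) {
        if (substr(utrseq, i, i + 6) == m) {
            t1 <- if (i + 7 <= L) substr(utrseq, i + 7, i + 7) else ""
            if (t1 == "A")
                rows[[length(rows) + 1]] <- data.frame(
                    start = i, end = i + 7, site_type = "8mer")
            else
                rows[[length(rows) + 1]] <- data.frame(
                    start = i, end = i + 6, site_type = "7mer-m8")
        }
        i <- i + 1
    }
    if (!length(rows))
        return(data.frame(start = integer(0), end = integer(0),
                          site_type = character(0)))
    do.call(rbind, rows)
}

# base-by-base projection of a spliced interval to genomic positions
oracleProject <- function(blockStarts, blockEnds, strand, s, e) {
    gpos <- unlist(lapply(seq_along(blockStarts), function(i)
        blockStarts[i]:blockEnds[i]))
    if (strand == "-") gpos <- rev(gpos)
    sort(gpos[s:e])
}

# exact two-sided Mann-Whitney p by full enumeration of assignments
oracleMWU <- function(xs, ys) {
    pool <- c(xs, ys)
    n1 <- length(xs); n2 <- length(ys)
    ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    u <- ustat(xs, ys)
    idx <- utils::combn(n1 + n2, n1)
    uall <- apply(idx, 2, function(ii) ustat(pool[ii], pool[-ii]))
    mu <- n1 * n2 / 2
    min(1, mean(abs(uall - mu) >= abs(u - mu) - 1e-9))
}

# step-up Benjamini-Hochberg by direct hand computation
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
        val <- min(prev, p[o[i]] * m / i)
        q[o[i]] <- val
        prev <- val
    }
    q
}

# upper-tail hypergeometric p by enumerating all draws of the hit set
oracleHyper <- function(universe, pathway, nhits, ov) {
    draws <- utils::combn(length(universe), nhits)
    inpw <- universe %in% pathway
    mean(apply(draws, 2, function(ii) sum(inpw[ii])) >= ov)
}

# log-density of y under N(mu, sigma2 * (lambda K + I))
oracleMVNlogL <- function(y, mu, sigma2, lambda, K) {
    n <- length(y)
    V <- sigma2 * (lambda * K + diag(n))
    as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(y - mu) %*% solve(V, y - mu)))
}

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")
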