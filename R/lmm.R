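#' Centered genomic kinship matrix
#'
#' K = Xc Xc' / p, where Xc is the dosage matrix with missing values
#' mean-imputed per SNP and each SNP column centered by its mean
#' (the centered relatedness construction commonly used for
#' mixed-model association).
#'
#' @param G Numeric matrix of dosages in \{0, 1, 2, NA\}, individuals
#'   in rows, SNPs in columns.
#' @return A symmetric n x n kinship matrix.
#' @examples
#' G <- matrix(c(0, 2), nrow = 2, ncol = 1)
#' centeredKinship(G) # [[1, -1], [-1, 1]]
#' @export
centeredKinship <- function(G) {
    stopifnot(is.matrix(G), nrow(G) >= 2L, ncol(G) >= 1L)
    allmiss <- colSums(!is.na(G)) == 0L
    if (any(allmiss)) {
        warning(sum(allmiss), " all-missing SNP column(s) dropped")
        G <- G[, !allmiss, drop = FALSE]
    }
    if (ncol(G) == 0L) stop("no usable SNP columns")
    mu <- colMeans(G, na.rm = TRUE)
    for (j in seq_len(ncol(G))) {
        miss <- is.na(G[, j])
        if (any(miss)) G[miss, j] <- mu[j]
    }
    Xc <- sweep(G, 2L, colMeans(G), "-")
    tcrossprod(Xc) / ncol(Xc)
}

#' Eigendecomposition of a kinship matrix
#'
#' Computed once per K and reused across phenotypes/SNPs; small
#' negative eigenvalues within numerical tolerance are clamped to
#' zero, larger ones are an error (K must be PSD).
#'
#' @param K Symmetric kinship matrix.
#' @param tol Tolerance for negative eigenvalues (relative to the
#'   largest eigenvalue).
#' @return A list with `vectors` (U) and `values` (d), K = U d U'.
#' @export
eigenKinship <- function(K, tol = 1e-8) {
    if (!isSymmetric(unname(K), tol = 1e-6)) stop("K must be symmetric")
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    scale <- max(abs(e$values), 1)
    if (min(e$values) < -tol * scale * 100)
        stop("K is not positive semi-definite")
    e$values[e$values < 0] <- 0
    list(vectors = e$vectors, values = e$values)
}

## Profile ML log-likelihood of the rotated model at variance ratio
## lambda; also returns the GLS estimates at that lambda.
.lmmProfile <- function(lambda, yr, Xr, d) {
    n <- length(yr)
    w <- 1 / (lambda * d + 1)
    Xw <- Xr * w
    XtWX <- crossprod(Xr, Xw)
    XtWy <- crossprod(Xw, yr)
    beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
    if (is.null(beta)) return(list(logL = -Inf))
    resid <- yr - Xr %*% beta
    rss <- sum(w * resid^2)
    sigma2 <- rss / n
    logL <- -n / 2 * log(2 * pi * sigma2) + sum(log(w)) / 2 - n / 2
    list(logL = as.numeric(logL), beta = as.numeric(beta),
         sigma2 = sigma2, XtWX = XtWX)
}

#' Fit the univariate kinship mixed model by maximum likelihood
#'
#' Fits y = W alpha + x delta + u + e with u ~ MVN(0, lambda tau^-1 K)
#' and e ~ MVN(0, tau^-1 I). K is eigendecomposed (once; pass `Keig`
#' to reuse), data are rotated so the covariance is diagonal, and for
#' a trial lambda the model reduces to weighted least squares with
#' weights 1/(lambda d_i + 1). The ML likelihood is maximised over
#' log10(lambda) on [-5, 5] by a 0.1-step grid followed by
#' [stats::optimize()] refinement. ML (not REML) is used throughout so
#' that nested fits can be compared by a likelihood-ratio test.
#'
#' @param y Numeric phenotype vector.
#' @param W Fixed-effect design matrix (n x c, full column rank,
#'   including the intercept).
#' @param x Optional genotype vector (the allele dosage); omit for
#'   the null model.
#' @param K Kinship matrix (ignored when `Keig` is given).
#' @param Keig Optional precomputed [eigenKinship()] result.
#' @return An [LMMFit-class] object.
#' @export
fitLMM <- function(y, W, x = NULL, K = NULL, Keig = NULL) {
    if (is.null(Keig)) {
        if (is.null(K)) stop("either K or Keig must be supplied")
        Keig <- eigenKinship(K)
    }
    n <- length(y)
    W <- as.matrix(W)
    stopifnot(nrow(W) == n, nrow(Keig$vectors) == n)
    hasX <- !is.null(x)
    if (hasX && stats::var(x) == 0)
        stop("constant genotype vector: delta is not estimable")
    X <- if (hasX) cbind(W, x = x) else W
    if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
    if (n < ncol(X) + 2L) stop("too few observations")
    U <- Keig$vectors
    d <- Keig$values
    yr <- crossprod(U, y)
    Xr <- crossprod(U, X)
    grid <- seq(-5, 5, by = 0.1)
    gl <- vapply(grid, function(lg) .lmmProfile(10^lg, yr, Xr, d)$logL,
                 numeric(1))
    best <- grid[which.max(gl)]
    opt <- stats::optimize(function(lg) .lmmProfile(10^lg, yr, Xr, d)$logL,
                           interval = c(best - 0.1, best + 0.1),
                           maximum = TRUE, tol = 1e-6)
    ## a boundary fit at the lower grid edge is effectively lambda = 0
    lambda <- 10^opt$maximum
    fit <- .lmmProfile(lambda, yr, Xr, d)
    se <- NA_real_
    delta <- NA_real_
    if (hasX) {
        covb <- fit$sigma2 * solve(fit$XtWX)
        delta <- fit$beta[ncol(X)]
        se <- sqrt(covb[ncol(X), ncol(X)])
    }
    new("LMMFit", lambda = lambda, sigma2 = fit$sigma2, beta = fit$beta,
        delta = delta, se = se, logLik = fit$logL, n = as.integer(n),
        hasX = hasX)
}

#' Likelihood-ratio test of the allele substitution effect
#'
#' Contrasts H1: delta != 0 against H0: delta = 0 using ML fits of the
#' same (y, W, K); the statistic 2 (logL1 - logL0), floored at zero,
#' is referred to chi-square with 1 df.
#'
#' @param fit_alt [LMMFit-class] with the genotype term.
#' @param fit_null [LMMFit-class] without it.
#' @return A list with `stat` and `p`.
#' @export
lrtTest <- function(fit_alt, fit_null) {
    if (fit_alt@n != fit_null@n)
        stop("fits are not on the same data")
    if (!fit_alt@hasX || fit_null@hasX)
        stop("expected an alternative fit with x and a null fit without")
    stat <- max(0, 2 * (fit_alt@logLik - fit_null@logLik))
    list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
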