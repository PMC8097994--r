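test_that("probe presence filter keeps the 50% boundary", {
    pres <- rbind(all = rep(TRUE, 10),
                  p49 = c(rep(TRUE, 4), rep(FALSE, 6)),
                  p50 = c(rep(TRUE, 5), rep(FALSE, 5)),
                  ctrl = rep(TRUE, 10))
    keep <- filterExpressedProbes(pres, is_control = c(FALSE, FALSE, FALSE,
                                                       TRUE))
    expect_setequal(keep, c("all", "p50"))
})

test_that("centered kinship matches hand computation and imputes means", {
    G <- matrix(c(0, 2), nrow = 2)
    expect_equal(centeredKinship(G),
                 matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)

    # identical individuals: off-diagonal equals diagonal
    G2 <- matrix(c(0, 0, 1, 1, 2, 2), nrow = 2)
    K2 <- centeredKinship(G2)
    expect_equal(K2[1, 1], K2[1, 2])
    expect_equal(K2[1, 1], K2[2, 2])

    # (0, NA, 2) imputes to 1 and centers to (-1, 0, 1)
    G3 <- matrix(c(0, NA, 2), nrow = 3)
    K3 <- centeredKinship(G3)
    expect_equal(K3, outer(c(-1, 0, 1), c(-1, 0, 1)), ignore_attr = TRUE)

    expect_warning(centeredKinship(cbind(c(0, 1, 2), NA)), "all-missing")
})

test_that("with K = I the LMM reduces to ordinary least squares", {
    set.seed(61)
    n <- 60
    W <- cbind(1, rnorm(n))
    x <- rbinom(n, 2, 0.4)
    y <- drop(W %*% c(2, 0.5)) + 0.3 * x + rnorm(n)
    f <- fitLMM(y, W, x, K = diag(n))
    ols <- stats::coef(stats::lm(y ~ 0 + W + x))
    expect_equal(f@delta, unname(ols["x"]), tolerance = 1e-6)
    expect_equal(f@beta[1:2], unname(ols[1:2]), tolerance = 1e-6)
})

test_that("the reported log-likelihood equals the direct MVN density", {
    set.seed(62)
    for (i in 1:6) {
        n <- 6
        K <- centeredKinship(matrix(rbinom(n * 12, 2, 0.5), n))
        W <- matrix(1, n)
        x <- rbinom(n, 2, 0.5)
        if (stats::var(x) == 0) x[1] <- x[1] + 1
        y <- rnorm(n) + 0.4 * x
        f <- fitLMM(y, W, x, K = K)
        mu <- drop(cbind(W, x) %*% f@beta)
        expect_equal(f@logLik, oracleMVNlogL(y, mu, f@sigma2, f@lambda, K),
                     tolerance = 1e-8)
        # the optimum cannot be improved along the lambda grid
        probe <- vapply(c(0.3, 1, 3), function(m)
            oracleMVNlogL(y, mu, f@sigma2, f@lambda * m, K), numeric(1))
        expect_true(all(f@logLik >= probe - 1e-6))
    }
})

test_that("the LMM recovers a planted effect within its standard error", {
    set.seed(63)
    cfg <- simConfig(n_individuals = 200, n_background_snps = 200)
    co <- simulateCohort(cfg)
    f <- fitLMM(co$y, co$W, co$G[, "causal"], K = co$K)
    expect_lt(abs(f@delta - cfg$delta_true), 3 * f@se)
    expect_gt(f@se, 0)
    expect_error(fitLMM(co$y, co$W, rep(1, length(co$y)), K = co$K),
                 "constant")
})

test_that("the likelihood-ratio test behaves at its boundaries", {
    mk <- function(logL, hasX) new("LMMFit", lambda = 1, sigma2 = 1,
                                   beta = 0, delta = 0, se = 1,
                                   logLik = logL, n = 10L, hasX = hasX)
    expect_equal(lrtTest(mk(-5, TRUE), mk(-5, FALSE))$p, 1)
    r <- lrtTest(mk(-5 + 3.841 / 2, TRUE), mk(-5, FALSE))
    expect_equal(r$p, 0.05, tolerance = 1e-3)
    # a null fit that happens to beat the alternative is floored at 0
    expect_equal(lrtTest(mk(-6, TRUE), mk(-5, FALSE))$stat, 0)
    expect_error(lrtTest(mk(-5, FALSE), mk(-5, FALSE)), "alternative")
})

test_that("BH adjustment matches the hand step-up oracle", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.1, 1.2)), "0, 1")
    set.seed(64)
    for (i in 1:25) {
        p <- runif(sample(1:40, 1))
        q <- bhAdjust(p)
        expect_equal(q, oracleBH(p))
        expect_true(all(q >= p & q <= 1))
        expect_equal(bhAdjust(q), oracleBH(q))   # idempotent family
        o <- order(p)
        expect_true(all(diff(q[o]) >= -1e-12))   # monotone in sorted p
    }
})

test_that("candidate target lists apply both filters and the presence cut", {
    snp_mirna <- data.frame(snp_id = "rs1", arm_id = "armX")
    pairs <- data.frame(arm_id = "armX", gene_id = c("g1", "g2"),
                        transcript_id = c("t1", "t2"),
                        n_7mer_m8 = 1L, n_8mer = 0L)
    validated <- data.frame(arm_id = "armX", gene_id = c("g1", "g3"))
    probe_gene <- data.frame(probe_id = c("p1", "p2", "p3"),
                             gene_id = c("g1", "g2", "g3"))
    expressed <- c("p1", "p2", "p3")

    got <- candidateTargets(snp_mirna, pairs, validated, probe_gene, expressed)
    expect_equal(got$probe_id, "p1")   # g2 lacks validation, g3 lacks a site

    free <- candidateTargets(snp_mirna, pairs, validated, probe_gene,
                             expressed, require_site = FALSE,
                             require_validated = FALSE)
    expect_setequal(free$probe_id, c("p1", "p2", "p3"))

    none <- candidateTargets(snp_mirna, pairs, validated, probe_gene,
                             expressed = "p2")
    expect_equal(nrow(none), 0L)
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
    universe <- sprintf("g%02d", 1:20)
    pw <- list(A = universe[1:5])
    hits <- c(universe[1:3], universe[10:11])
    got <- hypergeomEnrichment(hits, pw, universe)
    expect_equal(got$p, oracleHyper(universe, pw$A, 5, 3), tolerance = 1e-12)

    # zero overlap is never significant
    none <- hypergeomEnrichment(universe[10:12], list(A = universe[1:5]),
                                universe)
    expect_equal(none$p, 1)

    # a pathway identical to the hit set is the extremal case
    perfect <- hypergeomEnrichment(universe[1:5], list(A = universe[1:5],
                                                       B = universe[1:10]),
                                   universe)
    expect_lt(perfect$p[perfect$pathway == "A"],
              perfect$p[perfect$pathway == "B"])
    expect_equal(perfect$p[perfect$pathway == "A"], 1 / choose(20, 5),
                 tolerance = 1e-12)
    expect_error(hypergeomEnrichment("g", list(), character(0)), "universe")
})

test_that("Welch's test matches hand-computed examples", {
    same <- welchTest(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)

    r <- welchTest(c(1, 2, 3), c(2, 3, 4))
    expect_equal(r$t, -1.2247, tolerance = 1e-4)
    expect_equal(r$df, 4, tolerance = 1e-6)
    expect_equal(r$p, 0.288, tolerance = 1e-3)

    far <- welchTest(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1))
    expect_lt(far$p, 1e-4)

    degen <- welchTest(c(1, 1), c(1, 1))
    expect_true(degen$degenerate)
    expect_equal(degen$p, 1)
})

test_that("ddCt quantification follows the calibrator convention", {
    ct <- rbind(
        data.frame(sample = "s1", group = "GG", gene = "tgt", ct = c(25, 25, 25)),
        data.frame(sample = "s1", group = "GG", gene = "ctl", ct = c(20, 20, 20)),
        data.frame(sample = "s2", group = "AA", gene = "tgt", ct = c(24, 24, 24)),
        data.frame(sample = "s2", group = "AA", gene = "ctl", ct = c(20, 20, 20)))
    dq <- ddctQuantify(ct, "tgt", "ctl", "GG")
    rec <- dq$records
    expect_equal(rec$ddct[rec$sample == "s1"], 0)
    expect_equal(rec$rq[rec$sample == "s1"], 1)
    # ddCt of -1 doubles expression
    expect_equal(rec$ddct[rec$sample == "s2"], -1)
    expect_equal(rec$rq[rec$sample == "s2"], 2)
    expect_equal(rec$log2_rq, -rec$ddct)
    expect_error(ddctQuantify(ct, "tgt", "nope", "GG"), "control")
})

test_that("a planted qPCR fold change is recovered from triplicates", {
    set.seed(65)
    folds <- replicate(10, {
        co <- simulateCohort(simConfig(n_individuals = 120,
                                       n_background_snps = 60,
                                       expression_fold = 1.9))
        dq <- ddctQuantify(co$ct, "target", c("ctrl1", "ctrl2"), "GG")
        dq$group_means["AA"] / dq$group_means["GG"]
    })
    expect_equal(mean(folds), 1.9, tolerance = 0.06)
})

test_that("the association scan orders the causal probe first", {
    set.seed(66)
    co <- simulateCohort(simConfig(n_individuals = 150,
                                   n_background_snps = 100,
                                   expression_fold = 2.6),
                         n_probes = 12, n_target_probes = 2)
    res <- associationScan(co$expression, co$G[, "causal"], co$W, co$K)
    expect_equal(sort(res$phenotype[1:2]), c("probe001", "probe002"))
    expect_true(all(res$q >= res$p))
    expect_equal(res$q, bhAdjust(res$p))
    # repressive direction: negative delta for target probes
    expect_lt(res$delta[res$phenotype == "probe001"], 0)
})
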