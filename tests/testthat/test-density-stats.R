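test_that("region lengths partition the hairpin universe", {
    # one 80-bp hairpin with one 22-nt arm
    loci <- makeLoci(list(list(chrom = "c1", hp = c(1001, 1080), strand = "+",
                               arms = list(list(id = "a", start = 1011,
                                                end = 1032)),
                               id = "L1")))
    rl <- regionLengths(loci)
    expect_equal(unlist(rl[c("seed_bp", "mature_bp", "precursor_bp",
                             "total_bp")]),
                 c(seed_bp = 7L, mature_bp = 15L, precursor_bp = 58L,
                   total_bp = 80L))

    empty <- MiRNALoci(GRanges(), GRanges(arm_id = character(0),
                                          locus_id = character(0),
                                          sequence = character(0)))
    rl0 <- regionLengths(empty)
    expect_equal(rl0$total_bp, 0L)
    expect_equal(rl0$seed_bp + rl0$mature_bp + rl0$precursor_bp, 0L)
})

test_that("length conservation holds for arbitrary generated locus sets", {
    set.seed(51)
    for (i in 1:5) {
        cfg <- simConfig(n_loci = sample(10:40, 1),
                         n_two_arm = sample(0:5, 1), n_utrs = 0)
        rl <- regionLengths(simulateReference(cfg)$loci)
        expect_equal(rl$seed_bp + rl$mature_bp + rl$precursor_bp,
                     rl$total_bp)
    }
})

test_that("the density statistic matches its definition and scales", {
    expect_equal(round(snpDensity(12, 2863), 2), 0.42)
    expect_equal(round(snpDensity(52, 6053), 2), 0.86)
    expect_equal(snpDensity(0, 1000), 0)
    expect_error(snpDensity(1, 0), "positive")
    # linear in Nr, inverse in Lr, scale-invariant
    expect_equal(snpDensity(30, 500), 3 * snpDensity(10, 500))
    expect_equal(snpDensity(10, 1000), snpDensity(10, 500) / 2)
    expect_equal(snpDensity(7 * 10, 900 * 10), snpDensity(7, 900))
})

test_that("density folds reproduce the published ratios", {
    dseed <- snpDensity(12, 2863)
    dmat <- snpDensity(52, 6053)
    dpre <- snpDensity(221, 22229)
    expect_equal(round(densityFold(dpre, dseed), 1), 2.4)
    expect_equal(round(densityFold(dpre, dmat), 2), 1.16)
    expect_equal(densityFold(dpre, dpre), 1)
    expect_error(densityFold(1, 0), "denominator")
})

test_that("per-position density profiles count arms long enough", {
    loci <- makeLoci(list(list(chrom = "c1", hp = c(1001, 1080), strand = "+",
                               arms = list(list(id = "a", start = 1011,
                                                end = 1032)),
                               id = "L1")))
    ann <- annotateVariants(loci, makeVariants("c1", 1016))  # p = 6
    pd <- positionDensity(ann, loci)
    expect_equal(nrow(pd), 22L)
    expect_equal(pd$density[pd$p == 6], 100)
    expect_equal(sum(pd$density), 100)

    pd0 <- positionDensity(annotateVariants(loci, makeVariants("c1", 1050)),
                           loci)
    expect_equal(sum(pd0$n_snps), 0L)
})

test_that("anchor-position density at study scale matches the bookkeeping", {
    loci <- makeStudyScaleLoci()
    ar <- matureArms(loci)
    # plant one anchor SNP on two different arms (both plus-strand loci)
    a <- ar[as.character(strand(ar)) == "+"][1:2]
    v <- makeVariants(as.character(seqnames(a)), start(a))
    ann <- annotateVariants(loci, v)
    expect_equal(ann$region, c("ANCHOR", "ANCHOR"))
    pd <- positionDensity(ann, loci)
    expect_equal(round(pd$density[pd$p == 1], 3), round(2 * 100 / 409, 3))
})

test_that("flanking bins are strand-oriented and recover planted rates", {
    # one plus- and one minus-strand locus; SNP 50 bp 5' of each hairpin
    loci <- makeLoci(list(
        list(chrom = "c1", hp = c(2001, 2090), strand = "+",
             arms = list(list(id = "a1", start = 2011, end = 2032)),
             id = "L1"),
        list(chrom = "c2", hp = c(2001, 2090), strand = "-",
             arms = list(list(id = "a2", start = 2011, end = 2032)),
             id = "L2")))
    v <- makeVariants(c("c1", "c2"), c(2001 - 50, 2090 + 50),
                      vid = c("vplus", "vminus"))
    fl <- flankingDensity(loci, v)
    expect_equal(fl$n_snps[fl$bin == -1], 2L)
    expect_equal(sum(fl$n_snps), 2L)
    # genomic orientation puts the minus-strand SNP downstream instead
    flg <- flankingDensity(loci, v, orientation = "genomic")
    expect_equal(flg$n_snps[flg$bin == -1], 1L)
    expect_equal(flg$n_snps[flg$bin == 1], 1L)

    # no flanking SNPs -> all flanking bins zero
    fl0 <- flankingDensity(loci, makeVariants("c1", 2050))
    expect_true(all(fl0$n_snps[fl0$bin != 0] == 0L))
    expect_equal(fl0$n_snps[fl0$bin == 0], 1L)
})

test_that("uniform planted flanking SNPs give flat bin densities", {
    set.seed(52)
    cfg <- simConfig(n_loci = 150, n_two_arm = 15, n_utrs = 0,
                     r_seed = 0, r_mature = 0, r_precursor = 0,
                     r_flank = 0.02)
    ref <- simulateReference(cfg)
    vars <- simulateVariants(ref, cfg)
    fl <- flankingDensity(ref$loci, vars$variants)
    flanks <- fl[fl$bin != 0, ]
    # each bin pools 150 x 100 bp at rate 0.02/bp: expect 2 per 100 bp
    expect_true(all(abs(flanks$density - 2) <
                    4 * sqrt(0.02 * 150 * 100) / 150))
    expect_equal(fl$density[fl$bin == 0], 0)
})

test_that("rank-sum test matches enumeration and handles ties", {
    r <- rankSumTest(c(1, 2), c(1, 2))
    expect_equal(r$U, 2)
    expect_gt(r$p, 0.99)

    r2 <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r2$U, 0)
    expect_equal(r2$p, 0.1)
    expect_equal(r2$method, "exact")

    set.seed(53)
    for (i in 1:20) {
        n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
        xs <- round(rnorm(n1), 4); ys <- round(rnorm(n2, 0.5), 4)
        got <- rankSumTest(xs, ys)
        expect_equal(got$p, oracleMWU(xs, ys), tolerance = 1e-12)
    }
    expect_error(rankSumTest(numeric(0), 1), "empty")
})

test_that("synthetic rate gradient reproduces the region density ordering", {
    set.seed(54)
    ok <- 0L
    pooled <- c(seed = 0, mature = 0, precursor = 0)
    pooledL <- c(seed = 0, mature = 0, precursor = 0)
    for (rep in 1:10) {
        cfg <- simConfig(n_loci = 370, n_two_arm = 39, n_utrs = 0, r_flank = 0)
        ref <- simulateReference(cfg)
        vars <- simulateVariants(ref, cfg)
        ann <- annotateVariants(ref$loci, vars$variants)
        d <- regionDensityTable(ann, ref$loci)
        dd <- stats::setNames(d$D, d$region)
        ok <- ok + (dd["precursor"] > dd["mature"] &&
                    dd["mature"] > dd["seed"])
        rl <- regionLengths(ref$loci)
        pooled <- pooled + stats::setNames(d$Nr, d$region)[names(pooled)]
        pooledL <- pooledL + c(seed = rl$seed_bp, mature = rl$mature_bp,
                               precursor = rl$precursor_bp)
    }
    # the single-replicate ordering can tie-break the wrong way for the
    # close mature/precursor rates, but must hold in a clear majority
    expect_gte(ok, 6L)
    dpool <- snpDensity(pooled, pooledL)
    expect_true(dpool["precursor"] > dpool["mature"] &&
                dpool["mature"] > dpool["seed"])
})
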