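#' Region-length bookkeeping for a miRNA locus set
#'
#' The seed universe is 7 bp per mature arm; the mature universe is
#' the total arm length minus the seeds; the precursor universe is
#' the hairpin length not covered by arms.
#'
#' @param loci A [MiRNALoci-class] object.
#' @return A list with `seed_bp`, `mature_bp`, `precursor_bp`,
#'   `total_bp` and `n_arms`; the first three always sum to the total.
#' @export
regionLengths <- function(loci) {
    ar <- matureArms(loci)
    hp <- hairpins(loci)
    n_arms <- length(ar)
    seed_bp <- 7L * n_arms
    arm_bp <- sum(width(ar))
    total_bp <- sum(width(hp))
    list(seed_bp = as.integer(seed_bp),
         mature_bp = as.integer(arm_bp - seed_bp),
         precursor_bp = as.integer(total_bp - arm_bp),
         total_bp = as.integer(total_bp),
         n_arms = as.integer(n_arms))
}

#' SNP density per 100 bp
#'
#' D = Nr x 100 / Lr for a region with Nr SNPs over Lr bp.
#'
#' @param Nr SNP count (>= 0).
#' @param Lr Region length in bp (> 0).
#' @return Density in SNPs per 100 bp.
#' @examples
#' snpDensity(12, 2863) # ~0.42, the seed-region density
#' @export
snpDensity <- function(Nr, Lr) {
    stopifnot(Nr >= 0)
    if (any(Lr <= 0)) stop("region length must be positive")
    Nr * 100 / Lr
}

#' Ratio of two densities
#'
#' @param d_num,d_den Densities (denominator > 0).
#' @return `d_num / d_den`.
#' @export
densityFold <- function(d_num, d_den) {
    if (any(d_den <= 0)) stop("zero or negative denominator density")
    d_num / d_den
}

#' Per-region density table
#'
#' Convenience: counts annotated variants per three-way region and
#' divides by the region universes of the locus set.
#'
#' @param annotated Output of [annotateVariants()].
#' @param loci The [MiRNALoci-class] the variants were annotated on.
#' @return A `data.frame` with columns `region`, `Nr`, `Lr`, `D`,
#'   rows seed / mature / precursor / all.
#' @export
regionDensityTable <- function(annotated, loci) {
    rl <- regionLengths(loci)
    Nr <- c(seed = sum(annotated$region3 == "seed"),
            mature = sum(annotated$region3 == "mature"),
            precursor = sum(annotated$region3 == "precursor"))
    Lr <- c(seed = rl$seed_bp, mature = rl$mature_bp,
            precursor = rl$precursor_bp)
    data.frame(region = c(names(Nr), "all"),
               Nr = as.integer(c(Nr, sum(Nr))),
               Lr = as.integer(c(Lr, rl$total_bp)),
               D = snpDensity(c(Nr, sum(Nr)), c(Lr, rl$total_bp)),
               row.names = NULL)
}

#' SNP density along the mature miRNA sequence
#'
#' For each mature position p (1 = anchor), the number of SNPs at p
#' over the number of arms long enough to have a position p, per
#' 100 bp.
#'
#' @param annotated Output of [annotateVariants()].
#' @param loci The [MiRNALoci-class] object.
#' @return A `data.frame` with columns `p`, `n_snps`, `n_arms`,
#'   `density`, ordered by `p` up to the longest arm.
#' @export
positionDensity <- function(annotated, loci) {
    lens <- width(matureArms(loci))
    maxL <- if (length(lens)) max(lens) else 0L
    p <- seq_len(maxL)
    n_arms <- vapply(p, function(q) sum(lens >= q), integer(1))
    mp <- annotated$p[!is.na(annotated$p)]
    n_snps <- vapply(p, function(q) sum(mp == q), integer(1))
    data.frame(p = p, n_snps = n_snps, n_arms = n_arms,
               density = ifelse(n_arms > 0, n_snps * 100 / n_arms, NA_real_))
}

#' SNP density in miRNA loci and their flanking bins
#'
#' Pools, across loci, ten 100-bp bins upstream and downstream of each
#' hairpin plus the hairpin body (bin 0). By default "upstream" is the
#' 5' flank in the hairpin's transcriptional orientation, so bin -1
#' abuts the hairpin 5' end on both strands; set
#' `orientation = "genomic"` to use genomic left/right instead.
#'
#' @param loci A [MiRNALoci-class] object.
#' @param variants Variant `GRanges` including SNPs outside hairpins.
#' @param n_bins Number of flanking bins on each side (default 10).
#' @param bin_bp Bin width in bp (default 100).
#' @param orientation `"strand"` (default) or `"genomic"`.
#' @return A `data.frame` with columns `bin` (-n_bins..n_bins),
#'   `n_snps`, `bp`, `density` (SNPs per 100 bp).
#' @export
flankingDensity <- function(loci, variants, n_bins = 10L, bin_bp = 100L,
                            orientation = c("strand", "genomic")) {
    orientation <- match.arg(orientation)
    hp <- hairpins(loci)
    bins <- c(-seq_len(n_bins), seq_len(n_bins))
    counts <- stats::setNames(integer(2L * n_bins + 1L),
                              as.character(c(-(n_bins:1), 0L, 1:n_bins)))
    bp <- counts
    vpos <- start(variants)
    vchr <- as.character(seqnames(variants))
    for (i in seq_along(hp)) {
        chr <- as.character(seqnames(hp))[i]
        s <- start(hp)[i]; e <- end(hp)[i]
        flip <- orientation == "strand" && as.character(strand(hp))[i] == "-"
        onchr <- vchr == chr
        for (b in bins) {
            if (b < 0) { # upstream of the 5' end
                k <- -b
                if (!flip) { lo <- s - k * bin_bp; hi <- s - (k - 1L) * bin_bp - 1L }
                else { lo <- e + (k - 1L) * bin_bp + 1L; hi <- e + k * bin_bp }
            } else {
                k <- b
                if (!flip) { lo <- e + (k - 1L) * bin_bp + 1L; hi <- e + k * bin_bp }
                else { lo <- s - k * bin_bp; hi <- s - (k - 1L) * bin_bp - 1L }
            }
            key <- as.character(b)
            counts[key] <- counts[key] + sum(onchr & vpos >= lo & vpos <= hi)
            bp[key] <- bp[key] + bin_bp
        }
        counts["0"] <- counts["0"] + sum(onchr & vpos >= s & vpos <= e)
        bp["0"] <- bp["0"] + (e - s + 1L)
    }
    data.frame(bin = as.integer(names(counts)), n_snps = as.integer(counts),
               bp = as.integer(bp),
               density = ifelse(bp > 0, counts * 100 / bp, NA_real_))
}

#' Mann-Whitney U rank-sum test
#'
#' Two-sided by default. Mid-ranks are used for ties; the null
#' distribution is enumerated exactly for small samples without ties
#' (n1 + n2 <= 20), otherwise a normal approximation with tie
#' correction and 0.5 continuity correction is used.
#'
#' @param xs,ys Numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or
#'   `"greater"`.
#' @return A list with `U` (statistic for `xs`), `p`, and `method`
#'   (`"exact"` or `"normal-approximation"`).
#' @export
rankSumTest <- function(xs, ys, alternative = "two.sided") {
    if (length(xs) == 0L || length(ys) == 0L)
        stop("empty sample")
    ties <- anyDuplicated(c(xs, ys)) > 0L
    exact <- !ties && (length(xs) + length(ys)) <= 20L
    wt <- stats::wilcox.test(xs, ys, alternative = alternative,
                             exact = exact, correct = TRUE)
    list(U = unname(wt$statistic), p = wt$p.value,
         method = if (exact) "exact" else "normal-approximation")
}

#' Per-arm seed and mature densities
#'
#' One seed density and one mature (non-seed) density per arm, the
#' sampling units used for the nonparametric seed-vs-mature density
#' comparison.
#'
#' @param annotated Output of [annotateVariants()].
#' @param loci A [MiRNALoci-class] object.
#' @return A `data.frame` with `arm_id`, `seed_density`,
#'   `mature_density` (per 100 bp).
#' @export
perArmDensities <- function(annotated, loci) {
    ar <- matureArms(loci)
    ann <- annotated[!is.na(annotated$p), , drop = FALSE]
    seedN <- vapply(ar$arm_id, function(a)
        sum(ann$arm_id == a & ann$region == "SEED"), integer(1))
    matN <- vapply(ar$arm_id, function(a)
        sum(ann$arm_id == a & ann$region != "SEED"), integer(1))
    data.frame(arm_id = ar$arm_id,
               seed_density = seedN * 100 / 7,
               mature_density = matN * 100 / (width(ar) - 7L),
               row.names = NULL)
}
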