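#' Region classes within a miRNA hairpin
#'
#' Five mutually exclusive classes partition every hairpin position:
#' `SEED` (mature positions 2-8), `ANCHOR` (mature position 1),
#' `SUPPLEMENTARY` (mature positions 13-18), `MATURE_OTHER` (any other
#' mature position) and `PRECURSOR` (hairpin outside the mature arms).
#' The coarse three-way labels used in most summaries collapse
#' `ANCHOR`, `SUPPLEMENTARY` and `MATURE_OTHER` into `mature`.
#'
#' @format Character vector of the five class labels.
#' @export
REGION_CLASSES <- c("SEED", "ANCHOR", "SUPPLEMENTARY", "MATURE_OTHER", "PRECURSOR")

.regionFromP <- function(p) {
    ifelse(p == 1L, "ANCHOR",
    ifelse(p >= 2L & p <= 8L, "SEED",
    ifelse(p >= 13L & p <= 18L, "SUPPLEMENTARY", "MATURE_OTHER")))
}

#' Collapse five-way region classes to the coarse three-way labels
#'
#' @param region Character vector of five-way classes.
#' @return Character vector over `seed`, `mature`, `precursor`.
#' @export
collapseRegion <- function(region) {
    ifelse(region == "SEED", "seed",
    ifelse(region == "PRECURSOR", "precursor", "mature"))
}

#' Classify one variant within one miRNA locus
#'
#' If the position falls in a mature arm, the mature position p is
#' computed with [genomicToMaturePosition()] and mapped to a region
#' class; otherwise the variant is `PRECURSOR`.
#'
#' @param loci A [MiRNALoci-class] object.
#' @param locus_id Locus to classify against.
#' @param gpos Genomic position (1-based) inside the hairpin.
#' @return A list with `locus_id`, `region`, `arm_id` (NA outside
#'   arms) and `p` (mature position, NA outside arms).
#' @export
classifyVariant <- function(loci, locus_id, gpos) {
    hp <- hairpins(loci)[locus_id]
    if (gpos < start(hp) || gpos > end(hp))
        stop("variant at ", gpos, " outside hairpin ", locus_id)
    ar <- matureArms(loci)
    ar <- ar[ar$locus_id == locus_id]
    hit <- which(gpos >= start(ar) & gpos <= end(ar))
    if (length(hit) == 0L)
        return(list(locus_id = locus_id, region = "PRECURSOR",
                    arm_id = NA_character_, p = NA_integer_))
    a <- ar[hit[1]]
    p <- genomicToMaturePosition(a, gpos)
    list(locus_id = locus_id, region = .regionFromP(p),
         arm_id = a$arm_id, p = p)
}

#' Annotate all variants falling inside miRNA hairpins
#'
#' Only variants inside some hairpin are emitted. A variant inside two
#' overlapping loci is emitted once per locus, with a warning.
#'
#' @param loci A [MiRNALoci-class] object.
#' @param variants Variant `GRanges` (width 1, with `vid`, `ref`,
#'   `alt` and optional per-population columns).
#' @return A `data.frame` with columns `vid`, `chrom`, `pos`, `ref`,
#'   `alt`, `locus_id`, `arm_id`, `p`, `region` (five-way),
#'   `region3` (three-way), plus any `presence.*` / `freq.*` columns
#'   carried over from `variants`.
#' @export
annotateVariants <- function(loci, variants) {
    hp <- hairpins(loci)
    hits <- findOverlaps(variants, hp, ignore.strand = TRUE)
    empty <- data.frame(vid = character(0), chrom = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), locus_id = character(0),
                        arm_id = character(0), p = integer(0),
                        region = character(0), region3 = character(0))
    if (length(hits) == 0L) return(empty)
    if (anyDuplicated(queryHits(hits)))
        warning("variant(s) inside overlapping miRNA loci emitted once per locus")
    extra <- grep("^(presence|freq)\\.", colnames(mcols(variants)), value = TRUE)
    rows <- lapply(seq_along(hits), function(h) {
        v <- variants[queryHits(hits)[h]]
        lid <- names(hp)[subjectHits(hits)[h]]
        cls <- classifyVariant(loci, lid, start(v))
        d <- data.frame(vid = v$vid, chrom = as.character(seqnames(v)),
                        pos = start(v), ref = v$ref, alt = v$alt,
                        locus_id = lid, arm_id = cls$arm_id, p = cls$p,
                        region = cls$region,
                        region3 = collapseRegion(cls$region),
                        stringsAsFactors = FALSE)
        for (cn in extra) d[[cn]] <- mcols(v)[[cn]]
        d
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$chrom, out$pos, out$locus_id), ]
    rownames(out) <- NULL
    out
}

#' Histogram of SNP counts per polymorphic miRNA locus
#'
#' @param annotated Output of [annotateVariants()].
#' @return Named integer vector: k -> number of loci carrying exactly
#'   k SNPs (loci with zero SNPs do not appear).
#' @export
perMirnaSnpHistogram <- function(annotated) {
    if (nrow(annotated) == 0L) return(integer(0))
    per <- table(annotated$locus_id)
    tab <- table(factor(as.integer(per)))
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
}

#' Cross-population sharing summary
#'
#' Counts, across the given populations, how many variants are present
#' in all of them, how many are exclusive to each, and the full
#' subset (Venn) breakdown. Presence of a variant in a population
#' means the alternative allele was observed in at least one
#' individual of that group.
#'
#' @param annotated Output of [annotateVariants()] (or any data.frame
#'   with logical `presence.<pop>` columns).
#' @param populations Character vector of population labels.
#' @return A list with `n` (total variants), `shared_all`,
#'   `shared_all_pct` (two-decimal rounding), `exclusive` (named
#'   vector) and `subsets` (named vector over presence signatures,
#'   summing to `n`).
#' @export
sharingSummary <- function(annotated, populations) {
    cols <- paste0("presence.", populations)
    missing <- setdiff(cols, colnames(annotated))
    if (length(missing))
        stop("unknown population label(s): ",
             paste(sub("^presence\\.", "", missing), collapse = ", "))
    pres <- as.matrix(annotated[, cols, drop = FALSE])
    colnames(pres) <- populations
    n <- nrow(pres)
    sig <- apply(pres, 1, function(r)
        if (!any(r)) "(none)" else paste(populations[r], collapse = "+"))
    subsets <- table(sig)
    shared <- sum(rowSums(pres) == length(populations))
    excl <- vapply(seq_along(populations), function(j)
        sum(pres[, j] & rowSums(pres) == 1L), integer(1))
    names(excl) <- populations
    list(n = n, shared_all = shared,
         shared_all_pct = if (n > 0) percentValue(shared, n) else NA_real_,
         exclusive = excl,
         subsets = {
             s <- as.integer(subsets); names(s) <- names(subsets); s
         })
}

#' Render a percentage with two decimals
#'
#' Published percentages mix rounding conventions, so both are
#' offered: `round` is standard half-up-style rounding to two
#' decimals, `truncate` drops digits beyond the second decimal.
#'
#' @param k Numerator count (0 <= k <= n).
#' @param n Denominator count (> 0).
#' @param mode `"round"` (default) or `"truncate"`.
#' @return The percentage 100*k/n rendered per `mode`.
#' @examples
#' percentValue(43, 285)             # 15.09
#' percentValue(139, 370, "truncate") # 37.56 (exact value 37.5676...)
#' @export
percentValue <- function(k, n, mode = c("round", "truncate")) {
    mode <- match.arg(mode)
    if (n == 0) stop("denominator is zero")
    stopifnot(k >= 0, k <= n)
    x <- 100 * k / n
    if (mode == "round") round(x, 2) else floor(x * 100) / 100
}

#' Alternative-allele frequency spectrum
#'
#' Bins are `[0, w), [w, 2w), ..., [1-w, 1]` (the last bin is closed
#' above). Also reports the fraction of variants with frequency
#' less than or equal to 0.1, the conventional rare-variant cut.
#'
#' @param annotated Output of [annotateVariants()] (or any data.frame
#'   with a `freq.<population>` column).
#' @param population Population label whose frequencies to use.
#' @param bin_width Bin width w (default 0.1).
#' @return A list with `breaks`, `counts` (summing to the number of
#'   variants with a defined frequency) and `frac_le_0.1`.
#' @export
frequencySpectrum <- function(annotated, population, bin_width = 0.1) {
    col <- paste0("freq.", population)
    if (!col %in% colnames(annotated))
        stop("no frequencies for population ", population)
    f <- annotated[[col]]
    f <- f[!is.na(f)]
    breaks <- seq(0, 1, by = bin_width)
    if (max(breaks) < 1) breaks <- c(breaks, 1)
    ## right = FALSE gives [a,b) bins; include.lowest closes the last at 1
    counts <- if (length(f) == 0L) integer(length(breaks) - 1L) else
        as.integer(table(cut(f, breaks, include.lowest = TRUE, right = FALSE,
                             labels = FALSE) |>
                         factor(levels = seq_len(length(breaks) - 1L))))
    list(breaks = breaks, counts = counts,
         frac_le_0.1 = if (length(f)) mean(f <= 0.1) else NA_real_)
}
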