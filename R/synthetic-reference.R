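#' Simulation configuration
#'
#' Defaults encode the study conditions the rest of the package is
#' exercised against: 370 miRNA loci carrying 409 mature arms (39
#' two-arm loci), arm lengths of 20-24 nt, hairpins of 60-110 bp,
#' per-region SNP rates matching the observed purifying-selection
#' gradient (seed < mature < precursor < flank), a four-population
#' sharing probability of 0.15, rare-skewed alternative-allele
#' frequencies (Beta means 0.12 for mature/seed, 0.15 for precursor),
#' and a five-sire half-sib cohort of 345 individuals with
#' heritability 0.3 and an allele substitution effect of 0.4508 (the
#' scale of effects the mixed model is expected to detect).
#'
#' @param n_loci Number of miRNA loci.
#' @param n_two_arm How many loci carry both a 5p and a 3p arm.
#' @param arm_len_range,hairpin_len_range Length ranges (nt / bp).
#' @param r_seed,r_mature,r_precursor,r_flank Per-bp SNP rates.
#' @param populations Population labels.
#' @param share_all_prob Probability a miRNA SNP segregates in every
#'   population.
#' @param beta_mature,beta_precursor `c(shape1, shape2)` of the
#'   alternative-allele frequency Beta for mature/seed and precursor
#'   SNPs.
#' @param n_utrs,utr_length,sites_per_utr,frac_8mer,n_target_arms 3'UTR
#'   generation: number of UTRs, spliced length, planted seed-match
#'   sites per UTR, fraction planted as 8mer, number of distinct arms
#'   whose seeds are planted (their motifs are guaranteed absent
#'   elsewhere by rejection sampling).
#' @param n_individuals,n_sires,n_background_snps,h2,delta_true Cohort
#'   generation: size, sire count, background SNPs for the kinship,
#'   heritability of the simulated traits, true allele substitution
#'   effect.
#' @param expression_fold,ct_sd miRNA-target expression fold between
#'   homozygous genotype groups and qPCR technical SD.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(n_loci = 370L, n_two_arm = 39L,
                      arm_len_range = c(20L, 24L),
                      hairpin_len_range = c(60L, 110L),
                      r_seed = 12 / 2863, r_mature = 52 / 6053,
                      r_precursor = 221 / 22229, r_flank = 0.0238,
                      populations = c("EDM", "ADM", "EWB", "AWB"),
                      share_all_prob = 0.15,
                      beta_mature = c(0.6, 4.4),
                      beta_precursor = c(0.75, 4.25),
                      n_utrs = 20L, utr_length = 500L, sites_per_utr = 2L,
                      frac_8mer = 1 / 3, n_target_arms = 5L,
                      n_individuals = 345L, n_sires = 5L,
                      n_background_snps = 400L, h2 = 0.3,
                      delta_true = 0.4508, expression_fold = 1.9,
                      ct_sd = 0.15) {
    cfg <- as.list(environment())
    stopifnot(cfg$n_two_arm <= cfg$n_loci,
              all(c(r_seed, r_mature, r_precursor, r_flank) >= 0))
    class(cfg) <- "SimConfig"
    cfg
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Simulate a reference genome with miRNA annotation and 3'UTRs
#'
#' Builds one chromosome per miRNA locus (hairpin flanked by 1 kb on
#' each side) and one per 3'UTR (two blocks separated by a spacer).
#' Loci fall on both strands (~50/50). Each UTR carries the
#' configured number of planted exact seed-match sites for a small
#' set of target arms; UTR sequences are rejection-sampled so that
#' those arms' match motifs occur nowhere except at the planted
#' positions, making site recovery exact.
#'
#' @param config A [simConfig()] list.
#' @return A list with `genome` (`DNAStringSet`), `loci`
#'   ([MiRNALoci-class]), `utrs` ([UTRSet-class]), and `truth`
#'   (planted-site table with `arm_id`, `transcript_id`, `start`,
#'   `end`, `site_type`).
#' @export
simulateReference <- function(config = simConfig()) {
    n <- config$n_loci
    two_arm <- c(rep(TRUE, config$n_two_arm), rep(FALSE, n - config$n_two_arm))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    flank <- 1000L
    hplens <- sample(config$hairpin_len_range[1]:config$hairpin_len_range[2],
                     n, replace = TRUE)
    chroms <- sprintf("mchr%03d", seq_len(n))
    lids <- sprintf("sim-mir-%03d", seq_len(n))
    genome <- lapply(stats::setNames(hplens, chroms),
                     function(L) .randSeq(flank + L + flank))
    hs <- rep(flank + 1L, n)
    he <- flank + hplens
    ac <- as <- ae <- astr <- aid <- alid <- character(0)
    as <- ae <- integer(0)
    for (i in seq_len(n)) {
        L1 <- sample(config$arm_len_range[1]:config$arm_len_range[2], 1)
        if (two_arm[i]) {
            L2 <- sample(config$arm_len_range[1]:config$arm_len_range[2], 1)
            ## 5p arm just inside the 5' end, 3p arm 1 bp inside the 3' end
            as <- c(as, hs[i] + 1L, he[i] - L2)
            ae <- c(ae, hs[i] + L1, he[i] - 1L)
            aid <- c(aid, paste0(lids[i], c("-5p", "-3p")))
            alid <- c(alid, lids[i], lids[i])
            ac <- c(ac, chroms[i], chroms[i])
            astr <- c(astr, strands[i], strands[i])
        } else {
            side <- sample(c("5p", "3p"), 1)
            s1 <- if (side == "5p") hs[i] + 1L else he[i] - L1
            as <- c(as, s1); ae <- c(ae, s1 + L1 - 1L)
            aid <- c(aid, paste0(lids[i], "-", side))
            alid <- c(alid, lids[i])
            ac <- c(ac, chroms[i])
            astr <- c(astr, strands[i])
        }
    }
    hp <- GRanges(chroms, IRanges(hs, he), strand = strands)
    names(hp) <- lids
    arms <- GRanges(ac, IRanges(as, ae), strand = astr,
                    arm_id = aid, locus_id = alid)
    gen <- DNAStringSet(unlist(genome))
    chrchar <- stats::setNames(as.character(gen), names(gen))
    armseq <- substr(chrchar[ac], as, ae)
    onminus <- astr == "-"
    armseq[onminus] <- vapply(armseq[onminus], revComp, character(1),
                              USE.NAMES = FALSE)
    arms$sequence <- unname(armseq)
    loci <- MiRNALoci(hp, arms)

    ## pick target arms and plant their seed motifs into UTRs
    target_arms <- sample(arms$arm_id, config$n_target_arms)
    seeds <- vapply(target_arms, function(a)
        extractSeed(arms$sequence[arms$arm_id == a]), character(1))
    motifs <- vapply(seeds, revComp, character(1))
    utr_truth <- list()
    utr_seqs <- character(config$n_utrs)
    ustrand <- sample(c("+", "-"), config$n_utrs, replace = TRUE)
    for (j in seq_len(config$n_utrs)) {
        Lu <- config$utr_length
        placed <- NULL
        for (try in seq_len(200L)) {
            sq <- strsplit(.randSeq(Lu), "")[[1]]
            k <- config$sites_per_utr
            ## non-overlapping planting slots (8 bp incl. the t1 base)
            starts <- sort(sample(seq(1L, Lu - 8L), k))
            if (k > 1 && any(diff(starts) < 9L)) next
            arm_pick <- sample(target_arms, k, replace = TRUE)
            is8 <- stats::runif(k) < config$frac_8mer
            for (s in seq_len(k)) {
                m <- strsplit(motifs[arm_pick[s]], "")[[1]]
                sq[starts[s]:(starts[s] + 6L)] <- m
                sq[starts[s] + 7L] <- if (is8[s]) "A" else
                    sample(c("C", "G", "T"), 1)
            }
            seqchr <- paste(sq, collapse = "")
            ## accept only if every target motif occurs exactly as planted
            nocc <- vapply(unique(motifs), function(m)
                length(matchPattern(m, DNAString(seqchr))), integer(1))
            want <- vapply(unique(motifs), function(m)
                sum(motifs[arm_pick] == m), integer(1))
            if (!identical(nocc, want)) next
            placed <- data.frame(
                arm_id = arm_pick,
                transcript_id = sprintf("utr%03d", j),
                start = starts,
                end = ifelse(is8, starts + 7L, starts + 6L),
                site_type = ifelse(is8, "8mer", "7mer-m8"),
                stringsAsFactors = FALSE)
            break
        }
        if (is.null(placed))
            stop("could not plant sites in UTR ", j,
                 " (UTR too short for the requested sites?)")
        utr_truth[[j]] <- placed
        utr_seqs[j] <- seqchr
    }
    ## lay each spliced UTR onto its own chromosome as two blocks
    spacer <- 50L
    blocks <- list()
    for (j in seq_len(config$n_utrs)) {
        Lu <- nchar(utr_seqs[j])
        w1 <- Lu %/% 2L
        chrom <- sprintf("uchr%03d", j)
        b <- GRanges(chrom,
                     IRanges(c(101L, 101L + w1 + spacer),
                             width = c(w1, Lu - w1)),
                     strand = ustrand[j])
        blocks[[sprintf("utr%03d", j)]] <- b
        ## write the spliced sequence into the genome, strand-aware
        chrseq <- strsplit(.randSeq(200L + Lu + spacer), "")[[1]]
        spl <- utr_seqs[j]
        txb <- if (ustrand[j] == "-") rev(seq_along(b)) else seq_along(b)
        off <- 0L
        for (bi in txb) {
            wlen <- width(b)[bi]
            piece <- substr(spl, off + 1L, off + wlen)
            if (ustrand[j] == "-") piece <- revComp(piece)
            chrseq[start(b)[bi]:end(b)[bi]] <- strsplit(piece, "")[[1]]
            off <- off + wlen
        }
        genome[[chrom]] <- paste(chrseq, collapse = "")
    }
    gen <- DNAStringSet(unlist(genome))
    utrs <- UTRSet(GRangesList(blocks),
                   {
                       s <- DNAStringSet(utr_seqs)
                       names(s) <- names(blocks)
                       s
                   },
                   stats::setNames(sub("^utr", "gene", names(blocks)),
                                   names(blocks)))
    truth <- do.call(rbind, utr_truth)
    rownames(truth) <- NULL
    list(genome = gen, loci = loci, utrs = utrs, truth = truth,
         target_arms = target_arms)
}

#' Simulate SNPs over a synthetic reference
#'
#' Every bp of every hairpin region (seed / mature-other / precursor)
#' and of the 1-kb flanks carries an independent Bernoulli SNP at the
#' configured per-region rate. Population presence is drawn with the
#' configured all-population sharing probability (otherwise a random
#' non-empty population subset); alternative-allele frequencies come
#' from rare-skewed Beta distributions, with precursor SNPs slightly
#' less rare than mature/seed ones.
#'
#' @param reference Output of [simulateReference()].
#' @param config The same [simConfig()] list.
#' @return A list with `variants` (a `GRanges` with `vid`, `ref`,
#'   `alt`, `presence.*`, `freq.*` and a `true_region` column for
#'   in-hairpin SNPs; flank SNPs have `true_region = "flank"`) and
#'   `truth` (per-region planted counts).
#' @export
simulateVariants <- function(reference, config = simConfig()) {
    loci <- reference$loci
    genome <- reference$genome
    hp <- hairpins(loci)
    ar <- matureArms(loci)
    pops <- config$populations
    pos_list <- list()
    for (i in seq_along(hp)) {
        chrom <- as.character(seqnames(hp))[i]
        lid <- names(hp)[i]
        hrange <- start(hp)[i]:end(hp)[i]
        sub <- ar[ar$locus_id == lid]
        region <- rep("precursor", length(hrange))
        for (k in seq_along(sub)) {
            p <- genomicToMaturePosition(sub[k], start(sub)[k]:end(sub)[k])
            idx <- match(start(sub)[k]:end(sub)[k], hrange)
            region[idx] <- ifelse(p >= 2 & p <= 8, "seed", "mature")
        }
        rate <- c(seed = config$r_seed, mature = config$r_mature,
                  precursor = config$r_precursor)[region]
        hit <- stats::runif(length(hrange)) < rate
        fl <- c((start(hp)[i] - 1000L):(start(hp)[i] - 1L),
                (end(hp)[i] + 1L):(end(hp)[i] + 1000L))
        flhit <- stats::runif(length(fl)) < config$r_flank
        if (any(hit))
            pos_list[[length(pos_list) + 1L]] <- data.frame(
                chrom = chrom, pos = hrange[hit], region = region[hit])
        if (any(flhit))
            pos_list[[length(pos_list) + 1L]] <- data.frame(
                chrom = chrom, pos = fl[flhit], region = "flank")
    }
    tab <- do.call(rbind, pos_list)
    if (is.null(tab))
        tab <- data.frame(chrom = character(0), pos = integer(0),
                          region = character(0))
    nv <- nrow(tab)
    if (nv == 0L) {
        v <- GRanges(vid = character(0), ref = character(0),
                     alt = character(0), true_region = character(0))
        for (pop in pops) {
            mcols(v)[[paste0("presence.", pop)]] <- logical(0)
            mcols(v)[[paste0("freq.", pop)]] <- numeric(0)
        }
        return(list(variants = v,
                    truth = list(seed = 0L, mature = 0L, precursor = 0L,
                                 flank = 0L)))
    }
    chrchar <- stats::setNames(as.character(genome), names(genome))
    v <- GRanges(tab$chrom, IRanges(tab$pos, tab$pos), strand = "*")
    v$vid <- sprintf("simsnp%05d", seq_len(nv))
    v$ref <- substr(chrchar[tab$chrom], tab$pos, tab$pos)
    names(v$ref) <- NULL
    alts <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                     "A", "C", "G"), nrow = 4, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
    v$alt <- alts[cbind(match(v$ref, rownames(alts)),
                        sample(1:3, nv, replace = TRUE))]
    v$true_region <- tab$region
    ## population presence: shared in all four with the configured
    ## probability, otherwise a random non-empty proper subset
    all4 <- stats::runif(nv) < config$share_all_prob
    npop <- length(pops)
    pres <- matrix(FALSE, nv, npop, dimnames = list(NULL, pops))
    pres[all4, ] <- TRUE
    some <- which(!all4)
    nsub <- sample(seq_len(npop - 1L), length(some), replace = TRUE)
    for (i in seq_along(some))
        pres[some[i], sample.int(npop, nsub[i])] <- TRUE
    ism <- tab$region %in% c("seed", "mature")
    mpar <- config$beta_mature; ppar <- config$beta_precursor
    for (j in seq_len(npop)) {
        mcols(v)[[paste0("presence.", pops[j])]] <- pres[, j]
        f <- rep(NA_real_, nv)
        f[pres[, j] & ism] <- stats::rbeta(sum(pres[, j] & ism),
                                           mpar[1], mpar[2])
        f[pres[, j] & !ism] <- stats::rbeta(sum(pres[, j] & !ism),
                                            ppar[1], ppar[2])
        mcols(v)[[paste0("freq.", pops[j])]] <- f
    }
    truth <- table(factor(tab$region,
                          levels = c("seed", "mature", "precursor", "flank")))
    list(variants = v, truth = as.list(truth))
}

#' Write variants to per-population VCF files
#'
#' Emits one minimal VCF 4.2 file per population containing the
#' variants present in that population, with the population
#' alternative-allele frequency in the `AF` INFO field.
#'
#' @param variants Variant `GRanges` from [simulateVariants()].
#' @param dir Output directory.
#' @param populations Population labels (default: all `presence.*`
#'   columns found).
#' @return Named character vector of written file paths.
#' @export
writePopulationVcfs <- function(variants, dir,
                                populations = NULL) {
    if (is.null(populations))
        populations <- sub("^presence\\.", "",
                           grep("^presence\\.", colnames(mcols(variants)),
                                value = TRUE))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (pop in populations) {
        keep <- mcols(variants)[[paste0("presence.", pop)]]
        v <- variants[keep]
        f <- mcols(v)[[paste0("freq.", pop)]]
        path <- file.path(dir, paste0(pop, ".vcf"))
        hdr <- c("##fileformat=VCFv4.2",
                 paste0("##INFO=<ID=AF,Number=A,Type=Float,",
                        "Description=\"Allele Frequency\">"),
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", sep = "\t"))
        body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tAF=%.6f",
                        as.character(seqnames(v)), start(v), v$vid,
                        v$ref, v$alt, f)
        writeLines(c(hdr, body), path)
        paths[pop] <- path
    }
    paths
}

#' Write UTR models as BED12
#'
#' @param utrs A [UTRSet-class] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeUtrBed <- function(utrs, path) {
    bl <- utrBlocks(utrs)
    lines <- vapply(names(bl), function(tx) {
        b <- bl[[tx]]
        cs <- min(start(b)) - 1L   # BED 0-based
        ce <- max(end(b))
        sizes <- paste0(paste(width(b), collapse = ","), ",")
        offs <- paste0(paste(start(b) - 1L - cs, collapse = ","), ",")
        paste(as.character(seqnames(b))[1], cs, ce, tx, 0L,
              as.character(strand(b))[1], cs, cs, "0", length(b),
              sizes, offs, sep = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
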