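#' Pipeline run configuration
#'
#' A single configuration drives every pipeline stage. Values can come
#' from a YAML file, from `...` overrides, or from the defaults below;
#' unknown keys are rejected. The configuration is echoed into the
#' output directory by every stage so runs are self-describing.
#'
#' @param path Optional YAML file with configuration values.
#' @param ... Named overrides applied on top of the file.
#' @return A list of class `RunConfig`.
#' @export
pipelineConfig <- function(path = NULL, ...) {
    defaults <- list(
        seed = 1L,
        out_dir = "mirvar_out",
        populations = c("EDM", "ADM", "EWB", "AWB"),
        flank_orientation = "strand",   # or "genomic"
        percent_mode = "round",         # or "truncate"
        condition_free = FALSE,
        p_threshold = 0.05,
        q_threshold = 0.1,
        presence_threshold = 0.5)
    cfg <- defaults
    if (!is.null(path)) {
        if (!file.exists(path)) stop("config file not found: ", path)
        cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
    }
    dots <- list(...)
    unknown <- setdiff(c(names(dots),
                         if (!is.null(path)) names(yaml::read_yaml(path))),
                       names(defaults))
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, dots)
    class(cfg) <- "RunConfig"
    cfg
}

.echoConfig <- function(config, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
}

.tsv <- function(x, path)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Generate a complete synthetic fixture bundle
#'
#' Simulates a reference (genome, miRNA annotation, 3'UTRs), a variant
#' set and a half-sib cohort, and writes them in the formats the rest
#' of the pipeline reads: FASTA, GFF3, BED12, per-population VCFs and
#' TSV tables, plus ground-truth tables for validation.
#'
#' @param config A [pipelineConfig()] list.
#' @param sim A [simConfig()] list for the generator.
#' @return Invisibly, the output directory.
#' @export
runSimulate <- function(config = pipelineConfig(), sim = simConfig()) {
    dir <- config$out_dir
    .echoConfig(config, dir)
    set.seed(config$seed)
    ref <- simulateReference(sim)
    vars <- simulateVariants(ref, sim)
    Biostrings::writeXStringSet(ref$genome, file.path(dir, "genome.fa"))
    writeMiRNAGff3(ref$loci, file.path(dir, "mirna.gff3"))
    writeUtrBed(ref$utrs, file.path(dir, "utrs.bed"))
    writePopulationVcfs(vars$variants, dir, sim$populations)
    .tsv(ref$truth, file.path(dir, "truth_sites.tsv"))
    .tsv(as.data.frame(mcols(vars$variants))[, c("vid", "true_region")],
         file.path(dir, "truth_regions.tsv"))
    cohort <- simulateCohort(sim)
    .tsv(data.frame(individual = seq_len(nrow(cohort$G)), cohort$G,
                    check.names = FALSE),
         file.path(dir, "genotypes.tsv"))
    .tsv(data.frame(individual = seq_len(nrow(cohort$G)), cohort$covariates,
                    y = cohort$y), file.path(dir, "phenotypes.tsv"))
    .tsv(data.frame(individual = seq_len(nrow(cohort$G)), cohort$expression,
                    check.names = FALSE), file.path(dir, "expression.tsv"))
    .tsv(data.frame(probe_id = rownames(cohort$presence),
                    cohort$presence, check.names = FALSE),
         file.path(dir, "presence.tsv"))
    .tsv(cohort$probe_gene, file.path(dir, "probe_gene.tsv"))
    .tsv(cohort$ct, file.path(dir, "ct.tsv"))
    message("simulate: wrote fixture bundle to ", dir)
    invisible(dir)
}

.requireFiles <- function(dir, files) {
    for (f in files) {
        p <- file.path(dir, f)
        if (!file.exists(p))
            stop("missing input ", p, " (run runSimulate first or point ",
                 "out_dir at a fixture bundle)")
    }
}

#' Scan 3'UTRs for seed-match sites and build target pairs
#'
#' Reads the genome, miRNA annotation and UTR models from the output
#' directory, scans every mature-arm seed against every spliced UTR
#' and writes the site table (spliced and genomic coordinates, BED6+)
#' and the miRNA-mRNA target-pair table.
#'
#' @param config A [pipelineConfig()] list.
#' @return Invisibly, the site table.
#' @export
runScan <- function(config = pipelineConfig()) {
    dir <- config$out_dir
    .requireFiles(dir, c("genome.fa", "mirna.gff3", "utrs.bed"))
    genome <- readFastaSeqs(file.path(dir, "genome.fa"))
    loci <- readMiRNAGff3(file.path(dir, "mirna.gff3"), genome)
    utrs <- readUtrBed(file.path(dir, "utrs.bed"), genome)
    seeds <- as.character(seedSequences(loci))
    sites <- scanSeedSites(utrs, seeds)
    blocks <- siteGenomicBlocks(utrs, sites)
    pairs <- buildTargetPairs(sites, txGenes(utrs))
    .tsv(sites, file.path(dir, "sites.tsv"))
    if (length(blocks)) {
        bed <- data.frame(chrom = as.character(seqnames(blocks)),
                          start = start(blocks) - 1L, end = end(blocks),
                          name = paste(blocks$arm_id, blocks$transcript_id,
                                       blocks$site_type, sep = "|"),
                          score = 0L,
                          strand = as.character(strand(blocks)))
        utils::write.table(bed, file.path(dir, "sites.bed"), sep = "\t",
                           quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    .tsv(pairs, file.path(dir, "target_pairs.tsv"))
    message("scan: ", nrow(sites), " sites, ", nrow(pairs), " target pairs")
    invisible(sites)
}

#' Annotate miRNA SNPs and summarise sharing and frequencies
#'
#' Reads the miRNA annotation and the per-population VCFs, merges the
#' populations, classifies every in-hairpin SNP into a hairpin
#' sub-region and writes the annotated table, the cross-population
#' sharing summary and the per-population frequency spectra.
#'
#' @param config A [pipelineConfig()] list.
#' @return Invisibly, the annotated variant table.
#' @export
runAnnotate <- function(config = pipelineConfig()) {
    dir <- config$out_dir
    pops <- config$populations
    .requireFiles(dir, c("mirna.gff3", paste0(pops, ".vcf")))
    loci <- readMiRNAGff3(file.path(dir, "mirna.gff3"))
    varlist <- lapply(pops, function(p)
        readVcfSnps(file.path(dir, paste0(p, ".vcf")), p))
    names(varlist) <- pops
    variants <- mergeVariantPopulations(varlist)
    ann <- annotateVariants(loci, variants)
    .tsv(ann, file.path(dir, "annotated_snps.tsv"))
    sh <- sharingSummary(ann, pops)
    .tsv(data.frame(subset = names(sh$subsets), n = sh$subsets),
         file.path(dir, "sharing.tsv"))
    spec <- do.call(rbind, lapply(pops, function(p) {
        fs <- frequencySpectrum(ann, p)
        data.frame(population = p, bin_lo = fs$breaks[-length(fs$breaks)],
                   bin_hi = fs$breaks[-1], n = fs$counts)
    }))
    .tsv(spec, file.path(dir, "frequency_spectrum.tsv"))
    message("annotate: ", nrow(ann), " miRNA SNPs; ", sh$shared_all,
            " (", sh$shared_all_pct, "%) shared in all populations")
    invisible(ann)
}

#' Region, position and flanking density statistics
#'
#' Computes the per-region density table (SNPs per 100 bp), the
#' per-mature-position profile, the flanking-bin profile and the
#' seed-vs-mature rank-sum comparison on per-arm densities, writing
#' each as TSV.
#'
#' @param config A [pipelineConfig()] list.
#' @return Invisibly, the region density table.
#' @export
runDensity <- function(config = pipelineConfig()) {
    dir <- config$out_dir
    pops <- config$populations
    .requireFiles(dir, c("mirna.gff3", "annotated_snps.tsv",
                         paste0(pops, ".vcf")))
    loci <- readMiRNAGff3(file.path(dir, "mirna.gff3"))
    ann <- utils::read.delim(file.path(dir, "annotated_snps.tsv"))
    varlist <- lapply(pops, function(p)
        readVcfSnps(file.path(dir, paste0(p, ".vcf")), p))
    names(varlist) <- pops
    variants <- mergeVariantPopulations(varlist)
    dens <- regionDensityTable(ann, loci)
    posd <- positionDensity(ann, loci)
    flank <- flankingDensity(loci, variants,
                             orientation = config$flank_orientation)
    arm <- perArmDensities(ann, loci)
    rs <- rankSumTest(arm$seed_density, arm$mature_density)
    .tsv(dens, file.path(dir, "region_density.tsv"))
    .tsv(posd, file.path(dir, "position_density.tsv"))
    .tsv(flank, file.path(dir, "flank_density.tsv"))
    writeLines(sprintf("seed_vs_mature\tU=%g\tP=%g\tmethod=%s",
                       rs$U, rs$p, rs$method),
               file.path(dir, "ranksum.txt"))
    message("density: ", paste(sprintf("%s=%.2f", dens$region, dens$D),
                               collapse = " "))
    invisible(dens)
}

#' Mixed-model association of the simulated causal SNP
#'
#' Reads the cohort tables written by [runSimulate()], rebuilds the
#' kinship from the background SNPs and scans the causal SNP against
#' the expressed probes (and the lipid-like trait), writing the
#' association table plus counts of nominal (P) and FDR-significant
#' (q) hits.
#'
#' @param config A [pipelineConfig()] list.
#' @return Invisibly, the association table.
#' @export
runAssoc <- function(config = pipelineConfig()) {
    dir <- config$out_dir
    .requireFiles(dir, c("genotypes.tsv", "phenotypes.tsv",
                         "expression.tsv", "presence.tsv"))
    G <- as.matrix(utils::read.delim(file.path(dir, "genotypes.tsv"),
                                     check.names = FALSE)[, -1])
    phen <- utils::read.delim(file.path(dir, "phenotypes.tsv"))
    expr <- as.matrix(utils::read.delim(file.path(dir, "expression.tsv"),
                                        check.names = FALSE)[, -1])
    pres <- utils::read.delim(file.path(dir, "presence.tsv"),
                              check.names = FALSE)
    presence <- as.matrix(pres[, -1])
    rownames(presence) <- pres$probe_id
    keep <- filterExpressedProbes(presence)
    bg <- grep("^bg", colnames(G), value = TRUE)
    K <- centeredKinship(G[, bg, drop = FALSE])
    W <- stats::model.matrix(~ batch + farm, phen)
    x <- G[, "causal"]
    res <- associationScan(expr[, keep, drop = FALSE], x, W, K)
    res$snp_id <- "causal"
    trait <- associationScan(matrix(phen$y, ncol = 1,
                                    dimnames = list(NULL, "trait_y")),
                             x, W, K)
    trait$snp_id <- "causal"
    out <- rbind(res, trait)
    .tsv(out[, c("snp_id", "phenotype", "delta", "se", "p", "q")],
         file.path(dir, "association.tsv"))
    msg <- sprintf("assoc: %d tests, %d at P < %g, %d at q < %g",
                   nrow(out), sum(out$p < config$p_threshold),
                   config$p_threshold, sum(out$q < config$q_threshold),
                   config$q_threshold)
    writeLines(msg, file.path(dir, "assoc_counts.txt"))
    message(msg)
    invisible(out)
}

#' Relative quantification of the simulated qPCR experiment
#'
#' Runs [ddctQuantify()] on the triplicate Ct table written by
#' [runSimulate()], with the GG genotype group as calibrator.
#'
#' @param config A [pipelineConfig()] list.
#' @return Invisibly, the per-sample record table.
#' @export
runDdct <- function(config = pipelineConfig()) {
    dir <- config$out_dir
    .requireFiles(dir, "ct.tsv")
    ct <- utils::read.delim(file.path(dir, "ct.tsv"))
    dq <- ddctQuantify(ct, "target", c("ctrl1", "ctrl2"), "GG")
    .tsv(dq$records, file.path(dir, "ddct.tsv"))
    message(sprintf("ddct: mean Rq AA/GG = %.3f (Welch P = %.3g)",
                    dq$group_means["AA"] / dq$group_means["GG"],
                    dq$test$p))
    invisible(dq$records)
}
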