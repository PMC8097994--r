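#' Filter probes by expression presence
#'
#' A probe is retained when it was called present in at least 50% of
#' samples (a probe present in exactly half is kept: only probes
#' below threshold in *more* than half are discarded). Control probes
#' are always dropped.
#'
#' @param presence Logical matrix, probes x samples (TRUE = expressed
#'   above the detection threshold in that sample).
#' @param is_control Logical vector flagging control probes.
#' @return Character vector of retained probe ids (rownames).
#' @export
filterExpressedProbes <- function(presence, is_control = NULL) {
    stopifnot(is.matrix(presence), !is.null(rownames(presence)))
    if (is.null(is_control)) is_control <- rep(FALSE, nrow(presence))
    keep <- rowMeans(presence) >= 0.5 & !is_control
    rownames(presence)[keep]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q_i = min_{j >= i} p_(j) m / j on the
#' sorted p-values, capped at 1 and mapped back to input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must be in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Candidate target list for each miRNA SNP
#'
#' A probe enters the test list for a SNP when (1) its gene carries at
#' least one canonical 7mer-m8 or 8mer site for an arm of the miRNA
#' harbouring the SNP, (2) the (miRNA, gene) pair is in the supplied
#' experimentally-validated interaction table, and (3) the probe
#' survived the expression-presence filter. Switch either filter off
#' for a condition-free scan of the whole expressed transcriptome.
#'
#' @param snp_mirna `data.frame` with columns `snp_id`, `arm_id`
#'   mapping each genotyped SNP to the mature arm(s) of its miRNA.
#' @param target_pairs Output of [buildTargetPairs()].
#' @param validated `data.frame` with columns `arm_id`, `gene_id` of
#'   validated interactions (e.g. a curated interaction database
#'   export).
#' @param probe_gene `data.frame` with columns `probe_id`, `gene_id`.
#' @param expressed Character vector of probes that passed
#'   [filterExpressedProbes()].
#' @param require_site,require_validated Set to `FALSE` for the
#'   condition-free analysis.
#' @return A `data.frame` with columns `snp_id`, `probe_id`,
#'   `gene_id`.
#' @export
candidateTargets <- function(snp_mirna, target_pairs, validated,
                             probe_gene, expressed,
                             require_site = TRUE, require_validated = TRUE) {
    pg <- probe_gene[probe_gene$probe_id %in% expressed, , drop = FALSE]
    out <- lapply(unique(snp_mirna$snp_id), function(sid) {
        arms <- snp_mirna$arm_id[snp_mirna$snp_id == sid]
        genes <- unique(pg$gene_id)
        if (require_site) {
            with_site <- unique(target_pairs$gene_id[
                target_pairs$arm_id %in% arms])
            genes <- intersect(genes, with_site)
        }
        if (require_validated) {
            val <- unique(validated$gene_id[validated$arm_id %in% arms])
            genes <- intersect(genes, val)
        }
        probes <- pg[pg$gene_id %in% genes, , drop = FALSE]
        if (nrow(probes) == 0L) return(NULL)
        data.frame(snp_id = sid, probe_id = probes$probe_id,
                   gene_id = probes$gene_id, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(snp_id = character(0), probe_id = character(0),
                          gene_id = character(0))
    rownames(out) <- NULL
    out
}

#' Mixed-model association scan over phenotypes
#'
#' For one SNP, fits the alternative and null kinship mixed models for
#' every phenotype (expression probe or trait), tests delta by LRT and
#' adjusts p-values by Benjamini-Hochberg within the scan (the FDR
#' family is all phenotypes tested for this SNP in this tissue).
#' Individuals with missing genotype are excluded from every test of
#' that SNP.
#'
#' @param Y Numeric matrix of phenotypes, individuals x phenotypes
#'   (colnames are probe/trait ids).
#' @param x Genotype dosage vector (0/1/2, NA allowed).
#' @param W Fixed-effect design matrix including the intercept.
#' @param K Kinship matrix.
#' @return A `data.frame` with columns `phenotype`, `delta`, `se`,
#'   `p`, `q`, sorted by `p`.
#' @export
associationScan <- function(Y, x, W, K) {
    Y <- as.matrix(Y)
    keep <- !is.na(x)
    Y <- Y[keep, , drop = FALSE]
    W <- as.matrix(W)[keep, , drop = FALSE]
    K <- K[keep, keep]
    x <- x[keep]
    Keig <- eigenKinship(K)
    res <- lapply(seq_len(ncol(Y)), function(j) {
        y <- Y[, j]
        ok <- !is.na(y)
        fitA <- fitLMM(y[ok], W[ok, , drop = FALSE], x[ok],
                       Keig = if (all(ok)) Keig else NULL,
                       K = if (all(ok)) NULL else K[ok, ok])
        fit0 <- fitLMM(y[ok], W[ok, , drop = FALSE],
                       Keig = if (all(ok)) Keig else NULL,
                       K = if (all(ok)) NULL else K[ok, ok])
        lrt <- lrtTest(fitA, fit0)
        data.frame(phenotype = colnames(Y)[j], delta = fitA@delta,
                   se = fitA@se, p = lrt$p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$q <- bhAdjust(out$p)
    out <- out[order(out$p), ]
    rownames(out) <- NULL
    out
}

#' One-sided hypergeometric pathway enrichment
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the overlap seen between the hit list and the
#' set, given the universe; Benjamini-Hochberg adjustment across
#' sets.
#'
#' @param hits Character vector of hit genes (subset of `universe`).
#' @param pathways Named list of character vectors (gene sets, subsets
#'   of `universe`).
#' @param universe Character vector of all testable genes.
#' @return A `data.frame` with `pathway`, `overlap`, `size`,
#'   `n_hits`, `p`, `q`, ordered by `p`.
#' @export
hypergeomEnrichment <- function(hits, pathways, universe) {
    if (length(universe) == 0L) stop("empty universe")
    hits <- intersect(unique(hits), universe)
    rows <- lapply(names(pathways), function(pw) {
        set <- intersect(unique(pathways[[pw]]), universe)
        ov <- length(intersect(hits, set))
        p <- stats::phyper(ov - 1, length(set),
                           length(universe) - length(set),
                           length(hits), lower.tail = FALSE)
        data.frame(pathway = pw, overlap = ov, size = length(set),
                   n_hits = length(hits), p = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- bhAdjust(out$p)
    out <- out[order(out$p), ]
    rownames(out) <- NULL
    out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of
#' freedom, two-sided. The degenerate case of two zero-variance
#' samples with equal means returns t = 0, p = 1 (flagged).
#'
#' @param xs,ys Numeric samples, each of size >= 2.
#' @return A list with `t`, `df`, `p`, `degenerate`.
#' @export
welchTest <- function(xs, ys) {
    stopifnot(length(xs) >= 2L, length(ys) >= 2L)
    if (stats::var(xs) == 0 && stats::var(ys) == 0) {
        if (mean(xs) == mean(ys))
            return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
        return(list(t = sign(mean(xs) - mean(ys)) * Inf, df = NA_real_,
                    p = 0, degenerate = TRUE))
    }
    tt <- stats::t.test(xs, ys, var.equal = FALSE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, degenerate = FALSE)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample: the mean Ct of the technical triplicates is taken per
#' gene; dCt is the target mean Ct minus the arithmetic mean of the
#' control-gene mean Cts (equivalent to normalising expression by the
#' geometric mean of the controls); ddCt subtracts the mean dCt of
#' the calibrator genotype group; Rq = 2^-ddCt. Groups are compared
#' with [welchTest()] on log2 Rq (= -ddCt).
#'
#' @param ct `data.frame` with columns `sample`, `group`, `gene`,
#'   `ct` (one row per technical replicate).
#' @param target Target gene name.
#' @param controls Character vector of endogenous control gene names.
#' @param calibrator_group Genotype group used as calibrator.
#' @return A list with `records` (per-sample `data.frame`: `sample`,
#'   `group`, `ct_target`, `ct_control`, `dct`, `ddct`, `rq`,
#'   `log2_rq`), `group_means` (mean Rq per group) and `test`
#'   (Welch comparison of the two groups on log2 Rq).
#' @export
ddctQuantify <- function(ct, target, controls, calibrator_group) {
    stopifnot(all(c("sample", "group", "gene", "ct") %in% colnames(ct)))
    if (!all(controls %in% ct$gene))
        stop("missing control gene(s): ",
             paste(setdiff(controls, ct$gene), collapse = ", "))
    if (!target %in% ct$gene) stop("missing target gene ", target)
    samples <- unique(ct$sample)
    rows <- lapply(samples, function(s) {
        sub <- ct[ct$sample == s, , drop = FALSE]
        ctt <- mean(sub$ct[sub$gene == target])
        ctc <- mean(vapply(controls, function(g)
            mean(sub$ct[sub$gene == g]), numeric(1)))
        data.frame(sample = s, group = sub$group[1],
                   ct_target = ctt, ct_control = ctc, dct = ctt - ctc,
                   stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, rows)
    cal <- rec$dct[rec$group == calibrator_group]
    if (length(cal) == 0L) stop("no samples in calibrator group ",
                                calibrator_group)
    rec$ddct <- rec$dct - mean(cal)
    rec$rq <- 2^(-rec$ddct)
    rec$log2_rq <- -rec$ddct
    groups <- unique(rec$group)
    gm <- vapply(groups, function(g) mean(rec$rq[rec$group == g]), numeric(1))
    names(gm) <- groups
    test <- NULL
    other <- setdiff(groups, calibrator_group)
    if (length(other) == 1L &&
        sum(rec$group == other) >= 2L &&
        sum(rec$group == calibrator_group) >= 2L)
        test <- welchTest(rec$log2_rq[rec$group == other],
                          rec$log2_rq[rec$group == calibrator_group])
    list(records = rec, group_means = gm, test = test)
}
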