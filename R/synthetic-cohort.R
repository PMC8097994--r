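#' Simulate a five-sire half-sib cohort with known truth
#'
#' Genotypes are gene-dropped from a small set of sires mated to
#' unrelated dams: each offspring receives one allele from one of its
#' sire's two haplotypes and one from the population at the founder
#' frequency, which induces the half-sib kinship structure the mixed
#' model must absorb. One causal miRNA SNP plus background SNPs are
#' produced; phenotypes follow y = W alpha + x delta + u + e with
#' u ~ MVN(0, sigma_g^2 K) at the configured heritability. Expression
#' phenotypes for probes targeted by the causal miRNA carry the
#' genotype effect in the repressive direction (homozygous-alternative
#' lower); other probes are null. Presence flags and triplicate qPCR
#' Ct tables (with the configured fold between homozygous groups) are
#' generated for downstream filtering and ddCt quantification.
#'
#' @param config A [simConfig()] list.
#' @param n_probes Number of expression probes (first `n_target_probes`
#'   are causal-miRNA targets).
#' @param n_target_probes Number of probes whose genes are targets of
#'   the causal miRNA.
#' @return A list with `G` (dosage matrix, individuals x SNPs; column
#'   `causal` is the tested SNP), `K` (centered kinship from the
#'   background SNPs), `covariates` (`data.frame` of batch and farm),
#'   `W` (design matrix), `y` (one lipid-like trait with effect
#'   `delta_true`), `expression` (individuals x probes, log2 scale),
#'   `presence` (probes x individuals logical), `probe_gene`,
#'   `ct` (long triplicate Ct table for the causal target gene) and
#'   `truth` (list of the generating parameters).
#' @export
simulateCohort <- function(config = simConfig(), n_probes = 40L,
                           n_target_probes = 5L) {
    n <- config$n_individuals
    ns <- config$n_sires
    p <- config$n_background_snps
    ## founder allele frequencies; causal SNP kept common
    fq <- stats::rbeta(p, 2, 2)
    fq_causal <- stats::runif(1, 0.3, 0.6)
    sire <- sample(rep_len(seq_len(ns), n))
    sire_hap <- array(stats::rbinom(ns * 2L * (p + 1L), 1L,
                                    rep(c(fq, fq_causal), each = ns * 2L)),
                      dim = c(ns, 2L, p + 1L))
    pick <- matrix(sample(1:2, n * (p + 1L), replace = TRUE), n, p + 1L)
    G <- matrix(0L, n, p + 1L)
    for (j in seq_len(p + 1L)) {
        fa <- sire_hap[cbind(sire, pick[, j], j)]
        fr <- if (j <= p) fq[j] else fq_causal
        G[, j] <- fa + stats::rbinom(n, 1L, fr)
    }
    colnames(G) <- c(sprintf("bg%04d", seq_len(p)), "causal")
    K <- centeredKinship(G[, seq_len(p), drop = FALSE])
    x <- G[, "causal"]
    ## fixed effects: batch (4) and farm (3)
    covariates <- data.frame(
        batch = factor(sample(paste0("b", 1:4), n, replace = TRUE)),
        farm = factor(sample(paste0("f", 1:3), n, replace = TRUE)))
    W <- stats::model.matrix(~ batch + farm, covariates)
    alpha <- c(10, stats::rnorm(ncol(W) - 1L, 0, 0.3))
    ## variance components at the target heritability (sigma_e^2 = 1)
    sg2 <- config$h2 / (1 - config$h2)
    Kc <- chol(K + diag(1e-8, n))
    drawU <- function() sqrt(sg2) * drop(crossprod(Kc, stats::rnorm(n)))
    y <- drop(W %*% alpha) + x * config$delta_true + drawU() + stats::rnorm(n)
    ## expression matrix: target probes repressed per alt allele
    probes <- sprintf("probe%03d", seq_len(n_probes))
    genes <- sprintf("gene%03d", seq_len(n_probes))
    expr <- matrix(NA_real_, n, n_probes, dimnames = list(NULL, probes))
    dexpr <- -log2(config$expression_fold) / 2   # per-allele effect
    for (j in seq_len(n_probes)) {
        eff <- if (j <= n_target_probes) dexpr else 0
        expr[, j] <- 8 + drop(W %*% (alpha * 0.05)) + x * eff +
            drawU() * 0.5 + stats::rnorm(n, 0, 0.5)
    }
    ## presence flags: last two probes fall below the 50% threshold
    presence <- matrix(TRUE, n_probes, n, dimnames = list(probes, NULL))
    if (n_probes >= 2L) {
        low <- (n_probes - 1L):n_probes
        for (j in low)
            presence[j, ] <- stats::runif(n) < 0.3
    }
    ## triplicate Ct table for the first target gene, GG vs AA samples
    gg <- which(x == 0L)
    aa <- which(x == 2L)
    ctrows <- list()
    for (s in c(gg, aa)) {
        grp <- if (s %in% gg) "GG" else "AA"
        dct_true <- 5 - log2(config$expression_fold) * (grp == "AA")
        ctc <- 20 + stats::rnorm(1, 0, 0.1)
        for (g in c("target", "ctrl1", "ctrl2")) {
            base <- if (g == "target") ctc + dct_true else ctc
            ctrows[[length(ctrows) + 1L]] <- data.frame(
                sample = paste0("s", s), group = grp, gene = g,
                ct = base + stats::rnorm(3, 0, config$ct_sd))
        }
    }
    ct <- do.call(rbind, ctrows)
    list(G = G, K = K, covariates = covariates, W = W, y = y,
         expression = expr, presence = presence,
         probe_gene = data.frame(probe_id = probes, gene_id = genes),
         ct = ct,
         truth = list(delta_true = config$delta_true, h2 = config$h2,
                      expression_fold = config$expression_fold,
                      n_target_probes = n_target_probes,
                      fq_causal = fq_causal, sire = sire, alpha = alpha,
                      chol_K = Kc, sg2 = sg2))
}

#' Draw a fresh phenotype from a simulated cohort's generating model
#'
#' Used for replicate studies (null calibration, power, parameter
#' recovery) without regenerating genotypes: y = W alpha + x delta +
#' u + e with the cohort's kinship and heritability.
#'
#' @param cohort Output of [simulateCohort()].
#' @param delta Allele substitution effect for the draw (0 for a null
#'   replicate).
#' @return Numeric phenotype vector.
#' @export
simulatePhenotype <- function(cohort, delta = 0) {
    n <- length(cohort$y)
    u <- sqrt(cohort$truth$sg2) *
        drop(crossprod(cohort$truth$chol_K, stats::rnorm(n)))
    drop(cohort$W %*% cohort$truth$alpha) + cohort$G[, "causal"] * delta +
        u + stats::rnorm(n)
}
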