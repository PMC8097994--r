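#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand findOverlaps countOverlaps
#' @importFrom IRanges IRanges IRangesList overlapsAny subsetByOverlaps
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame metadata metadata<-
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq matchPattern
#' @importFrom BiocGenerics unlist sort
NULL

#' MiRNALoci: annotated miRNA hairpins and their mature arms
#'
#' Container for a set of miRNA genes. Each locus is a hairpin
#' (pre-miRNA) interval carrying one or two mature arms on the same
#' strand. Arm sequences are stored written 5'->3' in miRNA orientation,
#' so position 1 is the anchor nucleotide bound by the Argonaute MID
#' domain and positions 2-8 form the seed.
#'
#' @slot hairpins A [GenomicRanges::GRanges] of hairpin intervals, named
#'   by locus identifier.
#' @slot arms A [GenomicRanges::GRanges] of mature-arm intervals with
#'   metadata columns `arm_id`, `locus_id` and `sequence` (the arm
#'   sequence 5'->3', DNA alphabet, or `NA` when no genome was supplied).
#'
#' @section Validity:
#' Every arm must lie within its hairpin, share its strand, not overlap
#' a sibling arm, and be at least 8 nt long (otherwise no seed is
#' definable). When present, `sequence` must match the arm width.
#'
#' @name MiRNALoci-class
#' @aliases MiRNALoci-class
#' @exportClass MiRNALoci
setClass("MiRNALoci",
         slots = c(hairpins = "GRanges", arms = "GRanges"))

setValidity("MiRNALoci", function(object) {
    hp <- object@hairpins
    ar <- object@arms
    msg <- character(0)
    if (length(hp) && (is.null(names(hp)) || anyDuplicated(names(hp))))
        msg <- c(msg, "hairpins must carry unique names (locus ids)")
    need <- c("arm_id", "locus_id", "sequence")
    if (!all(need %in% colnames(mcols(ar))))
        return("arms must have metadata columns arm_id, locus_id, sequence")
    if (anyDuplicated(ar$arm_id))
        msg <- c(msg, "duplicated arm_id")
    bad <- !(ar$locus_id %in% names(hp))
    if (any(bad))
        msg <- c(msg, paste0("arm with unresolvable locus: ",
                             paste(ar$arm_id[bad], collapse = ", ")))
    if (length(msg)) return(msg)
    if (length(ar)) {
        parent <- hp[ar$locus_id]
        contained <- as.character(seqnames(ar)) == as.character(seqnames(parent)) &
            start(ar) >= start(parent) & end(ar) <= end(parent)
        if (!all(contained))
            msg <- c(msg, paste0("arm outside its hairpin at locus: ",
                                 paste(unique(ar$locus_id[!contained]), collapse = ", ")))
        if (!all(as.character(strand(ar)) == as.character(strand(parent))))
            msg <- c(msg, "arm strand differs from hairpin strand")
        if (any(width(ar) < 8))
            msg <- c(msg, "mature arm shorter than 8 nt (no seed definable)")
        for (lid in unique(ar$locus_id[duplicated(ar$locus_id)])) {
            sub <- ar[ar$locus_id == lid]
            if (length(sub) > 2)
                msg <- c(msg, paste0("locus ", lid, " has more than two arms"))
            hits <- findOverlaps(sub, sub)
            if (length(hits) > length(sub))
                msg <- c(msg, paste0("overlapping arms at locus ", lid))
        }
        seqs <- ar$sequence
        has <- !is.na(seqs)
        if (any(nchar(seqs[has]) != width(ar)[has]))
            msg <- c(msg, "arm sequence length does not match interval width")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MiRNALoci object
#'
#' @param hairpins `GRanges` of hairpin intervals named by locus id.
#' @param arms `GRanges` of mature arms with metadata columns `arm_id`,
#'   `locus_id` and optionally `sequence` (filled with `NA` if absent).
#' @return A [MiRNALoci-class] object.
#' @examples
#' hp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 190), strand = "+")
#' names(hp) <- "mir-1"
#' ar <- GenomicRanges::GRanges("chr1", IRanges::IRanges(110, 131), strand = "+",
#'                              arm_id = "miR-1-5p", locus_id = "mir-1",
#'                              sequence = strrep("A", 22))
#' MiRNALoci(hp, ar)
#' @export
MiRNALoci <- function(hairpins, arms) {
    if (!"sequence" %in% colnames(mcols(arms)))
        arms$sequence <- NA_character_
    new("MiRNALoci", hairpins = hairpins, arms = arms)
}

setMethod("show", "MiRNALoci", function(object) {
    cat("MiRNALoci with", length(object@hairpins), "hairpins and",
        length(object@arms), "mature arms\n")
    n2 <- sum(table(object@arms$locus_id) == 2)
    cat("  two-arm loci:", n2, "| strand(+):",
        sum(as.character(strand(object@hairpins)) == "+"), "\n")
})

#' @describeIn MiRNALoci-class number of hairpin loci
#' @param x,object A `MiRNALoci` object.
#' @export
setMethod("length", "MiRNALoci", function(x) length(x@hairpins))

#' Accessors for MiRNALoci
#'
#' `hairpins()` returns the hairpin intervals, `matureArms()` the mature
#' arm intervals (with `arm_id`, `locus_id`, `sequence` metadata) and
#' `seedSequences()` the 7-nt seeds (arm positions 2-8) as a
#' [Biostrings::DNAStringSet] named by arm id.
#'
#' @param x A [MiRNALoci-class] object.
#' @return A `GRanges` (`hairpins`, `matureArms`) or `DNAStringSet`
#'   (`seedSequences`).
#' @export
hairpins <- function(x) x@hairpins

#' @rdname hairpins
#' @export
matureArms <- function(x) x@arms

#' @rdname hairpins
#' @export
seedSequences <- function(x) {
    ar <- x@arms
    if (any(is.na(ar$sequence)))
        stop("arm sequences are not populated; re-read annotation with a genome")
    seeds <- DNAStringSet(vapply(ar$sequence, extractSeed, character(1),
                                 USE.NAMES = FALSE))
    names(seeds) <- ar$arm_id
    seeds
}

#' UTRSet: spliced 3'UTR models
#'
#' A set of 3'UTR gene models: per-transcript genomic blocks plus the
#' spliced mRNA-sense sequence. Blocks are stored in genomic order; for
#' minus-strand transcripts the spliced sequence runs from the last
#' block backwards (reverse-complemented), i.e. always 5'->3' of the
#' mRNA.
#'
#' @slot blocks A [GenomicRanges::GRangesList], one element per
#'   transcript (named by transcript id), blocks in genomic order.
#' @slot sequence A [Biostrings::DNAStringSet] of spliced sequences,
#'   parallel to `blocks`.
#' @slot txGene Character vector mapping transcript id -> gene id.
#'
#' @name UTRSet-class
#' @exportClass UTRSet
setClass("UTRSet",
         slots = c(blocks = "GRangesList", sequence = "DNAStringSet",
                   txGene = "character"))

setValidity("UTRSet", function(object) {
    msg <- character(0)
    ids <- names(object@blocks)
    if (length(object@blocks) && (is.null(ids) || anyDuplicated(ids)))
        msg <- c(msg, "blocks must be named by unique transcript ids")
    if (length(object@sequence) != length(object@blocks))
        msg <- c(msg, "sequence and blocks lengths differ")
    if (!identical(names(object@sequence), ids))
        msg <- c(msg, "sequence names must match block names")
    wid <- sum(width(object@blocks))
    if (any(Biostrings::width(object@sequence) != wid))
        msg <- c(msg, "spliced sequence length != sum of block lengths")
    ov <- vapply(object@blocks, function(b)
        length(IRanges::reduce(b)) < length(b) ||
            sum(width(IRanges::reduce(b))) < sum(width(b)), logical(1))
    if (any(ov)) msg <- c(msg, "overlapping blocks within a transcript")
    if (length(msg)) msg else TRUE
})

#' Construct a UTRSet
#'
#' @param blocks `GRangesList` of genomic blocks per transcript, named
#'   by transcript id, in genomic order, all blocks of a transcript on
#'   one chromosome and strand.
#' @param sequence `DNAStringSet` of spliced mRNA-sense sequences,
#'   parallel to `blocks`.
#' @param txGene named character vector transcript id -> gene id; by
#'   default each transcript is its own gene.
#' @return A [UTRSet-class] object.
#' @export
UTRSet <- function(blocks, sequence, txGene = NULL) {
    if (is.null(txGene)) {
        txGene <- names(blocks)
        names(txGene) <- names(blocks)
    }
    new("UTRSet", blocks = blocks, sequence = sequence,
        txGene = txGene[names(blocks)])
}

setMethod("show", "UTRSet", function(object) {
    cat("UTRSet with", length(object@blocks), "transcripts;",
        "total spliced length", sum(Biostrings::width(object@sequence)), "nt\n")
})

#' @describeIn UTRSet-class number of transcripts
#' @param x,object A `UTRSet`.
#' @export
setMethod("length", "UTRSet", function(x) length(x@blocks))

#' Accessors for UTRSet
#'
#' @param x A [UTRSet-class] object.
#' @return `utrBlocks()` the per-transcript `GRangesList`;
#'   `splicedSeqs()` the spliced sequences; `txGenes()` the transcript
#'   to gene map.
#' @export
utrBlocks <- function(x) x@blocks

#' @rdname utrBlocks
#' @export
splicedSeqs <- function(x) x@sequence

#' @rdname utrBlocks
#' @export
txGenes <- function(x) x@txGene

#' LMMFit: a fitted univariate kinship mixed model
#'
#' Maximum-likelihood fit of y = W alpha + x delta + u + e with
#' u ~ MVN(0, lambda tau^-1 K). `lambda` is the ratio of genetic to
#' residual variance, `sigma2` the residual variance (tau^-1), `delta`
#' the allele substitution effect (NA for the null fit).
#'
#' @slot lambda Variance ratio (>= 0).
#' @slot sigma2 Residual variance tau^-1.
#' @slot beta Fixed-effect estimates (last element is delta when a
#'   genotype vector was included).
#' @slot delta Allele substitution effect, `NA_real_` for null fits.
#' @slot se Standard error of delta (NA for null fits).
#' @slot logLik Maximised ML log-likelihood.
#' @slot n Number of individuals.
#' @slot hasX Whether a genotype term was fitted.
#'
#' @name LMMFit-class
#' @exportClass LMMFit
setClass("LMMFit",
         slots = c(lambda = "numeric", sigma2 = "numeric", beta = "numeric",
                   delta = "numeric", se = "numeric", logLik = "numeric",
                   n = "integer", hasX = "logical"))

setMethod("show", "LMMFit", function(object) {
    cat(sprintf("LMMFit (n = %d): lambda = %.4g, sigma2 = %.4g, logL = %.4f\n",
                object@n, object@lambda, object@sigma2, object@logLik))
    if (object@hasX)
        cat(sprintf("  delta = %.4f (se %.4f)\n", object@delta, object@se))
})
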