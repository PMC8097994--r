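#' Read a FASTA file into a normalised DNAStringSet
#'
#' Sequences are uppercased and RNA alphabet (U) converted to DNA (T)
#' so that all downstream matching happens in one alphabet. The
#' original alphabet of each record is kept in
#' `metadata(x)$alphabet` (`"DNA"` or `"RNA"`).
#'
#' @param path Path to a FASTA file; lines may wrap arbitrarily and
#'   lowercase is allowed.
#' @return A [Biostrings::DNAStringSet] named by record id (first
#'   whitespace-delimited token of the header).
#' @export
readFastaSeqs <- function(path) {
    raw <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(raw))
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
    chars <- toupper(as.character(raw))
    alphabet <- ifelse(grepl("U", chars, fixed = TRUE), "RNA", "DNA")
    chars <- gsub("U", "T", chars, fixed = TRUE)
    out <- DNAStringSet(chars)
    names(out) <- ids
    names(alphabet) <- ids
    metadata(out)$alphabet <- alphabet
    out
}

#' Reverse-complement a nucleotide string
#'
#' Strict DNA alphabet: ambiguity codes are rejected here because the
#' site scanner handles ambiguous bases by never matching them, so they
#' must not reach seed arithmetic.
#'
#' @param seq A character string over A, C, G, T (case-insensitive).
#' @return The reverse complement, uppercase.
#' @examples
#' revComp("AAAC") # "GTTT"
#' @export
revComp <- function(seq) {
    stopifnot(is.character(seq), length(seq) == 1L)
    if (nchar(seq) == 0L) return("")
    up <- toupper(seq)
    if (grepl("[^ACGT]", up))
        stop("ambiguous or non-DNA base in sequence: ", seq)
    as.character(reverseComplement(DNAString(up)))
}

## splice genomic blocks into an mRNA-sense sequence
.spliceSeq <- function(genome, blocks) {
    chrom <- as.character(seqnames(blocks))[1]
    if (!chrom %in% names(genome))
        stop("chromosome not in genome: ", chrom)
    chrseq <- genome[[chrom]]
    if (max(end(blocks)) > length(chrseq) || min(start(blocks)) < 1L)
        stop("block outside chromosome ", chrom)
    pieces <- lapply(seq_along(blocks), function(i)
        subseq(chrseq, start(blocks)[i], end(blocks)[i]))
    sq <- do.call(Biostrings::xscat, pieces)
    if (as.character(strand(blocks))[1] == "-")
        sq <- reverseComplement(sq)
    sq
}

#' Read miRNA hairpin/mature annotation from GFF3
#'
#' Expects the miRBase/miRCarta GFF3 dialect: hairpins as
#' `miRNA_primary_transcript` features and mature arms as `miRNA`
#' features referencing their hairpin through the `Parent` attribute.
#' When a genome is supplied, arm sequences (5'->3' in miRNA
#' orientation, i.e. reverse-complemented for minus-strand loci) are
#' extracted and stored.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional [Biostrings::DNAStringSet] of chromosome
#'   sequences used to populate arm sequences.
#' @return A [MiRNALoci-class] object.
#' @export
readMiRNAGff3 <- function(path, genome = NULL) {
    g <- rtracklayer::import(path, format = "gff3")
    hp <- g[g$type == "miRNA_primary_transcript"]
    ar <- g[g$type == "miRNA"]
    hp_ids <- if (!is.null(hp$ID)) hp$ID else hp$Name
    if (any(is.na(hp_ids))) stop("hairpin feature without ID")
    parents <- vapply(ar$Parent, function(p)
        if (length(p)) p[[1]] else NA_character_, character(1))
    if (any(is.na(parents)))
        stop("mature miRNA feature without resolvable Parent")
    if (!all(parents %in% hp_ids))
        stop("Parent not found among hairpins: ",
             paste(setdiff(parents, hp_ids), collapse = ", "))
    hairpins <- GRanges(seqnames(hp), IRanges(start(hp), end(hp)),
                        strand = strand(hp))
    names(hairpins) <- hp_ids
    arm_ids <- if (!is.null(ar$ID)) ar$ID else ar$Name
    arms <- GRanges(seqnames(ar), IRanges(start(ar), end(ar)), strand = strand(ar))
    arms$arm_id <- arm_ids
    arms$locus_id <- parents
    arms$sequence <- NA_character_
    if (!is.null(genome) && length(arms)) {
        arms$sequence <- vapply(seq_along(arms), function(i)
            as.character(.spliceSeq(genome, arms[i])), character(1))
    }
    MiRNALoci(hairpins, arms)
}

#' Write MiRNALoci back to GFF3
#'
#' Emits the same miRBase-style dialect that [readMiRNAGff3()] reads,
#' so a write/read round trip reproduces intervals and strands exactly.
#'
#' @param loci A [MiRNALoci-class] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMiRNAGff3 <- function(loci, path) {
    hp <- hairpins(loci)
    ar <- matureArms(loci)
    ghp <- GRanges(seqnames(hp), IRanges(start(hp), end(hp)), strand = strand(hp),
                   type = "miRNA_primary_transcript", ID = names(hp),
                   Name = names(hp))
    gar <- GRanges(seqnames(ar), IRanges(start(ar), end(ar)), strand = strand(ar),
                   type = "miRNA", ID = ar$arm_id, Name = ar$arm_id)
    ghp$Parent <- IRanges::CharacterList(rep(list(character(0)), length(ghp)))
    gar$Parent <- IRanges::CharacterList(as.list(ar$locus_id))
    rtracklayer::export(c(ghp, gar), path, format = "gff3")
    invisible(path)
}

#' Read biallelic SNPs from a VCF file
#'
#' Keeps only single-base substitutions: multiallelic records are split
#' into one variant per alternative allele, and any allele that is not
#' a single A/C/G/T base (InDels, symbolic alleles) is dropped.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param population Optional population label; when given, a logical
#'   column `presence.<label>` (all `TRUE`) and, if the VCF carries an
#'   `AF` INFO field, a numeric column `freq.<label>` are attached.
#' @return A width-1 [GenomicRanges::GRanges] with metadata columns
#'   `vid`, `ref`, `alt` (and per-population columns, see above).
#' @export
readVcfSnps <- function(path, population = NULL) {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    vcf <- VariantAnnotation::expand(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(rr$REF)
    alt <- as.character(rr$ALT)
    keep <- nchar(ref) == 1L & nchar(alt) == 1L &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
        ref != alt
    rr <- rr[keep]
    if (length(rr) == 0L) {
        out <- GRanges(vid = character(0), ref = character(0),
                       alt = character(0))
        if (!is.null(population)) {
            mcols(out)[[paste0("presence.", population)]] <- logical(0)
            mcols(out)[[paste0("freq.", population)]] <- numeric(0)
        }
        return(out)
    }
    out <- GRanges(seqnames(rr), IRanges(start(rr), start(rr)), strand = "*")
    out$vid <- if (is.null(names(rr))) character(length(rr)) else names(rr)
    out$ref <- ref[keep]
    out$alt <- alt[keep]
    if (!is.null(population)) {
        mcols(out)[[paste0("presence.", population)]] <- rep(TRUE, length(out))
        af <- tryCatch(VariantAnnotation::info(vcf)$AF, error = function(e) NULL)
        if (!is.null(af))
            mcols(out)[[paste0("freq.", population)]] <- as.numeric(af)[keep]
    }
    names(out) <- NULL
    out
}

#' Merge per-population variant sets
#'
#' Combines variant `GRanges` read with [readVcfSnps()] for several
#' populations into one set keyed by (chrom, pos, ref, alt), with
#' logical `presence.<pop>` columns (FALSE where the variant was absent
#' from that population's VCF) and any `freq.<pop>` columns carried
#' over (NA where absent).
#'
#' @param varlist Named list of variant `GRanges`, one per population.
#' @return A merged variant `GRanges`.
#' @export
mergeVariantPopulations <- function(varlist) {
    stopifnot(is.list(varlist), !is.null(names(varlist)))
    keyed <- lapply(varlist, function(v)
        paste(seqnames(v), start(v), v$ref, v$alt, sep = ":"))
    stripped <- lapply(varlist, function(v) {
        mcols(v) <- mcols(v)[c("vid", "ref", "alt")]
        v
    })
    pooled <- do.call(c, unname(stripped))
    pooledk <- unlist(keyed, use.names = FALSE)
    out <- pooled[!duplicated(pooledk)]
    outk <- pooledk[!duplicated(pooledk)]
    for (pop in names(varlist)) {
        mcols(out)[[paste0("presence.", pop)]] <- outk %in% keyed[[pop]]
        fcol <- paste0("freq.", pop)
        if (fcol %in% colnames(mcols(varlist[[pop]]))) {
            f <- rep(NA_real_, length(out))
            m <- match(outk, keyed[[pop]])
            f[!is.na(m)] <- mcols(varlist[[pop]])[[fcol]][m[!is.na(m)]]
            mcols(out)[[fcol]] <- f
        }
    }
    BiocGenerics::sort(out, ignore.strand = TRUE)
}

#' Read 3'UTR models from BED12
#'
#' Assembles the spliced mRNA-sense sequence of each transcript from
#' its blocks; minus-strand transcripts are reverse-complemented so
#' the stored sequence always runs 5'->3' of the mRNA.
#'
#' @param path Path to a BED12 file; the `name` field is used as
#'   transcript id.
#' @param genome A [Biostrings::DNAStringSet] of chromosome sequences.
#' @param txGene Optional named character vector mapping transcript id
#'   to gene id.
#' @return A [UTRSet-class] object.
#' @export
readUtrBed <- function(path, genome, txGene = NULL) {
    b <- rtracklayer::import(path, format = "bed")
    if (is.null(b$name) || anyDuplicated(b$name))
        stop("BED12 records must carry unique names")
    blocks <- lapply(seq_along(b), function(i) {
        bl <- b$blocks[[i]]
        if (is.null(bl) || length(bl) == 0L)
            bl <- IRanges(1L, width(b)[i])
        GRanges(seqnames(b)[i],
                IRanges::shift(bl, start(b)[i] - 1L),
                strand = strand(b)[i])
    })
    names(blocks) <- b$name
    blocks <- GRangesList(blocks)
    seqs <- DNAStringSet(lapply(blocks, function(bl) .spliceSeq(genome, bl)))
    UTRSet(blocks, seqs, txGene)
}

#' Map a genomic position to its mature-miRNA position
#'
#' Position 1 is the 5' end of the mature miRNA: the lowest genomic
#' coordinate on the plus strand, the highest on the minus strand.
#'
#' @param arm A length-1 `GRanges` (a row of [matureArms()]).
#' @param gpos Vector of genomic positions (1-based) within the arm.
#' @return Integer vector of mature positions p in 1..L.
#' @examples
#' arm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 122), strand = "-")
#' genomicToMaturePosition(arm, 122) # 1 (5' end of a minus-strand arm)
#' @export
genomicToMaturePosition <- function(arm, gpos) {
    stopifnot(length(arm) == 1L)
    if (any(gpos < start(arm) | gpos > end(arm)))
        stop("position outside mature arm")
    if (as.character(strand(arm)) == "-")
        as.integer(end(arm) - gpos + 1L)
    else
        as.integer(gpos - start(arm) + 1L)
}
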