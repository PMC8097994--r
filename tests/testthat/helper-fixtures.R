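# Programmatic fixtures shared across test files.

library(GenomicRanges)
library(Biostrings)

# a MiRNALoci object from compact per-locus specs:
# list(list(chrom, hp = c(start, end), strand,
#           arms = list(list(id, start, end)), id))
makeLoci <- function(specs, genome = NULL) {
    hp <- GRanges(vapply(specs, `[[`, "", "chrom"),
                  IRanges(vapply(specs, function(s) s$hp[1], 0),
                          vapply(specs, function(s) s$hp[2], 0)),
                  strand = vapply(specs, `[[`, "", "strand"))
    names(hp) <- vapply(specs, `[[`, "", "id")
    rows <- do.call(rbind, lapply(specs, function(s)
        do.call(rbind, lapply(s$arms, function(a)
            data.frame(chrom = s$chrom, start = a$start, end = a$end,
                       strand = s$strand, arm_id = a$id, locus_id = s$id)))))
    arms <- GRanges(rows$chrom, IRanges(rows$start, rows$end),
                    strand = rows$strand, arm_id = rows$arm_id,
                    locus_id = rows$locus_id)
    arms$sequence <- NA_character_
    if (!is.null(genome)) {
        sq <- substr(as.character(genome)[rows$chrom], rows$start, rows$end)
        minus <- rows$strand == "-"
        sq[minus] <- vapply(sq[minus], oracleRevComp, "", USE.NAMES = FALSE)
        arms$sequence <- unname(sq)
    }
    MiRNALoci(hp, arms)
}

# single-chromosome UTRSet built directly from blocks and a genome
makeUtr <- function(genome, chrom, blockStarts, blockEnds, strand,
                    tx = "tx1") {
    b <- GRanges(chrom, IRanges(blockStarts, blockEnds), strand = strand)
    chrseq <- as.character(genome)[[chrom]]
    pieces <- substr(rep(chrseq, length(blockStarts)), blockStarts, blockEnds)
    spl <- paste(pieces, collapse = "")
    if (strand == "-") spl <- oracleRevComp(spl)
    bl <- GRangesList(stats::setNames(list(b), tx))
    sq <- DNAStringSet(spl)
    names(sq) <- tx
    UTRSet(bl, sq)
}

makeVariants <- function(chrom, pos, vid = sprintf("v%03d", seq_along(pos)),
                         ref = "A", alt = "G") {
    GRanges(chrom, IRanges(pos, width = 1), strand = "*",
            vid = vid, ref = rep_len(ref, length(pos)),
            alt = rep_len(alt, length(pos)))
}

writeTempFasta <- function(seqs, width = 60) {
    path <- withr::local_tempfile(fileext = ".fa",
                                  .local_envir = parent.frame())
    lines <- unlist(lapply(names(seqs), function(id) {
        s <- seqs[[id]]
        c(paste0(">", id),
          substring(s, seq(1, nchar(s), width),
                    pmin(seq(1, nchar(s), width) + width - 1, nchar(s))))
    }))
    writeLines(lines, path)
    path
}

writeTempVcf <- function(rows) {
    path <- withr::local_tempfile(fileext = ".vcf",
                                  .local_envir = parent.frame())
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##INFO=<ID=AF,Number=A,Type=Float,",
                    "Description=\"Allele Frequency\">"),
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"))
    writeLines(c(hdr, rows), path)
    path
}

# loci whose arm/hairpin length totals reproduce the published region
# universe: 409 arms (327 x 22 nt + 82 x 21 nt = 8916 nt) over 370
# hairpins (305 x 84 bp + 65 x 85 bp = 31145 bp), 39 two-arm loci
makeStudyScaleLoci <- function() {
    arm_lens <- c(rep(22L, 327), rep(21L, 82))
    hp_lens <- c(rep(84L, 305), rep(85L, 65))
    two <- c(rep(TRUE, 39), rep(FALSE, 331))
    specs <- vector("list", 370)
    ai <- 1L
    for (i in 1:370) {
        hs <- 1001L
        he <- hs + hp_lens[i] - 1L
        if (two[i]) {
            L1 <- arm_lens[ai]; L2 <- arm_lens[ai + 1L]
            arms <- list(list(id = sprintf("arm%03d-5p", i), start = hs + 1L,
                              end = hs + L1),
                         list(id = sprintf("arm%03d-3p", i), start = he - L2,
                              end = he - 1L))
            ai <- ai + 2L
        } else {
            L1 <- arm_lens[ai]
            arms <- list(list(id = sprintf("arm%03d-5p", i), start = hs + 1L,
                              end = hs + L1))
            ai <- ai + 1L
        }
        specs[[i]] <- list(chrom = sprintf("c%03d", i), hp = c(hs, he),
                           strand = if (i %% 2) "+" else "-", arms = arms,
                           id = sprintf("loc%03d", i))
    }
    makeLoci(specs)
}
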