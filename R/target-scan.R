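#' Extract the 7-nt seed of a mature miRNA
#'
#' The seed is positions 2 to 8 (1-based) from the 5' end of the
#' mature miRNA, the primary determinant of target binding.
#'
#' @param sequence Mature miRNA sequence (character, 5'->3', >= 8 nt).
#' @return The 7-nt seed string.
#' @examples
#' extractSeed("ACGTACGTACGTACGTACGTAC") # "CGTACGT"
#' @export
extractSeed <- function(sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (is.na(sequence) || nchar(sequence) < 8L)
        stop("mature sequence shorter than 8 nt: no seed definable")
    toupper(substr(sequence, 2L, 8L))
}

#' Scan spliced 3'UTRs for canonical seed-match sites
#'
#' For each arm seed, the reverse complement of the seed is searched
#' along each spliced UTR sequence. Every exact occurrence is a
#' 7mer-m8 site (Watson-Crick pairing of miRNA positions 2-8); if the
#' base immediately 3' of the match on the mRNA (target position 1)
#' is an A the site is promoted to 8mer and extended by that base.
#' Overlapping occurrences are all reported; windows containing
#' ambiguous bases never match; matching is case-insensitive. A match
#' ending at the last UTR base (no downstream base) stays 7mer-m8.
#'
#' @param utrs A [UTRSet-class] object.
#' @param seeds Named character vector of 7-nt seeds (names are arm
#'   ids), e.g. from [seedSequences()].
#' @return A `data.frame` with columns `arm_id`, `transcript_id`,
#'   `start`, `end` (1-based inclusive positions in the spliced UTR;
#'   width 7 for 7mer-m8, 8 for 8mer) and `site_type`.
#' @export
scanSeedSites <- function(utrs, seeds) {
    seeds <- vapply(seeds, function(s) toupper(as.character(s)), character(1))
    if (any(nchar(seeds) != 7L))
        stop("seeds must be exactly 7 nt")
    if (any(grepl("[^ACGT]", seeds)))
        stop("seed with non-ACGT characters")
    seqs <- splicedSeqs(utrs)
    txids <- names(utrBlocks(utrs))
    res <- vector("list", length(seeds) * length(seqs))
    k <- 0L
    for (a in seq_along(seeds)) {
        motif <- revComp(seeds[a])
        for (t in seq_along(seqs)) {
            m <- matchPattern(motif, seqs[[t]], fixed = TRUE)
            if (length(m) == 0L) next
            st <- BiocGenerics::start(m)
            en <- BiocGenerics::end(m)
            L <- length(seqs[[t]])
            nextbase <- rep("", length(m))
            ok <- en < L
            if (any(ok))
                nextbase[ok] <- vapply(which(ok), function(i)
                    as.character(subseq(seqs[[t]], en[i] + 1L, en[i] + 1L)),
                    character(1))
            is8 <- nextbase == "A"
            k <- k + 1L
            res[[k]] <- data.frame(
                arm_id = names(seeds)[a], transcript_id = txids[t],
                start = st, end = ifelse(is8, en + 1L, en),
                site_type = ifelse(is8, "8mer", "7mer-m8"),
                stringsAsFactors = FALSE)
        }
    }
    if (k == 0L)
        return(data.frame(arm_id = character(0), transcript_id = character(0),
                          start = integer(0), end = integer(0),
                          site_type = character(0)))
    out <- do.call(rbind, res[seq_len(k)])
    out <- out[order(out$arm_id, out$transcript_id, out$start), ]
    rownames(out) <- NULL
    out
}

#' Project a spliced-UTR interval onto the genome
#'
#' Maps positions `start..end` of the spliced (mRNA-sense) sequence of
#' a transcript through its blocks, honouring strand. A site spanning
#' a block junction yields two or more genomic blocks.
#'
#' @param utrs A [UTRSet-class] object.
#' @param transcript_id Transcript to project through.
#' @param start,end 1-based inclusive interval in the spliced sequence.
#' @return A `GRanges` of genomic blocks (sorted by genomic position)
#'   whose widths sum to `end - start + 1`.
#' @export
mapSiteToGenome <- function(utrs, transcript_id, start, end) {
    bl <- utrBlocks(utrs)[[transcript_id]]
    if (is.null(bl)) stop("unknown transcript: ", transcript_id)
    L <- sum(width(bl))
    sstart <- start
    send <- end
    if (sstart < 1L || send > L || sstart > send)
        stop("site coordinates outside spliced sequence")
    minus <- as.character(strand(bl))[1] == "-"
    ## blocks in transcript (5'->3') order
    txbl <- if (minus) rev(bl) else bl
    bstarts <- BiocGenerics::start(txbl)
    bends <- BiocGenerics::end(txbl)
    offs <- cumsum(c(0L, width(txbl)))
    pieces <- list()
    for (i in seq_along(txbl)) {
        bs <- offs[i] + 1L   # spliced start of this block
        be <- offs[i + 1L]   # spliced end
        s <- max(sstart, bs)
        e <- min(send, be)
        if (s > e) next
        if (minus) {
            gend <- bends[i] - (s - bs)
            gstart <- bends[i] - (e - bs)
        } else {
            gstart <- bstarts[i] + (s - bs)
            gend <- bstarts[i] + (e - bs)
        }
        pieces[[length(pieces) + 1L]] <-
            GRanges(seqnames(txbl)[i], IRanges(gstart, gend), strand = strand(txbl)[i])
    }
    BiocGenerics::sort(do.call(c, pieces), ignore.strand = TRUE)
}

#' Genomic blocks for a table of seed-match sites
#'
#' Convenience wrapper over [mapSiteToGenome()]: one `GRanges` of
#' blocks for every row of a [scanSeedSites()] table, with metadata
#' columns identifying the site.
#'
#' @param utrs A [UTRSet-class] object.
#' @param sites A site table from [scanSeedSites()].
#' @return A `GRanges` with columns `site_idx` (row of `sites`),
#'   `arm_id`, `transcript_id`, `site_type`.
#' @export
siteGenomicBlocks <- function(utrs, sites) {
    if (nrow(sites) == 0L)
        return(GRanges(site_idx = integer(0), arm_id = character(0),
                       transcript_id = character(0), site_type = character(0)))
    out <- lapply(seq_len(nrow(sites)), function(i) {
        g <- mapSiteToGenome(utrs, sites$transcript_id[i],
                             sites$start[i], sites$end[i])
        g$site_idx <- i
        g$arm_id <- sites$arm_id[i]
        g$transcript_id <- sites$transcript_id[i]
        g$site_type <- sites$site_type[i]
        g
    })
    do.call(c, out)
}

#' Build the miRNA-mRNA target-pair table
#'
#' One row per (arm, transcript) pair with at least one canonical
#' site, with per-type site counts, ordered by (arm_id,
#' transcript_id).
#'
#' @param sites A site table from [scanSeedSites()].
#' @param txGene Optional named character vector transcript -> gene.
#' @return A `data.frame` with columns `arm_id`, `gene_id`,
#'   `transcript_id`, `n_7mer_m8`, `n_8mer`.
#' @export
buildTargetPairs <- function(sites, txGene = NULL) {
    if (nrow(sites) == 0L)
        return(data.frame(arm_id = character(0), gene_id = character(0),
                          transcript_id = character(0),
                          n_7mer_m8 = integer(0), n_8mer = integer(0)))
    key <- interaction(sites$arm_id, sites$transcript_id, drop = TRUE)
    agg <- do.call(rbind, lapply(split(sites, key), function(s)
        data.frame(arm_id = s$arm_id[1], transcript_id = s$transcript_id[1],
                   n_7mer_m8 = sum(s$site_type == "7mer-m8"),
                   n_8mer = sum(s$site_type == "8mer"),
                   stringsAsFactors = FALSE)))
    agg$gene_id <- if (is.null(txGene)) agg$transcript_id else
        unname(txGene[agg$transcript_id])
    agg <- agg[order(agg$arm_id, agg$transcript_id),
               c("arm_id", "gene_id", "transcript_id", "n_7mer_m8", "n_8mer")]
    rownames(agg) <- NULL
    agg
}

#' Intersect variants with predicted binding sites
#'
#' A variant hits a site when its position lies inside any genomic
#' block of that site. The reported offset is 0-based in the target's
#' 5'->3' (mRNA) orientation, so offset 0 is the first base of the
#' site on the mRNA.
#'
#' @param variants Variant `GRanges` (width 1, with `vid`).
#' @param blocks Site blocks from [siteGenomicBlocks()].
#' @param utrs The [UTRSet-class] the sites were scanned in.
#' @param sites The site table the blocks were derived from.
#' @return A `data.frame` with columns `vid`, `site_idx`, `arm_id`,
#'   `transcript_id`, `site_type`, `offset`.
#' @export
intersectVariantsWithSites <- function(variants, blocks, utrs, sites) {
    hits <- findOverlaps(variants, blocks, ignore.strand = TRUE)
    if (length(hits) == 0L)
        return(data.frame(vid = character(0), site_idx = integer(0),
                          arm_id = character(0), transcript_id = character(0),
                          site_type = character(0), offset = integer(0)))
    out <- lapply(seq_along(hits), function(h) {
        v <- variants[queryHits(hits)[h]]
        b <- blocks[subjectHits(hits)[h]]
        i <- b$site_idx
        ## spliced coordinate of the variant, then offset within the site
        sp <- .genomicToSpliced(utrs, b$transcript_id, start(v))
        data.frame(vid = v$vid, site_idx = i, arm_id = b$arm_id,
                   transcript_id = b$transcript_id, site_type = b$site_type,
                   offset = sp - sites$start[i], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out <- out[order(out$site_idx, out$offset), ]
    rownames(out) <- NULL
    out
}

## spliced (1-based, mRNA 5'->3') coordinate of a genomic position
.genomicToSpliced <- function(utrs, transcript_id, gpos) {
    bl <- utrBlocks(utrs)[[transcript_id]]
    minus <- as.character(strand(bl))[1] == "-"
    txbl <- if (minus) rev(bl) else bl
    bstarts <- BiocGenerics::start(txbl)
    bends <- BiocGenerics::end(txbl)
    offs <- cumsum(c(0L, width(txbl)))
    for (i in seq_along(txbl)) {
        if (gpos >= bstarts[i] && gpos <= bends[i]) {
            within <- if (minus) bends[i] - gpos else gpos - bstarts[i]
            return(offs[i] + within + 1L)
        }
    }
    stop("position not in any block of ", transcript_id)
}
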