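test_that("FASTA reading normalises wrapping, case and RNA alphabet", {
    p1 <- writeTempFasta(list(a = "ACGT"))
    expect_equal(as.character(readFastaSeqs(p1)), c(a = "ACGT"))

    path <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">a", "ac", "gu"), path)
    x <- readFastaSeqs(path)
    expect_equal(as.character(x), c(a = "ACGT"))
    expect_equal(unname(S4Vectors::metadata(x)$alphabet["a"]), "RNA")

    p2 <- writeTempFasta(list(a = "ACGT", b = "TTTT"))
    expect_equal(names(readFastaSeqs(p2)), c("a", "b"))

    path2 <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">a", "ACGT", ">a", "TTTT"), path2)
    expect_error(readFastaSeqs(path2), "duplicate.*a")
})

test_that("reverse complement handles examples and is an involution", {
    expect_equal(revComp("ACGT"), "ACGT")
    expect_equal(revComp("AAAC"), "GTTT")
    expect_equal(revComp(""), "")
    expect_error(revComp("ACGN"), "ambiguous")
    set.seed(11)
    for (i in 1:1000) {
        s <- randSeq(sample(1:40, 1))
        expect_identical(revComp(revComp(s)), s)
        expect_identical(revComp(s), oracleRevComp(s))
    }
})

test_that("GFF3 miRNA annotation is parsed with correct coordinates", {
    path <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\tsrc\tmiRNA_primary_transcript\t100\t190\t.\t+\t.\tID=mirA",
        "chr1\tsrc\tmiRNA\t110\t131\t.\t+\t.\tID=mirA-5p;Parent=mirA",
        "chr2\tsrc\tmiRNA_primary_transcript\t500\t590\t.\t-\t.\tID=mirB",
        "chr2\tsrc\tmiRNA\t505\t526\t.\t-\t.\tID=mirB-3p;Parent=mirB",
        "chr2\tsrc\tmiRNA\t560\t581\t.\t-\t.\tID=mirB-5p;Parent=mirB"),
        path)
    loci <- readMiRNAGff3(path)
    hp <- hairpins(loci)
    expect_equal(start(hp["mirA"]), 100)
    expect_equal(end(hp["mirA"]), 190)
    ar <- matureArms(loci)
    a5 <- ar[ar$arm_id == "mirA-5p"]
    expect_equal(c(start(a5), end(a5), width(a5)), c(110, 131, 22))
    armB <- ar[ar$locus_id == "mirB"]
    expect_equal(as.character(strand(armB)), c("-", "-"))
})

test_that("a minus-strand hairpin row with 1-based bounds reads back as printed", {
    # ssc-miR-326: SSC9 9,581,944..9,582,034, strand -
    path <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "9\tsrc\tmiRNA_primary_transcript\t9581944\t9582034\t.\t-\t.\tID=ssc-mir-326",
        "9\tsrc\tmiRNA\t9581990\t9582011\t.\t-\t.\tID=ssc-miR-326-3p;Parent=ssc-mir-326"),
        path)
    hp <- hairpins(readMiRNAGff3(path))
    expect_equal(start(hp), 9581944)
    expect_equal(end(hp), 9582034)
    expect_equal(as.character(strand(hp)), "-")
    expect_equal(width(hp), 9582034 - 9581944 + 1)
})

test_that("malformed miRNA annotation is rejected", {
    bad_parent <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\tsrc\tmiRNA_primary_transcript\t100\t190\t.\t+\t.\tID=mirA",
        "chr1\tsrc\tmiRNA\t110\t131\t.\t+\t.\tID=x-5p;Parent=nope"), bad_parent)
    expect_error(readMiRNAGff3(bad_parent), "nope")

    outside <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\tsrc\tmiRNA_primary_transcript\t100\t190\t.\t+\t.\tID=mirA",
        "chr1\tsrc\tmiRNA\t185\t206\t.\t+\t.\tID=x-5p;Parent=mirA"), outside)
    expect_error(readMiRNAGff3(outside), "mirA")

    short_arm <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\tsrc\tmiRNA_primary_transcript\t100\t190\t.\t+\t.\tID=mirA",
        "chr1\tsrc\tmiRNA\t110\t114\t.\t+\t.\tID=x-5p;Parent=mirA"), short_arm)
    expect_error(readMiRNAGff3(short_arm), "8 nt")
})

test_that("GFF3 write/read round trip preserves intervals and strands", {
    set.seed(21)
    cfg <- simConfig(n_loci = 12, n_two_arm = 4, n_utrs = 0)
    ref <- simulateReference(cfg)
    path <- withr::local_tempfile(fileext = ".gff3")
    writeMiRNAGff3(ref$loci, path)
    back <- readMiRNAGff3(path)
    expect_identical(as.data.frame(hairpins(back))[1:5],
                     as.data.frame(hairpins(ref$loci))[1:5])
    ar0 <- as.data.frame(matureArms(ref$loci))
    ar1 <- as.data.frame(matureArms(back))
    o0 <- order(ar0$arm_id); o1 <- order(ar1$arm_id)
    cols <- c("seqnames", "start", "end", "strand", "arm_id", "locus_id")
    expect_equal(ar1[o1, cols], ar0[o0, cols], ignore_attr = TRUE)
})

test_that("VCF reading keeps only single-base substitutions", {
    p <- writeTempVcf(c("chr1\t101\trs1\tA\tG\t.\tPASS\tAF=0.2"))
    v <- readVcfSnps(p)
    expect_equal(start(v), 101)
    expect_equal(v$ref, "A")
    expect_equal(v$alt, "G")

    p2 <- writeTempVcf(c("chr1\t150\trs2\tA\tG,TT\t.\tPASS\tAF=0.3,0.1"))
    v2 <- readVcfSnps(p2, population = "EDM")
    expect_equal(length(v2), 1L)   # the InDel allele is dropped
    expect_equal(v2$alt, "G")
    expect_equal(v2$freq.EDM, 0.3)
    expect_true(v2$presence.EDM)

    p3 <- writeTempVcf(character(0))
    expect_equal(length(readVcfSnps(p3)), 0L)
})

test_that("BED12 UTR models splice sequence correctly on both strands", {
    genome <- DNAStringSet(c(chrA = "AATTACGGTCAACCG"))
    bed <- withr::local_tempfile(fileext = ".bed")
    # single-block plus strand: chrA:3-8 (1-based)
    writeLines("chrA\t2\t8\ttxP\t0\t+\t2\t2\t0\t1\t6,\t0,", bed)
    u <- readUtrBed(bed, genome)
    expect_equal(as.character(splicedSeqs(u)[["txP"]]), "TTACGG")

    # single-block minus strand over "AACCG" -> "CGGTT"
    bed2 <- withr::local_tempfile(fileext = ".bed")
    writeLines("chrA\t10\t15\ttxM\t0\t-\t10\t10\t0\t1\t5,\t0,", bed2)
    u2 <- readUtrBed(bed2, genome)
    expect_equal(as.character(splicedSeqs(u2)[["txM"]]), "CGGTT")

    # two blocks: length equals the sum of block sizes
    bed3 <- withr::local_tempfile(fileext = ".bed")
    writeLines("chrA\t0\t15\ttx2\t0\t+\t0\t0\t0\t2\t4,6,\t0,9,", bed3)
    u3 <- readUtrBed(bed3, genome)
    expect_equal(nchar(as.character(splicedSeqs(u3)[["tx2"]])), 10)
    expect_equal(as.character(splicedSeqs(u3)[["tx2"]]),
                 paste0(substr("AATTACGGTCAACCG", 1, 4),
                        substr("AATTACGGTCAACCG", 10, 15)))
})

test_that("mature-position mapping follows the 5' end on each strand", {
    plus <- GRanges("c", IRanges(101, 122), strand = "+")
    expect_equal(genomicToMaturePosition(plus, 101), 1L)
    minus <- GRanges("c", IRanges(101, 122), strand = "-")
    expect_equal(genomicToMaturePosition(minus, 122), 1L)
    expect_equal(genomicToMaturePosition(minus, 101), 22L)
    expect_error(genomicToMaturePosition(plus, 123), "outside")

    # bijection onto 1..L for both strands
    for (st in c("+", "-")) {
        arm <- GRanges("c", IRanges(101, 122), strand = st)
        p <- genomicToMaturePosition(arm, 101:122)
        expect_setequal(p, 1:22)
    }
})

test_that("MiRNALoci validity enforces the structural invariants", {
    hp <- GRanges("chr1", IRanges(100, 190), strand = "+")
    names(hp) <- "locA"
    ok <- GRanges("chr1", IRanges(110, 131), strand = "+",
                  arm_id = "a1", locus_id = "locA", sequence = NA_character_)
    expect_s4_class(MiRNALoci(hp, ok), "MiRNALoci")
    wrong_strand <- ok
    strand(wrong_strand) <- "-"
    expect_error(MiRNALoci(hp, wrong_strand), "strand")
    overlapping <- c(ok, GRanges("chr1", IRanges(120, 141), strand = "+",
                                 arm_id = "a2", locus_id = "locA",
                                 sequence = NA_character_))
    expect_error(MiRNALoci(hp, overlapping), "verlapping")
})
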