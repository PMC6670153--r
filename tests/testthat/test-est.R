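estFixture <- function() {
    readEstTable(system.file("extdata", "synthetic_ests.tsv",
                             package = "IntraProm"))
}

paperAccessions <- c("BU689215", "BU684610", "AW204843", "BX111268",
                     "AI863417", "AI798118", "AI810863", "AA984901")

test_that("accession-list selection returns exactly the named records", {
    ests <- estFixture()
    sel <- selectEsts(ests, accessions = paperAccessions)
    expect_equal(nrow(sel), 8L)
    expect_setequal(sel$accession, paperAccessions)
    expect_true(all(sel$strand == "+"))
    expect_error(selectEsts(ests, accessions = c("BU689215", "NOPE123")),
                 "NOPE123")
})

test_that("region/strand selection matches a brute-force interval check", {
    ests <- estFixture()
    region <- grRegion("chr21", 36200000L, 36224800L, "intron5")
    none <- selectEsts(data.frame(accession = "x", chrom = "chr21",
                                  start = 1L, end = 10L, strand = "+"),
                       region = region, strand = "-")
    expect_equal(nrow(none), 0L)
    for (str in c("+", "-", NULL)) {
        sel <- selectEsts(ests, region = region, strand = str)
        want <- ests[ests$chrom == "chr21" & ests$start < 36224800 &
                     ests$end > 36200000 &
                     (if (is.null(str)) TRUE else ests$strand == str), ]
        expect_equal(sel$accession, want$accession)
    }
    set.seed(81)
    for (rep in 1:20) {
        n <- 30L
        s <- sample(0:5000, n, TRUE)
        tab <- data.frame(accession = paste0("e", 1:n), chrom = "chrT",
                          start = s, end = s + sample(50:800, n, TRUE),
                          strand = sample(c("+", "-"), n, TRUE))
        r0 <- sample(0:4000, 1)
        reg <- grRegion("chrT", r0, r0 + 1500L)
        sel <- selectEsts(tab, region = reg)
        want <- vapply(seq_len(n), function(i)
            tab$start[i] < (r0 + 1500) && tab$end[i] > r0, TRUE)
        expect_equal(sel$accession, tab$accession[want])
    }
})

test_that("pairwise alignment reproduces forced examples", {
    id <- pairwiseAlign("ACGTACGT", "ACGTACGT")
    expect_equal(id$score, 8)
    expect_identical(id$a, "ACGTACGT")
    expect_identical(id$b, "ACGTACGT")
    tr <- pairwiseAlign("ACGT", "ACG")
    expect_equal(tr$score, 3)
    expect_identical(tr$a, "ACGT")
    expect_identical(tr$b, "ACG-")
    expect_error(pairwiseAlign("", "ACG"), "non-empty")
})

test_that("overlap alignment score equals exhaustive path enumeration", {
    set.seed(91)
    for (rep in 1:60) {
        a <- randSeq(sample(3:7, 1))
        b <- randSeq(sample(3:7, 1))
        got <- pairwiseAlign(a, b)
        expect_equal(got$score, oracleAlignScore(a, b))
        # returned gapped pair must itself attain the reported score
        ca <- strsplit(got$a, "")[[1]]
        cb <- strsplit(got$b, "")[[1]]
        lead_a <- cumsum(ca != "-") == 0
        lead_b <- cumsum(cb != "-") == 0
        trail_a <- rev(cumsum(rev(ca) != "-") == 0)
        trail_b <- rev(cumsum(rev(cb) != "-") == 0)
        sc <- 0
        for (k in seq_along(ca)) {
            if (ca[k] == "-") {
                if (!(lead_a[k] || trail_a[k])) sc <- sc - 2
            } else if (cb[k] == "-") {
                if (!(lead_b[k] || trail_b[k])) sc <- sc - 2
            } else sc <- sc + if (ca[k] == cb[k]) 1 else -1
        }
        expect_equal(sc, got$score)
        # degapping recovers the inputs
        expect_identical(gsub("-", "", got$a), a)
        expect_identical(gsub("-", "", got$b), b)
    }
})

test_that("overlap alignment score agrees with Biostrings at moderate n", {
    set.seed(92)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    for (rep in 1:15) {
        a <- randSeq(sample(30:120, 1))
        b <- randSeq(sample(30:120, 1))
        ref <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
            substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
        expect_equal(pairwiseAlign(a, b)$score, Biostrings::score(ref))
    }
})

test_that("center-star MSA: identical rows stay gap-free, fragments tile", {
    same <- buildMsa(c(x = "ACGTA", y = "ACGTA", z = "ACGTA"))
    rows <- as.character(as(same, "DNAStringSet"))
    expect_identical(unname(rows), rep("ACGTA", 3))
    # staggered exact fragments of one template reassemble it
    template <- "ACGTACGGTTACGATCCGGATTACAGGT"
    frags <- c(f1 = substr(template, 1, 16),
               f2 = substr(template, 6, 24),
               f3 = substr(template, 12, 28))
    msa <- buildMsa(frags)
    rows <- as.character(as(msa, "DNAStringSet"))
    expect_true(all(nchar(rows) == nchar(rows[1])))
    expect_true(nchar(rows[1]) >= max(nchar(frags)))
    # every row degaps to its input
    expect_identical(unname(vapply(rows, function(r) gsub("-", "", r),
                                   character(1))),
                     unname(frags))
    cons <- callConsensus(msa, minDepth = 1L)
    expect_identical(consensusSequence(cons), template)
    expect_error(buildMsa("ACGT"), "at least 2")
})

test_that("center-star preserves the center's optimal pairwise scores", {
    set.seed(93)
    template <- randSeq(120)
    seqs <- vapply(1:5, function(i) {
        s <- sample(1:60, 1)
        substr(template, s, s + sample(40:60, 1))
    }, character(1))
    names(seqs) <- paste0("e", 1:5)
    msa <- buildMsa(seqs)
    rows <- as.character(as(msa, "DNAStringSet"))
    ctr <- attr(msa, "center")
    for (i in seq_along(seqs)) {
        if (i == ctr) next
        # score of the merged row pair vs the center row, end gaps free
        ca <- strsplit(rows[ctr], "")[[1]]
        cb <- strsplit(rows[i], "")[[1]]
        keep <- !(ca == "-" & cb == "-")
        ca <- ca[keep]; cb <- cb[keep]
        lead_a <- cumsum(ca != "-") == 0
        lead_b <- cumsum(cb != "-") == 0
        trail_a <- rev(cumsum(rev(ca) != "-") == 0)
        trail_b <- rev(cumsum(rev(cb) != "-") == 0)
        sc <- 0
        for (k in seq_along(ca)) {
            if (ca[k] == "-") {
                if (!(lead_a[k] || trail_a[k])) sc <- sc - 2
            } else if (cb[k] == "-") {
                if (!(lead_b[k] || trail_b[k])) sc <- sc - 2
            } else sc <- sc + if (ca[k] == cb[k]) 1 else -1
        }
        expect_equal(sc, pairwiseAlign(seqs[ctr], seqs[i])$score)
    }
})

test_that("consensus calling: unanimity, ties, depth filtering", {
    rows <- c("ACGT-", "ACGA-", "AC--T", "GC--T")
    # col1 {A,A,A,G}: A at 3/4; col3 {G,G}: depth 2; col4 {T,A}: tie -> N
    # col5 {T,T}: depth 2
    cons <- callConsensus(rows, minDepth = 2L, minSupport = 0.5)
    expect_identical(consensusSequence(cons), "ACGNT")
    expect_equal(consensusDepth(cons), c(4L, 4L, 2L, 2L, 2L))
    expect_equal(consensusSupport(cons)[1], 0.75)
    # {A,A,C,C} ties to N even though support reaches 0.5
    expect_identical(consensusSequence(callConsensus(
        c("A", "A", "C", "C"), minDepth = 1L)), "N")
    # depth filter drops shallow columns entirely
    expect_identical(consensusSequence(callConsensus(
        c("AC", "A-"), minDepth = 2L)), "A")
    # below-support columns become N
    expect_identical(consensusSequence(callConsensus(
        c("A", "C", "G"), minDepth = 1L, minSupport = 0.5)), "N")
})

test_that("consensus from noisy simulated ESTs recovers the template", {
    set.seed(94)
    template <- randSeq(600)
    ests <- vapply(1:8, function(i) {
        len <- sample(350:550, 1)
        s <- sample(1:(600 - len + 1), 1)
        ch <- strsplit(substr(template, s, s + len - 1), "")[[1]]
        nerr <- rbinom(1, len, 0.01)
        if (nerr > 0) {
            at <- sample(len, nerr)
            for (q in at)
                ch[q] <- sample(setdiff(c("A", "C", "G", "T"), ch[q]), 1)
        }
        paste(ch, collapse = "")
    }, character(1))
    names(ests) <- paste0("est", 1:8)
    msa <- buildMsa(ests)
    cons <- callConsensus(msa, minDepth = 2L, minSupport = 0.6)
    aln <- localAlign(consensusSequence(cons), template)
    expect_gte(aln$identity, 0.99)
    expect_gte(aln$n_cols, 400)  # covers most of the template
})

test_that("local matching finds substrings exactly and flags negatives", {
    set.seed(95)
    tx <- c(t1 = randSeq(300), t2 = randSeq(300))
    q <- substr(tx[["t2"]], 50, 200)
    hit <- matchConsensus(q, tx)
    expect_identical(hit$transcript, "t2")
    expect_equal(hit$identity, 1.0)
    expect_equal(hit$t_start, 49L)   # 0-based
    expect_equal(hit$t_end, 200L)
    expect_false(hit$below_threshold)
    # a query unrelated to the set matches only short chance islands
    neg <- matchConsensus(randSeq(150), tx)
    expect_lt(neg$score, 40)
    expect_error(matchConsensus("ACGT", character()), "non-empty")
})

test_that("local alignment equals the exhaustive substring-pair oracle", {
    set.seed(96)
    for (rep in 1:25) {
        a <- randSeq(sample(3:5, 1))
        b <- randSeq(sample(3:5, 1))
        expect_equal(localAlign(a, b)$score, oracleLocalScore(a, b))
    }
    # and Biostrings local alignment at moderate n
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    for (rep in 1:10) {
        a <- randSeq(60)
        b <- randSeq(80)
        ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
            substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
        expect_equal(localAlign(a, b)$score, Biostrings::score(ref))
    }
})

test_that("minus-strand ESTs are reverse-complemented into transcript
           orientation", {
    ests <- data.frame(accession = c("p", "m"), chrom = "chrT",
                       start = c(0L, 0L), end = c(4L, 4L),
                       strand = c("+", "-"),
                       sequence = c("ACGT", "GGCA"))
    or <- orientEsts(ests, transcriptStrand = "+")
    expect_identical(unname(or), c("ACGT", "TGCC"))
    or2 <- orientEsts(ests, transcriptStrand = "-")
    expect_identical(unname(or2), c("ACGT", "GGCA"))
})
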