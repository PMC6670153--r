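test_that("module arithmetic: widths, truncation, labels", {
    r <- grRegion("chr21", 0L, 24800L, "intron5")
    m <- makeModules(r, 2500L, geneStrand = "-")
    bins <- moduleBins(m)
    expect_length(bins, 10L)
    expect_equal(width(bins), c(rep(2500L, 9), 2300L))
    # gene-sense labels on a minus-strand gene descend genomically: I..X
    expect_identical(mcols(bins)$label,
                     c("X", "IX", "VIII", "VII", "VI", "V", "IV", "III",
                       "II", "I"))
    expect_identical(moduleLabels(m)[1:3], c("I", "II", "III"))
    gm <- makeModules(r, 2500L, labelOrientation = "genomic")
    expect_identical(mcols(moduleBins(gm))$label[1], "I")

    one <- makeModules(grRegion("chr1", 0L, 2500L), 2500L)
    expect_length(moduleBins(one), 1L)
    expect_identical(mcols(moduleBins(one))$label, "I")

    three <- makeModules(grRegion("chr1", 0L, 6000L), 2500L)
    expect_equal(width(moduleBins(three)), c(2500L, 2500L, 1000L))
    expect_equal(sum(width(moduleBins(three))), 6000L)

    expect_error(makeModules(r, 0L), "moduleWidth")
    expect_error(makeModules(r, -10L), "moduleWidth")
})

test_that("a boundary-spanning hotspot counts in every module it touches", {
    r <- grRegion("chrT", 0L, 5000L)
    m <- makeModules(r, 2500L)
    hs <- hotspotGRanges(data.frame(start = 2400L, end = 2600L,
                                    cell_type = "ct1"))
    tab <- prevalence(countPrevalence(m, hs))
    expect_equal(tab$count, c(1L, 1L))
    # several hotspots of one cell type in one module still contribute 1
    hs2 <- hotspotGRanges(data.frame(start = c(10L, 50L, 100L),
                                     end = c(20L, 70L, 200L),
                                     cell_type = "ct1"))
    tab2 <- prevalence(countPrevalence(m, hs2))
    expect_equal(tab2$count, c(1L, 0L))
})

test_that("zero hotspots give zero counts; cross-chromosome ignored", {
    r <- grRegion("chrT", 0L, 5000L)
    m <- makeModules(r, 2500L)
    tab <- prevalence(countPrevalence(m, hotspotGRanges(data.frame()),
                                      nCellTypes = c(DNASE = 5L)))
    expect_equal(tab$count, c(0L, 0L))
    expect_equal(unique(tab$n_cell_types), 5L)
    hs <- hotspotGRanges(data.frame(start = 0L, end = 100L,
                                    cell_type = "ct1"), chrom = "chrOther")
    expect_warning(p <- countPrevalence(m, hs, nCellTypes = c(DNASE = 1L)),
                   "ignored")
    expect_equal(prevalence(p)$count, c(0L, 0L))
})

test_that("prevalence equals the per-base brute-force oracle", {
    set.seed(101)
    for (rep in 1:60) {
        L <- sample(500:5000, 1)
        w <- sample(100:1500, 1)
        nct <- sample(1:12, 1)
        nhs <- sample(0:30, 1)
        r <- grRegion("chrT", 0L, L)
        m <- makeModules(r, w)
        if (nhs > 0) {
            s <- sample(0:(L - 10L), nhs, replace = TRUE)
            df <- data.frame(start = s,
                             end = pmin(s + sample(1:400, nhs, TRUE), L),
                             cell_type = paste0("ct",
                                 sample(nct, nhs, TRUE)))
        } else df <- data.frame(start = integer(), end = integer(),
                                cell_type = character())
        hs <- hotspotGRanges(df)
        got <- prevalence(countPrevalence(m, hs,
                              nCellTypes = c(DNASE = nct)))
        bins <- moduleBins(m)
        # oracle works in genomic order; table is in label order (same here)
        bins0 <- data.frame(start = start(bins) - 1L, end = end(bins))
        want <- if (nrow(df)) oraclePrevalence(bins0, df)
                else integer(nrow(bins0))
        expect_equal(got$count, want)
    }
})

test_that("prevalence is permutation-invariant and monotone", {
    set.seed(202)
    L <- 8000L
    m <- makeModules(grRegion("chrT", 0L, L), 1000L)
    s <- sample(0:(L - 200L), 40, TRUE)
    df <- data.frame(start = s, end = s + sample(20:600, 40, TRUE),
                     cell_type = paste0("ct", sample(8, 40, TRUE)))
    df$end <- pmin(df$end, L)
    base <- prevalence(countPrevalence(m, hotspotGRanges(df)))
    shuf <- df[sample(nrow(df)), ]
    expect_equal(prevalence(countPrevalence(m, hotspotGRanges(shuf))), base)
    # adding a track never decreases any count
    extra <- rbind(df, data.frame(start = 100L, end = 4000L,
                                  cell_type = "ct_new"))
    more <- prevalence(countPrevalence(m, hotspotGRanges(extra)))
    expect_true(all(more$count >= base$count))
    # widening every hotspot never decreases any count
    wide <- transform(df, start = pmax(start - 300L, 0L),
                      end = pmin(end + 300L, L))
    wider <- prevalence(countPrevalence(m, hotspotGRanges(wide)))
    expect_true(all(wider$count >= base$count))
})

test_that("whole-region prevalence matches the max-over-modules identity", {
    set.seed(303)
    L <- 6000L
    r <- grRegion("chrT", 0L, L)
    m <- makeModules(r, 1500L)
    expect_equal(regionPrevalence(r, hotspotGRanges(data.frame())), 0L)
    full <- hotspotGRanges(data.frame(start = 0L, end = L,
                                      cell_type = "ct1"))
    expect_equal(regionPrevalence(r, full), 1L)
    for (rep in 1:20) {
        s <- sample(0:(L - 100L), 25, TRUE)
        df <- data.frame(start = s, end = pmin(s + sample(10:900, 25, TRUE),
                                               L),
                         cell_type = paste0("ct", sample(6, 25, TRUE)))
        hs <- hotspotGRanges(df)
        whole <- regionPrevalence(r, hs)
        perMod <- prevalence(countPrevalence(m, hs))$count
        # union over modules: every cell type hitting the region hits some
        # module, so the whole-region count is >= any single module count
        expect_true(all(whole >= perMod))
        expect_equal(whole, length(unique(
            df$cell_type[df$start < L & df$end > 0])))
    }
})

test_that("presence matrices reconstruct to tracks with matching counts", {
    regs <- readRegionTable(system.file("extdata", "synthetic_regions.tsv",
                                        package = "IntraProm"))
    m <- makeModules(regs["RUNX1_intron5"], 2500L, geneStrand = "-")
    bins <- moduleBins(m)
    iv <- GenomicRanges::GRanges(seqnames(bins), IRanges::IRanges(
        start(bins), end(bins)))
    names(iv) <- mcols(bins)$label
    pres <- read.delim(system.file("extdata",
        "synthetic_dnase_presence.tsv", package = "IntraProm"),
        comment.char = "#", check.names = FALSE)
    hs <- presenceToHotspots(pres, iv, assay = "DNASE")
    got <- prevalence(countPrevalence(m, hs, nCellTypes = c(DNASE = 124L)))
    want <- colSums(pres[, -1])
    expect_equal(got$count, unname(want[got$module_label]))
})
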