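smallConfig <- function(seed = 5L, ...) {
    synthConfig(seed = seed, genome_length = 6000L,
                planted_promoters = data.frame(position = 1200L,
                                               strand = "+",
                                               n_inr_motifs = 2L),
                n_cell_types_dnase = 12L, n_cell_types_h3k4me3 = 8L,
                cage_cell_types = 6L, ...)
}

test_that("generation is bit-identical under one seed and changes with it", {
    s1 <- simulateScenario(smallConfig(5L))
    s2 <- simulateScenario(smallConfig(5L))
    expect_identical(s1$sequence, s2$sequence)
    expect_identical(s1$hotspots, s2$hotspots)
    expect_identical(s1$cage, s2$cage)
    expect_identical(s1$ests, s2$ests)
    s3 <- simulateScenario(smallConfig(6L))
    expect_false(identical(s1$sequence, s3$sequence))

    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    simulateScenario(smallConfig(5L), outdir = d1)
    simulateScenario(smallConfig(5L), outdir = d2)
    expect_identical(readLines(file.path(d1, "genome.fasta")),
                     readLines(file.path(d2, "genome.fasta")))
})

test_that("gc_fraction 0 yields A/T-only sequence outside planted motifs", {
    cfg <- smallConfig(7L, gc_fraction = 0)
    g <- generateGenome(cfg)
    ch <- strsplit(g$sequence, "")[[1]]
    w <- pwmWidth(inrDefaultPWM())
    planted <- unlist(lapply(g$truth$inr_centers$center, function(ctr)
        (ctr - w):(ctr + w)))  # generous mask around each motif
    outside <- setdiff(seq_along(ch) - 1L, planted)
    expect_true(all(ch[outside + 1L] %in% c("A", "T")))
})

test_that("planted INR centers are all recovered by the scanner at 0.99", {
    for (seed in c(5L, 11L, 23L)) {
        cfg <- smallConfig(seed)
        g <- generateGenome(cfg)
        hits <- scanInr(g$sequence, inrDefaultPWM(), 0.99)
        truth <- g$truth$inr_centers
        found <- paste(hits$center, hits$strand)
        expect_true(all(paste(truth$center, truth$strand) %in% found))
    }
})

test_that("hotspot generation honors degenerate rate/probability settings", {
    cfg <- smallConfig(9L, background_hotspot_rate = 0,
                       promoter_presence_prob = 1)
    g <- generateGenome(cfg)
    hs <- simulateHotspots(cfg, g$truth)
    dn <- hs[mcols(hs)$assay == "DNASE"]
    # every cell type has exactly one hotspot per promoter, none elsewhere
    expect_equal(length(dn), cfg$n_cell_types_dnase *
                 nrow(cfg$planted_promoters))
    expect_equal(as.vector(table(mcols(dn)$cell_type)),
                 rep(nrow(cfg$planted_promoters), cfg$n_cell_types_dnase))
    # all hotspots near the promoter
    expect_true(all(abs((start(dn) + end(dn)) / 2 -
                        cfg$planted_promoters$position[1]) < 600))

    off <- smallConfig(9L, promoter_presence_prob = 0,
                       background_hotspot_rate = 0)
    hs0 <- simulateHotspots(off, generateGenome(off)$truth)
    expect_length(hs0, 0L)
})

test_that("per-module prevalence at the planted promoter tracks the
           presence probability binomially", {
    # mean over seeds of the planted-module prevalence should sit within
    # 3 binomial SDs of n * p
    n <- 40L
    p <- 0.8
    seeds <- 1:25
    counts <- vapply(seeds, function(sd) {
        cfg <- synthConfig(seed = sd, genome_length = 6000L,
                           planted_promoters = data.frame(position = 1200L,
                               strand = "+", n_inr_motifs = 1L),
                           n_cell_types_dnase = n, n_cell_types_h3k4me3 = 4L,
                           background_hotspot_rate = 0,
                           promoter_presence_prob = p)
        truth <- generateGenome(cfg)$truth
        hs <- simulateHotspots(cfg, truth)
        m <- makeModules(grRegion(cfg$chrom, 0L, cfg$genome_length), 2500L)
        tab <- prevalence(countPrevalence(
            m, hs[mcols(hs)$assay == "DNASE"],
            nCellTypes = c(DNASE = n)))
        tab$count[tab$module_label == "I"]  # promoter at 1200: first bin
    }, 1L)
    se <- sqrt(n * p * (1 - p) / length(seeds))
    expect_lt(abs(mean(counts) - n * p), 3 * se)
})

test_that("CAGE draws conserve bookkeeping and cluster near promoters", {
    cfg <- smallConfig(13L, cage_false_rate = 0)
    truth <- generateGenome(cfg)$truth
    cage <- simulateCage(cfg, truth)
    expect_equal(nrow(cage), attr(cage, "n_true_draws"))
    expect_true(all(cage$true_tss))
    expect_true(all(cage$strand == "+"))
    # tail bound: all jittered TSSs within 4 sd of the planted promoter
    expect_true(all(abs(cage$position - cfg$planted_promoters$position) <=
                    4 * cfg$cage_jitter_sd))

    noProm <- synthConfig(seed = 13L, genome_length = 6000L,
                          planted_promoters = NULL, cage_cell_types = 6L,
                          cage_false_rate = 5)
    noise <- simulateCage(noProm, list(promoters = data.frame()))
    expect_true(all(!noise$true_tss))
    expect_equal(attr(noise, "n_true_draws"), 0L)
})

test_that("error-free full-length ESTs are exact substrings of the lncRNA", {
    cfg <- smallConfig(17L, est_error_rate = 0, est_length_mean = 600,
                       est_length_sd = 1e-9)
    g <- generateGenome(cfg)
    est <- simulateEsts(cfg, g$truth, g$sequence)
    expect_equal(nchar(est$lncrna$sequence), cfg$lnc_length)
    for (i in seq_len(nrow(est$ests)))
        expect_true(grepl(est$ests$sequence[i], est$lncrna$sequence,
                          fixed = TRUE))
    # genomic span matches the recorded sequence for a plus-strand lncRNA
    for (i in seq_len(nrow(est$ests))) {
        sub <- substr(g$sequence, est$ests$start[i] + 1L, est$ests$end[i])
        expect_identical(sub, est$ests$sequence[i])
    }
    none <- smallConfig(17L, n_ests = 0L)
    g0 <- generateGenome(none)
    expect_equal(nrow(simulateEsts(none, g0$truth, g0$sequence)$ests), 0L)
})

test_that("consensus from generated ESTs matches the hidden lncRNA", {
    scen <- simulateScenario(smallConfig(19L))
    oriented <- orientEsts(scen$ests, scen$lncrna$strand)
    cons <- callConsensus(buildMsa(oriented), minDepth = 2L,
                          minSupport = 0.6)
    aln <- localAlign(consensusSequence(cons), scen$lncrna$sequence)
    expect_gte(aln$identity, 0.99)
})
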