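#' Configuration for the synthetic-data generator
#'
#' Returns the default scenario, optionally overridden field-by-field. The
#' defaults mirror the scale of a cross-cell-type ENCODE-style survey of a
#' 25-kb intronic region of a minus-strand host gene: 10 modules of 2.5 kb,
#' one planted antisense promoter in the genomically-lowest module (the
#' module labelled X under gene-sense labelling, i.e. a BCR3-like bin), 124
#' DNase and 51 H3K4me3 cell types, 35 CAGE cell types, and a hidden 600-nt
#' antisense lncRNA sampled by 8 error-bearing ESTs.
#'
#' Rates are per 10 kb per cell type; probabilities in `[0, 1]`. Identical
#' config + seed gives bit-identical outputs, and each output stream draws
#' from its own substream so adding one output never perturbs another.
#'
#' @param seed integer master seed.
#' @param ... overrides for any default field (see the source for the full
#'   list: `genome_length`, `gc_fraction`, `chrom`, `host_gene_strand`,
#'   `planted_promoters` (data.frame `position`, `strand`, `n_inr_motifs`),
#'   `n_cell_types_dnase`, `n_cell_types_h3k4me3`, `background_hotspot_rate`,
#'   `promoter_presence_prob`, `hotspot_length_mean`, `hotspot_length_sd`,
#'   `hotspot_center_jitter_sd`, `cage_cell_types`,
#'   `cage_tss_per_promoter_mean`, `cage_jitter_sd`, `cage_false_rate`,
#'   `lnc_length`, `n_ests`, `est_length_mean`, `est_length_sd`,
#'   `est_error_rate`, `n_decoy_ests`).
#' @return list of class `synth_config`.
#' @export
synthConfig <- function(seed = 1L, ...) {
    cfg <- list(
        seed = as.integer(seed),
        genome_length = 25000L,
        gc_fraction = 0.41,
        chrom = "chrSyn",
        host_gene_strand = "-",
        planted_promoters = data.frame(position = 1250L, strand = "+",
                                       n_inr_motifs = 3L),
        n_cell_types_dnase = 124L,
        n_cell_types_h3k4me3 = 51L,
        background_hotspot_rate = 1,      # hotspots / 10 kb / cell type
        promoter_presence_prob = 0.8,
        hotspot_length_mean = 200,
        hotspot_length_sd = 50,
        hotspot_center_jitter_sd = 50,
        cage_cell_types = 35L,
        cage_tss_per_promoter_mean = 0.6,
        cage_jitter_sd = 25,
        cage_false_rate = 0.012,          # predictions / 10 kb / cell type
        lnc_length = 600L,
        n_ests = 8L,
        est_length_mean = 450,
        est_length_sd = 100,
        est_error_rate = 0.01,
        n_decoy_ests = 0L
    )
    dots <- list(...)
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
        stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
    probs <- c(cfg$gc_fraction, cfg$promoter_presence_prob,
               cfg$est_error_rate)
    if (any(probs < 0 | probs > 1))
        stop("probabilities must lie in [0, 1]")
    counts <- c(cfg$n_cell_types_dnase, cfg$n_cell_types_h3k4me3,
                cfg$cage_cell_types, cfg$n_ests, cfg$n_decoy_ests)
    if (any(counts < 0))
        stop("counts must be >= 0")
    class(cfg) <- "synth_config"
    cfg
}

#' @export
print.synth_config <- function(x, ...) {
    cat("synth_config: seed", x$seed, ",", x$genome_length, "bp genome,",
        nrow(x$planted_promoters), "planted promoter(s),",
        x$n_cell_types_dnase, "/", x$n_cell_types_h3k4me3, "/",
        x$cage_cell_types, "cell types (DNase/H3K4me3/CAGE)\n")
    invisible(x)
}

# Fixed-order substream seeds derived from the master seed: one stream per
# output, so adding a new output never perturbs existing ones.
substreamSeeds <- function(cfg) {
    set.seed(cfg$seed)
    s <- sample.int(.Machine$integer.max - 1L, 8L)
    names(s) <- c("genome", "dnase", "h3k4me3", "cage", "ests", "decoys",
                  "reserved1", "reserved2")
    s
}

# normal draw resampled until >= lo (clamped-normal with resampling)
rnormMin <- function(n, mean, sd, lo) {
    x <- round(rnorm(n, mean, sd))
    while (any(x < lo))
        x[x < lo] <- round(rnorm(sum(x < lo), mean, sd))
    as.integer(x)
}

#' Generate the synthetic genome and planted-promoter truth
#'
#' Draws i.i.d. bases at the configured GC fraction and, at each planted
#' promoter, inserts the configured number of consensus-maximal INR
#' instances (spaced 15 bp apart) on the stated strand, recording every
#' motif's +1 center. The truth record is sufficient to score INR recovery
#' downstream without re-reading the config.
#'
#' @param config a [synthConfig()].
#' @param pwm the [InrPWM-class] whose consensus is planted (default
#'   [inrDefaultPWM()]).
#' @return list with `sequence` (character), `truth` (list with data.frames
#'   `promoters` (`position`, `strand`, `n_inr_motifs`) and `inr_centers`
#'   (`center`, `strand`, `promoter`)).
#' @export
generateGenome <- function(config, pwm = inrDefaultPWM()) {
    ss <- substreamSeeds(config)
    set.seed(ss[["genome"]])
    L <- config$genome_length
    f <- config$gc_fraction
    p <- c(A = (1 - f) / 2, C = f / 2, G = f / 2, T = (1 - f) / 2)
    bases <- sample(names(p), L, replace = TRUE, prob = p)
    motif <- strsplit(pwmConsensus(pwm), "")[[1L]]
    w <- length(motif)
    cOff <- pwmCenter(pwm)
    spacing <- 15L
    proms <- config$planted_promoters
    centers <- list()
    if (!is.null(proms) && nrow(proms)) {
        for (i in seq_len(nrow(proms))) {
            pos <- proms$position[i]
            str <- proms$strand[i]
            for (k in seq_len(proms$n_inr_motifs[i]) - 1L) {
                ctr <- pos + k * spacing         # +1 position, 0-based
                ws <- if (str == "+") ctr - cOff
                      else ctr - (w - 1L - cOff)  # forward-frame window start
                if (ws < 0L || ws + w > L)
                    stop("planted motif falls outside the genome")
                ins <- if (str == "+") motif
                       else strsplit(revComp(paste(motif, collapse = "")),
                                     "")[[1L]]
                bases[(ws + 1L):(ws + w)] <- ins
                centers[[length(centers) + 1L]] <-
                    data.frame(center = ctr, strand = str, promoter = i)
            }
        }
    }
    truth <- list(
        promoters = if (is.null(proms)) data.frame() else proms,
        inr_centers = if (length(centers)) do.call(rbind, centers)
                      else data.frame(center = integer(),
                                      strand = character(),
                                      promoter = integer()))
    list(sequence = paste(bases, collapse = ""), truth = truth)
}

# one assay's hotspot tracks
simulateAssayHotspots <- function(cfg, truth, nCellTypes, rate, prefix) {
    L <- cfg$genome_length
    proms <- truth$promoters
    out <- list()
    for (ct in seq_len(nCellTypes)) {
        ctName <- sprintf("%s_ct%03d", prefix, ct)
        nBg <- rpois(1L, rate * L / 10000)
        s <- e <- integer(0)
        if (nBg > 0L) {
            len <- rnormMin(nBg, cfg$hotspot_length_mean,
                            cfg$hotspot_length_sd, 50L)
            st <- floor(runif(nBg, 0, L))
            s <- c(s, st)
            e <- c(e, pmin(st + len, L))
        }
        if (!is.null(proms) && nrow(proms)) {
            for (i in seq_len(nrow(proms))) {
                if (runif(1L) <= cfg$promoter_presence_prob) {
                    len <- rnormMin(1L, cfg$hotspot_length_mean,
                                    cfg$hotspot_length_sd, 50L)
                    ctr <- proms$position[i] +
                        round(rnorm(1L, 0, cfg$hotspot_center_jitter_sd))
                    st <- max(0L, as.integer(ctr - len %/% 2L))
                    s <- c(s, st)
                    e <- c(e, min(st + len, L))
                }
            }
        }
        if (length(s))
            out[[ctName]] <- data.frame(start = as.integer(s),
                                        end = as.integer(e),
                                        cell_type = ctName)
    }
    df <- if (length(out)) do.call(rbind, out)
          else data.frame(start = integer(), end = integer(),
                          cell_type = character())
    rownames(df) <- NULL
    df
}

#' Simulate per-cell-type DNase and H3K4me3 hotspot tracks
#'
#' Background hotspots arise as a homogeneous point process at
#' `background_hotspot_rate` (per 10 kb per cell type) with clamped-normal
#' lengths (minimum 50 bp; negative draws resampled). Each planted promoter
#' additionally receives, per cell type, one hotspot with probability
#' `promoter_presence_prob`, centered on the promoter with Gaussian jitter.
#' H3K4me3 — a promoter mark, not a general accessibility mark — gets the
#' promoter-linked hotspots plus background at one tenth of the DNase rate.
#'
#' @param config a [synthConfig()].
#' @param truth truth record from [generateGenome()].
#' @return `GRanges` with metadata `cell_type`, `assay`, on
#'   `config$chrom`.
#' @export
simulateHotspots <- function(config, truth) {
    ss <- substreamSeeds(config)
    set.seed(ss[["dnase"]])
    dn <- simulateAssayHotspots(config, truth, config$n_cell_types_dnase,
                                config$background_hotspot_rate, "dnase")
    set.seed(ss[["h3k4me3"]])
    h3 <- simulateAssayHotspots(config, truth, config$n_cell_types_h3k4me3,
                                config$background_hotspot_rate / 10,
                                "h3k4")
    mk <- function(df, assay) {
        if (!nrow(df)) {
            gr <- GRanges()
            mcols(gr) <- DataFrame(cell_type = character(),
                                   assay = character())
            return(gr)
        }
        GRanges(config$chrom, IRanges(df$start + 1L, df$end),
                cell_type = df$cell_type, assay = assay)
    }
    c(mk(dn, "DNASE"), mk(h3, "H3K4ME3"))
}

#' Simulate stranded CAGE TSS predictions
#'
#' Per cell type and planted promoter, `Poisson(cage_tss_per_promoter_mean)`
#' TSS points at the promoter position plus Gaussian jitter, on the
#' promoter's strand; plus uniform false predictions at `cage_false_rate`
#' (per 10 kb per cell type) with random strand. Positions are clipped to
#' the genome.
#'
#' @param config a [synthConfig()].
#' @param truth truth record from [generateGenome()].
#' @return data.frame with `chrom`, `position` (0-based), `strand`,
#'   `cell_type`, `true_tss` (logical); attribute `n_true_draws` records the
#'   summed Poisson draws (equal to the number of `true_tss` rows).
#' @export
simulateCage <- function(config, truth) {
    ss <- substreamSeeds(config)
    set.seed(ss[["cage"]])
    L <- config$genome_length
    proms <- truth$promoters
    rows <- list()
    nTrue <- 0L
    for (ct in seq_len(config$cage_cell_types)) {
        ctName <- sprintf("cage_ct%02d", ct)
        if (!is.null(proms) && nrow(proms)) {
            for (i in seq_len(nrow(proms))) {
                k <- rpois(1L, config$cage_tss_per_promoter_mean)
                nTrue <- nTrue + k
                if (k > 0L) {
                    pos <- pmin(pmax(round(proms$position[i] +
                        rnorm(k, 0, config$cage_jitter_sd)), 0L), L - 1L)
                    rows[[length(rows) + 1L]] <- data.frame(
                        chrom = config$chrom, position = as.integer(pos),
                        strand = proms$strand[i], cell_type = ctName,
                        true_tss = TRUE)
                }
            }
        }
        nF <- rpois(1L, config$cage_false_rate * L / 10000)
        if (nF > 0L) {
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = config$chrom,
                position = as.integer(floor(runif(nF, 0, L))),
                strand = sample(c("+", "-"), nF, replace = TRUE),
                cell_type = ctName, true_tss = FALSE)
        }
    }
    df <- if (length(rows)) do.call(rbind, rows)
          else data.frame(chrom = character(), position = integer(),
                          strand = character(), cell_type = character(),
                          true_tss = logical())
    rownames(df) <- NULL
    attr(df, "n_true_draws") <- nTrue
    df
}

#' Simulate error-bearing ESTs from a hidden antisense lncRNA
#'
#' The hidden lncRNA is the genome subsequence of `lnc_length` starting at
#' the first planted promoter whose strand differs from the host gene's
#' (read 5' to 3' on its own strand, i.e. reverse-complemented into
#' transcript orientation when that strand is `-`). Each EST is a uniform
#' subinterval of the transcript (clamped-normal length, minimum 50 bp)
#' with i.i.d. substitutions at `est_error_rate`; its genomic span and
#' strand are recorded and its sequence is stored in read orientation (5'
#' to 3' on its strand). Optional decoy ESTs are sampled from the host-gene
#' sense strand elsewhere in the genome, error-free.
#'
#' @param config a [synthConfig()].
#' @param truth truth record from [generateGenome()].
#' @param genome character, the genome sequence from [generateGenome()].
#' @return list with `ests` (data.frame `accession`, `chrom`, `start`,
#'   `end`, `strand`, `sequence`) and `lncrna` (list `sequence`, `start`,
#'   `end`, `strand` — transcript-oriented sequence plus 0-based half-open
#'   genomic span).
#' @export
simulateEsts <- function(config, truth, genome) {
    ss <- substreamSeeds(config)
    set.seed(ss[["ests"]])
    proms <- truth$promoters
    anti <- which(proms$strand != config$host_gene_strand)
    if (!length(anti))
        stop("no antisense planted promoter to anchor the lncRNA")
    p0 <- proms$position[anti[1L]]
    str <- proms$strand[anti[1L]]
    L <- config$genome_length
    lncLen <- config$lnc_length
    if (str == "+") {
        gStart <- p0
        gEnd <- min(p0 + lncLen, L)
    } else {
        gEnd <- p0 + 1L
        gStart <- max(0L, gEnd - lncLen)
    }
    fwd <- substr(genome, gStart + 1L, gEnd)
    tx <- if (str == "+") fwd else revComp(fwd)
    txLen <- nchar(tx)
    bases <- c("A", "C", "G", "T")
    makeEst <- function(i) {
        len <- min(rnormMin(1L, config$est_length_mean,
                            config$est_length_sd, 50L), txLen)
        s <- as.integer(floor(runif(1L, 0, txLen - len + 1)))
        estSeq <- strsplit(substr(tx, s + 1L, s + len), "")[[1L]]
        nerr <- stats::rbinom(1L, len, config$est_error_rate)
        if (nerr > 0L) {
            atPos <- sample.int(len, nerr)
            for (q in atPos)
                estSeq[q] <- sample(setdiff(bases, estSeq[q]), 1L)
        }
        # transcript offset -> genomic span
        if (str == "+") { gs <- gStart + s; ge <- gs + len }
        else { ge <- gEnd - s; gs <- ge - len }
        data.frame(accession = sprintf("SYNEST%03d", i),
                   chrom = config$chrom, start = gs, end = ge,
                   strand = str,
                   sequence = paste(estSeq, collapse = ""))
    }
    ests <- if (config$n_ests > 0L)
        do.call(rbind, lapply(seq_len(config$n_ests), makeEst))
    else data.frame(accession = character(), chrom = character(),
                    start = integer(), end = integer(),
                    strand = character(), sequence = character())
    if (config$n_decoy_ests > 0L) {
        set.seed(ss[["decoys"]])
        hostStr <- config$host_gene_strand
        decoys <- do.call(rbind, lapply(seq_len(config$n_decoy_ests),
                                        function(i) {
            len <- min(rnormMin(1L, config$est_length_mean,
                                config$est_length_sd, 50L), L)
            gs <- as.integer(floor(runif(1L, 0, L - len + 1)))
            fwdSub <- substr(genome, gs + 1L, gs + len)
            data.frame(accession = sprintf("SYNDEC%03d", i),
                       chrom = config$chrom, start = gs, end = gs + len,
                       strand = hostStr,
                       sequence = if (hostStr == "+") fwdSub
                                  else revComp(fwdSub))
        }))
        ests <- rbind(ests, decoys)
    }
    rownames(ests) <- NULL
    list(ests = ests,
         lncrna = list(sequence = tx, start = gStart, end = gEnd,
                       strand = str))
}

#' Run the full synthetic scenario
#'
#' Generates genome + truth, hotspot tracks, CAGE predictions and ESTs under
#' one master seed, and optionally persists everything (FASTA, BED, TSV,
#' seed-stamped headers) to a directory.
#'
#' @param config a [synthConfig()].
#' @param pwm [InrPWM-class] whose consensus is planted.
#' @param outdir optional output directory.
#' @return list with `config`, `sequence`, `truth`, `hotspots` (GRanges),
#'   `cage` (data.frame), `ests` (data.frame), `lncrna` (list), `region`
#'   (GRanges covering the genome).
#' @export
simulateScenario <- function(config = synthConfig(), pwm = inrDefaultPWM(),
                             outdir = NULL) {
    g <- generateGenome(config, pwm)
    hs <- simulateHotspots(config, g$truth)
    cage <- simulateCage(config, g$truth)
    est <- simulateEsts(config, g$truth, g$sequence)
    region <- GRanges(config$chrom, IRanges(1L, config$genome_length))
    names(region) <- "synthetic_region"
    res <- list(config = config, sequence = g$sequence, truth = g$truth,
                hotspots = hs, cage = cage, ests = est$ests,
                lncrna = est$lncrna, region = region)
    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        stamp <- paste0("seed=", config$seed)
        gseq <- DNAStringSet(setNames(g$sequence,
                                      paste(config$chrom, stamp)))
        writeXStringSet(gseq, file.path(outdir, "genome.fasta"))
        writeXStringSet(DNAStringSet(setNames(est$lncrna$sequence,
                            paste("lncRNA_truth", stamp))),
                        file.path(outdir, "lncrna_truth.fasta"))
        if (nrow(est$ests))
            writeXStringSet(DNAStringSet(setNames(est$ests$sequence,
                                paste(est$ests$accession, stamp))),
                            file.path(outdir, "ests.fasta"))
        write.table(est$ests[, c("accession", "chrom", "start", "end",
                                 "strand", "sequence")],
                    file.path(outdir, "ests.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        for (a in unique(mcols(hs)$assay)) {
            sub <- hs[mcols(hs)$assay == a]
            for (ct in unique(mcols(sub)$cell_type))
                writeBed(sub[mcols(sub)$cell_type == ct],
                         file.path(outdir, sprintf("%s.%s.bed", ct,
                                                   tolower(a))))
        }
        tssBed <- data.frame(chrom = cage$chrom, start = cage$position,
                             end = cage$position + 1L, name = "tss",
                             score = 0L, strand = cage$strand)
        write.table(tssBed, file.path(outdir, "cage_tss.bed"), sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
        write.table(g$truth$inr_centers,
                    file.path(outdir, "truth_inr_centers.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(g$truth$promoters,
                    file.path(outdir, "truth_promoters.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    res
}
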