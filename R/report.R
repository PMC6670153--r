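# atomic writer: write to a temp file in the same directory, then rename
atomicWrite <- function(writer, file) {
    tmp <- paste0(file, ".tmp")
    writer(tmp)
    file.rename(tmp, file)
    invisible(file)
}

#' Per-module promoter-feature profile of a region
#'
#' Runs the module binning + hotspot prevalence, INR scan and stranded TSS
#' count over one region and combines them into a single per-module table.
#' A module is flagged `promoter_like` when its DNase prevalence reaches
#' `fDnase * n_dnase_cell_types` AND its H3K4me3 prevalence reaches
#' `fH3k4me3 * n_h3k4me3_cell_types`. The flag is a labelled heuristic
#' convenience — a compact way of saying "open in most cell types and
#' carrying the promoter mark in most cell types" — not a calibrated
#' classifier, and the thresholds are configurable.
#'
#' @param region named `GRanges` of length 1.
#' @param hotspots `GRanges` with `cell_type`/`assay` metadata.
#' @param tss data.frame of TSS predictions ([loadTss()] format).
#' @param sequence character sequence of the region (forward strand,
#'   ascending genomic coordinates), or `NULL` to skip the INR scan.
#' @param pwm [InrPWM-class] (default [inrDefaultPWM()]).
#' @param cutoff INR score cutoff (default 0.99).
#' @param moduleWidth bin width (default 2500).
#' @param geneStrand host-gene strand for gene-sense labels.
#' @param nCellTypes named totals per assay (see [countPrevalence()]).
#' @param fDnase,fH3k4me3 promoter-like prevalence fractions (default 0.5).
#' @param outdir optional directory; writes `profile.tsv`, `inr_hits.bed`,
#'   `tss_counts.tsv`, `report.json` atomically.
#' @param seed optional seed recorded in the JSON provenance block.
#' @return data.frame, one row per module in label order: `module_label`,
#'   `start`, `end` (0-based half-open genomic), `dnase_count`,
#'   `h3k4me3_count`, `inr_hits`, `tss_plus`, `tss_minus`, `promoter_like`.
#' @export
runProfile <- function(region, hotspots, tss, sequence = NULL,
                       pwm = inrDefaultPWM(), cutoff = 0.99,
                       moduleWidth = 2500L, geneStrand = "-",
                       nCellTypes = NULL, fDnase = 0.5, fH3k4me3 = 0.5,
                       outdir = NULL, seed = NA_integer_) {
    mods <- makeModules(region, moduleWidth, geneStrand = geneStrand)
    prev <- countPrevalence(mods, hotspots, nCellTypes = nCellTypes)
    ptab <- prevalence(prev)
    tssCounts <- countTss(mods, tss)
    if (!is.null(sequence)) {
        if (nchar(sequence) != width(region))
            stop("sequence length must equal the region length")
        hits <- scanInr(sequence, pwm, cutoff)
        # sequence offset -> genomic 0-based position
        hits$genomic <- hits$center + start(region) - 1L
    } else {
        hits <- data.frame(center = integer(), strand = character(),
                           score = numeric(), genomic = integer())
    }
    bins <- moduleBins(mods)
    ord <- order(as.integer(as.roman(mcols(bins)$label)))
    bins <- bins[ord]
    getCount <- function(assay, lab) {
        r <- ptab$count[ptab$assay == assay & ptab$module_label == lab]
        if (length(r)) r else 0L
    }
    labs <- mcols(bins)$label
    out <- data.frame(
        module_label = labs,
        start = start(bins) - 1L,
        end = end(bins),
        dnase_count = vapply(labs, function(l) getCount("DNASE", l), 1L),
        h3k4me3_count = vapply(labs, function(l) getCount("H3K4ME3", l), 1L),
        inr_hits = vapply(seq_along(bins), function(i)
            sum(hits$genomic >= start(bins)[i] - 1L &
                hits$genomic < end(bins)[i]), 1L),
        tss_plus = tssCounts$plus_count,
        tss_minus = tssCounts$minus_count)
    nct <- prev@nCellTypes  # slot access: the arg shadows the accessor name
    nD <- if ("DNASE" %in% names(nct)) nct[["DNASE"]] else 0L
    nH <- if ("H3K4ME3" %in% names(nct)) nct[["H3K4ME3"]] else 0L
    out$promoter_like <- nD > 0L & nH > 0L &
        out$dnase_count >= fDnase * nD & out$h3k4me3_count >= fH3k4me3 * nH
    rownames(out) <- NULL
    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        atomicWrite(function(f) {
            con <- file(f, "w")
            writeLines(paste0("# promoter_like: heuristic flag, DNase >= ",
                              fDnase, " x ", nD, " AND H3K4me3 >= ",
                              fH3k4me3, " x ", nH, " cell types"), con)
            write.table(out, con, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            close(con)
        }, file.path(outdir, "profile.tsv"))
        atomicWrite(function(f)
            writeInrBed(hits, as.character(seqnames(region)),
                        start(region) - 1L, f),
            file.path(outdir, "inr_hits.bed"))
        atomicWrite(function(f) writeTssTsv(tssCounts, f),
                    file.path(outdir, "tss_counts.tsv"))
        report <- list(region = names(region),
                       chrom = as.character(seqnames(region)),
                       start = start(region) - 1L, end = end(region),
                       module_width = moduleWidth, cutoff = cutoff,
                       n_cell_types = as.list(nct),
                       promoter_like_modules =
                           out$module_label[out$promoter_like],
                       seed = seed)
        atomicWrite(function(f)
            jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA),
            file.path(outdir, "report.json"))
    }
    out
}

#' Transcript-evidence pipeline: select, align, call, match, amplify
#'
#' Chains EST selection, center-star multiple alignment, consensus calling,
#' matching of the consensus against a transcript set, and in-silico PCR of
#' primer pairs against the best-matching transcript (or the consensus
#' itself when no transcript set is given). Intermediates are all returned
#' and, when `outdir` is given, persisted.
#'
#' @param ests EST data.frame ([readEstTable()] format, `sequence` needed).
#' @param region,strand,accessions selection parameters ([selectEsts()]).
#' @param transcriptStrand strand of the transcript being reconstructed
#'   (defaults to `strand` if given, else `"+"`).
#' @param transcripts optional named character vector / `DNAStringSet` to
#'   match the consensus against.
#' @param primers optional list of primer pairs ([readPrimerPairs()]
#'   format); amplicons are predicted on the matched transcript when
#'   available, else on the consensus.
#' @param minDepth,minSupport consensus-calling parameters.
#' @param maxLen,maxMismatch in-silico PCR parameters.
#' @param outdir optional directory; writes `consensus.fasta`, `msa.fasta`,
#'   `match.tsv`, `amplicons.tsv`.
#' @return list with `selected`, `msa`, `consensus`, `match` (or `NULL`),
#'   `amplicons` (or `NULL`).
#' @export
runTranscript <- function(ests, region = NULL, strand = NULL,
                          accessions = NULL, transcriptStrand = NULL,
                          transcripts = NULL, primers = NULL,
                          minDepth = 2L, minSupport = 0.5,
                          maxLen = 5000L, maxMismatch = 0L,
                          outdir = NULL) {
    sel <- selectEsts(ests, region = region, strand = strand,
                      accessions = accessions)
    if (nrow(sel) < 2L)
        stop("fewer than 2 ESTs selected (", nrow(sel),
             "); cannot build an alignment")
    if (is.null(transcriptStrand))
        transcriptStrand <- if (!is.null(strand)) strand else "+"
    oriented <- orientEsts(sel, transcriptStrand)
    msa <- buildMsa(oriented)
    cons <- callConsensus(msa, minDepth = minDepth, minSupport = minSupport)
    matchRes <- NULL
    if (!is.null(transcripts))
        matchRes <- matchConsensus(cons, transcripts)
    amps <- NULL
    if (!is.null(primers)) {
        tmpl <- if (!is.null(transcripts) && !is.null(matchRes)) {
            tx <- if (methods::is(transcripts, "DNAStringSet"))
                as.character(transcripts) else transcripts
            setNames(tx[[matchRes$transcript]], matchRes$transcript)
        } else setNames(consensusSequence(cons), "consensus")
        amps <- do.call(rbind, lapply(primers, function(p) {
            a <- predictAmplicons(tmpl, p, maxLen = maxLen,
                                  maxMismatch = maxMismatch,
                                  templateId = names(tmpl))
            if (nrow(a)) a$pair <- p$name else a$pair <- character(0)
            a
        }))
    }
    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        atomicWrite(function(f)
            writeXStringSet(DNAStringSet(setNames(consensusSequence(cons),
                                                  "consensus")), f),
            file.path(outdir, "consensus.fasta"))
        atomicWrite(function(f)
            writeXStringSet(methods::as(msa, "DNAStringSet"), f),
            file.path(outdir, "msa.fasta"))
        if (!is.null(matchRes))
            atomicWrite(function(f)
                write.table(matchRes, f, sep = "\t", quote = FALSE,
                            row.names = FALSE),
                file.path(outdir, "match.tsv"))
        if (!is.null(amps))
            atomicWrite(function(f)
                write.table(amps, f, sep = "\t", quote = FALSE,
                            row.names = FALSE),
                file.path(outdir, "amplicons.tsv"))
    }
    list(selected = sel, msa = msa, consensus = cons, match = matchRes,
         amplicons = amps)
}
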