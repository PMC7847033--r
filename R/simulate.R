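.BASES <- c("A", "C", "G", "T")

.randomDna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                collapse = "")

#' Simulate a pair of species references
#'
#' Draws two uniform-random ACGT sequences of `genomeLength` bases -- one
#' per species -- and, when `sharedFraction > 0`, replaces the leading
#' block of the host genome (length `round(sharedFraction * genomeLength)`)
#' with the corresponding graft block, creating k-mers shared between the
#' two references (a stand-in for sequence conserved between species).
#' Deterministic under the config seed: the same config yields
#' byte-identical FASTA files.
#'
#' @param config a [SimConfig-class].
#' @param outDir directory for `graft.fa` and `host.fa` (created if
#'   needed).
#' @return list with `graftFasta`, `hostFasta` (paths), `graftSeq`,
#'   `hostSeq` (sequences) and `sharedBlock` (length of the copied block).
#' @export
simulateGenomes <- function(config, outDir) {
    stopifnot(is(config, "SimConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config@seed)
    L <- config@genomeLength
    graft <- .randomDna(L)
    host <- .randomDna(L)
    B <- as.integer(round(config@sharedFraction * L))
    if (B > 0L) substr(host, 1L, B) <- substr(graft, 1L, B)
    graftFasta <- file.path(outDir, "graft.fa")
    hostFasta <- file.path(outDir, "host.fa")
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(c(graft_chr1 = graft)), graftFasta)
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(c(host_chr1 = host)), hostFasta)
    list(graftFasta = graftFasta, hostFasta = hostFasta,
         graftSeq = graft, hostSeq = host, sharedBlock = B)
}

# substitution errors: each base independently mutated to one of the other
# three bases with probability errorRate
.applyErrors <- function(reads, width, errorRate) {
    if (errorRate <= 0 || length(reads) == 0L) return(reads)
    nerr <- stats::rbinom(length(reads), width, errorRate)
    for (i in which(nerr > 0L)) {
        for (p in sample.int(width, nerr[i])) {
            orig <- substr(reads[i], p, p)
            substr(reads[i], p, p) <-
                sample(setdiff(.BASES, orig), 1L)
        }
    }
    reads
}

.writeFastq <- function(path, headers, seqs, quals) {
    con <- .fqOpenWrite(path)
    on.exit(close(con))
    if (length(headers))
        writeLines(as.vector(rbind(headers, seqs,
                                   rep("+", length(headers)), quals)),
                   con)
    invisible(path)
}

#' Simulate barcoded paired reads with ground truth
#'
#' Assigns each cellular barcode a species identity -- graft singlet (with
#' probability `graftBarcodeFraction`), cross-species doublet (with
#' probability `doubletRate`), host singlet otherwise -- and an expected
#' host read proportion `host_mix` (0 for graft, 1 for host, uniform on
#' \[0.3, 0.7\] for doublets, placing them well inside the excluded
#' interval of the usual threshold regimes). Host singlets emulate
#' contaminating host cells in a xenograft sample. For every read the
#' source genome is drawn per `host_mix`, a uniform start position is
#' sampled (outside the shared block when `uniqueRegion` is set),
#' substitution errors are applied to the cDNA, and the pair is written
#' as R1 = barcode + random UMI filler (padded to `readLength`) and
#' R2 = cDNA. Read order is shuffled across barcodes. The per-barcode
#' truth is written as CSV (`barcode,identity,host_mix`).
#'
#' Reads are seeded with `config seed + 1` so the read stream is decoupled
#' from the genome stream; everything is deterministic under the config.
#'
#' @param config a [SimConfig-class].
#' @param genomes result of [simulateGenomes()].
#' @param outDir directory for `r1.fastq.gz`, `r2.fastq.gz`, `truth.csv`.
#' @return list with `r1`, `r2`, `truthPath` (paths) and `truth`
#'   (data.frame `barcode`, `identity`, `host_mix`).
#' @export
simulateReads <- function(config, genomes, outDir) {
    stopifnot(is(config, "SimConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    w <- config@readLength
    L <- config@genomeLength
    if (w > L) stop("readLength must not exceed genomeLength")
    if (config@barcodeLength > w)
        stop("barcodeLength must not exceed readLength")
    set.seed(config@seed + 1L)

    nb <- config@nBarcodes
    r1Path <- file.path(outDir, "r1.fastq.gz")
    r2Path <- file.path(outDir, "r2.fastq.gz")
    truthPath <- file.path(outDir, "truth.csv")

    if (nb == 0L) {
        .writeFastq(r1Path, character(), character(), character())
        .writeFastq(r2Path, character(), character(), character())
        truth <- data.frame(barcode = character(), identity = character(),
                            host_mix = numeric(), stringsAsFactors = FALSE)
        writeLines("barcode,identity,host_mix", truthPath)
        return(list(r1 = r1Path, r2 = r2Path, truthPath = truthPath,
                    truth = truth))
    }

    # unique random barcodes
    barcodes <- character(0)
    while (length(barcodes) < nb)
        barcodes <- unique(c(barcodes, vapply(
            seq_len(nb - length(barcodes)),
            function(i) .randomDna(config@barcodeLength), character(1))))

    u <- stats::runif(nb)
    identity <- ifelse(u < config@graftBarcodeFraction, "graft",
                ifelse(u < config@graftBarcodeFraction + config@doubletRate,
                       "doublet", "host"))
    hostMix <- numeric(nb)
    hostMix[identity == "host"] <- 1
    hostMix[identity == "doublet"] <-
        stats::runif(sum(identity == "doublet"), 0.3, 0.7)
    truth <- data.frame(barcode = barcodes, identity = identity,
                        host_mix = hostMix, stringsAsFactors = FALSE)

    rpb <- config@readsPerBarcode
    N <- nb * rpb
    readBc <- rep(barcodes, each = rpb)
    fromHost <- stats::runif(N) < rep(hostMix, each = rpb)

    lo <- 1L
    if (config@uniqueRegion && genomes$sharedBlock > 0L) {
        lo <- genomes$sharedBlock + 1L
        if (lo > L - w + 1L)
            stop("uniqueRegion sampling impossible: shared block leaves no room for reads")
    }
    starts <- sample.int(L - w + 1L - (lo - 1L), N, replace = TRUE) +
        (lo - 1L)
    r2 <- character(N)
    r2[!fromHost] <- substring(genomes$graftSeq, starts[!fromHost],
                               starts[!fromHost] + w - 1L)
    r2[fromHost] <- substring(genomes$hostSeq, starts[fromHost],
                              starts[fromHost] + w - 1L)
    r2 <- .applyErrors(r2, w, config@errorRate)

    nFill <- w - config@barcodeLength
    r1 <- if (nFill > 0L) {
        fill <- matrix(sample(.BASES, N * nFill, replace = TRUE), N, nFill)
        paste0(readBc, do.call(paste0, as.data.frame(fill)))
    } else readBc

    perm <- sample.int(N)
    qual <- strrep("I", w)
    ids <- sprintf("sim%08d", seq_len(N))
    .writeFastq(r1Path, paste0("@", ids, "/1"), r1[perm],
                rep(qual, N))
    .writeFastq(r2Path, paste0("@", ids, "/2"), r2[perm],
                rep(qual, N))

    truthOut <- truth[order(truth$barcode, method = "radix"), ]
    writeLines(c("barcode,identity,host_mix",
                 sprintf("%s,%s,%.10f", truthOut$barcode,
                         truthOut$identity, truthOut$host_mix)),
               truthPath)
    list(r1 = r1Path, r2 = r2Path, truthPath = truthPath, truth = truth)
}

#' Simulate a complete synthetic xenograft experiment
#'
#' Runs [simulateGenomes()] then [simulateReads()] under one config and
#' returns everything needed to drive the full workflow, including the
#' matching [BarcodeGeometry-class].
#'
#' @param config a [SimConfig-class].
#' @param outDir output directory.
#' @return list combining the two results plus `geometry` and `config`.
#' @examples
#' cfg <- SimConfig(genomeLength = 2000, nBarcodes = 10,
#'                  readsPerBarcode = 20, readLength = 50, seed = 7)
#' sim <- simulateExperiment(cfg, tempfile("sim"))
#' head(sim$truth)
#' @export
simulateExperiment <- function(config, outDir) {
    genomes <- simulateGenomes(config, outDir)
    reads <- simulateReads(config, genomes, outDir)
    c(genomes, reads,
      list(geometry = BarcodeGeometry(
               barcodeStart = 1L,
               barcodeLength = config@barcodeLength),
           config = config))
}
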