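#' Extract the cellular barcode from R1 sequences
#'
#' Slices the barcode out of each R1 sequence according to the geometry
#' (1-based, inclusive coordinates). A read is rejected -- `NA` in the
#' result -- when R1 is too short to contain the whole barcode or when the
#' barcode contains a non-ACGT character (e.g. N). Rejected pairs are
#' counted as discarded by [classifyExperiment()] and excluded from the
#' barcode table; no whitelist-distance error correction is attempted.
#'
#' @param r1Seq character vector of R1 sequences.
#' @param geometry a [BarcodeGeometry-class].
#' @return character vector of barcodes, `NA` where rejected.
#' @examples
#' geo <- BarcodeGeometry(barcodeStart = 1, barcodeLength = 5)
#' extractBarcode(c("ACGTACGT", "AANGTCCC", "ACG"), geo)
#' @export
extractBarcode <- function(r1Seq, geometry) {
    stopifnot(is(geometry, "BarcodeGeometry"))
    end <- geometry@barcodeStart + geometry@barcodeLength - 1L
    bc <- toupper(substr(as.character(r1Seq), geometry@barcodeStart, end))
    bc[nchar(r1Seq) < end | grepl("[^ACGT]", bc)] <- NA_character_
    bc
}

#' Classify a paired FASTQ experiment and tabulate barcodes (step A)
#'
#' Streams position-paired R1 (barcode + UMI) and R2 (cDNA) FASTQ files in
#' a single pass. For every pair the cellular barcode is extracted from R1
#' and the R2 read is classified into one of the five classes (see
#' [classifyReads()]). Per-barcode counts are accumulated over all five
#' classes; pairs whose R2 classified graft or host are written verbatim to
#' per-class paired FASTQ outputs (pairing and input order preserved). The
#' per-barcode table -- one row per observed (or whitelisted) barcode with
#' class counts and the graft/host read fractions -- is written as CSV, and
#' a run log records the totals.
#'
#' The fraction denominator is all reads associated with the barcode, i.e.
#' `fraction_graft = n_graft / n_total` with `n_total` summing all five
#' classes.
#'
#' @param r1,r2 paths to the paired FASTQ files (plain or gzip). Record i
#'   of R1 must mate record i of R2: equal record counts and matching
#'   headers (compared ignoring anything after the first whitespace and a
#'   trailing `/1`/`/2`).
#' @param index a [KmerIndex-class].
#' @param geometry a [BarcodeGeometry-class].
#' @param outDir output directory (created if needed); receives
#'   `graft_R1.fastq.gz`, `graft_R2.fastq.gz`, `host_R1.fastq.gz`,
#'   `host_R2.fastq.gz`, `barcode_table.csv` and `run_log.txt`.
#' @param whitelist optional character vector of allowed barcodes, or the
#'   path of a one-barcode-per-line file; pairs with other barcodes are
#'   discarded (and counted in the log).
#' @param minSpecific passed to [classifyReads()].
#' @param chunkSize read pairs per streaming chunk.
#' @return a [ClassifiedReadStore-class].
#' @export
classifyExperiment <- function(r1, r2, index, geometry, outDir,
                               whitelist = NULL, minSpecific = 1L,
                               chunkSize = 50000L) {
    stopifnot(is(index, "KmerIndex"), is(geometry, "BarcodeGeometry"))
    if (is.character(whitelist) && length(whitelist) == 1L &&
        file.exists(whitelist))
        whitelist <- readLines(whitelist)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    paths <- list(
        graftR1 = file.path(outDir, "graft_R1.fastq.gz"),
        graftR2 = file.path(outDir, "graft_R2.fastq.gz"),
        hostR1 = file.path(outDir, "host_R1.fastq.gz"),
        hostR2 = file.path(outDir, "host_R2.fastq.gz"),
        table = file.path(outDir, "barcode_table.csv"),
        log = file.path(outDir, "run_log.txt"))

    conR1 <- .fqOpenRead(r1); conR2 <- .fqOpenRead(r2)
    outCons <- list(
        graftR1 = .fqOpenWrite(paths$graftR1),
        graftR2 = .fqOpenWrite(paths$graftR2),
        hostR1 = .fqOpenWrite(paths$hostR1),
        hostR2 = .fqOpenWrite(paths$hostR2))
    on.exit({
        close(conR1); close(conR2)
        lapply(outCons, close)
    })

    chunks <- list()
    nPairs <- 0L
    nBadBarcode <- 0L
    nOffWhitelist <- 0L
    classTotals <- stats::setNames(integer(length(.READ_CLASSES)),
                                   .READ_CLASSES)

    repeat {
        l1 <- .fqReadChunk(conR1, chunkSize, r1)
        l2 <- .fqReadChunk(conR2, chunkSize, r2)
        n1 <- length(l1) %/% 4L
        n2 <- length(l2) %/% 4L
        if (n1 != n2)
            stop(sprintf(
                "R1/R2 record counts differ (R1 has %d, R2 has %d records beyond pair %d)",
                n1, n2, nPairs))
        if (n1 == 0L) break

        id1 <- .fqReadId(l1[seq(1L, by = 4L, length.out = n1)])
        id2 <- .fqReadId(l2[seq(1L, by = 4L, length.out = n1)])
        bad <- which(id1 != id2)
        if (length(bad))
            stop(sprintf(
                "mate header mismatch at record %d: '%s' vs '%s'",
                nPairs + bad[1L], id1[bad[1L]], id2[bad[1L]]))

        bc <- extractBarcode(l1[seq(2L, by = 4L, length.out = n1)],
                             geometry)
        lab <- classifyReads(l2[seq(2L, by = 4L, length.out = n1)],
                             index, minSpecific = minSpecific)

        retained <- !is.na(bc)
        nBadBarcode <- nBadBarcode + sum(!retained)
        if (!is.null(whitelist)) {
            off <- retained & !(bc %in% whitelist)
            nOffWhitelist <- nOffWhitelist + sum(off)
            retained <- retained & !off
        }

        if (any(retained)) {
            tab <- table(barcode = bc[retained], label = lab[retained])
            chunks[[length(chunks) + 1L]] <-
                as.data.frame(tab, stringsAsFactors = FALSE,
                              responseName = "n")
            classTotals <- classTotals +
                as.integer(table(lab[retained])[.READ_CLASSES])
        }
        for (side in c("graft", "host")) {
            keep <- which(retained & lab == side)
            if (length(keep)) {
                li <- .recLines(keep)
                writeLines(l1[li], outCons[[paste0(side, "R1")]])
                writeLines(l2[li], outCons[[paste0(side, "R2")]])
            }
        }
        nPairs <- nPairs + n1
    }

    records <- .aggregateBarcodeCounts(chunks)
    writeBarcodeTable(records, paths$table)

    logLines <- c(
        sprintf("input_pairs\t%d", nPairs),
        sprintf("retained_pairs\t%d", sum(classTotals)),
        sprintf("discarded_unparseable_barcode\t%d", nBadBarcode),
        sprintf("discarded_off_whitelist\t%d", nOffWhitelist),
        sprintf("n_barcodes\t%d", nrow(records)),
        sprintf("class_%s\t%d", names(classTotals), classTotals))
    writeLines(logLines, paths$log)

    new("ClassifiedReadStore",
        dir = outDir,
        graftR1 = paths$graftR1, graftR2 = paths$graftR2,
        hostR1 = paths$hostR1, hostR2 = paths$hostR2,
        tablePath = paths$table, logPath = paths$log,
        barcodeTable = records,
        classTotals = classTotals,
        nPairs = nPairs,
        nDiscardedBarcode = nBadBarcode,
        nDiscardedWhitelist = nOffWhitelist)
}

# fold per-chunk barcode x class count tables into the barcode table
.aggregateBarcodeCounts <- function(chunks) {
    empty <- data.frame(
        barcode = character(), n_total = integer(), n_graft = integer(),
        n_host = integer(), n_both = integer(), n_neither = integer(),
        n_ambiguous = integer(), fraction_graft = numeric(),
        fraction_host = numeric(), stringsAsFactors = FALSE)
    if (length(chunks) == 0L) return(empty)
    long <- do.call(rbind, chunks)
    long <- long[long$n > 0L, , drop = FALSE]
    if (nrow(long) == 0L) return(empty)
    wide <- stats::xtabs(n ~ barcode + label, data = long)
    bcs <- sort(rownames(wide), method = "radix")
    counts <- matrix(0L, nrow = length(bcs), ncol = length(.READ_CLASSES),
                     dimnames = list(bcs, .READ_CLASSES))
    counts[, colnames(wide)] <- as.integer(wide[bcs, , drop = FALSE])
    nTotal <- as.integer(rowSums(counts))
    data.frame(
        barcode = bcs,
        n_total = nTotal,
        n_graft = counts[, "graft"],
        n_host = counts[, "host"],
        n_both = counts[, "both"],
        n_neither = counts[, "neither"],
        n_ambiguous = counts[, "ambiguous"],
        fraction_graft = counts[, "graft"] / nTotal,
        fraction_host = counts[, "host"] / nTotal,
        row.names = NULL, stringsAsFactors = FALSE)
}

.BARCODE_TABLE_HEADER <- paste(
    "barcode", "n_total", "n_graft", "n_host", "n_both", "n_neither",
    "n_ambiguous", "fraction_graft", "fraction_host", sep = ",")

#' Read and write the per-barcode fraction table
#'
#' The CSV table produced by step A: one row per cellular barcode with its
#' per-class read counts and the graft/host read fractions (over all reads
#' of the barcode). The format is fixed: header
#' `barcode,n_total,n_graft,n_host,n_both,n_neither,n_ambiguous,fraction_graft,fraction_host`,
#' fractions printed with 6 decimal places, rows sorted by barcode in byte
#' order -- so a table written twice from the same records is
#' byte-identical.
#'
#' @param records barcode table data.frame (as in
#'   [ClassifiedReadStore-class]).
#' @param path CSV path.
#' @return `writeBarcodeTable()` returns `path` invisibly;
#'   `readBarcodeTable()` returns the data.frame.
#' @export
writeBarcodeTable <- function(records, path) {
    need <- strsplit(.BARCODE_TABLE_HEADER, ",")[[1L]]
    if (!all(need %in% names(records)))
        stop("barcode table lacks required columns: ",
             paste(setdiff(need, names(records)), collapse = ", "))
    records <- records[order(records$barcode, method = "radix"), ,
                       drop = FALSE]
    rows <- sprintf("%s,%d,%d,%d,%d,%d,%d,%.6f,%.6f",
                    records$barcode, records$n_total, records$n_graft,
                    records$n_host, records$n_both, records$n_neither,
                    records$n_ambiguous, records$fraction_graft,
                    records$fraction_host)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(.BARCODE_TABLE_HEADER, rows), con)
    invisible(path)
}

#' @rdname writeBarcodeTable
#' @export
readBarcodeTable <- function(path) {
    utils::read.csv(path, colClasses = c(
        barcode = "character", n_total = "integer", n_graft = "integer",
        n_host = "integer", n_both = "integer", n_neither = "integer",
        n_ambiguous = "integer", fraction_graft = "numeric",
        fraction_host = "numeric"))
}

#' Reopen a classified read store directory
#'
#' Rebuilds a [ClassifiedReadStore-class] from a directory written by
#' [classifyExperiment()] (e.g. in a later session, or from the command
#' line between step A and step B).
#'
#' @param dir the step A output directory.
#' @return a [ClassifiedReadStore-class].
#' @export
readClassifiedStore <- function(dir) {
    tablePath <- file.path(dir, "barcode_table.csv")
    logPath <- file.path(dir, "run_log.txt")
    if (!file.exists(tablePath) || !file.exists(logPath))
        stop(sprintf(
            "%s is not a classified read store; re-run classifyExperiment (step A)",
            dir))
    kv <- read.delim(logPath, header = FALSE, sep = "\t",
                     colClasses = "character", quote = "")
    log <- stats::setNames(kv[[2L]], kv[[1L]])
    classTotals <- stats::setNames(
        as.integer(log[paste0("class_", .READ_CLASSES)]), .READ_CLASSES)
    new("ClassifiedReadStore",
        dir = dir,
        graftR1 = file.path(dir, "graft_R1.fastq.gz"),
        graftR2 = file.path(dir, "graft_R2.fastq.gz"),
        hostR1 = file.path(dir, "host_R1.fastq.gz"),
        hostR2 = file.path(dir, "host_R2.fastq.gz"),
        tablePath = tablePath, logPath = logPath,
        barcodeTable = readBarcodeTable(tablePath),
        classTotals = classTotals,
        nPairs = as.integer(log[["input_pairs"]]),
        nDiscardedBarcode =
            as.integer(log[["discarded_unparseable_barcode"]]),
        nDiscardedWhitelist = as.integer(log[["discarded_off_whitelist"]]))
}
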