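#' Select cellular barcodes by host-read fraction (step B, selection)
#'
#' Returns the barcodes whose host-read fraction lies inside the closed
#' interval of `thresholds`. Selection is always expressed on the host
#' fraction axis -- the graft-side phrasing "at most 10% host-specific
#' reads" is the interval `[0, 0.1]`, the host-side "at least 90%" is
#' `[0.9, 1]`. The `side` of the thresholds does not change which barcodes
#' match; it decides which class's FASTQ pair is filtered downstream.
#'
#' Fractions are recomputed from the integer counts (`n_host / n_total`)
#' when both columns are present, so boundary comparisons are exact and do
#' not depend on the 6-decimal rounding of the CSV.
#'
#' @param table a barcode table data.frame ([readBarcodeTable()]) or a
#'   [ClassifiedReadStore-class].
#' @param thresholds an [ExtractionThresholds-class].
#' @return character vector of selected barcodes, byte-sorted.
#' @export
selectBarcodes <- function(table, thresholds) {
    stopifnot(is(thresholds, "ExtractionThresholds"))
    if (is(table, "ClassifiedReadStore")) table <- barcodeTable(table)
    f <- if (all(c("n_host", "n_total") %in% names(table)))
        table$n_host / table$n_total
    else table$fraction_host
    sel <- table$barcode[f >= thresholds@lower & f <= thresholds@upper]
    sort(sel, method = "radix")
}

#' Filter a per-class paired FASTQ down to selected barcodes (step B,
#' extraction)
#'
#' Streams the paired FASTQ of the chosen side (the graft-classified pair
#' for `side = "graft"`, the host-classified pair for `side = "host"`) and
#' keeps exactly the pairs whose cellular barcode is in `selected`.
#' Records are written verbatim and in their original order, so the output
#' is a byte-identical subsequence of the step A class files. The final
#' output therefore contains only reads unambiguously assigned to the
#' chosen species; ambiguous/both/neither reads of the selected barcodes
#' are absent by construction.
#'
#' @param store a [ClassifiedReadStore-class] (or step A output directory).
#' @param selected character vector of barcodes to keep (from
#'   [selectBarcodes()]).
#' @param thresholds an [ExtractionThresholds-class]; its `side` picks the
#'   class pair.
#' @param geometry the [BarcodeGeometry-class] used in step A.
#' @param outPrefix output path prefix; writes `<outPrefix>_R1.fastq.gz`,
#'   `<outPrefix>_R2.fastq.gz` and a selection report
#'   `<outPrefix>_selection_report.csv` (per-barcode kept read counts).
#' @param chunkSize read pairs per streaming chunk.
#' @return invisibly, a list with `r1`, `r2`, `report`, `selected`,
#'   `kept` and `dropped` (read-pair counts).
#' @export
filterFastqByBarcodes <- function(store, selected, thresholds, geometry,
                                  outPrefix, chunkSize = 50000L) {
    stopifnot(is(thresholds, "ExtractionThresholds"),
              is(geometry, "BarcodeGeometry"))
    if (is.character(store)) store <- readClassifiedStore(store)
    pair <- classFastqPair(store, thresholds@side)
    for (p in pair)
        if (!file.exists(p))
            stop(sprintf(
                "classified FASTQ missing: %s; re-run classifyExperiment (step A)",
                p))

    outR1 <- paste0(outPrefix, "_R1.fastq.gz")
    outR2 <- paste0(outPrefix, "_R2.fastq.gz")
    reportPath <- paste0(outPrefix, "_selection_report.csv")
    dir.create(dirname(outR1), showWarnings = FALSE, recursive = TRUE)

    conR1 <- .fqOpenRead(pair[["R1"]]); conR2 <- .fqOpenRead(pair[["R2"]])
    outConR1 <- .fqOpenWrite(outR1); outConR2 <- .fqOpenWrite(outR2)
    on.exit({ close(conR1); close(conR2); close(outConR1); close(outConR2) })

    selected <- unique(as.character(selected))
    keptPerBarcode <- stats::setNames(integer(length(selected)), selected)
    kept <- 0L; dropped <- 0L
    repeat {
        l1 <- .fqReadChunk(conR1, chunkSize, pair[["R1"]])
        l2 <- .fqReadChunk(conR2, chunkSize, pair[["R2"]])
        n <- length(l1) %/% 4L
        if (n == 0L) break
        bc <- extractBarcode(l1[seq(2L, by = 4L, length.out = n)], geometry)
        keep <- which(!is.na(bc) & bc %in% selected)
        kept <- kept + length(keep)
        dropped <- dropped + (n - length(keep))
        if (length(keep)) {
            li <- .recLines(keep)
            writeLines(l1[li], outConR1)
            writeLines(l2[li], outConR2)
            tab <- table(bc[keep])
            keptPerBarcode[names(tab)] <-
                keptPerBarcode[names(tab)] + as.integer(tab)
        }
    }

    report <- data.frame(
        barcode = sort(selected, method = "radix"),
        stringsAsFactors = FALSE)
    report$n_reads_kept <- as.integer(keptPerBarcode[report$barcode])
    reportCon <- file(reportPath, "w")
    writeLines(c("barcode,n_reads_kept",
                 sprintf("%s,%d", report$barcode, report$n_reads_kept)),
               reportCon)
    close(reportCon)

    invisible(list(r1 = outR1, r2 = outR2, report = reportPath,
                   selected = report$barcode, kept = kept,
                   dropped = dropped))
}

#' One-call barcode extraction (step B)
#'
#' Convenience composition of [selectBarcodes()] and
#' [filterFastqByBarcodes()]: selects the barcodes whose host-read
#' fraction lies in `[lower, upper]` and writes the filtered paired FASTQ
#' of the chosen side.
#'
#' @inheritParams filterFastqByBarcodes
#' @param lower,upper closed interval on the host-read fraction; defaults
#'   to the graft regime `[0, 0.1]` (at most 10% host-specific reads).
#' @param side which class pair to filter; defaults to `"graft"`.
#' @return as [filterFastqByBarcodes()].
#' @export
extractCellularBarcodes <- function(store, geometry, outPrefix,
                                    lower = 0, upper = 0.1,
                                    side = c("graft", "host"),
                                    chunkSize = 50000L) {
    side <- match.arg(side)
    if (is.character(store)) store <- readClassifiedStore(store)
    th <- ExtractionThresholds(lower = lower, upper = upper, side = side)
    selected <- selectBarcodes(barcodeTable(store), th)
    filterFastqByBarcodes(store, selected, th, geometry, outPrefix,
                          chunkSize = chunkSize)
}

#' @rdname extractCellularBarcodes
#' @details `hostSideExtraction()` is the optional repeat of step B on the
#'   host side, defaulting to the `[0.9, 1]` regime (at least 90%
#'   host-specific reads), so host cells can be analysed separately.
#' @export
hostSideExtraction <- function(store, geometry, outPrefix,
                               lower = 0.9, upper = 1,
                               chunkSize = 50000L) {
    extractCellularBarcodes(store, geometry, outPrefix, lower = lower,
                            upper = upper, side = "host",
                            chunkSize = chunkSize)
}
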