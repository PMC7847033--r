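#' @rdname KmerIndex-class
#' @param x a `KmerIndex`.
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))

#' @rdname KmerIndex-class
#' @export
setGeneric("graftKmers", function(x) standardGeneric("graftKmers"))

#' @rdname KmerIndex-class
#' @export
setGeneric("hostKmers", function(x) standardGeneric("hostKmers"))

#' @rdname KmerIndex-class
#' @export
setGeneric("sharedKmers", function(x) standardGeneric("sharedKmers"))

#' @rdname KmerIndex-class
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @rdname ClassifiedReadStore-class
#' @param x a `ClassifiedReadStore`.
#' @export
setGeneric("barcodeTable", function(x) standardGeneric("barcodeTable"))

#' @rdname ClassifiedReadStore-class
#' @export
setGeneric("classTotals", function(x) standardGeneric("classTotals"))

#' @rdname ClassifiedReadStore-class
#' @param side `"graft"` or `"host"`.
#' @export
setGeneric("classFastqPair",
           function(x, side) standardGeneric("classFastqPair"))

setMethod("kmerLength", "KmerIndex", function(x) x@k)
setMethod("graftKmers", "KmerIndex", function(x) x@graftOnly)
setMethod("hostKmers", "KmerIndex", function(x) x@hostOnly)
setMethod("sharedKmers", "KmerIndex", function(x) x@shared)
setMethod("speciesLabels", "KmerIndex",
          function(x) c(graft = x@graftLabel, host = x@hostLabel))

setMethod("show", "KmerIndex", function(object) {
    cat(sprintf("KmerIndex (k = %d)\n", object@k))
    cat(sprintf("  graft (%s) specific k-mers: %d\n",
                object@graftLabel, length(object@graftOnly)))
    cat(sprintf("  host  (%s) specific k-mers: %d\n",
                object@hostLabel, length(object@hostOnly)))
    cat(sprintf("  shared k-mers:              %d\n",
                length(object@shared)))
    invisible(NULL)
})

setMethod("show", "BarcodeGeometry", function(object) {
    cat(sprintf("BarcodeGeometry: barcode at R1[%d..%d]",
                object@barcodeStart,
                object@barcodeStart + object@barcodeLength - 1L))
    if (!is.na(object@umiStart) && !is.na(object@umiLength))
        cat(sprintf(", UMI at R1[%d..%d]", object@umiStart,
                    object@umiStart + object@umiLength - 1L))
    cat("\n")
    invisible(NULL)
})

setMethod("show", "ExtractionThresholds", function(object) {
    cat(sprintf(
        "ExtractionThresholds: host fraction in [%g, %g], side = %s\n",
        object@lower, object@upper, object@side))
    invisible(NULL)
})

setMethod("barcodeTable", "ClassifiedReadStore", function(x) x@barcodeTable)
setMethod("classTotals", "ClassifiedReadStore", function(x) x@classTotals)

setMethod("classFastqPair", "ClassifiedReadStore", function(x, side) {
    side <- match.arg(side, c("graft", "host"))
    if (side == "graft") c(R1 = x@graftR1, R2 = x@graftR2)
    else c(R1 = x@hostR1, R2 = x@hostR2)
})

setMethod("show", "ClassifiedReadStore", function(object) {
    cat("ClassifiedReadStore\n")
    cat(sprintf("  directory:  %s\n", object@dir))
    cat(sprintf("  read pairs: %d (%d barcode-discarded, %d off-whitelist)\n",
                object@nPairs, object@nDiscardedBarcode,
                object@nDiscardedWhitelist))
    ct <- object@classTotals[.READ_CLASSES]
    cat(sprintf("  classes:    %s\n",
                paste(sprintf("%s=%d", names(ct), ct), collapse = " ")))
    cat(sprintf("  barcodes:   %d\n", nrow(object@barcodeTable)))
    invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n")
    cat(sprintf("  genomes: 2 x %d bp, shared fraction %.3f\n",
                object@genomeLength, object@sharedFraction))
    cat(sprintf(
        "  barcodes: %d (graft %.2f, doublet %.2f), %d reads each\n",
        object@nBarcodes, object@graftBarcodeFraction, object@doubletRate,
        object@readsPerBarcode))
    cat(sprintf(
        "  reads: %d bp, barcode %d bp, error rate %.4f, seed %d\n",
        object@readLength, object@barcodeLength, object@errorRate,
        object@seed))
    invisible(NULL)
})
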