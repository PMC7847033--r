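#' @useDynLib xenosplit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.READ_CLASSES <- c("graft", "host", "both", "neither", "ambiguous")

#' Dual-species canonical k-mer index
#'
#' A `KmerIndex` partitions the union of the canonical k-mer sets of two
#' reference sequences (the graft species and the host species) into three
#' pairwise disjoint collections: k-mers unique to the graft reference,
#' k-mers unique to the host reference, and k-mers present in both. All
#' k-mers are stored in canonical form (the lexicographically smaller of a
#' k-mer and its reverse complement), so read classification is
#' strand-neutral.
#'
#' @slot k integer(1), k-mer length in bases (3--31).
#' @slot graftOnly sorted character vector of canonical k-mers found only
#'   in the graft reference.
#' @slot hostOnly sorted character vector of canonical k-mers found only in
#'   the host reference.
#' @slot shared sorted character vector of canonical k-mers found in both
#'   references.
#' @slot graftLabel,hostLabel character(1), species labels used in reports.
#' @slot metadata list of provenance details (source file names).
#'
#' @seealso [buildKmerIndex()], [writeKmerIndex()], [readKmerIndex()]
#' @exportClass KmerIndex
setClass("KmerIndex",
    representation(
        k = "integer",
        graftOnly = "character",
        hostOnly = "character",
        shared = "character",
        graftLabel = "character",
        hostLabel = "character",
        metadata = "list"
    ),
    prototype(
        k = 25L, graftOnly = character(), hostOnly = character(),
        shared = character(), graftLabel = "graft", hostLabel = "host",
        metadata = list()
    )
)

.validKmerSet <- function(kmers, k, what) {
    if (length(kmers) == 0L) return(NULL)
    if (any(nchar(kmers) != k))
        return(sprintf("%s contains k-mers whose length is not k = %d",
                       what, k))
    if (any(grepl("[^ACGT]", kmers)))
        return(sprintf("%s contains non-ACGT characters", what))
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(kmers)))
    if (any(kmers > rc))
        return(sprintf("%s contains non-canonical k-mers", what))
    NULL
}

setValidity("KmerIndex", function(object) {
    msg <- character()
    if (length(object@k) != 1L || is.na(object@k) ||
        object@k < 3L || object@k > 31L)
        msg <- c(msg, "k must be a single integer in [3, 31]")
    for (slot in c("graftOnly", "hostOnly", "shared")) {
        m <- .validKmerSet(slot(object, slot), object@k, slot)
        if (!is.null(m)) msg <- c(msg, m)
    }
    if (length(intersect(object@graftOnly, object@hostOnly)) ||
        length(intersect(object@graftOnly, object@shared)) ||
        length(intersect(object@hostOnly, object@shared)))
        msg <- c(msg, "graftOnly, hostOnly and shared must be pairwise disjoint")
    if (length(msg)) msg else TRUE
})

#' Cellular barcode geometry on read 1
#'
#' Describes where the cellular barcode (and, optionally, the UMI) sits on
#' the barcode-carrying read (R1). Coordinates are 1-based and inclusive,
#' matching common library-kit documentation: a 10x Chromium v3 library has
#' the barcode at positions 1--16 (`barcodeStart = 1`,
#' `barcodeLength = 16`) followed by a 12-base UMI.
#'
#' @slot barcodeStart integer(1), 1-based start of the barcode on R1.
#' @slot barcodeLength integer(1), barcode length in bases.
#' @slot umiStart,umiLength integer(1) or `NA`, UMI position (informational
#'   only: UMI bases are carried through untouched).
#'
#' @seealso [BarcodeGeometry()], [extractBarcode()]
#' @exportClass BarcodeGeometry
setClass("BarcodeGeometry",
    representation(
        barcodeStart = "integer",
        barcodeLength = "integer",
        umiStart = "integer",
        umiLength = "integer"
    ),
    prototype(barcodeStart = 1L, barcodeLength = 16L,
              umiStart = NA_integer_, umiLength = NA_integer_)
)

setValidity("BarcodeGeometry", function(object) {
    msg <- character()
    if (is.na(object@barcodeStart) || object@barcodeStart < 1L)
        msg <- c(msg, "barcodeStart must be >= 1")
    if (is.na(object@barcodeLength) || object@barcodeLength < 1L)
        msg <- c(msg, "barcodeLength must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @param barcodeStart,barcodeLength,umiStart,umiLength see slot
#'   descriptions above.
#' @rdname BarcodeGeometry-class
#' @export
BarcodeGeometry <- function(barcodeStart = 1L, barcodeLength = 16L,
                            umiStart = NA_integer_,
                            umiLength = NA_integer_) {
    new("BarcodeGeometry",
        barcodeStart = as.integer(barcodeStart),
        barcodeLength = as.integer(barcodeLength),
        umiStart = as.integer(umiStart),
        umiLength = as.integer(umiLength))
}

#' Barcode extraction thresholds
#'
#' A closed interval `[lower, upper]` on the per-barcode host-read fraction
#' (host-classified reads over all reads of the barcode), plus the side
#' whose classified reads are written out. Both endpoints are inclusive.
#' Typical regimes: `[0, 0.1]` with `side = "graft"` keeps barcodes with at
#' most 10% host-specific reads; `[0.9, 1]` with `side = "host"` keeps
#' barcodes with at least 90% host-specific reads. Cross-species doublets
#' show intermediate host fractions and fall in neither interval.
#'
#' @slot lower,upper numeric(1) in \[0, 1\] with `lower <= upper`.
#' @slot side `"graft"` or `"host"`: which class's paired FASTQ is
#'   filtered.
#'
#' @seealso [selectBarcodes()], [filterFastqByBarcodes()]
#' @exportClass ExtractionThresholds
setClass("ExtractionThresholds",
    representation(lower = "numeric", upper = "numeric", side = "character"),
    prototype(lower = 0, upper = 0.1, side = "graft")
)

setValidity("ExtractionThresholds", function(object) {
    msg <- character()
    if (is.na(object@lower) || object@lower < 0 || object@lower > 1)
        msg <- c(msg, "lower must be in [0, 1]")
    if (is.na(object@upper) || object@upper < 0 || object@upper > 1)
        msg <- c(msg, "upper must be in [0, 1]")
    if (!is.na(object@lower) && !is.na(object@upper) &&
        object@lower > object@upper)
        msg <- c(msg, "lower must be <= upper")
    if (length(object@side) != 1L || !object@side %in% c("graft", "host"))
        msg <- c(msg, "side must be 'graft' or 'host'")
    if (length(msg)) msg else TRUE
})

#' @param lower,upper,side see slot descriptions above.
#' @rdname ExtractionThresholds-class
#' @export
ExtractionThresholds <- function(lower = 0, upper = 0.1,
                                 side = c("graft", "host")) {
    side <- match.arg(side)
    new("ExtractionThresholds", lower = as.numeric(lower),
        upper = as.numeric(upper), side = side)
}

#' Classified read store
#'
#' The on-disk result of [classifyExperiment()] (workflow step A): the
#' graft- and host-classified paired FASTQ files (reads of the other three
#' classes are not retained), the per-barcode fraction table, and run
#' totals. R1/R2 pairing and input order are preserved within each class.
#'
#' @slot dir output directory.
#' @slot graftR1,graftR2,hostR1,hostR2 paths to the per-class paired FASTQ
#'   files (gzip).
#' @slot tablePath path to the per-barcode CSV table.
#' @slot logPath path to the run log.
#' @slot barcodeTable the barcode table as a data.frame (see
#'   [writeBarcodeTable()] for the columns).
#' @slot classTotals named integer, reads per class among retained
#'   barcodes.
#' @slot nPairs integer(1), input read-pair count.
#' @slot nDiscardedBarcode integer(1), pairs dropped for an unparseable
#'   barcode (R1 too short, or non-ACGT in the barcode).
#' @slot nDiscardedWhitelist integer(1), pairs dropped because the barcode
#'   was not on the whitelist.
#'
#' @seealso [classifyExperiment()], [readClassifiedStore()],
#'   [barcodeTable()]
#' @exportClass ClassifiedReadStore
setClass("ClassifiedReadStore",
    representation(
        dir = "character",
        graftR1 = "character", graftR2 = "character",
        hostR1 = "character", hostR2 = "character",
        tablePath = "character", logPath = "character",
        barcodeTable = "data.frame",
        classTotals = "integer",
        nPairs = "integer",
        nDiscardedBarcode = "integer",
        nDiscardedWhitelist = "integer"
    )
)

setValidity("ClassifiedReadStore", function(object) {
    msg <- character()
    if (!identical(sort(names(object@classTotals)), sort(.READ_CLASSES)))
        msg <- c(msg, "classTotals must be named by the five read classes")
    tab <- object@barcodeTable
    need <- c("barcode", "n_total", "n_graft", "n_host", "n_both",
              "n_neither", "n_ambiguous", "fraction_graft", "fraction_host")
    if (!all(need %in% names(tab)))
        msg <- c(msg, "barcodeTable lacks required columns")
    if (length(msg)) msg else TRUE
})

#' Simulation configuration for synthetic xenograft experiments
#'
#' Parameters of the ground-truth simulator. Defaults emulate a 1:1
#' mixed-species droplet experiment (equal numbers of graft and host
#' cells, a small cross-species doublet rate, 10x-v3-like barcode length
#' and read length, Illumina-like substitution error rate) at desk scale:
#' two 100 kb genomes standing in for the two species' references.
#'
#' @slot genomeLength integer(1), bases per species reference.
#' @slot sharedFraction numeric(1) in \[0, 1\], portion of the host genome
#'   copied verbatim from the graft genome (creates shared k-mers,
#'   emulating sequence conserved between species).
#' @slot nBarcodes integer(1), number of cellular barcodes.
#' @slot graftBarcodeFraction numeric(1), probability a barcode is a graft
#'   singlet.
#' @slot doubletRate numeric(1), probability a barcode is a cross-species
#'   doublet; host singlets take the remaining probability.
#' @slot readsPerBarcode integer(1), read pairs per barcode.
#' @slot readLength integer(1), length of R1 and R2 in bases.
#' @slot barcodeLength integer(1), cellular barcode length on R1.
#' @slot errorRate numeric(1), per-base substitution error rate applied to
#'   the cDNA read (no indels).
#' @slot uniqueRegion logical(1); if `TRUE`, cDNA reads are sampled
#'   entirely outside the shared genome block, so every read carries only
#'   species-specific k-mers.
#' @slot seed integer(1); fixes every random choice of the simulator.
#'
#' @seealso [SimConfig()], [simulateExperiment()]
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        genomeLength = "integer",
        sharedFraction = "numeric",
        nBarcodes = "integer",
        graftBarcodeFraction = "numeric",
        doubletRate = "numeric",
        readsPerBarcode = "integer",
        readLength = "integer",
        barcodeLength = "integer",
        errorRate = "numeric",
        uniqueRegion = "logical",
        seed = "integer"
    ),
    prototype(
        genomeLength = 100000L, sharedFraction = 0, nBarcodes = 400L,
        graftBarcodeFraction = 0.5, doubletRate = 0.05,
        readsPerBarcode = 200L, readLength = 90L, barcodeLength = 16L,
        errorRate = 0.005, uniqueRegion = FALSE, seed = 1L
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    rates <- c(sharedFraction = object@sharedFraction,
               graftBarcodeFraction = object@graftBarcodeFraction,
               doubletRate = object@doubletRate,
               errorRate = object@errorRate)
    bad <- names(rates)[is.na(rates) | rates < 0 | rates > 1]
    if (length(bad))
        msg <- c(msg, sprintf("rates must lie in [0, 1]: %s",
                              paste(bad, collapse = ", ")))
    if (!is.na(object@graftBarcodeFraction) && !is.na(object@doubletRate) &&
        object@graftBarcodeFraction + object@doubletRate > 1)
        msg <- c(msg, "graftBarcodeFraction + doubletRate must be <= 1")
    lens <- c(genomeLength = object@genomeLength,
              readsPerBarcode = object@readsPerBarcode,
              readLength = object@readLength,
              barcodeLength = object@barcodeLength)
    if (any(is.na(lens) | lens < 1L))
        msg <- c(msg, "lengths and counts must be positive")
    if (is.na(object@nBarcodes) || object@nBarcodes < 0L)
        msg <- c(msg, "nBarcodes must be >= 0")
    if (is.na(object@seed))
        msg <- c(msg, "seed must be a finite integer")
    if (length(msg)) msg else TRUE
})

#' @param genomeLength,sharedFraction,nBarcodes,graftBarcodeFraction
#'   see slot descriptions above.
#' @param doubletRate,readsPerBarcode,readLength,barcodeLength,errorRate
#'   see slot descriptions above.
#' @param uniqueRegion,seed see slot descriptions above.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(genomeLength = 100000L, sharedFraction = 0,
                      nBarcodes = 400L, graftBarcodeFraction = 0.5,
                      doubletRate = 0.05, readsPerBarcode = 200L,
                      readLength = 90L, barcodeLength = 16L,
                      errorRate = 0.005, uniqueRegion = FALSE, seed = 1L) {
    new("SimConfig",
        genomeLength = as.integer(genomeLength),
        sharedFraction = as.numeric(sharedFraction),
        nBarcodes = as.integer(nBarcodes),
        graftBarcodeFraction = as.numeric(graftBarcodeFraction),
        doubletRate = as.numeric(doubletRate),
        readsPerBarcode = as.integer(readsPerBarcode),
        readLength = as.integer(readLength),
        barcodeLength = as.integer(barcodeLength),
        errorRate = as.numeric(errorRate),
        uniqueRegion = isTRUE(uniqueRegion),
        seed = as.integer(seed))
}
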