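#' Canonical form of a k-mer
#'
#' Returns, for each input k-mer, the lexicographically smaller of the
#' k-mer and its reverse complement. Canonical k-mers make k-mer identity
#' strand-neutral: a read and its reverse complement yield the same
#' canonical k-mer set, so both strands classify identically.
#'
#' @param x character vector of DNA strings (uppercased internally).
#' @return character vector of the same length, each element canonical.
#'   The function is idempotent.
#' @examples
#' canonicalKmer(c("AAA", "TTT", "ACGTT"))
#' @export
canonicalKmer <- function(x) {
    x <- toupper(as.character(x))
    if (any(grepl("[^ACGT]", x)))
        stop("k-mers must contain only A, C, G, T")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(x)))
    ifelse(x <= rc, x, rc)
}

.readReference <- function(path, what) {
    if (length(path) != 1L || is.na(path) || !file.exists(path))
        stop(sprintf("%s reference FASTA not found: %s", what, path))
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) == 0L || sum(Biostrings::width(seqs)) == 0L)
        stop(sprintf("%s reference FASTA is empty: %s", what, path))
    as.character(seqs)
}

#' Build a dual-species canonical k-mer index
#'
#' Reads two reference FASTA files (plain or gzip; multi-record and
#' line-wrapped records are fine), enumerates the canonical k-mers of each
#' (soft-masked lowercase bases are uppercased; k-mers containing any
#' non-ACGT symbol are skipped), and partitions their union into
#' graft-only, host-only and shared collections.
#'
#' @param graftFasta,hostFasta paths to the graft and host reference FASTA
#'   files.
#' @param k k-mer length, 3--31. The default of 25 follows the convention
#'   of k-mer based read-deconvolution tools.
#' @param graftLabel,hostLabel species labels carried into reports.
#' @return a [KmerIndex-class] object.
#' @examples
#' g <- tempfile(fileext = ".fa"); h <- tempfile(fileext = ".fa")
#' writeLines(c(">g", "AAAAAA"), g)
#' writeLines(c(">h", "CCCCCC"), h)
#' buildKmerIndex(g, h, k = 3)
#' @export
buildKmerIndex <- function(graftFasta, hostFasta, k = 25L,
                           graftLabel = "graft", hostLabel = "host") {
    k <- as.integer(k)
    if (length(k) != 1L || is.na(k) || k < 3L || k > 31L)
        stop("k must be a single integer between 3 and 31")
    gseq <- .readReference(graftFasta, "graft")
    hseq <- .readReference(hostFasta, "host")
    gset <- .kmerSetCpp(gseq, k)
    hset <- .kmerSetCpp(hseq, k)
    shared <- intersect(gset, hset)   # preserves gset's sorted order
    new("KmerIndex",
        k = k,
        graftOnly = setdiff(gset, shared),
        hostOnly = setdiff(hset, shared),
        shared = shared,
        graftLabel = graftLabel,
        hostLabel = hostLabel,
        metadata = list(graft_fasta = basename(graftFasta),
                        host_fasta = basename(hostFasta)))
}

.INDEX_FILES <- c(graft_only = "graft_only.kmers.txt.gz",
                  host_only = "host_only.kmers.txt.gz",
                  shared = "shared.kmers.txt.gz")

#' Serialize / load a k-mer index
#'
#' `writeKmerIndex()` writes one gzip text file per k-mer class (one
#' canonical k-mer per line, byte-sorted, so serialization is
#' byte-reproducible) plus a `metadata.txt` key/value file recording k, the
#' species labels, the source FASTA names and the per-class k-mer counts.
#' `readKmerIndex()` reloads such a directory.
#'
#' @param x a [KmerIndex-class].
#' @param dir directory to write to (created if needed) or read from.
#' @return `writeKmerIndex()` returns `dir` invisibly; `readKmerIndex()`
#'   returns a [KmerIndex-class].
#' @export
writeKmerIndex <- function(x, dir) {
    stopifnot(is(x, "KmerIndex"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sets <- list(graft_only = x@graftOnly, host_only = x@hostOnly,
                 shared = x@shared)
    for (nm in names(.INDEX_FILES)) {
        con <- gzfile(file.path(dir, .INDEX_FILES[[nm]]), "w")
        writeLines(sets[[nm]], con)
        close(con)
    }
    meta <- c(
        k = x@k,
        graft_label = x@graftLabel,
        host_label = x@hostLabel,
        graft_fasta = if (is.null(x@metadata$graft_fasta)) ""
                      else x@metadata$graft_fasta,
        host_fasta = if (is.null(x@metadata$host_fasta)) ""
                     else x@metadata$host_fasta,
        n_graft_only = length(x@graftOnly),
        n_host_only = length(x@hostOnly),
        n_shared = length(x@shared))
    writeLines(paste(names(meta), meta, sep = "\t"),
               file.path(dir, "metadata.txt"))
    invisible(dir)
}

#' @rdname writeKmerIndex
#' @export
readKmerIndex <- function(dir) {
    metaPath <- file.path(dir, "metadata.txt")
    if (!dir.exists(dir) || !file.exists(metaPath))
        stop(sprintf("not a k-mer index directory (no metadata.txt): %s",
                     dir))
    kv <- read.delim(metaPath, header = FALSE, sep = "\t",
                     colClasses = "character", quote = "")
    meta <- stats::setNames(kv[[2L]], kv[[1L]])
    readSet <- function(nm) {
        p <- file.path(dir, .INDEX_FILES[[nm]])
        if (!file.exists(p))
            stop(sprintf("index file missing: %s", p))
        con <- gzfile(p, "r"); on.exit(close(con))
        readLines(con)
    }
    new("KmerIndex",
        k = as.integer(meta[["k"]]),
        graftOnly = readSet("graft_only"),
        hostOnly = readSet("host_only"),
        shared = readSet("shared"),
        graftLabel = meta[["graft_label"]],
        hostLabel = meta[["host_label"]],
        metadata = list(graft_fasta = meta[["graft_fasta"]],
                        host_fasta = meta[["host_fasta"]]))
}
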