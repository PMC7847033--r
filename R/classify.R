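#' Per-read k-mer evidence profiles
#'
#' Counts, for every position-wise k-mer of each read (after uppercasing;
#' k-mers containing non-ACGT characters such as N are excluded), how many
#' fall into each collection of the index. Membership is tested on the
#' canonical form, so a read and its reverse complement produce the same
#' profile. Reads shorter than k have all counts zero.
#'
#' @param x character vector of read sequences.
#' @param index a [KmerIndex-class].
#' @return integer matrix with one row per read and columns `n_graft`,
#'   `n_host`, `n_shared`, `n_unknown`, `n_valid`, where
#'   `n_valid = n_graft + n_host + n_shared + n_unknown` is the number of
#'   ACGT-only k-mers in the read.
#' @seealso [classifyReads()]
#' @export
profileReads <- function(x, index) {
    stopifnot(is(index, "KmerIndex"))
    .profileReadsCpp(as.character(x), index@graftOnly, index@hostOnly,
                     index@shared, index@k)
}

#' @rdname profileReads
#' @param seq a single read sequence.
#' @return `profileRead()` returns a named integer vector (one row of the
#'   matrix).
#' @export
profileRead <- function(seq, index) {
    profileReads(seq, index)[1L, ]
}

#' Five-class read classification
#'
#' Assigns each cDNA read one of five classes from its k-mer evidence:
#' \describe{
#'   \item{graft}{species-specific evidence from the graft only;}
#'   \item{host}{species-specific evidence from the host only;}
#'   \item{ambiguous}{species-specific evidence from both species;}
#'   \item{both}{no species-specific evidence, but k-mers shared by the
#'     two references;}
#'   \item{neither}{no indexed k-mers at all (including reads shorter than
#'     k or made of Ns).}
#' }
#' Only graft- and host-classified reads are considered unambiguously
#' assigned and carried into the filtered output.
#'
#' @param x character vector of read sequences, or a profile matrix as
#'   returned by [profileReads()].
#' @param index a [KmerIndex-class]; required when `x` is a character
#'   vector.
#' @param minSpecific minimum number of species-specific k-mers required to
#'   count as evidence for a species (default 1: a single specific k-mer
#'   decides). Counts below `minSpecific` are treated as absent.
#' @return factor of class labels with levels
#'   `c("graft", "host", "both", "neither", "ambiguous")`.
#' @examples
#' g <- tempfile(fileext = ".fa"); h <- tempfile(fileext = ".fa")
#' writeLines(c(">g", "AAAAAA"), g)
#' writeLines(c(">h", "CCCCCC"), h)
#' idx <- buildKmerIndex(g, h, k = 3)
#' classifyReads(c("AAAA", "CCCC", "AAACCC", "GTGTGT"), idx)
#' @export
classifyReads <- function(x, index = NULL, minSpecific = 1L) {
    if (is.character(x)) {
        if (is.null(index))
            stop("'index' is required when 'x' is a character vector")
        x <- profileReads(x, index)
    }
    stopifnot(is.matrix(x),
              all(c("n_graft", "n_host", "n_shared") %in% colnames(x)),
              minSpecific >= 1L)
    g <- x[, "n_graft"] >= minSpecific
    h <- x[, "n_host"] >= minSpecific
    s <- x[, "n_shared"] > 0L
    lab <- rep("neither", nrow(x))
    lab[g & !h] <- "graft"
    lab[h & !g] <- "host"
    lab[g & h] <- "ambiguous"
    lab[!g & !h & s] <- "both"
    factor(lab, levels = .READ_CLASSES)
}

#' @rdname classifyReads
#' @param profile a named vector or one-row matrix from [profileRead()].
#' @return `classifyRead()` returns a single factor level.
#' @export
classifyRead <- function(profile, minSpecific = 1L) {
    if (!is.matrix(profile)) profile <- t(as.matrix(profile))
    classifyReads(profile, minSpecific = minSpecific)[1L]
}
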