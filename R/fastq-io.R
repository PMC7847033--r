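# Minimal streaming layer over 4-line FASTQ records. Records pass through
# verbatim (headers, sequences, qualities untouched), which is the output
# contract of the whole tool; memory use is bounded by the chunk size and
# the number of distinct barcodes, not by the number of reads.

.fqOpenRead <- function(path) {
    if (!file.exists(path)) stop(sprintf("FASTQ file not found: %s", path))
    if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
}

# output is always gzip
.fqOpenWrite <- function(path) gzfile(path, "w")

# read up to n records (4n lines); errors on a truncated final record
.fqReadChunk <- function(con, n, path) {
    lines <- readLines(con, n = 4L * n)
    if (length(lines) %% 4L != 0L)
        stop(sprintf("truncated FASTQ record in %s", path))
    lines
}

# line indices of whole records, given record indices within a chunk
.recLines <- function(recIdx) {
    rep((recIdx - 1L) * 4L, each = 4L) + rep(1:4, length(recIdx))
}

# first whitespace-delimited token of the header, minus a trailing /1 or
# /2 mate suffix and the leading '@'
.fqReadId <- function(headers) {
    sub("/[12]$", "", sub("\\s.*$", "", sub("^@", "", headers)))
}
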