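# Shared fixtures and independent oracles, all built in code at test time.

revcomp_str <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
    path
}

write_fastq <- function(ids, seqs, path = tempfile(fileext = ".fastq"),
                        quals = strrep("I", nchar(seqs))) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    if (length(ids))
        writeLines(as.vector(rbind(paste0("@", ids), seqs,
                                   rep("+", length(ids)), quals)), con)
    close(con)
    path
}

read_fastq_lines <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
    on.exit(close(con))
    readLines(con)
}

random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent enumeration of the canonical k-mer set of sequences, via
# substring slicing and string comparison (no shared code with the package
# k-mer engine).
brute_canonical_set <- function(seqs, k) {
    out <- character()
    for (s in toupper(seqs)) {
        n <- nchar(s) - k + 1L
        if (n < 1L) next
        km <- substring(s, seq_len(n), seq_len(n) + k - 1L)
        km <- km[!grepl("[^ACGT]", km)]
        if (length(km)) {
            rc <- revcomp_str(km)
            out <- c(out, ifelse(km <= rc, km, rc))
        }
    }
    sort(unique(out), method = "radix")
}

# Brute-force read-classification oracle: membership of every read k-mer is
# decided by scanning the genome strings (forward and reverse-complement)
# with fixed-string search, never via the package's index.
oracle_classify <- function(reads, graft_seq, host_seq, k) {
    gF <- toupper(graft_seq); gR <- revcomp_str(gF)
    hF <- toupper(host_seq); hR <- revcomp_str(hF)
    vapply(toupper(reads), function(read) {
        n <- nchar(read) - k + 1L
        n_g <- 0L; n_h <- 0L; n_s <- 0L; n_u <- 0L
        if (n >= 1L) {
            for (i in seq_len(n)) {
                km <- substr(read, i, i + k - 1L)
                if (grepl("[^ACGT]", km)) next
                in_g <- grepl(km, gF, fixed = TRUE) ||
                    grepl(km, gR, fixed = TRUE)
                in_h <- grepl(km, hF, fixed = TRUE) ||
                    grepl(km, hR, fixed = TRUE)
                if (in_g && in_h) n_s <- n_s + 1L
                else if (in_g) n_g <- n_g + 1L
                else if (in_h) n_h <- n_h + 1L
                else n_u <- n_u + 1L
            }
        }
        if (n_g > 0L && n_h == 0L) "graft"
        else if (n_h > 0L && n_g == 0L) "host"
        else if (n_g > 0L && n_h > 0L) "ambiguous"
        else if (n_s > 0L) "both"
        else "neither"
    }, character(1), USE.NAMES = FALSE)
}

# Toy index with all three k-mer classes populated (k = 3):
#   graft "AAAAAAGTGTGTG", host "CCCCCCGTGTGTG"
# -> AAA (and A-rich boundary k-mers) graft-only, CCC-side host-only,
#    ACA/CAC (canonical forms of TGT/GTG) shared.
toy_refs <- function() {
    list(graft = "AAAAAAGTGTGTG", host = "CCCCCCGTGTGTG")
}

toy_index <- function() {
    refs <- toy_refs()
    buildKmerIndex(write_fasta(c(g = refs$graft)),
                   write_fasta(c(h = refs$host)), k = 3)
}

# Paired FASTQ for one experiment from per-read barcodes and cDNA
# sequences; R1 = barcode (+ T filler), headers shared between mates.
write_paired_fastq <- function(barcodes, cdna, dir = tempfile("fq"),
                               r1_extra = "") {
    dir.create(dir, showWarnings = FALSE)
    ids <- sprintf("read%04d", seq_along(barcodes))
    r1 <- write_fastq(paste0(ids, "/1"), paste0(barcodes, r1_extra),
                      file.path(dir, "r1.fastq"))
    r2 <- write_fastq(paste0(ids, "/2"), cdna, file.path(dir, "r2.fastq"))
    list(r1 = r1, r2 = r2)
}
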