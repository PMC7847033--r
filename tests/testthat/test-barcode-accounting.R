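geo5 <- BarcodeGeometry(barcodeStart = 1, barcodeLength = 5)

test_that("extractBarcode slices 1-based inclusive coordinates", {
    geo16 <- BarcodeGeometry(barcodeStart = 1, barcodeLength = 16)
    expect_identical(extractBarcode("ACGTACGTACGTACGT", geo16),
                     "ACGTACGTACGTACGT")
    # too short
    expect_identical(extractBarcode("ACGTACGT", geo16), NA_character_)
    # N inside the barcode
    expect_identical(extractBarcode("AANGTACGTACGT", geo5), NA_character_)
    # interior geometry
    geo <- BarcodeGeometry(barcodeStart = 3, barcodeLength = 4)
    expect_identical(extractBarcode("TTACGTTT", geo), "ACGT")
})

# classes on the toy index (k = 3): "AAAA" graft, "CCCC" host,
# "AAACCC" ambiguous, "GTGTG" both, "TATA" neither
toy_experiment <- function(barcodes, cdna) {
    pair <- write_paired_fastq(barcodes, cdna)
    classifyExperiment(pair$r1, pair$r2, toy_index(), geo5,
                       tempfile("store"))
}

test_that("a pure barcode yields fractions 1 and 0", {
    st <- toy_experiment(rep("ACGTA", 10), rep("AAAA", 10))
    tab <- barcodeTable(st)
    expect_equal(nrow(tab), 1L)
    expect_equal(tab$n_total, 10L)
    expect_equal(tab$fraction_graft, 1)
    expect_equal(tab$fraction_host, 0)
})

test_that("fractions use all reads of the barcode as denominator", {
    # (graft = 4, host = 4, ambiguous = 2) -> 0.4 / 0.4
    st <- toy_experiment(rep("ACGTA", 10),
                         c(rep("AAAA", 4), rep("CCCC", 4),
                           rep("AAACCC", 2)))
    tab <- barcodeTable(st)
    expect_equal(tab$fraction_graft, 0.4)
    expect_equal(tab$fraction_host, 0.4)

    # (graft = 6, host = 1, both = 2, neither = 1) -> 0.6 / 0.1:
    # both/neither inflate only the denominator
    st2 <- toy_experiment(rep("ACGTA", 10),
                          c(rep("AAAA", 6), "CCCC", rep("GTGTG", 2),
                            "TATA"))
    tab2 <- barcodeTable(st2)
    expect_equal(tab2$n_both, 2L)
    expect_equal(tab2$n_neither, 1L)
    expect_equal(tab2$fraction_graft, 0.6)
    expect_equal(tab2$fraction_host, 0.1)
})

test_that("the CSV table has the fixed dialect and round-trips", {
    st <- toy_experiment(rep("ACGTA", 10),
                         c(rep("AAAA", 4), rep("CCCC", 4),
                           rep("AAACCC", 2)))
    lines <- readLines(st@tablePath)
    expect_identical(lines[1],
        "barcode,n_total,n_graft,n_host,n_both,n_neither,n_ambiguous,fraction_graft,fraction_host")
    expect_identical(lines[2], "ACGTA,10,4,4,0,0,2,0.400000,0.400000")

    back <- readBarcodeTable(st@tablePath)
    expect_equal(back$n_graft, barcodeTable(st)$n_graft)
    expect_equal(back$fraction_host, barcodeTable(st)$fraction_host,
                 tolerance = 1e-6)

    # rewriting the parsed records is byte-identical
    p2 <- tempfile(fileext = ".csv")
    writeBarcodeTable(back, p2)
    expect_identical(readLines(p2), lines)

    # empty record set -> header-only file
    p3 <- tempfile(fileext = ".csv")
    writeBarcodeTable(back[0, ], p3)
    expect_identical(readLines(p3), lines[1])
})

test_that("rows are sorted by barcode in byte order", {
    st <- toy_experiment(c("TTTTT", "AAAAA", "GGGGG"),
                         rep("AAAA", 3))
    expect_identical(barcodeTable(st)$barcode,
                     c("AAAAA", "GGGGG", "TTTTT"))
})

test_that("reads are conserved across table rows and discards", {
    barcodes <- c(rep("ACGTA", 5), rep("TTTTT", 4), "AANGT", "ACG")
    cdna <- c(rep("AAAA", 5), rep("CCCC", 4), "AAAA", "AAAA")
    st <- toy_experiment(barcodes, cdna)
    tab <- barcodeTable(st)
    # per-row counts sum to n_total
    expect_equal(tab$n_graft + tab$n_host + tab$n_both + tab$n_neither +
                 tab$n_ambiguous, tab$n_total)
    # conservation: table totals + discards = input pairs
    expect_equal(sum(tab$n_total) + st@nDiscardedBarcode, st@nPairs)
    expect_equal(st@nDiscardedBarcode, 2L)
    expect_true(all(tab$fraction_graft >= 0 & tab$fraction_graft <= 1))
    expect_true(all(tab$fraction_graft + tab$fraction_host <= 1))
})

test_that("per-class FASTQ outputs hold exactly the right pairs, in order", {
    barcodes <- c("AAAAA", "CCCCC", "AAAAA", "GGGGG", "CCCCC")
    cdna <- c("AAAA", "CCCC", "AAACCC", "AAAA", "TATA")
    pair <- write_paired_fastq(barcodes, cdna)
    st <- classifyExperiment(pair$r1, pair$r2, toy_index(), geo5,
                             tempfile("store"))
    in1 <- readLines(pair$r1); in2 <- readLines(pair$r2)
    g1 <- read_fastq_lines(st@graftR1); g2 <- read_fastq_lines(st@graftR2)
    h1 <- read_fastq_lines(st@hostR1); h2 <- read_fastq_lines(st@hostR2)
    # graft pair: records 1 and 4 verbatim, in input order
    expect_identical(g1, in1[c(1:4, 13:16)])
    expect_identical(g2, in2[c(1:4, 13:16)])
    # host pair: record 2 only (record 5 is neither)
    expect_identical(h1, in1[5:8])
    expect_identical(h2, in2[5:8])
    # pairing preserved: mate ids line up record by record
    ids <- function(l) sub("/[12]$", "", sub("^@", "", l[seq(1, length(l), 4)]))
    expect_identical(ids(g1), ids(g2))
})

test_that("a whitelist restricts the table and outputs", {
    barcodes <- c(rep("AAAAA", 4), rep("CCCCC", 3), rep("GGGGG", 3))
    cdna <- rep("AAAA", 10)
    pair <- write_paired_fastq(barcodes, cdna)
    st <- classifyExperiment(pair$r1, pair$r2, toy_index(), geo5,
                             tempfile("store"),
                             whitelist = c("AAAAA", "CCCCC"))
    tab <- barcodeTable(st)
    expect_identical(tab$barcode, c("AAAAA", "CCCCC"))
    expect_equal(st@nDiscardedWhitelist, 3L)
    expect_equal(sum(tab$n_total) + st@nDiscardedWhitelist, st@nPairs)
    # whitelist may come from a file, too
    wl <- tempfile(); writeLines(c("AAAAA", "CCCCC"), wl)
    st2 <- classifyExperiment(pair$r1, pair$r2, toy_index(), geo5,
                              tempfile("store"), whitelist = wl)
    expect_identical(barcodeTable(st2), tab)
})

test_that("pairing violations are fatal and name the record", {
    pair <- write_paired_fastq(rep("AAAAA", 3), rep("AAAA", 3))
    short <- write_fastq(c("read0001/2", "read0002/2"), rep("AAAA", 2))
    expect_error(
        classifyExperiment(pair$r1, short, toy_index(), geo5,
                           tempfile("store")),
        "record counts differ")
    renamed <- write_fastq(c("read0001/2", "other/2", "read0003/2"),
                           rep("AAAA", 3))
    expect_error(
        classifyExperiment(pair$r1, renamed, toy_index(), geo5,
                           tempfile("store")),
        "mismatch at record 2")
})

test_that("mate headers match ignoring /1 /2 and read-number suffixes", {
    r1 <- write_fastq(c("a:1 1:N:0:ACGT", "a:2/1"), c("AAAAA", "AAAAA"))
    r2 <- write_fastq(c("a:1 2:N:0:ACGT", "a:2/2"), c("AAAA", "CCCC"))
    st <- classifyExperiment(r1, r2, toy_index(), geo5, tempfile("store"))
    expect_equal(st@nPairs, 2L)
})

test_that("a store directory can be reopened", {
    st <- toy_experiment(rep("ACGTA", 6),
                         c(rep("AAAA", 3), rep("CCCC", 3)))
    back <- readClassifiedStore(st@dir)
    expect_identical(barcodeTable(back), barcodeTable(st))
    expect_identical(classTotals(back), classTotals(st))
    expect_identical(back@nPairs, st@nPairs)
    expect_error(readClassifiedStore(tempfile("nope")),
                 "classifyExperiment")
})
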