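geo5 <- BarcodeGeometry(barcodeStart = 1, barcodeLength = 5)

# a small barcode table with known host fractions
fraction_table <- function(fracs, n_total = 20L) {
    n_host <- as.integer(round(fracs * n_total))
    data.frame(
        barcode = sprintf("BC%03d", seq_along(fracs)),
        n_total = n_total,
        n_graft = n_total - n_host,
        n_host = n_host,
        n_both = 0L, n_neither = 0L, n_ambiguous = 0L,
        fraction_graft = (n_total - n_host) / n_total,
        fraction_host = n_host / n_total,
        stringsAsFactors = FALSE)
}

test_that("selectBarcodes keeps the closed host-fraction interval", {
    tab <- fraction_table(c(0, 0.05, 0.1, 0.15, 0.5, 0.9, 0.95, 1))
    # graft regime: at most 10% host-specific reads, bounds inclusive
    sel <- selectBarcodes(tab, ExtractionThresholds(0, 0.1, "graft"))
    expect_identical(sel, c("BC001", "BC002", "BC003"))
    # host regime: at least 90% host-specific reads
    selH <- selectBarcodes(tab, ExtractionThresholds(0.9, 1, "host"))
    expect_identical(selH, c("BC006", "BC007", "BC008"))
    # full interval keeps everything; side never changes selection
    expect_identical(selectBarcodes(tab, ExtractionThresholds(0, 1, "graft")),
                     sort(tab$barcode))
    expect_identical(
        selectBarcodes(tab, ExtractionThresholds(0, 0.1, "host")), sel)
})

test_that("threshold objects validate their interval", {
    expect_error(ExtractionThresholds(0.5, 0.1, "graft"), "lower")
    expect_error(ExtractionThresholds(-0.1, 0.5, "graft"), "lower")
    expect_error(ExtractionThresholds(0, 1.5, "graft"), "upper")
})

# store with 3 barcodes x 10 graft reads and 2 barcodes x 5 host reads
fixture_store <- function() {
    barcodes <- c(rep("AAAAA", 10), rep("CCCCC", 10), rep("GGGGG", 10),
                  rep("TTTTT", 5), rep("ATATA", 5))
    cdna <- c(rep("AAAA", 30), rep("CCCC", 10))
    pair <- write_paired_fastq(barcodes, cdna)
    classifyExperiment(pair$r1, pair$r2, toy_index(), geo5,
                       tempfile("store"))
}

test_that("filterFastqByBarcodes keeps exactly the selected barcodes", {
    st <- fixture_store()
    th <- ExtractionThresholds(0, 0.1, "graft")
    res <- filterFastqByBarcodes(st, c("AAAAA", "GGGGG"), th, geo5,
                                 tempfile("out"))
    expect_equal(res$kept, 20L)
    expect_equal(res$dropped, 10L)
    lines <- read_fastq_lines(res$r1)
    expect_length(lines, 80L)
    bcs <- substr(lines[seq(2, length(lines), 4)], 1, 5)
    expect_setequal(unique(bcs), c("AAAAA", "GGGGG"))
    report <- read.csv(res$report, colClasses = c("character", "integer"))
    expect_identical(report$barcode, c("AAAAA", "GGGGG"))
    expect_equal(report$n_reads_kept, c(10L, 10L))
})

test_that("empty selection writes empty, selecting all is the identity", {
    st <- fixture_store()
    th <- ExtractionThresholds(0, 0.1, "graft")
    resEmpty <- filterFastqByBarcodes(st, character(0), th, geo5,
                                      tempfile("out"))
    expect_true(file.exists(resEmpty$r1) && file.exists(resEmpty$r2))
    expect_length(read_fastq_lines(resEmpty$r1), 0L)
    expect_equal(resEmpty$kept, 0L)

    all_bcs <- barcodeTable(st)$barcode
    resAll <- filterFastqByBarcodes(st, all_bcs, th, geo5, tempfile("out"))
    expect_identical(read_fastq_lines(resAll$r1),
                     read_fastq_lines(st@graftR1))
    expect_identical(read_fastq_lines(resAll$r2),
                     read_fastq_lines(st@graftR2))
})

test_that("output is a byte-identical subsequence of the class files", {
    st <- fixture_store()
    th <- ExtractionThresholds(0, 0.1, "graft")
    res <- filterFastqByBarcodes(st, c("CCCCC"), th, geo5, tempfile("out"))
    out <- read_fastq_lines(res$r1)
    src <- read_fastq_lines(st@graftR1)
    srcBc <- substr(src[seq(2, length(src), 4)], 1, 5)
    keep <- which(srcBc == "CCCCC")
    li <- rep((keep - 1L) * 4L, each = 4L) + rep(1:4, length(keep))
    expect_identical(out, src[li])
})

test_that("one-call extraction composes selection and filtering", {
    st <- fixture_store()
    # host fractions: AAAAA/CCCCC/GGGGG = 0, TTTTT/ATATA = 1
    resG <- extractCellularBarcodes(st, geo5, tempfile("g"),
                                    lower = 0, upper = 0.1)
    expect_setequal(resG$selected, c("AAAAA", "CCCCC", "GGGGG"))
    expect_equal(resG$kept, 30L)
    resH <- hostSideExtraction(st, geo5, tempfile("h"))
    expect_setequal(resH$selected, c("ATATA", "TTTTT"))
    expect_equal(resH$kept, 10L)
    # graft and host selections are disjoint when the intervals are
    expect_length(intersect(resG$selected, resH$selected), 0)
    # a store directory path works in place of the object
    resDir <- extractCellularBarcodes(st@dir, geo5, tempfile("d"),
                                      lower = 0, upper = 0.1)
    expect_setequal(resDir$selected, resG$selected)
})

test_that("host-side selection follows the 0.9-1 regime", {
    tab <- fraction_table(c(0.95, 0.5, 1))
    sel <- selectBarcodes(tab, ExtractionThresholds(0.9, 1, "host"))
    expect_identical(sel, c("BC001", "BC003"))
    # empty table -> empty selection
    expect_length(selectBarcodes(tab[0, ],
                                 ExtractionThresholds(0.9, 1, "host")), 0)
})

test_that("widening the interval never shrinks selection or output", {
    st <- fixture_store()
    tab <- barcodeTable(st)
    intervals <- list(c(0, 0), c(0, 0.1), c(0, 0.6), c(0, 1))
    prevSel <- character(0); prevKept <- -1L
    for (iv in intervals) {
        th <- ExtractionThresholds(iv[1], iv[2], "graft")
        sel <- selectBarcodes(tab, th)
        expect_true(all(prevSel %in% sel))
        res <- filterFastqByBarcodes(st, sel, th, geo5, tempfile("mono"))
        expect_gte(res$kept, prevKept)
        prevSel <- sel; prevKept <- res$kept
    }
})

test_that("missing class files are fatal with a remediation hint", {
    st <- fixture_store()
    unlink(st@hostR1)
    expect_error(
        filterFastqByBarcodes(st, "TTTTT",
                              ExtractionThresholds(0.9, 1, "host"),
                              geo5, tempfile("out")),
        "re-run classifyExperiment")
})
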