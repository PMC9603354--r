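test_that("simulated records round-trip through write and parse exactly", {
    for (cfg in list(simConfig(seed = 101),
                     simConfig(seed = 102, wrap_cr = TRUE))) {
        set.seed(cfg$seed)
        g <- simulateRecord(ancestralOrder(), cfg)
        tf <- withr::local_tempfile(fileext = ".gb")
        writeGenBank(g, tf)
        g2 <- parseGenBank(tf)[[1]]
        expect_identical(featureTable(g2), featureTable(g))
        expect_identical(as.character(genomeSeq(g2)),
                         as.character(genomeSeq(g)))
        expect_identical(accession(g2), accession(g))
        expect_true(orderIdentical(extractOrder(g2), ancestralOrder()))
    }
})

test_that("origin-spanning control region gets the modular length", {
    set.seed(9)
    seq16500 <- paste(sample(c("A", "C", "G", "T"), 16500, replace = TRUE),
                      collapse = "")
    g <- annotatedMitogenome("wrap1", seq16500, data.frame(
        symbol = c("cox1", "CR"),
        start = c(1000, 16300), end = c(2535, 500),
        strand = c("+", "+")))
    ft <- featureTable(g)
    expect_equal(ft$length[ft$symbol == "CR"], 701)
    # and the coordinates survive a write/parse cycle as a join() location
    tf <- withr::local_tempfile(fileext = ".gb")
    writeGenBank(g, tf)
    # (the two-feature toy record also warns about missing genes)
    ft2 <- featureTable(suppressWarnings(parseGenBank(tf))[[1]])
    expect_identical(ft2, ft)
    expect_equal(length(featureSeq(g, "CR")), 701)
})

test_that("a record lacking trnI parses with a warning, not an error", {
    reduced <- arrangementTypeOrders()$IV   # the trnI-less arrangement
    set.seed(31)
    g <- simulateRecord(reduced, simConfig(seed = 31))
    tf <- withr::local_tempfile(fileext = ".gb")
    writeGenBank(g, tf)
    expect_warning(parsed <- parseGenBank(tf), "trnI")
    expect_length(genomeFeatures(parsed[[1]]), 37L)
})

test_that("unmappable features are skipped with a warning, parse succeeds", {
    set.seed(77)
    g <- simulateRecord(ancestralOrder(), simConfig(seed = 77))
    tf <- withr::local_tempfile(fileext = ".gb")
    writeGenBank(g, tf)
    lines <- readLines(tf)
    i <- grep('/gene="nad2"', lines)[1]
    lines[i] <- sub("nad2", "mystery_orf", lines[i])
    lines[i + 1L] <- sub("NADH dehydrogenase subunit 2", "hypothetical protein",
                         lines[i + 1L])
    writeLines(lines, tf)
    w <- capture_warnings(parsed <- parseGenBank(tf))
    expect_true(any(grepl("unmappable", w)))   # plus a missing-gene warning
    expect_false("nad2" %in% featureTable(parsed[[1]])$symbol)
    expect_length(genomeFeatures(parsed[[1]]), 37L)
})

test_that("gene-name normalization resolves aliases and anticodon families", {
    expect_identical(normalizeSymbol("tRNA-Leu", anticodon = "tag"), "trnL1")
    expect_identical(normalizeSymbol("tRNA-Leu", anticodon = "uaa"), "trnL2")
    expect_identical(normalizeSymbol("tRNA-Ser", anticodon = "gct"), "trnS1")
    expect_identical(normalizeSymbol("", product = "tRNA-Ser (UCN)"), "trnS2")
    expect_identical(
        normalizeSymbol("ND2", product = "NADH dehydrogenase subunit 2"),
        "nad2")
    expect_identical(normalizeSymbol("COI"), "cox1")
    expect_identical(normalizeSymbol("CYTB"), "cob")
    expect_identical(normalizeSymbol("", product = "16S ribosomal RNA"),
                     "rrnL")
    expect_identical(normalizeSymbol("D-loop"), "CR")
    expect_identical(normalizeSymbol("trnW"), "trnW")
    err <- tryCatch(normalizeSymbol("", product = "tRNA-Ser"),
                    condition = identity)
    expect_s3_class(err, "mitoRearr_unresolved_symbol")
    err2 <- tryCatch(normalizeSymbol("orf1234"), condition = identity)
    expect_s3_class(err2, "mitoRearr_unresolved_symbol")
})

test_that("non-GenBank input fails with a format error naming the problem", {
    tf <- withr::local_tempfile(fileext = ".gb")
    writeLines(c(">seq1", "ACGT"), tf)
    expect_error(parseGenBank(tf), "LOCUS")
})
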