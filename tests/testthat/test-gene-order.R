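rotate <- function(o, k) {
    n <- length(o)
    idx <- c((k + 1):n, seq_len(k))
    signedGeneOrder(geneSymbols(o)[idx], geneSigns(o)[idx], provenance(o))
}

test_that("the ancestral order constant has the landmark neighbourhoods", {
    anc <- ancestralOrder()
    expect_length(anc, 38L)
    syms <- geneSymbols(anc)
    nb <- function(g) syms[match(g, syms) + c(-1L, 1L)]
    # rrnL lies between trnL1 and trnV; rrnS between trnV and the CR
    expect_setequal(nb("rrnL"), c("trnL1", "trnV"))
    expect_setequal(nb("rrnS"), c("trnV", "CR"))
    # the A-R-N-S1-E-F tRNA run
    i <- match("trnA", syms)
    expect_identical(syms[i:(i + 5)],
                     c("trnA", "trnR", "trnN", "trnS1", "trnE", "trnF"))
    # minority-strand genes as in the ancestral arrangement
    minus <- syms[geneSigns(anc) < 0]
    expect_setequal(minus, c("trnQ", "trnC", "trnY", "trnF", "nad5", "trnH",
                             "nad4", "nad4l", "trnP", "nad1", "trnL1",
                             "rrnL", "trnV", "rrnS"))
})

test_that("extractOrder walks features by start and respects strands", {
    set.seed(71)
    g <- simulateRecord(ancestralOrder(), simConfig(seed = 71))
    expect_true(orderIdentical(extractOrder(g), ancestralOrder()))
    # overlapping atp8/atp6: order by start position
    s <- paste(rep("ACGT", 300), collapse = "")
    g2 <- annotatedMitogenome("ovl", s, data.frame(
        symbol = c("atp8", "atp6", "cox1"),
        start = c(10, 150, 500), end = c(168, 820, 1100),
        strand = "+"))
    expect_identical(geneSymbols(extractOrder(g2))[1:2], c("atp8", "atp6"))
    # identical starts: longer feature first, with a warning
    g3 <- annotatedMitogenome("tie", s, data.frame(
        symbol = c("atp8", "atp6"), start = c(10, 10), end = c(168, 820),
        strand = "+"))
    expect_warning(o3 <- extractOrder(g3), "share start")
    expect_identical(geneSymbols(o3), c("atp6", "atp8"))
})

test_that("canonicalization is idempotent and collapses rotations", {
    anc <- ancestralOrder()
    can <- canonicalizeOrder(anc)
    expect_identical(geneSymbols(canonicalizeOrder(can)), geneSymbols(can))
    expect_identical(geneSymbols(can)[1], "cox1")
    for (k in c(1, 7, 20, 37)) {
        r <- canonicalizeOrder(rotate(anc, k))
        expect_identical(geneSymbols(r), geneSymbols(can))
        expect_identical(geneSigns(r), geneSigns(can))
    }
    # a single sign difference survives canonicalization
    flip <- geneSigns(anc)
    flip[match("trnW", geneSymbols(anc))] <- -1L
    can2 <- canonicalizeOrder(signedGeneOrder(geneSymbols(anc), flip))
    expect_false(identical(geneSigns(can2), geneSigns(can)))
    # records deposited on the opposite strand normalize to the same form
    refl <- signedGeneOrder(rev(geneSymbols(anc)), -rev(geneSigns(anc)))
    can3 <- canonicalizeOrder(refl)
    expect_identical(geneSymbols(can3), geneSymbols(can))
    expect_identical(geneSigns(can3), geneSigns(can))
    # anchor fallback: no cox1 -> rrnS leads; both absent is an error
    no_cox1 <- signedGeneOrder(setdiff(geneSymbols(anc), "cox1"))
    expect_identical(geneSymbols(canonicalizeOrder(no_cox1))[1], "rrnS")
    expect_error(canonicalizeOrder(signedGeneOrder(c("trnA", "trnB"))),
                 "anchor")
})

test_that("type classification partitions by canonical identity", {
    anc <- ancestralOrder()
    # three rotated copies of the ancestor form one type, labelled I
    cohort <- list(rotate(anc, 3), rotate(anc, 11), anc)
    cl <- classifyTypes(cohort)
    expect_identical(unique(cl$assignments$type_id), "I")
    # the eight packaged canonical orders give exactly eight types
    cl8 <- classifyTypes(arrangementTypeOrders())
    expect_length(unique(cl8$assignments$type_id), 8L)
    expect_identical(cl8$assignments$type_id[1], "I")
    # classification is invariant under arbitrary per-genome rotation
    set.seed(72)
    rotated <- lapply(arrangementTypeOrders(), function(o) {
        rotate(o, sample(length(o) - 1L, 1L))
    })
    expect_identical(classifyTypes(rotated)$assignments$type_id,
                     cl8$assignments$type_id)
})

test_that("novel arrangements get NEW labels, one per distinct order", {
    anc <- ancestralOrder()
    set.seed(73)
    k <- 4L
    derived <- list()
    while (length(derived) < k) {
        cand <- randomSingleEvent(anc)$result
        dup <- any(vapply(derived, orderIdentical, logical(1), b = cand)) ||
            orderIdentical(cand, anc)
        if (!dup) derived[[length(derived) + 1L]] <- cand
    }
    cl <- classifyTypes(c(list(anc), derived))
    expect_length(unique(cl$assignments$type_id), k + 1L)
    expect_identical(cl$assignments$type_id[1], "I")
    expect_true(all(grepl("^NEW-", cl$assignments$type_id[-1]) |
                        cl$assignments$type_id[-1] %in%
                            c("II", "III", "IV", "V", "VI", "VII", "VIII")))
})

test_that("a genome missing a gene forms its own reduced-order type", {
    anc <- ancestralOrder()
    t4 <- arrangementTypeOrders()$IV
    cl <- classifyTypes(list(anc, t4, t4))
    tab <- table(cl$assignments$type_id)
    expect_equal(unname(tab[["IV"]]), 2L)
    expect_equal(unname(tab[["I"]]), 1L)
})

test_that("the gene-order text format round-trips canonical forms", {
    orders <- arrangementTypeOrders()
    tf <- withr::local_tempfile(fileext = ".txt")
    writeGeneOrders(orders, tf)
    back <- readGeneOrders(tf)
    expect_length(back, length(orders))
    for (i in seq_along(orders)) {
        expect_true(orderIdentical(back[[i]], orders[[i]]))
        expect_identical(provenance(back[[i]]), provenance(orders[[i]]))
    }
})
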