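idx_of <- function(g, o) match(g, geneSymbols(o))

test_that("the four published single-event mechanisms reproduce their types", {
    anc <- ancestralOrder()
    tt <- arrangementTypeOrders()
    # TDRL of I-Q-M losing both trnI copies, the first trnQ and first trnM
    t4 <- applyEvent(anc, tdrlEvent(idx_of("trnI", anc), 3L, c(1, 2, 3, 4)))
    expect_true(orderIdentical(t4, tt$IV))
    expect_false("trnI" %in% geneSymbols(t4))
    # TDRL of Q-M-ND2 losing the first trnQ, second trnM, second nad2
    t7 <- applyEvent(anc, tdrlEvent(idx_of("trnQ", anc), 3L, c(1, 5, 6)))
    expect_true(orderIdentical(t7, tt$VII))
    # transposition of trnM to 5' of trnI gives the M-I-Q arrangement
    t6 <- applyEvent(anc, transpositionEvent(idx_of("trnM", anc), 1L, 0L))
    expect_true(orderIdentical(t6, tt$VI))
    expect_identical(geneSymbols(t6)[1:3], c("trnM", "trnI", "trnQ"))
    # inversion of the N-S1-E cluster gives -E -S1 -N
    t2 <- applyEvent(anc, inversionEvent(idx_of("trnN", anc), 3L))
    expect_true(orderIdentical(t2, tt$II))
})

test_that("inversion is an involution and TDRL can undo itself", {
    set.seed(91)
    for (rep in 1:10) {
        o <- randomOrder(12)
        n <- length(o)
        start <- sample(n, 1); len <- sample(3, 1)
        idx <- (((start - 1) + seq_len(len) - 1) %% n) + 1
        if (match("CR", geneSymbols(o)) %in% idx) next
        ev <- inversionEvent(start, len)
        expect_true(orderIdentical(applyEvent(applyEvent(o, ev), ev), o))
        # losing the entire second copy of a TDRL block is the identity
        ev2 <- tdrlEvent(start, len, len + seq_len(len))
        expect_true(orderIdentical(applyEvent(o, ev2), o))
    }
})

test_that("blocks spanning the circular origin are handled", {
    anc <- ancestralOrder()
    n <- length(anc)
    # invert a block wrapping from the penultimate element through the first
    ev <- inversionEvent(n - 1L, 3L)
    out <- applyEvent(anc, ev)
    expect_length(out, n)
    expect_true(orderIdentical(applyEvent(out, inversionEvent(1L, 3L)), anc))
})

test_that("invalid events are rejected", {
    anc <- ancestralOrder()
    # loss set keeping both copies of a symbol
    expect_error(tdrlEvent(1L, 2L, loss = 3L), "two copies")
    # empty loss set
    expect_error(tdrlEvent(1L, 2L, loss = integer(0)), "non-empty")
    # deleting every CR copy
    i_cr <- idx_of("CR", anc)
    expect_error(applyEvent(anc, tdrlEvent(i_cr, 1L, c(1L, 2L))),
                 "control region")
    # destination outside the excised order
    expect_error(applyEvent(anc, transpositionEvent(1L, 2L, 37L)),
                 "destination")
})

test_that("inference reports identical orders and exhausted limits explicitly", {
    anc <- ancestralOrder()
    inf0 <- inferEvents(anc, anc)
    expect_identical(inf0@status, "identical")
    expect_identical(inf0@minEvents, 0L)
    # Type VIII needs more than one event: depth-1 search must say so
    inf8 <- inferEvents(anc, arrangementTypeOrders()$VIII,
                        max_events = 1L, max_block_len = 3L)
    expect_identical(inf8@status, "limits exhausted")
    expect_true(is.na(inf8@minEvents))
    expect_length(inf8@solutions, 0L)
})

test_that("depth-1 inference finds published events and all solutions fold to the target", {
    anc <- ancestralOrder()
    tt <- arrangementTypeOrders()
    for (ty in c("II", "IV", "VI", "VII")) {
        inf <- inferEvents(anc, tt[[ty]], max_events = 1L, max_block_len = 3L)
        expect_identical(inf@status, "ok")
        expect_identical(inf@minEvents, 1L)
        for (sol in inf@solutions) {
            o <- inf@source
            for (e in sol) o <- applyEvent(o, e)
            expect_true(sameArrangement(o, inf@target))
        }
    }
    # a single-transposition account of the M-I-Q arrangement is reported
    # (equivalent parameterisations - moving trnM, or moving trnI/-trnQ past
    # it - are deduplicated to one representative)
    inf6 <- inferEvents(anc, tt$VI, max_events = 1L, max_block_len = 3L)
    kinds <- vapply(inf6@solutions, function(s) s[[1]]@kind, character(1))
    expect_true("transposition" %in% kinds)
    tr <- inf6@solutions[[match("transposition", kinds)]][[1]]
    moved <- describeEvent(inf6@source, tr)$block
    expect_true(identical(moved, "trnM") ||
                    setequal(moved, c("trnI", "-trnQ")))
})

test_that("depth-1 search is complete on a reduced alphabet", {
    set.seed(92)
    base <- randomOrder(10)
    for (rep in 1:25) {
        drawn <- randomSingleEvent(base, max_block_len = 3L)
        inf <- inferEvents(base, drawn$result, max_events = 1L,
                           max_block_len = 3L)
        expect_identical(inf@status, "ok")
        expect_identical(inf@minEvents, 1L)
    }
})

test_that("two-event histories are found on a reduced alphabet", {
    set.seed(93)
    base <- randomOrder(7)
    e1 <- randomSingleEvent(base, max_block_len = 2L)
    e2 <- randomSingleEvent(e1$result, max_block_len = 2L)
    inf <- inferEvents(base, e2$result, max_events = 2L, max_block_len = 2L)
    expect_true(inf@status %in% c("ok", "identical"))
    expect_true(is.na(inf@minEvents) || inf@minEvents <= 2L)
    if (inf@status == "ok") {
        sol <- inf@solutions[[1]]
        o <- inf@source
        for (e in sol) o <- applyEvent(o, e)
        expect_true(sameArrangement(o, inf@target))
    }
})

test_that("event reports serialize to stable JSON", {
    anc <- ancestralOrder()
    tt <- arrangementTypeOrders()
    infs <- list(typeVI = inferEvents(anc, tt$VI, 1L, 3L),
                 typeII = inferEvents(anc, tt$II, 1L, 3L))
    tf <- withr::local_tempfile(fileext = ".json")
    writeEventReport(infs, tf)
    parsed <- jsonlite::read_json(tf)
    expect_named(parsed, c("typeII", "typeVI"))
    expect_identical(parsed$typeII$status, "ok")
    expect_identical(parsed$typeII$min_events, 1L)
})
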