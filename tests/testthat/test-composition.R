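test_that("skew formulas and undefined denominators behave as specified", {
    expect_equal(skews("ACGT")$at_skew, 0)
    expect_equal(skews("ACGT")$gc_skew, 0)
    expect_equal(skews("AAAT")$at_skew, 0.5)
    # zero denominators are undefined, not 0
    expect_true(is.na(skews("GGCC")$at_skew))
    expect_true(is.na(skews("AATT")$gc_skew))
    # N excluded from counts and content
    expect_equal(skews("AANN")$at_content, 1)
    expect_equal(skews("AANN")$length, 4L)
})

test_that("reverse complement negates both skews on N-free sequences", {
    set.seed(55)
    for (rep in 1:20) {
        s <- paste(sample(c("A", "C", "G", "T"), sample(20:400, 1),
                          replace = TRUE, prob = c(.4, .15, .1, .35)),
                   collapse = "")
        rc <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(s)))
        a <- skews(s); b <- skews(rc)
        if (!is.na(a$at_skew)) expect_equal(b$at_skew, -a$at_skew)
        if (!is.na(a$gc_skew)) expect_equal(b$gc_skew, -a$gc_skew)
        expect_equal(b$at_content, a$at_content)
    }
})

test_that("skews over concatenated genes equal count-weighted pooling", {
    set.seed(56)
    genes <- replicate(6, paste(
        sample(c("A", "C", "G", "T"), sample(50:200, 1), replace = TRUE),
        collapse = ""))
    pooled <- skews(paste(genes, collapse = ""))
    per <- do.call(rbind, lapply(genes, skews))
    a <- sum(per$A); t <- sum(per$T); g <- sum(per$G); c_ <- sum(per$C)
    expect_equal(pooled$at_skew, (a - t) / (a + t))
    expect_equal(pooled$gc_skew, (g - c_) / (g + c_))
})

test_that("RSCU satisfies its defining identities", {
    # equal use of a full family gives RSCU 1 everywhere in it
    code <- mitoGeneticCode()
    gly <- names(code)[code == "G"]
    cu <- codonUsage(list(x = paste(c(gly, "TAA"), collapse = "")))
    expect_equal(cu$rscu[cu$aa == "G"], rep(1, 4))
    # a single codon carrying all of a 6-codon family scores the family size
    cu2 <- codonUsage(list(x = paste(rep("TTA", 10), collapse = "")))
    expect_equal(cu2$rscu[cu2$codon == "TTA"], 6)
    expect_true(all(cu2$rscu[cu2$aa == "L" & cu2$codon != "TTA"] == 0))
    # unused families are flagged, not divided by zero
    expect_true(all(cu2$zero_family[cu2$aa == "G"]))
    expect_true(all(cu2$rscu[cu2$zero_family]  == 0))
})

test_that("RSCU family sums equal the family size on random CDS sets", {
    set.seed(57)
    code <- mitoGeneticCode()
    sense <- names(code)[code != "*"]
    for (rep in 1:10) {
        cds <- paste(sample(sense, 300, replace = TRUE), collapse = "")
        cu <- codonUsage(list(x = cds))
        sums <- tapply(cu$rscu, cu$aa, sum)
        fam <- tapply(cu$family_size, cu$aa, unique)
        used <- tapply(cu$count, cu$aa, sum) > 0
        expect_equal(as.numeric(sums[used]), as.numeric(fam[used]))
    }
})

test_that("codon statistics drop incomplete terminal codons and catch stops", {
    # trailing T/TA (truncated stop) is dropped, not completed
    cu <- codonUsage(list(x = "TTATT"))
    expect_equal(sum(cu$count), 1L)
    expect_error(codonUsage(list(nad2 = "TTATAATTA")), "nad2")
})

test_that("region stats agree with the whole genome when one feature spans it", {
    set.seed(58)
    s <- paste(sample(c("A", "C", "G", "T"), 900, replace = TRUE),
               collapse = "")
    g <- annotatedMitogenome("one", s, data.frame(
        symbol = "rrnL", start = 1, end = 900, strand = "+"))
    rs <- suppressWarnings(regionStats(g))
    cmp <- rs[rs$scope == "complete", c("at_skew", "gc_skew", "at_content")]
    rrn <- rs[rs$scope == "rRNA", c("at_skew", "gc_skew", "at_content")]
    expect_equal(unname(unlist(rrn)), unname(unlist(cmp)))
    # minus-strand feature is reported on its coding strand
    g2 <- annotatedMitogenome("one", s, data.frame(
        symbol = "rrnL", start = 1, end = 900, strand = "-"))
    rs2 <- suppressWarnings(regionStats(g2))
    expect_equal(rs2$at_skew[rs2$scope == "rRNA"],
                 -rs$at_skew[rs$scope == "rRNA"])
})

test_that("synthetic genomes recover the generator's base frequencies", {
    cfg <- simConfig(seed = 59)
    set.seed(cfg$seed)
    g <- simulateRecord(ancestralOrder(), cfg)
    rs <- regionStats(g)
    cr_at <- rs$at_content[rs$scope == "CR"]
    p <- sum(cfg$base_freqs$CR[c("A", "T")])
    se <- sqrt(p * (1 - p) / cfg$cr_len)
    expect_lt(abs(cr_at - p), 2 * se + 1e-9)
})
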