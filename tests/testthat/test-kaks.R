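test_that("identical sequences give an explicit 'identical' status, not 0/0", {
    aln <- codonAlignment("cox1", "ATGACACGT", "ATGACACGT")
    r <- ng86(aln)
    expect_identical(r@status, "identical")
    expect_equal(r@ka, 0)
    expect_equal(r@ks, 0)
    expect_true(is.na(r@omega))
})

test_that("purely synonymous third-position changes force omega = 0", {
    # one GGA->GGG (Gly) third-position change among identical codons
    aln <- codonAlignment("toy", "GGAGGAGGACCTCCT", "GGGGGAGGACCTCCT")
    r <- ng86(aln)
    expect_equal(r@ka, 0)
    expect_gt(r@ks, 0)
    expect_equal(r@omega, 0)
    expect_identical(r@status, "ok")
})

test_that("site counting under the mitochondrial code is exact", {
    # TTA (Leu): pos1 TTA->CTA synonymous (of C/A/G: CTA Leu syn, ATA Met,
    # GTA Val), pos2 none, pos3 TTG/TTC/TTT -> Leu,Phe,Phe: 1/3.
    r <- ng86(codonAlignment("one", "TTA", "TTA"))
    expect_equal(r@sSites, 1 / 3 + 0 + 1 / 3)
    expect_equal(r@nSites + r@sSites, 3)
})

test_that("ng86 is symmetric and conserves sites on random pairs", {
    set.seed(111)
    for (rep in 1:8) {
        aln <- simulateCodonPair(60, 0.25, 0.15, seed = rep)
        a <- ng86(aln)
        b <- ng86(codonAlignment(aln@gene, aln@seqB, aln@seqA))
        expect_equal(a@ka, b@ka)
        expect_equal(a@ks, b@ks)
        expect_equal(a@nSites, b@nSites)
        expect_equal(a@sDiffs, b@sDiffs)
        expect_equal(a@nSites + a@sSites, 3 * a@countedCodons)
    }
})

test_that("counts equal the exhaustive pathway-enumeration oracle", {
    set.seed(112)
    for (rep in 1:25) {
        aln <- simulateCodonPair(80, 0.3, 0.12, seed = 1000 + rep)
        got <- ng86(aln)
        want <- oracleNG86(aln@seqA, aln@seqB)
        expect_equal(got@nSites, want$N)
        expect_equal(got@sSites, want$S)
        expect_equal(got@nDiffs, want$Nd)
        expect_equal(got@sDiffs, want$Sd)
        expect_equal(got@countedCodons, want$counted)
    }
})

test_that("gap and N codon columns are excluded and tallied", {
    aln <- codonAlignment("g", "ATG---CGTNNA", "ATGAAACGAGGA")
    r <- ng86(aln)
    expect_equal(r@excludedCodons, 2L)
    expect_equal(r@countedCodons, 2L)
})

test_that("internal stops are an error naming the codon position", {
    expect_error(ng86(codonAlignment("nad2", "ATGTAAACA", "ATGTACACA")),
                 "codon position 2 of gene 'nad2'")
    # a terminal stop pair is silently dropped, as in real CDS annotation
    r <- ng86(codonAlignment("g", "ATGTAA", "ATGTAA"))
    expect_equal(r@countedCodons, 1L)
})

test_that("estimated ka rises strictly with the nonsynonymous rate on matched seeds", {
    for (seed in 1:6) {
        kas <- vapply(c(0.02, 0.08, 0.2), function(p) {
            ng86(simulateCodonPair(200, 0.15, p, seed = seed))@ka
        }, numeric(1))
        expect_true(all(diff(kas) > 0))
    }
})

test_that("a purifying regime yields omega < 1 and a relaxed gene stands out", {
    genes <- c("atp8", "cox1", "nad2")
    alns <- list()
    for (i in seq_along(genes)) {
        p_nonsyn <- if (genes[i] == "atp8") 0.10 else 0.02  # 5x relaxed
        for (rep in 1:4) {
            a <- simulateCodonPair(150, 0.25, p_nonsyn,
                                   seed = 100 * i + rep, gene = genes[i])
            alns[[length(alns) + 1L]] <- a
        }
    }
    tab <- cohortKaKs(alns)
    expect_true(all(tab$mean_omega < 1))
    expect_identical(tab$gene[which.max(tab$mean_omega)], "atp8")
})

test_that("all-identical cohorts report zero means and undefined omega", {
    aln <- codonAlignment("cox2", "ATGACC", "ATGACC")
    tab <- cohortKaKs(list(aln, aln))
    expect_equal(tab$mean_ka, 0)
    expect_equal(tab$mean_ks, 0)
    expect_true(is.nan(tab$mean_omega))
})

test_that("alignment files pair against the designated reference", {
    dir <- withr::local_tempdir()
    writeLines(c(">ref", "ATGACACGT", ">s1", "ATGACGCGT", ">s2", "ATGACACGA"),
               file.path(dir, "cox1.fasta"))
    alns <- readCodonAlignments(dir, reference = "ref")
    expect_length(alns, 2L)
    expect_identical(alns[[1]]@gene, "cox1")
    expect_identical(alns[[1]]@seqA, "ATGACACGT")
})
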