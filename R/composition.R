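## Nucleotide composition, strand skews, codon usage / RSCU ------------------

#' AT and GC skew of a nucleotide sequence
#'
#' AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C), computed on the
#' strand as given. N bases are excluded from all counts and denominators.
#' A skew whose denominator is zero is reported as \code{NA} (undefined),
#' never as 0.
#'
#' @param seq character(1) or \code{DNAString} over A,C,G,T,N.
#' @param scope label recorded in the output (e.g. \code{"complete"},
#'   \code{"PCG"}, a gene symbol).
#' @return One-row data.frame: scope, length (total bp including N), base
#'   counts, at_content, gc_content, at_skew, gc_skew.
#' @export
#' @examples
#' skews("AAAT")$at_skew  # (3-1)/(3+1) = 0.5
skews <- function(seq, scope = "complete") {
    if (!is(seq, "DNAString")) seq <- Biostrings::DNAString(toupper(seq))
    if (length(seq) == 0L) stop("empty sequence")
    cnt <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T", "N"))
    a <- cnt[["A"]]; c_ <- cnt[["C"]]; g <- cnt[["G"]]; t <- cnt[["T"]]
    counted <- a + c_ + g + t
    data.frame(
        scope = scope,
        length = length(seq),
        A = a, C = c_, G = g, T = t, N = cnt[["N"]],
        at_content = if (counted > 0) (a + t) / counted else NA_real_,
        gc_content = if (counted > 0) (g + c_) / counted else NA_real_,
        at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
        gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_,
        stringsAsFactors = FALSE
    )
}

#' The invertebrate mitochondrial genetic code
#'
#' @return Named character vector mapping the 64 codons (DNA alphabet) to
#'   one-letter amino acids, \code{"*"} for stops (NCBI translation
#'   table 5).
#' @export
mitoGeneticCode <- function() Biostrings::getGeneticCode("5")

.splitCodons <- function(s) {
    s <- toupper(as.character(s))
    extra <- nchar(s) %% 3L
    if (extra) s <- substr(s, 1L, nchar(s) - extra)  # drop incomplete codon
    if (nchar(s) == 0L) return(character(0))
    substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

#' Codon usage and relative synonymous codon usage (RSCU)
#'
#' Counts codons across a set of in-frame coding sequences under the
#' invertebrate mitochondrial code. Incomplete terminal codons (the
#' truncated T/TA stops common in mitogenome annotation) are dropped, as is
#' a complete terminal stop codon; stop codons never enter the RSCU table.
#' RSCU(codon) = observed count x family size / total family count; a codon
#' whose whole family is unused has RSCU 0 and is flagged.
#'
#' @param cds_list named list (or character vector / DNAStringSet) of CDS
#'   nucleotide sequences; names identify genes in error messages.
#' @param code genetic code, default \code{\link{mitoGeneticCode}()}.
#' @return data.frame: codon, aa, count, family_size, rscu, zero_family.
#' @export
#' @examples
#' cu <- codonUsage(c(x = "TTATTATAA"))
#' cu[cu$codon == "TTA", ]
codonUsage <- function(cds_list, code = mitoGeneticCode()) {
    if (is(cds_list, "DNAStringSet")) cds_list <- as.character(cds_list)
    cds_list <- as.list(cds_list)
    if (is.null(names(cds_list)) || any(!nzchar(names(cds_list))))
        names(cds_list) <- paste0("cds_", seq_along(cds_list))
    counts <- integer(0)
    for (g in names(cds_list)) {
        codons <- .splitCodons(cds_list[[g]])
        if (!length(codons)) next
        last <- codons[length(codons)]
        if (!is.na(code[last]) && code[last] == "*")
            codons <- codons[-length(codons)]
        codons <- codons[codons %in% names(code)]   # skip N/gap codons
        if (any(code[codons] == "*"))
            stop(sprintf("internal stop codon in CDS '%s'", g))
        tab <- table(codons)
        counts[names(tab)] <- ifelse(is.na(counts[names(tab)]), 0L,
                                     counts[names(tab)]) + as.integer(tab)
    }
    sense <- names(code)[code != "*"]
    aa <- code[sense]
    fam_size <- table(aa)[aa]
    cnt <- ifelse(is.na(counts[sense]), 0L, counts[sense])
    fam_total <- tapply(cnt, aa, sum)[aa]
    rscu <- ifelse(fam_total > 0, cnt * as.integer(fam_size) / fam_total, 0)
    data.frame(
        codon = sense, aa = as.character(aa), count = as.integer(cnt),
        family_size = as.integer(fam_size), rscu = as.numeric(rscu),
        zero_family = as.vector(fam_total == 0),
        row.names = NULL, stringsAsFactors = FALSE
    )
}

#' Extract a feature's sequence on its coding strand
#'
#' Resolves origin-spanning coordinates on the circular molecule and
#' reverse-complements minority-strand features.
#'
#' @param genome an \code{\link{AnnotatedMitogenome}}.
#' @param symbol canonical gene symbol of the feature.
#' @return A \code{DNAString}.
#' @export
featureSeq <- function(genome, symbol) {
    ft <- featureTable(genome)
    i <- match(symbol, ft$symbol)
    if (is.na(i)) stop(sprintf("no feature '%s' in %s", symbol,
                               accession(genome)))
    s <- genomeSeq(genome)
    L <- length(s)
    if (ft$end[i] <= L) {
        out <- Biostrings::subseq(s, ft$start[i], ft$end[i])
    } else {
        out <- Biostrings::xscat(
            Biostrings::subseq(s, ft$start[i], L),
            Biostrings::subseq(s, 1L, ft$end[i] - L))
        out <- Biostrings::DNAString(out)
    }
    if (ft$strand[i] == "-") out <- Biostrings::reverseComplement(out)
    out
}

#' Composition and skew report per genomic region
#'
#' One \code{\link{skews}} row per scope: the complete genome (on the
#' published strand as deposited, which is how one overall skew per genome
#' is conventionally reported), the concatenated protein-coding genes, all
#' tRNAs, all rRNAs, and the control region, the last four concatenated on
#' each feature's coding strand in genome order. Optionally also one row
#' per individual gene.
#'
#' @param genome an \code{\link{AnnotatedMitogenome}}.
#' @param per_gene also emit one row per feature (default FALSE).
#' @return data.frame with an added \code{accession} column. A missing
#'   control region drops that scope with a warning.
#' @export
regionStats <- function(genome, per_gene = FALSE) {
    ft <- featureTable(genome)
    ft <- ft[order(ft$start), , drop = FALSE]
    rows <- list(skews(genomeSeq(genome), "complete"))
    for (kd in c("PCG", "tRNA", "rRNA")) {
        symbols <- ft$symbol[ft$kind == kd]
        if (!length(symbols)) {
            warning(sprintf("no %s features in %s; scope omitted", kd,
                            accession(genome)))
            next
        }
        cat_seq <- do.call(Biostrings::xscat,
                           lapply(symbols, featureSeq, genome = genome))
        rows[[length(rows) + 1L]] <- skews(Biostrings::DNAString(cat_seq), kd)
    }
    if ("CR" %in% ft$symbol) {
        rows[[length(rows) + 1L]] <- skews(featureSeq(genome, "CR"), "CR")
    } else {
        warning(sprintf("no control region in %s; CR scope omitted",
                        accession(genome)))
    }
    if (per_gene) {
        for (g in ft$symbol[ft$symbol != "CR"]) {
            rows[[length(rows) + 1L]] <- skews(featureSeq(genome, g), g)
        }
    }
    out <- do.call(rbind, rows)
    cbind(accession = accession(genome), out, stringsAsFactors = FALSE)
}
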