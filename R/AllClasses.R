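#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

## Canonical gene inventory -------------------------------------------------

#' Canonical mitochondrial gene symbols
#'
#' The 37 genes of a typical insect mitogenome plus the control region:
#' 13 protein-coding genes, 22 tRNAs (leucine and serine tRNAs disambiguated
#' as trnL1/trnL2 and trnS1/trnS2 by anticodon family), two rRNAs and the
#' A+T-rich control region (\code{CR}).
#'
#' @return Character vector of 38 canonical symbols.
#' @export
#' @examples
#' canonicalSymbols()
canonicalSymbols <- function() {
    c(
        paste0("nad", c(1:6, "4l")),
        paste0("cox", 1:3),
        "atp6", "atp8", "cob",
        paste0("trn", c(
            "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "K", "M",
            "F", "P", "T", "W", "Y", "V"
        )),
        "trnL1", "trnL2", "trnS1", "trnS2",
        "rrnS", "rrnL",
        "CR"
    )
}

.PCG_SYMBOLS <- c(paste0("nad", c(1:6, "4l")), paste0("cox", 1:3),
                  "atp6", "atp8", "cob")

#' Classify a canonical symbol into its feature kind
#' @param symbol character vector of canonical symbols.
#' @return character vector over \code{c("PCG","tRNA","rRNA","CR")}.
#' @export
#' @examples
#' symbolKind(c("cox1", "trnL1", "rrnS", "CR"))
symbolKind <- function(symbol) {
    ifelse(symbol %in% .PCG_SYMBOLS, "PCG",
        ifelse(startsWith(symbol, "trn"), "tRNA",
            ifelse(symbol %in% c("rrnS", "rrnL"), "rRNA",
                ifelse(symbol == "CR", "CR", NA_character_))))
}

## AnnotatedMitogenome ------------------------------------------------------

#' AnnotatedMitogenome: a circular annotated mitochondrial genome
#'
#' Holds the genome sequence together with its typed gene features. The
#' molecule is circular: a feature may span the origin, in which case its
#' coordinates are stored unwrapped (\code{end > length(sequence)}) so that
#' \code{end - start + 1} is always the feature length. Coordinates are
#' 1-based inclusive throughout the package (GenBank convention).
#'
#' @slot accession character(1) record identifier.
#' @slot taxon character(1) free-text species label.
#' @slot sequence a \link[Biostrings]{DNAString} over A,C,G,T,N.
#' @slot features a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{symbol} (canonical gene symbol) and \code{kind}
#'   (PCG/tRNA/rRNA/CR); strand is \code{+} (majority/J strand) or \code{-}.
#'
#' @export
setClass("AnnotatedMitogenome",
    representation(
        accession = "character",
        taxon = "character",
        sequence = "ANY",          # Biostrings::DNAString
        features = "ANY"           # GenomicRanges::GRanges
    )
)

setValidity("AnnotatedMitogenome", function(object) {
    msg <- character(0)
    if (length(object@accession) != 1L)
        msg <- c(msg, "'accession' must be character(1)")
    if (!is(object@sequence, "DNAString"))
        msg <- c(msg, "'sequence' must be a DNAString")
    fr <- object@features
    if (!is(fr, "GRanges"))
        msg <- c(msg, "'features' must be a GRanges")
    else {
        if (!all(c("symbol", "kind") %in% names(mcols(fr))))
            msg <- c(msg, "features must carry 'symbol' and 'kind' columns")
        else {
            sym <- mcols(fr)$symbol
            if (anyDuplicated(sym))
                msg <- c(msg, sprintf("duplicated feature symbol(s): %s",
                    paste(unique(sym[duplicated(sym)]), collapse = ", ")))
            if (length(fr) > 38L)
                msg <- c(msg, "more than 38 features (37 genes + CR)")
        }
        L <- length(object@sequence)
        if (length(fr) && L > 0L) {
            if (any(GenomicRanges::start(fr) < 1L))
                msg <- c(msg, "feature start < 1")
            if (any(GenomicRanges::start(fr) > L))
                msg <- c(msg, "feature start beyond record length")
            # unwrapped ends may exceed L (origin-spanning) but never 2L
            if (any(GenomicRanges::end(fr) > 2L * L))
                msg <- c(msg, "feature end beyond one full wrap of the circle")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedMitogenome
#'
#' @param accession character(1) identifier.
#' @param sequence character(1) or \code{DNAString}; the circular genome on
#'   its published (majority/J) strand.
#' @param features a \code{data.frame} with columns \code{symbol},
#'   \code{start}, \code{end}, \code{strand} (\code{"+"}/\code{"-"}) and
#'   optionally \code{kind} (derived from the symbol when absent). Features
#'   spanning the circular origin are given either with \code{start > end}
#'   (wrapped, GenBank-style) or with \code{end > length(sequence)}
#'   (unwrapped); both are stored unwrapped.
#' @param taxon character(1) species label.
#' @return An \code{AnnotatedMitogenome}.
#' @export
#' @examples
#' g <- annotatedMitogenome("X1", "ACGTACGTAA",
#'     data.frame(symbol = "trnI", start = 1, end = 4, strand = "+"))
#' featureTable(g)
annotatedMitogenome <- function(accession, sequence, features,
                                taxon = NA_character_) {
    if (is.character(sequence))
        sequence <- Biostrings::DNAString(sequence)
    L <- length(sequence)
    stopifnot(is.data.frame(features),
              all(c("symbol", "start", "end", "strand") %in% names(features)))
    start <- as.integer(features$start)
    end <- as.integer(features$end)
    wrap <- end < start
    end[wrap] <- end[wrap] + L
    kind <- if ("kind" %in% names(features)) as.character(features$kind)
            else symbolKind(as.character(features$symbol))
    gr <- GenomicRanges::GRanges(
        seqnames = accession,
        ranges = IRanges::IRanges(start = start, end = end),
        strand = as.character(features$strand)
    )
    mcols(gr)$symbol <- as.character(features$symbol)
    mcols(gr)$kind <- kind
    new("AnnotatedMitogenome", accession = as.character(accession),
        taxon = as.character(taxon), sequence = sequence, features = gr)
}

## SignedGeneOrder ----------------------------------------------------------

#' SignedGeneOrder: a signed circular gene order
#'
#' The object all rearrangement arithmetic operates on: a circular sequence
#' of gene symbols, each carrying a sign. Sign \code{+1} denotes the
#' majority/J strand (the strand encoding cox1), \code{-1} the minority/N
#' strand. Equality of gene orders is defined up to rotation of the circle,
#' never up to reflection; see \code{\link{orderIdentical}} and
#' \code{\link{canonicalizeOrder}}.
#'
#' @slot symbols character vector of canonical gene symbols (no duplicates).
#' @slot signs integer vector of +1/-1, parallel to \code{symbols}.
#' @slot provenance character(1): accession or a label such as
#'   \code{"canonical:TypeI"}.
#'
#' @export
setClass("SignedGeneOrder",
    representation(
        symbols = "character",
        signs = "integer",
        provenance = "character"
    )
)

setValidity("SignedGeneOrder", function(object) {
    msg <- character(0)
    if (length(object@symbols) != length(object@signs))
        msg <- c(msg, "'symbols' and 'signs' differ in length")
    if (anyDuplicated(object@symbols))
        msg <- c(msg, "duplicate gene symbols in order")
    if (length(object@symbols) > 38L)
        msg <- c(msg, "more than 38 elements")
    if (!all(object@signs %in% c(-1L, 1L)))
        msg <- c(msg, "signs must be +1 or -1")
    if (length(msg)) msg else TRUE
})

#' Construct a SignedGeneOrder
#'
#' @param symbols character vector of gene symbols, or a single string of
#'   space-separated signed symbols (\code{"trnI -trnQ trnM ..."}).
#' @param signs integer vector of +1/-1; defaults to all +1. Ignored when
#'   \code{symbols} is a single signed string.
#' @param provenance character(1) label.
#' @return A \code{SignedGeneOrder}.
#' @export
#' @examples
#' signedGeneOrder("cox1 trnL2 -trnQ")
signedGeneOrder <- function(symbols, signs = NULL, provenance = "") {
    if (length(symbols) == 1L && grepl("\\s", symbols)) {
        toks <- strsplit(trimws(symbols), "\\s+")[[1]]
        signs <- ifelse(startsWith(toks, "-"), -1L, 1L)
        symbols <- sub("^[-+]", "", toks)
    }
    if (is.null(signs)) signs <- rep(1L, length(symbols))
    new("SignedGeneOrder", symbols = as.character(symbols),
        signs = as.integer(signs), provenance = as.character(provenance))
}

## RearrangementEvent -------------------------------------------------------

#' RearrangementEvent: one gene-order rearrangement
#'
#' Three mechanisms are modelled. A tandem duplication--random loss
#' (\code{TDRL}) duplicates a contiguous block in place and then deletes a
#' subset of the duplicated gene copies; an \code{inversion} reverses a block
#' and flips every sign in it; a \code{transposition} excises a block and
#' reinserts it elsewhere with signs unchanged.
#'
#' @slot kind character(1): \code{"TDRL"}, \code{"inversion"} or
#'   \code{"transposition"}.
#' @slot start integer(1): 1-based index of the block's first element on the
#'   circular order the event applies to.
#' @slot len integer(1): block length (number of genes).
#' @slot loss integer vector (TDRL only): positions within the 2*len tandem
#'   array (1..len = first copy, len+1..2*len = second copy) that are
#'   deleted. Every symbol must lose at least one of its two copies; losing
#'   both constitutes gene loss.
#' @slot destination integer(1) (transposition only): the block is inserted
#'   after this position of the order that remains once the block is excised
#'   (0 = in front of the first remaining element).
#'
#' @export
setClass("RearrangementEvent",
    representation(
        kind = "character",
        start = "integer",
        len = "integer",
        loss = "integer",
        destination = "integer"
    )
)

setValidity("RearrangementEvent", function(object) {
    msg <- character(0)
    if (!object@kind %in% c("TDRL", "inversion", "transposition"))
        msg <- c(msg, "kind must be TDRL, inversion or transposition")
    if (object@len < 1L) msg <- c(msg, "block length must be >= 1")
    if (object@kind == "TDRL") {
        if (length(object@loss) == 0L)
            msg <- c(msg, "TDRL requires a non-empty loss set")
        if (any(object@loss < 1L | object@loss > 2L * object@len))
            msg <- c(msg, "loss positions outside the tandem array")
        k <- object@len
        for (j in seq_len(k)) {
            if (!any(c(j, j + k) %in% object@loss)) {
                msg <- c(msg, sprintf(
                    "loss set keeps two copies of block position %d", j))
                break
            }
        }
    }
    if (object@kind == "transposition" && is.na(object@destination))
        msg <- c(msg, "transposition requires a destination")
    if (length(msg)) msg else TRUE
})

#' @rdname RearrangementEvent-class
#' @param start,len block position and length (see slots).
#' @param loss TDRL loss positions within the tandem array.
#' @export
tdrlEvent <- function(start, len, loss) {
    new("RearrangementEvent", kind = "TDRL", start = as.integer(start),
        len = as.integer(len), loss = sort(as.integer(loss)),
        destination = NA_integer_)
}

#' @rdname RearrangementEvent-class
#' @export
inversionEvent <- function(start, len) {
    new("RearrangementEvent", kind = "inversion", start = as.integer(start),
        len = as.integer(len), loss = integer(0), destination = NA_integer_)
}

#' @rdname RearrangementEvent-class
#' @param destination insertion point in the excised order (see slots).
#' @export
transpositionEvent <- function(start, len, destination) {
    new("RearrangementEvent", kind = "transposition",
        start = as.integer(start), len = as.integer(len), loss = integer(0),
        destination = as.integer(destination))
}

## EventInference -----------------------------------------------------------

#' EventInference: result of a minimal event-history search
#'
#' @slot source,target the two \code{SignedGeneOrder}s compared (canonical
#'   forms).
#' @slot solutions list of event sequences (each a list of
#'   \code{RearrangementEvent}); all have length \code{minEvents} and all,
#'   applied left to right to \code{source}, yield \code{target} up to
#'   canonical equality (rotation and strand-reading convention; see
#'   \code{\link{sameArrangement}}).
#' @slot minEvents integer(1); \code{NA} when the search limits were
#'   exhausted without a solution.
#' @slot status character(1): \code{"ok"}, \code{"identical"} or
#'   \code{"limits exhausted"}.
#' @slot maxEvents,maxBlockLen the search limits used.
#'
#' @export
setClass("EventInference",
    representation(
        source = "SignedGeneOrder",
        target = "SignedGeneOrder",
        solutions = "list",
        minEvents = "integer",
        status = "character",
        maxEvents = "integer",
        maxBlockLen = "integer"
    )
)

## KaKsResult ---------------------------------------------------------------

#' KaKsResult: pairwise Ka/Ks for one codon alignment
#'
#' Nei--Gojobori (1986) counting with Jukes--Cantor correction. Site and
#' difference counts are fractional (pathway-averaged). \code{omega} is
#' \code{NA} when Ks is zero or a rate is saturated; \code{status} says why.
#'
#' @slot gene character(1) gene symbol.
#' @slot ka,ks numeric(1) corrected substitution rates (NA if saturated).
#' @slot omega numeric(1) ka/ks (NA when undefined).
#' @slot nSites,sSites fractional nonsynonymous/synonymous site counts.
#' @slot nDiffs,sDiffs fractional difference counts.
#' @slot countedCodons,excludedCodons integer codon tallies (excluded =
#'   gap/N columns plus codons with no stop-free mutational pathway).
#' @slot status character(1): \code{"ok"}, \code{"identical"},
#'   \code{"ks_zero"}, \code{"ka_saturated"}, \code{"ks_saturated"}.
#'
#' @export
setClass("KaKsResult",
    representation(
        gene = "character",
        ka = "numeric", ks = "numeric", omega = "numeric",
        nSites = "numeric", sSites = "numeric",
        nDiffs = "numeric", sDiffs = "numeric",
        countedCodons = "integer", excludedCodons = "integer",
        status = "character"
    )
)

#' CodonAlignment: a pairwise in-frame codon alignment
#'
#' @slot gene character(1) gene symbol.
#' @slot seqA,seqB character(1) gap-aligned nucleotide strings of equal
#'   length divisible by 3. Codon columns containing gaps or N are excluded
#'   from counting (and tallied).
#'
#' @export
setClass("CodonAlignment",
    representation(gene = "character", seqA = "character", seqB = "character")
)

setValidity("CodonAlignment", function(object) {
    msg <- character(0)
    if (nchar(object@seqA) != nchar(object@seqB))
        msg <- c(msg, "aligned sequences differ in length")
    if (nchar(object@seqA) %% 3L != 0L)
        msg <- c(msg, "alignment length not divisible by 3")
    if (nchar(object@seqA) == 0L)
        msg <- c(msg, "empty alignment")
    if (length(msg)) msg else TRUE
})

#' Construct a CodonAlignment
#' @param gene gene symbol label.
#' @param seqA,seqB aligned in-frame nucleotide strings (character or
#'   \code{DNAString}); equal length, divisible by 3.
#' @return A \code{CodonAlignment}.
#' @export
codonAlignment <- function(gene, seqA, seqB) {
    new("CodonAlignment", gene = as.character(gene),
        seqA = toupper(as.character(seqA)), seqB = toupper(as.character(seqB)))
}
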