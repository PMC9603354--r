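## Accessors and show methods ----------------------------------------------

#' @rdname AnnotatedMitogenome-class
#' @param object,x an \code{AnnotatedMitogenome}.
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))

#' @rdname AnnotatedMitogenome-class
#' @export
setMethod("accession", "AnnotatedMitogenome", function(x) x@accession)

#' @rdname AnnotatedMitogenome-class
#' @export
setGeneric("taxon", function(x) standardGeneric("taxon"))

#' @rdname AnnotatedMitogenome-class
#' @export
setMethod("taxon", "AnnotatedMitogenome", function(x) x@taxon)

#' @rdname AnnotatedMitogenome-class
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname AnnotatedMitogenome-class
#' @export
setMethod("genomeSeq", "AnnotatedMitogenome", function(x) x@sequence)

#' @rdname AnnotatedMitogenome-class
#' @export
setGeneric("genomeFeatures", function(x) standardGeneric("genomeFeatures"))

#' @rdname AnnotatedMitogenome-class
#' @export
setMethod("genomeFeatures", "AnnotatedMitogenome", function(x) x@features)

#' Feature table of an annotated mitogenome
#'
#' @param x an \code{AnnotatedMitogenome}.
#' @return A \code{data.frame} with columns symbol, kind, start, end
#'   (unwrapped; end may exceed the record length for origin-spanning
#'   features), strand and length.
#' @export
featureTable <- function(x) {
    fr <- genomeFeatures(x)
    data.frame(
        symbol = mcols(fr)$symbol,
        kind = mcols(fr)$kind,
        start = GenomicRanges::start(fr),
        end = GenomicRanges::end(fr),
        strand = as.character(GenomicRanges::strand(fr)),
        length = GenomicRanges::width(fr),
        stringsAsFactors = FALSE
    )
}

setMethod("show", "AnnotatedMitogenome", function(object) {
    cat(sprintf("AnnotatedMitogenome %s (%s)\n", object@accession,
        ifelse(is.na(object@taxon), "unknown taxon", object@taxon)))
    cat(sprintf("  circular sequence: %d bp\n", length(object@sequence)))
    tab <- table(mcols(object@features)$kind)
    cat(sprintf("  features: %d (%s)\n", length(object@features),
        paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
})

#' @rdname SignedGeneOrder-class
#' @param x a \code{SignedGeneOrder}.
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname SignedGeneOrder-class
#' @export
setMethod("geneSymbols", "SignedGeneOrder", function(x) x@symbols)

#' @rdname SignedGeneOrder-class
#' @export
setGeneric("geneSigns", function(x) standardGeneric("geneSigns"))

#' @rdname SignedGeneOrder-class
#' @export
setMethod("geneSigns", "SignedGeneOrder", function(x) x@signs)

#' @rdname SignedGeneOrder-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname SignedGeneOrder-class
#' @export
setMethod("provenance", "SignedGeneOrder", function(x) x@provenance)

#' @rdname SignedGeneOrder-class
#' @export
setMethod("length", "SignedGeneOrder", function(x) length(x@symbols))

#' Format a signed gene order as a single string
#'
#' Minority-strand (sign -1) genes are prefixed with \code{-}.
#'
#' @param x a \code{SignedGeneOrder}.
#' @return character(1), e.g. \code{"trnI -trnQ trnM ..."}.
#' @export
formatOrder <- function(x) {
    paste(ifelse(x@signs < 0L, paste0("-", x@symbols), x@symbols),
          collapse = " ")
}

setMethod("show", "SignedGeneOrder", function(object) {
    cat(sprintf("SignedGeneOrder (%d genes%s)\n", length(object@symbols),
        if (nzchar(object@provenance))
            paste0(", ", object@provenance) else ""))
    cat(" ", formatOrder(object), "\n")
})

setMethod("show", "RearrangementEvent", function(object) {
    detail <- switch(object@kind,
        TDRL = sprintf("loss {%s}", paste(object@loss, collapse = ",")),
        inversion = "",
        transposition = sprintf("destination %d", object@destination))
    cat(sprintf("RearrangementEvent: %s block [%d, len %d] %s\n",
        object@kind, object@start, object@len, detail))
})

setMethod("show", "EventInference", function(object) {
    cat(sprintf("EventInference: %s -> %s\n",
        if (nzchar(provenance(object@source))) provenance(object@source)
        else "source",
        if (nzchar(provenance(object@target))) provenance(object@target)
        else "target"))
    cat(sprintf("  status: %s; limits: max_events %d, max_block_len %d\n",
        object@status, object@maxEvents, object@maxBlockLen))
    if (!is.na(object@minEvents))
        cat(sprintf("  min_events: %d; %d minimal solution(s)\n",
            object@minEvents, length(object@solutions)))
})

setMethod("show", "KaKsResult", function(object) {
    cat(sprintf("KaKsResult [%s] status=%s\n", object@gene, object@status))
    cat(sprintf("  Ka=%.4g Ks=%.4g omega=%.4g (N=%.2f S=%.2f Nd=%.2f Sd=%.2f)\n",
        object@ka, object@ks, object@omega, object@nSites, object@sSites,
        object@nDiffs, object@sDiffs))
    cat(sprintf("  codons counted=%d excluded=%d\n",
        object@countedCodons, object@excludedCodons))
})

#' Tabulate a KaKsResult (or list of them) as a data.frame
#'
#' @param x a \code{KaKsResult} or a list of them.
#' @return One row per result: gene, ka, ks, omega, n_sites, s_sites,
#'   n_diffs, s_diffs, counted, excluded, status.
#' @export
kaksTable <- function(x) {
    if (is(x, "KaKsResult")) x <- list(x)
    do.call(rbind, lapply(x, function(r) data.frame(
        gene = r@gene, ka = r@ka, ks = r@ks, omega = r@omega,
        n_sites = r@nSites, s_sites = r@sSites,
        n_diffs = r@nDiffs, s_diffs = r@sDiffs,
        counted = r@countedCodons, excluded = r@excludedCodons,
        status = r@status, stringsAsFactors = FALSE)))
}
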