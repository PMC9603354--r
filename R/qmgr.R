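## qMGR-style rearrangement scoring ------------------------------------------

## Oriented adjacency of gene g in a canonical order: the signed predecessor
## and signed successor on the circle. A gene's rearrangement score against a
## reference order is the number of its two oriented adjacencies that differ,
## with two fixed conventions: a gene whose own sign flipped scores 2
## regardless of neighbours, and a gene absent from the order scores the
## maximum 2 (deleted-gene convention). The control region anchors
## adjacencies of its neighbours but is itself unscored (it is not a gene).

.adjacencyOf <- function(symbols, signs, i) {
    n <- length(symbols)
    pred <- if (i == 1L) n else i - 1L
    succ <- if (i == n) 1L else i + 1L
    c(pred_sym = symbols[pred], pred_sign = signs[pred],
      succ_sym = symbols[succ], succ_sign = signs[succ])
}

#' Per-gene rearrangement scores of one genome against a reference
#'
#' Each gene of the reference (the control region excepted) receives a score
#' in 0..2: the number of its two oriented adjacencies
#' (predecessor -> gene and gene -> successor, compared with strand signs)
#' that differ from the reference. A gene whose own strand sign differs
#' scores 2 regardless of neighbours; a gene deleted from the genome scores
#' the maximum 2 (a message notes the convention). Both orders are
#' canonicalized before comparison, so scores are invariant under rotation.
#'
#' @param order a \code{\link{SignedGeneOrder}}.
#' @param reference the reference order; defaults to
#'   \code{\link{ancestralOrder}()}. Every gene of \code{order} must be
#'   present in the reference.
#' @return Named integer vector: score per reference gene symbol.
#' @export
#' @examples
#' sum(geneScores(arrangementTypeOrders()$II))  # genome RS of Type II
geneScores <- function(order, reference = ancestralOrder()) {
    o <- canonicalizeOrder(order)
    r <- canonicalizeOrder(reference)
    os <- geneSymbols(o); og <- geneSigns(o)
    rs <- geneSymbols(r); rg <- geneSigns(r)
    extra <- setdiff(os, rs)
    if (length(extra))
        stop(sprintf(
            "gene(s) %s present in order but missing from the reference; %s",
            paste(extra, collapse = ", "),
            "the reference must contain every scored gene"))
    genes <- setdiff(rs, "CR")
    missing <- setdiff(genes, os)
    if (length(missing))
        message(sprintf(
            "gene(s) %s absent from %s: scored 2 (deleted-gene convention)",
            paste(missing, collapse = ", "),
            if (nzchar(provenance(o))) provenance(o) else "order"))
    scores <- vapply(genes, function(g) {
        j <- match(g, os)
        if (is.na(j)) return(2L)
        i <- match(g, rs)
        if (og[j] != rg[i]) return(2L)
        a <- .adjacencyOf(os, og, j)
        b <- .adjacencyOf(rs, rg, i)
        sum(!identical(a[c("pred_sym", "pred_sign")],
                       b[c("pred_sym", "pred_sign")]),
            !identical(a[c("succ_sym", "succ_sign")],
                       b[c("succ_sym", "succ_sign")]))
    }, integer(1))
    scores
}

#' Genome rearrangement score (RS)
#'
#' The RS of a genome is the sum of the rearrangement scores of all its
#' genes against the reference.
#'
#' @inheritParams geneScores
#' @return integer(1).
#' @export
genomeRS <- function(order, reference = ancestralOrder()) {
    sum(geneScores(order, reference))
}

#' Cohort rearrangement report: per-gene scores, genome RS, gene RF
#'
#' Applies \code{\link{geneScores}} to every genome and aggregates:
#' the genome RS accumulates the scores of all genes in one genome, and the
#' rearrangement frequency of a gene is
#' \code{RF = 100 * sum(scores across genomes) / (2 * N)} percent, the
#' score mass realised out of its maximum over \code{N} genomes.
#'
#' @param cohort list of \code{\link{SignedGeneOrder}}s.
#' @param reference reference order (default ancestral).
#' @return A list with data.frames \code{scores} (accession, gene, score),
#'   \code{genome_rs} (accession, rs) and \code{gene_rf} (gene, rf).
#' @export
#' @examples
#' rep8 <- cohortReport(arrangementTypeOrders())
#' rep8$genome_rs
cohortReport <- function(cohort, reference = ancestralOrder()) {
    stopifnot(length(cohort) >= 1L)
    acc <- vapply(seq_along(cohort), function(i) {
        p <- provenance(cohort[[i]])
        if (nzchar(p)) p else sprintf("genome_%02d", i)
    }, character(1))
    acc <- make.unique(acc)
    per <- lapply(cohort, geneScores, reference = reference)
    genes <- names(per[[1]])
    scores <- data.frame(
        accession = rep(acc, each = length(genes)),
        gene = rep(genes, times = length(cohort)),
        score = unlist(per, use.names = FALSE),
        stringsAsFactors = FALSE
    )
    genome_rs <- data.frame(
        accession = acc,
        rs = vapply(per, sum, integer(1)),
        stringsAsFactors = FALSE
    )
    totals <- Reduce(`+`, per)
    gene_rf <- data.frame(
        gene = genes,
        rf = 100 * as.numeric(totals) / (2 * length(cohort)),
        stringsAsFactors = FALSE
    )
    list(scores = scores, genome_rs = genome_rs, gene_rf = gene_rf)
}
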