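## Signed circular gene orders ----------------------------------------------

#' The ancestral insect mitochondrial gene order (arrangement Type I)
#'
#' The putative ancestral arrangement of the 37 mitochondrial genes plus the
#' control region shared by most insects, with the majority/J strand carrying
#' sign +1. Landmarks: rrnL lies between trnL1 and trnV, rrnS between trnV
#' and the control region, and the tRNA cluster trnA-trnR-trnN-trnS1-trnE
#' precedes trnF on the J strand.
#'
#' @return A \code{\link{SignedGeneOrder}} of all 38 elements, provenance
#'   \code{"canonical:TypeI"}.
#' @export
#' @examples
#' ancestralOrder()
ancestralOrder <- function() {
    signedGeneOrder(paste(
        "trnI -trnQ trnM nad2 trnW -trnC -trnY cox1 trnL2 cox2 trnK trnD",
        "atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5",
        "-trnH -nad4 -nad4l trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL",
        "-trnV -rrnS CR"),
        provenance = "canonical:TypeI")
}

.dropGenes <- function(order, drop) {
    keep <- !(geneSymbols(order) %in% drop)
    signedGeneOrder(geneSymbols(order)[keep], geneSigns(order)[keep],
                    provenance(order))
}

.replaceSegment <- function(order, seg_symbols, new_string) {
    ## replace the contiguous run starting at seg_symbols[1] and of the same
    ## length by the parsed new_string (helper for transcribing type orders)
    syms <- geneSymbols(order); sgns <- geneSigns(order)
    i <- match(seg_symbols[1], syms)
    idx <- i + seq_along(seg_symbols) - 1L
    stopifnot(identical(syms[idx], seg_symbols))
    repl <- signedGeneOrder(new_string)
    symbols <- append(syms[-idx], geneSymbols(repl), after = i - 1L)
    signs <- append(sgns[-idx], geneSigns(repl), after = i - 1L)
    signedGeneOrder(symbols, signs, provenance(order))
}

#' Canonical gene orders of the eight Ensifera arrangement types
#'
#' The eight arrangement types observed across Ensifera mitogenomes,
#' transcribed from their published descriptions and shipped as package
#' data. Type I is the ancestral insect order. Type II inverts the
#' trnN-trnS1-trnE cluster to the minority strand; Type III additionally
#' swaps trnV and rrnS; Type IV lacks trnI; Type V carries a
#' strand-flipping tRNA translocation (best-effort transcription; its exact
#' order is not asserted anywhere); Type VI has trnM moved 5' of trnI
#' (M-I-Q); Type VII has I-M-ND2-Q; Type VIII rearranges the
#' cox3..trnF neighbourhood (trnA/trnR and trnG-nad3 relocated with
#' inversion, trnS1 transposed after trnR).
#'
#' @return Named list of \code{\link{SignedGeneOrder}}s, names
#'   \code{"I".."VIII"}, provenance \code{"canonical:TypeN"}.
#' @export
#' @examples
#' names(arrangementTypeOrders())
arrangementTypeOrders <- function() {
    anc <- ancestralOrder()
    relabel <- function(o, id) {
        signedGeneOrder(geneSymbols(o), geneSigns(o),
                        paste0("canonical:Type", id))
    }
    t2 <- .replaceSegment(anc, c("trnN", "trnS1", "trnE"),
                          "-trnE -trnS1 -trnN")
    t3 <- .replaceSegment(t2, c("trnV", "rrnS"), "-rrnS -trnV")
    t4 <- .dropGenes(anc, "trnI")
    t5 <- .replaceSegment(anc, c("trnI", "trnQ", "trnM"),
                          "-trnQ trnM -trnI")
    t6 <- .replaceSegment(anc, c("trnI", "trnQ", "trnM"),
                          "trnM trnI -trnQ")
    t7 <- .replaceSegment(anc, c("trnI", "trnQ", "trnM", "nad2"),
                          "trnI trnM nad2 -trnQ")
    t8 <- .replaceSegment(anc,
        c("trnG", "nad3", "trnA", "trnR", "trnN", "trnS1", "trnE"),
        "-trnR trnS1 -trnA trnN -nad3 -trnG trnE")
    out <- list(I = anc, II = t2, III = t3, IV = t4, V = t5, VI = t6,
                VII = t7, VIII = t8)
    mapply(relabel, out, names(out), SIMPLIFY = FALSE)
}

#' Extract the signed gene order of an annotated mitogenome
#'
#' Features are walked around the circle by start position; each element
#' carries its strand sign (+1 = majority/J strand). The control region is
#' included as an ordinary element. Two features sharing a start are ordered
#' longer-first, with a warning.
#'
#' @param genome an \code{\link{AnnotatedMitogenome}}.
#' @return A \code{\link{SignedGeneOrder}} with provenance set to the
#'   accession.
#' @export
extractOrder <- function(genome) {
    ft <- featureTable(genome)
    if (nrow(ft) == 0L) stop("genome has no features")
    if (anyDuplicated(ft$start)) {
        dup <- ft$start[duplicated(ft$start)]
        warning(sprintf(
            "features share start position(s) %s; longer feature placed first",
            paste(unique(dup), collapse = ", ")))
    }
    o <- order(ft$start, -ft$length)
    signedGeneOrder(ft$symbol[o], ifelse(ft$strand[o] == "-", -1L, 1L),
                    provenance = accession(genome))
}

#' Canonicalize a signed gene order
#'
#' Rotates the circle so the anchor gene comes first. When the anchor sits
#' on the minority strand the whole record was deposited on the opposite
#' strand; the order is then reflected (reversed with all signs flipped)
#' before rotation, so that comparisons are invariant to which strand a
#' record calls "plus". The anchor defaults to cox1 (present and
#' unrearranged in all eight types), falling back to rrnS.
#'
#' Canonicalization is idempotent, and two orders have identical canonical
#' forms exactly when they are circularly equal (up to rotation, signs and
#' orientation of the anchor preserved).
#'
#' @param order a \code{\link{SignedGeneOrder}}.
#' @param anchor,fallback anchor gene symbols.
#' @return The canonical \code{SignedGeneOrder}.
#' @export
#' @examples
#' canonicalizeOrder(ancestralOrder())
canonicalizeOrder <- function(order, anchor = "cox1", fallback = "rrnS") {
    syms <- geneSymbols(order); sgns <- geneSigns(order)
    i <- match(anchor, syms)
    if (is.na(i)) i <- match(fallback, syms)
    if (is.na(i))
        stop(sprintf("neither anchor '%s' nor fallback '%s' present",
                     anchor, fallback))
    if (sgns[i] < 0L) {          # deposited on the opposite strand: reflect
        syms <- rev(syms); sgns <- -rev(sgns)
        i <- match(anchor, syms)
        if (is.na(i)) i <- match(fallback, syms)
    }
    n <- length(syms)
    rot <- c(i:n, seq_len(i - 1L))
    signedGeneOrder(syms[rot], sgns[rot], provenance(order))
}

#' Test circular equality of two signed gene orders
#'
#' TRUE when one order is a rotation of the other with identical symbols and
#' signs. Reflection is never considered equal.
#'
#' @param a,b \code{\link{SignedGeneOrder}}s.
#' @return logical(1).
#' @export
orderIdentical <- function(a, b) {
    n <- length(a)
    if (n != length(b)) return(FALSE)
    sa <- geneSymbols(a); ga <- geneSigns(a)
    sb <- geneSymbols(b); gb <- geneSigns(b)
    starts <- which(sb == sa[1] & gb == ga[1])
    for (i in starts) {
        rot <- c(i:n, seq_len(i - 1L))
        if (identical(sb[rot], sa) && identical(gb[rot], ga)) return(TRUE)
    }
    FALSE
}

#' Test whether two orders describe the same arrangement
#'
#' Canonical equality: equal after \code{\link{canonicalizeOrder}}, i.e. up
#' to rotation of the circle and up to which strand the record calls
#' "plus" (a signed circular order and its reflection describe the same
#' molecule read from opposite strands). This is the comparison used by
#' type classification and event inference.
#'
#' @param a,b \code{\link{SignedGeneOrder}}s.
#' @return logical(1).
#' @export
sameArrangement <- function(a, b) {
    orderIdentical(canonicalizeOrder(a), canonicalizeOrder(b))
}

.orderKey <- function(order) {
    co <- canonicalizeOrder(order)
    paste(geneSigns(co) * match(geneSymbols(co), canonicalSymbols()),
          collapse = ",")
}

#' Cluster gene orders into arrangement types
#'
#' Partitions a cohort by canonical-form identity. Canonical forms matching
#' one of the packaged type orders receive that label (the ancestral order
#' is always Type I); novel forms are labelled \code{NEW-1}, \code{NEW-2},
#' ... in order of first occurrence. A genome missing a gene forms its own
#' type unless another genome shares the identical reduced order.
#'
#' @param cohort list of \code{\link{SignedGeneOrder}}s.
#' @return A list with \code{assignments} (data.frame: accession, type_id)
#'   and \code{representatives} (named list of canonical
#'   \code{SignedGeneOrder}s, one per type).
#' @export
#' @examples
#' classifyTypes(arrangementTypeOrders())$assignments
classifyTypes <- function(cohort) {
    stopifnot(length(cohort) >= 1L)
    known <- vapply(arrangementTypeOrders(), .orderKey, character(1))
    keys <- vapply(cohort, .orderKey, character(1))
    acc <- vapply(seq_along(cohort), function(i) {
        p <- provenance(cohort[[i]])
        if (nzchar(p)) p else sprintf("genome_%02d", i)
    }, character(1))
    type_of <- character(length(cohort))
    new_keys <- character(0)
    for (i in seq_along(keys)) {
        hit <- match(keys[i], known)
        if (!is.na(hit)) {
            type_of[i] <- names(known)[hit]
        } else {
            j <- match(keys[i], new_keys)
            if (is.na(j)) {
                new_keys <- c(new_keys, keys[i])
                j <- length(new_keys)
            }
            type_of[i] <- paste0("NEW-", j)
        }
    }
    reps <- lapply(split(seq_along(cohort), type_of), function(ix) {
        canonicalizeOrder(cohort[[ix[1]]])
    })
    list(
        assignments = data.frame(accession = acc, type_id = type_of,
                                 stringsAsFactors = FALSE),
        representatives = reps
    )
}

## Gene-order text format ----------------------------------------------------

#' Read and write the one-genome-per-line gene-order text format
#'
#' Each line is \code{"accession: g1 g2 -g3 ..."} with signed,
#' space-separated symbols in canonical (rotation-free) form.
#'
#' @param orders list of \code{\link{SignedGeneOrder}}s.
#' @param path file path.
#' @return \code{readGeneOrders} returns a list of \code{SignedGeneOrder}s;
#'   \code{writeGeneOrders} returns \code{path} invisibly.
#' @export
writeGeneOrders <- function(orders, path) {
    lines <- vapply(seq_along(orders), function(i) {
        o <- canonicalizeOrder(orders[[i]])
        p <- provenance(o)
        if (!nzchar(p)) p <- sprintf("genome_%02d", i)
        sprintf("%s: %s", p, formatOrder(o))
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeGeneOrders
#' @export
readGeneOrders <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lapply(lines, function(ln) {
        ## split on the last colon: accessions/labels may contain colons
        sep <- max(gregexpr(":", ln, fixed = TRUE)[[1]])
        if (sep < 1L)
            stop(sprintf("malformed gene-order line: '%s'", ln))
        signedGeneOrder(trimws(substring(ln, sep + 1L)),
                        provenance = trimws(substring(ln, 1L, sep - 1L)))
    })
}
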