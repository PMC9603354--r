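## Rearrangement events: application and minimal-history inference -----------

#' Apply a rearrangement event to a signed gene order
#'
#' Deterministic application of one \code{\link{RearrangementEvent}}:
#' \itemize{
#'   \item TDRL: the block is duplicated in tandem and the loss positions of
#'     the resulting 2k-element array are deleted. Each symbol must lose at
#'     least one of its two copies; losing both copies removes the gene from
#'     the genome. The control region may sit inside a duplicated block but
#'     must keep exactly one copy.
#'   \item inversion: the block is reversed and every sign in it flipped.
#'   \item transposition: the block is excised and reinserted after
#'     \code{destination} elements of the remaining order, signs unchanged.
#' }
#' Blocks may wrap the circular origin; the result is then returned rotated
#' so the block starts the linear representation (immaterial under circular
#' equality).
#'
#' @param order a \code{\link{SignedGeneOrder}}.
#' @param event a \code{\link{RearrangementEvent}}; block indices refer to
#'   positions in \code{order}.
#' @return The rearranged \code{SignedGeneOrder}.
#' @export
#' @examples
#' o <- ancestralOrder()
#' applyEvent(o, inversionEvent(match("trnN", geneSymbols(o)), 3))
applyEvent <- function(order, event) {
    validObject(event)
    syms <- geneSymbols(order); sgns <- geneSigns(order)
    n <- length(syms); k <- event@len
    if (k > n) stop("block longer than the order")
    start <- ((event@start - 1L) %% n) + 1L
    if (start + k - 1L > n) {      # block wraps the origin: rotate block-first
        rot <- c(start:n, seq_len(start - 1L))
        syms <- syms[rot]; sgns <- sgns[rot]
        start <- 1L
    }
    idx <- start:(start + k - 1L)
    out <- switch(event@kind,
        inversion = {
            syms[idx] <- rev(syms[idx])
            sgns[idx] <- -rev(sgns[idx])
            list(syms, sgns)
        },
        transposition = {
            d <- event@destination
            if (d < 0L || d > n - k)
                stop("transposition destination outside the excised order")
            rs <- syms[-idx]; rg <- sgns[-idx]
            list(append(rs, syms[idx], after = d),
                 append(rg, sgns[idx], after = d))
        },
        TDRL = {
            tandem_sym <- c(syms[idx], syms[idx])
            tandem_sgn <- c(sgns[idx], sgns[idx])
            keep <- setdiff(seq_len(2L * k), event@loss)
            if ("CR" %in% syms[idx] &&
                sum(tandem_sym[keep] == "CR") != 1L)
                stop("the control region must keep exactly one copy")
            before <- if (start > 1L) seq_len(start - 1L) else integer(0)
            after <- if (start + k <= n) (start + k):n else integer(0)
            list(c(syms[before], tandem_sym[keep], syms[after]),
                 c(sgns[before], tandem_sgn[keep], sgns[after]))
        },
        stop("unknown event kind"))
    signedGeneOrder(out[[1]], out[[2]], provenance(order))
}

#' Human-readable description of an event in the context of an order
#'
#' @param order the \code{SignedGeneOrder} the event applies to.
#' @param event a \code{\link{RearrangementEvent}}.
#' @return A list: kind, block (signed gene symbols), and for TDRL the lost
#'   copies (\code{"symbol/1"} = first copy, \code{"symbol/2"} = second),
#'   for transposition the gene after which the block reinserts (or
#'   \code{"(origin)"}).
#' @export
describeEvent <- function(order, event) {
    syms <- geneSymbols(order); sgns <- geneSigns(order)
    n <- length(syms)
    idx <- (((event@start - 1L) + seq_len(event@len) - 1L) %% n) + 1L
    block <- ifelse(sgns[idx] < 0, paste0("-", syms[idx]), syms[idx])
    out <- list(kind = event@kind, block = block)
    if (event@kind == "TDRL") {
        copy <- ifelse(event@loss > event@len, 2L, 1L)
        pos <- ((event@loss - 1L) %% event@len) + 1L
        out$losses <- paste0(syms[idx][pos], "/", copy)
    } else if (event@kind == "transposition") {
        rest <- syms[-idx]
        out$destination <- if (event@destination == 0L) "(origin)"
                           else rest[event@destination]
    }
    out
}

## --- fast internal representation for the search ---------------------------
##
## Inside the breadth-first search an order is a plain integer vector
## v = sign * symbol-code (codes indexing an alphabet vector); events are
## parameter tuples. S4 objects are built only at the boundaries. Blocks
## containing the control region are excluded from the search space: no
## observed arrangement type moves, duplicates or loses the CR, and the
## duplications the TDRL model invokes are themselves seeded from the CR.

## Canonical key mirroring canonicalizeOrder (the circular comparison after
## each event goes through the same anchor rotation and reflection rule): a
## circular signed order and its reflection describe the same molecule read
## from the opposite strand.
.rawKey <- function(v, anchor, fallback) {
    i <- match(TRUE, abs(v) == anchor)
    if (is.na(i)) i <- match(TRUE, abs(v) == fallback)
    n <- length(v)
    if (is.na(i)) {
        i <- which.min(abs(v))   # both anchors deleted in a search state
        if (v[i] < 0L) {
            v <- -rev(v)
            i <- n + 1L - i
        }
    } else if (v[i] < 0L) {
        v <- -rev(v)
        i <- n + 1L - i
    }
    paste(c(v[i:n], v[seq_len(i - 1L)]), collapse = ",")
}

.rawApply <- function(v, kind, start, len, loss, dest) {
    n <- length(v)
    if (start + len - 1L > n) {           # block wraps: rotate block-first
        v <- c(v[start:n], v[seq_len(start - 1L)])
        start <- 1L
    }
    idx <- start:(start + len - 1L)
    if (kind == 1L) {                     # TDRL
        tandem <- c(v[idx], v[idx])
        keep <- setdiff(seq_len(2L * len), loss)
        before <- if (start > 1L) v[seq_len(start - 1L)] else integer(0)
        after <- if (start + len <= n) v[(start + len):n] else integer(0)
        c(before, tandem[keep], after)
    } else if (kind == 2L) {              # inversion
        v[idx] <- -rev(v[idx])
        v
    } else {                              # transposition
        rest <- v[-idx]
        append(rest, v[idx], after = dest)
    }
}

## loss patterns per block length: each of the k tandem pairs keeps its
## first copy, its second copy, or neither (3^k patterns)
.lossPatterns <- function(k) {
    choice <- expand.grid(rep(list(1:3), k))
    lapply(seq_len(nrow(choice)), function(r) {
        loss <- integer(0)
        for (j in seq_len(k)) {
            loss <- c(loss, switch(choice[r, j],
                `1` = j + k,        # keep first copy
                `2` = j,            # keep second copy
                `3` = c(j, j + k))) # lose the gene entirely
        }
        sort(loss)
    })
}

## Candidate events as parameter tuples list(kind, start, len, loss, dest),
## in lexicographic (kind, start, len) order with TDRL < inversion <
## transposition, so the first hit of a deduplicated solution is its
## canonical representative.
.rawEnumerate <- function(v, max_block_len, cr_code, loss_patterns) {
    n <- length(v)
    events <- vector("list", 0L)
    cr_at <- match(TRUE, abs(v) == cr_code)
    block_ok <- function(start, len) {
        if (is.na(cr_at)) return(TRUE)
        idx <- (((start - 1L) + seq_len(len) - 1L) %% n) + 1L
        !(cr_at %in% idx)
    }
    for (start in seq_len(n)) {
        for (len in seq_len(min(max_block_len, n - 1L))) {
            if (!block_ok(start, len)) next
            for (loss in loss_patterns[[len]]) {
                events[[length(events) + 1L]] <-
                    list(1L, start, len, loss, NA_integer_)
            }
        }
    }
    for (start in seq_len(n)) {
        for (len in seq_len(min(max_block_len, n - 1L))) {
            if (!block_ok(start, len)) next
            events[[length(events) + 1L]] <-
                list(2L, start, len, integer(0), NA_integer_)
        }
    }
    for (start in seq_len(n)) {
        for (len in seq_len(min(max_block_len, n - 1L))) {
            if (!block_ok(start, len)) next
            wraps <- start + len - 1L > n
            for (d in 0:(n - len)) {
                if (!wraps && d == start - 1L) next   # identity placement
                events[[length(events) + 1L]] <-
                    list(3L, start, len, integer(0), d)
            }
        }
    }
    events
}

.tupleToEvent <- function(tp) {
    switch(tp[[1L]],
        tdrlEvent(tp[[2L]], tp[[3L]], tp[[4L]]),
        inversionEvent(tp[[2L]], tp[[3L]]),
        transpositionEvent(tp[[2L]], tp[[3L]], tp[[5L]]))
}

#' Infer minimal rearrangement event histories between two orders
#'
#' Breadth-first search over the event space (TDRL, inversion,
#' transposition; blocks up to \code{max_block_len} genes, the control
#' region excluded from blocks), deduplicating states by canonical form.
#' All minimal-length solutions are returned, deduplicated by their sequence
#' of event kinds and intermediate canonical orders, each represented by the
#' lexicographically first event parameterisation (by kind, then block
#' start). The search is exhaustive within its limits but exponential in
#' depth: with 38 genes and blocks up to 3 a depth-1 search examines a few
#' thousand events; each further level multiplies that by the frontier
#' size, so depths above 1 are practical mainly on reduced gene alphabets.
#'
#' @param source,target \code{\link{SignedGeneOrder}}s.
#' @param max_events maximum history length searched (default 1; must be
#'   <= 3).
#' @param max_block_len maximum block length (default 6).
#' @return An \code{\link{EventInference}}. When no history within the
#'   limits maps source to target the status is \code{"limits exhausted"}
#'   (never silent), \code{minEvents} is \code{NA} and \code{solutions} is
#'   empty.
#' @export
#' @examples
#' inferEvents(ancestralOrder(), arrangementTypeOrders()$VI)
inferEvents <- function(source, target, max_events = 1L, max_block_len = 6L) {
    stopifnot(max_events >= 0L, max_events <= 3L, max_block_len >= 1L)
    src <- canonicalizeOrder(source)
    tgt <- canonicalizeOrder(target)
    tkey <- .orderKey(tgt)
    res <- function(sol, m, status) {
        new("EventInference", source = src, target = tgt, solutions = sol,
            minEvents = as.integer(m), status = status,
            maxEvents = as.integer(max_events),
            maxBlockLen = as.integer(max_block_len))
    }
    ## encode on a shared alphabet (canonical symbols plus any extras)
    alph <- union(canonicalSymbols(),
                  union(geneSymbols(src), geneSymbols(tgt)))
    enc <- function(o) geneSigns(o) * match(geneSymbols(o), alph)
    anchor <- match("cox1", alph)
    fallback <- match("rrnS", alph)
    cr_code <- match("CR", alph)
    key_of <- function(v) .rawKey(v, anchor, fallback)
    v0 <- enc(src)
    tkey <- key_of(enc(tgt))
    if (key_of(v0) == tkey)
        return(res(list(list()), 0L, "identical"))
    loss_patterns <- lapply(seq_len(max_block_len), .lossPatterns)
    frontier <- list(list(v = v0, path = list(), trace = character(0)))
    visited <- new.env(parent = emptyenv())
    assign(key_of(v0), TRUE, envir = visited)
    for (depth in seq_len(max_events)) {
        hits <- list()
        hit_sig <- character(0)
        nxt <- list()
        for (node in frontier) {
            for (tp in .rawEnumerate(node$v, max_block_len, cr_code,
                                     loss_patterns)) {
                child <- .rawApply(node$v, tp[[1L]], tp[[2L]], tp[[3L]],
                                   tp[[4L]], tp[[5L]])
                key <- key_of(child)
                if (key == tkey) {
                    sig <- paste(c(node$trace, paste(tp[[1L]], key)),
                                 collapse = ";")
                    if (!sig %in% hit_sig) {
                        hit_sig <- c(hit_sig, sig)
                        hits[[length(hits) + 1L]] <-
                            c(node$path, list(tp))
                    }
                } else if (depth < max_events &&
                           !exists(key, envir = visited,
                                   inherits = FALSE)) {
                    assign(key, TRUE, envir = visited)
                    nxt[[length(nxt) + 1L]] <- list(
                        v = child, path = c(node$path, list(tp)),
                        trace = c(node$trace, paste(tp[[1L]], key)))
                }
            }
        }
        if (length(hits)) {
            sols <- lapply(hits, function(path) lapply(path, .tupleToEvent))
            return(res(sols, depth, "ok"))
        }
        frontier <- nxt
        if (!length(frontier)) break
    }
    res(list(), NA_integer_, "limits exhausted")
}

#' Serialize event inferences as a JSON report
#'
#' @param inferences named list of \code{\link{EventInference}} objects
#'   (names = accessions).
#' @param path output file.
#' @return \code{path}, invisibly. JSON keys are sorted for diffability.
#' @export
writeEventReport <- function(inferences, path) {
    payload <- lapply(inferences, function(inf) {
        sols <- lapply(inf@solutions, function(path_events) {
            o <- inf@source
            out <- vector("list", length(path_events))
            ## event indices refer to the running (uncanonicalized) order
            for (i in seq_along(path_events)) {
                out[[i]] <- describeEvent(o, path_events[[i]])
                o <- applyEvent(o, path_events[[i]])
            }
            out
        })
        list(
            source = provenance(inf@source),
            target = provenance(inf@target),
            status = inf@status,
            min_events = if (is.na(inf@minEvents)) NULL else inf@minEvents,
            search_limits = list(max_events = inf@maxEvents,
                                 max_block_len = inf@maxBlockLen),
            solutions = sols
        )
    })
    jsonlite::write_json(payload[order(names(payload))], path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(path)
}
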