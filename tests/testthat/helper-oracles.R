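# Independent oracles used to cross-check the package implementations.
# They share the contracts (conventions) but not the code paths.

# Brute-force adjacency-set rearrangement scorer: represents each order as a
# set of directed signed edge strings and scores a gene by membership of its
# two reference edges in the observed edge set (deleted gene or flipped sign
# score the maximum 2).
oracleGeneScores <- function(order, reference) {
    # share the boundary convention (rotation/reflection normalization via
    # the cox1 anchor); the scoring arithmetic below stays independent
    order <- canonicalizeOrder(order)
    reference <- canonicalizeOrder(reference)
    lab <- function(o) {
        s <- geneSymbols(o)
        ifelse(geneSigns(o) < 0, paste0("-", s), s)
    }
    edges <- function(o) {
        l <- lab(o)
        n <- length(l)
        paste(l, l[c(2:n, 1L)], sep = " > ")
    }
    eo <- edges(order)
    er <- edges(reference)
    rsym <- geneSymbols(reference)
    n <- length(rsym)
    out <- integer(0)
    for (i in seq_len(n)) {
        gene <- rsym[i]
        if (gene == "CR") next
        j <- match(gene, geneSymbols(order))
        if (is.na(j)) { out[gene] <- 2L; next }
        if (geneSigns(order)[j] != geneSigns(reference)[i]) {
            out[gene] <- 2L
            next
        }
        incident <- c(er[if (i == 1L) n else i - 1L], er[i])
        out[gene] <- sum(!incident %in% eo)
    }
    out
}

# Exhaustive pathway-enumeration NG86 counter: per-codon site fractions by
# direct enumeration of the nine single-base changes, difference counts by
# explicit enumeration of all orderings of the differing positions, stop
# codons excluded from sites and pathways alike.
oracleNG86 <- function(seqA, seqB, code = Biostrings::getGeneticCode("5")) {
    splitc <- function(s) {
        s <- toupper(s)
        substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    }
    ca <- splitc(seqA)
    cb <- splitc(seqB)
    ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
    ca <- ca[ok]; cb <- cb[ok]
    m <- length(ca)
    if (m && (code[[ca[m]]] == "*" || code[[cb[m]]] == "*")) {
        ca <- ca[-m]; cb <- cb[-m]
    }
    bases <- c("A", "C", "G", "T")
    synSites <- function(cod) {
        tot <- 0
        for (p in 1:3) {
            syn <- 0L; valid <- 0L
            for (b in bases) {
                if (b == substr(cod, p, p)) next
                mut <- cod
                substr(mut, p, p) <- b
                if (code[[mut]] == "*") next
                valid <- valid + 1L
                if (code[[mut]] == code[[cod]]) syn <- syn + 1L
            }
            if (valid > 0L) tot <- tot + syn / valid
        }
        tot
    }
    permute <- function(v) {
        if (length(v) <= 1L) return(list(v))
        do.call(c, lapply(seq_along(v), function(i) {
            lapply(permute(v[-i]), function(r) c(v[i], r))
        }))
    }
    N <- S <- Nd <- Sd <- 0
    counted <- 0L
    for (i in seq_along(ca)) {
        pos <- which(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
        sd_nd <- c(0, 0); n_valid <- 0L
        if (!length(pos)) {
            n_valid <- 1L
        } else {
            for (pp in permute(pos)) {
                cur <- ca[i]; sd <- 0L; nd <- 0L; good <- TRUE
                for (p in pp) {
                    nxt <- cur
                    substr(nxt, p, p) <- substr(cb[i], p, p)
                    if (code[[nxt]] == "*") { good <- FALSE; break }
                    if (code[[nxt]] == code[[cur]]) sd <- sd + 1L
                    else nd <- nd + 1L
                    cur <- nxt
                }
                if (good) {
                    sd_nd <- sd_nd + c(sd, nd)
                    n_valid <- n_valid + 1L
                }
            }
        }
        if (n_valid == 0L) next   # no stop-free pathway: codon excluded
        counted <- counted + 1L
        Sd <- Sd + sd_nd[1] / n_valid
        Nd <- Nd + sd_nd[2] / n_valid
        sbar <- (synSites(ca[i]) + synSites(cb[i])) / 2
        S <- S + sbar
        N <- N + 3 - sbar
    }
    list(N = N, S = S, Nd = Nd, Sd = Sd, counted = counted)
}

# Random signed order over a reduced alphabet (always keeps cox1 as anchor).
randomOrder <- function(n = 10L, with_cr = TRUE) {
    pool <- setdiff(canonicalSymbols(), c("cox1", "CR"))
    syms <- c("cox1", sample(pool, n - 1L - with_cr), if (with_cr) "CR")
    syms <- sample(syms)
    signs <- sample(c(-1L, 1L), length(syms), replace = TRUE)
    signs[syms == "cox1"] <- 1L
    signedGeneOrder(syms, signs)
}

# One random non-identity event on an order (for recovery-style tests),
# drawn through the package's own generator machinery via simulateCohort
# would couple the test to it; this draws independently.
randomSingleEvent <- function(order, max_block_len = 3L) {
    n <- length(order)
    repeat {
        kind <- sample(c("TDRL", "inversion", "transposition"), 1L)
        len <- sample.int(max_block_len, 1L)
        start <- sample.int(n, 1L)
        idx <- (((start - 1L) + seq_len(len) - 1L) %% n) + 1L
        if (match("CR", geneSymbols(order)) %in% idx) next
        ev <- switch(kind,
            inversion = inversionEvent(start, len),
            transposition = transpositionEvent(start, len,
                                               sample(0:(n - len), 1L)),
            TDRL = {
                loss <- unlist(lapply(seq_len(len), function(j) {
                    sample(list(j, j + len), 1L)[[1]]
                }))
                tdrlEvent(start, len, loss)
            })
        res <- applyEvent(order, ev)
        if (!orderIdentical(canonicalizeOrder(res),
                            canonicalizeOrder(order)))
            return(list(event = ev, result = res))
    }
}
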