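## Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction --------------------

.BASES <- c("A", "C", "G", "T")

## Per-codon synonymous site fractions under a genetic code. For each codon
## position, the fraction of the single-base changes that are synonymous;
## changes creating a stop codon are excluded from the denominator (nonsense
## mutations are not counted as either class). Each position contributes one
## site, split s : (1 - s).
.codonSites <- function(codon, code) {
    aa <- code[[codon]]
    s <- 0
    for (p in 1:3) {
        syn <- 0L; valid <- 0L
        for (b in setdiff(.BASES, substr(codon, p, p))) {
            mut <- codon
            substr(mut, p, p) <- b
            maa <- code[[mut]]
            if (maa == "*") next
            valid <- valid + 1L
            if (maa == aa) syn <- syn + 1L
        }
        if (valid > 0L) s <- s + syn / valid
    }
    c(s = s, n = 3 - s)
}

## All orderings of the differing positions between two codons; each ordering
## is a mutational pathway. Paths through stop codons are discarded. Returns
## c(sd, nd) averaged over valid paths, or NULL when every path is blocked.
.codonDiffs <- function(ca, cb, code) {
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    d <- length(pos)
    if (d == 0L) return(c(sd = 0, nd = 0))
    perms <- function(v) {
        if (length(v) <= 1L) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (rest in perms(v[-i]))
                out[[length(out) + 1L]] <- c(v[i], rest)
        out
    }
    sd_tot <- 0; nd_tot <- 0; n_valid <- 0L
    for (path in perms(pos)) {
        cur <- ca
        sd <- 0L; nd <- 0L
        ok <- TRUE
        for (p in path) {
            nxt <- cur
            substr(nxt, p, p) <- substr(cb, p, p)
            if (code[[nxt]] == "*") { ok <- FALSE; break }
            if (code[[nxt]] == code[[cur]]) sd <- sd + 1L else nd <- nd + 1L
            cur <- nxt
        }
        if (ok) {
            sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd
            n_valid <- n_valid + 1L
        }
    }
    if (n_valid == 0L) return(NULL)
    c(sd = sd_tot / n_valid, nd = nd_tot / n_valid)
}

.jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)      # saturated
    -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Ka/Ks by Nei-Gojobori (1986) counting
#'
#' Classic equal-weight NG86 under the invertebrate mitochondrial code:
#' per-codon synonymous site fractions (averaged over the two sequences),
#' fractional difference counts averaged over all minimal mutational
#' pathways with equal weight, proportions pN = Nd/N and pS = Sd/S, and the
#' Jukes-Cantor correction d = -(3/4) log(1 - 4p/3) applied to each. Codon
#' columns containing gaps or N are excluded and tallied; mutations through
#' stop codons are excluded (a codon pair with no stop-free pathway is
#' excluded entirely); a proportion >= 3/4 is reported as saturated
#' (\code{NA} rate).
#'
#' @param aln a \code{\link{CodonAlignment}} (or the result of
#'   \code{codonAlignment(...)}).
#' @param code genetic code, default \code{\link{mitoGeneticCode}()}.
#' @return A \code{\link{KaKsResult}}. \code{omega} is \code{NA} with an
#'   explicit status when the sequences are identical or Ks is
#'   zero/saturated, never 0/0.
#' @export
#' @examples
#' ng86(codonAlignment("toy", "TTATTA", "TTGTTA"))
ng86 <- function(aln, code = mitoGeneticCode()) {
    stopifnot(is(aln, "CodonAlignment"))
    validObject(aln)
    ca <- .splitCodons(aln@seqA)
    cb <- .splitCodons(aln@seqB)
    clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
    excluded <- sum(!clean)
    ia <- ca[clean]; ib <- cb[clean]
    ## a terminal stop codon pair is dropped; an internal stop is an error
    ncod <- length(ia)
    if (ncod > 0L && (code[[ia[ncod]]] == "*" || code[[ib[ncod]]] == "*")) {
        ia <- ia[-ncod]; ib <- ib[-ncod]
    }
    stops <- which(code[ia] == "*" | code[ib] == "*")
    if (length(stops))
        stop(sprintf("internal stop codon at codon position %d of gene '%s'",
                     stops[1], aln@gene))
    if (!length(ia)) stop("no counted codons in alignment")
    S <- 0; N <- 0; Sd <- 0; Nd <- 0
    drop <- logical(length(ia))
    site_a <- vapply(ia, .codonSites, numeric(2), code = code)
    site_b <- vapply(ib, .codonSites, numeric(2), code = code)
    for (i in seq_along(ia)) {
        dd <- .codonDiffs(ia[i], ib[i], code)
        if (is.null(dd)) { drop[i] <- TRUE; next }  # no stop-free pathway
        Sd <- Sd + dd[["sd"]]; Nd <- Nd + dd[["nd"]]
        S <- S + (site_a["s", i] + site_b["s", i]) / 2
        N <- N + (site_a["n", i] + site_b["n", i]) / 2
    }
    counted <- sum(!drop)
    excluded <- excluded + sum(drop)
    if (counted == 0L) stop("no counted codons in alignment")
    pS <- if (S > 0) Sd / S else NA_real_
    pN <- if (N > 0) Nd / N else NA_real_
    ks <- .jc(pS)
    ka <- .jc(pN)
    status <- if (Sd == 0 && Nd == 0) "identical"
        else if (!is.na(pN) && pN >= 0.75) "ka_saturated"
        else if (!is.na(pS) && pS >= 0.75) "ks_saturated"
        else if (!is.na(ks) && ks == 0) "ks_zero"
        else "ok"
    omega <- if (status == "ok") ka / ks else NA_real_
    new("KaKsResult", gene = aln@gene,
        ka = ka, ks = ks, omega = omega,
        nSites = N, sSites = S, nDiffs = Nd, sDiffs = Sd,
        countedCodons = as.integer(counted),
        excludedCodons = as.integer(excluded),
        status = status)
}

#' Per-gene mean Ka, Ks and omega over a cohort of pairwise alignments
#'
#' Groups alignments by gene and averages \code{\link{ng86}} results.
#' Saturated or identical pairs contribute their defined quantities only:
#' pairs with saturated rates are excluded from the ka/ks means and
#' reported; omega is averaged over pairs where it is defined.
#'
#' @param alignments list of \code{\link{CodonAlignment}}s.
#' @param code genetic code, default \code{\link{mitoGeneticCode}()}.
#' @return data.frame: gene, n_pairs, n_saturated, mean_ka, mean_ks,
#'   mean_omega (NaN when no pair defines it).
#' @export
cohortKaKs <- function(alignments, code = mitoGeneticCode()) {
    stopifnot(length(alignments) >= 1L)
    res <- lapply(alignments, ng86, code = code)
    tab <- kaksTable(res)
    out <- do.call(rbind, lapply(split(tab, tab$gene), function(d) {
        sat <- grepl("saturated", d$status)
        data.frame(
            gene = d$gene[1],
            n_pairs = nrow(d),
            n_saturated = sum(sat),
            mean_ka = mean(d$ka[!sat]),
            mean_ks = mean(d$ks[!sat]),
            mean_omega = mean(d$omega[!is.na(d$omega)]),
            stringsAsFactors = FALSE
        )
    }))
    rownames(out) <- NULL
    out
}

#' Read per-gene codon alignments from FASTA and form reference pairs
#'
#' Reads each aligned FASTA file (one gene per file, file name =
#' \code{<gene>.fasta}/\code{.fa}) and pairs every sequence against the
#' designated reference sequence.
#'
#' @param dir directory of aligned FASTA files.
#' @param reference name (or 1-based index, default 1) of the reference
#'   sequence within each file.
#' @return list of \code{\link{CodonAlignment}}s.
#' @export
readCodonAlignments <- function(dir, reference = 1L) {
    files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    if (!length(files)) stop(sprintf("no FASTA files in %s", dir))
    out <- list()
    for (f in sort(files)) {
        gene <- sub("\\.(fa|fasta)$", "", basename(f))
        ss <- Biostrings::readDNAStringSet(f)
        ref <- if (is.character(reference)) match(reference, names(ss))
               else as.integer(reference)
        if (is.na(ref) || ref > length(ss))
            stop(sprintf("reference sequence not found in %s", f))
        for (i in setdiff(seq_along(ss), ref)) {
            out[[length(out) + 1L]] <- codonAlignment(
                gene, as.character(ss[[ref]]), as.character(ss[[i]]))
        }
    }
    out
}
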