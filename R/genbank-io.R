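## GenBank flat-file reading/writing and gene-name normalization -------------
##
## Mitogenome records come annotated with heterogeneous gene/product names;
## everything downstream operates on canonical symbols, so normalization
## happens here, at the boundary. The alias table is shipped as editable
## data (inst/extdata/gene_symbols.tsv), not code.

.AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Glu = "E",
          Gln = "Q", Gly = "G", His = "H", Ile = "I", Lys = "K", Met = "M",
          Phe = "F", Pro = "P", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
          Leu = "L", Ser = "S")

.symbolTable <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            path <- system.file("extdata", "gene_symbols.tsv",
                                package = "MitoRearr", mustWork = TRUE)
            tab <- utils::read.delim(path, stringsAsFactors = FALSE)
            cache <<- stats::setNames(tab$symbol, tab$alias)
        }
        cache
    }
})

.normKey <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.unresolvedError <- function(msg) {
    stop(errorCondition(msg,
        class = c("mitoRearr_unresolved_symbol", "error", "condition")))
}

## Leu/Ser tRNA families by anticodon (DNA or RNA alphabet):
## Leu(CUN) anticodon UAG -> trnL1; Leu(UUR) anticodon UAA -> trnL2;
## Ser(AGN) anticodon GCU/UCU -> trnS1; Ser(UCN) anticodon UGA -> trnS2.
.leuSerByAnticodon <- function(aa1, anticodon) {
    ac <- gsub("u", "t", tolower(gsub("[^A-Za-z]", "", anticodon)))
    if (aa1 == "L") {
        if (ac == "tag") return("trnL1")
        if (ac == "taa") return("trnL2")
    } else {
        if (ac %in% c("gct", "tct")) return("trnS1")
        if (ac == "tga") return("trnS2")
    }
    NA_character_
}

.leuSerByFamily <- function(aa1, text) {
    key <- tolower(text)
    if (aa1 == "L") {
        if (grepl("cun", key)) return("trnL1")
        if (grepl("uur|ttr", key)) return("trnL2")
    } else {
        if (grepl("agn", key)) return("trnS1")
        if (grepl("ucn|tcn", key)) return("trnS2")
    }
    NA_character_
}

#' Normalize a raw gene/product name to a canonical symbol
#'
#' Deterministic mapping from annotation names (gene or product qualifiers)
#' to the package's canonical symbols. Protein-coding, rRNA and
#' control-region names go through the shipped alias table; tRNA names are
#' resolved from the amino acid, with the leucine and serine families
#' disambiguated by anticodon (or by a codon-family tag such as
#' \code{"(CUN)"} in the name): Leu(CUN) is trnL1, Leu(UUR) trnL2,
#' Ser(AGN) trnS1, Ser(UCN) trnS2.
#'
#' @param raw_name gene qualifier text (may be empty).
#' @param anticodon anticodon sequence, DNA or RNA alphabet (may be empty).
#' @param product product qualifier text (may be empty).
#' @return character(1) canonical symbol. An ambiguous Leu/Ser tRNA with no
#'   anticodon information, or an unmappable name, raises an error of class
#'   \code{"mitoRearr_unresolved_symbol"} (callers may catch it and skip
#'   the feature).
#' @export
#' @examples
#' normalizeSymbol("tRNA-Leu", anticodon = "tag")  # CUN family -> trnL1
#' normalizeSymbol("ND2", product = "NADH dehydrogenase subunit 2")
normalizeSymbol <- function(raw_name, anticodon = "", product = "") {
    cands <- c(raw_name, product)
    cands <- cands[nzchar(cands)]
    if (!length(cands)) .unresolvedError("empty gene and product qualifiers")
    tab <- .symbolTable()
    for (cand in cands) {
        key <- .normKey(cand)
        ## canonical symbols pass through (trnL1 handled below via trn path)
        if (key %in% .normKey(canonicalSymbols()))
            return(canonicalSymbols()[match(key,
                                            .normKey(canonicalSymbols()))])
        if (!is.na(tab[key])) return(unname(tab[key]))
    }
    ## tRNA naming: trnX / tRNA-Xxx / transfer RNA Xxx
    for (cand in cands) {
        key <- .normKey(cand)
        m <- regmatches(key, regexec("^t?rna?([a-z]{3})", key))[[1]]
        aa3 <- NA_character_
        if (grepl("^trn[a-z]\\d?$", key)) {
            aa1 <- toupper(substr(key, 4L, 4L))
            if (aa1 %in% .AA3) aa3 <- names(.AA3)[match(aa1, .AA3)]
        } else if (grepl("trna|transferrna", key)) {
            mm <- regmatches(key, regexec(
                "(ala|arg|asn|asp|cys|glu|gln|gly|his|ile|lys|met|phe|pro|thr|trp|tyr|val|leu|ser)",
                key))[[1]]
            if (length(mm)) {
                aa3 <- paste0(toupper(substr(mm[2], 1, 1)),
                              substr(mm[2], 2, 3))
            }
        }
        if (!is.na(aa3)) {
            aa1 <- .AA3[[aa3]]
            if (!aa1 %in% c("L", "S")) return(paste0("trn", aa1))
            if (nzchar(anticodon)) {
                hit <- .leuSerByAnticodon(aa1, anticodon)
                if (!is.na(hit)) return(hit)
            }
            for (txt in cands) {
                hit <- .leuSerByFamily(aa1, txt)
                if (!is.na(hit)) return(hit)
            }
            .unresolvedError(sprintf(
                "ambiguous %s tRNA '%s': no anticodon information",
                aa3, cands[1]))
        }
    }
    .unresolvedError(sprintf("cannot map '%s' to a canonical gene symbol",
                             paste(cands, collapse = "' / '")))
}

## --- location strings ------------------------------------------------------

.parseLocation <- function(loc, L, line_no) {
    raw <- gsub("[[:space:]<>]", "", loc)
    strand <- "+"
    body <- raw
    if (startsWith(body, "complement(")) {
        strand <- "-"
        body <- sub("^complement\\((.*)\\)$", "\\1", body)
    }
    body <- sub("^(join|order)\\((.*)\\)$", "\\2", body)
    segs <- strsplit(body, ",", fixed = TRUE)[[1]]
    parse_seg <- function(s) {
        m <- regmatches(s, regexec("^(\\d+)\\.\\.(\\d+)$", s))[[1]]
        if (length(m) == 3L) return(as.integer(m[2:3]))
        if (grepl("^\\d+$", s)) return(rep(as.integer(s), 2L))
        stop(sprintf("unparseable location '%s' at line %d", loc, line_no))
    }
    coords <- lapply(segs, parse_seg)
    if (length(coords) == 1L) {
        start <- coords[[1]][1]; end <- coords[[1]][2]
    } else if (length(coords) == 2L &&
               coords[[1]][2] == L && coords[[2]][1] == 1L) {
        start <- coords[[1]][1]          # origin-spanning join
        end <- L + coords[[2]][2]
    } else {
        start <- min(vapply(coords, `[`, integer(1), 1))
        end <- max(vapply(coords, `[`, integer(1), 2))
        warning(sprintf(
            "multi-segment location '%s' collapsed to its span", loc))
    }
    list(start = start, end = end, strand = strand)
}

## --- parsing ---------------------------------------------------------------

.parseRecord <- function(lines, offset) {
    locus <- grep("^LOCUS", lines)
    if (!length(locus))
        stop(sprintf("not GenBank format: no LOCUS line near line %d",
                     offset + 1L))
    locus_f <- strsplit(trimws(lines[locus[1]]), "[[:space:]]+")[[1]]
    accession <- locus_f[2]
    L <- suppressWarnings(as.integer(locus_f[3]))
    acc_line <- grep("^ACCESSION", lines, value = TRUE)
    if (length(acc_line)) {
        a <- strsplit(trimws(acc_line[1]), "[[:space:]]+")[[1]]
        if (length(a) >= 2L) accession <- a[2]
    }
    org_line <- grep("^ {2,}ORGANISM", lines, value = TRUE)
    taxon <- if (length(org_line))
        trimws(sub("^ +ORGANISM +", "", org_line[1])) else NA_character_

    feat_from <- grep("^FEATURES", lines)
    origin_at <- grep("^ORIGIN", lines)
    if (!length(feat_from) || !length(origin_at))
        stop(sprintf(
            "record '%s': missing FEATURES or ORIGIN section (near line %d)",
            accession, offset + 1L))
    seq_lines <- lines[(origin_at[1] + 1L):length(lines)]
    seq_txt <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (is.na(L)) L <- nchar(seq_txt)
    if (nchar(seq_txt) != L)
        stop(sprintf("record '%s': LOCUS length %d but %d sequence characters",
                     accession, L, nchar(seq_txt)))

    flines <- lines[(feat_from[1] + 1L):(origin_at[1] - 1L)]
    ## group feature blocks: a new feature starts with a key in column 6
    starts <- grep("^ {5}\\S", flines)
    feats <- list()
    skipped <- character(0)
    for (i in seq_along(starts)) {
        from <- starts[i]
        to <- if (i < length(starts)) starts[i + 1L] - 1L else length(flines)
        block <- flines[from:to]
        head_f <- strsplit(trimws(block[1]), "[[:space:]]+")[[1]]
        key <- head_f[1]
        loc <- paste0(head_f[-1], collapse = "")
        ## location may continue before the first qualifier line
        j <- 2L
        while (j <= length(block) && !grepl("^ +/", block[j])) {
            loc <- paste0(loc, gsub("[[:space:]]", "", block[j]))
            j <- j + 1L
        }
        if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop"))
            next
        quals <- paste(block[j - 1L + seq_len(length(block) - j + 1L)],
                       collapse = "\n")
        getq <- function(name) {
            m <- regmatches(quals, regexec(
                sprintf('/%s="?([^"\n]*)"?', name), quals))[[1]]
            if (length(m) == 2L) m[2] else ""
        }
        gene <- getq("gene")
        product <- getq("product")
        note <- getq("note")
        anticodon <- ""
        ac <- regmatches(quals, regexec("seq:([A-Za-z]{3})", quals))[[1]]
        if (length(ac) == 2L) anticodon <- ac[2]
        sym <- tryCatch({
            if (key %in% c("misc_feature", "D-loop")) {
                txt <- tolower(paste(gene, product, note))
                if (key == "D-loop" || grepl("control|a\\+t|d-loop", txt))
                    "CR"
                else normalizeSymbol(gene, anticodon,
                                     if (nzchar(product)) product else note)
            } else {
                normalizeSymbol(gene, anticodon, product)
            }
        }, mitoRearr_unresolved_symbol = function(e) {
            skipped <<- c(skipped, conditionMessage(e))
            NA_character_
        })
        if (is.na(sym)) next
        pl <- .parseLocation(loc, L, offset + feat_from[1] + from)
        kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", "CR")
        feats[[length(feats) + 1L]] <- data.frame(
            symbol = sym, start = pl$start, end = pl$end, strand = pl$strand,
            kind = kind, stringsAsFactors = FALSE)
    }
    if (length(skipped))
        warning(sprintf("record '%s': skipped %d unmappable feature(s): %s",
                        accession, length(skipped),
                        paste(skipped, collapse = "; ")))
    if (!length(feats))
        stop(sprintf("record '%s': no mappable gene features", accession))
    ft <- do.call(rbind, feats)
    ft <- ft[order(ft$start, -(ft$end - ft$start)), , drop = FALSE]
    missing <- setdiff(setdiff(canonicalSymbols(), "CR"), ft$symbol)
    if (length(missing))
        warning(sprintf("record '%s': gene(s) missing from annotation: %s",
                        accession, paste(missing, collapse = ", ")))
    annotatedMitogenome(accession, seq_txt, ft, taxon = taxon)
}

#' Parse a GenBank flat file of annotated mitogenomes
#'
#' Reads one or more records from a GenBank flat file (.gb/.gbk). CDS,
#' tRNA, rRNA and control-region (misc_feature/D-loop) features are mapped
#' to canonical symbols via \code{\link{normalizeSymbol}};
#' \code{complement()} and origin-spanning \code{join()} locations are
#' resolved; features are sorted by start position. Features whose names
#' cannot be mapped are skipped with a warning, as is a record missing any
#' of the 37 canonical genes (the parse still succeeds).
#'
#' @param path file path.
#' @return list of \code{\link{AnnotatedMitogenome}}, one per record.
#' @export
parseGenBank <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines)) stop(sprintf("empty file: %s", path))
    ends <- grep("^//", lines)
    if (!length(ends)) ends <- length(lines)
    out <- list()
    from <- 1L
    for (e in ends) {
        chunk <- lines[from:e]
        if (any(grepl("^LOCUS", chunk)))
            out[[length(out) + 1L]] <- .parseRecord(chunk, from - 1L)
        from <- e + 1L
    }
    if (!length(out))
        stop(sprintf("no GenBank records found in %s (no LOCUS line)", path))
    out
}

## --- writing ---------------------------------------------------------------

.PRODUCT <- c(
    nad1 = "NADH dehydrogenase subunit 1",
    nad2 = "NADH dehydrogenase subunit 2",
    nad3 = "NADH dehydrogenase subunit 3",
    nad4 = "NADH dehydrogenase subunit 4",
    nad4l = "NADH dehydrogenase subunit 4L",
    nad5 = "NADH dehydrogenase subunit 5",
    nad6 = "NADH dehydrogenase subunit 6",
    cox1 = "cytochrome c oxidase subunit I",
    cox2 = "cytochrome c oxidase subunit II",
    cox3 = "cytochrome c oxidase subunit III",
    atp6 = "ATP synthase F0 subunit 6",
    atp8 = "ATP synthase F0 subunit 8",
    cob = "cytochrome b",
    rrnL = "16S ribosomal RNA",
    rrnS = "12S ribosomal RNA"
)

.TRNA_ANTICODON <- c(trnL1 = "tag", trnL2 = "taa", trnS1 = "tct",
                     trnS2 = "tga")

.trnaProduct <- function(sym) {
    aa1 <- substr(sym, 4L, 4L)
    aa3 <- names(.AA3)[match(aa1, .AA3)]
    paste0("tRNA-", aa3)
}

.formatLocation <- function(start, end, strand, L) {
    body <- if (end <= L) sprintf("%d..%d", start, end)
            else sprintf("join(%d..%d,1..%d)", start, L, end - L)
    if (strand == "-") sprintf("complement(%s)", body) else body
}

#' Write an annotated mitogenome as a GenBank flat file
#'
#' Emits a syntactically valid single-record flat file that round-trips
#' through \code{\link{parseGenBank}} (symbols, coordinates and strands are
#' preserved exactly; origin-spanning features are written as
#' \code{join()} locations).
#'
#' @param genome an \code{\link{AnnotatedMitogenome}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenBank <- function(genome, path) {
    ft <- featureTable(genome)
    s <- tolower(as.character(genomeSeq(genome)))
    L <- nchar(s)
    acc <- accession(genome)
    taxon <- if (is.na(taxon(genome))) "synthetic organism" else taxon(genome)
    out <- c(
        sprintf("LOCUS       %-16s %d bp    DNA     circular INV 01-JAN-2026",
                acc, L),
        sprintf("DEFINITION  %s mitochondrion, complete genome.", taxon),
        sprintf("ACCESSION   %s", acc),
        sprintf("SOURCE      mitochondrion %s", taxon),
        sprintf("  ORGANISM  %s", taxon),
        "FEATURES             Location/Qualifiers",
        sprintf("     source          1..%d", L),
        sprintf("                     /organism=\"%s\"", taxon),
        "                     /organelle=\"mitochondrion\""
    )
    qline <- function(txt) sprintf("                     %s", txt)
    for (i in seq_len(nrow(ft))) {
        sym <- ft$symbol[i]
        loc <- .formatLocation(ft$start[i], ft$end[i], ft$strand[i], L)
        key <- switch(ft$kind[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                      CR = "misc_feature")
        out <- c(out, sprintf("     %-15s %s", key, loc))
        if (ft$kind[i] == "CR") {
            out <- c(out, qline("/note=\"control region (A+T-rich region)\""))
            next
        }
        out <- c(out, qline(sprintf("/gene=\"%s\"", sym)))
        if (ft$kind[i] == "tRNA") {
            out <- c(out, qline(sprintf("/product=\"%s\"",
                                        .trnaProduct(sym))))
            if (sym %in% names(.TRNA_ANTICODON))
                out <- c(out, qline(sprintf(
                    "/anticodon=\"(pos:complement,aa:%s,seq:%s)\"",
                    sub("tRNA-", "", .trnaProduct(sym)),
                    .TRNA_ANTICODON[[sym]])))
        } else {
            out <- c(out, qline(sprintf("/product=\"%s\"", .PRODUCT[[sym]])))
            if (ft$kind[i] == "PCG")
                out <- c(out, qline("/transl_table=5"))
        }
    }
    out <- c(out, "ORIGIN")
    for (pos in seq(1L, L, 60L)) {
        chunk <- substr(s, pos, min(pos + 59L, L))
        tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
        out <- c(out, sprintf("%9d %s", pos, paste(tens, collapse = " ")))
    }
    out <- c(out, "//")
    writeLines(out, path)
    invisible(path)
}
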