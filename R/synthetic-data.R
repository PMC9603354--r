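## Seeded synthetic data: cohorts, annotated records, codon alignments -------

#' Simulation configuration
#'
#' Collects every tunable of the synthetic generators and validates it. All
#' generators are fully deterministic given \code{seed}.
#'
#' @param seed integer seed driving every draw.
#' @param n_genomes number of genomes in a simulated cohort.
#' @param event_rate expected rearrangement events per genome (Poisson
#'   mean); at low rates most genomes stay unrearranged, emulating the
#'   rare-accident regime of mitogenome rearrangement.
#' @param fixed_events \code{NULL} (Poisson draws, the default) or an
#'   integer forcing exactly this many events in every genome, for
#'   controlled recovery experiments.
#' @param event_mix probabilities over the three mechanisms, in the order
#'   TDRL, inversion, transposition; normalised to sum 1.
#' @param max_block_len maximum rearranged block length (default 3: every
#'   described Ensifera rearrangement involves blocks of at most three
#'   genes).
#' @param p_gene_loss probability that a TDRL deletes both copies of a
#'   duplicated gene (complete gene loss, as for trnI in Type IV).
#' @param base_freqs named list of nucleotide frequency vectors
#'   (A, C, G, T) per region class: \code{default} and optionally
#'   \code{CR}; defaults reflect the AT-rich composition of insect
#'   mitogenomes (about 70 percent AT overall, 80 percent in the CR).
#' @param codon_sub_probs numeric c(p_syn, p_nonsyn): per-site acceptance
#'   probabilities for synonymous/nonsynonymous change in codon-pair
#'   simulation.
#' @param cr_len control-region length in the simulated record.
#' @param wrap_cr if TRUE the record is rotated so the control region spans
#'   the circular origin (exercises join()-style coordinates).
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed = 1L, n_genomes = 10L, event_rate = 0.5,
                      fixed_events = NULL,
                      event_mix = c(TDRL = 0.4, inversion = 0.3,
                                    transposition = 0.3),
                      max_block_len = 3L, p_gene_loss = 0.02,
                      base_freqs = list(
                          default = c(A = 0.36, C = 0.16, G = 0.12, T = 0.36),
                          CR = c(A = 0.41, C = 0.11, G = 0.09, T = 0.39)),
                      codon_sub_probs = c(p_syn = 0.10, p_nonsyn = 0.02),
                      cr_len = 1275L, wrap_cr = FALSE) {
    stopifnot(length(event_mix) == 3L, all(event_mix >= 0),
              sum(event_mix) > 0, event_rate >= 0, max_block_len >= 1L,
              p_gene_loss >= 0, p_gene_loss <= 1)
    for (f in base_freqs) {
        stopifnot(all(c("A", "C", "G", "T") %in% names(f)), all(f >= 0))
    }
    cfg <- list(
        seed = as.integer(seed), n_genomes = as.integer(n_genomes),
        event_rate = event_rate,
        fixed_events = if (is.null(fixed_events)) NULL
                       else as.integer(fixed_events),
        event_mix = event_mix / sum(event_mix),
        max_block_len = as.integer(max_block_len),
        p_gene_loss = p_gene_loss,
        base_freqs = lapply(base_freqs, function(f) f[c("A","C","G","T")] /
                                sum(f[c("A","C","G","T")])),
        codon_sub_probs = codon_sub_probs,
        cr_len = as.integer(cr_len), wrap_cr = isTRUE(wrap_cr)
    )
    class(cfg) <- "SimConfig"
    cfg
}

## Draw one random event applicable to `order`, never touching the CR and
## never the identity (resampled until the canonical order changes).
.randomEvent <- function(order, cfg) {
    n <- length(order)
    key0 <- .orderKey(order)
    repeat {
        kind <- sample(c("TDRL", "inversion", "transposition"), 1L,
                       prob = cfg$event_mix)
        len <- sample.int(cfg$max_block_len, 1L)
        start <- sample.int(n, 1L)
        idx <- (((start - 1L) + seq_len(len) - 1L) %% n) + 1L
        if (match("CR", geneSymbols(order)) %in% idx) next
        ev <- switch(kind,
            inversion = inversionEvent(start, len),
            transposition = transpositionEvent(start, len,
                                               sample(0:(n - len), 1L)),
            TDRL = {
                loss <- integer(0)
                for (j in seq_len(len)) {
                    u <- stats::runif(1)
                    loss <- c(loss, if (u < cfg$p_gene_loss) c(j, j + len)
                              else if (u < (1 + cfg$p_gene_loss) / 2) j + len
                              else j)
                }
                tdrlEvent(start, len, loss)
            })
        out <- applyEvent(order, ev)
        if (.orderKey(out) != key0) return(list(event = ev, result = out))
    }
}

#' Simulate a cohort of gene orders with a known event history
#'
#' Each genome starts from the ancestral order and receives a
#' Poisson(\code{event_rate}) number of random events (TDRL, inversion or
#' transposition per \code{event_mix}); every event is recorded in a ground
#' truth log for recovery experiments. Events never involve the control
#' region and are conditioned on actually changing the order.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{orders} (list of \code{SignedGeneOrder},
#'   provenance \code{"sim_001"}, ...) and \code{log} (list per genome:
#'   accession, n_events, events as \code{\link{describeEvent}} lists,
#'   events_raw as \code{RearrangementEvent}s applied left to right).
#' @export
#' @examples
#' sim <- simulateCohort(simConfig(seed = 7, n_genomes = 3, event_rate = 1))
#' vapply(sim$log, `[[`, integer(1), "n_events")
simulateCohort <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    anc <- ancestralOrder()
    orders <- vector("list", cfg$n_genomes)
    log <- vector("list", cfg$n_genomes)
    for (i in seq_len(cfg$n_genomes)) {
        accn <- sprintf("sim_%03d", i)
        k <- if (is.null(cfg$fixed_events)) stats::rpois(1L, cfg$event_rate)
             else cfg$fixed_events
        o <- signedGeneOrder(geneSymbols(anc), geneSigns(anc), accn)
        evs <- list(); descr <- list()
        for (e in seq_len(k)) {
            draw <- .randomEvent(o, cfg)
            descr[[e]] <- describeEvent(o, draw$event)
            evs[[e]] <- draw$event
            o <- draw$result
        }
        orders[[i]] <- o
        log[[i]] <- list(accession = accn, n_events = as.integer(k),
                         events = descr, events_raw = evs)
    }
    list(orders = orders, log = log)
}

## Typical insect mitochondrial gene lengths (bp); PCGs are multiples of 3.
.GENE_LEN <- c(
    cox1 = 1536L, cox2 = 687L, cox3 = 789L, cob = 1137L,
    nad1 = 942L, nad2 = 1023L, nad3 = 354L, nad4 = 1341L, nad4l = 297L,
    nad5 = 1719L, nad6 = 525L, atp6 = 675L, atp8 = 159L,
    rrnL = 1285L, rrnS = 765L
)

.sampleSeq <- function(n, freqs) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
          collapse = "")
}

## Random in-frame CDS: ATG start, sense-codon interior drawn from base
## frequencies by rejection of stops, TAA stop.
.sampleCDS <- function(len, freqs, code) {
    n_codons <- len %/% 3L
    inner <- character(n_codons - 2L)
    for (i in seq_along(inner)) {
        repeat {
            cod <- .sampleSeq(3L, freqs)
            if (code[[cod]] != "*") break
        }
        inner[i] <- cod
    }
    paste(c("ATG", inner, "TAA"), collapse = "")
}

#' Simulate an annotated mitogenome record realising a gene order
#'
#' Lays the genes of \code{order} contiguously around a circular molecule:
#' tRNAs are 63-72 bp, protein-coding and rRNA genes use typical insect
#' mitochondrial lengths, the control region is \code{cfg$cr_len} bp drawn
#' from the CR base frequencies. Minority-strand genes are
#' reverse-complemented into the genome. With \code{cfg$wrap_cr} the record
#' is rotated so the control region spans the origin. The record
#' round-trips through \code{\link{writeGenBank}} and
#' \code{\link{parseGenBank}}, and \code{\link{extractOrder}} recovers
#' \code{order}.
#'
#' @param order a \code{\link{SignedGeneOrder}}.
#' @param cfg a \code{\link{simConfig}} (its seed is NOT set here so that
#'   cohorts of records can be generated in one seeded stream; call
#'   \code{set.seed} or use \code{\link{simulateCohortRecords}} for full
#'   determinism).
#' @param taxon species label written to the record.
#' @return An \code{\link{AnnotatedMitogenome}}.
#' @export
simulateRecord <- function(order, cfg = simConfig(),
                           taxon = "Synthetica exempli") {
    code <- mitoGeneticCode()
    syms <- geneSymbols(order); sgns <- geneSigns(order)
    pieces <- character(length(syms))
    for (i in seq_along(syms)) {
        g <- syms[i]
        kind <- symbolKind(g)
        freqs <- if (g == "CR" && !is.null(cfg$base_freqs$CR))
            cfg$base_freqs$CR else cfg$base_freqs$default
        gene_seq <- switch(kind,
            PCG = .sampleCDS(.GENE_LEN[[g]], freqs, code),
            rRNA = .sampleSeq(.GENE_LEN[[g]] +
                                  sample(-15:15, 1L), freqs),
            tRNA = .sampleSeq(sample(63:72, 1L), freqs),
            CR = .sampleSeq(cfg$cr_len, freqs))
        if (sgns[i] < 0L)
            gene_seq <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(gene_seq)))
        pieces[i] <- gene_seq
    }
    lens <- nchar(pieces)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    genome_seq <- paste(pieces, collapse = "")
    L <- nchar(genome_seq)
    if (cfg$wrap_cr && "CR" %in% syms) {
        i <- match("CR", syms)
        shift <- starts[i] + lens[i] %/% 2L  # put mid-CR at the origin
        genome_seq <- paste0(substr(genome_seq, shift, L),
                             substr(genome_seq, 1L, shift - 1L))
        starts <- ((starts - shift) %% L) + 1L
        ends <- starts + lens - 1L           # unwrapped; may exceed L
    }
    annotatedMitogenome(
        accession = if (nzchar(provenance(order))) provenance(order)
                    else "synthetic",
        sequence = genome_seq,
        features = data.frame(symbol = syms, start = starts, end = ends,
                              strand = ifelse(sgns < 0L, "-", "+"),
                              stringsAsFactors = FALSE),
        taxon = taxon
    )
}

#' Simulate a cohort and write it as GenBank records plus ground truth
#'
#' Convenience wrapper: runs \code{\link{simulateCohort}}, realises every
#' order as an annotated record, writes one \code{.gb} file per genome into
#' \code{dir} together with \code{ground_truth.json} (sorted keys). Fully
#' deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the \code{\link{simulateCohort}} result with an added
#'   \code{genomes} element.
#' @export
simulateCohortRecords <- function(cfg, dir) {
    sim <- simulateCohort(cfg)   # seeds the stream; record draws continue it
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    genomes <- vector("list", length(sim$orders))
    for (i in seq_along(sim$orders)) {
        genomes[[i]] <- simulateRecord(sim$orders[[i]], cfg)
        writeGenBank(genomes[[i]],
                     file.path(dir, paste0(accession(genomes[[i]]), ".gb")))
    }
    truth <- lapply(sim$log, function(l)
        list(accession = l$accession, n_events = l$n_events,
             events = l$events))
    names(truth) <- vapply(sim$log, `[[`, character(1), "accession")
    jsonlite::write_json(truth[order(names(truth))],
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    sim$genomes <- genomes
    invisible(sim)
}

#' Simulate a codon-alignment pair with controlled divergence
#'
#' Draws an ancestral sequence of sense codons (uniform over the
#' invertebrate-mitochondrial sense codons) and mutates the descendant
#' site by site: a proposed random base change is accepted with probability
#' \code{p_syn} when the resulting codon change is synonymous and
#' \code{p_nonsyn} when nonsynonymous; proposals creating stop codons are
#' rejected. Probabilities must stay below 0.5 (saturation guard).
#'
#' @param gene_length_codons number of codons.
#' @param p_syn,p_nonsyn per-site acceptance probabilities (< 0.5).
#' @param seed integer seed.
#' @param gene gene label for the alignment.
#' @return A \code{\link{CodonAlignment}}.
#' @export
#' @examples
#' aln <- simulateCodonPair(50, 0.2, 0.05, seed = 1)
#' ng86(aln)
simulateCodonPair <- function(gene_length_codons, p_syn, p_nonsyn, seed,
                              gene = "sim") {
    if (p_syn >= 0.5 || p_nonsyn >= 0.5 || p_syn < 0 || p_nonsyn < 0)
        stop("substitution probabilities must lie in [0, 0.5) (saturation guard)")
    set.seed(as.integer(seed))
    code <- mitoGeneticCode()
    sense <- names(code)[code != "*"]
    anc <- sample(sense, gene_length_codons, replace = TRUE)
    des <- anc
    for (i in seq_along(des)) {
        for (p in 1:3) {
            cur <- des[i]
            b <- sample(setdiff(.BASES, substr(cur, p, p)), 1L)
            cand <- cur
            substr(cand, p, p) <- b
            if (code[[cand]] == "*") next
            pr <- if (code[[cand]] == code[[cur]]) p_syn else p_nonsyn
            if (stats::runif(1) < pr) des[i] <- cand
        }
    }
    codonAlignment(gene, paste(anc, collapse = ""),
                   paste(des, collapse = ""))
}
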