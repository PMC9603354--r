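## End-to-end orchestration and report serialization -------------------------

.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run the full gene-arrangement pipeline on a directory of GenBank files
#'
#' Parses every \code{.gb}/\code{.gbk} file in \code{input_dir}, then
#' writes into \code{output_dir}: per-region composition and RSCU tables,
#' the canonical gene-order file, arrangement-type assignments, the
#' rearrangement report (per-gene scores, genome RS, gene RF), a minimal
#' event-history JSON for every rearranged genome, an optional Ka/Ks table
#' when \code{kaks_dir} holds per-gene codon alignments, a machine-readable
#' \code{warnings.json}, and the serialized run configuration. Per-record
#' parse failures are logged and skipped; only an empty cohort is a hard
#' error. Outputs are byte-reproducible for identical inputs and
#' configuration (timestamps are confined to the log file).
#'
#' @param input_dir directory of GenBank flat files.
#' @param output_dir report directory (created if needed).
#' @param reference \code{"ancestral"} or the accession of a cohort genome
#'   to score against.
#' @param max_events,max_block_len search limits for event inference.
#' @param kaks_dir optional directory of per-gene aligned FASTA files.
#' @param kaks_reference reference sequence (name or index) within each
#'   alignment file.
#' @return Invisibly, a list with the in-memory results (genomes, orders,
#'   types, qmgr report, inferences, kaks table, warnings).
#' @export
runPipeline <- function(input_dir, output_dir, reference = "ancestral",
                        max_events = 1L, max_block_len = 6L,
                        kaks_dir = NULL, kaks_reference = 1L) {
    files <- sort(list.files(input_dir, pattern = "\\.(gb|gbk)$",
                             full.names = TRUE))
    if (!length(files))
        stop(sprintf("no GenBank files in %s", input_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    logfile <- file.path(output_dir, "run.log")
    warnings_log <- list()
    note <- function(kind, msg) {
        warnings_log[[length(warnings_log) + 1L]] <<-
            list(kind = kind, message = msg)
        cat(sprintf("[%s] %s: %s\n", format(Sys.time()), kind, msg),
            file = logfile, append = TRUE)
    }
    cat(sprintf("[%s] run started: %d input file(s)\n",
                format(Sys.time()), length(files)),
        file = logfile)

    genomes <- list()
    for (f in files) {
        recs <- withCallingHandlers(
            tryCatch(parseGenBank(f), error = function(e) {
                note("parse_error", sprintf("%s: %s", basename(f),
                                            conditionMessage(e)))
                NULL
            }),
            warning = function(w) {
                note("parse_warning", sprintf("%s: %s", basename(f),
                                              conditionMessage(w)))
                invokeRestart("muffleWarning")
            })
        genomes <- c(genomes, recs)
    }
    if (!length(genomes)) stop("no parseable records in input directory")

    withCallingHandlers({
        comp <- do.call(rbind, lapply(genomes, regionStats))
        rscu <- do.call(rbind, lapply(genomes, function(g) {
            cds <- lapply(featureTable(g)$symbol[featureTable(g)$kind == "PCG"],
                          function(sym) as.character(featureSeq(g, sym)))
            names(cds) <- featureTable(g)$symbol[featureTable(g)$kind == "PCG"]
            cbind(accession = accession(g), codonUsage(cds),
                  stringsAsFactors = FALSE)
        }))
        orders <- lapply(genomes, extractOrder)
        types <- classifyTypes(orders)
        ref_order <- if (identical(reference, "ancestral")) ancestralOrder()
            else {
                hit <- which(vapply(orders, provenance, character(1)) ==
                             reference)
                if (!length(hit))
                    stop(sprintf("reference accession '%s' not in cohort",
                                 reference))
                orders[[hit[1]]]
            }
        qr <- cohortReport(orders, ref_order)
        inferences <- list()
        for (o in orders) {
            inf <- inferEvents(ref_order, o, max_events = max_events,
                               max_block_len = max_block_len)
            if (inf@status != "identical")
                inferences[[provenance(o)]] <- inf
        }
        kk <- NULL
        if (!is.null(kaks_dir)) {
            kk <- cohortKaKs(readCodonAlignments(kaks_dir, kaks_reference))
        }
    },
    warning = function(w) {
        note("analysis_warning", conditionMessage(w))
        invokeRestart("muffleWarning")
    },
    message = function(m) {
        note("analysis_note", sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
    })

    .writeTSV(comp, file.path(output_dir, "composition.tsv"))
    .writeTSV(rscu, file.path(output_dir, "rscu.tsv"))
    writeGeneOrders(orders, file.path(output_dir, "gene_orders.txt"))
    .writeTSV(types$assignments, file.path(output_dir, "types.tsv"))
    .writeTSV(qr$scores, file.path(output_dir, "qmgr_gene_scores.tsv"))
    .writeTSV(qr$genome_rs, file.path(output_dir, "qmgr_genome_rs.tsv"))
    .writeTSV(qr$gene_rf, file.path(output_dir, "qmgr_gene_rf.tsv"))
    if (length(inferences))
        writeEventReport(inferences, file.path(output_dir, "tdrl.json"))
    if (!is.null(kk)) .writeTSV(kk, file.path(output_dir, "kaks.tsv"))
    jsonlite::write_json(warnings_log, file.path(output_dir, "warnings.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    cfg <- list(input_dir = input_dir, reference = reference,
                max_events = as.integer(max_events),
                max_block_len = as.integer(max_block_len),
                kaks_dir = if (is.null(kaks_dir)) NULL else kaks_dir,
                kaks_reference = kaks_reference,
                n_records = length(genomes))
    jsonlite::write_json(cfg[order(names(cfg))],
                         file.path(output_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    cat(sprintf("[%s] run finished: %d genome(s), %d warning(s)\n",
                format(Sys.time()), length(genomes), length(warnings_log)),
        file = logfile, append = TRUE)
    invisible(list(genomes = genomes, orders = orders, types = types,
                   qmgr = qr, inferences = inferences, kaks = kk,
                   warnings = warnings_log))
}
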