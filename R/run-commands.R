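# Config-driven pipeline commands. These are the programmatic equivalents of
# the shell entry point in inst/scripts/pairmark.R: each takes a configuration
# (YAML/JSON path or named list), writes its outputs atomically, never mutates
# its inputs, and records the config hash and seed in every report.

.loadConfig <- function(config, allowed, required = character()) {
    if (is.character(config) && length(config) == 1L) {
        config <- if (grepl("\\.json$", config, ignore.case = TRUE))
            jsonlite::read_json(config, simplifyVector = TRUE)
        else yaml::read_yaml(config)
    }
    if (!is.list(config)) stop("config must be a named list or a file path")
    unknown <- setdiff(names(config), allowed)
    if (length(unknown))
        stop(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")))
    miss <- setdiff(required, names(config))
    if (length(miss))
        stop(sprintf("missing config key(s): %s", paste(miss, collapse = ", ")))
    config
}

.hpFromConfig <- function(config) {
    keys <- c("tau_min", "dispersion_max", "alpha", "bulk_min", "f_on",
              "e_min", "w_auc", "w_off", "w_tau", "max_candidates",
              "require_target_call")
    args <- config[intersect(keys, names(config))]
    names(args) <- c(tau_min = "tauMin", dispersion_max = "dispersionMax",
                     alpha = "alpha", bulk_min = "bulkMin", f_on = "fOn",
                     e_min = "eMin", w_auc = "wAuc", w_off = "wOff",
                     w_tau = "wTau", max_candidates = "maxCandidates",
                     require_target_call = "requireTargetCall")[names(args)]
    do.call(markerHyperparams, args)
}

.hpConfigKeys <- c("tau_min", "dispersion_max", "alpha", "bulk_min", "f_on",
                   "e_min", "w_auc", "w_off", "w_tau", "max_candidates",
                   "require_target_call")

.readAnnotatedAtlas <- function(config) {
    sce <- readCountMatrix(config$matrix, config$genes, config$cells)
    sce <- addClusterAnnotation(sce, config$clusters, config$cluster_tissues)
    normalizeAtlas(sce,
                   scaleTarget = config$scale_target %||% 1e4,
                   pseudocount = config$pseudocount %||% 1,
                   dropEmpty = isTRUE(config$drop_empty_cells))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline commands
#'
#' Config-driven entry points tying the modules into a pipeline. `config` is
#' a named list or the path of a YAML/JSON file; extra arguments in `...`
#' override config values (flags beat file beats defaults). Unknown keys are
#' rejected. All outputs are written atomically and are byte-identical across
#' reruns with the same config.
#'
#' * `cmdSimulate` writes a synthetic atlas as the exact formats the readers
#'   consume: `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, `clusters.tsv`,
#'   `cluster_tissues.tsv`, `bulk.tsv`, and the ground truth `truth.json`.
#'   Keys: `out_dir`, `seed`, and any [simulateAtlas()] parameter
#'   (`n_clusters`, `n_tissues`, `cells_per_cluster`, `n_genes`,
#'   `baseline_mean`, `nb_size`, `marker_fold`, `n_decoy_pairs`,
#'   `decoy_offtargets`, `bulk_noise_sd`).
#' * `cmdCandidates` writes per-gene metrics with pass flags to
#'   `out` (TSV). Keys: `matrix`, `genes`, `cells`, `clusters`,
#'   `cluster_tissues`, `target_cluster`, optional `bulk`, `target_tissue`,
#'   hyperparameter keys (`tau_min`, ...), `out`, `seed`.
#' * `cmdRank` writes the ranked pair report to `out.tsv` and `out.json`.
#'   Same keys as `cmdCandidates`.
#' * `cmdDesignArms` writes homology-arm designs. Keys: `genome_fasta`,
#'   `gff3`, `transcripts`, `arm_length`, `codon`, `out` (prefix for
#'   `.tsv`/`.fasta`).
#'
#' @param config named list or YAML/JSON path.
#' @param ... config overrides.
#' @return the primary result invisibly (`cmdSimulate`: the simulation list;
#'   `cmdCandidates`: the metrics table; `cmdRank`: the
#'   [PairRanking-class]; `cmdDesignArms`: the design list), with output
#'   paths in attribute `"paths"`.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmdSimulate <- function(config = list(), ...) {
    allowed <- c("out_dir", "seed", "n_clusters", "n_tissues",
                 "cells_per_cluster", "n_genes", "baseline_mean", "nb_size",
                 "marker_fold", "n_decoy_pairs", "decoy_offtargets",
                 "bulk_noise_sd")
    config <- utils::modifyList(.loadConfig(config, allowed), list(...))
    config <- .loadConfig(config, allowed, required = "out_dir")
    simArgs <- list(
        nClusters = config$n_clusters %||% 12L,
        nTissues = config$n_tissues %||% 4L,
        cellsPerCluster = config$cells_per_cluster %||% 50L,
        nGenes = config$n_genes %||% 300L,
        baselineMean = config$baseline_mean %||% 2,
        nbSize = config$nb_size %||% 10,
        markerFold = config$marker_fold %||% 8,
        nDecoyPairs = config$n_decoy_pairs %||% 3L,
        decoyOfftargets = config$decoy_offtargets %||% 2L,
        bulkNoiseSd = config$bulk_noise_sd %||% 0.1,
        seed = config$seed %||% 1L)
    sim <- do.call(simulateAtlas, simArgs)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    writeCountMatrix(sim$sce, p("matrix.mtx"), p("genes.tsv"),
                     p("barcodes.tsv"))
    cd <- colData(sim$sce)
    .writeAtomic(p("clusters.tsv"), function(f)
        write.table(data.frame(colnames(sim$sce), cd$cluster), f,
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE))
    map <- metadata(sim$sce)$clusterToTissue
    .writeAtomic(p("cluster_tissues.tsv"), function(f)
        write.table(data.frame(names(map), unname(map)), f, sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE))
    writeBulkTable(sim$bulk, p("bulk.tsv"))
    truth <- sim$truth
    .writeAtomic(p("truth.json"), function(f)
        jsonlite::write_json(list(
            planted_pair = plantedPair(truth),
            decoy_pairs = truth@decoyPairs,
            decoy_offtargets = truth@decoyOfftargets,
            target_cluster = targetCluster(truth),
            target_tissue = targetTissue(truth),
            seed = simArgs$seed,
            config_hash = .configHash(simArgs)), f, auto_unbox = TRUE,
            pretty = TRUE))
    out <- sim
    attr(out, "paths") <- p(c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                              "clusters.tsv", "cluster_tissues.tsv",
                              "bulk.tsv", "truth.json"))
    invisible(out)
}

.rankKeys <- c("matrix", "genes", "cells", "clusters", "cluster_tissues",
               "bulk", "target_cluster", "target_tissue", "out", "seed",
               "scale_target", "pseudocount", "drop_empty_cells",
               .hpConfigKeys)

#' @rdname pipeline-commands
#' @export
cmdCandidates <- function(config = list(), ...) {
    config <- utils::modifyList(.loadConfig(config, .rankKeys), list(...))
    config <- .loadConfig(config, .rankKeys,
                          required = c("matrix", "clusters",
                                       "cluster_tissues", "target_cluster",
                                       "out"))
    sce <- .readAnnotatedAtlas(config)
    bulk <- if (!is.null(config$bulk)) readBulkTable(config$bulk)
            else pseudobulkProfiles(sce)
    hp <- .hpFromConfig(config)
    metrics <- geneMetrics(sce, bulk, config$target_cluster)
    cand <- candidateGenes(metrics, hp)
    tab <- as.data.frame(metrics)
    tab <- data.frame(gene_id = rownames(tab), tab,
                      passTau = !is.na(metrics$tau) & metrics$tau >= hp@tauMin,
                      passDispersion = metrics$dispersion <= hp@dispersionMax,
                      passTTest = !is.na(metrics$qT) & metrics$qT <= hp@alpha &
                          metrics$meanTarget > metrics$meanRest,
                      passBulk = !is.na(metrics$bulkTarget) &
                          metrics$bulkTarget >= hp@bulkMin,
                      candidate = rownames(tab) %in% cand$genes,
                      stringsAsFactors = FALSE)
    .writeAtomic(config$out, function(f)
        write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE))
    out <- metrics
    attr(out, "paths") <- config$out
    attr(out, "candidates") <- cand
    invisible(out)
}

#' @rdname pipeline-commands
#' @export
cmdRank <- function(config = list(), ...) {
    config <- utils::modifyList(.loadConfig(config, .rankKeys), list(...))
    config <- .loadConfig(config, .rankKeys,
                          required = c("matrix", "clusters",
                                       "cluster_tissues", "target_cluster",
                                       "out"))
    sce <- .readAnnotatedAtlas(config)
    bulk <- if (!is.null(config$bulk)) readBulkTable(config$bulk)
            else pseudobulkProfiles(sce)
    hp <- .hpFromConfig(config)
    ranking <- rankPairs(sce, bulk, config$target_cluster, hp)
    if (!is.null(config$target_tissue) &&
        tolower(ranking@targetTissue) != tolower(config$target_tissue))
        stop(sprintf("target cluster maps to tissue '%s', not '%s'",
                     ranking@targetTissue, config$target_tissue))
    ranking@diagnostics$seed <- config$seed %||% NA_integer_
    ranking@diagnostics$configHash <- .configHash(config)
    writeReport(ranking, config$out, format = "both")
    attr(ranking, "paths") <- paste0(config$out, c(".tsv", ".json"))
    invisible(ranking)
}

#' @rdname pipeline-commands
#' @export
cmdDesignArms <- function(config = list(), ...) {
    allowed <- c("genome_fasta", "gff3", "transcripts", "arm_length",
                 "codon", "out", "seed")
    config <- utils::modifyList(.loadConfig(config, allowed), list(...))
    config <- .loadConfig(config, allowed,
                          required = c("genome_fasta", "gff3", "transcripts",
                                       "out"))
    designs <- designArms(config$genome_fasta, config$gff3,
                          transcripts = unlist(config$transcripts),
                          armLength = config$arm_length %||% 200L,
                          codon = config$codon %||% "first_valid")
    writeArmDesigns(designs, tsvPath = paste0(config$out, ".tsv"),
                    fastaPath = paste0(config$out, ".fasta"))
    attr(designs, "paths") <- paste0(config$out, c(".tsv", ".fasta"))
    invisible(designs)
}
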