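.FLUCT_COLS <- c("strain", "culture", "sel_count", "perm_count")

.typeCheck <- function(tab, numeric_cols, path) {
    for (cc in intersect(numeric_cols, colnames(tab))) {
        v <- suppressWarnings(as.numeric(tab[[cc]]))
        bad <- which(is.na(v) & !is.na(tab[[cc]]))
        if (length(bad))
            stop("parse error in ", basename(path), ": column '", cc,
                 "' is not numeric at row ", bad[1L])
        tab[[cc]] <- v
    }
    tab
}

#' Read a colony observation table
#'
#' Tab-separated table with the exact header \code{plate_id, row, col,
#' strain_id, medium, area, circularity}. Fields are type-checked and
#' the key (plate_id, row, col, medium) must be unique; violations are
#' reported with their row number.
#'
#' @param path file path.
#' @return validated colony data.frame.
#' @export
readColonyTable <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE,
                             colClasses = "character")
    if (!identical(colnames(tab), .COLONY_COLS))
        stop("parse error in ", basename(path),
             ": header must be exactly (",
             paste(.COLONY_COLS, collapse = ", "), "), got (",
             paste(colnames(tab), collapse = ", "), ")")
    tab <- .typeCheck(tab, c("row", "col", "area", "circularity"), path)
    key <- paste(tab$plate_id, tab$row, tab$col, tab$medium)
    dup <- which(duplicated(key))
    if (length(dup))
        stop("parse error in ", basename(path),
             ": duplicate (plate_id,row,col,medium) key at row ", dup[1L])
    .checkColonies(tab)
    tab
}

#' Read a fluctuation-test counts table
#'
#' Tab-separated table with header \code{strain, culture, sel_count,
#' perm_count} (an optional \code{test} column, for repeated tests per
#' strain, may follow \code{strain}).
#'
#' @param path file path.
#' @return validated counts data.frame.
#' @export
readFluctuationTable <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE,
                             colClasses = "character")
    ok <- identical(colnames(tab), .FLUCT_COLS) ||
        identical(colnames(tab), append(.FLUCT_COLS, "test", after = 1L))
    if (!ok)
        stop("parse error in ", basename(path),
             ": header must be exactly (",
             paste(.FLUCT_COLS, collapse = ", "),
             ") with an optional 'test' column after 'strain'")
    tab <- .typeCheck(tab, c("test", "culture", "sel_count", "perm_count"),
                      path)
    if (any(tab$sel_count < 0 | tab$perm_count < 0))
        stop("parse error in ", basename(path), ": negative counts")
    key <- paste(tab$strain, if ("test" %in% colnames(tab)) tab$test else 1,
                 tab$culture)
    dup <- which(duplicated(key))
    if (length(dup))
        stop("parse error in ", basename(path),
             ": duplicate (strain,test,culture) key at row ", dup[1L])
    tab
}

#' Read a plain-text gene or strain list
#'
#' One identifier per line; blank lines and \code{#} comments ignored.
#'
#' @param path file path.
#' @return uppercase character vector.
#' @export
readGeneList <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    x <- trimws(readLines(path, warn = FALSE))
    toupper(x[nzchar(x) & !startsWith(x, "#")])
}

#' Write a tab-separated table
#'
#' Plain TSV with header, no quoting, no row names: the round trip
#' through \code{\link{readColonyTable}} /
#' \code{\link{readFluctuationTable}} is lossless.
#'
#' @param x data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Load a screen configuration file
#'
#' A single human-readable YAML file with up to three blocks:
#' \code{screen} (thresholds of \linkS4class{ScreenConfig};
#' \code{exclusion_file} may name a plain-text strain list),
#' \code{sim} (fields of \linkS4class{SimConfig}, with
#' \code{strain_rates} as a name: rate map), and \code{integrate}
#' (currently \code{universe}).
#'
#' @param path YAML file path.
#' @return list with elements \code{screen} (\code{ScreenConfig}),
#'   \code{sim} (\code{SimConfig} or \code{NULL}), and
#'   \code{integrate} (list).
#' @export
readScreenConfig <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    raw <- yaml::read_yaml(path)
    sc <- raw$screen
    if (!is.null(sc$exclusion_file)) {
        ex_path <- sc$exclusion_file
        if (!file.exists(ex_path))
            ex_path <- file.path(dirname(path), sc$exclusion_file)
        sc$exclusion_strains <- readGeneList(ex_path)
        sc$exclusion_file <- NULL
    }
    screen <- do.call(ScreenConfig, if (is.null(sc)) list() else sc)
    sim <- NULL
    if (!is.null(raw$sim)) {
        s <- raw$sim
        rates <- unlist(s$strain_rates)
        s$strain_rates <- stats::setNames(as.numeric(rates), names(rates))
        sim <- do.call(SimConfig, s)
    }
    list(screen = screen, sim = sim,
         integrate = if (is.null(raw$integrate)) list() else raw$integrate)
}

.manifest <- function(command, params, seed, inputs, outputs) {
    list(command = command, config = params, seed = seed,
         input_digests = as.list(tools::md5sum(inputs)),
         output_digests = as.list(tools::md5sum(outputs)),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run the simulate-score-integrate pipeline end to end
#'
#' Simulates a replica-pinning screen from the configured strain rates,
#' writes the colony tables, scores them into per-strain recombinant
#' frequencies, classifies strains against the frequency cutoffs, and
#' writes an integration summary (class counts, flagged-group
#' distribution medians, and the hypergeometric overlap of the detected
#' hyper set with the truly elevated strains) plus a run manifest
#' recording the seed, resolved parameters, and file digests.
#'
#' @param config_file YAML configuration (see
#'   \code{\link{readScreenConfig}}); must contain a \code{sim} block.
#' @param seed integer seed for every source of randomness.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the frequency table, the summary, and
#'   the manifest.
#' @export
runPipeline <- function(config_file, seed, out_dir) {
    cfg <- readScreenConfig(config_file)
    if (is.null(cfg$sim))
        stop("configuration error: pipeline needs a 'sim' block")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    sim <- simulateScreen(cfg$sim, seed = seed)
    colony_path <- file.path(out_dir, "colonies.tsv")
    writeTsv(sim$colonies, colony_path)

    scored <- scoreColonies(readColonyTable(colony_path), cfg$screen)
    freq <- classifyFrequencies(strainFrequencies(scored, cfg$screen),
                                cfg$screen)
    freq_path <- file.path(out_dir, "frequencies.tsv")
    writeTsv(freq, freq_path)

    callable <- freq[!freq$excluded & !is.na(freq$class), , drop = FALSE]
    hyper <- callable$strain_id[callable$class == "hyper"]
    universe <- cfg$integrate$universe
    if (is.null(universe)) universe <- length(unique(freq$strain_id))
    truly_up <- sim$truth$strain_id[sim$truth$rate >
                                    stats::median(sim$truth$rate)]
    summary <- list(
        n_strains = nrow(freq),
        n_excluded = sum(freq$excluded),
        class_counts = as.list(table(callable$class)),
        flagged_group = length(cfg$screen@exclusion_strains),
        overlap = if (length(hyper) && length(truly_up)) {
            ov <- hypergeomOverlap(hyper, truly_up, universe,
                                   "detected-hyper", "true-elevated")
            list(k = ov@k, K = ov@K, n = ov@n, N = ov@N,
                 p_value = ov@p_value)
        } else NULL)
    if (length(cfg$screen@exclusion_strains)) {
        ds <- distributionSummary(freq, cfg$screen@exclusion_strains)
        summary$flagged_median <- ds$group$median
        summary$rest_median <- ds$rest$median
    }
    summary_path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    manifest <- .manifest("run", yaml::read_yaml(config_file), seed,
                          config_file,
                          c(colony_path, freq_path, summary_path))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(frequencies = freq, summary = summary,
                   manifest = manifest))
}
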