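.extdata <- function(file) {
    path <- system.file("extdata", file, package = "RecScreen")
    if (!nzchar(path))
        stop("packaged fixture not found: ", file)
    path
}

#' Normalise a character vector into a gene set
#'
#' Uppercases, deduplicates, and drops wild-type/control labels.
#'
#' @param genes character vector of systematic or standard yeast gene
#'   names.
#' @return character vector, unique and uppercased.
#' @export
geneSet <- function(genes) {
    g <- unique(toupper(trimws(as.character(genes))))
    setdiff(g[nzchar(g)], c("WT", "WILD-TYPE", "WILDTYPE"))
}

.readFixture <- function(path, need) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("malformed fixture ", basename(path), ": missing column(s) ",
             paste(miss, collapse = ", "))
    bad <- which(!nzchar(trimws(tab[[need[1L]]])))
    if (length(bad))
        stop("malformed fixture ", basename(path), ": empty gene name at row ",
             bad[1L])
    tab
}

#' Hit tables shipped with the package
#'
#' Transcriptions of the published screen hit tables: the
#' fluctuation-validated hyper-recombination genes from the patch assay
#' (with mean rate, standard deviation, and one-sided t-test p-value),
#' the pinning-assay hyper- and hypo-recombination gene lists (with
#' recombinant-colony percentages), and the validated gene table with
#' human orthologs.
#'
#' @return \code{patchRateTable}: data.frame(gene, mean_rate, sd,
#'   p_value) including the wild-type reference row;
#'   \code{patchHits}, \code{pinningHyperHits}, \code{pinningHypoHits},
#'   \code{validatedGenes}: character vectors of gene names;
#'   \code{orthologTable}: data.frame(gene, description,
#'   human_orthologs).
#' @examples
#' length(patchHits())
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
patchRateTable <- function() {
    .readFixture(.extdata("table1_patch_rates.tsv"),
                 c("gene", "mean_rate", "sd", "p_value"))
}

#' @rdname fixtures
#' @export
patchHits <- function() {
    geneSet(patchRateTable()$gene)
}

#' @rdname fixtures
#' @export
pinningHyperHits <- function() {
    geneSet(.readFixture(.extdata("table1_pinning_hyper.tsv"),
                         c("gene", "recombinant_pct"))$gene)
}

#' @rdname fixtures
#' @export
pinningHypoHits <- function() {
    geneSet(.readFixture(.extdata("table2_pinning_hypo.tsv"),
                         c("gene", "recombinant_pct"))$gene)
}

#' @rdname fixtures
#' @export
orthologTable <- function() {
    .readFixture(.extdata("table3_validated.tsv"),
                 c("gene", "description", "human_orthologs"))
}

#' @rdname fixtures
#' @export
validatedGenes <- function() {
    geneSet(orthologTable()$gene)
}

#' Assemble the screen hit sets
#'
#' Loads (or accepts) the patch-validated, pinning hyper-recombination
#' and pinning hypo-recombination gene sets, and forms the validated
#' union: the patch-validated genes plus the pinning hits that were
#' additionally validated by fluctuation analysis.
#'
#' @param patch,pinning_hyper,pinning_hypo character vectors of gene
#'   names; defaults are the packaged fixtures.
#' @param extra_validated pinning genes validated by follow-up
#'   fluctuation tests (default \code{c("CSM1", "NUP170")}).
#' @return list with elements \code{patch}, \code{pinning_hyper},
#'   \code{pinning_hypo}, \code{validated}.
#' @examples
#' sets <- assembleHits()
#' lengths(sets)
#' @export
assembleHits <- function(patch = patchHits(),
                         pinning_hyper = pinningHyperHits(),
                         pinning_hypo = pinningHypoHits(),
                         extra_validated = c("CSM1", "NUP170")) {
    patch <- geneSet(patch)
    hyper <- geneSet(pinning_hyper)
    hypo <- geneSet(pinning_hypo)
    list(patch = patch, pinning_hyper = hyper, pinning_hypo = hypo,
         validated = sort(union(patch, geneSet(extra_validated))))
}

#' Hypergeometric gene-set overlap
#'
#' Tests whether two gene sets share more members than expected when
#' both are drawn from a universe of \code{universe} genes: with
#' \code{k} shared genes, \eqn{P(X \ge k)} under the hypergeometric
#' distribution with parameters (|A|, universe - |A|, |B|).
#'
#' @param setA,setB character vectors of gene names.
#' @param universe universe size; must be at least the union size.
#' @param nameA,nameB labels used in display.
#' @return an \linkS4class{OverlapResult}.
#' @examples
#' hypergeomOverlap(letters[1:5], letters[3:8], universe = 26)
#' @export
hypergeomOverlap <- function(setA, setB, universe,
                             nameA = "setA", nameB = "setB") {
    A <- geneSet(setA)
    B <- geneSet(setB)
    K <- length(A)
    n <- length(B)
    k <- length(intersect(A, B))
    N <- as.integer(universe)
    if (N < length(union(A, B)))
        stop("universe (", N, ") smaller than the union (",
             length(union(A, B)), ")")
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    new("OverlapResult", k = as.integer(k), K = as.integer(K),
        n = as.integer(n), N = N, p_value = p,
        setA_name = nameA, setB_name = nameB)
}

#' Count genes with at least one human ortholog
#'
#' @param table data.frame with a \code{human_orthologs} column holding
#'   comma-separated ortholog lists (possibly empty); default is the
#'   packaged validated-gene table.
#' @return integer count of rows with a non-empty ortholog list.
#' @examples
#' orthologSummary()
#' @export
orthologSummary <- function(table = orthologTable()) {
    if (!"human_orthologs" %in% colnames(table))
        stop("need a 'human_orthologs' column")
    sum(nzchar(trimws(table$human_orthologs)))
}

#' Frequency distribution of a flagged group versus the rest
#'
#' Summarises recombinant frequencies for a flagged strain group (e.g.
#' deletion strains carrying the secondary msh3 mutation) against all
#' non-flagged strains: medians and fixed-width histograms on [0,1].
#'
#' @param frequencies data.frame from \code{\link{strainFrequencies}}
#'   (or any table with \code{strain_id} and \code{frequency} columns).
#' @param group_strains character vector of flagged strain identifiers.
#' @param bin_width histogram bin width (default 0.05).
#' @return list with elements \code{group} and \code{rest}, each a list
#'   of \code{n}, \code{median}, and \code{histogram} (counts per bin);
#'   plus \code{breaks}.
#' @export
distributionSummary <- function(frequencies, group_strains,
                                bin_width = 0.05) {
    stopifnot(all(c("strain_id", "frequency") %in% colnames(frequencies)))
    keep <- !is.na(frequencies$frequency)
    freq <- frequencies[keep, , drop = FALSE]
    if (nrow(freq) == 0L)
        stop("no usable frequencies")
    flagged <- toupper(freq$strain_id) %in% toupper(group_strains)
    breaks <- seq(0, 1, by = bin_width)
    summarise <- function(x)
        list(n = length(x),
             median = if (length(x)) stats::median(x) else NA_real_,
             histogram = if (length(x))
                 graphics::hist(x, breaks = breaks, plot = FALSE)$counts
             else integer(length(breaks) - 1L))
    list(group = summarise(freq$frequency[flagged]),
         rest = summarise(freq$frequency[!flagged]),
         breaks = breaks)
}
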