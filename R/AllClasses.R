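#' @import methods
NULL

.EPS <- 1e-12

#' Luria-Delbruck growth model
#'
#' Parameters of clonal expansion of a culture (or pinned colony) in which
#' recombination events arise at a constant per-cell rate during growth.
#' The expected number of events per clone is \code{m}; when the per-cell
#' rate \code{mu} is supplied instead, \code{m = mu * (nf - n0)}.
#'
#' @slot m expected number of recombination events per clone (>= 0).
#' @slot mu per-cell per-division recombination rate; \code{NA} when the
#'   model is parameterised by \code{m} directly.
#' @slot n0 initial cell count (>= 1).
#' @slot nf final cell count (> \code{n0}).
#'
#' @exportClass LDModel
setClass("LDModel",
    representation(m = "numeric", mu = "numeric", n0 = "numeric",
                   nf = "numeric"),
    prototype(m = 1, mu = NA_real_, n0 = 1, nf = 1e7))

setValidity("LDModel", function(object) {
    msg <- character()
    if (length(object@m) != 1L || is.na(object@m) || object@m < 0)
        msg <- c(msg, "'m' must be a single number >= 0")
    if (object@n0 < 1)
        msg <- c(msg, "'n0' must be >= 1")
    if (object@nf <= object@n0)
        msg <- c(msg, "'nf' must exceed 'n0'")
    if (!is.na(object@mu)) {
        expect <- object@mu * (object@nf - object@n0)
        if (abs(object@m - expect) / max(object@m, .EPS) > 1e-9)
            msg <- c(msg, "'m' inconsistent with mu * (nf - n0)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Luria-Delbruck model
#'
#' @param m expected events per clone; omit to derive from \code{mu}.
#' @param mu per-cell recombination rate (events/cell/division).
#' @param n0 initial cell count.
#' @param nf final cell count.
#' @return an \linkS4class{LDModel}.
#' @examples
#' LDModel(mu = 1.14e-5, nf = 1e7)
#' @export
LDModel <- function(m = NULL, mu = NULL, n0 = 1, nf = 1e7) {
    if (is.null(m) && is.null(mu))
        stop("supply 'm' or 'mu'")
    if (is.null(m))
        m <- mu * (nf - n0)
    new("LDModel", m = as.numeric(m),
        mu = if (is.null(mu)) NA_real_ else as.numeric(mu),
        n0 = as.numeric(n0), nf = as.numeric(nf))
}

#' @describeIn LDModel expected number of recombination events per clone.
#' @param object,x an \code{LDModel}.
#' @export
setGeneric("expectedEvents", function(object) standardGeneric("expectedEvents"))

#' @rdname LDModel
#' @export
setMethod("expectedEvents", "LDModel", function(object) object@m)

#' @describeIn LDModel final cell count of the clone.
#' @export
setGeneric("finalCells", function(object) standardGeneric("finalCells"))

#' @rdname LDModel
#' @export
setMethod("finalCells", "LDModel", function(object) object@nf)

setMethod("show", "LDModel", function(object) {
    cat("LDModel: m =", format(object@m),
        if (!is.na(object@mu)) paste0("(mu = ", format(object@mu), ")"),
        " n0 =", format(object@n0), " nf =", format(object@nf), "\n")
})

#' Fluctuation-test plating design
#'
#' Volumes and fold-dilutions used to plate each culture on selective and
#' permissive medium, plus the cell-count denominator used to normalise
#' recombinant counts (default: recombinants per 1e7 viable cells).
#' Defaults follow the standard design: a 4 ml culture, 200 ul of a
#' 1e2-fold dilution on selective plates and 100 ul of a 1e5-fold dilution
#' on permissive plates.
#'
#' @slot culture_volume_ml culture volume in ml.
#' @slot sel_dilution fold-dilution plated on selective medium.
#' @slot sel_volume_ml volume plated on selective medium (ml).
#' @slot perm_dilution fold-dilution plated on permissive medium.
#' @slot perm_volume_ml volume plated on permissive medium (ml).
#' @slot norm_cells normalisation denominator in cells.
#'
#' @exportClass PlatingDesign
setClass("PlatingDesign",
    representation(culture_volume_ml = "numeric", sel_dilution = "numeric",
                   sel_volume_ml = "numeric", perm_dilution = "numeric",
                   perm_volume_ml = "numeric", norm_cells = "numeric"),
    prototype(culture_volume_ml = 4, sel_dilution = 1e2, sel_volume_ml = 0.2,
              perm_dilution = 1e5, perm_volume_ml = 0.1, norm_cells = 1e7))

setValidity("PlatingDesign", function(object) {
    msg <- character()
    vols <- c(object@culture_volume_ml, object@sel_volume_ml,
              object@perm_volume_ml)
    if (any(vols <= 0)) msg <- c(msg, "all volumes must be > 0")
    if (object@sel_dilution < 1 || object@perm_dilution < 1)
        msg <- c(msg, "dilutions must be >= 1")
    if (object@norm_cells <= 0) msg <- c(msg, "'norm_cells' must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct a plating design
#'
#' @param culture_volume_ml,sel_dilution,sel_volume_ml,perm_dilution,perm_volume_ml,norm_cells
#'   see \linkS4class{PlatingDesign}.
#' @return a \linkS4class{PlatingDesign}.
#' @export
PlatingDesign <- function(culture_volume_ml = 4, sel_dilution = 1e2,
                          sel_volume_ml = 0.2, perm_dilution = 1e5,
                          perm_volume_ml = 0.1, norm_cells = 1e7) {
    new("PlatingDesign", culture_volume_ml = culture_volume_ml,
        sel_dilution = sel_dilution, sel_volume_ml = sel_volume_ml,
        perm_dilution = perm_dilution, perm_volume_ml = perm_volume_ml,
        norm_cells = norm_cells)
}

setMethod("show", "PlatingDesign", function(object) {
    cat("PlatingDesign:", format(object@culture_volume_ml), "ml culture;",
        "selective", format(object@sel_volume_ml), "ml of 1/",
        format(object@sel_dilution), "; permissive",
        format(object@perm_volume_ml), "ml of 1/",
        format(object@perm_dilution), "; per",
        format(object@norm_cells), "cells\n")
})

#' A fluctuation test
#'
#' Per-culture colony counts on selective and permissive plates for one
#' strain, together with the plating design.
#'
#' @slot counts data.frame with columns \code{sel_count} and
#'   \code{perm_count}, one row per independent culture.
#' @slot design a \linkS4class{PlatingDesign}.
#'
#' @exportClass FluctuationTest
setClass("FluctuationTest",
    representation(counts = "data.frame", design = "PlatingDesign"))

setValidity("FluctuationTest", function(object) {
    msg <- character()
    cn <- colnames(object@counts)
    if (!all(c("sel_count", "perm_count") %in% cn))
        msg <- c(msg, "counts need columns 'sel_count' and 'perm_count'")
    else {
        if (nrow(object@counts) < 1)
            msg <- c(msg, "at least one culture is required")
        if (any(object@counts$sel_count < 0, na.rm = TRUE) ||
            any(object@counts$perm_count < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a fluctuation test
#'
#' @param sel_count integer vector of selective-plate colony counts.
#' @param perm_count integer vector of permissive-plate colony counts.
#' @param design a \linkS4class{PlatingDesign}.
#' @return a \linkS4class{FluctuationTest}.
#' @examples
#' FluctuationTest(c(3, 0, 12, 1, 5), c(110, 95, 130, 102, 99))
#' @export
FluctuationTest <- function(sel_count, perm_count, design = PlatingDesign()) {
    new("FluctuationTest",
        counts = data.frame(sel_count = sel_count, perm_count = perm_count),
        design = design)
}

#' @describeIn FluctuationTest number of cultures.
#' @param object a \code{FluctuationTest}.
#' @export
setGeneric("nCultures", function(object) standardGeneric("nCultures"))

#' @rdname FluctuationTest
#' @export
setMethod("nCultures", "FluctuationTest", function(object)
    nrow(object@counts))

setMethod("show", "FluctuationTest", function(object) {
    cat("FluctuationTest with", nrow(object@counts), "cultures\n")
    print(utils::head(object@counts, 5))
})

#' Screen scoring configuration
#'
#' Every filter threshold and exclusion list of the replica-pinning
#' scoring pipeline.
#'
#' @slot circularity_min colonies with circularity at or below this value
#'   are discarded as artifacts (strict inequality; default 0.8).
#' @slot perm_area_frac a permissive colony is scored when its area
#'   strictly exceeds this fraction of the plate mean area (default 0.5).
#' @slot sel_area_frac a selective colony is scored when its area strictly
#'   exceeds this fraction of its strain's mean scored permissive area
#'   (default 0.10).
#' @slot min_colonies strains with fewer scored permissive colonies than
#'   this are excluded (default 10).
#' @slot exclusion_strains strain identifiers excluded from hit calling
#'   (e.g. deletion strains carrying a secondary msh3 mutation).
#' @slot hyper_cutoff recombinant frequency at or above which a strain is
#'   classified hyper-recombinant (default 0.87).
#' @slot hypo_cutoff recombinant frequency at or below which a strain is
#'   classified recombination-deficient (default 0.33).
#'
#' @exportClass ScreenConfig
setClass("ScreenConfig",
    representation(circularity_min = "numeric", perm_area_frac = "numeric",
                   sel_area_frac = "numeric", min_colonies = "numeric",
                   exclusion_strains = "character", hyper_cutoff = "numeric",
                   hypo_cutoff = "numeric"),
    prototype(circularity_min = 0.8, perm_area_frac = 0.5,
              sel_area_frac = 0.10, min_colonies = 10,
              exclusion_strains = character(), hyper_cutoff = 0.87,
              hypo_cutoff = 0.33))

setValidity("ScreenConfig", function(object) {
    msg <- character()
    if (object@circularity_min < 0 || object@circularity_min > 1)
        msg <- c(msg, "'circularity_min' must be in [0,1]")
    if (object@perm_area_frac <= 0 || object@perm_area_frac > 1)
        msg <- c(msg, "'perm_area_frac' must be in (0,1]")
    if (object@sel_area_frac <= 0 || object@sel_area_frac > 1)
        msg <- c(msg, "'sel_area_frac' must be in (0,1]")
    if (object@min_colonies < 1)
        msg <- c(msg, "'min_colonies' must be >= 1")
    if (!(object@hypo_cutoff >= 0 && object@hypo_cutoff < object@hyper_cutoff &&
          object@hyper_cutoff <= 1))
        msg <- c(msg, "need 0 <= hypo_cutoff < hyper_cutoff <= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a screen scoring configuration
#'
#' @param circularity_min,perm_area_frac,sel_area_frac,min_colonies,exclusion_strains,hyper_cutoff,hypo_cutoff
#'   see \linkS4class{ScreenConfig}.
#' @return a \linkS4class{ScreenConfig}.
#' @export
ScreenConfig <- function(circularity_min = 0.8, perm_area_frac = 0.5,
                         sel_area_frac = 0.10, min_colonies = 10,
                         exclusion_strains = character(),
                         hyper_cutoff = 0.87, hypo_cutoff = 0.33) {
    new("ScreenConfig", circularity_min = circularity_min,
        perm_area_frac = perm_area_frac, sel_area_frac = sel_area_frac,
        min_colonies = min_colonies,
        exclusion_strains = toupper(as.character(exclusion_strains)),
        hyper_cutoff = hyper_cutoff, hypo_cutoff = hypo_cutoff)
}

setMethod("show", "ScreenConfig", function(object) {
    cat("ScreenConfig:\n",
        " circularity >", object@circularity_min, "\n",
        " permissive area >", object@perm_area_frac, "x plate mean\n",
        " selective area >", object@sel_area_frac, "x strain mean\n",
        " min colonies:", object@min_colonies, "\n",
        " excluded strains:", length(object@exclusion_strains), "\n",
        " cutoffs: hyper >=", object@hyper_cutoff, ", hypo <=",
        object@hypo_cutoff, "\n")
})

#' Replica-pinning screen simulator configuration
#'
#' Forward-model parameters of the synthetic screen: per-strain per-cell
#' recombination rates, colony growth scale, pin-transfer subsampling, a
#' background positive probability, array geometry, and the measurement
#' models for colony area and circularity.
#'
#' @slot strain_rates named numeric vector of per-cell recombination rates.
#' @slot cells_per_colony cells in a grown colony (default 1e7).
#' @slot transfer_fraction fraction of colony cells moved per pinning
#'   (default 5e-4, calibrated so a wild-type rate of 1.14e-5 yields a
#'   recombinant frequency in the 0.46--0.56 band over the background).
#' @slot background_positive_prob probability that a colony with no
#'   transferred recombinant still yields a scored selective colony
#'   (default 0.21, the frequency observed for a recombination-deficient
#'   strain).
#' @slot replicates pinned replicates per strain (default 48).
#' @slot plate_nrow,plate_ncol array geometry (default 32 x 48 = 1536
#'   density; strains are placed as 2x2 quadruplicate blocks).
#' @slot pin_fail_prob probability a pinning leaves no colony (default 0.02).
#' @slot artifact_prob probability a colony is a low-circularity artifact
#'   (default 0.03).
#' @slot area_mean,area_sd permissive scored-colony area model (pixels).
#' @slot sel_area_mean,sel_area_sd selective-positive colony area model.
#' @slot fail_area_mean,fail_area_sd area model for absent/failed growth.
#' @slot circ_mean,circ_sd circularity model for true colonies.
#' @slot artifact_circ_mean,artifact_circ_sd circularity model for artifacts.
#'
#' @exportClass SimConfig
setClass("SimConfig",
    representation(strain_rates = "numeric", cells_per_colony = "numeric",
                   transfer_fraction = "numeric",
                   background_positive_prob = "numeric",
                   replicates = "numeric", plate_nrow = "numeric",
                   plate_ncol = "numeric", pin_fail_prob = "numeric",
                   artifact_prob = "numeric", area_mean = "numeric",
                   area_sd = "numeric", sel_area_mean = "numeric",
                   sel_area_sd = "numeric", fail_area_mean = "numeric",
                   fail_area_sd = "numeric", circ_mean = "numeric",
                   circ_sd = "numeric", artifact_circ_mean = "numeric",
                   artifact_circ_sd = "numeric"),
    prototype(cells_per_colony = 1e7, transfer_fraction = 5e-4,
              background_positive_prob = 0.21, replicates = 48,
              plate_nrow = 32, plate_ncol = 48, pin_fail_prob = 0.02,
              artifact_prob = 0.03, area_mean = 500, area_sd = 75,
              sel_area_mean = 450, sel_area_sd = 80, fail_area_mean = 15,
              fail_area_sd = 8, circ_mean = 0.95, circ_sd = 0.03,
              artifact_circ_mean = 0.5, artifact_circ_sd = 0.15))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@strain_rates) < 1 ||
        is.null(names(object@strain_rates)) ||
        any(!nzchar(names(object@strain_rates))))
        msg <- c(msg, "'strain_rates' must be a named numeric vector")
    if (any(object@strain_rates < 0))
        msg <- c(msg, "rates must be >= 0")
    if (!(object@transfer_fraction > 0 && object@transfer_fraction <= 1))
        msg <- c(msg, "'transfer_fraction' must be in (0,1]")
    probs <- c(object@background_positive_prob, object@pin_fail_prob,
               object@artifact_prob)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "probabilities must be in [0,1]")
    if (object@replicates < 1) msg <- c(msg, "'replicates' must be >= 1")
    if (object@replicates %% 4 != 0)
        msg <- c(msg, "'replicates' must be a multiple of 4 (quadruplicates)")
    if (length(msg)) msg else TRUE
})

#' Construct a simulator configuration
#'
#' @param strain_rates named numeric vector of per-cell recombination rates.
#' @param ... overrides for any other \linkS4class{SimConfig} slot.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' SimConfig(c(WT = 1.14e-5, elg1 = 5.1e-5))
#' @export
SimConfig <- function(strain_rates, ...) {
    new("SimConfig", strain_rates = strain_rates, ...)
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", length(object@strain_rates), "strain(s),",
        object@replicates, "replicates each;",
        format(object@cells_per_colony), "cells/colony, transfer",
        format(object@transfer_fraction), ", background",
        format(object@background_positive_prob), "\n")
})

#' Gene-set overlap under a hypergeometric null
#'
#' Intersection statistics of two gene sets drawn from a finite universe:
#' \code{k} genes shared between a set of size \code{K} and one of size
#' \code{n}, out of \code{N} genes, with the upper-tail probability
#' \eqn{P(X \ge k)}.
#'
#' @slot k intersection size.
#' @slot K size of the first set.
#' @slot n size of the second set.
#' @slot N universe size.
#' @slot p_value upper-tail hypergeometric probability.
#' @slot setA_name,setB_name labels for reporting.
#'
#' @exportClass OverlapResult
setClass("OverlapResult",
    representation(k = "integer", K = "integer", n = "integer",
                   N = "integer", p_value = "numeric",
                   setA_name = "character", setB_name = "character"))

setValidity("OverlapResult", function(object) {
    msg <- character()
    if (object@k > min(object@K, object@n))
        msg <- c(msg, "'k' cannot exceed min(K, n)")
    if (object@N < object@K + object@n - object@k)
        msg <- c(msg, "universe smaller than the union")
    if (!(object@p_value > 0 && object@p_value <= 1))
        msg <- c(msg, "'p_value' must lie in (0,1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn OverlapResult intersection size.
#' @param object an \code{OverlapResult}.
#' @export
setGeneric("overlapSize", function(object) standardGeneric("overlapSize"))

#' @rdname OverlapResult
#' @export
setMethod("overlapSize", "OverlapResult", function(object) object@k)

#' @describeIn OverlapResult upper-tail hypergeometric p-value.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname OverlapResult
#' @export
setMethod("pValue", "OverlapResult", function(object) object@p_value)

setMethod("show", "OverlapResult", function(object) {
    cat("OverlapResult:", object@setA_name, "(", object@K, ") x",
        object@setB_name, "(", object@n, ") in universe", object@N,
        "\n  intersection:", object@k,
        "  P(X >=", paste0(object@k, ")"), "=",
        format(object@p_value, digits = 3), "\n")
})
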