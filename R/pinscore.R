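.COLONY_COLS <- c("plate_id", "row", "col", "strain_id", "medium",
                  "area", "circularity")

.checkColonies <- function(records) {
    miss <- setdiff(.COLONY_COLS, colnames(records))
    if (length(miss))
        stop("colony table is missing column(s): ",
             paste(miss, collapse = ", "))
    bad <- which(records$circularity < 0 | records$circularity > 1)
    if (length(bad))
        stop("circularity outside [0,1] at row(s) ",
             paste(utils::head(bad, 5), collapse = ", "))
    if (any(records$area < 0))
        stop("negative colony areas")
    if (!all(records$medium %in% c("permissive", "selective")))
        stop("'medium' must be 'permissive' or 'selective'")
    invisible(records)
}

#' Remove colony artifacts by circularity
#'
#' Keeps records whose circularity strictly exceeds the configured
#' minimum (artifacts on plate scans are irregular; the default retains
#' circularity > 0.8). Row order is preserved and per-plate removal
#' counts are attached as the \code{"removed"} attribute.
#'
#' @param records colony data.frame with columns \code{plate_id},
#'   \code{row}, \code{col}, \code{strain_id}, \code{medium},
#'   \code{area}, \code{circularity}.
#' @param config a \linkS4class{ScreenConfig}.
#' @return the retained records.
#' @export
filterCircularity <- function(records, config = ScreenConfig()) {
    validObject(config)
    .checkColonies(records)
    keep <- records$circularity > config@circularity_min
    removed <- table(factor(records$plate_id[!keep],
                            levels = unique(records$plate_id)))
    out <- records[keep, , drop = FALSE]
    attr(out, "removed") <- removed
    out
}

#' Score permissive-plate colonies by relative area
#'
#' A permissive colony is scored (counted as having grown) when its area
#' strictly exceeds \code{perm_area_frac} times the mean area of the
#' circularity-passing permissive colonies on the same plate. Plates with
#' no passing permissive colonies are skipped with a warning.
#'
#' @param records circularity-filtered colony data.frame.
#' @param config a \linkS4class{ScreenConfig}.
#' @return the permissive records with a logical \code{scored} column.
#' @export
scorePermissive <- function(records, config = ScreenConfig()) {
    validObject(config)
    perm <- records[records$medium == "permissive", , drop = FALSE]
    if (nrow(perm) == 0L) {
        warning("no permissive colonies to score")
        perm$scored <- logical(0)
        return(perm)
    }
    plate_mean <- tapply(perm$area, perm$plate_id, mean)
    perm$scored <- perm$area > config@perm_area_frac *
        as.vector(plate_mean[as.character(perm$plate_id)])
    perm
}

#' Score selective-plate colonies against their strain's permissive mean
#'
#' A selective colony at grid position (plate, row, col) is scored as a
#' recombinant when (i) its position-paired permissive colony was scored
#' and (ii) its area strictly exceeds \code{sel_area_frac} times the mean
#' area of that strain's scored permissive colonies. Selective colonies
#' with no scored permissive partner are never scored, which guarantees
#' recombinant frequencies of at most 1.
#'
#' @param records circularity-filtered colony data.frame (both media).
#' @param permissive_scores output of \code{\link{scorePermissive}}.
#' @param config a \linkS4class{ScreenConfig}.
#' @return the selective records with a logical \code{scored} column.
#' @export
scoreSelective <- function(records, permissive_scores,
                           config = ScreenConfig()) {
    validObject(config)
    sel <- records[records$medium == "selective", , drop = FALSE]
    if (nrow(sel) == 0L) {
        sel$scored <- logical(0)
        return(sel)
    }
    perm <- permissive_scores
    scored_perm <- perm[perm$scored, , drop = FALSE]
    strain_mean <- tapply(scored_perm$area, scored_perm$strain_id, mean)
    key <- function(d) paste(d$plate_id, d$row, d$col, sep = "\r")
    paired <- key(sel) %in% key(scored_perm)
    mu <- as.vector(strain_mean[as.character(sel$strain_id)])
    sel$scored <- paired & !is.na(mu) & sel$area > config@sel_area_frac * mu
    sel
}

#' Run the full colony-scoring pipeline
#'
#' Applies the circularity filter, permissive scoring and selective
#' scoring in order.
#'
#' @param records raw colony data.frame (both media).
#' @param config a \linkS4class{ScreenConfig}.
#' @return list with elements \code{permissive} and \code{selective},
#'   each a data.frame with a \code{scored} column.
#' @export
scoreColonies <- function(records, config = ScreenConfig()) {
    filt <- filterCircularity(records, config)
    perm <- scorePermissive(filt, config)
    sel <- scoreSelective(filt, perm, config)
    list(permissive = perm, selective = sel)
}

#' Per-strain recombinant frequencies with exclusion rules
#'
#' For each strain, \code{n_total} is the number of scored permissive
#' colonies, \code{n_recombinant} the number of scored selective
#' colonies, and the recombinant frequency their ratio. Strains with
#' fewer than \code{min_colonies} scored permissive colonies are
#' excluded (reason \code{"too-few-colonies"}, frequency \code{NA});
#' strains on the exclusion list are excluded from hit calling (reason
#' \code{"msh3-list"}) but keep their frequency for distribution
#' analysis.
#'
#' @param scored output of \code{\link{scoreColonies}}.
#' @param config a \linkS4class{ScreenConfig}.
#' @return data.frame with columns \code{strain_id}, \code{n_total},
#'   \code{n_recombinant}, \code{frequency}, \code{excluded},
#'   \code{exclusion_reason}.
#' @export
strainFrequencies <- function(scored, config = ScreenConfig()) {
    validObject(config)
    perm <- scored$permissive
    sel <- scored$selective
    strains <- sort(unique(as.character(perm$strain_id)))
    n_total <- vapply(strains, function(s)
        sum(perm$scored & perm$strain_id == s), numeric(1))
    n_rec <- vapply(strains, function(s)
        sum(sel$scored & sel$strain_id == s), numeric(1))
    too_few <- n_total < config@min_colonies
    on_list <- toupper(strains) %in% config@exclusion_strains
    freq <- ifelse(n_total > 0, n_rec / n_total, NA_real_)
    freq[too_few] <- NA_real_
    out <- data.frame(strain_id = strains, n_total = n_total,
                      n_recombinant = n_rec, frequency = freq,
                      excluded = too_few | on_list,
                      exclusion_reason = ifelse(too_few, "too-few-colonies",
                                         ifelse(on_list, "msh3-list",
                                                "none")),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Classify strains by recombinant-frequency cutoffs
#'
#' Non-excluded strains at or above \code{hyper_cutoff} are
#' hyper-recombinant, at or below \code{hypo_cutoff} recombination
#' deficient, otherwise unclassified. The cutoffs (defaults 0.87 and
#' 0.33) are configuration determined externally, e.g. by
#' interaction-knowledge analysis of the ranked hit list.
#'
#' @param frequencies output of \code{\link{strainFrequencies}}.
#' @param config a \linkS4class{ScreenConfig}.
#' @return the input with a \code{class} column (\code{"hyper"},
#'   \code{"hypo"}, \code{"unclassified"}; \code{NA} for excluded
#'   strains).
#' @export
classifyFrequencies <- function(frequencies, config = ScreenConfig()) {
    validObject(config)
    cls <- ifelse(frequencies$frequency >= config@hyper_cutoff, "hyper",
           ifelse(frequencies$frequency <= config@hypo_cutoff, "hypo",
                  "unclassified"))
    cls[frequencies$excluded | is.na(frequencies$frequency)] <- NA_character_
    frequencies$class <- cls
    frequencies
}
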