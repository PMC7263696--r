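## Positivity of one pinned colony, drawn from the current RNG stream.
## r recombinant cells accumulate during colony growth (LD forward model);
## pinning draws round(tf * N) of the N cells without replacement, so the
## transferred recombinants are hypergeometric (binomial is an excellent
## approximation at screen-scale transfer fractions but breaks the
## full-transfer identity); any transferred recombinant gives selective
## growth, otherwise the background channel fires.
.colonyPositive <- function(m, config) {
    N <- config@cells_per_colony
    r <- .cloneR(m, N)
    transferred <- stats::rhyper(1L, r, N - r,
                                 round(config@transfer_fraction * N))
    if (transferred >= 1L)
        TRUE
    else
        stats::runif(1L) < config@background_positive_prob
}

#' Simulate selective growth of one pinned colony
#'
#' Forward model of replica pinning to selective medium: recombinants
#' accumulate in the growing colony under the Luria-Delbruck model with
#' \code{m = rate * cells_per_colony}; the pin transfers a binomial
#' subsample; the colony is positive when at least one recombinant cell
#' is transferred, and otherwise with the background positive
#' probability (which models residual growth and post-pinning
#' recombination).
#'
#' @param rate per-cell recombination rate.
#' @param config a \linkS4class{SimConfig} (its \code{strain_rates} are
#'   ignored here).
#' @param seed integer seed.
#' @return logical: did the pinned colony grow on selective medium?
#' @examples
#' cfg <- SimConfig(c(WT = 1.14e-5))
#' simulateColonyPositive(1.14e-5, cfg, seed = 1)
#' @export
simulateColonyPositive <- function(rate, config, seed) {
    stopifnot(is(config, "SimConfig"), rate >= 0)
    validObject(config)
    set.seed(as.integer(seed))
    .colonyPositive(rate * config@cells_per_colony, config)
}

.truncNorm <- function(n, mean, sd, lo = 0, hi = Inf) {
    pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Simulate a full replica-pinning screen
#'
#' Generates paired permissive/selective colony tables in the exact
#' input format of the scoring pipeline. Strains are placed as 2x2
#' quadruplicate blocks in a high-density array (default 32 x 48 = 1536
#' positions) and replicated across \code{replicates / 4} plates. Each
#' position can suffer a pinning failure (near-zero area) or a
#' low-circularity artifact; otherwise the permissive colony's area and
#' circularity are drawn from the configured measurement models, the
#' colony's selective outcome is simulated with
#' \code{\link{simulateColonyPositive}}'s forward model, and the
#' selective area is large for positives and near zero otherwise.
#' Fully reproducible from the seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed integer seed.
#' @return list with \code{colonies} (data.frame with columns
#'   \code{plate_id}, \code{row}, \code{col}, \code{strain_id},
#'   \code{medium}, \code{area}, \code{circularity}) and \code{truth}
#'   (data.frame of strain, rate, and simulated positive count).
#' @examples
#' out <- simulateScreen(SimConfig(c(WT = 1.14e-5, rad54 = 0)), seed = 1)
#' head(out$colonies)
#' @export
simulateScreen <- function(config, seed) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    strains <- names(config@strain_rates)
    blocks_per_plate <- (config@plate_nrow %/% 2L) * (config@plate_ncol %/% 2L)
    if (length(strains) > blocks_per_plate)
        stop("configuration error: ", length(strains),
             " strains exceed the ", blocks_per_plate,
             " quadruplicate blocks per plate")
    n_plates <- config@replicates %/% 4L
    set.seed(as.integer(seed))

    bc_per_row <- config@plate_ncol %/% 2L
    idx <- seq_along(strains) - 1L
    block_r <- idx %/% bc_per_row
    block_c <- idx %% bc_per_row
    # quadruplicate corner offsets within the 2x2 block
    off <- cbind(r = c(0L, 0L, 1L, 1L), c = c(0L, 1L, 0L, 1L))

    grid <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
        data.frame(plate_id = sprintf("plate%02d", p),
                   row = rep(2L * block_r + 1L, each = 4L) + off[, "r"],
                   col = rep(2L * block_c + 1L, each = 4L) + off[, "c"],
                   strain_id = rep(strains, each = 4L),
                   stringsAsFactors = FALSE)
    }))
    n <- nrow(grid)
    m <- config@strain_rates[grid$strain_id] * config@cells_per_colony

    failed <- stats::runif(n) < config@pin_fail_prob
    artifact <- !failed & stats::runif(n) < config@artifact_prob

    positive <- logical(n)
    for (i in seq_len(n)) {
        # draw in fixed order so output is byte-identical given the seed;
        # failed positions transfer nothing and see only the background
        positive[i] <- if (failed[i])
            stats::runif(1L) < config@background_positive_prob
        else
            .colonyPositive(m[i], config)
    }

    perm_area <- .truncNorm(n, config@area_mean, config@area_sd, lo = 1)
    perm_area[failed] <- .truncNorm(sum(failed), config@fail_area_mean,
                                    config@fail_area_sd)
    perm_circ <- .truncNorm(n, config@circ_mean, config@circ_sd, hi = 1)
    perm_circ[failed | artifact] <-
        .truncNorm(sum(failed | artifact), config@artifact_circ_mean,
                   config@artifact_circ_sd, hi = 1)

    sel_grow <- positive & !failed
    sel_area <- .truncNorm(n, config@fail_area_mean, config@fail_area_sd)
    sel_area[sel_grow] <- .truncNorm(sum(sel_grow), config@sel_area_mean,
                                     config@sel_area_sd, lo = 1)
    sel_circ <- .truncNorm(n, config@artifact_circ_mean,
                           config@artifact_circ_sd, hi = 1)
    sel_circ[sel_grow] <- .truncNorm(sum(sel_grow), config@circ_mean,
                                     config@circ_sd, hi = 1)

    colonies <- rbind(
        cbind(grid, medium = "permissive", area = round(perm_area, 1),
              circularity = round(perm_circ, 3)),
        cbind(grid, medium = "selective", area = round(sel_area, 1),
              circularity = round(sel_circ, 3)))
    rownames(colonies) <- NULL

    truth <- data.frame(strain_id = strains,
                        rate = unname(config@strain_rates[strains]),
                        n_positive = vapply(strains, function(s)
                            sum(positive[grid$strain_id == s]), numeric(1)),
                        stringsAsFactors = FALSE)
    list(colonies = colonies, truth = truth)
}

#' Simulate fluctuation-test count tables
#'
#' For each strain and test, grows \code{n_cultures} independent
#' cultures to \code{culture_cells} viable cells under the
#' Luria-Delbruck forward model (\code{m = rate * culture_cells}), then
#' subsamples each plate binomially according to the plating design:
#' the selective plate receives the fraction
#' \code{sel_volume / (sel_dilution * culture_volume)} of the culture
#' (recombinants only are counted) and the permissive plate the
#' corresponding permissive fraction of all viable cells.
#'
#' @param rates named numeric vector of per-cell recombination rates.
#' @param design a \linkS4class{PlatingDesign}.
#' @param n_cultures cultures per test (default 5).
#' @param n_tests repeated tests per strain (default 1).
#' @param seed integer seed.
#' @param culture_cells viable cells per saturated culture (default 4e8,
#'   i.e. 1e8 cells/ml in a 4 ml culture).
#' @return data.frame with columns \code{strain}, \code{test},
#'   \code{culture}, \code{sel_count}, \code{perm_count}.
#' @examples
#' d <- PlatingDesign()
#' simulateFluctuationTables(c(WT = 1.14e-5), d, seed = 1)
#' @export
simulateFluctuationTables <- function(rates, design = PlatingDesign(),
                                      n_cultures = 5, n_tests = 1, seed,
                                      culture_cells = 4e8) {
    validObject(design)
    if (is.null(names(rates)) || any(!nzchar(names(rates))))
        stop("'rates' must be named by strain")
    stopifnot(all(rates >= 0), n_cultures >= 1, n_tests >= 1)
    set.seed(as.integer(seed))
    sel_frac <- design@sel_volume_ml /
        (design@sel_dilution * design@culture_volume_ml)
    perm_frac <- design@perm_volume_ml /
        (design@perm_dilution * design@culture_volume_ml)
    rows <- expand.grid(culture = seq_len(n_cultures),
                        test = seq_len(n_tests),
                        strain = names(rates),
                        stringsAsFactors = FALSE)[, 3:1]
    m <- rates[rows$strain] * culture_cells
    sel <- integer(nrow(rows))
    perm <- integer(nrow(rows))
    for (i in seq_len(nrow(rows))) {
        r <- .cloneR(m[i], culture_cells)
        sel[i] <- stats::rbinom(1L, r, sel_frac)
        perm[i] <- stats::rbinom(1L, culture_cells, perm_frac)
    }
    data.frame(strain = rows$strain, test = rows$test,
               culture = rows$culture, sel_count = sel, perm_count = perm,
               stringsAsFactors = FALSE)
}
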