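#' Normalise a selective-plate count to recombinants per fixed cell number
#'
#' Converts paired selective/permissive colony counts into recombinants
#' per \code{norm_cells} viable cells, using the plating dilutions and
#' volumes: \deqn{\frac{sel \cdot d_{sel} / v_{sel}}
#'   {perm \cdot d_{perm} / v_{perm}} \cdot norm\_cells.}
#' With the default design this reduces to \code{5000 * sel / perm}
#' recombinants per 1e7 viable cells.
#'
#' @param sel_count colonies on the selective plate.
#' @param perm_count colonies on the permissive plate (> 0).
#' @param design a \linkS4class{PlatingDesign}.
#' @return recombinants per \code{norm_cells} viable cells (vectorised).
#' @examples
#' normalizeCount(20, 100)  # 1000 per 1e7 cells
#' @export
normalizeCount <- function(sel_count, perm_count, design = PlatingDesign()) {
    validObject(design)
    if (any(perm_count <= 0))
        stop("viable-count error: 'perm_count' must be > 0")
    sel_density <- sel_count * design@sel_dilution / design@sel_volume_ml
    perm_density <- perm_count * design@perm_dilution / design@perm_volume_ml
    sel_density / perm_density * design@norm_cells
}

#' Lea-Coulson method of the median
#'
#' Solves the median equation \eqn{r_{med}/m - \ln m = 1.24} for the
#' expected number of events \code{m}, given the median recombinant count
#' per culture. The left-hand side is strictly decreasing in \code{m}, so
#' the root is unique; it is found by bisection over
#' \eqn{[10^{-9}, 10^{6}]} to relative tolerance \eqn{10^{-9}}.
#'
#' @param median_r median recombinant count per culture (> 0 for a
#'   determinate estimate).
#' @return the estimate \code{m_hat}, or \code{NA_real_} when
#'   \code{median_r <= 0} (indeterminate, not an error, so batch runs
#'   continue).
#' @examples
#' leaCoulsonM(1.24)  # exactly 1
#' @export
leaCoulsonM <- function(median_r) {
    if (length(median_r) != 1L || is.na(median_r))
        stop("'median_r' must be a single number")
    if (median_r <= 0)
        return(NA_real_)
    f <- function(m) median_r / m - log(m) - 1.24
    lo <- 1e-9
    hi <- 1e6
    if (f(hi) > 0)
        stop("'median_r' too large for the solver bracket")
    root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root
    # polish to relative tolerance with a few bisection-safe Newton steps
    for (i in 1:4) {
        fr <- median_r / root - log(root) - 1.24
        dfr <- -median_r / root^2 - 1 / root
        step <- fr / dfr
        if (!is.finite(step)) break
        cand <- root - step
        if (cand > 0) root <- cand
    }
    root
}

#' Estimate a recombination rate from a fluctuation test
#'
#' Implements the method-of-the-median workflow: each culture's counts
#' are normalised to recombinants per \code{norm_cells} viable cells, the
#' sample median is taken (even n: mean of the central pair), the
#' Lea-Coulson equation converts the median to \code{m_hat}, and the rate
#' is \code{m_hat / norm_cells}. Cultures whose permissive count is zero
#' are dropped with a warning. The estimate is flagged indeterminate when
#' the median is zero or when more than \code{jackpot_ceiling} of the
#' cultures are jackpots (normalised count above half of
#' \code{norm_cells}).
#'
#' @param test a \linkS4class{FluctuationTest}.
#' @param jackpot_ceiling maximum tolerated jackpot fraction (default 0.5).
#' @return one-row data.frame with columns \code{rate}, \code{m_hat},
#'   \code{median_r}, \code{jackpot_fraction}, \code{status}
#'   (\code{"ok"} or \code{"indeterminate"}).
#' @examples
#' estimateRate(FluctuationTest(c(3, 0, 12, 1, 5), rep(100, 5)))
#' @export
estimateRate <- function(test, jackpot_ceiling = 0.5) {
    stopifnot(is(test, "FluctuationTest"))
    validObject(test)
    counts <- test@counts
    usable <- counts$perm_count > 0
    if (!all(usable)) {
        warning(sum(!usable), " culture(s) dropped: no viable-count colonies")
        counts <- counts[usable, , drop = FALSE]
    }
    if (nrow(counts) == 0L)
        stop("no usable cultures: all permissive counts are zero")
    norm <- normalizeCount(counts$sel_count, counts$perm_count, test@design)
    med <- stats::median(norm)
    jackpot <- mean(norm > 0.5 * test@design@norm_cells)
    m_hat <- leaCoulsonM(med)
    status <- if (is.na(m_hat) || jackpot > jackpot_ceiling)
        "indeterminate" else "ok"
    data.frame(rate = if (status == "ok") m_hat / test@design@norm_cells
                      else NA_real_,
               m_hat = if (status == "ok") m_hat else NA_real_,
               median_r = med, jackpot_fraction = jackpot,
               status = status, stringsAsFactors = FALSE)
}

#' Estimate rates for every strain (and test) in a counts table
#'
#' @param counts data.frame with columns \code{strain}, \code{culture},
#'   \code{sel_count}, \code{perm_count}, and optionally \code{test} for
#'   repeated fluctuation tests per strain.
#' @param design a \linkS4class{PlatingDesign}.
#' @param jackpot_ceiling passed to \code{\link{estimateRate}}.
#' @return data.frame with one row per strain (and test), columns
#'   \code{strain}, (\code{test},) \code{rate}, \code{m_hat},
#'   \code{median_r}, \code{jackpot_fraction}, \code{status}.
#' @export
estimateRates <- function(counts, design = PlatingDesign(),
                          jackpot_ceiling = 0.5) {
    need <- c("strain", "culture", "sel_count", "perm_count")
    if (!all(need %in% colnames(counts)))
        stop("counts table needs columns: ", paste(need, collapse = ", "))
    keys <- if ("test" %in% colnames(counts))
        interaction(counts$strain, counts$test, drop = TRUE, sep = "\r")
    else factor(counts$strain)
    out <- lapply(levels(keys), function(k) {
        sub <- counts[keys == k, , drop = FALSE]
        est <- estimateRate(FluctuationTest(sub$sel_count, sub$perm_count,
                                            design),
                            jackpot_ceiling = jackpot_ceiling)
        id <- strsplit(k, "\r", fixed = TRUE)[[1L]]
        pre <- data.frame(strain = id[1L], stringsAsFactors = FALSE)
        if (length(id) > 1L) pre$test <- id[2L]
        cbind(pre, est)
    })
    do.call(rbind, out)
}

#' One-sided two-sample Student's t-test (mutant greater than wild type)
#'
#' Pooled-variance Student's t-test of the alternative that the mutant
#' rates exceed the wild-type rates.
#'
#' @param rates_mutant numeric vector, length >= 2.
#' @param rates_wt numeric vector, length >= 2.
#' @return the one-sided p-value.
#' @examples
#' tTestOneSided(c(3, 4, 5), c(1, 2, 3))
#' @export
tTestOneSided <- function(rates_mutant, rates_wt) {
    if (length(rates_mutant) < 2L || length(rates_wt) < 2L)
        stop("insufficient replicates: each group needs >= 2 rates")
    stats::t.test(rates_mutant, rates_wt, alternative = "greater",
                  var.equal = TRUE)$p.value
}

#' Two-stage triage of candidate hyper-recombination strains
#'
#' Stage 1 keeps strains whose first-pass rate estimate reaches
#' \code{rate_cutoff} (default 2e-5, roughly twofold the wild-type rate).
#' Stage 2 validates the survivors whose repeated-test rates exceed the
#' wild-type rates by a one-sided pooled-variance t-test at
#' \code{p < alpha}.
#'
#' @param first_rates named numeric vector: first-pass rate per strain
#'   (\code{NA} for strains whose rate was indeterminate, e.g. jackpot
#'   dominated).
#' @param repeat_rates named list: per strain, the rates from repeated
#'   fluctuation tests (used only for stage-1 survivors).
#' @param wt_rates wild-type reference rates (length >= 2).
#' @param rate_cutoff stage-1 rate threshold (default 2e-5).
#' @param alpha stage-2 significance level (default 0.05).
#' @return data.frame with columns \code{strain}, \code{first_rate},
#'   \code{p_value}, \code{verdict} in \code{"validated"},
#'   \code{"rejected-stage1"}, \code{"rejected-stage2"},
#'   \code{"indeterminate"}.
#' @export
triageStrains <- function(first_rates, repeat_rates, wt_rates,
                          rate_cutoff = 2e-5, alpha = 0.05) {
    if (length(wt_rates) == 0L)
        stop("empty wild-type reference")
    stopifnot(rate_cutoff > 0, alpha > 0, alpha < 1)
    strains <- names(first_rates)
    if (is.null(strains)) stop("'first_rates' must be named by strain")
    res <- lapply(strains, function(s) {
        fr <- first_rates[[s]]
        if (is.na(fr))
            return(data.frame(strain = s, first_rate = NA_real_,
                              p_value = NA_real_,
                              verdict = "indeterminate"))
        if (fr < rate_cutoff)
            return(data.frame(strain = s, first_rate = fr,
                              p_value = NA_real_,
                              verdict = "rejected-stage1"))
        rr <- repeat_rates[[s]]
        if (is.null(rr) || length(rr) < 2L)
            return(data.frame(strain = s, first_rate = fr,
                              p_value = NA_real_,
                              verdict = "indeterminate"))
        p <- tTestOneSided(rr, wt_rates)
        data.frame(strain = s, first_rate = fr, p_value = p,
                   verdict = if (p < alpha) "validated"
                             else "rejected-stage2")
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
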