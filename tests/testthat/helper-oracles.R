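# Independent oracles used to freeze expected values; none of these call
# the code paths they are used to check.

# Exhaustive hypergeometric upper tail: enumerate every draw of n items
# from a universe of N with K marked, and count draws sharing >= k with
# the marked set. Feasible for N <= 12.
enumHyperTail <- function(k, K, n, N) {
    draws <- utils::combn(N, n)
    marked <- seq_len(K)
    hits <- apply(draws, 2L, function(col) sum(col %in% marked))
    mean(hits >= k)
}

# Two-stage dense grid scan of the monotone median equation
# r/m - ln(m) = 1.24 (coarse log grid, then a fine linear grid around the
# coarse solution).
gridLeaCoulson <- function(median_r) {
    g <- 10^seq(-6, 5, length.out = 200001)
    i <- which.min(abs(median_r / g - log(g) - 1.24))
    lo <- g[max(1L, i - 1L)]
    hi <- g[min(length(g), i + 1L)]
    f <- seq(lo, hi, length.out = 200001)
    f[which.min(abs(median_r / f - log(f) - 1.24))]
}

# Grid-search maximum-likelihood estimate of m under the count
# distribution computed by the Ma-Sandri-Sarkar recursion, with counts
# above r_cap treated as right-censored. Used only as a cross-check of
# the median method.
mssMLEGrid <- function(counts, m_grid, r_cap = 500L) {
    counts <- pmin(counts, r_cap + 1L)
    loglik <- vapply(m_grid, function(m) {
        p <- ldPmf(m, r_cap)
        tail_mass <- max(1 - sum(p), 1e-300)
        lp <- log(pmax(p, 1e-300))
        sum(ifelse(counts > r_cap, log(tail_mass), lp[counts + 1L]))
    }, numeric(1))
    m_grid[which.max(loglik)]
}

# Small hand-built colony tables for scoring tests.
colonyRow <- function(plate, row, col, strain, medium, area, circ = 0.95) {
    data.frame(plate_id = plate, row = row, col = col, strain_id = strain,
               medium = medium, area = area, circularity = circ,
               stringsAsFactors = FALSE)
}

# A paired two-plate toy screen: for each strain, `n` permissive
# colonies of the given areas and matching selective colonies.
pairedPlate <- function(strain, perm_areas, sel_areas, plate = "p1",
                        circ = 0.95, row0 = 1) {
    n <- length(perm_areas)
    rows <- seq(row0, length.out = n)
    rbind(colonyRow(plate, rows, 1, strain, "permissive", perm_areas, circ),
          colonyRow(plate, rows, 1, strain, "selective", sel_areas, circ))
}
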