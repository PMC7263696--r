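#' Luria-Delbruck probability mass function (Ma-Sandri-Sarkar recursion)
#'
#' Probability of observing \code{r} pre-existing recombinants in a clone
#' with \code{m} expected recombination events, under the classical model
#' of deterministic exponential growth: events arise uniformly over the
#' population increase and each founds a clone whose size follows
#' \eqn{P(size \ge k) = 1/k}. The recursion is
#' \deqn{p_0 = e^{-m}, \qquad
#'       p_r = \frac{m}{r} \sum_{i=0}^{r-1} \frac{p_i}{r - i + 1}.}
#'
#' @param m expected number of recombination events per clone (>= 0).
#' @param r_max largest count to evaluate.
#' @return numeric vector of length \code{r_max + 1}; element \code{r + 1}
#'   is \eqn{P(R = r)}.
#' @examples
#' ldPmf(2, 5)
#' @export
ldPmf <- function(m, r_max) {
    if (length(m) != 1L || is.na(m) || m < 0)
        stop("'m' must be a single number >= 0")
    if (length(r_max) != 1L || is.na(r_max) || r_max < 0)
        stop("'r_max' must be a single count >= 0")
    r_max <- as.integer(r_max)
    p <- numeric(r_max + 1L)
    p[1L] <- exp(-m)
    if (r_max >= 1L) {
        for (r in seq_len(r_max)) {
            # p[1:r] holds p_0 .. p_{r-1}; weights 1/(r - i + 1), i = 0..r-1
            p[r + 1L] <- (m / r) * sum(p[seq_len(r)] / ((r + 1L):2L))
        }
    }
    p
}

#' Quantile of the Luria-Delbruck count distribution
#'
#' Smallest count \code{r} whose cumulative probability reaches \code{prob}.
#' Used for median-based oracles; the pmf is extended until the requested
#' mass is covered (the distribution is heavy-tailed, so an upper guard is
#' applied).
#'
#' @param m expected events per clone.
#' @param prob probability in (0,1).
#' @param r_guard hard ceiling on the search (default 1e6).
#' @return the integer quantile.
#' @export
ldQuantile <- function(m, prob = 0.5, r_guard = 1e6) {
    stopifnot(prob > 0, prob < 1)
    r_max <- max(16L, ceiling(4 * m * (2 + log(max(m, 1)))))
    repeat {
        p <- ldPmf(m, r_max)
        cp <- cumsum(p)
        if (cp[length(cp)] >= prob)
            return(which(cp >= prob)[1L] - 1L)
        if (r_max >= r_guard)
            stop("quantile beyond guard; increase 'r_guard'")
        r_max <- min(r_guard, r_max * 4L)
    }
}

## Clone realisation drawn from the current RNG stream: K ~ Poisson(m)
## events, each founding a clone of size min(nf, floor(1/u)), u ~ U(0,1].
.cloneR <- function(m, nf) {
    k <- stats::rpois(1L, m)
    if (k == 0L)
        return(0)
    sizes <- pmin(nf, floor(1 / stats::runif(k)))
    min(sum(sizes), nf)
}

#' Simulate one clonal expansion
#'
#' Forward simulation of recombinant accumulation in a single culture or
#' colony: the number of recombination events is Poisson(\code{m}); each
#' event founds a recombinant clone of size \code{min(nf, floor(1/u))}
#' with \code{u ~ Uniform(0,1]} (deterministic exponential growth, no
#' death, no reversion); the total is capped at \code{nf}.
#'
#' @param model an \linkS4class{LDModel}.
#' @param seed integer seed; the outcome is deterministic given the seed.
#' @return list with components \code{r} (pre-existing recombinant cells)
#'   and \code{nf} (total viable cells).
#' @examples
#' simulateClone(LDModel(m = 2), seed = 1)
#' @export
simulateClone <- function(model, seed) {
    stopifnot(is(model, "LDModel"))
    validObject(model)
    set.seed(as.integer(seed))
    list(r = .cloneR(model@m, model@nf), nf = model@nf)
}

## Counter-based split of a master seed into per-culture streams
## (Lehmer step modulo the Mersenne prime 2^31 - 1; stable across runs).
.deriveSeed <- function(seed, i) {
    as.integer((as.double(seed) %% 2147483647 * 48271 + i * 8191) %%
               2147483647)
}

#' Sample recombinant counts for independent cultures
#'
#' Element \code{i} is reproducible as \code{simulateClone} run with a
#' seed derived deterministically from \code{(seed, i)}.
#'
#' @param model an \linkS4class{LDModel}.
#' @param n_cultures number of independent cultures (>= 1).
#' @param seed master integer seed.
#' @return numeric vector of recombinant counts, length \code{n_cultures}.
#' @examples
#' sampleLdCounts(LDModel(m = 4), 10, seed = 42)
#' @export
sampleLdCounts <- function(model, n_cultures, seed) {
    stopifnot(is(model, "LDModel"))
    if (length(n_cultures) != 1L || is.na(n_cultures) || n_cultures < 1)
        stop("'n_cultures' must be >= 1")
    validObject(model)
    vapply(seq_len(n_cultures), function(i) {
        set.seed(.deriveSeed(seed, i))
        .cloneR(model@m, model@nf)
    }, numeric(1))
}
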