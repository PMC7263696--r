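test_that("hypergeometric overlap matches closed forms", {
    # identical sets of size 5 in a universe of 10: p = 1 / C(10,5)
    ab <- paste0("g", 1:5)
    ov <- hypergeomOverlap(ab, ab, universe = 10)
    expect_identical(overlapSize(ov), 5L)
    expect_equal(pValue(ov), 1 / choose(10, 5))
    # disjoint sets: k = 0, P(X >= 0) = 1
    dis <- hypergeomOverlap(paste0("a", 1:3), paste0("b", 1:3),
                            universe = 20)
    expect_identical(overlapSize(dis), 0L)
    expect_equal(pValue(dis), 1)
    expect_error(hypergeomOverlap(paste0("g", 1:6), paste0("g", 4:9),
                                  universe = 8), "universe")
})

test_that("overlap p-values equal exhaustive enumeration for small universes", {
    for (N in c(6L, 9L, 12L)) {
        genes <- paste0("g", seq_len(N))
        for (K in c(2L, N %/% 2L, N - 1L)) {
            for (n in c(2L, N %/% 2L)) {
                for (k in 1:min(K, n)) {
                    # build sets with exactly k shared genes
                    A <- genes[seq_len(K)]
                    B <- c(genes[seq_len(k)],
                           genes[K + seq_len(n - k)])
                    if (K + n - k > N) next
                    ov <- hypergeomOverlap(A, B, universe = N)
                    expect_equal(pValue(ov), enumHyperTail(k, K, n, N),
                                 tolerance = 1e-12)
                }
            }
        }
    }
})

test_that("overlap p-values are non-increasing in the intersection size", {
    p <- vapply(0:10, function(k)
        phyper(k - 1, 20, 80, 10, lower.tail = FALSE), numeric(1))
    # independent check of the property on our own construction
    genes <- paste0("g", 1:60)
    ps <- vapply(1:8, function(k) {
        A <- genes[1:20]
        B <- c(genes[1:k], genes[20 + seq_len(8 - k)])
        pValue(hypergeomOverlap(A, B, universe = 60))
    }, numeric(1))
    expect_true(all(diff(ps) < 0))
    expect_true(all(diff(p) <= 0))
})

test_that("packaged hit tables assemble into consistent gene sets", {
    sets <- assembleHits()
    expect_identical(length(sets$patch), 33L)
    expect_identical(length(sets$pinning_hyper), 75L)
    expect_identical(length(sets$pinning_hypo), 122L)
    expect_identical(length(sets$validated), 35L)
    expect_identical(length(intersect(sets$pinning_hyper,
                                      sets$pinning_hypo)), 0L)
    # validated union = patch hits plus the two pinning-only validations
    expect_setequal(sets$validated, union(sets$patch, c("CSM1", "NUP170")))
    expect_setequal(sets$validated, validatedGenes())
    # the wild-type reference row never enters a gene set
    expect_false("WT" %in% sets$patch)
})

test_that("malformed fixtures are rejected with the offending row", {
    bad <- tempfile(fileext = ".tsv")
    writeLines(c("gene\trecombinant_pct", "ABC1\t90", "\t80"), bad)
    expect_error(RecScreen:::.readFixture(bad, c("gene", "recombinant_pct")),
                 "row 2")
    nohdr <- tempfile(fileext = ".tsv")
    writeLines(c("name\tvalue", "ABC1\t90"), nohdr)
    expect_error(RecScreen:::.readFixture(nohdr, c("gene", "recombinant_pct")),
                 "missing column")
})

test_that("ortholog summaries count non-empty ortholog lists", {
    expect_identical(orthologSummary(data.frame(gene = character(),
        human_orthologs = character())), 0L)
    toy <- data.frame(gene = c("A", "B", "C"),
                      human_orthologs = c("HSA1", "", "HSB1, HSB2"))
    expect_identical(orthologSummary(toy), 2L)
    expect_error(orthologSummary(data.frame(gene = "A")), "human_orthologs")
})

test_that("distribution summaries report group and rest medians", {
    freq <- data.frame(strain_id = c("a", "b", "c"),
                       frequency = c(0.2, 0.4, 0.6))
    none <- distributionSummary(freq, character())
    expect_equal(none$rest$median, 0.4)
    expect_identical(none$group$n, 0L)
    # identically distributed group and rest give equal medians
    freq2 <- data.frame(strain_id = paste0("s", 1:20),
                        frequency = rep(c(0.1, 0.3, 0.5, 0.7), 5))
    ds <- distributionSummary(freq2, paste0("s", 1:4))
    expect_equal(ds$group$median, ds$rest$median)
    expect_identical(sum(ds$group$histogram) + sum(ds$rest$histogram), 20L)
    expect_error(distributionSummary(freq[0, ], "a"), "no usable")
})
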