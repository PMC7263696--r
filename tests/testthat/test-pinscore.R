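test_that("the circularity filter is strict at the boundary", {
    recs <- colonyRow("p1", 1:3, 1, "s", "permissive", 100,
                      circ = c(0.80, 0.81, 0.95))
    kept <- filterCircularity(recs)
    expect_identical(kept$circularity, c(0.81, 0.95))
    empty <- filterCircularity(recs[0, ])
    expect_identical(nrow(empty), 0L)
    # removal counts logged per plate
    expect_identical(as.integer(attr(kept, "removed")[["p1"]]), 1L)
})

test_that("permissive colonies are scored against the plate mean area", {
    recs <- colonyRow("p1", 1:4, 1, "s", "permissive", c(100, 100, 100, 20))
    perm <- scorePermissive(filterCircularity(recs))
    # plate mean 80, threshold 40: three scored, the small one not
    expect_identical(perm$scored, c(TRUE, TRUE, TRUE, FALSE))
    equal <- scorePermissive(colonyRow("p2", 1:3, 1, "s", "permissive", 55))
    expect_true(all(equal$scored))
    single <- scorePermissive(colonyRow("p3", 1, 1, "s", "permissive", 1))
    expect_true(single$scored)
})

test_that("selective scoring pairs by position and uses the strain mean", {
    recs <- rbind(
        colonyRow("p1", 1:2, 1, "s", "permissive", c(300, 500)),
        colonyRow("p1", 1:2, 1, "s", "selective", c(41, 40)),
        # unpaired selective colony at an empty permissive position
        colonyRow("p1", 9, 9, "s", "selective", 400))
    sc <- scoreColonies(recs)
    # strain mean permissive area 400; 10% threshold 40 is strict
    expect_identical(sc$selective$scored, c(TRUE, FALSE, FALSE))

    # selective colony whose permissive partner failed scoring
    recs2 <- rbind(
        colonyRow("p1", 1:3, 1, "s", "permissive", c(500, 500, 100)),
        colonyRow("p1", 1:3, 1, "s", "selective", c(450, 450, 450)))
    sc2 <- scoreColonies(recs2)
    expect_identical(sc2$selective$scored, c(TRUE, TRUE, FALSE))

    # strain with no scored permissive colonies: never scored
    recs3 <- rbind(
        colonyRow("p1", 1, 1, "big", "permissive", 1000),
        colonyRow("p1", 2, 1, "small", "permissive", 10),
        colonyRow("p1", 2, 1, "small", "selective", 900))
    sc3 <- scoreColonies(recs3)
    expect_false(any(sc3$selective$scored))
})

test_that("strain frequencies apply the colony-count and list exclusions", {
    cfg <- ScreenConfig(exclusion_strains = "MSH3X")
    mk <- function(strain, n_perm, n_sel_big) {
        pairedPlate(strain, rep(100, n_perm),
                    c(rep(90, n_sel_big), rep(1, n_perm - n_sel_big)))
    }
    recs <- rbind(mk("ok", 48, 24), mk("few", 9, 5), mk("msh3x", 40, 30))
    freq <- strainFrequencies(scoreColonies(recs, cfg), cfg)
    rownames(freq) <- freq$strain_id
    expect_equal(freq["ok", "frequency"], 0.5)
    expect_false(freq["ok", "excluded"])
    expect_true(freq["few", "excluded"])
    expect_identical(freq["few", "exclusion_reason"], "too-few-colonies")
    expect_true(is.na(freq["few", "frequency"]))
    # excluded from hit calling but the frequency is kept for distributions
    expect_true(freq["msh3x", "excluded"])
    expect_identical(freq["msh3x", "exclusion_reason"], "msh3-list")
    expect_equal(freq["msh3x", "frequency"], 0.75)
})

test_that("cutoff classification splits hyper, hypo and unclassified", {
    cfg <- ScreenConfig()
    freq <- data.frame(strain_id = c("a", "b", "c", "d", "e", "x"),
                       n_total = 48, n_recombinant = 0,
                       frequency = c(0.92, 0.56, 0.292, 0.87, 0.33, 0.9),
                       excluded = c(rep(FALSE, 5), TRUE),
                       exclusion_reason = c(rep("none", 5), "msh3-list"))
    cls <- classifyFrequencies(freq, cfg)
    expect_identical(cls$class,
                     c("hyper", "unclassified", "hypo", "hyper", "hypo",
                       NA_character_))
})

test_that("scoring is idempotent and robust to tighter circularity", {
    cfg <- ScreenConfig()
    set.seed(42)
    sim <- simulateScreen(SimConfig(c(a = 1e-5, b = 1e-4, c = 0)), seed = 9)
    once <- filterCircularity(sim$colonies, cfg)
    twice <- filterCircularity(once, cfg)
    attr(once, "removed") <- attr(twice, "removed") <- NULL
    expect_identical(once, twice)

    freq <- strainFrequencies(scoreColonies(sim$colonies, cfg), cfg)
    ok <- !is.na(freq$frequency)
    expect_true(all(freq$frequency[ok] >= 0 & freq$frequency[ok] <= 1))

    tighter <- ScreenConfig(circularity_min = 0.95)
    freq2 <- strainFrequencies(scoreColonies(sim$colonies, tighter), tighter)
    merged <- merge(freq, freq2, by = "strain_id")
    expect_true(all(merged$n_total.y <= merged$n_total.x))
})

test_that("a zero-noise synthetic screen gives exact hand-computed ratios", {
    cfg <- SimConfig(c(null = 0, hot = 1), cells_per_colony = 1e3,
                     transfer_fraction = 1, background_positive_prob = 0,
                     pin_fail_prob = 0, artifact_prob = 0, area_sd = 0,
                     sel_area_sd = 0, fail_area_sd = 0, circ_sd = 0,
                     artifact_circ_sd = 0)
    sim <- simulateScreen(cfg, seed = 2)
    freq <- strainFrequencies(scoreColonies(sim$colonies, ScreenConfig()),
                              ScreenConfig())
    rownames(freq) <- freq$strain_id
    expect_identical(freq["null", "n_total"], 48)
    expect_equal(freq["null", "frequency"], 0)
    # m = 1000 per colony: every colony carries recombinants
    expect_equal(freq["hot", "frequency"], 1)
})
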