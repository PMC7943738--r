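make_digestion <- function(n_obs_per_sub) {
    # substrates of length 18: exactly 10 theoretical 9mer windows each
    set.seed(13)
    subs <- data.frame(id = sprintf("S%d", seq_along(n_obs_per_sub)),
                       sequence = vapply(rep(18, length(n_obs_per_sub)),
                                         random_protein, character(1)))
    prods <- do.call(rbind, lapply(seq_along(n_obs_per_sub), function(i) {
        n <- n_obs_per_sub[i]
        if (n == 0) return(NULL)
        starts <- seq_len(n)
        data.frame(substrate_id = subs$id[i],
                   peptide = substring(subs$sequence[i], starts, starts + 8),
                   type = "nonspliced")
    }))
    if (is.null(prods))
        prods <- data.frame(substrate_id = character(),
                            peptide = character(), type = character())
    digestionDataset(subs, prods)
}

test_that("f_non is the median per-substrate observed window fraction", {
    expect_identical(estimateFnon(make_digestion(c(2, 3, 4))), 0.3)
    expect_identical(estimateFnon(make_digestion(c(10, 10))), 1)
    expect_identical(estimateFnon(make_digestion(c(0, 0, 0))), 0)

    # duplicate product rows do not change the estimate
    ds <- make_digestion(c(2, 3, 4))
    ds2 <- digestionDataset(ds$substrates,
                            rbind(ds$products, ds$products))
    expect_identical(estimateFnon(ds2), 0.3)

    bad <- data.frame(substrate_id = "S1", peptide = "WWWWWWWWW",
                      type = "nonspliced")
    expect_error(digestionDataset(make_digestion(1)$substrates, bad),
                 "not a substring of its substrate: WWWWWWWWW")
    expect_error(digestionDataset(data.frame(id = "S1", sequence = "ACD"),
                                  data.frame(substrate_id = "S9",
                                             peptide = "A",
                                             type = "nonspliced")),
                 "unknown substrate")
})

test_that("digestion datasets round-trip through their TSV pair", {
    ds <- make_digestion(c(2, 5))
    sp <- tempfile(); pp <- tempfile()
    writeDigestionDataset(ds, sp, pp)
    back <- readDigestionDataset(sp, pp)
    expect_identical(back$substrates$sequence, ds$substrates$sequence)
    expect_identical(nrow(back$products), nrow(ds$products))
})

test_that("presented-fraction formulas match hand arithmetic and invert exactly", {
    expect_identical(fCisFrom(0, 0.27), 0)
    expect_equal(fCisFrom(15, 0.27, 398), 4.05 / 33830, tolerance = 1e-12)
    expect_equal(fCisFrom(15, 0.27, 398), 1.197e-4, tolerance = 1e-3)
    expect_equal(fCisFrom(1, 0.27, 398), 0.27 / 39402, tolerance = 1e-12)
    expect_error(fCisFrom(100, 0.27), "0 <= f < 100")

    expect_identical(nCisFrom(0, 1000, 0.27), 0)
    expect_equal(nCisFrom(15, 1000, 0.27), 4050 / 85, tolerance = 1e-12)

    # round trip: f == 100 n_cis / (n_cis + N_non f_non) over a grid
    for (f in seq(0.5, 99, by = 0.5)) {
        for (fNon in c(0.1, 0.27, 1)) {
            n_cis <- nCisFrom(f, 1000, fNon)
            f_back <- 100 * n_cis / (n_cis + 1000 * fNon)
            expect_equal(f_back, f, tolerance = 1e-9)
        }
    }
})

test_that("universe subsampling rounds half-even and is seed-reproducible", {
    set.seed(29)
    u <- pu(unique(vapply(rep(9, 120), random_protein, character(1)))[1:100],
            "h")
    expect_identical(peptides(subsampleUniverse(u, 1, 1)), peptides(u))
    expect_identical(length(subsampleUniverse(u, 0, 1)), 0L)
    expect_identical(length(subsampleUniverse(u, 0.27, 1)), 27L)
    expect_true(all(peptides(subsampleUniverse(u, 0.5, 3)) %in% peptides(u)))
    expect_identical(peptides(subsampleUniverse(u, 0.4, 7)),
                     peptides(subsampleUniverse(u, 0.4, 7)))
    # round-half-even: 0.5 * 5 = 2.5 -> 2
    u5 <- pu(peptides(u)[1:5], "h")
    expect_identical(length(subsampleUniverse(u5, 0.5, 1)), 2L)
    expect_error(subsampleUniverse(u, 1.2, 1), "fraction")
})

test_that("the sweep reduces to the unsampled pipeline in the identity limit", {
    set.seed(47)
    shared <- unique(vapply(rep(9, 12), random_protein, character(1)))
    vu <- list(v1 = list(
        non = pu(c(shared[1:3],
                   vapply(rep(9, 10), random_protein, character(1))), "v1"),
        cis = pu(c(shared[4:6],
                   vapply(rep(9, 10), random_protein, character(1))), "v1",
                 "cis")))
    hN <- pu(c(shared[c(1:3, 5)],
               vapply(rep(9, 10), random_protein, character(1))), "h")
    hC <- pu(c(shared[c(4, 6)],
               vapply(rep(9, 10), random_protein, character(1))), "h", "cis")

    # f = 50, fNon = 1, gamma = 1 gives f_cis = 1: nothing is dropped
    sw <- pcpsSweep(vu, hN, hC, fValues = 50, fNon = 1, gamma = 1,
                    repeats = 3, seed = 9)
    hits <- findZwitter(vu$v1$non, vu$v1$cis, hN, hC)
    cis_unique <- length(unique(hits$table$peptide[
        hits$table$viral_category == "cis" |
        hits$table$human_category == "cis"]))
    expect_true(all(sw$draws$nonspliced == hits$counts[["z_i"]]))
    expect_true(all(sw$draws$cis == cis_unique))
    expect_true(all(sw$draws$combined == hits$counts[["z_all"]]))
})

test_that("sweeps are reproducible and stable under f-grid extension", {
    set.seed(3)
    vu <- list(v1 = list(non = pu(vapply(rep(9, 30), random_protein,
                                         character(1)), "v1"),
                         cis = pu(vapply(rep(9, 30), random_protein,
                                         character(1)), "v1", "cis")))
    hN <- pu(vapply(rep(9, 40), random_protein, character(1)), "h")
    hC <- pu(vapply(rep(9, 40), random_protein, character(1)), "h", "cis")

    a <- pcpsSweep(vu, hN, hC, fValues = c(5, 15), fNon = 0.5, gamma = 2,
                   repeats = 4, seed = 11)
    b <- pcpsSweep(vu, hN, hC, fValues = c(5, 15), fNon = 0.5, gamma = 2,
                   repeats = 4, seed = 11)
    expect_identical(a$draws, b$draws)

    # the per-f seed stream means adding f values never perturbs
    # existing repeats
    wide <- pcpsSweep(vu, hN, hC, fValues = c(5, 15, 25), fNon = 0.5,
                      gamma = 2, repeats = 4, seed = 11)
    sub <- wide$draws[wide$draws$f %in% c(5, 15), ]
    rownames(sub) <- NULL
    expect_identical(sub, a$draws)
})

test_that("per-repeat surviving counts never exceed the unsampled counts", {
    set.seed(81)
    shared <- unique(vapply(rep(9, 20), random_protein, character(1)))
    vu <- list(v1 = list(
        non = pu(c(shared[1:8],
                   vapply(rep(9, 20), random_protein, character(1))), "v1"),
        cis = pu(c(shared[9:16],
                   vapply(rep(9, 20), random_protein, character(1))), "v1",
                 "cis")))
    hN <- pu(c(shared[1:12],
               vapply(rep(9, 20), random_protein, character(1))), "h")
    hC <- pu(c(shared[5:16],
               vapply(rep(9, 20), random_protein, character(1))), "h", "cis")
    full <- findZwitter(vu$v1$non, vu$v1$cis, hN, hC)
    sw <- pcpsSweep(vu, hN, hC, fValues = c(10, 30), fNon = 0.5, gamma = 0.1,
                    repeats = 30, seed = 2)
    expect_true(all(sw$draws$nonspliced <= full$counts[["z_i"]]))
    expect_true(all(sw$draws$combined <= full$counts[["z_all"]]))
})
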