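test_that("microarray summarization takes the max over subset means", {
    tab <- data.frame(gene = c("g1", "g1", "g1", "g2"),
                      subset = c("A", "A", "B", "A"),
                      value = c(2, 4, 5, 7))
    E <- microarrayExpression(tab)
    expect_identical(unname(E["g1"]), 5)   # max(mean(2,4) = 3, 5)
    expect_identical(unname(E["g2"]), 7)   # single subset, single replicate

    # identical replicates everywhere return the constant
    same <- data.frame(gene = "g", subset = rep(c("A", "B"), each = 3),
                       value = rep(4.2, 6))
    expect_identical(unname(microarrayExpression(same)["g"]), 4.2)

    # genes without finite values are excluded with a message
    with_na <- rbind(tab, data.frame(gene = "g3", subset = "A", value = NA))
    expect_message(E2 <- microarrayExpression(with_na), "excluded")
    expect_false("g3" %in% names(E2))
})

test_that("single-cell log-normalization implements ln(1e5 * UMI / total + 1)", {
    m <- matrix(c(10, 990), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
    x <- scrnaLognormalize(m)$x
    expect_equal(x["g1", "c1"], log(1e5 * 10 / 1000 + 1), tolerance = 1e-12)
    expect_equal(x["g1", "c1"], log(1001), tolerance = 1e-12)  # ~6.9088

    zero_gene <- matrix(c(0, 50), 2, 1,
                        dimnames = list(c("g1", "g2"), "c1"))
    expect_identical(scrnaLognormalize(zero_gene)$x["g1", "c1"], 0)

    # one cell, one gene holding all counts
    all_in <- matrix(c(100, 0), 1, 2, dimnames = list("g1", c("c1", "c2")))
    expect_error(scrnaLognormalize(all_in), "zero total UMI count: c2")
    one <- matrix(7, 1, 1, dimnames = list("g1", "c1"))
    expect_equal(scrnaLognormalize(one)$x[1, 1], log(100001),
                 tolerance = 1e-12)

    # E is the mean of x over cells
    set.seed(4)
    cm <- matrix(rpois(50, 5) + 1, 10, 5,
                 dimnames = list(paste0("g", 1:10), paste0("c", 1:5)))
    out <- scrnaLognormalize(cm)
    expect_equal(out$E, rowMeans(out$x), tolerance = 1e-12)
})

test_that("presentation weights are min-max scaled and normalized to one", {
    w <- computeWeights(c(a = 1, b = 2, c = 3))
    expect_equal(unname(w), c(0, 1 / 3, 2 / 3), tolerance = 1e-12)
    expect_equal(unname(computeWeights(c(a = 0, b = 10))), c(0, 1),
                 tolerance = 1e-12)
    set.seed(8)
    for (i in 1:20) {
        E <- rnorm(sample(2:50, 1))
        names(E) <- paste0("g", seq_along(E))
        expect_equal(sum(computeWeights(E)), 1, tolerance = 1e-9)
        expect_true(all(computeWeights(E) >= 0))
    }
    expect_warning(u <- computeWeights(c(a = 3, b = 3, c = 3)), "uniform")
    expect_equal(unname(u), rep(1 / 3, 3), tolerance = 1e-12)
    expect_error(computeWeights(c(a = 1)), ">= 2 genes")
})

test_that("peptide weights add over source genes; unmapped genes contribute zero", {
    w <- c(g1 = 0.5, g2 = 0.3, g3 = 0.2)
    sm <- data.frame(peptide = c("P1", "P1", "P2", "P2"),
                     gene = c("g1", "g2", "g3", "ghost"))
    expect_message(pw <- peptideWeights(sm, w), "absent")
    expect_equal(unname(pw["P1"]), 0.8, tolerance = 1e-12)
    expect_equal(unname(pw["P2"]), 0.2, tolerance = 1e-12)
})

test_that("weighted sampling respects degenerate pools and weights", {
    cfg <- samplingConfig(repeats = 25, seed = 5)
    tab1 <- data.frame(peptide = "AAAAAAAAA", virus = "v1")
    out1 <- weightedZwitterSampling(tab1, c(AAAAAAAAA = 1), cfg,
                                    c(v1 = 10))
    expect_true(all(out1$perRepeat[, "v1"] == 1L))
    expect_equal(unname(out1$M["v1"]), 10, tolerance = 1e-12)

    # weight concentrated on one peptide: the zero-weight peptide is
    # never drawn
    tab2 <- data.frame(peptide = c("AAAAAAAAA", "CCCCCCCCC"),
                       virus = c("v1", "v2"))
    out2 <- weightedZwitterSampling(tab2, c(AAAAAAAAA = 1, CCCCCCCCC = 0),
                                    cfg, c(v1 = 5, v2 = 5))
    expect_true(all(out2$perRepeat[, "v2"] == 0L))
    expect_true(all(out2$perRepeat[, "v1"] == 1L))

    expect_error(weightedZwitterSampling(tab2,
                                         c(AAAAAAAAA = 0, CCCCCCCCC = 0),
                                         cfg, c(v1 = 5, v2 = 5)),
                 "all peptide weights are zero")

    # same seed, same report, bitwise
    again <- weightedZwitterSampling(tab2, c(AAAAAAAAA = 1, CCCCCCCCC = 0),
                                     cfg, c(v1 = 5, v2 = 5))
    expect_identical(again$perRepeat, out2$perRepeat)
})

test_that("uniform-weight sampling matches the closed-form distinct-draw expectation", {
    set.seed(61)
    n <- 100
    peps <- vapply(rep(9, n), random_protein, character(1))
    while (anyDuplicated(peps))
        peps <- vapply(rep(9, n), random_protein, character(1))
    tab <- data.frame(peptide = peps, virus = "v1")
    w <- setNames(rep(1, n), peps)
    cfg <- samplingConfig(repeats = 1000, sizeFraction = 1, seed = 17)
    out <- weightedZwitterSampling(tab, w, cfg, c(v1 = n))
    mom <- distinct_draw_moments(n, n)
    observed_mean <- mean(out$perRepeat[, "v1"])
    se <- sqrt(mom$var / cfg@repeats)
    expect_lt(abs(observed_mean - mom$mean), 3 * se)
    # the classic limit: fraction ~ 1 - (1 - 1/n)^n ~ 0.634
    expect_equal(mom$mean / n, 1 - (1 - 1 / n)^n, tolerance = 1e-12)
})

test_that("per-peptide inclusion frequency tracks weight (doubling the weight ~ doubles inclusion)", {
    set.seed(33)
    n <- 400
    peps <- unique(vapply(rep(9, n + 50), random_protein, character(1)))[1:n]
    w <- setNames(rep(1, n), peps)
    w[peps[1]] <- 0.05
    w[peps[2]] <- 0.10
    tab <- data.frame(peptide = peps,
                      virus = c("special1", "special2",
                                rep("bulk", n - 2)))
    cfg <- samplingConfig(repeats = 3000, sizeFraction = 1, seed = 71)
    out <- weightedZwitterSampling(tab, w, cfg, setNames(rep(1, 3),
                        c("special1", "special2", "bulk")))
    # exact per-draw inclusion probabilities under multinomial sampling
    p_incl <- function(wi) 1 - (1 - wi / sum(w))^n
    f1 <- mean(out$perRepeat[, "special1"])
    f2 <- mean(out$perRepeat[, "special2"])
    se <- function(p) sqrt(p * (1 - p) / cfg@repeats)
    expect_lt(abs(f1 - p_incl(0.05)), 3 * se(p_incl(0.05)))
    expect_lt(abs(f2 - p_incl(0.10)), 3 * se(p_incl(0.10)))
    # and the ratio is near 2 for small weights
    expect_equal(p_incl(0.10) / p_incl(0.05), 2, tolerance = 0.05)
})
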