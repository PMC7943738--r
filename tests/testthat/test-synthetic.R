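test_that("random proteomes have the requested size, composition and determinism", {
    p <- generateProteome(10, 100, seed = 1, name = "s")
    expect_identical(length(p), 10L)
    expect_identical(totalResidues(p), 1000L)
    expect_identical(proteinSequences(generateProteome(10, 100, seed = 1)),
                     proteinSequences(generateProteome(10, 100, seed = 1)))

    # uniform composition within 3 sigma per letter at 1e5 residues
    big <- generateProteome(10, 10000, seed = 5)
    letters_all <- strsplit(paste(proteinSequences(big), collapse = ""), "")[[1]]
    counts <- table(factor(letters_all, levels = STD_AA))
    n <- length(letters_all)
    sigma <- sqrt(n * 0.05 * 0.95)
    expect_true(all(abs(counts - n * 0.05) < 3 * sigma))

    bad_freq <- setNames(rep(0.06, 20), STD_AA)  # sums to 1.2
    expect_error(generateProteome(2, 50, aaFreq = bad_freq), "summing to 1")
})

test_that("planting writes recoverable schemes and verifies its own ground truth", {
    cfg <- enumerationConfig(minReactantLength = 4, minGapReverse = 1)
    human <- generateProteome(25, 100, seed = 2, name = "h")
    viral <- generateProteome(2, 90, seed = 3, name = "v")
    res <- plantZwitter(human, viral,
                        data.frame(pair = c("non_non", "cis_cis",
                                            "non_cis", "cis_non"),
                                   count = 1),
                        config = cfg, seed = 6)
    gt <- res$groundTruth
    expect_identical(nrow(gt), 4L)
    # re-verify externally: full enumeration + intersection
    obs <- findZwitter(peptideUniverse(res$viral, "nonspliced", cfg),
                       peptideUniverse(res$viral, "cis", cfg),
                       peptideUniverse(res$human, "nonspliced", cfg),
                       peptideUniverse(res$human, "cis", cfg))
    expect_identical(sort(unique(obs$table$peptide)), sort(gt$peptide))
    expect_identical(unname(obs$counts[c("z_i", "z_j", "z_k", "z_l")]),
                     rep(1L, 4))
    # cis schemes recorded in the truth decompose the peptide as claimed
    cis_rows <- gt[!is.na(gt$viral_scheme), ]
    for (i in seq_len(nrow(cis_rows))) {
        parsed <- parseSchemeNotation(cis_rows$viral_scheme[i])
        vseq <- proteinSequences(res$viral)[[parsed$protein_id]]
        expect_identical(paste0(substr(vseq, parsed$s1, parsed$e1),
                                substr(vseq, parsed$s2, parsed$e2)),
                         cis_rows$peptide[i])
    }
})

test_that("empty specs plant nothing and invalid geometry errors early", {
    cfg <- enumerationConfig(minReactantLength = 4, minGapReverse = 1)
    human <- generateProteome(10, 80, seed = 2, name = "h")
    viral <- generateProteome(2, 80, seed = 3, name = "v")
    res <- plantZwitter(human, viral, data.frame(pair = character(),
                                                 count = integer()),
                        config = cfg, seed = 1)
    obs <- findZwitter(peptideUniverse(res$viral, "nonspliced", cfg),
                       peptideUniverse(res$viral, "cis", cfg),
                       peptideUniverse(res$human, "nonspliced", cfg),
                       peptideUniverse(res$human, "cis", cfg))
    expect_true(all(obs$counts == 0))

    expect_error(plantZwitter(human, viral,
                              data.frame(pair = "cis_non", count = 1,
                                         len1 = 4, gap = 26,
                                         order = "normal"),
                              config = cfg, seed = 1),
                 "geometry violates config")
})

test_that("multi-virus fixtures distribute plants and verify globally", {
    fx <- zwitterFixture(kPerCategory = c(non_non = 2, cis_cis = 1,
                                          non_cis = 1, cis_non = 2),
                         seed = 19)
    expect_identical(as.integer(table(fx$groundTruth$pair)[c("cis_cis", "cis_non",
                                                           "non_cis", "non_non")]),
                     c(1L, 2L, 1L, 2L))
    # stored ground truth always agrees with a fresh end-to-end run
    for (v in names(fx$viruses)) {
        obs <- findZwitter(
            peptideUniverse(fx$viruses[[v]], "nonspliced", fx$config),
            peptideUniverse(fx$viruses[[v]], "cis", fx$config),
            peptideUniverse(fx$human, "nonspliced", fx$config),
            peptideUniverse(fx$human, "cis", fx$config))
        expect_identical(sort(unique(obs$table$peptide)),
                         sort(fx$groundTruth$peptide[
                             fx$groundTruth$virus == v]))
    }
})

test_that("synthetic expression tables have the promised structure", {
    genes <- paste0("g", 1:20)
    ma <- generateExpression(genes, "microarray", seed = 3)
    expect_identical(sort(unique(ma$gene)), sort(genes))
    expect_identical(length(unique(ma$subset)), 3L)
    expect_identical(generateExpression(genes, "microarray", seed = 3),
                     generateExpression(genes, "microarray", seed = 3))

    sc <- generateExpression(genes, "scrna", seed = 3, nCells = 1,
                             librarySize = 1e4)
    expect_identical(unname(colSums(sc)), 1e4)

    # a strongly expressed gene receives a larger weight
    tab <- data.frame(gene = rep(c("lo", "hi"), each = 2),
                      subset = "A", value = c(3, 3, 13, 13))
    w <- computeWeights(microarrayExpression(tab))
    expect_gt(w["hi"], w["lo"])
})

test_that("synthetic digestions recover the target f_non", {
    expect_identical(estimateFnon(generateDigestionDataset(
        10, 60, targetFnon = 1, seed = 1, splicedPerSubstrate = 0)), 1)
    expect_identical(estimateFnon(generateDigestionDataset(
        10, 60, targetFnon = 0, seed = 1, splicedPerSubstrate = 0)), 0)

    ds <- generateDigestionDataset(47, 100, targetFnon = 0.27, seed = 4)
    est <- estimateFnon(ds)
    # median of 47 per-substrate binomial fractions: sd of one fraction is
    # sqrt(p(1-p)/92); the median's sd ~ 1.25 x that / sqrt(47)
    s_frac <- sqrt(0.27 * 0.73 / 92)
    expect_lt(abs(est - 0.27), 3 * 1.25 * s_frac / sqrt(47) + 0.01)
    # spliced products are present but ignored by the estimator
    expect_true(any(ds$products$type == "spliced"))
})

test_that("calibrated binding matrices are deterministic and hit their rate", {
    m1 <- generateBindingMatrix(9, 0.5, seed = 21)
    m2 <- generateBindingMatrix(9, 0.5, seed = 21)
    expect_identical(m1@scores, m2@scores)
    expect_identical(m1@intercept, m2@intercept)

    set.seed(90)
    fresh <- unique(vapply(rep(9, 2000), random_protein, character(1)))
    rate <- mean(predictIC50(fresh, m1) <= 500)
    expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / length(fresh)) + 0.01)

    # near-zero target: almost nothing passes the filter
    tiny <- generateBindingMatrix(9, 0.005, seed = 22)
    expect_lt(mean(predictIC50(fresh, tiny) <= 500), 0.03)

    expect_error(generateBindingMatrix(9, 0), "targetBinderRate")
})
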