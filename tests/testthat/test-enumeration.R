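test_that("non-spliced enumeration yields every window, left to right", {
    out <- enumerateNonspliced("ACDEFGHIKL")
    expect_identical(out$peptide, c("ACDEFGHIK", "CDEFGHIKL"))
    expect_identical(out$start, 1:2)
    expect_identical(nrow(enumerateNonspliced("ACDEFGHI")), 0L)  # L = 8

    # windows containing non-standard residues are omitted by default
    out_x <- enumerateNonspliced("ACDEFGHIXKL")
    expect_false(any(grepl("X", out_x$peptide)))
    cfg_keep <- enumerationConfig(excludeNonstandard = FALSE)
    expect_identical(nrow(enumerateNonspliced("ACDEFGHIXKL", cfg_keep)), 3L)
})

test_that("cis enumeration of a 10mer matches the hand-checked scheme set", {
    s <- enumerateCisSpliced("ACDEFGHIKL")
    expect_identical(nrow(s), 32L)
    expect_identical(as.integer(table(s$order)[c("normal", "reverse")]),
                     c(8L, 24L))
    # one specific normal scheme: 'A' + 'DEFGHIKL' over gap 1
    hit <- s[s$s1 == 1 & s$e1 == 1 & s$s2 == 3 & s$e2 == 10, ]
    expect_identical(hit$order, "normal")
    expect_identical(hit$peptide, "ADEFGHIKL")
    # every scheme reconstructs its peptide from the substrate
    rebuilt <- paste0(substring("ACDEFGHIKL", s$s1, s$e1),
                      substring("ACDEFGHIKL", s$s2, s$e2))
    expect_identical(rebuilt, s$peptide)
    expect_true(all(nchar(s$peptide) == 9L))
})

test_that("a 9-residue protein admits exactly the oracle's schemes (gap-0 reverse tilings)", {
    # the quadruple-loop oracle decides this boundary case: the 8 reverse
    # splits with gap 0 tile the window and rotate the sequence
    seq <- "ACDEFGHIK"
    cfg <- enumerationConfig()
    keys <- sort(scheme_keys(enumerateCisSpliced(seq, cfg)))
    oracle <- sort(brute_cis_keys(seq, cfg))
    expect_identical(keys, oracle)
    expect_identical(length(oracle), 8L)
    expect_true(all(enumerateCisSpliced(seq, cfg)$order == "reverse"))
})

test_that("optimized cis enumeration equals the quadruple-loop oracle on random proteins", {
    set.seed(101)
    for (i in 1:30) {
        L <- sample(9:40, 1)
        seq <- random_protein(L)
        cfg <- enumerationConfig(maxIntervening = sample(c(0, 1, 5, 25), 1))
        expect_identical(sort(scheme_keys(enumerateCisSpliced(seq, cfg))),
                         sort(brute_cis_keys(seq, cfg)))
    }
    # also with non-standard residues present
    seq_x <- "ACDXFGHIKLMXNPQRSTV"
    expect_identical(sort(scheme_keys(enumerateCisSpliced(seq_x))),
                     sort(brute_cis_keys(seq_x, enumerationConfig())))
})

test_that("closed-form counts equal enumeration for all lengths and random configs", {
    cfg <- enumerationConfig()
    for (L in 2:60) {
        seq <- random_protein(L)
        expect_identical(countCisSchemes(L, cfg),
                         as.numeric(nrow(enumerateCisSpliced(seq, cfg))))
        expect_identical(countNonspliced(L, cfg),
                         as.numeric(nrow(enumerateNonspliced(seq, cfg))))
    }
    set.seed(55)
    for (i in 1:5) {
        rcfg <- enumerationConfig(
            peptideLength = sample(5:10, 1),
            maxIntervening = sample(0:30, 1),
            minGapNormal = sample(1:3, 1),
            minGapReverse = sample(0:2, 1),
            minReactantLength = sample(1:3, 1))
        for (L in c(2, 7, 9, 13, 21, 40)) {
            seq <- random_protein(L)
            expect_identical(countCisSchemes(L, rcfg),
                             as.numeric(nrow(enumerateCisSpliced(seq, rcfg))))
        }
    }
})

test_that("headline closed-form values: 800 at L=18, 195536 at L=500, ratio ~397.4", {
    expect_identical(countCisSchemes(18), 800)
    s18 <- enumerateCisSpliced(random_protein(18))
    expect_identical(as.integer(table(s18$order)[c("normal", "reverse")]),
                     c(360L, 440L))
    expect_identical(countCisSchemes(500), 195536)
    expect_equal(countCisSchemes(500) / countNonspliced(500), 397.4,
                 tolerance = 1e-3)
    expect_identical(countNonspliced(500), 492)
    expect_identical(countNonspliced(c(10, 9, 500)), c(2, 1, 492))
})

test_that("counts are monotone in protein length and intervening cap; no normal gap-0 scheme", {
    Ls <- 2:80
    expect_true(all(diff(countCisSchemes(Ls)) >= 0))
    counts_by_cap <- vapply(0:30, function(mi)
        countCisSchemes(45, enumerationConfig(maxIntervening = mi)),
        numeric(1))
    expect_true(all(diff(counts_by_cap) >= 0))

    set.seed(77)
    for (i in 1:10) {
        s <- enumerateCisSpliced(random_protein(sample(15:35, 1)))
        expect_false(any(s$order == "normal" & s$intervening == 0))
    }
})

test_that("unique peptide universes deduplicate and are order-stable", {
    u <- uniquePeptides(c("AAAAAAAAA", "AAAAAAAAA", "CCCCCCCCC"),
                        "toy", "nonspliced")
    expect_identical(length(u), 2L)
    u_rev <- uniquePeptides(c("CCCCCCCCC", "AAAAAAAAA"), "toy", "nonspliced")
    expect_identical(peptides(u), peptides(u_rev))
    expect_identical(length(uniquePeptides(character(), "toy", "cis",
                                           peptideLength = 9)), 0L)
    expect_identical(peptides(peptideUniverse(
        Proteome(c(P1 = "ACDEFGHIKL"), "toy"), "nonspliced")),
        sort(c("ACDEFGHIK", "CDEFGHIKL")))
})

test_that("streamed universes agree with per-protein enumeration", {
    set.seed(9)
    prot <- generateProteome(6, 45, seed = 3, name = "u")
    cfg <- enumerationConfig(maxIntervening = 10)
    seqs <- proteinSequences(prot)
    by_enum_cis <- sort(unique(unlist(
        lapply(seqs, function(s) enumerateCisSpliced(s, cfg)$peptide))))
    expect_identical(peptides(peptideUniverse(prot, "cis", cfg)), by_enum_cis)
    by_enum_non <- sort(unique(unlist(
        lapply(seqs, function(s) enumerateNonspliced(s, cfg)$peptide))))
    expect_identical(peptides(peptideUniverse(prot, "nonspliced", cfg)),
                     by_enum_non)
})

test_that("cis decomposition search recovers planted schemes and honours the cap", {
    # build a substrate carrying QLAE ... VVQKV with a 20-residue gap
    set.seed(15)
    bg <- random_protein(120)
    sub <- bg
    substr(sub, 10, 13) <- "QLAE"
    substr(sub, 34, 38) <- "VVQKV"          # intervening 34 - 13 - 1 = 20
    prot <- Proteome(c(HOST = sub), name = "host")
    dec <- findCisDecompositions("QLAEVVQKV", prot)
    expect_true(any(dec$s1 == 10 & dec$e1 == 13 & dec$s2 == 34 &
                    dec$order == "normal" & dec$intervening == 20))

    # a 40-residue gap is invisible at the default cap but found without it
    sub2 <- bg
    substr(sub2, 5, 8) <- "QLAE"
    substr(sub2, 49, 53) <- "VVQKV"         # intervening 40
    prot2 <- Proteome(c(HOST = sub2), name = "host2")
    capped <- findCisDecompositions("QLAEVVQKV", prot2)
    expect_false(any(capped$s1 == 5 & capped$s2 == 49))
    free <- findCisDecompositions("QLAEVVQKV", prot2, maxIntervening = Inf)
    expect_true(any(free$s1 == 5 & free$s2 == 49 & free$intervening == 40))
})
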