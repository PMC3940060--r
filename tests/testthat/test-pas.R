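test_that("OYR is the floored old/young-mean ratio", {
    expect_equal(computeOYR(4, 2), 2)
    expect_equal(computeOYR(3, 3), 1)
    expect_equal(computeOYR(0, 1, floor = 1e-6), 1e-6)
    expect_equal(computeOYR(1, 0, floor = 1e-6), 1e6)
    expect_equal(computeOYR(c(4, 0), c(2, 1)), c(2, 1e-6))
    expect_error(computeOYR(-1, 2), "non-negative")
    expect_error(computeOYR(1, -2), "non-negative")
})

test_that("BTIF requires both the fold and the 2-SD criteria, strictly", {
    ## both criteria met: ratio 2 and 4 SD out
    expect_identical(computeBTIF(2.0, 4, 2, 0.5), 1L)
    ## within the fold tolerance, however large the deviation
    expect_identical(computeBTIF(1.4, 4, 2, 0.5), 0L)
    ## fold criterion met but only ~1.33 SD out
    expect_identical(computeBTIF(2.0, 4, 2, 1.5), 0L)
    ## strict boundaries: exactly 3/2, 2/3 and exactly 2 SD all fail
    expect_identical(computeBTIF(1.5, 3, 2, 0.1), 0L)
    expect_identical(computeBTIF(2 / 3, 2, 3, 0.1), 0L)
    expect_identical(computeBTIF(2.0, 4, 2, 1), 0L)   # deviation exactly 2 SD
    ## just past the boundaries
    expect_identical(computeBTIF(1.5 + 1e-9, 3, 2, 0.1), 1L)
    expect_identical(computeBTIF(2 / 3 - 1e-9, 2, 3, 0.1), 1L)
})

test_that("zero young SD follows the documented convention and is configurable", {
    expect_identical(computeBTIF(4, 8, 2, 0), 1L)       # old != mean -> Inf SD
    expect_identical(computeBTIF(1.0, 2, 2, 0), 0L)     # old == mean -> 0 SD
    expect_identical(computeBTIF(4, 8, 2, 0, sdZero = "fail"), 0L)
    expect_identical(deviationSD(8, 2, 0), Inf)
    expect_identical(deviationSD(2, 2, 0), 0)
    expect_equal(deviationSD(4, 2, 0.5), 4)
})

test_that("PAS is the ARR x BTIF x log(OYR) sum over measured members", {
    p <- RoleAnnotatedPathway("P1", "GENEA", 1)
    expect_equal(computePAS(p, c(GENEA = 10), c(GENEA = 1L))$pas, 1)

    ## everything inside the tolerance interval scores zero
    p2 <- RoleAnnotatedPathway("P2", c("GENEA", "GENEB"), c(1, -1))
    expect_equal(computePAS(p2, c(GENEA = 1.2, GENEB = 0.9),
                            c(GENEA = 0L, GENEB = 0L))$pas, 0)

    ## activator and repressor with equal OYR cancel: +log - log
    expect_equal(computePAS(p2, c(GENEA = 10, GENEB = 10),
                            c(GENEA = 1L, GENEB = 1L))$pas, 0)

    ## unmeasured members are skipped and counted, never imputed
    r <- computePAS(p2, c(GENEA = 10), c(GENEA = 1L))
    expect_equal(r$pas, 1)
    expect_identical(r$skipped, 1L)
    r0 <- computePAS(p2, c(OTHER = 10), c(OTHER = 1L))
    expect_equal(r0$pas, 0)
    expect_identical(r0$skipped, 2L)
})

test_that("PAS is invariant under member-gene permutation", {
    set.seed(21)
    genes <- paste0("G", 1:8)
    arr <- sample(c(-1, -0.5, 0, 0.5, 1), 8, replace = TRUE)
    oyr <- setNames(exp(rnorm(8)), genes)
    btif <- setNames(sample(0:1, 8, replace = TRUE), genes)
    p1 <- RoleAnnotatedPathway("P", genes, arr)
    o <- sample(8)
    p2 <- RoleAnnotatedPathway("P", genes[o], arr[o])
    expect_equal(computePAS(p1, oyr, btif)$pas, computePAS(p2, oyr, btif)$pas)
})

test_that("SPCD is the activator/repressor product ratio and links to log-additivity", {
    expect_equal(computeSPCD(c(2, 3), 2), 3)
    expect_equal(computeSPCD(c(1, 1, 1), c(1, 1)), 1)
    expect_equal(computeSPCD(0, 2, floor = 1e-6), 5e-7)
    expect_error(computeSPCD(-1, 2), "non-negative")

    set.seed(5)
    for (i in 1:20) {
        a <- exp(rnorm(sample(1:6, 1)))
        r <- exp(rnorm(sample(1:6, 1)))
        expect_equal(log(computeSPCD(a, r)), sum(log(a)) - sum(log(r)),
                     tolerance = 1e-12)
    }
})

test_that("PAS with natural log and unit ARR equals log SPCD on OYR values", {
    ## all-activator/all-repressor pathway, BTIF forced to 1: the additive
    ## score is exactly the log of the multiplicative estimator
    set.seed(6)
    for (i in 1:10) {
        nA <- sample(1:5, 1); nR <- sample(1:5, 1)
        genes <- paste0("G", seq_len(nA + nR))
        p <- RoleAnnotatedPathway("P", genes, c(rep(1, nA), rep(-1, nR)))
        oyr <- setNames(exp(rnorm(nA + nR)), genes)
        btif <- setNames(rep(1L, nA + nR), genes)
        expect_equal(computePAS(p, oyr, btif, logBase = exp(1))$pas,
                     log(computeSPCD(oyr[1:nA], oyr[nA + 1:nR])),
                     tolerance = 1e-12)
    }
})

test_that("disturbance norms match hand arithmetic and the zero law", {
    expect_equal(computeDisturbance(c(0, 0, 0)), 0)
    expect_equal(computeDisturbance(c(1, -2), "L1"), 3)
    expect_equal(computeDisturbance(c(3, 4), "L2"), 5)
    expect_error(computeDisturbance(c(1, 2), "L3"))
})

test_that("scoring the toy study recovers the hand-computed profile", {
    rep <- scoreStudy(makeToyStudy(), makeToyCloud())
    ## GENEA: OYR 8/2 = 4 (up, activator), GENEB: OYR 1/4 = 0.25 (down,
    ## repressor); both flagged, both push P1 positive by log10(4)
    expect_equal(unname(pasMean(rep)["P1"]), 2 * log10(4), tolerance = 1e-12)
    expect_equal(unname(pasMean(rep)["P2"]), 0)
    expect_equal(disturbanceMean(rep), 2 * log10(4), tolerance = 1e-12)
    ## identical old samples: per-sample profiles equal the mean profile
    expect_equal(pasMatrix(rep)[, "o1"], pasMatrix(rep)[, "o2"])
    expect_equal(pasMatrix(rep)[, "o1"], pasMean(rep))
})

test_that("old samples equal to the young means give an exactly null profile", {
    rep <- scoreStudy(makeNullStudy(), PathwayCloud(list(
        RoleAnnotatedPathway("P1", c("G1", "G2"), c(1, -1)),
        RoleAnnotatedPathway("P2", c("G3", "G4"), c(0.5, -0.5)))))
    expect_true(all(pasMatrix(rep) == 0))
    expect_identical(disturbanceMean(rep), 0)
    expect_identical(unname(disturbance(rep)), c(0, 0))
})

test_that("raising an activator never lowers PAS; raising a repressor never raises it", {
    st <- makeToyStudy()
    cloud <- makeToyCloud()
    base <- unname(pasMean(scoreStudy(st, cloud))["P1"])
    for (mult in c(1.5, 2, 5)) {
        v <- exprValues(st)
        v["GENEA", c("o1", "o2")] <- v["GENEA", c("o1", "o2")] * mult
        up <- scoreStudy(ExpressionStudy(v, cohort(st)), cloud)
        expect_gte(unname(pasMean(up)["P1"]), base)

        v2 <- exprValues(st)
        v2["GENEB", c("o1", "o2")] <- v2["GENEB", c("o1", "o2")] * mult
        dn <- scoreStudy(ExpressionStudy(v2, cohort(st)), cloud)
        expect_lte(unname(pasMean(dn)["P1"]), base)
    }
})

test_that("changing the log base rescales PAS by the expected factor", {
    sim <- simulateStudy(simulationConfig(seed = 9))
    p10 <- pasMean(scoreStudy(sim$study, sim$cloud, logBase = 10))
    p2 <- pasMean(scoreStudy(sim$study, sim$cloud, logBase = 2))
    expect_equal(p2, p10 * log2(10), tolerance = 1e-9)
})

test_that("scoring degenerate inputs errors or warns as designed", {
    st <- makeToyStudy()
    expect_error(scoreStudy(st, PathwayCloud()), "nothing to score")
    ## a pathway none of whose members is measured is flagged
    cloud <- PathwayCloud(list(RoleAnnotatedPathway("PX", "ABSENT", 1)))
    expect_warning(rep <- scoreStudy(st, cloud), "unmeasured pathway")
    expect_equal(unname(pasMean(rep)["PX"]), 0)
    expect_identical(skippedGenes(rep)[["PX"]], 1L)
})

test_that("the PAS report TSV carries per-sample columns and the disturbance row", {
    rep <- scoreStudy(makeToyStudy(), makeToyCloud())
    tf <- withr::local_tempfile(fileext = ".tsv")
    writePASReport(rep, tf)
    tab <- utils::read.delim(tf, check.names = FALSE)
    expect_identical(colnames(tab), c("pathway_id", "o1", "o2", "pas_mean"))
    expect_identical(tab$pathway_id, c("P1", "P2", "__disturbance__"))
    expect_equal(as.numeric(tab[3, "pas_mean"]), disturbanceMean(rep),
                 tolerance = 1e-9)
})
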