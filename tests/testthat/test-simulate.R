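test_that("simulation is a deterministic function of the configuration seed", {
    cfg <- simulationConfig(seed = 101)
    s1 <- simulateStudy(cfg)
    s2 <- simulateStudy(cfg)
    expect_identical(exprValues(s1$study), exprValues(s2$study))
    expect_identical(pathwayIds(s1$cloud), pathwayIds(s2$cloud))
    expect_identical(s1$truth$geneShifts, s2$truth$geneShifts)
    expect_identical(s1$truth$seed, 101L)

    l1 <- simulateDrugLibrary(s1$truth)
    l2 <- simulateDrugLibrary(s2$truth)
    expect_identical(drugEffects(l1$library), drugEffects(l2$library))

    s3 <- simulateStudy(simulationConfig(seed = 102))
    expect_false(identical(exprValues(s1$study), exprValues(s3$study)))
})

test_that("configuration invariants are enforced", {
    expect_error(simulationConfig(nPathways = 6, genesPerPathway = 10,
                                  nGenes = 50), "exceeds nGenes")
    expect_error(simulationConfig(nYoung = 1))
    expect_error(simulationConfig(perturbations = data.frame(
        pathway = 1L, direction = "activated", fold = -2)))
    expect_error(simulationConfig(perturbations = data.frame(
        pathway = 9L, direction = "activated", fold = 2)))
})

test_that("a null simulation (no shift, no noise) scores exactly zero disturbance", {
    cfg <- simulationConfig(noiseSd = 0, seed = 5,
                            perturbations = data.frame(
                                pathway = 1L, direction = "activated",
                                fold = 1))
    sim <- simulateStudy(cfg)
    rep <- scoreStudy(sim$study, sim$cloud)
    expect_true(all(pasMatrix(rep) == 0))
    expect_identical(disturbanceMean(rep), 0)

    ## with mild noise and no planted shift, disturbance stays small
    simn <- simulateStudy(simulationConfig(seed = 5, perturbations =
        data.frame(pathway = 1L, direction = "activated", fold = 1)))
    expect_lt(disturbanceMean(scoreStudy(simn$study, simn$cloud)), 0.5)
})

test_that("a planted activated pathway is the unique nonzero, positive PAS entry", {
    sim <- simulateStudy(simulationConfig(noiseSd = 0, seed = 23))
    rep <- scoreStudy(sim$study, sim$cloud)
    planted <- sim$truth$perturbedPathways
    expect_identical(planted, "SIMP01")
    expect_gt(pasMean(rep)[planted], 0)
    expect_true(all(pasMean(rep)[setdiff(names(pasMean(rep)), planted)] == 0))

    ## hand value: every member with ARR != 0 contributes |ARR| * log10(4)
    arr <- members(sim$cloud[[planted]])$arr
    expect_equal(unname(pasMean(rep)[planted]),
                 sum(abs(arr)) * log10(4), tolerance = 1e-9)

    ## a repressed planting drives PAS negative
    simr <- simulateStudy(simulationConfig(noiseSd = 0, seed = 23,
        perturbations = data.frame(pathway = 1L, direction = "repressed",
                                   fold = 4)))
    expect_lt(pasMean(scoreStudy(simr$study, simr$cloud))["SIMP01"], 0)
})

test_that("observed OYR of perturbed genes matches the planted fold over replicates", {
    reps <- 200
    obs <- numeric(0)
    for (s in seq_len(reps)) {
        sim <- simulateStudy(simulationConfig(nGenes = 10, nPathways = 1,
                                              genesPerPathway = 5, seed = s))
        up <- names(sim$truth$geneShifts)[sim$truth$geneShifts == 4]
        if (length(up) == 0) next
        g <- up[1]
        ref <- youngReference(sim$study)
        obs <- c(obs, exprValues(sim$study)[g, oldSamples(sim$study)[1]] /
                          ref[g, "mean"])
    }
    expect_gt(length(obs), 150)
    se <- sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - 4), 3 * se)
})

test_that("the simulated antidote restores old values to the young means when noise-free", {
    sim <- simulateStudy(simulationConfig(noiseSd = 0, seed = 29))
    lib <- simulateDrugLibrary(sim$truth)
    folds <- with(subset(drugEffects(lib$library), drug_id == "antidote"),
                  setNames(fold_change, gene))
    treated <- applyDrug(sim$study, folds)
    ref <- youngReference(treated)
    olds <- oldSamples(treated)
    for (s in olds)
        expect_equal(exprValues(treated)[, s], setNames(ref$mean, rownames(ref)),
                     tolerance = 1e-12)
    expect_equal(disturbanceMean(scoreStudy(treated, sim$cloud)), 0)

    ## library composition: a null drug with fold 1 is always present
    eff <- drugEffects(lib$library)
    expect_true(all(eff$fold_change[eff$drug_id == "null"] == 1))
    expect_setequal(lib$labels$type,
                    c("antidote", "partial", "distractor", "null"))
})

test_that("a drug that touches no pathway member leaves D unchanged", {
    ## 60 genes but only 50 in pathways: 10 genes sit outside the cloud
    sim <- simulateStudy(simulationConfig(nGenes = 60, noiseSd = 0, seed = 37))
    base <- disturbanceMean(scoreStudy(sim$study, sim$cloud))
    in_cloud <- unlist(lapply(pathwayIds(sim$cloud), function(id)
        members(sim$cloud[[id]])$gene))
    clean <- setdiff(names(sim$truth$geneShifts), in_cloud)
    expect_gte(length(clean), 2)
    treated <- applyDrug(sim$study, setNames(c(2, 0.5), clean[1:2]))
    expect_equal(disturbanceMean(scoreStudy(treated, sim$cloud)), base)
})

test_that("ORA on the perturbed members recovers every planted pathway", {
    for (s in c(41, 42, 43)) {
        sim <- simulateStudy(simulationConfig(seed = s, perturbations =
            data.frame(pathway = c(1L, 3L), direction = "activated",
                       fold = c(4, 4))))
        res <- runORA(sim$truth$perturbedMembers, sim$cloud,
                      universeSize = sim$truth$config$nGenes)
        expect_true(all(sim$truth$perturbedPathways %in% res$pathway_id))
        expect_true(all(res$p_value < 0.01))
        expect_true(all(res$overlap_count >= 2))
    }
})

test_that("simulation files round-trip through the package readers", {
    dir <- withr::local_tempdir()
    sim <- simulateStudy(simulationConfig(seed = 47))
    lib <- simulateDrugLibrary(sim$truth, nDistractors = 2)
    writeSimulation(sim, lib$library, dir)
    st <- readExpression(file.path(dir, "expr.tsv"), file.path(dir, "meta.tsv"))
    expect_equal(exprValues(st), exprValues(sim$study), tolerance = 1e-6)
    cl <- readPathwayFile(file.path(dir, "cloud.tsv"))
    expect_identical(pathwayIds(cl), pathwayIds(sim$cloud))
    dr <- readDrugLibrary(file.path(dir, "drugs.tsv"))
    expect_identical(drugIds(dr), drugIds(lib$library))
    truth <- utils::read.delim(file.path(dir, "truth.tsv"))
    expect_equal(setNames(truth$planted_shift, truth$gene),
                 sim$truth$geneShifts, tolerance = 1e-6)
})
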