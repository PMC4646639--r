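test_that("simulation is fully deterministic given a seed", {
  d1 <- simulateDesign(seed = 7, preset = "table1")
  d2 <- simulateDesign(seed = 7, preset = "table1")
  expect_identical(probes(d1), probes(d2))
  cfg <- simulationConfig(seed = 8)
  tr <- truthSet(data.frame(gene = "BRCA1", exon_from = 1, exon_to = 5,
                            copies = 1, origin = "germline"))
  a <- simulateCounts(d1, tr, cfg, "detection", sampleId = "x")
  cfg2 <- simulationConfig(seed = 8)
  set.seed(cfg$seed); ca <- probeCounts(simulateCounts(d1, tr, cfg, "detection"))
  set.seed(cfg2$seed); cb <- probeCounts(simulateCounts(d1, tr, cfg2, "detection"))
  expect_identical(ca, cb)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulateFastq(a, d1, f1); simulateFastq(a, d1, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("noise-free simulation reproduces dosage exactly", {
  d <- tinyDesign()
  cfg <- simulationConfig(seed = 5, probeNoiseSd = 0, poisson = FALSE)
  eff <- simulateEfficiency(d, seed = 6)
  dns <- lapply(1:3, function(i)
    depthNormalize(simulateCounts(d, truthSet(), cfg, "detection", eff,
                                  sprintf("c%d", i)), d))
  bl <- buildBaseline(dns, d)
  # diploid: every ratio exactly 1
  dip <- simulateCounts(d, truthSet(), cfg, "detection", eff, "dip")
  r0 <- cnvRatios(computeRatios(depthNormalize(dip, d), bl, d))
  expect_equal(unname(r0), rep(1, length(r0)), tolerance = 1e-3)
  # heterozygous deletion: affected ratios exactly 0.5
  tr <- truthSet(data.frame(gene = "GENE1", exon_from = 1, exon_to = 4,
                            copies = 1, origin = "germline"))
  del <- simulateCounts(d, tr, cfg, "detection", eff, "del")
  r <- cnvRatios(computeRatios(depthNormalize(del, d), bl, d))
  p <- probes(d)
  det <- p[p$mix %in% c("detection", "both"), ]
  hit <- intersect(det$probe_id[det$gene == "GENE1"], names(r))
  # deleted probes shrink the normalizer: X drops by the efficiency-weighted
  # dose deficit over the non-amplification probes
  nonAmp <- det$probe_id[!(det$gene %in% d@amplificationGenes)]
  dose <- ifelse(nonAmp %in% hit, 0.5, 1)
  shift <- sum(eff[nonAmp] * dose) / sum(eff[nonAmp])
  nDel <- length(hit)
  expect_equal(unname(r[hit]), rep(0.5 / shift, nDel), tolerance = 0.01)
  other <- setdiff(names(r), c(hit, det$probe_id[det$gene %in%
                                                 d@amplificationGenes]))
  expect_equal(unname(r[other]), rep(1 / shift, length(other)),
               tolerance = 0.01)
})

test_that("somatic events are diluted by tumour purity", {
  d <- tinyDesign()
  tr <- truthSet(data.frame(gene = "GENE1", exon_from = 1, exon_to = 1,
                            copies = 0, origin = "somatic"), purity = 0.5)
  cp <- mlpaseq:::expectedProbeCopies(d, tr)
  p <- probes(d)
  hit <- p$probe_id[p$exon_label == "GENE1_ex01"]
  expect_equal(unname(cp[hit]), rep(1, length(hit)))  # 0.5*0 + 0.5*2
  expect_true(all(cp[setdiff(names(cp), hit)] == 2))
})

test_that("per-probe ratio noise is recovered at the configured SD", {
  d <- simulateDesign(nGenes = 4L, exonsPerGene = 10L, probesPerExon = 1L,
                      nReference = 5L, seed = 71L)
  cfg <- simulationConfig(seed = 72, targetDepth = 5000)  # damp Poisson part
  set.seed(cfg$seed)
  libs <- lapply(1:20, function(i)
    simulateCounts(d, truthSet(), cfg, "detection", sampleId = i))
  vals <- vapply(libs, function(l) normValues(depthNormalize(l, d)),
                 numeric(length(probeCounts(libs[[1]]))))
  cvs <- apply(vals, 1L, function(v) sd(v) / mean(v))
  expect_equal(mean(cvs), 0.103, tolerance = 0.1)
})

test_that("FASTQ output round-trips through the read counter exactly", {
  d <- tinyDesign()
  cfg <- simulationConfig(seed = 81, targetDepth = 40)
  set.seed(cfg$seed)
  lib <- simulateCounts(d, truthSet(), cfg, "confirmation", sampleId = "s")
  path <- withr::local_tempfile(fileext = ".fastq.gz")
  simulateFastq(lib, d, path)
  lib2 <- countProbes(path, d, "confirmation", sampleId = "s")
  expect_identical(probeCounts(lib2)[names(probeCounts(lib))],
                   probeCounts(lib))
  # zero counts give a valid empty FASTQ
  zero <- libraryCounts("z", "detection",
                        setNames(integer(3), probeIds(d)[1:3]))
  pz <- withr::local_tempfile(fileext = ".fastq")
  simulateFastq(zero, d, pz)
  expect_equal(sum(probeCounts(countProbes(pz, d, "detection"))), 0L)
})

test_that("call evaluation scores sensitivity and specificity", {
  d <- simulateDesign(nGenes = 1L, exonsPerGene = 10L, probesPerExon = 1L,
                      nReference = 2L, seed = 91L)
  et <- mlpaseq:::exonTable(d)
  tr <- truthSet(data.frame(gene = "GENE1", exon_from = 2, exon_to = 4,
                            copies = 1, origin = "germline"))
  perfect <- data.frame(gene = et$gene, exon_label = et$exon_label,
                        category = "normal", stringsAsFactors = FALSE)
  idx <- match(paste0("GENE1_ex", sprintf("%02d", 2:4)), perfect$exon_label)
  perfect$category[idx] <- "het_deletion"
  ev <- evaluateCalls(perfect, tr, d)
  expect_equal(ev$sensitivity, 100)
  expect_equal(ev$specificity, 100)
  # all-normal calls miss the event but stay fully specific
  none <- perfect; none$category <- "normal"
  ev2 <- evaluateCalls(none, tr, d)
  expect_equal(ev2$sensitivity, 0)
  expect_equal(ev2$specificity, 100)
  # wrong direction does not count as detection
  wrong <- none; wrong$category[idx] <- "duplication"
  expect_equal(evaluateCalls(wrong, tr, d)$sensitivity, 0)
})

test_that("specificity arithmetic matches the negative-exon bookkeeping", {
  # 766 truly two-copy exon regions with 4 false calls: (766-4)/766
  d <- simulateDesign(nGenes = 1L, exonsPerGene = 766L, probesPerExon = 1L,
                      nReference = 1L, seed = 92L)
  et <- mlpaseq:::exonTable(d)
  g1 <- et[et$gene == "GENE1", ]
  calls <- data.frame(gene = g1$gene, exon_label = g1$exon_label,
                      category = "normal", stringsAsFactors = FALSE)
  calls$category[c(10, 200, 400, 600)] <- "duplication"
  ev <- evaluateCalls(calls, truthSet(), d)
  expect_equal(ev$n_negative, 766L)
  expect_equal(ev$n_false, 4L)
  expect_equal(ev$specificity, 100 * 762 / 766)
  expect_gt(ev$specificity, 99.4)
})

test_that("heavy dropout produces QC-failing libraries", {
  d <- tinyDesign()
  cfg <- simulationConfig(seed = 93, dropoutRate = 0.2)
  set.seed(cfg$seed)
  fails <- vapply(1:10, function(i) {
    lib <- simulateCounts(d, truthSet(), cfg, "detection",
                          sampleId = sprintf("low%d", i))
    qc <- qcLibrary(lib)
    !qc$pass || qc$n_probes_below_floor > 0L
  }, logical(1))
  expect_gt(sum(fails), 0L)
})

test_that("simulated cohorts carry one multi-exon germline event per case", {
  d <- tinyDesign()
  cfg <- simulationConfig(seed = 94, nControls = 3L)
  coh <- simulateCohort(d, cfg, nCases = 5L, minExons = 2L, maxExons = 3L)
  expect_length(coh$controls, 3L)
  expect_length(coh$cases, 5L)
  for (cs in coh$cases) {
    ev <- cs$truth$events
    expect_equal(nrow(ev), 1L)
    expect_gte(ev$exon_to - ev$exon_from + 1L, 2L)
    expect_true(ev$copies %in% c(1L, 3L))
    expect_equal(ev$origin, "germline")
    expect_s4_class(cs$detection, "LibraryCounts")
    expect_s4_class(cs$confirmation, "LibraryCounts")
  }
})
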