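test_that("depth normalization divides by the non-amplification mean", {
  d <- tinyDesign()
  p <- probesForMixLocal <- probes(d)
  det <- p[p$mix %in% c("detection", "both"), ]
  nonAmp <- det$probe_id[!(det$gene %in% d@amplificationGenes)]
  amp <- det$probe_id[det$gene %in% d@amplificationGenes]
  x <- setNames(rep(0L, nrow(det)), det$probe_id)
  x[nonAmp[1:4]] <- c(100L, 200L, 300L, 400L)
  x[setdiff(nonAmp, nonAmp[1:4])] <- 250L
  dn <- depthNormalize(libraryCounts("s", "detection", x), d)
  expect_equal(dn@normalizer, 250)
  expect_equal(unname(normValues(dn)[nonAmp[1:4]]), c(0.4, 0.8, 1.2, 1.6))
  expect_equal(mean(normValues(dn)[nonAmp]), 1, tolerance = 1e-12)
})

test_that("normalization is scale-invariant and idempotent", {
  d <- tinyDesign()
  cfg <- simulationConfig(seed = 21, poisson = FALSE)
  lib <- simulateCounts(d, truthSet(), cfg, "detection", sampleId = "s")
  v1 <- normValues(depthNormalize(lib, d))
  x7 <- probeCounts(lib) * 7L
  v7 <- normValues(depthNormalize(libraryCounts("s", "detection", x7), d))
  expect_equal(v1, v7, tolerance = 1e-12)
  # values already have unit non-amplification mean: renormalising a library
  # whose counts are proportional to the values changes nothing
  big <- libraryCounts("s", "detection", round(v1 * 1e7))
  v2 <- normValues(depthNormalize(big, d))
  expect_equal(v2, v1, tolerance = 1e-6)
  zero <- libraryCounts("s", "detection", probeCounts(lib) * 0L)
  expect_error(depthNormalize(zero, d), "X is 0")
})

test_that("amplification-gene probes never influence the normalizer", {
  d <- tinyDesign()
  p <- probes(d)
  det <- p[p$mix %in% c("detection", "both"), ]
  amp <- det$probe_id[det$gene %in% d@amplificationGenes]
  expect_gt(length(amp), 0L)
  x <- setNames(rep(500L, nrow(det)), det$probe_id)
  base <- normValues(depthNormalize(libraryCounts("s", "detection", x), d))
  x2 <- x; x2[amp] <- 500000L   # thousand-fold amplification
  up <- normValues(depthNormalize(libraryCounts("s", "detection", x2), d))
  others <- setdiff(names(x), amp)
  expect_equal(up[others], base[others], tolerance = 1e-12)
  expect_equal(unname(up[amp]), rep(1000, length(amp)))
})

test_that("baselines average controls and flag noisy probes", {
  v <- c(p1 = 1.0, p2 = 0.9, p3 = 1.2)
  d <- tinyDesign()
  same <- list(dnFromValues(v), dnFromValues(v))
  bl <- buildBaseline(same, d, minControls = 2L)
  expect_equal(baselineMeans(bl), v)
  expect_equal(unname(bl@perProbeCV), rep(0, 3))
  two <- list(dnFromValues(c(p1 = 0.9)), dnFromValues(c(p1 = 1.1)))
  bl2 <- buildBaseline(two, d, minControls = 2L)
  expect_equal(unname(baselineMeans(bl2)), 1.0)
  expect_error(buildBaseline(two, d, minControls = 3L), "at least 3")
  # a probe wobbling far beyond the CV cap is unusable
  noisy <- list(dnFromValues(c(p1 = 1, p2 = 0.2)),
                dnFromValues(c(p1 = 1, p2 = 1.8)))
  bl3 <- buildBaseline(noisy, d, minControls = 2L)
  expect_false(bl3@usable[["p2"]])
  expect_true(bl3@usable[["p1"]])
})

test_that("control-sample noise at the assay operating point recovers the
           per-probe CV", {
  d <- simulateDesign(nGenes = 3L, exonsPerGene = 8L, probesPerExon = 1L,
                      nReference = 4L, seed = 2L)
  cfg <- simulationConfig(seed = 31)
  eff <- simulateEfficiency(d, seed = 32)
  dns <- lapply(1:8, function(i)
    depthNormalize(simulateCounts(d, truthSet(), cfg, "detection", eff,
                                  sprintf("c%d", i), isControl = TRUE), d))
  bl <- buildBaseline(dns, d)
  # noise SD 0.103 plus ~3% Poisson at 1000x; CV averaged over many probes
  expect_equal(mean(bl@perProbeCV), 0.107, tolerance = 0.15)
})

test_that("ratios are identity on the baseline and scale with dosage", {
  d <- tinyDesign()
  ids <- probes(d)$probe_id[probes(d)$mix %in% c("detection", "both")]
  v <- setNames(seq(0.5, 1.5, length.out = length(ids)), ids)
  bl <- buildBaseline(list(dnFromValues(v), dnFromValues(v)), d,
                      minControls = 2L)
  r1 <- cnvRatios(computeRatios(dnFromValues(v), bl, d))
  expect_equal(unname(r1), rep(1, length(ids)))
  r2 <- cnvRatios(computeRatios(dnFromValues(v * 0.5), bl, d))
  expect_equal(unname(r2), rep(0.5, length(ids)))
  # checksum guard
  d2 <- tinyDesign(seed = 999L)
  expect_error(computeRatios(dnFromValues(v), bl, d2), "checksum")
})

test_that("simulated heterozygous deletions give ratios near 0.5", {
  d <- tinyDesign()
  cfg <- simulationConfig(seed = 41)
  eff <- simulateEfficiency(d, seed = 42)
  dns <- lapply(1:8, function(i)
    depthNormalize(simulateCounts(d, truthSet(), cfg, "detection", eff,
                                  sprintf("c%d", i)), d))
  bl <- buildBaseline(dns, d)
  tr <- truthSet(data.frame(gene = "GENE1", exon_from = 2, exon_to = 3,
                            copies = 1, origin = "germline"))
  case <- simulateCounts(d, tr, cfg, "detection", eff, "case")
  r <- cnvRatios(computeRatios(depthNormalize(case, d), bl, d))
  p <- probes(d)
  hit <- p$probe_id[p$gene == "GENE1" &
                    p$exon_label %in% c("GENE1_ex02", "GENE1_ex03") &
                    p$mix == "detection"]
  other <- setdiff(names(r), hit)
  expect_true(all(abs(r[hit] - 0.5) < 3 * 0.103))
  expect_true(all(abs(r[other] - 1) < 4 * 0.12))
})

test_that("exon summaries pool probes with sample SD", {
  d <- tinyDesign()
  p <- probes(d)
  ex1 <- p$exon_label[p$gene == "GENE1"][1]
  ids <- p$probe_id[p$exon_label == ex1]   # detection + confirmation probe
  expect_length(ids, 2L)
  det <- new("RatioMatrix", sampleId = "s", mix = "detection",
             ratios = setNames(0.9, ids[1]),
             excluded = data.frame(probe_id = character(),
                                   reason = character()))
  conf <- new("RatioMatrix", sampleId = "s", mix = "confirmation",
              ratios = setNames(1.1, ids[2]),
              excluded = data.frame(probe_id = character(),
                                    reason = character()))
  ex <- summarizeExons(det, conf, d)
  row <- ex[ex$exon_label == ex1, ]
  expect_equal(row$mean_ratio, 1.0)
  expect_equal(row$sd_ratio, sd(c(0.9, 1.1)))
  expect_equal(row$n_probes, 2L)
  # exons with no usable probes are flagged, not dropped
  expect_true(all(ex$missing[ex$n_probes == 0L]))
  expect_equal(nrow(ex), length(unique(p$exon_label)))
  # a single-probe exon has sd 0
  only <- summarizeExons(det, NULL, d)
  expect_equal(only$sd_ratio[only$exon_label == ex1], 0)
  expect_equal(only$mean_ratio[only$exon_label == ex1], 0.9)
})

test_that("pooling k independent probes shrinks exon SD like 1/sqrt(k)", {
  set.seed(90)
  for (k in 2:4) {
    m <- matrix(rnorm(6000 * k, mean = 1, sd = 0.103), ncol = k)
    expect_equal(sd(rowMeans(m)), 0.103 / sqrt(k), tolerance = 0.05)
  }
})

test_that("a large deletion spanning normalization probes inflates the rest", {
  # the assay's known false-positive mechanism: deleted probes stay in the
  # normalization mean, so every other ratio rises; asserted directionally
  d <- simulateDesign(nGenes = 2L, exonsPerGene = 10L, probesPerExon = 1L,
                      nReference = 2L, seed = 55L)
  cfg <- simulationConfig(seed = 56, probeNoiseSd = 0, poisson = FALSE)
  dns <- lapply(1:3, function(i)
    depthNormalize(simulateCounts(d, truthSet(), cfg, "detection",
                                  sampleId = sprintf("c%d", i)), d))
  bl <- buildBaseline(dns, d)
  tr <- truthSet(data.frame(gene = "GENE1", exon_from = 1, exon_to = 10,
                            copies = 1, origin = "germline"))
  case <- simulateCounts(d, tr, cfg, "detection", sampleId = "case")
  r <- cnvRatios(computeRatios(depthNormalize(case, d), bl, d))
  p <- probes(d)
  unaffected <- p$probe_id[p$gene != "GENE1" &
                           p$mix %in% c("detection", "both")]
  expect_true(all(r[unaffected] > 1))
})

test_that("baselines persist to disk with a design checksum guard", {
  d <- tinyDesign()
  cfg <- simulationConfig(seed = 61)
  dns <- lapply(1:4, function(i)
    depthNormalize(simulateCounts(d, truthSet(), cfg, "detection",
                                  sampleId = sprintf("c%d", i)), d))
  bl <- buildBaseline(dns, d)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeBaseline(bl, path)
  bl2 <- readBaseline(path, d)
  expect_equal(baselineMeans(bl2), baselineMeans(bl))
  expect_equal(bl2@usable, bl@usable)
  expect_equal(bl2@nControls, bl@nControls)
  expect_error(readBaseline(path, tinyDesign(seed = 999L)), "checksum")
})
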