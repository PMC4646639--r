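# Synthetic-data generation: probe designs, truth sets, count matrices,
# FASTQ reads, and truth-aware evaluation of calls.

#' Simulation settings
#'
#' Defaults mirror the assay's operating point: ~1000-fold per-probe
#' coverage, per-probe copy-ratio noise with standard deviation 0.103 across
#' control samples, eight accumulated controls, and fixed per-probe
#' efficiency multipliers (spread 0.25) shared by all libraries of a run so
#' that, like real probe biases, they cancel against the control baseline.
#' Quality tiers emulate increasingly degraded (FFPE/low-input) DNA as a
#' noise multiplier plus per-probe dropout.
#'
#' @param seed integer seed; mandatory, every simulation is reproducible.
#' @param nControls number of control samples (default 8).
#' @param targetDepth expected reads per probe (default 1000).
#' @param probeNoiseSd ratio-scale noise SD per probe (default 0.103).
#' @param probeEfficiencySpread SD (log scale) of the fixed per-probe
#'   efficiency multipliers (default 0.25).
#' @param dropoutRate per-probe zero-inflation probability (default 0).
#' @param qualityTier one of "very_good", "good", "moderate", "poor",
#'   "very_poor"; scales noise and dropout multiplicatively on top of the
#'   explicit settings.
#' @param poisson logical; Poisson-sample the final counts (default TRUE).
#'   Disable for exact expected counts in analytic checks.
#' @return A list of class \code{SimulationConfig} with the resolved noise
#'   SD and dropout rate.
#' @export
simulationConfig <- function(seed, nControls = 8L, targetDepth = 1000,
                             probeNoiseSd = 0.103,
                             probeEfficiencySpread = 0.25,
                             dropoutRate = 0,
                             qualityTier = c("very_good", "good", "moderate",
                                             "poor", "very_poor"),
                             poisson = TRUE) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  qualityTier <- match.arg(qualityTier)
  tiers <- list(very_good = c(noise = 1.0, dropout = 0.00),
                good      = c(noise = 1.2, dropout = 0.00),
                moderate  = c(noise = 1.5, dropout = 0.01),
                poor      = c(noise = 2.0, dropout = 0.05),
                very_poor = c(noise = 3.0, dropout = 0.10))
  tier <- tiers[[qualityTier]]
  stopifnot(targetDepth > 0, probeNoiseSd >= 0, probeEfficiencySpread >= 0,
            dropoutRate >= 0, dropoutRate <= 1)
  structure(list(seed = as.integer(seed), nControls = as.integer(nControls),
                 targetDepth = targetDepth,
                 probeNoiseSd = probeNoiseSd * tier[["noise"]],
                 probeEfficiencySpread = probeEfficiencySpread,
                 dropoutRate = min(1, dropoutRate + tier[["dropout"]]),
                 qualityTier = qualityTier, poisson = poisson),
            class = "SimulationConfig")
}

randomDna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

makeProbeRows <- function(gene, exonIdx, suffix, mix, role, armLen = 25L) {
  n <- length(exonIdx)
  data.frame(
    probe_id = paste0(gene, "_ex", exonIdx, suffix, "_",
                      substr(mix, 1, 3)),
    gene = gene,
    exon_label = paste0(gene, "_ex", sprintf("%02d", exonIdx)),
    mix = mix, role = role,
    leftArm = randomDna(n, armLen), rightArm = randomDna(n, armLen),
    stringsAsFactors = FALSE)
}

finishDesign <- function(rows, adapters = nexteraAdapters(), maxTries = 20L) {
  for (try in seq_len(maxTries)) {
    keys <- deriveMiddleKey(rows$leftArm, rows$rightArm)
    collide <- logical(nrow(rows))
    for (m in c("detection", "confirmation")) {
      inMix <- rows$mix %in% c(m, "both")
      km <- keys[inMix]
      collide[inMix] <- collide[inMix] |
        duplicated(km) | duplicated(km, fromLast = TRUE)
    }
    if (!any(collide)) break
    if (try == maxTries) stop("could not resolve middle-key collisions")
    # redraw all but the first holder of each colliding key
    redo <- collide & duplicated(keys)
    if (!any(redo)) redo <- collide
    rows$leftArm[redo] <- randomDna(sum(redo), nchar(rows$leftArm[1]))
    rows$rightArm[redo] <- randomDna(sum(redo), nchar(rows$rightArm[1]))
  }
  rows$left_seq <- paste0(adapters[["left"]], rows$leftArm)
  rows$right_seq <- paste0(rows$rightArm, adapters[["right"]])
  rows$leftArm <- NULL; rows$rightArm <- NULL
  probeDesign(rows, adapters)
}

#' Simulate a probe design
#'
#' Generates random, non-colliding hybridising arms (25 bases each, giving
#' ~60 bp ligated inserts once adapters are stripped) for a configurable
#' panel, or — with \code{preset = "table1"} — a panel that reproduces the
#' published per-gene probe counts of the ovarian-cancer assay: 157 probes
#' over BRCA1 (52, half confirmation), BRCA2 (64, 33 confirmation), PTEN
#' (20), single- or two-probe amplification targets (ERBB2, MYC, MET, CCNE1,
#' AURKA, EMSY), NF1, RB1, four PTEN-deletion-confirmation genes and seven
#' reference genes. The detection/confirmation partition is the generator's
#' own and is recorded in the design table.
#'
#' @param nGenes,exonsPerGene,probesPerExon,nReference panel shape for the
#'   generic generator (ignored with a preset).
#' @param nAmplification number of single-exon amplification-target genes
#'   (generic generator; default 0).
#' @param seed integer seed.
#' @param preset NULL or "table1".
#' @return A validated [ProbeDesign-class].
#' @export
simulateDesign <- function(nGenes = 3L, exonsPerGene = 10L,
                           probesPerExon = 1L, nReference = 5L,
                           nAmplification = 0L, seed, preset = NULL) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  set.seed(seed)
  if (!is.null(preset)) {
    preset <- match.arg(preset, "table1")
    rows <- rbind(
      makeProbeRows("BRCA1", 1:24, "", "detection", "target_deletion"),
      makeProbeRows("BRCA1", c(12, 12), c("b", "c"), "detection",
                    "target_deletion"),
      makeProbeRows("BRCA1", 1:24, "", "confirmation", "target_deletion"),
      makeProbeRows("BRCA1", c(12, 12), c("b", "c"), "confirmation",
                    "target_deletion"),
      makeProbeRows("BRCA2", 1:27, "", "detection", "target_deletion"),
      makeProbeRows("BRCA2", c(2, 3, 11, 27), "b", "detection",
                    "target_deletion"),
      makeProbeRows("BRCA2", 1:27, "", "confirmation", "target_deletion"),
      makeProbeRows("BRCA2", c(2, 3, 11, 17, 22, 27), "b", "confirmation",
                    "target_deletion"),
      makeProbeRows("PTEN", rep(1:9, length.out = 20),
                    rep(c("", "b", "c"), times = c(9, 9, 2)),
                    "detection", "target_deletion"),
      makeProbeRows("ERBB2", c(7, 13), "", "both", "target_amplification"),
      makeProbeRows("MYC", 3, "", "both", "target_amplification"),
      makeProbeRows("MET", 4, "", "both", "target_amplification"),
      makeProbeRows("CCNE1", c(6, 11), "", "both", "target_amplification"),
      makeProbeRows("NF1", 26, "", "both", "target_deletion"),
      makeProbeRows("RB1", 6, "", "both", "target_deletion"),
      makeProbeRows("AURKA", 10, "", "both", "target_amplification"),
      makeProbeRows("EMSY", 16, "", "both", "target_amplification"),
      makeProbeRows("PTENP1", 1, "", "confirmation", "pten_pseudogene"),
      makeProbeRows("ITIH5", 1, "", "confirmation", "pten_flank"),
      makeProbeRows("ANXA7", 1, "", "confirmation", "pten_flank"),
      makeProbeRows("HTRA1", 1, "", "confirmation", "pten_flank"))
    for (g in c("CFTR", "GCH1", "JAG1", "OPTN", "GPC3", "PANK2", "FLCN"))
      rows <- rbind(rows, makeProbeRows(g, 1, "", "both", "reference"))
    return(finishDesign(rows))
  }
  stopifnot(nGenes > 0, exonsPerGene > 0, probesPerExon > 0, nReference > 0,
            nAmplification >= 0)
  rows <- NULL
  for (g in seq_len(nGenes)) {
    idx <- rep(seq_len(exonsPerGene), each = probesPerExon)
    sfx <- rep(letters[seq_len(probesPerExon)], times = exonsPerGene)
    if (probesPerExon == 1L) sfx <- ""
    rows <- rbind(rows,
      makeProbeRows(paste0("GENE", g), idx, sfx, "detection",
                    "target_deletion"),
      makeProbeRows(paste0("GENE", g), idx, paste0(sfx, "q"), "confirmation",
                    "target_deletion"))
  }
  for (a in seq_len(nAmplification))
    rows <- rbind(rows, makeProbeRows(paste0("AMP", a), 1, "", "both",
                                      "target_amplification"))
  for (r in seq_len(nReference))
    rows <- rbind(rows, makeProbeRows(paste0("REF", r), 1, "", "both",
                                      "reference"))
  finishDesign(rows)
}

#' Define a simulation truth set
#'
#' Events are copy-number states over exon index ranges within a gene,
#' carried by the neoplastic (or constitutional) fraction of the specimen.
#' Germline events affect every cell; somatic events only the tumour
#' fraction, so their dosage is diluted toward diploid by (1 - purity).
#'
#' @param events data.frame with columns gene, exon_from, exon_to (1-based
#'   exon indices within the gene's panel order), copies (non-negative
#'   integer in the carrier cells) and origin ("germline" or "somatic").
#'   NULL or zero rows = fully diploid.
#' @param purity tumour cell fraction in (0, 1] (default 1; only relevant
#'   for somatic events).
#' @return A list of class \code{TruthSet}.
#' @export
truthSet <- function(events = NULL, purity = 1) {
  if (is.null(events))
    events <- data.frame(gene = character(), exon_from = integer(),
                         exon_to = integer(), copies = integer(),
                         origin = character(), stringsAsFactors = FALSE)
  stopifnot(purity > 0, purity <= 1,
            all(c("gene", "exon_from", "exon_to", "copies", "origin")
                %in% names(events)),
            all(events$copies >= 0),
            all(events$origin %in% c("germline", "somatic")))
  structure(list(events = events, purity = purity), class = "TruthSet")
}

# expected real-valued copies per probe under the mixture model
expectedProbeCopies <- function(design, truth) {
  p <- probes(design)
  et <- exonTable(design)
  exonIdx <- stats::ave(seq_len(nrow(et)), et$gene, FUN = seq_along)
  names(exonIdx) <- et$exon_label
  copies <- setNames(rep(2, nrow(p)), p$probe_id)
  ev <- truth$events
  for (i in seq_len(nrow(ev))) {
    inGene <- p$gene == ev$gene[i]
    idx <- exonIdx[p$exon_label]
    hit <- inGene & idx >= ev$exon_from[i] & idx <= ev$exon_to[i]
    carrier <- if (ev$origin[i] == "germline") 1 else truth$purity
    copies[hit] <- carrier * ev$copies[i] + (1 - carrier) * 2
  }
  copies
}

# exon-level truth: expected copies per exon label
expectedExonCopies <- function(design, truth) {
  pc <- expectedProbeCopies(design, truth)
  p <- probes(design)
  vapply(split(pc[p$probe_id], p$exon_label), mean, numeric(1))
}

#' Fixed per-probe efficiency multipliers
#'
#' Drawn once per design/run and shared by every simulated library so that,
#' like real probe-specific hybridisation and amplification biases, they
#' cancel exactly against the control baseline.
#'
#' @param design a [ProbeDesign-class].
#' @param spread SD on the log scale (default 0.25).
#' @param seed integer seed.
#' @return Named numeric vector of multipliers with unit median.
#' @export
simulateEfficiency <- function(design, spread = 0.25, seed) {
  set.seed(seed)
  ids <- probeIds(design)
  eff <- rlnorm(length(ids), meanlog = 0, sdlog = spread)
  setNames(eff / median(eff), ids)
}

#' Simulate per-probe read counts for one library
#'
#' Expected count for probe k: targetDepth x efficiency_k x (local copies /
#' 2) x multiplicative lognormal noise whose ratio-scale SD equals the
#' configured per-probe noise, optionally zero-inflated (dropout) and
#' Poisson-sampled. Local copies come from the truth set's mixture model.
#'
#' @param design a [ProbeDesign-class].
#' @param truth a [truthSet()].
#' @param cfg a [simulationConfig()].
#' @param mix "detection" or "confirmation".
#' @param efficiency per-probe multipliers from [simulateEfficiency()]
#'   (default: unit efficiencies).
#' @param sampleId,isControl,isNTC metadata for the resulting library.
#' @return A [LibraryCounts-class].
#' @export
simulateCounts <- function(design, truth, cfg, mix,
                           efficiency = NULL, sampleId = "sim",
                           isControl = FALSE, isNTC = FALSE) {
  p <- probesForMix(design, mix)
  ids <- p$probe_id
  if (is.null(efficiency)) efficiency <- setNames(rep(1, nrow(p)), ids)
  copies <- expectedProbeCopies(design, truth)[ids]
  # lognormal with unit mean whose ratio-scale SD is probeNoiseSd
  sdlog <- sqrt(log1p(cfg$probeNoiseSd^2))
  noise <- if (cfg$probeNoiseSd > 0)
    rlnorm(length(ids), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  else rep(1, length(ids))
  mu <- cfg$targetDepth * efficiency[ids] * (copies / 2) * noise
  if (cfg$dropoutRate > 0)
    mu[runif(length(mu)) < cfg$dropoutRate] <- 0
  counts <- if (cfg$poisson) rpois(length(mu), mu) else round(mu)
  libraryCounts(sampleId, mix, setNames(counts, ids),
                isControl = isControl, isNTC = isNTC)
}

#' Write a simulated library as FASTQ
#'
#' Emits, for each probe with count c, c identical reads consisting of the
#' adapter-free ligated insert (left arm + right arm) followed by the
#' downstream adapter, padded to the read length (constant quality);
#' [countProbes()] on the output recovers the input counts exactly.
#'
#' @param lib a [LibraryCounts-class].
#' @param design a [ProbeDesign-class] with oligo sequences.
#' @param path output FASTQ path (".gz" suffix compresses).
#' @param readLength read length in bases (default 150).
#' @param adapters adapter set as from [nexteraAdapters()].
#' @return Invisibly, the path written.
#' @export
simulateFastq <- function(lib, design, path, readLength = 150L,
                          adapters = nexteraAdapters()) {
  inserts <- ampliconInserts(design, adapters)
  cnt <- probeCounts(lib)
  cnt <- cnt[cnt > 0]
  if (!length(cnt)) {
    file.create(path)
    return(invisible(path))
  }
  tmpl <- paste0(inserts[names(cnt)], adapters[["downstream"]])
  tmpl <- vapply(tmpl, function(s) {
    if (nchar(s) >= readLength) substr(s, 1L, readLength)
    else paste0(s, strrep("G", readLength - nchar(s)))
  }, character(1), USE.NAMES = FALSE)
  seqs <- rep(tmpl, times = cnt)
  ids <- paste0(rep(names(cnt), times = cnt), ":",
                sequence(unname(cnt)))
  dss <- DNAStringSet(seqs)
  names(dss) <- ids
  quals <- BStringSet(rep(strrep("I", readLength), length(dss)))
  writeXStringSet(dss, path, format = "fastq", qualities = quals,
                  compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Simulate a full cohort of control and case libraries
#'
#' Generates \code{cfg$nControls} copy-neutral controls plus \code{nCases}
#' case samples, each case carrying one germline multi-exon single-copy-change
#' event (heterozygous deletion, 1 copy, or duplication, 3 copies) at a
#' random location within the deletion-target genes. Detection and
#' confirmation libraries share the run's fixed probe efficiencies.
#'
#' @param design a [ProbeDesign-class].
#' @param cfg a [simulationConfig()].
#' @param nCases number of case samples (default 50).
#' @param minExons,maxExons event span in exons (defaults 3 and 6).
#' @param pDeletion probability a case event is a deletion rather than a
#'   duplication (default 0.5).
#' @return A list with elements \code{controls} and \code{cases}; each case
#'   is a list with \code{sample_id}, \code{truth} and per-mix
#'   [LibraryCounts-class] objects (\code{detection}, \code{confirmation}).
#' @export
simulateCohort <- function(design, cfg, nCases = 50L, minExons = 3L,
                           maxExons = 6L, pDeletion = 0.5) {
  set.seed(cfg$seed)
  eff <- list(
    detection = simulateEfficiency(design, cfg$probeEfficiencySpread,
                                   seed = cfg$seed + 1L),
    confirmation = simulateEfficiency(design, cfg$probeEfficiencySpread,
                                      seed = cfg$seed + 2L))
  diploid <- truthSet()
  mkSample <- function(id, truth, isControl) {
    libs <- lapply(c(detection = "detection", confirmation = "confirmation"),
                   function(m) simulateCounts(design, truth, cfg, m,
                                              efficiency = eff[[m]],
                                              sampleId = id,
                                              isControl = isControl))
    c(list(sample_id = id, truth = truth), libs)
  }
  controls <- lapply(seq_len(cfg$nControls), function(i)
    mkSample(sprintf("control%02d", i), diploid, TRUE))
  # events go into multi-exon deletion-target genes
  p <- probes(design)
  delGenes <- unique(p$gene[p$role == "target_deletion"])
  nExons <- vapply(delGenes, function(g)
    length(unique(p$exon_label[p$gene == g])), integer(1))
  delGenes <- delGenes[nExons >= minExons]
  if (!length(delGenes)) stop("design has no gene with enough exons for events")
  cases <- lapply(seq_len(nCases), function(i) {
    g <- sample(delGenes, 1L)
    ng <- length(unique(p$exon_label[p$gene == g]))
    span <- sample(seq(minExons, min(maxExons, ng)), 1L)
    from <- sample(seq_len(ng - span + 1L), 1L)
    copies <- if (runif(1) < pDeletion) 1L else 3L
    tr <- truthSet(data.frame(gene = g, exon_from = from,
                              exon_to = from + span - 1L, copies = copies,
                              origin = "germline",
                              stringsAsFactors = FALSE))
    mkSample(sprintf("case%02d", i), tr, FALSE)
  })
  list(controls = controls, cases = cases, efficiency = eff)
}

#' Evaluate per-exon calls against a truth set
#'
#' Event-level sensitivity: an event counts as detected when at least one of
#' its exons is called in the correct direction (loss categories for true
#' copies < 2, gain categories for true copies > 2). Exon-level specificity:
#' the percentage of truly two-copy exons classified normal.
#'
#' @param exonCalls data.frame with columns gene, exon_label, category for
#'   one sample (as from [summarizeExons()] + [classifyExon()]).
#' @param truth the sample's [truthSet()].
#' @param design the [ProbeDesign-class].
#' @return A list with \code{n_events}, \code{n_detected},
#'   \code{sensitivity} (percent, NaN when no events), \code{n_negative},
#'   \code{n_false}, \code{specificity} (percent) and a per-event
#'   \code{detail} data.frame.
#' @export
evaluateCalls <- function(exonCalls, truth, design) {
  lossCats <- c("het_deletion", "hom_deletion")
  gainCats <- c("duplication", "amplification")
  exCopies <- expectedExonCopies(design, truth)
  cat <- setNames(exonCalls$category, exonCalls$exon_label)
  et <- exonTable(design)
  exonIdx <- stats::ave(seq_len(nrow(et)), et$gene, FUN = seq_along)
  names(exonIdx) <- et$exon_label
  ev <- truth$events
  detected <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    labs <- et$exon_label[et$gene == ev$gene[i] &
                          exonIdx[et$exon_label] >= ev$exon_from[i] &
                          exonIdx[et$exon_label] <= ev$exon_to[i]]
    want <- if (ev$copies[i] < 2) lossCats else gainCats
    detected[i] <- any(cat[labs] %in% want, na.rm = TRUE)
  }
  negLabs <- names(exCopies)[abs(exCopies - 2) < 1e-9]
  negLabs <- intersect(negLabs, names(cat))
  nFalse <- sum(cat[negLabs] != "normal" & cat[negLabs] != "missing")
  list(n_events = nrow(ev), n_detected = sum(detected),
       sensitivity = if (nrow(ev)) 100 * sum(detected) / nrow(ev) else NaN,
       n_negative = length(negLabs), n_false = nFalse,
       specificity = if (length(negLabs))
         100 * (length(negLabs) - nFalse) / length(negLabs) else NaN,
       detail = cbind(ev, detected = detected))
}
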