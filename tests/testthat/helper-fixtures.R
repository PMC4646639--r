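# Shared fixtures: all built in code, deterministically.

# small generic panel: 2 deletion-target genes x 4 exons, 1 amplification
# gene, 3 reference genes (detection + confirmation probes per exon)
tinyDesign <- function(seed = 101L) {
  simulateDesign(nGenes = 2L, exonsPerGene = 4L, probesPerExon = 1L,
                 nReference = 3L, nAmplification = 1L, seed = seed)
}

# write a plain 4-line-record FASTQ from read sequences
writeFastqLines <- function(seqs, path) {
  if (length(seqs)) {
    rec <- as.vector(rbind(paste0("@read", seq_along(seqs)), seqs,
                           "+", strrep("I", nchar(seqs))))
    writeLines(rec, path)
  } else {
    file.create(path)
  }
  path
}

randomReads <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# embed a 20-base key in a read with deterministic flanks
readWithKey <- function(key, len = 60L, seed = 1L) {
  set.seed(seed)
  pad <- len - nchar(key)
  left <- sample.int(pad, 1L) - 1L
  flank <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                 collapse = "")
  paste0(substr(flank, 1, left), key, substr(flank, left + 1, pad))
}

# depth-normalised values for simple vectors, bypassing integer coercion
dnFromValues <- function(values, mix = "detection", id = "s") {
  new("DepthNormalized", sampleId = id, mix = mix, values = values,
      normalizer = 1)
}
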