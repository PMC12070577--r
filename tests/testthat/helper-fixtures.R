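# Text fixtures built in code at test time.

write_test_gtf <- function(path, shuffle = FALSE, duplicate = FALSE) {
  attrs <- function(g, t) {
    sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  }
  lines <- c(
    paste("chr1", "test", "exon", 1, 100, ".", "+", ".",
          attrs("geneA", "txA1"), sep = "\t"),
    paste("chr1", "test", "exon", 51, 150, ".", "+", ".",
          attrs("geneA", "txA2"), sep = "\t"),
    paste("chrM", "test", "exon", 1, 60, ".", "+", ".",
          attrs("geneM", "txM1"), sep = "\t")
  )
  if (duplicate) lines <- c(lines, lines[1])
  if (shuffle) lines <- rev(lines)
  writeLines(lines, path)
  path
}

write_test_fasta <- function(path) {
  # chr1: 150 nt alternating blocks with known composition; chrM: 60 nt all A.
  chr1 <- paste(c(strrep("A", 50), strrep("G", 50), strrep("C", 50)),
                collapse = "")
  chrM <- strrep("A", 60)
  writeLines(c(">chr1", chr1, ">chrM", chrM), path)
  path
}

# Minimal SAM with poly(A) tags; converted to BAM via Rsamtools.
write_test_bam <- function(dir, tags = c(40L, 55L, 70L, 85L, 100L),
                           add_secondary = FALSE, untagged = integer(0)) {
  sam <- file.path(dir, "reads.sam")
  seq10 <- strrep("A", 10)
  recs <- vapply(seq_along(tags), function(i) {
    paste(sprintf("read%d", i), 0, "geneA", 10 * i, 60, "10M", "*", 0, 0,
          seq10, strrep("I", 10), sprintf("pt:i:%d", tags[i]), sep = "\t")
  }, "")
  if (length(untagged) > 0) {
    recs <- c(recs, vapply(untagged, function(i) {
      paste(sprintf("readU%d", i), 0, "geneA", 5, 60, "10M", "*", 0, 0,
            seq10, strrep("I", 10), sep = "\t")
    }, ""))
  }
  if (add_secondary) {
    recs <- c(recs, paste("read1", 256, "geneA", 12, 0, "10M", "*", 0, 0,
                          "*", "*", "pt:i:40", sep = "\t"))
  }
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               "@SQ\tSN:geneA\tLN:1000", recs), sam)
  bam <- suppressMessages(Rsamtools::asBam(
    sam, file.path(dir, "reads"), overwrite = TRUE, indexDestination = TRUE))
  bam
}
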