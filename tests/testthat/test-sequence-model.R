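test_that("FASTA loading normalizes case, keeps ids and flags ambiguity", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">repA some description", "acgtACGT", ">repB", "GGNNATCG"), fa)
  g <- load_genome(fa)
  expect_named(g$seq, c("repA", "repB"))
  expect_equal(as.character(g$seq[["repA"]]), "ACGTACGT")
  expect_equal(Biostrings::width(g$seq), c(8L, 8L))
  # flagged set equals a linear scan for non-ACGT characters
  chars <- strsplit("GGNNATCG", "")[[1]]
  expect_equal(g$ambiguous[["repB"]], which(!chars %in% c("A", "C", "G", "T")) - 1L)
  expect_equal(g$ambiguous[["repA"]], integer())
})

test_that("genome loading rejects duplicate ids and empty records", {
  expect_error(genome_from_seqs(c(a = "ACGT", a = "GGGG")), "duplicate")
  expect_error(genome_from_seqs(c(a = "")), "empty")
})

test_that("GFF3 and BED targets convert to 0-based half-open and round-trip", {
  g <- genome_from_seqs(c(chr = strrep("ACGT", 30)))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tncRNA\t11\t20\t.\t+\t.\tID=geneA",
               "chr\tsrc\tncRNA\t31\t45\t.\t-\t.\tID=geneB"), gff)
  genes <- load_targets(gff, g)
  expect_equal(genes$start, c(10L, 30L))
  expect_equal(genes$end, c(20L, 45L))
  expect_equal(genes$tss, c(10L, 44L))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr\t10\t20\tgeneA\t0\t+"), bed)
  genes_bed <- load_targets(bed, g)
  expect_equal(genes_bed$start, 10L)
  expect_equal(genes_bed$end, 20L)

  # GFF3 -> internal -> GFF3 reproduces the printed coordinates exactly
  out <- withr::local_tempfile(fileext = ".gff3")
  crispacer:::write_gff3(genes, out)
  reread <- load_targets(out, g)
  expect_equal(reread[, c("gene_id", "start", "end", "strand", "tss")],
               genes[, c("gene_id", "start", "end", "strand", "tss")])
})

test_that("targets on unknown replicons or without strand are rejected", {
  g <- genome_from_seqs(c(chr = strrep("ACGT", 30)))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "plasmid\tsrc\tncRNA\t5\t20\t.\t+\t.\tID=geneA"), gff)
  expect_error(load_targets(gff, g), "unknown replicon")
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tncRNA\t5\t20\t.\t.\t.\tID=geneA"), gff2)
  expect_error(load_targets(gff2, g), "strand")
})

test_that("promoter windows sit strand-aware upstream of the TSS", {
  g <- genome_from_seqs(c(chr = paste(rep("ACGT", 1000), collapse = "")))
  gene_fwd <- data.frame(gene_id = "f", replicon_id = "chr", start = 1000L,
                         end = 1100L, strand = "+", tss = 1000L)
  r <- derive_regions(gene_fwd, g, 50)
  expect_equal(r$start[r$kind == "promoter"], 950L)
  expect_equal(r$end[r$kind == "promoter"], 1000L)

  gene_rev <- data.frame(gene_id = "r", replicon_id = "chr", start = 1900L,
                         end = 2001L, strand = "-", tss = 2000L)
  r2 <- derive_regions(gene_rev, g, 50)
  expect_equal(r2$start[r2$kind == "promoter"], 2001L)
  expect_equal(r2$end[r2$kind == "promoter"], 2051L)
})

test_that("minus-strand promoter is the mirror image of the plus-strand rule", {
  # reverse-complement the replicon, map the gene to the other strand, apply
  # the + rule there, and map the resulting window back
  set.seed(11)
  seq <- random_dna(600)
  g <- genome_from_seqs(c(chr = seq))
  len <- nchar(seq)
  gene_rev <- data.frame(gene_id = "x", replicon_id = "chr", start = 200L,
                         end = 300L, strand = "-", tss = 299L)
  prom_rev <- derive_regions(gene_rev, g, 50)
  prom_rev <- prom_rev[prom_rev$kind == "promoter", ]

  g_rc <- genome_from_seqs(c(chr = oracle_revcomp(seq)))
  gene_mirror <- data.frame(gene_id = "x", replicon_id = "chr",
                            start = len - 300L, end = len - 200L,
                            strand = "+", tss = len - 300L)
  prom_fwd <- derive_regions(gene_mirror, g_rc, 50)
  prom_fwd <- prom_fwd[prom_fwd$kind == "promoter", ]
  expect_equal(prom_rev$start, len - prom_fwd$end)
  expect_equal(prom_rev$end, len - prom_fwd$start)
  # and the extracted promoter sequences agree
  expect_equal(
    extract_seq(g, "chr", prom_rev$start, prom_rev$end, "-"),
    extract_seq(g_rc, "chr", prom_fwd$start, prom_fwd$end, "+"))
})

test_that("promoters truncate at linear edges and never overlap the gene", {
  g <- genome_from_seqs(c(chr = strrep("ACGT", 100)))
  gene <- data.frame(gene_id = "e", replicon_id = "chr", start = 30L,
                     end = 90L, strand = "+", tss = 30L)
  expect_warning(r <- derive_regions(gene, g, 50), "truncated")
  p <- r[r$kind == "promoter", ]
  expect_equal(c(p$start, p$end), c(0L, 30L))
  expect_true(p$truncated)

  set.seed(42)
  for (i in 1:20) {
    strand <- sample(c("+", "-"), 1)
    start <- sample(100:200, 1)
    end <- start + sample(50:120, 1)
    gene_i <- data.frame(gene_id = "p", replicon_id = "chr", start = start,
                         end = end, strand = strand,
                         tss = if (strand == "+") start else end - 1L)
    r <- derive_regions(gene_i, g, sample(1:60, 1))
    p <- r[r$kind == "promoter", ]
    t <- r[r$kind == "transcribed", ]
    expect_false(intervals_overlap <- p$start < t$end && t$start < p$end)
    if (strand == "+") expect_equal(p$end, t$start)  # adjacent at the TSS
    else expect_equal(t$end, p$start)
  }
})

test_that("sequence extraction is strand-aware and wraps only when circular", {
  g <- genome_from_seqs(c(chr = "GTTCAA"))
  expect_equal(extract_seq(g, "chr", 1, 4, "+"), "TTC")
  expect_equal(extract_seq(g, "chr", 1, 4, "-"), "GAA")
  expect_error(extract_seq(g, "chr", 4, 8, "+"), "out of range")

  gc <- genome_from_seqs(c(chr = "GTTCAA"), circular = TRUE)
  expect_equal(extract_seq(gc, "chr", 4, 8, "+"), "AAGT")
  expect_equal(extract_seq(gc, "chr", -2, 2, "+"), "AAGT")

  set.seed(7)
  for (i in 1:10) {
    s <- random_dna(50)
    expect_equal(revcomp(revcomp(s)), s)
    gg <- genome_from_seqs(c(chr = s))
    a <- sort(sample(0:50, 2))
    if (a[1] == a[2]) next
    expect_equal(extract_seq(gg, "chr", a[1], a[2], "-"),
                 oracle_revcomp(extract_seq(gg, "chr", a[1], a[2], "+")))
  }
})
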