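test_that("gc_fraction computes (G+C)/length", {
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("AAAA"), 0)
  expect_equal(gc_fraction("GCGC"), 1)
  expect_error(gc_fraction(""), "empty")
})

test_that("config validation rejects bad values and unknown keys", {
  expect_error(design_config(gc_min = 0.8, gc_max = 0.5), "gc_min")
  expect_error(design_config(spacer_length = 5), "spacer_length")
  expect_error(design_config(not_a_key = 1), "unused argument")
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("spacer_length: 21", "promotor_window: 50"), yml)
  expect_error(load_config(yml), "promotor_window")
  writeLines("spacer_length: 21", yml)
  expect_equal(load_config(yml)$spacer_length, 21L)
})

test_that("a promoter with one TTV per strand yields the two promoter candidates", {
  set.seed(5)
  prom <- pamfree_dna(50)
  substr(prom, 6, 8) <- "TTC"   # forward-strand PAM, spacer [8, 28)
  substr(prom, 46, 48) <- "GAA" # reverse-strand PAM (TTC on -), spacer [25, 45)
  body <- pamfree_dna(60)
  fx <- toy_gene(prom, body, "+")
  cand <- enumerate_candidates(fx$gene, fx$genome)
  expect_equal(nrow(cand), 2L)
  expect_setequal(cand$annealing, c("promoter_fwd", "promoter_rev"))
  expect_true(all(cand$region_kind == "promoter"))
  expect_true(all(cand$pam_sequence %in% c("TTA", "TTC", "TTG")))
  # protospacer re-extraction from the genome equals the reported spacer
  for (i in seq_len(nrow(cand))) {
    expect_equal(extract_seq(fx$genome, "chr", cand$proto_start[i],
                             cand$proto_end[i], cand$strand[i]),
                 cand$spacer_sequence[i])
  }
})

test_that("transcribed-region spacers obey the template-strand rule", {
  set.seed(6)
  prom <- pamfree_dna(50)
  # coding-strand PAM in the gene body -> gRNA anneals to the template: kept
  body_ok <- pamfree_dna(60)
  substr(body_ok, 11, 13) <- "TTC"
  fx <- toy_gene(prom, body_ok, "+")
  cand <- enumerate_candidates(fx$gene, fx$genome)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$annealing, "template")
  expect_equal(cand$region_kind, "transcribed")
  expect_equal(cand$strand, "+")

  # template-strand PAM (gRNA would anneal to the nontemplate): rejected
  body_bad <- pamfree_dna(60)
  substr(body_bad, 31, 33) <- "GAA"
  fx2 <- toy_gene(prom, body_bad, "+")
  expect_equal(nrow(enumerate_candidates(fx2$gene, fx2$genome)), 0L)

  # same rule on a minus-strand gene
  fx3 <- toy_gene(prom, body_ok, "-")
  cand3 <- enumerate_candidates(fx3$gene, fx3$genome)
  expect_equal(nrow(cand3), 1L)
  expect_equal(cand3$annealing, "template")
  expect_equal(cand3$strand, "-")
  expect_equal(cand3$spacer_sequence, cand$spacer_sequence)
})

test_that("candidates touching ambiguity codes are excluded", {
  set.seed(8)
  prom <- pamfree_dna(50)
  substr(prom, 6, 8) <- "TTC"
  substr(prom, 15, 15) <- "N"  # inside the spacer window [8, 28)
  fx <- toy_gene(prom, pamfree_dna(60), "+")
  expect_equal(nrow(enumerate_candidates(fx$gene, fx$genome)), 0L)
})

test_that("ranking is the documented lexicographic order and deterministic", {
  base <- data.frame(
    gene_id = "g", replicon_id = "chr", spacer_sequence = "A",
    proto_start = c(100L, 200L, 300L, 400L, 500L),
    proto_end = c(120L, 220L, 320L, 420L, 520L),
    strand = "+", pam_start = 0L, pam_end = 3L, pam_sequence = "TTA",
    region_kind = c("promoter", "transcribed", "transcribed",
                    "promoter", "promoter"),
    annealing = "template",
    gc = c(0.5, 0.5, 0.5, 0.9, 0.5),
    tss_offset = c(-30L, 10L, 10L, -5L, -40L),
    extended_pam = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    five_prime_portion = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  r <- rank_candidates(base, design_config())
  # GC window dominates: the gc=0.9 promoter candidate sinks to the bottom
  expect_equal(r$proto_start[5], 400L)
  # promoter beats 5' transcribed beats 3' transcribed
  expect_equal(r$region_kind[1:2], c("promoter", "promoter"))
  expect_equal(r$proto_start[1:2], c(100L, 500L))  # |tss_offset| tiebreak
  expect_equal(r$five_prime_portion[3], TRUE)
  # extended PAM only breaks ties within the same region class
  expect_equal(r$proto_start[3:4], c(200L, 300L))

  tie <- base[c(1, 1), ]
  tie$proto_start <- c(150L, 100L)
  tie$proto_end <- tie$proto_start + 20L
  r2 <- rank_candidates(tie, design_config())
  expect_equal(r2$proto_start, c(100L, 150L))
  expect_identical(rank_candidates(base, design_config()),
                   rank_candidates(base, design_config()))
})

test_that("guide selection fills quotas with the documented constraints", {
  fx <- make_genome(n_genes = 6, genome_length = 25000, seed = 21)
  cfg <- design_config()
  idx <- build_offtarget_index(fx$genome, cfg)
  for (i in seq_len(nrow(fx$genes))) {
    gd <- select_guides(fx$genes[i, ], fx$genome, cfg, idx)
    gr <- gd$grnas
    expect_lte(nrow(gr), cfg$guides_per_gene)
    if (nrow(gr) > 1) {
      # pairwise distinct protospacers
      expect_equal(anyDuplicated(paste(gr$proto_start, gr$strand)), 0L)
    }
    ar <- gd$array_spacers
    expect_true(nrow(ar) %in% c(0L, cfg$array_spacers_per_gene))
    both <- rbind(gr, ar)
    if (nrow(ar) > 0) {
      # array spacers pairwise non-overlapping and disjoint from gRNAs
      for (a in seq_len(nrow(ar))) {
        others <- rbind(gr, ar[-a, ])
        expect_false(any(ar$proto_start[a] < others$proto_end &
                           others$proto_start < ar$proto_end[a]))
      }
    }
    # every selected spacer re-validates against the genome: TTV PAM
    # immediately 5' of the protospacer on the protospacer strand
    for (j in seq_len(nrow(both))) {
      pam <- extract_seq(fx$genome, both$replicon_id[j], both$pam_start[j],
                         both$pam_end[j], both$strand[j])
      expect_match(pam, "^TT[ACG]$")
      if (both$strand[j] == "+") {
        expect_equal(both$pam_end[j], both$proto_start[j])
      } else {
        expect_equal(both$proto_end[j], both$pam_start[j])
      }
      expect_false(both$annealing[j] == "nontemplate")
    }
    # when enough preferred-GC candidates exist, all gRNAs are in-window
    all_cand <- rank_candidates(enumerate_candidates(fx$genes[i, ],
                                                     fx$genome, cfg), cfg)
    n_gc_ok <- sum(all_cand$gc >= cfg$gc_min & all_cand$gc <= cfg$gc_max)
    if (n_gc_ok >= cfg$guides_per_gene && nrow(gr) == cfg$guides_per_gene) {
      expect_true(all(gr$gc >= cfg$gc_min & gr$gc <= cfg$gc_max))
    }
  }
})

test_that("scarce or absent candidates degrade with documented notes", {
  set.seed(31)
  prom <- pamfree_dna(50)
  substr(prom, 6, 8) <- "TTC"
  substr(prom, 46, 48) <- "GAA"
  fx <- toy_gene(prom, pamfree_dna(60), "+")
  gd <- select_guides(fx$gene, fx$genome)
  expect_equal(nrow(gd$grnas), 2L)
  expect_equal(nrow(gd$array_spacers), 0L)
  expect_match(gd$failure_notes[1], "insufficient spacers")

  fx0 <- toy_gene(pamfree_dna(50), pamfree_dna(60), "+")
  gd0 <- select_guides(fx0$gene, fx0$genome)
  expect_equal(nrow(gd0$grnas), 0L)
  expect_true(length(gd0$failure_notes) > 0)
})

test_that("design output is byte-identical across runs", {
  fx <- make_genome(n_genes = 4, genome_length = 15000, seed = 13)
  lib1 <- design_library(fx$genome, fx$genes)
  lib2 <- design_library(fx$genome, fx$genes)
  expect_identical(lib1$spacer_table, lib2$spacer_table)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_library(lib1, d1); p2 <- write_library(lib2, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
})
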