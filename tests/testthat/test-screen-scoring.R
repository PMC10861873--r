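FL5 <- "ACGTTGGCTTAAGCG"
FL3 <- "CGATCCTGAAGGTTC"

test_that("spacer extraction handles orientation and flank mismatches", {
  sp <- "ACGTACGTACGTACGTACGA"
  read <- paste0("GG", FL5, sp, FL3, "TT")
  expect_equal(extract_spacer(read, NULL, FL5, FL3), sp)
  expect_equal(extract_spacer(revcomp(read), NULL, FL5, FL3), sp)
  expect_equal(extract_spacer("AAAAA", revcomp(read), FL5, FL3), sp)

  # one flank mismatch tolerated at the default budget, two are not
  f5_1mm <- FL5; substr(f5_1mm, 3, 3) <- "A"
  read1 <- paste0(f5_1mm, sp, FL3)
  expect_equal(extract_spacer(read1, NULL, FL5, FL3), sp)
  f5_2mm <- f5_1mm; substr(f5_2mm, 7, 7) <- "T"
  read2 <- paste0(f5_2mm, sp, FL3)
  expect_true(is.na(extract_spacer(read2, NULL, FL5, FL3)))
  expect_equal(extract_spacer(read2, NULL, FL5, FL3,
                              max_flank_mismatch = 2), sp)
  # implausible enclosed length is rejected
  expect_true(is.na(extract_spacer(paste0(FL5, "ACGT", FL3), NULL, FL5, FL3)))
})

test_that("counting a rendered FASTQ recovers the simulated matrix exactly", {
  genes <- sprintf("gene%02d", 1:6)
  manifest <- synthetic_manifest(genes, members_per_gene = 2, seed = 3)
  sim <- simulate_screen(manifest, replicates = 2, depth = 300, phi = 0.1,
                         seed = 4)
  dir <- withr::local_tempdir()
  samples <- render_fastq(sim$counts, manifest, dir, FL5, FL3)
  counted <- count_members(samples, manifest, FL5, FL3)
  expect_equal(counted$counts, sim$counts$counts)
  expect_true(all(counted$log$unmatched == 0))
})

test_that("array members are counted when any constituent spacer is seen", {
  manifest <- data.frame(member_id = c("gA_array", "gB_g1"),
                         type = c("array", "gRNA"),
                         gene_id = c("gA", "gB"), stringsAsFactors = FALSE)
  manifest$spacers <- list(c("ACGTACGTACGTACGTACGA", "TTTTACGTACGTACGTACGA",
                             "GGGGACGTACGTACGTACGA"),
                           "CCCCACGTACGTACGTACGA")
  dir <- withr::local_tempdir()
  reads <- paste0(FL5, c(manifest$spacers[[1]][2], manifest$spacers[[1]][3],
                         manifest$spacers[[2]][1],
                         "AAAACCCCGGGGTTTTAAAA"), FL3)
  fq <- file.path(dir, "s1.fastq")
  writeLines(as.vector(rbind(sprintf("@r%d", seq_along(reads)), reads, "+",
                             strrep("I", nchar(reads)))), fq)
  samples <- data.frame(sample_id = c("s1", "s2"),
                        condition = c("control", "stress"), replicate = 1L,
                        fastq1 = fq, fastq2 = NA, stringsAsFactors = FALSE)
  counted <- count_members(samples, manifest, FL5, FL3)
  expect_equal(counted$counts["gA_array", "s1"], 2L)
  expect_equal(counted$counts["gB_g1", "s1"], 1L)
  expect_equal(counted$log$unmatched[1], 1L)

  dup <- manifest
  dup$spacers[[2]] <- dup$spacers[[1]][1]
  expect_error(count_members(samples, dup, FL5, FL3), "more than one member")
})

test_that("log2 fold changes follow the CPM + pseudocount definition", {
  samples <- data.frame(sample_id = c("c1", "s1"),
                        condition = c("control", "stress"), replicate = 1L,
                        stringsAsFactors = FALSE)
  # totals of 1e6 make CPM equal raw counts
  mk <- function(ctrl, strs) {
    m <- cbind(c1 = c(ctrl, 1e6 - sum(ctrl)), s1 = c(strs, 1e6 - sum(strs)))
    rownames(m) <- c(paste0("m", seq_along(ctrl)), "filler")
    count_matrix(m, samples)
  }
  eq <- guide_log2fc(mk(c(100, 7), c(100, 7)))
  expect_equal(unname(eq$mean_log2fc[1:2]), c(0, 0))
  # control 0, stress 10 at equal depth, pseudocount 0.5: log2(21)
  zero <- guide_log2fc(mk(0, 10))
  expect_equal(unname(zero$mean_log2fc[1]), log2(21), tolerance = 1e-6)
  # stress = 2x control at equal depth: ~1 up to the pseudocount
  dbl <- guide_log2fc(mk(5000, 10000))
  expect_equal(unname(dbl$mean_log2fc[1]), 1, tolerance = 1e-3)
  expect_error(guide_log2fc(mk(0, 10), pseudocount = 0), "pseudocount")
})

test_that("log2FC is invariant to per-sample scaling and signs enrichment", {
  set.seed(99)
  samples <- data.frame(sample_id = c("c1", "s1", "c2", "s2"),
                        condition = rep(c("control", "stress"), 2),
                        replicate = rep(1:2, each = 2), stringsAsFactors = FALSE)
  m <- matrix(rpois(40, 500), nrow = 10,
              dimnames = list(paste0("m", 1:10), samples$sample_id))
  f1 <- guide_log2fc(count_matrix(m, samples))
  m2 <- m; m2[, "s1"] <- m2[, "s1"] * 7L
  f2 <- guide_log2fc(count_matrix(m2, samples))
  expect_equal(f1$per_replicate, f2$per_replicate)

  # members enriched under stress get positive scores
  m3 <- m; m3["m1", c("s1", "s2")] <- m3["m1", c("c1", "c2")] * 50L
  f3 <- guide_log2fc(count_matrix(m3, samples))
  expect_gt(f3$mean_log2fc["m1"], 0)
})

test_that("per-gene aggregation averages members and applies both cutoffs", {
  manifest <- data.frame(member_id = paste0("m", 1:9), type = "gRNA",
                         gene_id = rep(c("gA", "gB", "gC"), each = 3),
                         stringsAsFactors = FALSE)
  manifest$spacers <- as.list(paste0("SP", 1:9))
  per_rep <- rbind(
    matrix(c(1, 0.5, 1.5), 3, 3) + matrix(rnorm(9, 0, 0.01), 3, 3),
    matrix(-0.7, 3, 3) + matrix(rnorm(9, 0, 0.01), 3, 3),
    matrix(0.4, 3, 3) + matrix(rnorm(9, 0, 0.01), 3, 3))
  rownames(per_rep) <- manifest$member_id
  colnames(per_rep) <- paste0("rep", 1:3)
  fitness <- structure(list(per_replicate = per_rep,
                            mean_log2fc = rowMeans(per_rep)),
                       class = "crispacer_guide_fitness")
  res <- aggregate_srna(fitness, manifest)
  expect_equal(res$mean_log2fc[res$gene_id == "gA"], 1, tolerance = 0.05)
  a <- res[res$gene_id == "gA", ]; b <- res[res$gene_id == "gB", ]
  c_ <- res[res$gene_id == "gC", ]
  expect_true(a$hit); expect_equal(a$direction, "enriched")
  expect_true(b$hit); expect_equal(b$direction, "depleted")
  expect_false(c_$hit)  # significant but |log2FC| <= 0.5
  expect_lt(c_$fdr, 0.05)
})

test_that("permuted condition labels keep hit calls near the nominal rate", {
  genes <- sprintf("g%03d", 1:135)
  manifest <- synthetic_manifest(genes, members_per_gene = 4, seed = 7)
  rates <- vapply(1:3, function(s) {
    sim <- simulate_screen(manifest, effects = numeric(), replicates = 3,
                           depth = 1e6, phi = 0.1, seed = 100 + s)
    res <- aggregate_srna(guide_log2fc(sim$counts), manifest)
    mean(res$hit, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(rates), 0.07)
})

test_that("the per-gene scores track an independent count-model analysis", {
  genes <- sprintf("g%02d", 1:40)
  manifest <- synthetic_manifest(genes, members_per_gene = 4, seed = 17)
  sim <- simulate_screen(manifest,
                         effects = c(g01 = 1.5, g02 = -1.5, g03 = 1),
                         replicates = 3, depth = 1e6, phi = 0.1, seed = 18)
  ours <- aggregate_srna(guide_log2fc(sim$counts), manifest)

  suppressPackageStartupMessages(requireNamespace("edgeR"))
  grp <- factor(sim$counts$samples$condition, levels = c("control", "stress"))
  y <- edgeR::DGEList(sim$counts$counts, group = grp)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y, model.matrix(~grp))
  fit <- edgeR::exactTest(y)
  member_lfc <- fit$table$logFC
  names(member_lfc) <- rownames(fit$table)
  gene_lfc <- tapply(member_lfc[manifest$member_id], manifest$gene_id, mean)
  expect_gt(cor(ours$mean_log2fc, gene_lfc[ours$gene_id]), 0.9)
  # both routes agree on the planted effects' direction
  expect_gt(ours$mean_log2fc[ours$gene_id == "g01"], 0.5)
  expect_lt(ours$mean_log2fc[ours$gene_id == "g02"], -0.5)
})
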