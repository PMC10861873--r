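#' Read a library manifest
#'
#' A manifest maps each library member (a single gRNA or an array) to its
#' spacer sequence(s) and the gene it targets.
#'
#' @param path TSV with columns `member_id`, `type` (`gRNA`/`array`),
#'   `spacers` (`;`-separated for arrays) and `gene_id`.
#' @return a `data.frame`; the `spacers` column is a list column of character
#'   vectors.
#' @export
read_manifest <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  needed <- c("member_id", "type", "spacers", "gene_id")
  assert_that(all(needed %in% names(df)),
              paste("manifest needs columns:", paste(needed, collapse = ", ")))
  assert_that(!anyDuplicated(df$member_id), "duplicate member_ids in manifest")
  df$spacers <- strsplit(toupper(df$spacers), ";", fixed = TRUE)
  df
}

#' Write a library manifest
#'
#' @param manifest a manifest `data.frame` (list-column `spacers`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  out$spacers <- vapply(manifest$spacers, paste, character(1), collapse = ";")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the spacer from an amplicon read (pair)
#'
#' Searches the read, its reverse complement, and optionally the mate for the
#' two constant vector flanks (allowing up to `max_flank_mismatch` mismatches
#' each) and returns the sequence they enclose, or `NA` when the flanks are
#' not found or the enclosed length is implausible.
#'
#' @param read1 read sequence (character scalar).
#' @param read2 optional mate sequence.
#' @param flank_5,flank_3 constant sequences flanking the spacer on the
#'   amplicon top strand.
#' @param max_flank_mismatch mismatches tolerated per flank (default 1).
#' @param spacer_length_range plausible spacer lengths, inclusive.
#' @return the spacer string or `NA_character_`.
#' @export
extract_spacer <- function(read1, read2 = NULL, flank_5, flank_3,
                           max_flank_mismatch = 1L,
                           spacer_length_range = c(15L, 30L)) {
  sources <- c(read1, revcomp(read1))
  if (!is.null(read2) && !is.na(read2))
    sources <- c(sources, read2, revcomp(read2))
  for (s in sources) {
    hit <- locate_between_flanks(s, flank_5, flank_3, max_flank_mismatch)
    if (!is.na(hit) && nchar(hit) >= spacer_length_range[1] &&
        nchar(hit) <= spacer_length_range[2])
      return(hit)
  }
  NA_character_
}

locate_between_flanks <- function(seq, flank_5, flank_3, max_mm) {
  subj <- Biostrings::DNAString(seq)
  m5 <- Biostrings::matchPattern(flank_5, subj, max.mismatch = max_mm)
  if (length(m5) == 0L) return(NA_character_)
  start5 <- BiocGenerics::end(m5)[1] + 1L
  m3 <- Biostrings::matchPattern(flank_3, subj, max.mismatch = max_mm)
  if (length(m3) == 0L) return(NA_character_)
  ok <- BiocGenerics::start(m3) >= start5
  if (!any(ok)) return(NA_character_)
  end3 <- BiocGenerics::start(m3)[ok][1] - 1L
  if (end3 < start5) return("")
  substr(seq, start5, end3)
}

#' Count library members across sequenced samples
#'
#' Extracts spacers from every read (pair) of every sample and matches them
#' exactly against the manifest's spacers. An array member is counted when
#' any of its constituent spacers is observed. Reads without an extractable
#' or matchable spacer are tallied separately.
#'
#' @param samples a `data.frame` sample sheet with columns `sample_id`,
#'   `condition` (`control`/`stress`), `replicate`, `fastq1` and optionally
#'   `fastq2`.
#' @param manifest see [read_manifest()].
#' @param flank_5,flank_3 constant flanks around the spacer in the amplicon.
#' @param max_flank_mismatch mismatches tolerated per flank.
#' @return a list of class `crispacer_counts`: `counts` (integer matrix,
#'   members x samples), `samples` (the sample sheet), `log` (data.frame of
#'   per-sample totals and unmatched read counts).
#' @export
count_members <- function(samples, manifest, flank_5, flank_3,
                          max_flank_mismatch = 1L) {
  validate_sample_sheet(samples)
  spacer_map <- manifest_spacer_map(manifest)
  counts <- matrix(0L, nrow = nrow(manifest), ncol = nrow(samples),
                   dimnames = list(manifest$member_id, samples$sample_id))
  log_rows <- list()
  rng <- range(vapply(unlist(manifest$spacers), nchar, integer(1)))
  for (si in seq_len(nrow(samples))) {
    r1 <- as.character(Biostrings::readDNAStringSet(samples$fastq1[si],
                                                    format = "fastq"))
    r2 <- if (!is.null(samples$fastq2) && !is.na(samples$fastq2[si]) &&
              nzchar(samples$fastq2[si])) {
      as.character(Biostrings::readDNAStringSet(samples$fastq2[si],
                                                format = "fastq"))
    } else NULL
    unmatched <- 0L
    for (ri in seq_along(r1)) {
      sp <- extract_spacer(r1[ri], if (is.null(r2)) NULL else r2[ri],
                           flank_5, flank_3, max_flank_mismatch,
                           spacer_length_range = rng)
      member <- if (is.na(sp)) NA_character_ else spacer_map[[sp]]
      if (is.na(sp) || is.null(member)) {
        unmatched <- unmatched + 1L
      } else {
        counts[member, si] <- counts[member, si] + 1L
      }
    }
    log_rows[[si]] <- data.frame(sample_id = samples$sample_id[si],
                                 total_reads = length(r1),
                                 unmatched = unmatched,
                                 stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, samples = samples,
                 log = do.call(rbind, log_rows)),
            class = "crispacer_counts")
}

manifest_spacer_map <- function(manifest) {
  map <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(manifest))) {
    for (sp in manifest$spacers[[i]]) {
      assert_that(is.null(map[[sp]]),
                  sprintf("spacer %s present in more than one member", sp))
      map[[sp]] <- manifest$member_id[i]
    }
  }
  map
}

validate_sample_sheet <- function(samples) {
  assert_that(all(c("sample_id", "condition", "replicate") %in%
                    names(samples)),
              "sample sheet needs sample_id, condition, replicate")
  assert_that(all(samples$condition %in% c("control", "stress")),
              "condition must be 'control' or 'stress'")
  assert_that(!anyDuplicated(samples$sample_id), "duplicate sample ids")
  reps <- sort(unique(samples$replicate))
  for (r in reps) {
    sub <- samples[samples$replicate == r, ]
    assert_that(sum(sub$condition == "control") == 1 &&
                  sum(sub$condition == "stress") == 1,
                sprintf("replicate %s needs exactly one control and one stress sample", r))
  }
  invisible(samples)
}

#' Build a count container from an existing matrix
#'
#' @param counts integer matrix, members x samples.
#' @param samples sample sheet (`sample_id`, `condition`, `replicate`).
#' @return a `crispacer_counts`.
#' @export
count_matrix <- function(counts, samples) {
  validate_sample_sheet(samples)
  assert_that(all(colnames(counts) == samples$sample_id),
              "count matrix columns must match the sample sheet order")
  assert_that(all(counts >= 0), "negative counts")
  structure(list(counts = counts, samples = samples, log = NULL),
            class = "crispacer_counts")
}

#' Per-guide fitness scores (log2 fold changes)
#'
#' Normalizes every sample to counts per million, adds a pseudocount and
#' computes, per replicate, `log2((stress + pc) / (control + pc))`; the mean
#' over replicates is the member's fitness score. Positive values mean
#' enrichment under stress.
#'
#' @param counts a `crispacer_counts`.
#' @param pseudocount added to normalized counts (default 0.5).
#' @return a list of class `crispacer_guide_fitness`: `per_replicate` (matrix
#'   members x replicates), `mean_log2fc` (named numeric), `samples`.
#' @export
guide_log2fc <- function(counts, pseudocount = 0.5) {
  assert_that(pseudocount > 0, "pseudocount must be > 0")
  totals <- colSums(counts$counts)
  assert_that(all(totals > 0), "sample with zero total counts")
  cpm <- sweep(counts$counts, 2, totals / 1e6, "/")
  reps <- sort(unique(counts$samples$replicate))
  lfc <- sapply(reps, function(r) {
    ctrl <- counts$samples$sample_id[counts$samples$replicate == r &
                                       counts$samples$condition == "control"]
    strs <- counts$samples$sample_id[counts$samples$replicate == r &
                                       counts$samples$condition == "stress"]
    log2((cpm[, strs] + pseudocount) / (cpm[, ctrl] + pseudocount))
  })
  lfc <- matrix(lfc, nrow = nrow(counts$counts),
                dimnames = list(rownames(counts$counts), paste0("rep", reps)))
  structure(list(per_replicate = lfc, mean_log2fc = rowMeans(lfc),
                 samples = counts$samples),
            class = "crispacer_guide_fitness")
}

#' Aggregate guide fitness to per-gene calls
#'
#' Averages fitness scores over all members targeting the same gene, tests
#' the pooled per-member-per-replicate log2 fold changes against zero
#' (two-sided one-sample t test by default; pluggable), corrects across genes
#' with Benjamini-Hochberg, and flags hits at the screen thresholds
#' `|mean log2FC| > lfc_cutoff` and `FDR < fdr_cutoff`.
#'
#' @param fitness a `crispacer_guide_fitness`.
#' @param manifest library manifest (member -> gene map).
#' @param lfc_cutoff absolute mean log2FC threshold (default 0.5).
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @param test_fun function mapping a numeric vector of pooled log2FC values
#'   to a two-sided p-value for a zero-location null; defaults to the
#'   one-sample t test.
#' @return a `data.frame` with one row per gene: `gene_id`, `n_members`,
#'   `mean_log2fc`, `p_value`, `fdr`, `hit`, `direction`.
#' @export
aggregate_srna <- function(fitness, manifest, lfc_cutoff = 0.5,
                           fdr_cutoff = 0.05, test_fun = NULL) {
  if (is.null(test_fun)) {
    test_fun <- function(x) {
      if (length(x) < 2L || stats::sd(x) == 0) return(NA_real_)
      stats::t.test(x, mu = 0)$p.value
    }
  }
  members <- rownames(fitness$per_replicate)
  gene_of <- setNames(manifest$gene_id, manifest$member_id)
  assert_that(all(members %in% names(gene_of)),
              "count matrix contains members absent from the manifest")
  genes <- unique(manifest$gene_id)
  rows <- lapply(genes, function(g) {
    mem <- members[gene_of[members] == g]
    if (length(mem) == 0L) {
      return(data.frame(gene_id = g, n_members = 0L,
                        mean_log2fc = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    mean_lfc <- mean(fitness$mean_log2fc[mem])
    pooled <- as.vector(fitness$per_replicate[mem, , drop = FALSE])
    data.frame(gene_id = g, n_members = length(mem), mean_log2fc = mean_lfc,
               p_value = test_fun(pooled), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res$hit <- !is.na(res$fdr) & abs(res$mean_log2fc) > lfc_cutoff &
    res$fdr < fdr_cutoff
  res$direction <- ifelse(is.na(res$mean_log2fc), NA_character_,
                          ifelse(res$mean_log2fc > 0, "enriched", "depleted"))
  res
}

#' Volcano-ready summary table
#'
#' @param srna output of [aggregate_srna()].
#' @return a `data.frame` with `gene_id`, `mean_log2fc`, `neg_log10_fdr`,
#'   `hit`.
#' @export
volcano_table <- function(srna) {
  data.frame(gene_id = srna$gene_id, mean_log2fc = srna$mean_log2fc,
             neg_log10_fdr = -log10(srna$fdr), hit = srna$hit,
             stringsAsFactors = FALSE)
}
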