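#' Generate a synthetic AT-rich genome with planted target genes
#'
#' Emulates the genomic context of an AT-rich gut bacterium: a random
#' sequence at a target GC fraction (default 35%) carrying non-overlapping
#' intergenic small-RNA-sized genes on both strands, each with a free
#' upstream promoter window. Optionally, selected genes are converted into
#' "PAM deserts": their promoter and gene body are rewritten without TT or AA
#' dinucleotides so that no TTV PAM exists on either strand, which must make
#' spacer design fail for them in a documented way.
#'
#' @param n_genes number of genes to plant.
#' @param genome_length replicon length in nt.
#' @param gc target GC fraction.
#' @param gene_length_range inclusive range of gene lengths.
#' @param promoter_window promoter width kept gene-free upstream of each TSS.
#' @param pam_desert_genes indices (into the planted genes) to strip of TTV
#'   PAMs.
#' @param circular circular replicon flag.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a list with `genome` (a `crispacer_genome`), `genes` (gene table)
#'   and the realized `gc`.
#' @export
make_genome <- function(n_genes = 20L, genome_length = 100000L, gc = 0.35,
                        gene_length_range = c(80L, 250L),
                        promoter_window = 50L, pam_desert_genes = integer(),
                        circular = FALSE, seed = 1L) {
  assert_that(gc > 0 && gc < 1, "gc must be in (0, 1)")
  withr::with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seq_chars <- sample(names(probs), genome_length, replace = TRUE,
                        prob = probs)
    # place genes with promoter + margin headroom, non-overlapping
    margin <- promoter_window + 10L
    slots <- place_intervals(n_genes, genome_length,
                             gene_length_range, margin)
    assert_that(nrow(slots) == n_genes,
                "genes do not fit the requested genome length")
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("srna%03d", seq_len(n_genes)),
      replicon_id = "chr",
      start = slots$start, end = slots$end, strand = strand,
      tss = ifelse(strand == "+", slots$start, slots$end - 1L),
      stringsAsFactors = FALSE)
    for (gi in pam_desert_genes) {
      g <- genes[gi, ]
      lo <- max(1L, g$start - promoter_window + 1L)
      hi <- min(genome_length, g$end + promoter_window)
      seq_chars[lo:hi] <- desert_sequence(hi - lo + 1L)
    }
    genome <- genome_from_seqs(
      setNames(paste(seq_chars, collapse = ""), "chr"), circular)
    list(genome = genome, genes = genes,
         gc = mean(seq_chars %in% c("G", "C")))
  })
}

# sequence without TT or AA dinucleotides (and hence without TTV on either
# strand); GC-neutral-ish alternation of all four bases
desert_sequence <- function(n) {
  out <- character(n)
  prev <- "C"
  pool <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    allowed <- setdiff(pool, if (prev %in% c("A", "T")) prev else character())
    out[i] <- sample(allowed, 1L)
    prev <- out[i]
  }
  out
}

place_intervals <- function(n, total_len, len_range, margin) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  needed <- sum(lens) + n * 2L * margin
  assert_that(needed <= total_len, "genes do not fit the genome length")
  # distribute the slack between genes deterministically given the RNG
  slack <- total_len - needed
  gaps <- if (n > 0) as.integer(stats::rmultinom(1, slack, rep(1, n + 1L)))
          else integer()
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i] + margin
    starts[i] <- pos
    pos <- pos + lens[i]
    ends[i] <- pos
    pos <- pos + margin
  }
  data.frame(start = starts, end = ends)
}

#' Write a fixture genome and annotation to files
#'
#' @param fixture output of [make_genome()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector with paths `fasta` and `gff3`.
#' @export
write_fixture <- function(fixture, dir, prefix = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  Biostrings::writeXStringSet(fixture$genome$seq, fasta)
  write_gff3(fixture$genes, gff)
  c(fasta = fasta, gff3 = gff)
}

write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attrs <- sprintf("ID=%s;tss=%d", g$gene_id, g$tss + 1L)
    writeLines(sprintf("%s\tcrispacer\tncRNA\t%d\t%d\t.\t%s\t.\t%s",
                       g$replicon_id, g$start + 1L, g$end, g$strand, attrs),
               con)
  }
  invisible(path)
}

#' Plant off-target decoys into a genome
#'
#' Copies chosen spacers back into intergenic space at a stated Hamming
#' distance, with or without a 5' TTV PAM, so that the off-target filter's
#' behaviour can be verified against ground truth.
#'
#' @param fixture output of [make_genome()].
#' @param decoys `data.frame` with columns `spacer` (sequence to mimic),
#'   `mismatches` (Hamming distance of the planted copy) and `pam` (logical:
#'   plant a TTV immediately 5' of the copy, else a non-PAM triplet).
#' @param seed integer seed for decoy placement and mutation choice.
#' @return the fixture with modified genome plus a `decoy_truth` data.frame
#'   (planted locus, strand, realized sequence, PAM).
#' @export
plant_decoys <- function(fixture, decoys, seed = 1L) {
  genome <- fixture$genome
  genes <- fixture$genes
  seq_chars <- strsplit(as.character(genome$seq[[1]]), "")[[1]]
  len <- length(seq_chars)
  occupied <- c()
  for (i in seq_len(nrow(genes)))
    occupied <- c(occupied, (genes$start[i] - 60L):(genes$end[i] + 60L))
  truth <- list()
  withr::with_seed(seed, {
    for (d in seq_len(nrow(decoys))) {
      spacer <- toupper(decoys$spacer[d])
      k <- nchar(spacer)
      need <- k + 3L
      repeat {
        pos <- sample(len - need - 10L, 1L)  # 0-based insert start for PAM
        span <- pos:(pos + need + 1L)
        if (!any(span %in% occupied)) break
      }
      occupied <- c(occupied, (pos - k):(pos + need + k))
      mutated <- mutate_spacer(spacer, decoys$mismatches[d])
      pam <- if (isTRUE(decoys$pam[d])) {
        paste0("TT", sample(c("A", "C", "G"), 1L))
      } else {
        "GAC"  # cannot be part of any TTV on the forward strand
      }
      insert <- paste0(pam, mutated)
      seq_chars[(pos + 1L):(pos + need)] <- strsplit(insert, "")[[1]]
      truth[[d]] <- data.frame(
        decoy = d, spacer = spacer, planted = mutated,
        mismatches = decoys$mismatches[d], pam = isTRUE(decoys$pam[d]),
        pam_sequence = pam, start = pos + 3L, end = pos + 3L + k,
        strand = "+", stringsAsFactors = FALSE)
    }
  })
  genome2 <- genome_from_seqs(
    setNames(paste(seq_chars, collapse = ""), names(genome$seq)[1]),
    genome$circular[[1]])
  fixture$genome <- genome2
  fixture$decoy_truth <- do.call(rbind, truth)
  fixture
}

mutate_spacer <- function(spacer, n_mismatch) {
  if (n_mismatch == 0L) return(spacer)
  chars <- strsplit(spacer, "")[[1]]
  pos <- sample(length(chars), n_mismatch)
  for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Build a library manifest for a fixture gene set
#'
#' Deterministic synthetic manifest: `members_per_gene` gRNA members per
#' gene with arbitrary distinct spacer sequences. Used by the screen
#' simulator when design output is not needed.
#'
#' @param gene_ids character vector of gene ids.
#' @param members_per_gene members per gene.
#' @param spacer_length spacer length.
#' @param seed integer seed.
#' @return a manifest `data.frame` (list-column `spacers`).
#' @export
synthetic_manifest <- function(gene_ids, members_per_gene = 4L,
                               spacer_length = 20L, seed = 1L) {
  withr::with_seed(seed, {
    n <- length(gene_ids) * members_per_gene
    spacers <- character(n)
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      repeat {
        s <- paste(sample(DNA_BASES, spacer_length, replace = TRUE),
                   collapse = "")
        if (is.null(seen[[s]])) { seen[[s]] <- TRUE; break }
      }
      spacers[i] <- s
    }
    data.frame(
      member_id = paste0(rep(gene_ids, each = members_per_gene), "_m",
                         rep(seq_len(members_per_gene), length(gene_ids))),
      type = "gRNA",
      spacers = I(as.list(spacers)),
      gene_id = rep(gene_ids, each = members_per_gene),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a two-condition pooled CRISPRi screen
#'
#' Baseline member abundances are drawn log-normal and normalized; the
#' stress-condition mean of members targeting an affected gene is multiplied
#' by `2^effect`. Counts are negative binomial with mean `mu` and variance
#' `mu + phi * mu^2` (`phi = 0` reduces to Poisson). The planted effects are
#' returned as ground truth.
#'
#' @param manifest library manifest.
#' @param effects named numeric vector of planted per-gene log2 fold changes
#'   (genes absent from it are null).
#' @param replicates number of replicate control/stress pairs.
#' @param depth expected total reads per sample.
#' @param phi negative binomial dispersion.
#' @param seed integer seed.
#' @return a list: `counts` (a `crispacer_counts`), `truth` (data.frame
#'   `gene_id`, `effect`).
#' @export
simulate_screen <- function(manifest, effects = numeric(), replicates = 3L,
                            depth = 1e6, phi = 0.1, seed = 1L) {
  assert_that(phi >= 0, "phi must be >= 0")
  withr::with_seed(seed, {
    n <- nrow(manifest)
    base <- rlnorm(n, meanlog = 0, sdlog = 1)
    base <- base / sum(base)
    eff <- setNames(rep(0, n), manifest$member_id)
    for (g in names(effects))
      eff[manifest$gene_id == g] <- effects[[g]]
    mu_ctrl <- depth * base
    mu_strs <- depth * base * 2^eff
    draw <- function(mu) {
      if (phi == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / phi)
    }
    samples <- data.frame(
      sample_id = paste0(rep(c("control", "stress"), replicates), "_r",
                         rep(seq_len(replicates), each = 2)),
      condition = rep(c("control", "stress"), replicates),
      replicate = rep(seq_len(replicates), each = 2),
      stringsAsFactors = FALSE)
    counts <- sapply(seq_len(nrow(samples)), function(si) {
      draw(if (samples$condition[si] == "control") mu_ctrl else mu_strs)
    })
    dimnames(counts) <- list(manifest$member_id, samples$sample_id)
    truth <- data.frame(gene_id = unique(manifest$gene_id),
                        stringsAsFactors = FALSE)
    truth$effect <- ifelse(truth$gene_id %in% names(effects),
                           unlist(effects)[truth$gene_id], 0)
    truth$effect[is.na(truth$effect)] <- 0
    list(counts = count_matrix(counts, samples), truth = truth)
  })
}

#' Render a count matrix as paired FASTQ amplicon reads
#'
#' Writes, per sample, `count` read pairs per member embedding the member's
#' (first) spacer between the constant flanks; read 2 is the reverse
#' complement of read 1. Base qualities are fixed at `I`. Intended for
#' small-scale verification of the counting path, not for large simulations.
#'
#' @param counts a `crispacer_counts`.
#' @param manifest library manifest.
#' @param dir output directory.
#' @param flank_5,flank_3 constant flanks.
#' @return the sample sheet with `fastq1`/`fastq2` path columns added.
#' @export
render_fastq <- function(counts, manifest, dir,
                         flank_5 = "ACGTTGGCTTAAGCG", flank_3 = "CGATCCTGAAGGTTC") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spacer1 <- vapply(manifest$spacers, `[`, character(1), 1L)
  names(spacer1) <- manifest$member_id
  samples <- counts$samples
  samples$fastq1 <- file.path(dir, paste0(samples$sample_id, "_R1.fastq"))
  samples$fastq2 <- file.path(dir, paste0(samples$sample_id, "_R2.fastq"))
  for (si in seq_len(nrow(samples))) {
    members <- rep(rownames(counts$counts), counts$counts[, si])
    amplicon <- paste0(flank_5, spacer1[members], flank_3)
    q <- strrep("I", nchar(amplicon))
    ids <- sprintf("@read%06d", seq_along(amplicon))
    writeLines(as.vector(rbind(ids, amplicon, "+", q)), samples$fastq1[si])
    writeLines(as.vector(rbind(ids, revcomp(amplicon), "+",
                               strrep("I", nchar(amplicon)))),
               samples$fastq2[si])
  }
  samples
}
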