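#' Design configuration
#'
#' Collects every tunable of the library designer with the defaults used
#' throughout the package. Unknown arguments are rejected, so configuration
#' typos fail loudly.
#'
#' @param spacer_length spacer (and protospacer) length in nt.
#' @param promoter_window promoter width in nt upstream of the TSS.
#' @param gc_min,gc_max preferred spacer GC-content window (fractions).
#' @param guides_per_gene number of single gRNAs designed per gene.
#' @param array_spacers_per_gene number of additional spacers reserved for the
#'   CRISPR array of each gene.
#' @param pam IUPAC motif of the PAM, 5' of the protospacer (Cas12a TTV).
#' @param extended_pam preferred extended PAM (TTTV); candidates whose PAM is
#'   part of this longer motif are prioritized.
#' @param offtarget_max_mismatch discard spacers with a second genomic site at
#'   up to this Hamming distance (PAM-adjacent); 2 means "fewer than three
#'   mismatches".
#' @param five_prime_fraction fraction of the gene length counted as the
#'   5' portion for ranking.
#' @param energy_window suboptimal-structure energy window (kcal/mol) for
#'   array folding validation.
#' @param max_structures cap on retained suboptimal structures.
#' @param array_attempt_cap maximum spacer triple/orderings tried per array.
#' @param strict_fold require a single structure in which every repeat folds
#'   (default `FALSE`: each repeat may fold in a different near-optimal
#'   structure).
#' @param trailing_repeat append a final direct repeat after the last spacer.
#' @param gibson_arm_5,gibson_arm_3 homology arms flanking single-gRNA spacers
#'   for Gibson assembly.
#' @param vector_overhang_left,vector_overhang_right constant 4-nt overhangs
#'   joining the first/last array unit to the destination vector.
#' @return a named list of class `crispacer_config`.
#' @export
design_config <- function(spacer_length = 20L,
                          promoter_window = 50L,
                          gc_min = 0.35,
                          gc_max = 0.75,
                          guides_per_gene = 3L,
                          array_spacers_per_gene = 3L,
                          pam = "TTV",
                          extended_pam = "TTTV",
                          offtarget_max_mismatch = 2L,
                          five_prime_fraction = 0.5,
                          energy_window = 2,
                          max_structures = 20L,
                          array_attempt_cap = 50L,
                          strict_fold = FALSE,
                          trailing_repeat = FALSE,
                          gibson_arm_5 = "GTTATAGTGCGTAACGTAGCTTG",
                          gibson_arm_3 = "CTTAGCTGGACTTGCACGTATCC",
                          vector_overhang_left = "AGGT",
                          vector_overhang_right = "CGCT") {
  cfg <- list(spacer_length = as.integer(spacer_length),
              promoter_window = as.integer(promoter_window),
              gc_min = gc_min, gc_max = gc_max,
              guides_per_gene = as.integer(guides_per_gene),
              array_spacers_per_gene = as.integer(array_spacers_per_gene),
              pam = pam, extended_pam = extended_pam,
              offtarget_max_mismatch = as.integer(offtarget_max_mismatch),
              five_prime_fraction = five_prime_fraction,
              energy_window = energy_window,
              max_structures = as.integer(max_structures),
              array_attempt_cap = as.integer(array_attempt_cap),
              strict_fold = strict_fold,
              trailing_repeat = trailing_repeat,
              gibson_arm_5 = toupper(gibson_arm_5),
              gibson_arm_3 = toupper(gibson_arm_3),
              vector_overhang_left = toupper(vector_overhang_left),
              vector_overhang_right = toupper(vector_overhang_right))
  assert_that(cfg$spacer_length >= 10L, "spacer_length must be >= 10")
  assert_that(cfg$gc_min >= 0 && cfg$gc_min < cfg$gc_max && cfg$gc_max <= 1,
              "need 0 <= gc_min < gc_max <= 1")
  assert_that(cfg$offtarget_max_mismatch >= 0L,
              "offtarget_max_mismatch must be >= 0")
  assert_that(cfg$five_prime_fraction > 0 && cfg$five_prime_fraction <= 1,
              "five_prime_fraction must be in (0, 1]")
  assert_that(is_valid_iupac(cfg$pam) && is_valid_iupac(cfg$extended_pam),
              "PAM motifs must be valid IUPAC strings")
  assert_that(nchar(cfg$vector_overhang_left) == 4L &&
                nchar(cfg$vector_overhang_right) == 4L,
              "vector overhangs must be 4 nt")
  structure(cfg, class = c("crispacer_config", "list"))
}

#' Read a design configuration from a YAML file
#'
#' Keys mirror the arguments of [design_config()]; unknown keys are rejected
#' with a message naming them.
#'
#' @param path YAML file path.
#' @return a `crispacer_config`.
#' @export
load_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(design_config))
  bad <- setdiff(names(vals), known)
  assert_that(length(bad) == 0,
              paste("unknown config key(s):", paste(bad, collapse = ", ")))
  do.call(design_config, vals)
}

#' GC fraction of a DNA sequence
#'
#' @param sequence DNA string(s) over A/C/G/T.
#' @return numeric vector: (#G + #C) / length.
#' @export
gc_fraction <- function(sequence) {
  assert_that(all(nchar(sequence) > 0), "empty sequence")
  vapply(sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    sum(chars %in% c("G", "C")) / length(chars)
  }, numeric(1), USE.NAMES = FALSE)
}

empty_candidates <- function() {
  data.frame(gene_id = character(), replicon_id = character(),
             spacer_sequence = character(), proto_start = integer(),
             proto_end = integer(), strand = character(),
             pam_start = integer(), pam_end = integer(),
             pam_sequence = character(), region_kind = character(),
             annealing = character(), gc = numeric(),
             tss_offset = integer(), extended_pam = logical(),
             five_prime_portion = logical(), stringsAsFactors = FALSE)
}

#' Enumerate candidate spacers for one gene
#'
#' Applies the Cas12a CRISPRi strand rules: within the promoter window the
#' protospacer may sit on either strand; within the transcribed region only
#' protospacers on the gene's coding (nontemplate) strand are allowed, so that
#' the gRNA anneals to the template strand. Every candidate consists of a PAM
#' match immediately 5' of a full spacer-length protospacer, both lying inside
#' the promoter-plus-gene window; candidates touching ambiguity-coded genome
#' positions are excluded. Candidates straddling the promoter/gene boundary
#' are classified by the position of the protospacer 5' end.
#'
#' @param gene one row of a gene table.
#' @param genome a `crispacer_genome`.
#' @param config a [design_config()].
#' @return a `data.frame` of candidates, one row each, with protospacer and
#'   PAM coordinates (0-based half-open, forward strand; `proto_end` may
#'   exceed the replicon length when the site wraps a circular origin),
#'   `region_kind`, `annealing` (`promoter_fwd`, `promoter_rev`, `template`),
#'   `gc`, `tss_offset` (protospacer 5' end relative to the TSS, in gene
#'   orientation), `extended_pam` and `five_prime_portion`.
#' @export
enumerate_candidates <- function(gene, genome, config = design_config()) {
  regions <- suppressWarnings(derive_regions(gene, genome,
                                             config$promoter_window))
  prom <- regions[regions$kind == "promoter", ]
  k <- config$spacer_length
  pam_len <- nchar(config$pam)
  len <- replicon_length(genome, gene$replicon_id)

  # contiguous promoter+gene window, in forward genomic coordinates
  win_start <- min(prom$start, gene$start)
  win_end <- max(prom$end, gene$end)
  if (win_end - win_start < pam_len + k) return(empty_candidates())
  win_seq <- extract_seq(genome, gene$replicon_id, win_start, win_end, "+")
  pam_hits <- scan_pattern(win_seq, config$pam, "both")
  if (nrow(pam_hits) == 0L) return(empty_candidates())

  rows <- list()
  gene_len <- gene$end - gene$start
  for (i in seq_len(nrow(pam_hits))) {
    p <- pam_hits$start[i] + win_start  # genomic forward coord of PAM start
    if (pam_hits$strand[i] == "+") {
      proto_start <- p + pam_len
      proto_end <- proto_start + k
      if (pam_hits$start[i] + pam_len + k > nchar(win_seq)) next
      pos5 <- proto_start
      ext_pos <- p - 1L  # base 5' of the PAM on the + strand
      ext_ok <- ext_pos >= win_start
      ext_base <- if (ext_ok) substr(win_seq, ext_pos - win_start + 1L,
                                     ext_pos - win_start + 1L) else ""
    } else {
      proto_end <- p
      proto_start <- proto_end - k
      if (pam_hits$start[i] - k < 0L) next
      pos5 <- proto_end - 1L
      ext_pos <- p + pam_len  # base 5' of the PAM on the - strand
      ext_ok <- ext_pos < win_end
      ext_base <- if (ext_ok) {
        revcomp(substr(win_seq, ext_pos - win_start + 1L,
                       ext_pos - win_start + 1L))
      } else ""
    }
    # classify by protospacer 5' end: inside the gene interval -> transcribed
    in_gene <- pos5 >= gene$start && pos5 < gene$end
    region_kind <- if (in_gene) "transcribed" else "promoter"
    strand <- pam_hits$strand[i]
    if (region_kind == "transcribed" && strand != gene$strand) next  # template rule
    annealing <- if (region_kind == "transcribed") "template"
                 else if (strand == gene$strand) "promoter_fwd"
                 else "promoter_rev"
    spacer <- substr(win_seq, proto_start - win_start + 1L,
                     proto_end - win_start + 1L - 1L)
    if (strand == "-") spacer <- revcomp(spacer)
    pam_seq <- substr(win_seq, p - win_start + 1L, p - win_start + pam_len)
    if (strand == "-") pam_seq <- revcomp(pam_seq)
    if (grepl("[^ACGT]", spacer) || grepl("[^ACGT]", pam_seq)) next
    tss_offset <- if (gene$strand == "+") pos5 - gene$tss else gene$tss - pos5
    dist_from_start <- if (gene$strand == "+") pos5 - gene$start
                       else (gene$end - 1L) - pos5
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene$gene_id, replicon_id = gene$replicon_id,
      spacer_sequence = spacer,
      proto_start = normalize_wrap(proto_start, len),
      proto_end = normalize_wrap(proto_start, len) + k,
      strand = strand,
      pam_start = normalize_wrap(p, len),
      pam_end = normalize_wrap(p, len) + pam_len,
      pam_sequence = pam_seq, region_kind = region_kind,
      annealing = annealing, gc = gc_fraction(spacer),
      tss_offset = as.integer(tss_offset),
      extended_pam = isTRUE(ext_ok && !grepl("[^ACGT]", ext_base) &&
                              iupac_match(paste0(ext_base, pam_seq),
                                          config$extended_pam)),
      five_prime_portion = in_gene &&
        dist_from_start < config$five_prime_fraction * gene_len,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_candidates())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# exact IUPAC membership test for equal-length strings
iupac_match <- function(seq, motif) {
  if (nchar(seq) != nchar(motif)) return(FALSE)
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  all(vapply(seq_along(s), function(i) s[i] %in% IUPAC_SETS[[m[i]]],
             logical(1)))
}

#' Rank spacer candidates for one gene
#'
#' Deterministic lexicographic order encoding the design priorities:
#' preferred GC content (within `[gc_min, gc_max]`) first, then region
#' (promoter, then 5' portion of the transcribed region, then 3' portion),
#' then extended TTTV PAM, then proximity of the protospacer 5' end to the
#' TSS; remaining ties break on forward-strand coordinate and strand.
#'
#' @param candidates output of [enumerate_candidates()].
#' @param config a [design_config()].
#' @return the candidates, reordered; a `rank` column is added.
#' @export
rank_candidates <- function(candidates, config = design_config()) {
  if (nrow(candidates) == 0L) {
    candidates$rank <- integer()
    return(candidates)
  }
  gc_ok <- candidates$gc >= config$gc_min & candidates$gc <= config$gc_max
  region_priority <- ifelse(candidates$region_kind == "promoter", 1L,
                            ifelse(candidates$five_prime_portion, 2L, 3L))
  ord <- order(!gc_ok, region_priority, !candidates$extended_pam,
               abs(candidates$tss_offset), candidates$proto_start,
               candidates$strand)
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Select gRNAs and array spacers for one gene
#'
#' Walks the ranked candidate list, testing each candidate against the
#' genome-wide off-target filter only when it could still be selected, and
#' fills up to `guides_per_gene` gRNA slots followed by
#' `array_spacers_per_gene` array-spacer slots. gRNAs prefer non-overlapping
#' protospacers but may overlap when nothing else remains; array spacers must
#' be pairwise non-overlapping and must not overlap any selected gRNA.
#' Candidates with preferred GC content are exhausted before any
#' out-of-window candidate is taken. Shortfalls are recorded in
#' `failure_notes`.
#'
#' @param gene one row of a gene table.
#' @param genome a `crispacer_genome`.
#' @param config a [design_config()].
#' @param index a `crispacer_offtarget_index` built over `genome` with the
#'   same config.
#' @return a list of class `crispacer_gene_design` with elements `gene_id`,
#'   `grnas` (data.frame), `array_spacers` (data.frame), `failure_notes`
#'   (character), and `n_candidates` / `n_tested` / `n_offtarget_discarded`
#'   bookkeeping counts.
#' @export
select_guides <- function(gene, genome, config = design_config(),
                          index = build_offtarget_index(genome, config)) {
  cands <- rank_candidates(enumerate_candidates(gene, genome, config), config)
  notes <- character()
  clean_cache <- rep(NA, nrow(cands))  # lazily filled off-target verdicts
  n_tested <- 0L
  is_clean <- function(i) {
    if (is.na(clean_cache[i])) {
      clean_cache[i] <<- offtarget_clean(cands[i, , drop = FALSE], index)
      n_tested <<- n_tested + 1L
    }
    clean_cache[i]
  }
  overlaps_any <- function(i, idx) {
    if (length(idx) == 0L) return(FALSE)
    any(intervals_overlap(cands$proto_start[i], cands$proto_end[i],
                          cands$proto_start[idx], cands$proto_end[idx]))
  }
  gc_ok <- cands$gc >= config$gc_min & cands$gc <= config$gc_max

  grna_idx <- integer()
  # four passes: preferred-GC non-overlapping, preferred-GC any, then the
  # same two for out-of-window candidates; this guarantees that when enough
  # preferred-GC candidates survive the filter, only those are selected
  for (pass in 1:4) {
    allow_overlap <- pass %in% c(2L, 4L)
    pool <- which(if (pass <= 2L) gc_ok else !gc_ok)
    for (i in pool) {
      if (length(grna_idx) >= config$guides_per_gene) break
      if (i %in% grna_idx) next
      if (!allow_overlap && overlaps_any(i, grna_idx)) next
      if (allow_overlap &&
          any(cands$proto_start[grna_idx] == cands$proto_start[i] &
              cands$strand[grna_idx] == cands$strand[i])) next
      if (is_clean(i)) grna_idx <- c(grna_idx, i)
    }
    if (length(grna_idx) >= config$guides_per_gene) break
  }
  if (length(grna_idx) < config$guides_per_gene)
    notes <- c(notes, sprintf(
      "insufficient spacers: %d of %d gRNAs designed",
      length(grna_idx), config$guides_per_gene))

  array_idx <- integer()
  for (pass in 1:2) {
    pool <- which(if (pass == 1L) gc_ok else !gc_ok)
    for (i in pool) {
      if (length(array_idx) >= config$array_spacers_per_gene) break
      if (i %in% c(grna_idx, array_idx)) next
      if (overlaps_any(i, c(grna_idx, array_idx))) next
      if (is_clean(i)) array_idx <- c(array_idx, i)
    }
    if (length(array_idx) >= config$array_spacers_per_gene) break
  }
  if (length(array_idx) < config$array_spacers_per_gene) {
    notes <- c(notes, sprintf(
      "insufficient spacers for array: %d of %d reserved",
      length(array_idx), config$array_spacers_per_gene))
    array_idx <- integer()  # an incomplete array is not emitted
  }

  tested <- which(!is.na(clean_cache))
  structure(list(
    gene_id = gene$gene_id,
    grnas = cands[grna_idx, , drop = FALSE],
    array_spacers = cands[array_idx, , drop = FALSE],
    failure_notes = notes,
    n_candidates = nrow(cands),
    n_tested = n_tested,
    n_offtarget_discarded = sum(!unlist(clean_cache[tested]))
  ), class = "crispacer_gene_design")
}

#' @export
print.crispacer_gene_design <- function(x, ...) {
  cat(sprintf("<crispacer_gene_design> %s: %d gRNA(s), %d array spacer(s)\n",
              x$gene_id, nrow(x$grnas), nrow(x$array_spacers)))
  if (length(x$failure_notes))
    cat("  notes:", paste(x$failure_notes, collapse = "; "), "\n")
  invisible(x)
}
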