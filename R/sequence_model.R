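#' Load a genome from a FASTA file
#'
#' Reads one or more replicons into a `crispacer_genome` object. Sequences are
#' uppercased on load; positions carrying IUPAC ambiguity codes (anything other
#' than A/C/G/T) are tolerated but recorded per replicon, so that downstream
#' spacer enumeration can exclude windows touching them.
#'
#' @param path path to a (multi-record) FASTA file.
#' @param circular logical scalar or vector (recycled / matched by replicon
#'   name) flagging circular replicons. Bacterial chromosomes and plasmids are
#'   typically circular; the default `FALSE` is the conservative choice for
#'   draft assemblies.
#' @return an object of class `crispacer_genome`: a list with elements
#'   `seq` ([Biostrings::DNAStringSet]), `circular` (named logical) and
#'   `ambiguous` (named list of 0-based positions of non-ACGT characters).
#' @export
load_genome <- function(path, circular = FALSE) {
  assert_that(file.exists(path), sprintf("genome FASTA not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header, as
  # annotation files refer to replicons by that token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_from_seqs(seqs, circular)
}

#' Build a genome object from in-memory sequences
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @inheritParams load_genome
#' @return a `crispacer_genome` object; see [load_genome()].
#' @export
genome_from_seqs <- function(seqs, circular = FALSE) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  assert_that(length(seqs) > 0, "genome has no records")
  assert_that(!is.null(names(seqs)) && !anyNA(names(seqs)) &&
                all(nzchar(names(seqs))), "every replicon needs an id")
  assert_that(!anyDuplicated(names(seqs)), "duplicate replicon ids")
  assert_that(all(Biostrings::width(seqs) > 0), "empty replicon sequence")
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  circular <- rep_len(as.logical(circular), length(seqs))
  names(circular) <- names(seqs)
  ambiguous <- lapply(as.character(seqs), function(s) {
    chars <- strsplit(s, "")[[1]]
    which(!chars %in% DNA_BASES) - 1L  # 0-based
  })
  structure(list(seq = seqs, circular = circular, ambiguous = ambiguous),
            class = "crispacer_genome")
}

#' @export
print.crispacer_genome <- function(x, ...) {
  cat(sprintf("<crispacer_genome> %d replicon(s), %s bp total\n",
              length(x$seq), format(sum(Biostrings::width(x$seq)),
                                    big.mark = ",")))
  for (id in names(x$seq)) {
    cat(sprintf("  %s: %d bp%s%s\n", id, Biostrings::width(x$seq[id]),
                if (x$circular[[id]]) " (circular)" else "",
                if (length(x$ambiguous[[id]]))
                  sprintf(", %d ambiguous", length(x$ambiguous[[id]])) else ""))
  }
  invisible(x)
}

replicon_length <- function(genome, replicon_id) {
  assert_that(replicon_id %in% names(genome$seq),
              sprintf("unknown replicon: %s", replicon_id))
  Biostrings::width(genome$seq[replicon_id])
}

#' Load target genes from GFF3 or BED
#'
#' Reads a target-gene table and converts it to the internal coordinate
#' convention (0-based, half-open, forward strand). GFF3 input is 1-based
#' inclusive; BED input is 0-based half-open. Strand is mandatory. The
#' transcription start site (TSS) defaults to the strand-aware 5' end of the
#' feature; a GFF3 attribute `tss` (1-based genomic coordinate) overrides it,
#' accommodating TSS-resolved annotations.
#'
#' @param path path to a `.gff`/`.gff3` or `.bed` file. Gene ids are taken
#'   from the GFF3 `ID`/`Name`/`locus_tag` attribute or the BED name column.
#' @param genome a `crispacer_genome`; coordinates are validated against it.
#' @param format `"auto"` (by file extension), `"gff3"` or `"bed"`.
#' @return a `data.frame` with columns `gene_id`, `replicon_id`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`), `tss` (0-based
#'   coordinate of the first transcribed base).
#' @export
load_targets <- function(path, genome, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("target file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3"
              else if (ext == "bed") "bed"
              else stop("cannot infer target file format from extension: ",
                        path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  ids <- if (format == "gff3") {
    m <- S4Vectors::mcols(gr)
    id <- m$ID %||% m$Name %||% m$locus_tag
    assert_that(!is.null(id), "GFF3 features need an ID, Name or locus_tag")
    as.character(id)
  } else {
    as.character(S4Vectors::mcols(gr)$name)
  }
  assert_that(!anyNA(ids) && all(nzchar(ids)), "missing gene id")
  assert_that(!anyDuplicated(ids), "duplicate gene ids in target table")
  strand <- as.character(BiocGenerics::strand(gr))
  assert_that(all(strand %in% c("+", "-")),
              "every target needs an explicit +/- strand")
  # GRanges is 1-based inclusive regardless of source format
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  repl <- as.character(GenomicRanges::seqnames(gr))
  for (i in seq_along(gr)) {
    assert_that(repl[i] %in% names(genome$seq),
                sprintf("gene %s on unknown replicon %s", ids[i], repl[i]))
    assert_that(start0[i] >= 0 && start0[i] < end0[i] &&
                  end0[i] <= replicon_length(genome, repl[i]),
                sprintf("gene %s has invalid coordinates [%d,%d)",
                        ids[i], start0[i], end0[i]))
  }
  tss <- ifelse(strand == "+", start0, end0 - 1L)
  if (format == "gff3") {
    tss_attr <- S4Vectors::mcols(gr)$tss
    if (!is.null(tss_attr)) {
      override <- !is.na(tss_attr)
      tss[override] <- as.integer(tss_attr[override]) - 1L  # 1-based in file
    }
  }
  genes <- data.frame(gene_id = ids, replicon_id = repl,
                      start = start0, end = end0, strand = strand,
                      tss = as.integer(tss), stringsAsFactors = FALSE)
  validate_gene_table(genes, genome)
  genes
}

validate_gene_table <- function(genes, genome) {
  needed <- c("gene_id", "replicon_id", "start", "end", "strand", "tss")
  assert_that(all(needed %in% names(genes)),
              paste("gene table needs columns:", paste(needed, collapse = ", ")))
  ok_tss <- ifelse(genes$strand == "+",
                   genes$tss >= genes$start & genes$tss < genes$end,
                   genes$tss >= genes$start & genes$tss < genes$end)
  assert_that(all(ok_tss), "TSS outside gene interval")
  invisible(genes)
}

#' Derive promoter and transcribed regions for a gene
#'
#' The promoter window covers `promoter_window` nucleotides immediately
#' upstream (strand-aware) of the TSS; the transcribed region is the annotated
#' gene interval itself. The two regions are adjacent at the TSS and never
#' overlap. On a linear replicon a promoter running off the sequence edge is
#' truncated and flagged.
#'
#' @param gene one row of a gene table (see [load_targets()]).
#' @param genome a `crispacer_genome`.
#' @param promoter_window promoter width in nt upstream of the TSS
#'   (default 50).
#' @return a `data.frame` with one row per region and columns `gene_id`,
#'   `kind` (`"promoter"`/`"transcribed"`), `replicon_id`, `start`, `end`
#'   (0-based half-open; a circular promoter may carry `start < 0`, meaning it
#'   wraps across the origin), `strand` and `truncated`.
#' @export
derive_regions <- function(gene, genome, promoter_window = 50L) {
  assert_that(promoter_window >= 1, "promoter_window must be >= 1")
  w <- as.integer(promoter_window)
  len <- replicon_length(genome, gene$replicon_id)
  circ <- genome$circular[[gene$replicon_id]]
  if (gene$strand == "+") {
    p_start <- gene$tss - w
    p_end <- gene$tss
  } else {
    p_start <- gene$tss + 1L
    p_end <- gene$tss + 1L + w
  }
  truncated <- FALSE
  if (!circ) {
    if (p_start < 0L) {
      p_start <- 0L
      truncated <- TRUE
    }
    if (p_end > len) {
      p_end <- len
      truncated <- TRUE
    }
    if (truncated)
      warning(sprintf("promoter of %s truncated at replicon edge",
                      gene$gene_id), call. = FALSE)
  }
  data.frame(
    gene_id = gene$gene_id,
    kind = c("promoter", "transcribed"),
    replicon_id = gene$replicon_id,
    start = c(p_start, gene$start),
    end = c(p_end, gene$end),
    strand = gene$strand,
    truncated = c(truncated, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Extract a sequence window from a genome
#'
#' Returns the 5'->3' sequence of `[start, end)` on the requested strand.
#' Intervals may run past either end of a circular replicon (they wrap); on a
#' linear replicon that is an error.
#'
#' @param genome a `crispacer_genome`.
#' @param replicon_id replicon name.
#' @param start,end 0-based half-open interval on the forward strand. `start`
#'   may be negative and `end` may exceed the replicon length when the
#'   replicon is circular.
#' @param strand `"+"` or `"-"`; `"-"` returns the reverse complement.
#' @return a single character string.
#' @export
extract_seq <- function(genome, replicon_id, start, end, strand = "+") {
  len <- replicon_length(genome, replicon_id)
  assert_that(start < end, "empty or inverted interval")
  assert_that(end - start <= len, "interval longer than replicon")
  circ <- genome$circular[[replicon_id]]
  if (!circ)
    assert_that(start >= 0 && end <= len,
                sprintf("interval [%d,%d) out of range on linear replicon %s",
                        start, end, replicon_id))
  s <- normalize_wrap(start, len)
  e <- s + (end - start)
  seq <- genome$seq[[replicon_id]]
  out <- if (e <= len) {
    as.character(Biostrings::subseq(seq, s + 1L, e))
  } else {
    paste0(as.character(Biostrings::subseq(seq, s + 1L, len)),
           as.character(Biostrings::subseq(seq, 1L, e - len)))
  }
  if (strand == "-") revcomp(out) else out
}

normalize_wrap <- function(pos, len) ((pos %% len) + len) %% len

# does [start,end) on this replicon touch an ambiguity-coded position?
window_has_ambiguity <- function(genome, replicon_id, start, end) {
  amb <- genome$ambiguous[[replicon_id]]
  if (length(amb) == 0L) return(FALSE)
  len <- replicon_length(genome, replicon_id)
  s <- normalize_wrap(start, len)
  e <- s + (end - start)
  if (e <= len) any(amb >= s & amb < e)
  else any(amb >= s | amb < e - len)
}
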