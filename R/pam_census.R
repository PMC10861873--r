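#' Default PAM pattern set
#'
#' The six protospacer-adjacent motifs recognized by commonly used Cas
#' nucleases: NGG (SpCas9), NNAGAA (Sth1Cas9), TTV (FnCas12a, Pb2Cas12a,
#' Lb6Cas12a), NNNNGATT (NmCas9), TTTV (AsCas12a) and NGRR (SaCas9). Cas12a
#' PAMs sit 5' of the protospacer, Cas9 PAMs 3' of it.
#'
#' @return a `data.frame` with columns `name`, `iupac` and `orientation`
#'   (`"five_prime_of_protospacer"` or `"three_prime_of_protospacer"`).
#' @export
default_pam_patterns <- function() {
  data.frame(
    name = c("SpCas9", "Sth1Cas9", "Cas12a_TTV", "NmCas9", "AsCas12a_TTTV",
             "SaCas9"),
    iupac = c("NGG", "NNAGAA", "TTV", "NNNNGATT", "TTTV", "NGRR"),
    orientation = c("three_prime_of_protospacer", "three_prime_of_protospacer",
                    "five_prime_of_protospacer", "three_prime_of_protospacer",
                    "five_prime_of_protospacer", "three_prime_of_protospacer"),
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence for an IUPAC motif
#'
#' Finds all (including overlapping) occurrences of an IUPAC motif on the
#' forward strand, the reverse strand, or both. Reverse-strand matches are
#' reported in forward coordinates. Windows containing a non-ACGT character
#' never match.
#'
#' @param sequence a DNA string (character scalar).
#' @param pattern IUPAC motif string, e.g. `"TTV"`.
#' @param strands `"both"` (default), `"forward"` or `"reverse"`.
#' @return a `data.frame` with columns `start`, `end` (0-based half-open,
#'   forward coordinates) and `strand`.
#' @export
scan_pattern <- function(sequence, pattern, strands = c("both", "forward", "reverse")) {
  strands <- match.arg(strands)
  assert_that(is_valid_iupac(pattern), sprintf("invalid IUPAC motif: %s", pattern))
  k <- nchar(pattern)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (nchar(sequence) < k) return(empty)
  subj <- Biostrings::DNAString(sequence)
  hits <- list()
  scan_one <- function(motif, strand_label) {
    m <- Biostrings::matchPattern(motif, subj, fixed = "subject")
    if (length(m) == 0L) return(NULL)
    st <- BiocGenerics::start(m) - 1L
    win <- as.character(m)
    clean <- !grepl("[^ACGT]", win)
    if (!any(clean)) return(NULL)
    data.frame(start = st[clean], end = st[clean] + k,
               strand = strand_label, stringsAsFactors = FALSE)
  }
  if (strands %in% c("both", "forward"))
    hits$fwd <- scan_one(pattern, "+")
  if (strands %in% c("both", "reverse"))
    hits$rev <- scan_one(revcomp(pattern), "-")
  out <- do.call(rbind, hits)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

# Scan a whole replicon, honouring circularity: a motif spanning the origin of
# a circular replicon is counted exactly once (reported with start in [0, len)
# and end possibly > len).
scan_replicon <- function(genome, replicon_id, pattern,
                          strands = "both") {
  len <- replicon_length(genome, replicon_id)
  k <- nchar(pattern)
  seq <- as.character(genome$seq[[replicon_id]])
  if (genome$circular[[replicon_id]] && k > 1L && len > k) {
    ext <- paste0(seq, substr(seq, 1L, k - 1L))
    hits <- scan_pattern(ext, pattern, strands)
    hits[hits$start < len, , drop = FALSE]
  } else {
    scan_pattern(seq, pattern, strands)
  }
}

#' PAM occurrence census across a gene set
#'
#' Counts motif occurrences (both strands, overlaps included) of each PAM
#' pattern within each gene's interval, plus a genome-wide count and density
#' per kb for every pattern. This is the analysis used to pick a nuclease
#' whose PAM is abundant in the targeted gene set: in AT-rich genomes the
#' Cas12a TTV motif typically dwarfs the Cas9 NGG motif.
#'
#' @param genes a gene table (see [load_targets()]).
#' @param genome a `crispacer_genome`.
#' @param patterns a PAM pattern table; defaults to [default_pam_patterns()].
#' @return an object of class `crispacer_census`: a list with `counts`
#'   (data.frame, one row per gene, one column per pattern), `genome_wide`
#'   (data.frame with `pattern`, `count`, `density_per_kb`).
#' @export
pam_census <- function(genes, genome, patterns = default_pam_patterns()) {
  counts <- matrix(0L, nrow = nrow(genes), ncol = nrow(patterns),
                   dimnames = list(genes$gene_id, patterns$name))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gene_seq <- extract_seq(genome, g$replicon_id, g$start, g$end, "+")
    for (j in seq_len(nrow(patterns))) {
      counts[i, j] <- nrow(scan_pattern(gene_seq, patterns$iupac[j], "both"))
    }
  }
  total_len <- sum(Biostrings::width(genome$seq))
  gw <- vapply(seq_len(nrow(patterns)), function(j) {
    sum(vapply(names(genome$seq), function(id) {
      nrow(scan_replicon(genome, id, patterns$iupac[j], "both"))
    }, integer(1)))
  }, integer(1))
  structure(list(
    counts = as.data.frame(counts),
    genome_wide = data.frame(pattern = patterns$name, count = gw,
                             density_per_kb = gw / (total_len / 1000),
                             stringsAsFactors = FALSE)
  ), class = "crispacer_census")
}

#' @export
print.crispacer_census <- function(x, ...) {
  cat(sprintf("<crispacer_census> %d genes x %d PAM patterns\n",
              nrow(x$counts), ncol(x$counts)))
  cat("mean per-gene counts:\n")
  print(round(colMeans(x$counts), 2))
  invisible(x)
}

#' Write a census to TSV
#'
#' One row per gene, one column per PAM pattern, followed by genome-wide
#' summary rows (`#genome_wide` / `#density_per_kb`).
#'
#' @param census a `crispacer_census`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  df <- cbind(gene_id = rownames(census$counts), census$counts)
  footer <- rbind(
    c("#genome_wide", as.character(census$genome_wide$count)),
    c("#density_per_kb", sprintf("%.4f", census$genome_wide$density_per_kb))
  )
  con <- file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(footer, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
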