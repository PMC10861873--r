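# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's scanning/matching code paths: motif
# matching expands IUPAC codes by table lookup over every window, and the
# off-target oracle is a vectorized sliding-window Hamming scan.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# every window of |motif| on the chosen strand(s), checked by IUPAC table
oracle_scan <- function(sequence, motif, strands = "both") {
  k <- nchar(motif)
  n <- nchar(sequence)
  hits <- list()
  check <- function(win, mot) {
    wc <- strsplit(win, "")[[1]]
    mc <- strsplit(mot, "")[[1]]
    all(vapply(seq_len(k), function(i) wc[i] %in% ORACLE_IUPAC[[mc[i]]],
               logical(1)))
  }
  if (n >= k) {
    for (i in 0:(n - k)) {
      win <- substr(sequence, i + 1, i + k)
      if (grepl("[^ACGT]", win)) next
      if (strands %in% c("both", "forward") && check(win, motif))
        hits[[length(hits) + 1]] <- data.frame(start = i, end = i + k,
                                               strand = "+")
      if (strands %in% c("both", "reverse") &&
          check(oracle_revcomp(win), motif))
        hits[[length(hits) + 1]] <- data.frame(start = i, end = i + k,
                                               strand = "-")
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# vectorized per-offset Hamming scan of one strand for PAM-adjacent hits
oracle_scan_strand <- function(chars, spacer, max_mm) {
  k <- nchar(spacer)
  n <- length(chars)
  if (n < k + 3) return(data.frame(start = integer(), mismatches = integer()))
  sc <- strsplit(spacer, "")[[1]]
  starts <- (3:(n - k)) + 1L  # 1-based window starts with room for the PAM
  mm <- integer(length(starts))
  for (j in seq_len(k)) {
    cj <- chars[starts + j - 1L]
    mm <- mm + (cj != sc[j]) + 10L * !(cj %in% c("A", "C", "G", "T"))
  }
  pam_ok <- chars[starts - 3L] == "T" & chars[starts - 2L] == "T" &
    chars[starts - 1L] %in% c("A", "C", "G")
  keep <- mm <= max_mm & pam_ok
  data.frame(start = starts[keep] - 1L, mismatches = mm[keep])
}

# full-genome off-target oracle; same output convention as find_offtargets
oracle_offtargets <- function(genome, spacer, max_mm,
                              exclude = NULL) {
  k <- nchar(spacer)
  out <- list()
  for (id in names(genome$seq)) {
    fwd <- as.character(genome$seq[[id]])
    len <- nchar(fwd)
    circ <- genome$circular[[id]]
    for (str in c("+", "-")) {
      s <- if (str == "+") fwd else oracle_revcomp(fwd)
      if (circ) {
        s <- paste0(substr(s, len - 2, len), s, substr(s, 1, k + 2))
        off <- 3L
      } else off <- 0L
      chars <- strsplit(s, "")[[1]]
      h <- oracle_scan_strand(chars, spacer, max_mm)
      h$start <- h$start - off
      h <- h[h$start >= 0 & h$start < len, , drop = FALSE]
      if (nrow(h) == 0) next
      fstart <- if (str == "+") h$start else len - h$start - k
      fstart <- ((fstart %% len) + len) %% len
      out[[length(out) + 1]] <- data.frame(
        replicon_id = id, start = fstart, end = fstart + k, strand = str,
        mismatches = h$mismatches, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(out)) do.call(rbind, out)
          else data.frame(replicon_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          mismatches = integer())
  if (!is.null(exclude) && nrow(hits)) {
    hits <- hits[!(hits$replicon_id == exclude$replicon_id &
                     hits$start == exclude$start &
                     hits$strand == exclude$strand), , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits[order(hits$replicon_id, hits$start, hits$strand), , drop = FALSE]
}

hit_key <- function(df) {
  if (nrow(df) == 0) return(character())
  sort(paste(df$replicon_id, df$start, df$strand, df$mismatches))
}

random_dna <- function(n, gc = 0.35) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# sequence guaranteed free of TTV on either strand (no TT and no AA
# dinucleotides), used to build controlled promoter/gene backbones
pamfree_dna <- function(n) {
  out <- character(n)
  prev <- "C"
  for (i in seq_len(n)) {
    pool <- setdiff(c("A", "C", "G", "T"),
                    if (prev %in% c("A", "T")) prev else character())
    out[i] <- sample(pool, 1)
    prev <- out[i]
  }
  paste(out, collapse = "")
}

# a synthetic gene fixture on a single linear replicon with controlled
# flanks; returns list(genome, gene)
toy_gene <- function(promoter, body, strand = "+", pad = 30) {
  left <- strrep("C", pad)
  right <- strrep("G", pad)
  if (strand == "+") {
    seq <- paste0(left, promoter, body, right)
    start <- pad + nchar(promoter)
    end <- start + nchar(body)
    tss <- start
  } else {
    seq <- paste0(left, oracle_revcomp(body), oracle_revcomp(promoter), right)
    start <- pad
    end <- start + nchar(body)
    tss <- end - 1
  }
  genome <- genome_from_seqs(c(chr = seq))
  gene <- data.frame(gene_id = "toy", replicon_id = "chr",
                     start = start, end = end, strand = strand, tss = tss,
                     stringsAsFactors = FALSE)
  list(genome = genome, gene = gene)
}
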