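#' Build an off-target search index over a genome
#'
#' Precomputes, for every replicon, the forward and reverse-complement strand
#' sequences padded for PAM lookup and (on circular replicons) origin wrap,
#' so that repeated off-target queries avoid re-deriving them. The search
#' itself is an early-exit Hamming scan in compiled code; results are
#' identical to a naive sliding-window scan.
#'
#' @param genome a `crispacer_genome`.
#' @param config a [design_config()]; `spacer_length` fixes the window size
#'   the index serves, `offtarget_max_mismatch` the default mismatch budget.
#' @return an object of class `crispacer_offtarget_index`.
#' @export
build_offtarget_index <- function(genome, config = design_config()) {
  k <- config$spacer_length
  replicons <- lapply(names(genome$seq), function(id) {
    fwd <- as.character(genome$seq[[id]])
    len <- nchar(fwd)
    circ <- genome$circular[[id]]
    pad_strand <- function(s) {
      if (circ && len > 3L) {
        # 3 nt of left context for the PAM, k+2 nt of right context so that
        # windows starting at the last forward position still fit
        paste0(substr(s, len - 2L, len), s, substr(s, 1L, min(len, k + 2L)))
      } else {
        s
      }
    }
    list(id = id, len = len, circular = circ,
         fwd = pad_strand(fwd), rc = pad_strand(revcomp(fwd)),
         offset = if (circ && len > 3L) 3L else 0L)
  })
  names(replicons) <- names(genome$seq)
  structure(list(replicons = replicons, spacer_length = k,
                 max_mismatch = config$offtarget_max_mismatch),
            class = "crispacer_offtarget_index")
}

#' @export
print.crispacer_offtarget_index <- function(x, ...) {
  cat(sprintf("<crispacer_offtarget_index> %d replicon(s), spacer length %d, max mismatch %d\n",
              length(x$replicons), x$spacer_length, x$max_mismatch))
  invisible(x)
}

#' Find near-identical PAM-adjacent second sites for a spacer
#'
#' Scans both strands of every replicon for windows of spacer length whose
#' Hamming distance to the spacer is at most `max_mismatch` and that carry a
#' TTV PAM immediately 5' on the same strand. The intended protospacer locus
#' itself (exact replicon + interval + strand identity) is excluded; a shifted
#' overlapping window does count as a second site. Indels are not considered.
#'
#' @param spacer spacer sequence (character scalar), or a one-row candidate
#'   data.frame from [enumerate_candidates()] (its protospacer locus is then
#'   used for self-exclusion).
#' @param index a `crispacer_offtarget_index` from [build_offtarget_index()].
#' @param max_mismatch mismatch budget; defaults to the index's setting
#'   (2, i.e. "fewer than three mismatches").
#' @return a `data.frame` with columns `replicon_id`, `start`, `end` (0-based
#'   half-open forward coordinates; `end` may exceed the replicon length when
#'   the hit wraps a circular origin), `strand`, `mismatches` and
#'   `pam_sequence`.
#' @export
find_offtargets <- function(spacer, index, max_mismatch = NULL) {
  if (is.data.frame(spacer)) {
    self <- spacer[1, c("replicon_id", "proto_start", "strand")]
    query <- spacer$spacer_sequence[1]
  } else {
    self <- NULL
    query <- as.character(spacer)
  }
  assert_that(nchar(query) == index$spacer_length,
              sprintf("spacer length %d does not match index (%d)",
                      nchar(query), index$spacer_length))
  mm_max <- max_mismatch %||% index$max_mismatch
  k <- index$spacer_length
  out <- list()
  for (rep in index$replicons) {
    len <- rep$len
    for (str in c("+", "-")) {
      subj <- if (str == "+") rep$fwd else rep$rc
      h <- .pam_mismatch_scan(subj, query, mm_max, 3L, nchar(subj) - k)
      if (nrow(h) == 0L) next
      # position on the scanned (strand-local) sequence, unpadded
      local <- h$start - rep$offset
      keep <- local >= 0L & local < len
      if (!any(keep)) next
      local <- local[keep]
      mms <- h$mismatches[keep]
      if (str == "+") {
        start <- local
      } else {
        start <- len - local - k  # forward coordinates of the rc window
      }
      start_norm <- normalize_wrap(start, len)
      pam <- vapply(seq_along(local), function(i) {
        if (str == "+") {
          substr_wrap(rep$fwd, rep$offset + local[i] - 3L + 1L, 3L)
        } else {
          substr_wrap(rep$rc, rep$offset + local[i] - 3L + 1L, 3L)
        }
      }, character(1))
      out[[length(out) + 1L]] <- data.frame(
        replicon_id = rep$id, start = start_norm, end = start_norm + k,
        strand = str, mismatches = mms, pam_sequence = pam,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(out)) do.call(rbind, out)
          else data.frame(replicon_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          mismatches = integer(), pam_sequence = character(),
                          stringsAsFactors = FALSE)
  if (!is.null(self) && nrow(hits)) {
    len_self <- index$replicons[[self$replicon_id]]$len
    self_start <- normalize_wrap(self$proto_start, len_self)
    drop <- hits$replicon_id == self$replicon_id &
      hits$start == self_start & hits$strand == self$strand
    hits <- hits[!drop, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits[order(hits$replicon_id, hits$start, hits$strand), , drop = FALSE]
}

substr_wrap <- function(s, start1, n) substr(s, start1, start1 + n - 1L)

#' Is a spacer free of off-target sites?
#'
#' @inheritParams find_offtargets
#' @return `TRUE` when [find_offtargets()] returns no hit.
#' @export
offtarget_clean <- function(spacer, index, max_mismatch = NULL) {
  nrow(find_offtargets(spacer, index, max_mismatch)) == 0L
}
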