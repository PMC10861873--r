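#' Predict near-optimal RNA secondary structures
#'
#' Adapter around the ViennaRNA `RNAsubopt` program: returns the
#' minimum-free-energy (MFE) structure plus all suboptimal structures within
#' `energy_window` kcal/mol of it, sorted by ascending free energy and capped
#' at `max_structures`. DNA input is transcribed (T -> U) before folding.
#'
#' @param sequence nucleotide string (DNA or RNA alphabet).
#' @param energy_window energy band above the MFE, kcal/mol (`0` retains only
#'   the MFE structure(s)).
#' @param max_structures maximum number of structures returned.
#' @return a `data.frame` with columns `structure` (dot-bracket) and `energy`
#'   (kcal/mol).
#' @export
fold <- function(sequence, energy_window = 2, max_structures = 20L) {
  assert_that(nchar(sequence) > 0, "cannot fold an empty sequence")
  assert_that(energy_window >= 0, "energy_window must be >= 0")
  bin <- Sys.which("RNAsubopt")
  assert_that(nzchar(bin),
              "RNAsubopt not found on PATH; install ViennaRNA to validate array folding")
  rna <- chartr("Tt", "Uu", toupper(sequence))
  out <- system2(bin, args = c("-e", format(energy_window), "-s"),
                 input = rna, stdout = TRUE, stderr = FALSE)
  status <- attr(out, "status") %||% 0L
  assert_that(status == 0L, "RNAsubopt failed")
  # first line echoes the sequence (with the energy range); the rest are
  # "structure energy" pairs, already sorted by energy under -s
  lines <- out[-1]
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexpr("^[.()]+", lines))
  energies <- as.numeric(sub("^[.()]+\\s+", "", lines))
  keep <- seq_len(min(length(parts), max_structures))
  res <- data.frame(structure = parts[keep], energy = energies[keep],
                    stringsAsFactors = FALSE)
  assert_that(all(nchar(res$structure) == nchar(sequence)),
              "folding engine returned malformed structures")
  res
}

# dot-bracket -> integer matrix of (i, j) pairs, 0-based, i < j
dotbracket_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer()
  pairs <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      assert_that(length(stack) > 0, "unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[[length(pairs) + 1L]] <- c(j - 1L, i - 1L)
    }
  }
  assert_that(length(stack) == 0, "unbalanced dot-bracket string")
  if (length(pairs) == 0L)
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  m <- do.call(rbind, pairs)
  colnames(m) <- c("i", "j")
  m[order(m[, "i"]), , drop = FALSE]
}

#' Define a direct-repeat unit
#'
#' A Cas12a direct repeat together with the reference base pairs of its
#' 3'-terminal hairpin, derived once from the MFE structure of the isolated
#' repeat (see [reference_hairpin()]). Cas12a recognizes and cleaves this
#' hairpin when processing a primary array transcript into mature gRNAs, so
#' array validation checks that every repeat copy can still form exactly
#' these pairs in the context of the full transcript.
#'
#' @param name repeat name.
#' @param dna_sequence repeat sequence (DNA alphabet).
#' @return a list of class `crispacer_repeat` with `name`, `dna_sequence` and
#'   `reference_pairs` (0-based repeat-local index pairs).
#' @export
repeat_unit <- function(name, dna_sequence) {
  dna_sequence <- toupper(dna_sequence)
  assert_that(!grepl("[^ACGT]", dna_sequence),
              "repeat sequence must be plain A/C/G/T")
  rp <- structure(list(name = name, dna_sequence = dna_sequence,
                       reference_pairs = NULL),
                  class = "crispacer_repeat")
  rp$reference_pairs <- reference_hairpin(rp)
  rp
}

#' Bundled synthetic direct repeat
#'
#' A 26-nt synthetic stand-in for a Cas12a direct repeat: an AT-rich 5'
#' segment followed by a stable 6-bp GC stem closed by a GAAA tetraloop at
#' the 3' terminus. It is not any natural repeat; real libraries should
#' supply their nuclease's repeat via [repeat_unit()].
#'
#' @return a `crispacer_repeat`.
#' @export
synthetic_repeat <- function() {
  repeat_unit("synthetic_dr", "AATTTCTACTGGCAGCGAAAGCTGCC")
}

#' Reference hairpin pairs of an isolated repeat
#'
#' Folds the repeat alone, takes its MFE structure and returns the base pairs
#' of the 3'-terminal stem-loop: the pairs enclosing the 3'-most hairpin loop
#' without enclosing any other hairpin loop. An unstructured repeat (no pairs
#' in the MFE structure) is unusable and raises an error.
#'
#' @param rep a `crispacer_repeat` (its `reference_pairs` may still be
#'   unset).
#' @return integer matrix of 0-based `(i, j)` pairs.
#' @export
reference_hairpin <- function(rep) {
  mfe <- fold(rep$dna_sequence, energy_window = 0, max_structures = 1L)
  pairs <- dotbracket_pairs(mfe$structure[1])
  assert_that(nrow(pairs) > 0,
              sprintf("repeat %s is predicted unstructured; unusable", rep$name))
  # hairpin-closing pairs: no other pair nested inside
  closing <- vapply(seq_len(nrow(pairs)), function(r) {
    !any(pairs[, "i"] > pairs[r, "i"] & pairs[, "j"] < pairs[r, "j"])
  }, logical(1))
  terminal <- which(closing)[which.max(pairs[closing, "i"])]
  ti <- pairs[terminal, "i"]; tj <- pairs[terminal, "j"]
  # the terminal helix: pairs enclosing the 3'-most hairpin loop but no other
  enclosing <- pairs[, "i"] <= ti & pairs[, "j"] >= tj
  other_loops <- which(closing)[which(closing) != terminal]
  clean <- vapply(seq_len(nrow(pairs)), function(r) {
    !any(pairs[other_loops, "i"] > pairs[r, "i"] &
           pairs[other_loops, "j"] < pairs[r, "j"])
  }, logical(1))
  out <- pairs[enclosing & clean, , drop = FALSE]
  assert_that(nrow(out) > 0,
              sprintf("repeat %s has no 3'-terminal hairpin", rep$name))
  out
}

#' Assemble a CRISPR array transcript
#'
#' Concatenates `(repeat + spacer)` units in order, optionally closing with a
#' trailing repeat, and records the transcript-local interval of every repeat
#' copy.
#'
#' @param gene_id target gene id.
#' @param rep a `crispacer_repeat`.
#' @param spacers character vector of spacer sequences, in array order.
#' @param trailing_repeat append a final repeat after the last spacer.
#' @return a list of class `crispacer_array` with `gene_id`, `units`,
#'   `full_sequence`, `repeat_intervals` (0-based half-open, transcript
#'   coordinates), `spacer_intervals` and `trailing_repeat`.
#' @export
array_transcript <- function(gene_id, rep, spacers, trailing_repeat = FALSE) {
  assert_that(length(spacers) >= 1, "array needs at least one spacer")
  rl <- nchar(rep$dna_sequence)
  units <- lapply(spacers, function(s) list(repeat_name = rep$name, spacer = s))
  pieces <- character()
  rep_iv <- list(); sp_iv <- list()
  pos <- 0L
  for (s in spacers) {
    rep_iv[[length(rep_iv) + 1L]] <- c(pos, pos + rl)
    pieces <- c(pieces, rep$dna_sequence)
    pos <- pos + rl
    sp_iv[[length(sp_iv) + 1L]] <- c(pos, pos + nchar(s))
    pieces <- c(pieces, s)
    pos <- pos + nchar(s)
  }
  if (trailing_repeat) {
    rep_iv[[length(rep_iv) + 1L]] <- c(pos, pos + rl)
    pieces <- c(pieces, rep$dna_sequence)
  }
  structure(list(gene_id = gene_id, repeat_unit = rep, units = units,
                 full_sequence = paste(pieces, collapse = ""),
                 repeat_intervals = do.call(rbind, rep_iv),
                 spacer_intervals = do.call(rbind, sp_iv),
                 trailing_repeat = trailing_repeat),
            class = "crispacer_array")
}

#' Validate the folding of a CRISPR array transcript
#'
#' Folds the full primary transcript and checks, for every repeat copy, that
#' its reference 3'-terminal hairpin pairs all occur in at least one of the
#' most probable structures (MFE plus suboptimals within `energy_window`). In
#' the default per-instance mode each repeat may be satisfied by a different
#' structure; in strict mode one single structure must satisfy all repeats
#' simultaneously.
#'
#' @param array a `crispacer_array`.
#' @param energy_window,max_structures see [fold()].
#' @param strict require a single structure covering all repeat instances.
#' @return a list of class `crispacer_fold_report`: `instances` (data.frame
#'   with `instance`, `start`, `end`, `pass`, `structure_index`), `pass`
#'   (overall), `n_structures`, `strict`.
#' @export
check_array_folding <- function(array, energy_window = 2,
                                max_structures = 20L, strict = FALSE) {
  structs <- fold(array$full_sequence, energy_window, max_structures)
  pair_sets <- lapply(structs$structure, dotbracket_pairs)
  ref <- array$repeat_unit$reference_pairs
  n_inst <- nrow(array$repeat_intervals)
  sat_matrix <- matrix(FALSE, nrow = n_inst, ncol = length(pair_sets))
  for (ii in seq_len(n_inst)) {
    off <- array$repeat_intervals[ii, 1]
    want <- ref + off
    for (ss in seq_along(pair_sets)) {
      ps <- pair_sets[[ss]]
      have <- paste(ps[, 1], ps[, 2])
      sat_matrix[ii, ss] <- all(paste(want[, 1], want[, 2]) %in% have)
    }
  }
  if (strict) {
    full <- which(colSums(sat_matrix) == n_inst)
    pass_inst <- rep(length(full) > 0, n_inst)
    first_idx <- rep(if (length(full)) full[1] else NA_integer_, n_inst)
  } else {
    pass_inst <- apply(sat_matrix, 1, any)
    first_idx <- apply(sat_matrix, 1, function(x)
      if (any(x)) which(x)[1] else NA_integer_)
  }
  structure(list(
    instances = data.frame(instance = seq_len(n_inst),
                           start = array$repeat_intervals[, 1],
                           end = array$repeat_intervals[, 2],
                           pass = pass_inst,
                           structure_index = first_idx),
    pass = all(pass_inst),
    n_structures = nrow(structs),
    strict = strict
  ), class = "crispacer_fold_report")
}

#' @export
print.crispacer_fold_report <- function(x, ...) {
  cat(sprintf("<crispacer_fold_report> %s (%d structure(s) examined%s)\n",
              if (x$pass) "PASS" else "FAIL", x$n_structures,
              if (x$strict) ", strict" else ""))
  print(x$instances)
  invisible(x)
}

#' Design a folding-validated CRISPR array for one gene
#'
#' Iterates over orderings (and, when more spacers than needed are supplied,
#' subsets) of the gene's reserved array spacers, assembling each candidate
#' transcript and keeping the first one whose every repeat passes
#' [check_array_folding()]. Attempts are capped; on exhaustion the gene keeps
#' its single gRNAs only.
#'
#' @param gene_design a `crispacer_gene_design` from [select_guides()].
#' @param rep a `crispacer_repeat`.
#' @param config a [design_config()].
#' @return a list with `array` (a `crispacer_array`, or `NULL` on failure),
#'   `report` (the passing fold report, or `NULL`), `attempts`, and
#'   `failure_note` (`NULL` on success).
#' @export
design_array <- function(gene_design, rep, config = design_config()) {
  n_need <- config$array_spacers_per_gene
  sp <- gene_design$array_spacers
  if (nrow(sp) < n_need) {
    return(list(array = NULL, report = NULL, attempts = 0L,
                failure_note = "insufficient spacers for array"))
  }
  triples <- combn(seq_len(nrow(sp)), n_need, simplify = FALSE)
  orderings <- all_permutations(n_need)
  attempts <- 0L
  for (tri in triples) {
    for (perm in orderings) {
      if (attempts >= config$array_attempt_cap) {
        return(list(array = NULL, report = NULL, attempts = attempts,
                    failure_note = sprintf(
                      "array folding failed (attempt cap %d reached)",
                      config$array_attempt_cap)))
      }
      attempts <- attempts + 1L
      arr <- array_transcript(gene_design$gene_id, rep,
                              sp$spacer_sequence[tri[perm]],
                              trailing_repeat = config$trailing_repeat)
      rep_report <- check_array_folding(arr, config$energy_window,
                                        config$max_structures,
                                        config$strict_fold)
      if (rep_report$pass) {
        arr$spacer_rows <- sp[tri[perm], , drop = FALSE]
        return(list(array = arr, report = rep_report, attempts = attempts,
                    failure_note = NULL))
      }
    }
  }
  list(array = NULL, report = NULL, attempts = attempts,
       failure_note = "improper folding of all possible arrays")
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
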