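#' Emit a Gibson assembly fragment for a single gRNA spacer
#'
#' @param member_id fragment name.
#' @param spacer spacer sequence.
#' @param arm_5,arm_3 homology arms (non-empty) matching the destination
#'   vector around the spacer cloning site.
#' @return a list of class `crispacer_gibson` with `member_id`, `sequence`
#'   (5' arm + spacer + 3' arm, reported 5'->3'), `arm_5`, `spacer`, `arm_3`.
#' @export
emit_gibson <- function(member_id, spacer, arm_5, arm_3) {
  assert_that(!is.null(arm_5) && !is.null(arm_3) &&
                nzchar(arm_5) && nzchar(arm_3),
              "both Gibson homology arms must be configured and non-empty")
  structure(list(member_id = member_id,
                 sequence = paste0(arm_5, spacer, arm_3),
                 arm_5 = arm_5, spacer = spacer, arm_3 = arm_3),
            class = "crispacer_gibson")
}

is_palindromic4 <- function(x) x == revcomp(x)

#' Emit a Golden-Gate style oligo set for a CRISPR array
#'
#' Partitions the array DNA at its repeat-spacer unit boundaries and emits,
#' per unit, a top-strand and a bottom-strand oligo offset by 4 nt, so that
#' annealing each pair leaves 4-nt single-stranded overhangs at the unit
#' junctions. Ligating the units in order reconstructs the full array duplex.
#' Internal junction overhangs default to the first 4 nt of the downstream
#' unit; the outermost (vector-facing) overhangs are configured constants.
#' All overhangs must be pairwise distinct and non-palindromic; on a clash
#' the offending junction is shifted by up to +-3 nt before giving up.
#'
#' @param array a `crispacer_array` (3 units for the canonical six-oligo
#'   set).
#' @param config a [design_config()] supplying the vector-end overhangs.
#' @return a list of class `crispacer_oligoset` with `member_id`, `oligos`
#'   (data.frame: `oligo`, `unit`, `strand`, `sequence`), `junctions`
#'   (data.frame: `junction`, `position`, `overhang`, `shift`), and
#'   `array_sequence`.
#' @export
emit_crates <- function(array, config = design_config()) {
  s <- array$full_sequence
  L <- nchar(s)
  n_units <- length(array$units)
  rl <- nchar(array$repeat_unit$dna_sequence)
  # unit boundaries: starts of the repeat copies
  bounds <- array$repeat_intervals[seq_len(n_units), 1]
  vecL <- config$vector_overhang_left
  vecR <- config$vector_overhang_right
  for (v in c(vecL, vecR))
    assert_that(!is_palindromic4(v),
                sprintf("vector overhang %s is palindromic", v))
  assert_that(vecL != vecR && vecL != revcomp(vecR),
              "vector overhangs must differ and not be complementary")

  internal <- bounds[-1]  # junctions between consecutive units
  shifts <- rep(0L, length(internal))
  overhang_at <- function(pos) substr(s, pos + 1L, pos + 4L)
  shift_order <- c(0L, 1L, -1L, 2L, -2L, 3L, -3L)
  taken <- c(vecL, vecR)
  for (j in seq_along(internal)) {
    placed <- FALSE
    for (d in shift_order) {
      pos <- internal[j] + d
      if (pos < 4L || pos + 4L > L) next
      ov <- overhang_at(pos)
      # sticky ends anneal to their reverse complement, so orthogonality
      # requires overhangs distinct, non-palindromic and pairwise
      # non-complementary
      if (is_palindromic4(ov) || ov %in% taken || revcomp(ov) %in% taken) next
      internal[j] <- pos
      shifts[j] <- d
      taken <- c(taken, ov)
      placed <- TRUE
      break
    }
    assert_that(placed, sprintf(
      "no compatible overhang found at array junction %d (unit %d/%d)",
      j, j, j + 1L))
  }
  cuts <- c(0L, internal, L)  # shifts of <= 3 nt keep junctions ordered
  assert_that(all(diff(cuts) > 4L), "array units too short for 4-nt overhangs")

  tops <- character(); bottoms <- character()
  for (i in seq_len(length(cuts) - 1L)) {
    a <- cuts[i]; b <- cuts[i + 1L]
    top <- substr(s, a + 1L, b)
    if (i == 1L) top <- paste0(vecL, top)
    # the bottom strand is staggered 4 nt rightwards; at the outer ends the
    # stagger is taken up by the constant vector overhangs
    bot_start <- if (i == 1L) 0L else a + 4L
    bot_top_coords <- if (i == length(cuts) - 1L) {
      paste0(substr(s, bot_start + 1L, L), vecR)
    } else {
      substr(s, bot_start + 1L, b + 4L)
    }
    tops <- c(tops, top)
    bottoms <- c(bottoms, revcomp(bot_top_coords))
  }
  n <- length(tops)
  oligos <- data.frame(
    oligo = paste0(array$gene_id, "_u", rep(seq_len(n), each = 2),
                   c("_top", "_bottom")),
    unit = rep(seq_len(n), each = 2),
    strand = rep(c("top", "bottom"), n),
    sequence = as.vector(rbind(tops, bottoms)),
    stringsAsFactors = FALSE)
  junctions <- data.frame(
    junction = seq_len(length(internal) + 2L) - 1L,
    position = c(NA_integer_, internal, NA_integer_),
    overhang = c(vecL, overhang_at_vec(s, internal), vecR),
    shift = c(NA_integer_, shifts, NA_integer_),
    stringsAsFactors = FALSE)
  structure(list(member_id = array$gene_id, oligos = oligos,
                 junctions = junctions, array_sequence = s),
            class = "crispacer_oligoset")
}

overhang_at_vec <- function(s, pos) {
  vapply(pos, function(p) substr(s, p + 1L, p + 4L), character(1))
}

#' Reassemble an array from a CRATES oligo set
#'
#' Simulates annealing and ligation: pairs oligos into unit duplexes by exact
#' complementarity with a 4-nt stagger, chains the duplexes by matching
#' single-stranded overhangs and returns the double-stranded portion of the
#' unique assembled product (which equals the original array sequence for
#' sets from [emit_crates()]). A duplex has no intrinsic top strand, so every
#' valid set assembles in two strand readings of the same molecule;
#' `left_overhang` (the vector-facing overhang of the first unit) anchors
#' which reading is reported — without it the lexicographically smaller
#' strand is returned. Sets admitting no assembly, or more than one distinct
#' molecule (e.g. duplicated junction overhangs), raise an error.
#'
#' @param oligos character vector of oligo sequences (order-independent), or
#'   a `crispacer_oligoset` (its recorded left vector overhang is then used).
#' @param left_overhang optional 4-nt overhang identifying the left end of
#'   the top strand.
#' @return the assembled top-strand DNA string.
#' @export
reconstruct_from_oligos <- function(oligos, left_overhang = NULL) {
  if (inherits(oligos, "crispacer_oligoset")) {
    left_overhang <- left_overhang %||% oligos$junctions$overhang[1]
    oligos <- oligos$oligos$sequence
  }
  n <- length(oligos)
  assert_that(n >= 2L && n %% 2L == 0L, "need an even number of oligos")
  # candidate unit duplexes: top oligo T, bottom oligo B such that
  # revcomp(B) equals T shifted left by 4 (T = l_ov + core, revcomp(B) =
  # core + r_ov)
  units <- list()
  for (ti in seq_len(n)) for (bi in seq_len(n)) {
    if (ti == bi) next
    T <- oligos[ti]; B <- revcomp(oligos[bi])
    if (nchar(T) != nchar(B) || nchar(T) <= 8L) next
    if (substr(T, 5L, nchar(T)) == substr(B, 1L, nchar(B) - 4L)) {
      units[[length(units) + 1L]] <- list(
        top = ti, bottom = bi, top_seq = T,
        l_ov = substr(T, 1L, 4L),
        r_ov = substr(B, nchar(B) - 3L, nchar(B)))
    }
  }
  n_units <- n / 2L
  assemblies <- list()
  # choose a consistent set of unit duplexes covering each oligo once, then
  # chain them by overhang identity; exhaustive over the (tiny) search space
  pick <- function(chosen, used) {
    if (length(chosen) == n_units) {
      for (ch in chain_units(chosen))
        assemblies[[length(assemblies) + 1L]] <<- ch
      return(invisible())
    }
    for (u in units) {
      if (u$top %in% used || u$bottom %in% used) next
      # canonical ordering to avoid revisiting permutations of the same set
      if (length(chosen) && u$top < chosen[[length(chosen)]]$top) next
      pick(c(chosen, list(u)), c(used, u$top, u$bottom))
    }
  }
  pick(list(), integer())
  assert_that(length(assemblies) > 0, "oligos do not assemble into an array")
  seqs <- vapply(assemblies, `[[`, character(1), "sequence")
  canonical <- pmin(seqs, revcomp(seqs))
  assert_that(length(unique(canonical)) == 1,
              "ambiguous assembly: overhangs admit more than one product")
  if (!is.null(left_overhang)) {
    starts <- vapply(assemblies, `[[`, character(1), "start_overhang")
    pickx <- which(starts == left_overhang)
    assert_that(length(pickx) > 0,
                sprintf("no assembly starts at overhang %s", left_overhang))
    seqs[pickx[1]]
  } else {
    canonical[1]
  }
}

# all strand readings obtainable by chaining every unit exactly once; each
# result carries the double-stranded sequence and the chain-start overhang
chain_units <- function(units) {
  n <- length(units)
  res <- list()
  extend <- function(order_idx) {
    if (length(order_idx) == n) {
      tops <- vapply(order_idx, function(i) units[[i]]$top_seq, character(1))
      start_ov <- substr(tops[1], 1L, 4L)
      tops[1] <- substr(tops[1], 5L, nchar(tops[1]))  # left overhang is ss
      res[[length(res) + 1L]] <<- list(sequence = paste(tops, collapse = ""),
                                       start_overhang = start_ov)
      return(invisible())
    }
    for (i in seq_len(n)) {
      if (i %in% order_idx) next
      if (length(order_idx) == 0L) {
        # a chain can only start at a unit whose left overhang no unit feeds
        feeds <- any(vapply(units, function(u) u$r_ov == units[[i]]$l_ov,
                            logical(1)))
        if (feeds) next
      } else {
        last <- units[[order_idx[length(order_idx)]]]
        if (last$r_ov != units[[i]]$l_ov) next
      }
      extend(c(order_idx, i))
    }
  }
  extend(integer())
  res
}

#' Write order sheets for a designed library
#'
#' @param gibson list of `crispacer_gibson` fragments.
#' @param oligosets list of `crispacer_oligoset`s.
#' @param path output TSV path (columns: member_id, oligo, type, sequence,
#'   overhang).
#' @return `path`, invisibly.
#' @export
write_order_sheet <- function(gibson, oligosets, path) {
  rows <- list()
  for (g in gibson) {
    rows[[length(rows) + 1L]] <- data.frame(
      member_id = g$member_id, oligo = g$member_id, type = "gibson_fragment",
      sequence = g$sequence, overhang = NA_character_,
      stringsAsFactors = FALSE)
  }
  for (o in oligosets) {
    ov <- rep(NA_character_, nrow(o$oligos))
    rows[[length(rows) + 1L]] <- data.frame(
      member_id = o$member_id, oligo = o$oligos$oligo, type = "crates_oligo",
      sequence = o$oligos$sequence, overhang = ov, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
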