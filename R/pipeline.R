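#' Design a CRISPRi library for a gene set
#'
#' End-to-end driver: builds the off-target index once, then per gene
#' enumerates, ranks, filters and selects spacers ([select_guides()]),
#' attempts a folding-validated CRISPR array ([design_array()]), and emits
#' cloning-ready output ([emit_gibson()], [emit_crates()]).
#'
#' @param genome a `crispacer_genome`.
#' @param genes a gene table (see [load_targets()]).
#' @param config a [design_config()].
#' @param repeat_unit a `crispacer_repeat`; default [synthetic_repeat()].
#' @param progress print one line per gene.
#' @return a list of class `crispacer_library`: `designs` (per-gene
#'   `crispacer_gene_design`), `arrays`, `oligosets`, `gibson`, `spacer_table`
#'   (data.frame of all selected spacers), `failures` (data.frame gene_id /
#'   note), `manifest` (screen-ready member table), `config`.
#' @export
design_library <- function(genome, genes, config = design_config(),
                           repeat_unit = synthetic_repeat(),
                           progress = FALSE) {
  index <- build_offtarget_index(genome, config)
  designs <- list(); arrays <- list(); oligosets <- list(); gibson <- list()
  spacer_rows <- list(); failure_rows <- list(); manifest_rows <- list()
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, ]
    gd <- select_guides(gene, genome, config, index)
    notes <- gd$failure_notes
    arr_res <- if (nrow(gd$array_spacers) >= config$array_spacers_per_gene) {
      design_array(gd, repeat_unit, config)
    } else {
      list(array = NULL, report = NULL, attempts = 0L,
           failure_note = if (length(notes) == 0)
             "insufficient spacers for array" else NULL)
    }
    if (!is.null(arr_res$failure_note))
      notes <- unique(c(notes, arr_res$failure_note))
    gd$failure_notes <- notes
    designs[[gene$gene_id]] <- gd
    if (nrow(gd$grnas) > 0) {
      gr <- gd$grnas
      gr$member_id <- paste0(gene$gene_id, "_g", seq_len(nrow(gr)))
      gr$role <- "gRNA"
      spacer_rows[[length(spacer_rows) + 1L]] <- gr
      for (j in seq_len(nrow(gr))) {
        gibson[[gr$member_id[j]]] <- emit_gibson(
          gr$member_id[j], gr$spacer_sequence[j],
          config$gibson_arm_5, config$gibson_arm_3)
        manifest_rows[[length(manifest_rows) + 1L]] <- data.frame(
          member_id = gr$member_id[j], type = "gRNA",
          spacers = I(list(gr$spacer_sequence[j])), gene_id = gene$gene_id,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(arr_res$array)) {
      arrays[[gene$gene_id]] <- arr_res$array
      oligosets[[gene$gene_id]] <- emit_crates(arr_res$array, config)
      ar <- arr_res$array$spacer_rows
      ar$member_id <- paste0(gene$gene_id, "_array")
      ar$role <- "array"
      spacer_rows[[length(spacer_rows) + 1L]] <- ar
      manifest_rows[[length(manifest_rows) + 1L]] <- data.frame(
        member_id = paste0(gene$gene_id, "_array"), type = "array",
        spacers = I(list(ar$spacer_sequence)), gene_id = gene$gene_id,
        stringsAsFactors = FALSE)
    }
    for (nt in notes)
      failure_rows[[length(failure_rows) + 1L]] <- data.frame(
        gene_id = gene$gene_id, note = nt, stringsAsFactors = FALSE)
    if (progress)
      message(sprintf("%s: %d gRNAs, array %s", gene$gene_id,
                      nrow(gd$grnas),
                      if (is.null(arr_res$array)) "-" else "ok"))
  }
  structure(list(
    designs = designs, arrays = arrays, oligosets = oligosets,
    gibson = gibson,
    spacer_table = if (length(spacer_rows)) do.call(rbind, spacer_rows)
                   else NULL,
    failures = if (length(failure_rows)) do.call(rbind, failure_rows)
               else data.frame(gene_id = character(), note = character()),
    manifest = if (length(manifest_rows)) do.call(rbind, manifest_rows)
               else NULL,
    config = config
  ), class = "crispacer_library")
}

#' @export
print.crispacer_library <- function(x, ...) {
  n_genes <- length(x$designs)
  n_grna <- sum(vapply(x$designs, function(d) nrow(d$grnas), integer(1)))
  cat(sprintf("<crispacer_library> %d genes: %d gRNAs, %d arrays, %d design notes\n",
              n_genes, n_grna, length(x$arrays), nrow(x$failures)))
  invisible(x)
}

#' Write the design output tables
#'
#' Emits the per-gene spacer TSV (1-based inclusive coordinates), the
#' failure report, the order sheet and the library manifest.
#'
#' @param library a `crispacer_library`.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return named character vector of written paths.
#' @export
write_library <- function(library, dir, prefix = "library") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(spacers = file.path(dir, paste0(prefix, "_spacers.tsv")),
             failures = file.path(dir, paste0(prefix, "_failures.tsv")),
             orders = file.path(dir, paste0(prefix, "_orders.tsv")),
             manifest = file.path(dir, paste0(prefix, "_manifest.tsv")))
  st <- library$spacer_table
  if (!is.null(st)) {
    rep_1b <- to_one_based(st$proto_start, st$proto_end)
    out <- data.frame(member_id = st$member_id, gene_id = st$gene_id,
                      role = st$role, replicon_id = st$replicon_id,
                      start = rep_1b$start, end = rep_1b$end,
                      strand = st$strand, spacer = st$spacer_sequence,
                      pam = st$pam_sequence, region = st$region_kind,
                      annealing = st$annealing, gc = round(st$gc, 3),
                      tss_offset = st$tss_offset,
                      extended_pam = st$extended_pam,
                      stringsAsFactors = FALSE)
    write.table(out, paths["spacers"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write.table(library$failures, paths["failures"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_order_sheet(library$gibson, library$oligosets, paths["orders"])
  if (!is.null(library$manifest))
    write_manifest(library$manifest, paths["manifest"])
  paths
}
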