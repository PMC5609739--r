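#' Predicted complexes unmatched by any reference
#'
#' The false positives of a prediction run: complexes whose overlap
#' score stays strictly below the match threshold against every complex
#' of the (merged) gold standard. These are the candidates worth
#' screening against structural databases, since they may be real but
#' uncataloged complexes.
#'
#' @param pred a [complex_set] of predictions.
#' @param refs the merged reference [complex_set].
#' @param w match threshold (default 0.25); a prediction reaching
#'   exactly `w` counts as matched, mirroring the true-positive rule.
#' @return the false-positive [complex_set] (possibly empty).
#' @export
false_positives <- function(pred, refs, w = 0.25) {
  if (length(pred$complexes) == 0L) return(pred)
  os <- .os_matrix(pred, refs)
  best <- if (nrow(os) == 0L) rep(0, ncol(os)) else apply(os, 2L, max)
  keep <- best < w
  structure(list(complexes = pred$complexes[keep],
                 labels = if (is.null(pred$labels)) NULL else
                   pred$labels[keep]),
            class = "complex_set")
}

#' Read a protein-to-PDB-chain snapshot table
#'
#' Local snapshot of SIFTS-style chain assignments: a TSV with columns
#' `protein_name`, `pdb_id`, `chain_id` (header optional). Rows are
#' deduplicated; empty PDB ids are rejected.
#'
#' @param path file path.
#' @return data.frame of class `chain_map` with those three columns.
#' @export
read_chain_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("protein_name", "pdb_id",
                                         "chain_id"),
                           colClasses = "character")
  if (nrow(tab) > 0L && identical(tolower(tab$protein_name[1L]),
                                  "protein_name")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  if (any(!nzchar(tab$pdb_id))) stop("chain map contains empty pdb ids")
  tab <- unique(tab)
  rownames(tab) <- NULL
  class(tab) <- c("chain_map", "data.frame")
  tab
}

#' Read a local PDB entry metadata snapshot
#'
#' TSV with columns `pdb_id`, `form_name`, `title` and optionally
#' `release_date`, replacing live PDBe entry-summary queries.
#'
#' @param path file path.
#' @return data.frame keyed by `pdb_id`.
#' @export
read_pdb_metadata <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(c("pdb_id", "form_name", "title") %in% names(tab))) {
    stop("metadata snapshot needs pdb_id, form_name and title columns")
  }
  tab
}

#' Potential complexes among false positives, by shared PDB structure
#'
#' For each false-positive predicted complex, groups its members by the
#' PDB entries they map to. A group of at least two proteins sharing a
#' PDB id is a *potential complex* — structural evidence that these
#' proteins were purified together — unless its member set is already
#' contained in some gold-standard complex, in which case it brings no
#' new information and is discarded.
#'
#' @param fps the false-positive [complex_set] (see
#'   [false_positives()]).
#' @param chainmap a [read_chain_map()] table.
#' @param refs the merged gold-standard [complex_set].
#' @return data.frame with columns `pdb_id`, `members` (space-separated
#'   protein names), `n_members`, `n_mapped` (distinct proteins the
#'   chain map assigns to that PDB entry), `source_complex_index`.
#' @export
potential_complexes <- function(fps, chainmap, refs) {
  empty <- data.frame(pdb_id = character(), members = character(),
                      n_members = integer(), n_mapped = integer(),
                      source_complex_index = integer())
  if (nrow(chainmap) == 0L) {
    warning("empty chain map: no potential complexes can be found")
    return(empty)
  }
  prot2pdb <- unique(chainmap[, c("protein_name", "pdb_id")])
  pdb_size <- table(prot2pdb$pdb_id)  # proteins mapped per entry
  rows <- list()
  for (i in seq_along(fps$complexes)) {
    members <- fps$complexes[[i]]
    hits <- prot2pdb[prot2pdb$protein_name %in% members, , drop = FALSE]
    if (nrow(hits) == 0L) next
    groups <- split(hits$protein_name, hits$pdb_id)
    for (pdb in names(groups)) {
      g <- sort(unique(groups[[pdb]]), method = "radix")
      if (length(g) < 2L) next
      in_ref <- any(vapply(refs$complexes,
                           function(rc) all(g %in% rc), NA))
      if (in_ref) next
      rows[[length(rows) + 1L]] <-
        data.frame(pdb_id = pdb, members = paste(g, collapse = " "),
                   n_members = length(g),
                   n_mapped = as.integer(pdb_size[[pdb]]),
                   source_complex_index = i)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write potential complexes as a CSV report
#'
#' One row per potential complex: `pdb_id`, the gene ids with counts in
#' the form `"GENE1 GENE2 (k/total)"` where `k` is the number of
#' false-positive members found in the entry and `total` the number of
#' proteins the chain map assigns to it, plus `form_name` and `title`
#' when a metadata snapshot is supplied.
#'
#' @param pcs a [potential_complexes()] data.frame.
#' @param path output CSV path.
#' @param metadata optional [read_pdb_metadata()] table.
#' @export
write_potential_complexes <- function(pcs, path, metadata = NULL) {
  genes <- sprintf("%s (%d/%d)", pcs$members, pcs$n_members, pcs$n_mapped)
  out <- data.frame(pdb_id = pcs$pdb_id, gene_ids = genes)
  if (!is.null(metadata)) {
    at <- match(pcs$pdb_id, metadata$pdb_id)
    out$form_name <- metadata$form_name[at]
    out$title <- metadata$title[at]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
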