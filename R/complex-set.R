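#' Construct a set of protein complexes
#'
#' A complex set is an ordered collection of protein-name sets, used both
#' for predictions and for gold-standard references. Member vectors are
#' deduplicated within each complex; complexes that repeat an earlier
#' member set exactly are dropped (first occurrence wins).
#'
#' @param complexes list of character vectors of protein names.
#' @param labels optional character vector of per-complex names (e.g. the
#'   catalog identifiers of a curated reference).
#' @return An object of class `complex_set`: list with `complexes`
#'   (each sorted, unique) and `labels` (possibly `NULL`).
#' @export
complex_set <- function(complexes, labels = NULL) {
  complexes <- lapply(complexes, function(x) sort(unique(as.character(x)),
                                                  method = "radix"))
  if (any(lengths(complexes) == 0L)) {
    stop("every complex must have at least one member")
  }
  if (!is.null(labels) && length(labels) != length(complexes)) {
    stop("one label per complex required")
  }
  key <- vapply(complexes, paste, "", collapse = "\r")
  keep <- !duplicated(key)
  structure(list(complexes = complexes[keep],
                 labels = if (is.null(labels)) NULL else labels[keep]),
            class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  sz <- lengths(x$complexes)
  cat(sprintf("complex set: %d complexes (sizes %s)\n", length(sz),
              if (length(sz)) paste0(min(sz), "-", max(sz)) else "-"))
  invisible(x)
}

#' @export
length.complex_set <- function(x) length(x$complexes)

#' Read a complex set from a plain-text file
#'
#' One complex per non-empty line, members whitespace-separated. Exact
#' duplicate complexes are collapsed, preserving line order otherwise.
#'
#' @param path file path.
#' @return a [complex_set]; an empty file yields an empty set with a
#'   warning.
#' @export
read_complex_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("no complexes found in ", path)
    return(structure(list(complexes = list(), labels = NULL),
                     class = "complex_set"))
  }
  complex_set(strsplit(lines, "[ \t]+"))
}

#' Write a complex set to a plain-text file
#'
#' One complex per line, members space-separated in lexicographic order,
#' so that output is deterministic and `read_complex_set()` round-trips.
#'
#' @param cs a [complex_set].
#' @param path file path.
#' @export
write_complex_set <- function(cs, path) {
  writeLines(vapply(cs$complexes, paste, "", collapse = " "), path)
  invisible(path)
}

#' Merge two complex references
#'
#' Approximates the union of two curated catalogs: complexes sharing a
#' label are kept once; complexes with different labels but identical
#' member sets are kept once; complexes differing in both label and
#' members are both retained. Unlabeled complexes are compared by member
#' set only.
#'
#' @param a,b [complex_set] objects.
#' @return the merged [complex_set].
#' @export
merge_references <- function(a, b) {
  la <- if (is.null(a$labels)) rep(NA_character_, length(a$complexes)) else a$labels
  lb <- if (is.null(b$labels)) rep(NA_character_, length(b$complexes)) else b$labels
  keys_a <- vapply(a$complexes, paste, "", collapse = "\r")
  keys_b <- vapply(b$complexes, paste, "", collapse = "\r")
  drop <- vapply(seq_along(b$complexes), function(j) {
    (!is.na(lb[j]) && lb[j] %in% la) || keys_b[j] %in% keys_a
  }, NA)
  merged <- c(a$complexes, b$complexes[!drop])
  labels <- c(la, lb[!drop])
  if (all(is.na(labels))) labels <- NULL
  complex_set(merged, labels)
}
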