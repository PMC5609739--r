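#' Overlap score between two complexes
#'
#' `OS(pc, rc) = |pc ∩ rc|^2 / (|pc| |rc|)`; 1 exactly when the sets are
#' identical, 0 when they are disjoint.
#'
#' @param pc,rc nonempty character vectors of protein names.
#' @return numeric in \[0, 1\].
#' @export
overlap_score <- function(pc, rc) {
  if (length(pc) == 0L || length(rc) == 0L) {
    stop("overlap score is undefined for empty complexes")
  }
  pc <- unique(pc)
  rc <- unique(rc)
  length(intersect(pc, rc))^2 / (length(pc) * length(rc))
}

# OS matrix: rows = reference complexes, columns = predictions
.os_matrix <- function(pred, ref) {
  outer(seq_along(ref$complexes), seq_along(pred$complexes),
        Vectorize(function(i, j) {
          overlap_score(pred$complexes[[j]], ref$complexes[[i]])
        }))
}

#' Precision, recall and FMeasure of a prediction
#'
#' A predicted complex is a true positive when its overlap score against
#' some reference complex reaches the match threshold `w`; a reference
#' complex unmatched by every prediction is a false negative. FMeasure
#' is the harmonic mean of precision and recall (0 when both are 0).
#'
#' @param pred,ref [complex_set] objects (both nonempty).
#' @param w match threshold on the overlap score (default 0.25; 0.2 is
#'   the other conventional choice).
#' @return list with `precision`, `recall`, `fmeasure`, `tp`, `fp`,
#'   `fn`.
#' @export
fmeasure_stats <- function(pred, ref, w = 0.25) {
  os <- .os_matrix(pred, ref)
  tp <- sum(apply(os, 2L, max) >= w)
  fp <- length(pred$complexes) - tp
  fn <- sum(apply(os, 1L, max) < w)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  fmeasure <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, fmeasure = fmeasure,
       tp = tp, fp = fp, fn = fn)
}

#' Clustering sensitivity, positive predictive value and accuracy
#'
#' With `T[i, j]` the number of proteins shared by reference complex `i`
#' and prediction `j`: sensitivity is the sum of row maxima over the sum
#' of reference sizes; PPV is the sum of column maxima over the total
#' overlap mass `sum(T)` (the Brohee-van Helden convention, in which
#' predictions overlapping no reference contribute to neither sum);
#' accuracy is their geometric mean.
#'
#' @param pred,ref [complex_set] objects (both nonempty).
#' @return list with `sn`, `ppv`, `acc`.
#' @export
accuracy_stats <- function(pred, ref) {
  tmat <- outer(seq_along(ref$complexes), seq_along(pred$complexes),
                Vectorize(function(i, j) {
                  length(intersect(ref$complexes[[i]], pred$complexes[[j]]))
                }))
  sn <- sum(apply(tmat, 1L, max)) / sum(lengths(ref$complexes))
  tot <- sum(tmat)
  ppv <- if (tot == 0) 0 else sum(apply(tmat, 2L, max)) / tot
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

# maximum-weight one-to-one matching between references and predictions;
# only pairs with OS >= min_os enter the bipartite graph
.mmr_matching <- function(pred, ref, min_os = 0.2) {
  os <- .os_matrix(pred, ref)
  nr <- nrow(os)
  np <- ncol(os)
  idx <- which(os >= min_os & os > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(total = 0,
                pairs = data.frame(ref = integer(), pred = integer(),
                                   os = numeric())))
  }
  g <- igraph::make_bipartite_graph(types = rep(c(FALSE, TRUE), c(nr, np)),
                                    edges = as.vector(t(cbind(idx[, 1L],
                                                              nr + idx[, 2L]))))
  m <- igraph::max_bipartite_match(g, weights = os[idx])
  matched_ref <- which(!is.na(m$matching[seq_len(nr)]))
  matched_pred <- m$matching[matched_ref] - nr
  pairs <- data.frame(ref = matched_ref, pred = matched_pred,
                      os = os[cbind(matched_ref, matched_pred)])
  list(total = sum(pairs$os), pairs = pairs)
}

#' Maximum matching ratio
#'
#' Builds the bipartite graph whose edges connect reference and
#' predicted complexes with overlap score at least `min_os`, weighted by
#' that score; computes a maximum-total-weight one-to-one matching; and
#' divides its weight by the number of reference complexes.
#'
#' @param pred a [complex_set] of predictions.
#' @param ref a nonempty [complex_set] of reference complexes.
#' @param min_os overlap-score floor for matchable pairs (default 0.2).
#' @return numeric in \[0, 1\].
#' @export
mmr <- function(pred, ref, min_os = 0.2) {
  if (length(ref$complexes) == 0L) stop("reference set is empty")
  .mmr_matching(pred, ref, min_os)$total / length(ref$complexes)
}

#' Restrict a reference to proteins present in a network
#'
#' A reference complex with fewer than half of its members among the
#' network's proteins is dropped entirely (its prediction could never be
#' attributed to the algorithm); otherwise it is kept restricted to the
#' members the network knows about. Complexes reduced below two members
#' are dropped, since a singleton is not a complex.
#'
#' @param ref a [complex_set].
#' @param net a [ppi_network].
#' @return the filtered [complex_set].
#' @export
filter_reference <- function(ref, net) {
  known <- net$names
  kept <- list()
  labs <- character()
  for (i in seq_along(ref$complexes)) {
    members <- ref$complexes[[i]]
    present <- members[members %in% known]
    if (length(present) < length(members) / 2) next
    if (length(present) < 2L) next
    kept[[length(kept) + 1L]] <- present
    if (!is.null(ref$labels)) labs <- c(labs, ref$labels[i])
  }
  if (length(kept) == 0L) {
    return(structure(list(complexes = list(), labels = NULL),
                     class = "complex_set"))
  }
  complex_set(kept, if (is.null(ref$labels)) NULL else labs)
}

#' Count perfectly matched predictions
#'
#' Number of predicted complexes identical (overlap score 1) to some
#' reference complex.
#'
#' @param pred,ref [complex_set] objects.
#' @return integer count.
#' @export
perfect_match_count <- function(pred, ref) {
  ref_keys <- vapply(ref$complexes, paste, "", collapse = "\r")
  pred_keys <- vapply(pred$complexes, paste, "", collapse = "\r")
  sum(pred_keys %in% ref_keys)
}

#' Cumulative overlap histogram along the MMR matching
#'
#' Over a grid of overlap-score thresholds `x` from `min_os` to 1,
#' reports how many matched reference-prediction pairs reach `OS >= x`
#' and what the maximum matching ratio becomes when only pairs with
#' `OS >= x` are matchable. By default the counted pairs are those of
#' the maximum-weight matching computed at `min_os`; `pairs = "all"`
#' instead counts every reference-prediction pair with `OS >= x`.
#'
#' @param pred,ref [complex_set] objects.
#' @param min_os lower end of the threshold grid (default 0.2).
#' @param step grid spacing (default 0.05).
#' @param pairs `"matched"` or `"all"`.
#' @return data.frame with columns `threshold`, `n_pairs`, `mmr`.
#' @export
overlap_histogram <- function(pred, ref, min_os = 0.2, step = 0.05,
                              pairs = c("matched", "all")) {
  pairs <- match.arg(pairs)
  grid <- seq(min_os, 1, by = step)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  os_pairs <- if (pairs == "matched") {
    .mmr_matching(pred, ref, min_os)$pairs$os
  } else {
    os <- .os_matrix(pred, ref)
    os[os >= min_os & os > 0]
  }
  data.frame(threshold = grid,
             n_pairs = vapply(grid, function(x) sum(os_pairs >= x), 0L),
             mmr = vapply(grid, function(x) mmr(pred, ref, x), 0))
}

#' Score predictions against a reference with every metric
#'
#' Convenience wrapper computing the whole evaluation bundle. When a
#' network is supplied the reference is first run through
#' [filter_reference()].
#'
#' @param pred,ref [complex_set] objects.
#' @param w match threshold for FMeasure counts (default 0.25).
#' @param mmr_min_os overlap-score floor for the MMR matching
#'   (default 0.2).
#' @param net optional [ppi_network] for reference filtering.
#' @return An `eval_report`: list with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `fmeasure`, `sn`, `ppv`, `acc`, `mmr`,
#'   `perfect_matches`, `n_predicted`, `n_reference`.
#' @export
evaluate_complexes <- function(pred, ref, w = 0.25, mmr_min_os = 0.2,
                               net = NULL) {
  if (w <= 0 || w > 1 || mmr_min_os <= 0 || mmr_min_os > 1) {
    stop("thresholds must lie in (0, 1]")
  }
  if (!is.null(net)) {
    ref <- filter_reference(ref, net)
  }
  if (length(pred$complexes) == 0L || length(ref$complexes) == 0L) {
    stop("need at least one predicted and one reference complex")
  }
  fm <- fmeasure_stats(pred, ref, w)
  ac <- accuracy_stats(pred, ref)
  structure(c(fm[c("tp", "fp", "fn", "precision", "recall", "fmeasure")],
              ac,
              list(mmr = mmr(pred, ref, mmr_min_os),
                   perfect_matches = perfect_match_count(pred, ref),
                   n_predicted = length(pred$complexes),
                   n_reference = length(ref$complexes))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("predicted %d complexes vs %d reference complexes\n",
              x$n_predicted, x$n_reference))
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  Precision %.4f  Recall %.4f  FMeasure %.4f\n",
              x$precision, x$recall, x$fmeasure))
  cat(sprintf("  Sn %.4f  PPV %.4f  Acc %.4f\n", x$sn, x$ppv, x$acc))
  cat(sprintf("  MMR %.4f  perfect matches %d\n", x$mmr,
              x$perfect_matches))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @export
write_eval_report <- function(report, path) {
  df <- data.frame(metric = names(unclass(report)),
                   value = unlist(report, use.names = FALSE))
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
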