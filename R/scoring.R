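## Turning a fitted state into ranked enhancer-gene predictions, and a small
## precision-recall evaluation utility for externally labelled pairs.

#' Score enhancer-gene pairs by relative contribution
#'
#' For each stored contact pair, the interaction score is the enhancer's
#' relative contribution to the gene's modelled expression,
#' `h_gr = c_gr w_r* / sum_r' c_gr' w_r'*` with `w_r* = E[w_r]`; the
#' promoter activity `v_g* = E[v_g]` cancels in the ratio but is reported.
#' Scores within a gene sum to one.
#'
#' @param state fitted `inference_state`.
#' @param inp the matching `inference_input`.
#' @param pair_annotations optional data.frame keyed by (`gene_id`,
#'   `element_id`) with extra columns (e.g. `distance_bp`, element
#'   coordinates, `tss`) carried through to the output.
#' @return data.frame with one row per contact pair: `gene_id`,
#'   `element_id`, `contact`, `enhancer_activity`, `promoter_activity`,
#'   `score`, plus any annotation columns.
#' @export
interaction_scores <- function(state, inp, pair_annotations = NULL) {
  wstar <- state$Ew[inp$ci_elem]
  num <- inp$c * wstar
  den <- row_sum(inp, num)
  out <- data.frame(gene_id = inp$gene_id[inp$ci_gene],
                    element_id = inp$element_id[inp$ci_elem],
                    contact = inp$c,
                    enhancer_activity = wstar,
                    promoter_activity = state$Ev[inp$ci_gene],
                    score = num / den[inp$ci_gene],
                    stringsAsFactors = FALSE)
  if (!is.null(pair_annotations)) {
    key <- paste(out$gene_id, out$element_id)
    akey <- paste(pair_annotations$gene_id, pair_annotations$element_id)
    extra <- setdiff(names(pair_annotations), c("gene_id", "element_id"))
    for (col in extra) out[[col]] <- pair_annotations[[col]][match(key, akey)]
  }
  out
}

#' Top-scoring pairs per gene
#'
#' @param pairs scored pair table from [interaction_scores()].
#' @param n number of pairs to keep per gene (default 10); ties broken by
#'   ascending `distance_bp` (when present) then `element_id`.
#' @return the filtered table, ordered by gene then descending score.
#' @export
top_pairs_per_gene <- function(pairs, n = 10) {
  d <- if ("distance_bp" %in% names(pairs)) pairs$distance_bp else
    rep(0, nrow(pairs))
  o <- order(pairs$gene_id, -pairs$score, d, pairs$element_id,
             method = "radix")
  pairs <- pairs[o, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$gene_id),
                        head, n), use.names = FALSE)
  out <- pairs[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision-recall evaluation of labelled pairs
#'
#' Matches labelled intervals to predicted elements of the same gene by any
#' base-pair overlap, ranks the labelled predictions by score, and computes
#' the area under the precision-recall curve as average precision
#' (sum over positives of precision at each positive's rank).  Unlabelled
#' predictions are ignored.
#'
#' @param pairs scored pair table; must carry element coordinates `chrom`,
#'   `start`, `end` (e.g. via `pair_annotations`).
#' @param labels data.frame `gene_id`, `chrom`, `start`, `end`, `label`
#'   (1/TRUE = positive, 0/FALSE = negative).
#' @return list with `auprc` and the PR `curve` (data.frame of
#'   `recall`, `precision` at each rank).
#' @export
evaluate_labelled_pairs <- function(pairs, labels) {
  lab <- rep(NA, nrow(pairs))
  for (i in seq_len(nrow(labels))) {
    m <- pairs$gene_id == labels$gene_id[i] &
      pairs$chrom == labels$chrom[i] &
      pairs$start < labels$end[i] & pairs$end > labels$start[i]
    lab[m] <- as.integer(as.logical(labels$label[i]))
  }
  keep <- !is.na(lab)
  y <- lab[keep]
  sc <- pairs$score[keep]
  if (sum(y) == 0) stop("no positive labelled pairs matched")
  o <- order(-sc)
  y <- y[o]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  auprc <- sum(precision[y == 1]) / sum(y)
  list(auprc = auprc,
       curve = data.frame(recall = recall, precision = precision))
}
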