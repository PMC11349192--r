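## Construction of candidate regulatory elements and promoter elements from
## accessibility peak calls and a gene annotation table.
##
## Coordinates are 0-based half-open (BED dialect) throughout.  Interval
## machinery is delegated to IRanges (shifted to 1-based closed internally);
## tests check it against brute-force scans.

#' Select, resize and merge accessibility peaks into regulatory elements
#'
#' Keeps the `top_n` peaks with the highest read counts, recenters each kept
#' peak on its summit at a fixed width, clips at position 0, and merges
#' strictly overlapping intervals per chromosome (bookended intervals, where
#' one ends exactly where the next starts, are kept separate).  Read counts
#' of merged constituents are summed, so total reads over kept peaks are
#' conserved.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`,
#'   `summit_offset` (bp from `start`) and `read_count`.
#' @param top_n number of peaks to keep, ranked by `read_count` (ties broken
#'   by genomic order); `Inf` keeps all.
#' @param width resized width in bp (default 500, centered on the summit);
#'   `NA` keeps the native interval of each peak.
#' @return data.frame of elements: `element_id` ("chrom:start-end"), `chrom`,
#'   `start`, `end`, `length_kb`, `read_count`, sorted by (chrom, start).
#' @export
select_resize_merge_peaks <- function(peaks, top_n = 150000, width = 500) {
  cols <- c("chrom", "start", "end", "summit_offset", "read_count")
  if (nrow(peaks) == 0) {
    warning("empty peak input; returning no elements")
    return(empty_elements())
  }
  missing <- setdiff(cols, names(peaks))
  if (length(missing) && !identical(missing, "summit_offset"))
    stop("peaks lack columns: ", paste(missing, collapse = ", "))
  if (is.na(width) && !("summit_offset" %in% names(peaks)))
    peaks$summit_offset <- (peaks$end - peaks$start) %/% 2
  if (any(peaks$read_count < 0))
    stop("negative read_count in peak input")
  if (any(peaks$summit_offset < 0 | peaks$summit_offset >= peaks$end - peaks$start))
    stop("summit_offset outside peak interval")
  if (top_n < 1) stop("top_n must be >= 1")

  ## top-N by count; stable tie-break by (chrom, start)
  o <- order(-peaks$read_count, peaks$chrom, peaks$start, method = "radix")
  keep <- peaks[o[seq_len(min(top_n, nrow(peaks)))], , drop = FALSE]

  if (is.na(width)) {
    s <- keep$start
    e <- keep$end
  } else {
    if (width < 1) stop("width must be >= 1")
    summit <- keep$start + keep$summit_offset
    s <- pmax(0L, summit - floor(width / 2))
    e <- summit + ceiling(width / 2)
  }

  out <- do.call(rbind, lapply(split(seq_along(s), keep$chrom), function(ix) {
    ir <- IRanges::IRanges(start = s[ix] + 1L, end = e[ix])
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    rc <- vapply(S4Vectors::mcols(red)$revmap,
                 function(m) sum(keep$read_count[ix][m]), numeric(1))
    data.frame(chrom = keep$chrom[ix[1]],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               read_count = rc)
  }))
  rownames(out) <- NULL
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  data.frame(element_id = sprintf("%s:%d-%d", out$chrom, out$start, out$end),
             chrom = out$chrom, start = out$start, end = out$end,
             length_kb = (out$end - out$start) / 1000,
             read_count = out$read_count,
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_elements <- function() {
  data.frame(element_id = character(), chrom = character(),
             start = integer(), end = integer(),
             length_kb = numeric(), read_count = numeric(),
             stringsAsFactors = FALSE)
}

#' Aggregate regulatory elements into per-gene promoter elements
#'
#' Collects all elements overlapping the promoter window
#' `[tss - flank, tss + flank)` of each gene and sums their lengths (in kb)
#' and read counts.  Genes without any overlapping element are dropped and
#' reported in the `"excluded_genes"` attribute.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss` (0-based).
#' @param elements element table from [select_resize_merge_peaks()].
#' @param flank promoter half-width in bp (default 1000).
#' @return data.frame `gene_id`, `length_kb`, `read_count`,
#'   `constituent_ids` (comma-separated element ids); attribute
#'   `excluded_genes` lists gene ids with no promoter element.
#' @export
build_promoter_elements <- function(genes, elements, flank = 1000) {
  if (flank <= 0) stop("flank must be positive")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in annotation")
  n <- nrow(genes)
  len_kb <- numeric(n); rc <- numeric(n); ids <- character(n)
  hit <- logical(n)
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    ei <- which(elements$chrom == chr)
    if (!length(ei)) next
    ## half-open windows/elements -> 1-based closed
    win <- IRanges::IRanges(start = genes$tss[gi] - flank + 1L,
                            end = genes$tss[gi] + flank)
    ele <- IRanges::IRanges(start = elements$start[ei] + 1L,
                            end = elements$end[ei])
    ov <- IRanges::findOverlaps(win, ele)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (k in unique(qh)) {
      sel <- ei[sh[qh == k]]
      g <- gi[k]
      hit[g] <- TRUE
      len_kb[g] <- sum(elements$length_kb[sel])
      rc[g] <- sum(elements$read_count[sel])
      ids[g] <- paste(elements$element_id[sel], collapse = ",")
    }
  }
  excluded <- genes$gene_id[!hit]
  if (length(excluded))
    message(length(excluded), " gene(s) without promoter elements excluded")
  out <- data.frame(gene_id = genes$gene_id[hit], length_kb = len_kb[hit],
                    read_count = rc[hit], constituent_ids = ids[hit],
                    stringsAsFactors = FALSE)
  attr(out, "excluded_genes") <- excluded
  out
}

#' Enhancer universe
#'
#' All regulatory elements act as candidate enhancers individually, including
#' elements inside promoter regions (promoters can act as enhancers of other
#' genes); this is the identity on the element set, kept as an explicit step
#' of the pipeline.
#'
#' @param elements element table.
#' @return the same table.
#' @export
enhancer_universe <- function(elements) elements

#' Transcripts-per-million from counts and effective lengths
#'
#' `tpm_g = 1e6 * (count_g / eff_len_kb_g) / sum_g'(count_g' / eff_len_kb_g')`,
#' computed over all supplied genes (i.e. before any expression filtering).
#'
#' @param expr data.frame with `gene_id`, `read_count`,
#'   `effective_length_kb`.
#' @return `expr` with a `tpm` column added (or replaced).
#' @export
compute_tpm <- function(expr) {
  if (any(expr$effective_length_kb <= 0))
    stop("effective_length_kb must be positive")
  r <- expr$read_count / expr$effective_length_kb
  expr$tpm <- if (sum(r) > 0) 1e6 * r / sum(r) else r * 0
  expr
}

#' Filter genes by expression level
#'
#' Keeps genes with TPM strictly greater than the cut-off.  The default of
#' 8 TPM restricts inference to clearly expressed genes, where enhancer
#' contributions are identifiable.
#'
#' @param expr expression table; a `tpm` column is computed via
#'   [compute_tpm()] if absent.
#' @param cutoff_tpm non-negative cut-off (default 8).
#' @return the filtered table (with `tpm` column).
#' @export
filter_genes_by_expression <- function(expr, cutoff_tpm = 8) {
  if (cutoff_tpm < 0) stop("cutoff_tpm must be >= 0")
  if (!("tpm" %in% names(expr))) expr <- compute_tpm(expr)
  expr[expr$tpm > cutoff_tpm, , drop = FALSE]
}

#' TSS from gene body coordinates
#'
#' For a 0-based half-open gene body, the TSS is `start` on the + strand and
#' `end - 1` on the - strand.
#'
#' @param start,end integer vectors (0-based half-open).
#' @param strand character vector of "+" / "-".
#' @return integer vector of TSS coordinates.
#' @export
tss_from_body <- function(start, end, strand) {
  ifelse(strand == "-", end - 1L, start)
}
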