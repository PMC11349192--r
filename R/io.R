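## Readers and writers for the plain-text dialects the pipeline consumes and
## emits.  All genomic coordinates on disk are 0-based half-open (BED).

#' Read accessibility peaks
#'
#' Accepts 10-column narrowPeak (column 7 = signal used as read count when
#' no dedicated count column exists, column 10 = summit offset from start)
#' or a headered TSV with columns `chrom`, `start`, `end`, `summit_offset`,
#' `read_count`.
#'
#' @param path file path.
#' @return peak data.frame for [select_resize_merge_peaks()].
#' @export
read_peaks <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("chrom", first)) {
    pk <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "summit_offset", "read_count")
    if (!all(need %in% names(pk)))
      stop("peak TSV must have columns: ", paste(need, collapse = ", "))
    return(pk[need])
  }
  pk <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(pk) < 10)
    stop("narrowPeak input needs 10 columns (got ", ncol(pk),
         "); column 10 is the summit offset")
  data.frame(chrom = pk[[1]], start = pk[[2]], end = pk[[3]],
             summit_offset = pk[[10]], read_count = pk[[7]],
             stringsAsFactors = FALSE)
}

#' Read the gene annotation table
#'
#' Headered TSV with columns `gene_id`, `symbol`, `chrom`, `strand`, `tss`,
#' `start`, `end` (0-based half-open body).
#'
#' @param path file path.
#' @return gene data.frame.
#' @export
read_genes <- function(path) {
  g <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "symbol", "chrom", "strand", "tss", "start", "end")
  if (!all(need %in% names(g)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (any(g$start >= g$end)) stop("gene body must satisfy start < end")
  g
}

#' Read gene-level expression
#'
#' Headered TSV with `gene_id`, `count`, `effective_length` (nucleotides,
#' converted to kb internally).
#'
#' @param path file path.
#' @return data.frame `gene_id`, `read_count`, `effective_length_kb`, `tpm`.
#' @export
read_expression <- function(path) {
  e <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "count", "effective_length")
  if (!all(need %in% names(e)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  compute_tpm(data.frame(gene_id = e$gene_id, read_count = e$count,
                         effective_length_kb = e$effective_length / 1000,
                         stringsAsFactors = FALSE))
}

#' Read a burst-size table
#'
#' Headered TSV `gene_id`, `s` with strictly positive sequence-based burst
#' sizes.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_burst_sizes <- function(path) {
  b <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "s") %in% names(b)))
    stop("burst-size table must have columns gene_id, s")
  if (any(b$s <= 0)) stop("burst sizes must be positive")
  b
}

#' Read a sparse binned contact map
#'
#' Three-column whitespace text `bin1_start bin2_start value` (short-dump
#' dialect) for one chromosome, plus an optional norm-factor file: either
#' one factor per line (line i = bin starting at (i-1)*resolution) or two
#' columns `bin factor`.
#'
#' @param path map file.
#' @param chrom chromosome name.
#' @param resolution bin size in bp (default 5000).
#' @param norm_path optional normalization-factor file.
#' @return a [contact_map()].
#' @export
read_contact_map <- function(path, chrom, resolution = 5000,
                             norm_path = NULL) {
  m <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(m) != 3) stop("contact map file must have 3 columns")
  names(m) <- c("bin1", "bin2", "value")
  nf <- NULL
  if (!is.null(norm_path)) {
    n <- read.table(norm_path, header = FALSE, stringsAsFactors = FALSE)
    nf <- if (ncol(n) == 1) {
      data.frame(bin = (seq_len(nrow(n)) - 1) * resolution,
                 factor = n[[1]])
    } else {
      data.frame(bin = n[[1]], factor = n[[2]])
    }
  }
  contact_map(chrom, m, resolution, nf)
}

#' Write / read gene-element contact pairs
#'
#' Headered TSV `gene_id`, `element_id`, `distance_bp`, `contact`.
#'
#' @param pairs pair data.frame.
#' @param path file path.
#' @return `read_pair_contacts` returns the data.frame.
#' @export
write_pair_contacts <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_contacts
#' @export
read_pair_contacts <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write elements as BED6 plus a sidecar TSV
#'
#' BED6 carries the read count in the score column; the sidecar TSV carries
#' the full table.
#'
#' @param elements element table.
#' @param prefix output path prefix (writes `<prefix>.bed` and
#'   `<prefix>.tsv`).
#' @return invisibly, the two paths.
#' @export
write_elements <- function(elements, prefix) {
  bed <- data.frame(elements$chrom, elements$start, elements$end,
                    elements$element_id, elements$read_count, ".")
  write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(elements, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paste0(prefix, ".bed"), paste0(prefix, ".tsv")))
}

#' Serialize an inference input to a directory
#'
#' Writes `genes.tsv` (per-gene arrays), `elements.tsv` (per-element
#' arrays) and `contacts.tsv` (sparse triplet by id); `read_inference_input`
#' restores the object.
#'
#' @param inp an `inference_input`.
#' @param dir directory (created if needed).
#' @return the directory, invisibly; `read_inference_input` returns the
#'   `inference_input`.
#' @export
write_inference_input <- function(inp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(gene_id = inp$gene_id, t = inp$t, lT = inp$lT,
                         s = inp$s, xP = inp$xP, lP = inp$lP),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(element_id = inp$element_id, xE = inp$xE,
                         lE = inp$lE),
              file.path(dir, "elements.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene_id = inp$gene_id[inp$ci_gene],
                         element_id = inp$element_id[inp$ci_elem],
                         contact = inp$c),
              file.path(dir, "contacts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_inference_input
#' @export
read_inference_input <- function(dir) {
  g <- read.table(file.path(dir, "genes.tsv"), header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  e <- read.table(file.path(dir, "elements.tsv"), header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  ct <- read.table(file.path(dir, "contacts.tsv"), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  inp <- structure(list(
    gene_id = g$gene_id, t = g$t, lT = g$lT, s = g$s, xP = g$xP, lP = g$lP,
    element_id = e$element_id, xE = e$xE, lE = e$lE,
    ci_gene = match(ct$gene_id, g$gene_id),
    ci_elem = match(ct$element_id, e$element_id),
    c = ct$contact), class = "inference_input")
  validate_inference_input(inp)
}

#' Write the posterior dump of a fitted state
#'
#' One TSV per variational family with columns (id, shape/lambda, rate/chi,
#' psi, mean, mean_log), mirroring the gamma and GIG parameterizations.
#'
#' @param state fitted `inference_state`.
#' @param inp matching `inference_input`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_posteriors <- function(state, inp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(data.frame(id = inp$gene_id, shape = state$av, rate = state$bv,
                mean = state$Ev, mean_log = state$Elnv), "q_v.tsv")
  wt(data.frame(id = inp$element_id, shape = state$aw, rate = state$bw,
                mean = state$Ew, mean_log = state$Elnw), "q_w.tsv")
  wt(data.frame(id = inp$gene_id, lambda = state$lamP, chi = state$chiP,
                psi = state$psiP, mean = state$EoP,
                inv_mean = state$EioP), "q_oP.tsv")
  wt(data.frame(id = inp$element_id, lambda = state$lamE, chi = state$chiE,
                psi = state$psiE, mean = state$EoE,
                inv_mean = state$EioE), "q_oE.tsv")
  wt(data.frame(id = "k", shape = state$ak, rate = state$bk,
                mean = state$Ek, mean_log = state$Elnk), "q_k.tsv")
  if (length(state$elbo_trace))
    wt(data.frame(iteration = seq_along(state$elbo_trace),
                  elbo = state$elbo_trace), "elbo_trace.tsv")
  invisible(dir)
}

#' Write a simulated dataset to disk
#'
#' Emits `genes.tsv`, `expression.tsv`, `peaks.narrowPeak`,
#' `burst_sizes.tsv`, `contacts_pairs.tsv`, a binned map
#' `map_<chrom>.txt` (pair contacts placed at their TSS/midpoint bins;
#' colliding bin pairs are summed), `ground_truth.tsv` per family, and the
#' assembled inference-input directory under `input/`.
#'
#' @param dataset result of [sample_dataset()].
#' @param dir output directory.
#' @param resolution map resolution in bp.
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir, resolution = 5000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f, col = TRUE)
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = col)
  wt(dataset$genes, "genes.tsv")
  wt(data.frame(gene_id = dataset$expression$gene_id,
                count = dataset$expression$read_count,
                effective_length = dataset$expression$effective_length_kb *
                  1000), "expression.tsv")
  pk <- dataset$peaks
  np <- data.frame(pk$chrom, pk$start, pk$end,
                   sprintf("peak%d", seq_len(nrow(pk))), 0, ".",
                   pk$read_count, -1, -1, pk$summit_offset)
  wt(np, "peaks.narrowPeak", col = FALSE)
  wt(dataset$burst_sizes, "burst_sizes.tsv")
  wt(dataset$contacts, "contacts_pairs.tsv")
  ## binned map rendering of the pair contacts
  tr <- dataset$truth
  tssb <- (dataset$genes$tss[tr$pair_gene] %/% resolution) * resolution
  mide <- (dataset$elements$start + dataset$elements$end) %/% 2
  midb <- (mide[tr$pair_elem] %/% resolution) * resolution
  b1 <- pmin(tssb, midb); b2 <- pmax(tssb, midb)
  agg <- rowsum(tr$c, paste(b1, b2))
  bb <- do.call(rbind, strsplit(rownames(agg), " "))
  wt(data.frame(as.numeric(bb[, 1]), as.numeric(bb[, 2]),
                as.numeric(agg)),
     paste0("map_", dataset$config$chrom, ".txt"), col = FALSE)
  wt(data.frame(gene_id = dataset$genes$gene_id, v = tr$v, oP = tr$oP,
                y = tr$y, s = tr$s), "ground_truth_genes.tsv")
  wt(data.frame(element_id = dataset$elements$element_id, w = tr$w,
                oE = tr$oE), "ground_truth_elements.tsv")
  wt(data.frame(k = tr$k), "ground_truth_scalars.tsv")
  wt(data.frame(gene_id = dataset$genes$gene_id[tr$pair_gene],
                element_id = dataset$elements$element_id[tr$pair_elem],
                c = tr$c, h = tr$h), "ground_truth_pairs.tsv")
  write_inference_input(dataset$input, file.path(dir, "input"))
  invisible(dir)
}
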