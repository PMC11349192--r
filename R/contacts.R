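## Processing of sparse binned chromatin contact maps into per-pair contact
## frequencies, with the standard corrections: diagonal replacement,
## substitution of unreliable (NaN / low balancing factor) entries by a
## power-law expectation, and a pseudocount so every stored pair is nonzero.

#' Binned contact map container
#'
#' Sparse symmetric intra-chromosomal contact map at a fixed resolution.
#' Entries are stored once with `bin1 <= bin2` (bin start coordinates in bp);
#' absent entries read as zero.
#'
#' @param chrom chromosome name.
#' @param entries data.frame with columns `bin1`, `bin2` (bin start bp) and
#'   `value`.
#' @param resolution bin size in bp (default 5000).
#' @param norm_factors optional data.frame `bin`, `factor` of balancing
#'   (e.g. Knight-Ruiz) normalization factors; low factors mark unreliable
#'   bins.
#' @return object of class `"contact_map"`.
#' @export
contact_map <- function(chrom, entries, resolution = 5000,
                        norm_factors = NULL) {
  if (resolution <= 0) stop("resolution must be positive")
  stopifnot(all(c("bin1", "bin2", "value") %in% names(entries)))
  b1 <- pmin(entries$bin1, entries$bin2)
  b2 <- pmax(entries$bin1, entries$bin2)
  if (any((b1 %% resolution) != 0) || any((b2 %% resolution) != 0))
    stop("bin coordinates must be multiples of the resolution")
  ent <- data.frame(bin1 = b1, bin2 = b2, value = entries$value)
  ent <- ent[order(ent$bin1, ent$bin2), , drop = FALSE]
  dup <- duplicated(ent[, c("bin1", "bin2")])
  if (any(dup)) stop("duplicate contact entries after symmetrization")
  rownames(ent) <- NULL
  structure(list(chrom = chrom, resolution = resolution, entries = ent,
                 norm_factors = norm_factors),
            class = "contact_map")
}

map_key <- function(map, b1, b2) {
  paste(pmin(b1, b2), pmax(b1, b2))
}

#' Look up contact values (zero when absent)
#'
#' @param map a [contact_map()].
#' @param b1,b2 bin start coordinates (bp), any order.
#' @return numeric vector of values; absent entries are 0.
#' @export
map_value <- function(map, b1, b2) {
  key <- map_key(map, b1, b2)
  idx <- match(key, map_key(map, map$entries$bin1, map$entries$bin2))
  v <- map$entries$value[idx]
  v[is.na(idx)] <- 0
  v
}

#' Replace diagonal entries by their neighbour maximum
#'
#' Each diagonal entry (i,i) is replaced by the maximum of the four matrix
#' cells adjacent to it along its row and column; by symmetry of the map
#' these reduce to the two stored upper-triangle neighbours (i-1,i) and
#' (i,i+1).  Missing neighbours are treated as absent (zero); off-diagonal
#' entries are never modified.  This removes the self-ligation artifact that
#' dominates the raw diagonal.
#'
#' @param map a [contact_map()].
#' @return the corrected map.
#' @export
fix_diagonal <- function(map) {
  ent <- map$entries
  res <- map$resolution
  diag_idx <- which(ent$bin1 == ent$bin2)
  if (!length(diag_idx)) return(map)
  b <- ent$bin1[diag_idx]
  left <- map_value(map, b - res, b)
  right <- map_value(map, b, b + res)
  ent$value[diag_idx] <- pmax(left, right)
  map$entries <- ent
  map
}

#' Power-law distance model of expected contact
#'
#' Expected contact frequency decays with genomic distance as
#' `scale * max(d, d_min)^(-gamma)`; `d_min` (one bin by default) caps the
#' divergence at zero distance.  The default exponent 0.7 is the canonical
#' intra-chromosomal decay.
#'
#' @param gamma positive decay exponent (default 0.7).
#' @param scale positive reference scale (default 1).
#' @param d_min minimum effective distance in bp (default 5000).
#' @return object of class `"power_law_model"`.
#' @export
power_law_model <- function(gamma = 0.7, scale = 1, d_min = 5000) {
  if (gamma <= 0 || scale <= 0 || d_min <= 0)
    stop("power_law_model parameters must be positive")
  structure(list(gamma = gamma, scale = scale, d_min = d_min),
            class = "power_law_model")
}

#' Expected contact at a distance
#'
#' @param model a [power_law_model()].
#' @param distance genomic distance in bp (vectorized, >= 0).
#' @return expected contact frequency.
#' @export
expected_contact <- function(model, distance) {
  if (any(distance < 0)) stop("distance must be non-negative")
  model$scale * pmax(distance, model$d_min)^(-model$gamma)
}

#' Replace unreliable map entries by the power-law expectation
#'
#' Entries that are NaN, or whose row or column bin has a balancing
#' normalization factor below `threshold` (or a missing/NaN factor), are
#' replaced by `expected_contact(model, |bin1 - bin2|)`.  A map without
#' normalization factors only has its NaN entries replaced.
#'
#' @param map a [contact_map()].
#' @param threshold factor threshold in (0, 1] (default 0.25).
#' @param model a [power_law_model()].
#' @return the corrected map; the number of replaced entries is reported in
#'   attribute `"n_replaced"`.
#' @export
replace_low_confidence <- function(map, threshold = 0.25,
                                   model = power_law_model()) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0,1]")
  ent <- map$entries
  bad <- is.na(ent$value)
  nf <- map$norm_factors
  if (!is.null(nf)) {
    f1 <- nf$factor[match(ent$bin1, nf$bin)]
    f2 <- nf$factor[match(ent$bin2, nf$bin)]
    bad <- bad | is.na(f1) | f1 < threshold | is.na(f2) | f2 < threshold
  }
  if (any(bad))
    ent$value[bad] <- expected_contact(model, abs(ent$bin1 - ent$bin2)[bad])
  map$entries <- ent
  attr(map, "n_replaced") <- sum(bad)
  map
}

#' Extract contact frequencies for gene-element pairs
#'
#' For every gene and element on the same chromosome whose TSS-to-element-
#' midpoint distance is at most `window`, looks up the contact between the
#' bin containing the TSS and the bin containing the element midpoint and
#' adds a pseudocount so all stored contacts are positive.  Without a map
#' for a chromosome (or with `maps = NULL`), contacts are the power-law
#' expectation of the distance, which is already positive.
#'
#' The default pseudocount is the power-law expectation at
#' `min(distance, 1 Mb)`, so near pairs get a distance-matched floor while
#' far pairs share the 1 Mb floor; a fixed constant can be supplied instead.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss`.
#' @param elements element table (`element_id`, `chrom`, `start`, `end`).
#' @param maps named list of [contact_map()] objects keyed by chromosome, or
#'   `NULL` for pure power-law contacts.
#' @param model a [power_law_model()] for fallback and pseudocount.
#' @param window maximum TSS-midpoint distance in bp (default 5e6).
#' @param pseudocount `"powerlaw"` (default) or a non-negative number; used
#'   only in map mode.
#' @return data.frame `gene_id`, `element_id`, `distance_bp`, `contact`.
#' @export
extract_pair_contacts <- function(genes, elements, maps = NULL,
                                  model = power_law_model(),
                                  window = 5e6, pseudocount = "powerlaw") {
  if (window <= 0) stop("window must be positive")
  out <- vector("list", length(unique(genes$chrom)))
  names(out) <- unique(genes$chrom)
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    ei <- which(elements$chrom == chr)
    if (!length(ei)) next
    mid <- (elements$start[ei] + elements$end[ei]) %/% 2
    pg <- rep(gi, each = length(ei))
    pe <- rep(ei, times = length(gi))
    d <- abs(genes$tss[pg] - mid[match(pe, ei)])
    keep <- d <= window
    pg <- pg[keep]; pe <- pe[keep]; d <- d[keep]
    if (!length(pg)) next
    map <- if (!is.null(maps)) maps[[chr]] else NULL
    if (is.null(map)) {
      if (!is.null(maps))
        warning("no contact map for ", chr, "; using power-law fallback")
      contact <- expected_contact(model, d)
    } else {
      res <- map$resolution
      btss <- (genes$tss[pg] %/% res) * res
      bmid <- (((elements$start[pe] + elements$end[pe]) %/% 2) %/% res) * res
      pc <- if (identical(pseudocount, "powerlaw")) {
        expected_contact(model, pmin(d, 1e6))
      } else {
        if (!is.numeric(pseudocount) || pseudocount < 0)
          stop("pseudocount must be 'powerlaw' or a non-negative number")
        rep(pseudocount, length(d))
      }
      contact <- map_value(map, btss, bmid) + pc
    }
    out[[chr]] <- data.frame(gene_id = genes$gene_id[pg],
                             element_id = elements$element_id[pe],
                             distance_bp = d, contact = contact,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(gene_id = character(), element_id = character(),
                      distance_bp = numeric(), contact = numeric())
  rownames(res) <- NULL
  drop0 <- res$contact <= 0
  if (any(drop0)) res <- res[!drop0, , drop = FALSE]
  res
}
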