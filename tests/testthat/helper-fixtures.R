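# Fixtures are generated in code and cached for the whole test run; the
# medium fixture and its fitted state are shared by several files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, seed = 1) {
  key <- paste0(name, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_fixture(name, seed = seed)
  .fixture_cache[[key]]
}

fitted_fixture <- function(name, seed = 1) {
  key <- paste0("fit_", name, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- run_inference(fixture(name, seed)$input)
  .fixture_cache[[key]]
}

# index into truth pair arrays for each row of the input contact triplet
truth_pair_index <- function(ds) {
  eidx <- match(ds$input$element_id, ds$elements$element_id)
  gidx <- match(ds$input$gene_id, ds$genes$gene_id)
  match(paste(gidx[ds$input$ci_gene], eidx[ds$input$ci_elem]),
        paste(ds$truth$pair_gene, ds$truth$pair_elem))
}

# truth w aligned with the input's element vector
truth_w <- function(ds) {
  ds$truth$w[match(ds$input$element_id, ds$elements$element_id)]
}

# tiny hand-built inference input: G genes, R elements, dense contacts
toy_input <- function(t, xP, xE, cmat, lT = rep(1, length(t)),
                      s = rep(1, length(t)), lP = rep(1, length(t)),
                      lE = rep(1, length(xE))) {
  G <- length(t); R <- length(xE)
  idx <- which(cmat > 0, arr.ind = TRUE)
  expr <- data.frame(gene_id = paste0("g", seq_len(G)), read_count = t,
                     effective_length_kb = lT)
  prom <- data.frame(gene_id = expr$gene_id, length_kb = lP, read_count = xP,
                     constituent_ids = "")
  elem <- data.frame(element_id = paste0("e", seq_len(R)), chrom = "chrT",
                     start = seq_len(R) * 1000L,
                     end = seq_len(R) * 1000L + 500L,
                     length_kb = lE, read_count = xE)
  contacts <- data.frame(gene_id = expr$gene_id[idx[, 1]],
                         element_id = elem$element_id[idx[, 2]],
                         contact = cmat[idx])
  burst <- data.frame(gene_id = expr$gene_id, s = s)
  assemble_inference_input(expr, prom, elem, contacts, burst)
}
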