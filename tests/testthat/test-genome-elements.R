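# Element construction: resize/merge, promoter aggregation, TPM filtering.

test_that("resize-then-merge follows the hand-traced rule", {
  pk <- data.frame(chrom = "chr1", start = c(900, 1200), end = c(1100, 1400),
                   summit_offset = c(100, 100), read_count = c(10, 5))
  # summits 1000 and 1300, width 500 -> [750,1250) and [1050,1550) overlap
  el <- select_resize_merge_peaks(pk, top_n = Inf, width = 500)
  expect_equal(nrow(el), 1)
  expect_equal(el$start, 750)
  expect_equal(el$end, 1550)
  expect_equal(el$read_count, 15)
  expect_equal(el$element_id, "chr1:750-1550")
  expect_equal(el$length_kb, 0.8)

  # clipping at the chromosome start truncates
  pk1 <- data.frame(chrom = "chr1", start = 0, end = 200,
                    summit_offset = 100, read_count = 3)
  el1 <- select_resize_merge_peaks(pk1, top_n = Inf, width = 500)
  expect_equal(c(el1$start, el1$end), c(0, 350))

  # bookended intervals (end == next start) are NOT merged
  pk2 <- data.frame(chrom = "chr1", start = c(0, 500), end = c(500, 1000),
                    summit_offset = c(250, 250), read_count = c(1, 2))
  el2 <- select_resize_merge_peaks(pk2, top_n = Inf, width = NA)
  expect_equal(nrow(el2), 2)
})

test_that("top-N selection keeps the highest counts with genomic tie-break", {
  pk <- data.frame(chrom = "chr1",
                   start = c(10000, 30000, 50000, 70000, 90000),
                   end = c(10000, 30000, 50000, 70000, 90000) + 300,
                   summit_offset = 150,
                   read_count = c(5, 50, 20, 50, 7))
  el <- select_resize_merge_peaks(pk, top_n = 3, width = 500)
  expect_equal(nrow(el), 3)
  expect_equal(sort(el$read_count), c(20, 50, 50))
  # tie at the boundary: count 5 vs 7 -> 7 would enter at top_n = 4
  el4 <- select_resize_merge_peaks(pk, top_n = 4, width = 500)
  expect_true((90000 + 150 - 250) %in% el4$start)
  expect_false(any(el4$read_count == 5))
})

test_that("degenerate peak inputs are handled", {
  expect_warning(el <- select_resize_merge_peaks(
    data.frame(chrom = character(), start = integer(), end = integer(),
               summit_offset = integer(), read_count = integer())),
    "empty")
  expect_equal(nrow(el), 0)
  expect_error(select_resize_merge_peaks(
    data.frame(chrom = "chr1", start = 0, end = 100, summit_offset = 10,
               read_count = -1)), "negative")
})

test_that("merge matches the brute-force oracle and conserves reads", {
  set.seed(42)
  for (rep in 1:5) {
    pk <- random_peaks(200)
    top_n <- sample(c(50, 150, Inf), 1)
    el <- select_resize_merge_peaks(pk, top_n = top_n, width = 500)
    or <- oracle_merge(pk, top_n = top_n, width = 500)
    expect_equal(el$chrom, or$chrom)
    expect_equal(el$start, or$start)
    expect_equal(el$end, or$end)
    expect_equal(el$read_count, or$read_count)
    # read conservation over the kept peaks
    o <- order(-pk$read_count, pk$chrom, pk$start, method = "radix")
    kept <- pk[o[seq_len(min(top_n, nrow(pk)))], ]
    expect_equal(sum(el$read_count), sum(kept$read_count))
  }
})

test_that("merging is idempotent on its own output", {
  set.seed(7)
  pk <- random_peaks(300)
  el <- select_resize_merge_peaks(pk, top_n = Inf, width = 500)
  again <- select_resize_merge_peaks(
    data.frame(chrom = el$chrom, start = el$start, end = el$end,
               read_count = el$read_count),
    top_n = Inf, width = NA)
  expect_equal(again, el)
})

test_that("promoter aggregation sums constituents over a half-open window", {
  el <- data.frame(element_id = c("a", "b", "c", "d"), chrom = "chr1",
                   start = c(900, 1600, 4999, 51000),
                   end = c(1400, 2100, 5499, 51500),
                   length_kb = 0.5, read_count = c(10, 20, 99, 7))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      tss = c(1000, 4000, 50000))
  expect_message(pr <- build_promoter_elements(genes, el, flank = 1000),
                 "excluded")
  expect_equal(pr$gene_id, c("g1", "g2"))
  # g1 catches both 500 bp elements: lP = 1.0 kb, xP = 30
  expect_equal(pr$length_kb[1], 1.0)
  expect_equal(pr$read_count[1], 30)
  expect_equal(pr$read_count[2], 99)
  expect_equal(pr$constituent_ids[2], "c")
  # g3's nearest element starts exactly at tss + flank (half-open window):
  # excluded
  expect_equal(attr(pr, "excluded_genes"), "g3")

  expect_error(build_promoter_elements(
    data.frame(gene_id = c("g", "g"), chrom = "chr1", tss = c(1, 2)), el),
    "duplicate")
})

test_that("promoter aggregation matches a brute-force overlap scan", {
  set.seed(11)
  pk <- random_peaks(400)
  el <- select_resize_merge_peaks(pk, top_n = Inf, width = 500)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:100),
                      chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
                      tss = sample.int(5e5, 100))
  pr <- suppressMessages(build_promoter_elements(genes, el))
  or <- oracle_promoters(genes, el)
  expect_equal(pr$gene_id, or$gene_id)
  expect_equal(pr$length_kb, or$length_kb)
  expect_equal(pr$read_count, or$read_count)
})

test_that("the enhancer universe is the identity on elements", {
  el <- select_resize_merge_peaks(random_peaks(50), top_n = Inf)
  expect_identical(enhancer_universe(el), el)
  expect_identical(enhancer_universe(el[0, ]), el[0, ])
})

test_that("TPM is normalized to one million and filtered strictly", {
  expr <- data.frame(gene_id = c("a", "b", "c", "d"),
                     read_count = c(100, 200, 50, 0),
                     effective_length_kb = c(1, 2, 0.5, 3))
  expr <- compute_tpm(expr)
  expect_equal(sum(expr$tpm), 1e6)
  expect_equal(expr$tpm[1], expr$tpm[2]) # same rate
  expect_equal(nrow(filter_genes_by_expression(expr, 0)), 3)

  e2 <- data.frame(gene_id = c("x", "y", "z"), read_count = c(79, 80, 81),
                   effective_length_kb = 1)
  e2$tpm <- c(7.9, 8.0, 8.1)
  expect_equal(filter_genes_by_expression(e2, 8)$gene_id, "z")
})

test_that("TSS derivation follows the strand convention", {
  expect_equal(tss_from_body(c(100, 100), c(200, 200), c("+", "-")),
               c(100, 199))
})
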