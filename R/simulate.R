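## Generative simulator: samples the model forward with known latent
## activities so inference can be validated by parameter recovery, and emits
## the same on-disk formats the preprocessing modules read.

#' Simulation configuration
#'
#' The stated world of the generator: one synthetic chromosome carrying
#' `n_elements` non-overlapping accessibility elements, `n_genes` of
#' which (spread along the chromosome) double as promoter elements of the
#' genes (one promoter element per gene, centred on its TSS; the same
#' element also appears in the enhancer universe, as promoters can act as
#' enhancers).  Latents are drawn
#' from the model priors under `hyper`; element widths are log-uniform
#' 500-2000 bp, effective transcript lengths log-uniform 0.5-5 kb, and
#' sequence-based burst sizes log-uniform 0.5-2.  Contacts follow the
#' power-law decay of distance with multiplicative log-normal noise
#' (`contact_noise_sd`, default 0.25) to mimic contact-map dispersion, and
#' are globally rescaled so the mean RNA-seq count matches `depth_t`
#' (inference is invariant to that global contact scale).
#'
#' @param n_genes,n_elements counts (`n_elements >= n_genes >= 1`).
#' @param chrom chromosome name.
#' @param chrom_length length in bp (default 30 kb per element).
#' @param hyper [hyperparameters()] used for sampling.
#' @param contact_mode `"powerlaw"` (all in-window pairs) or
#'   `"random_sparse"` (each in-window pair kept with probability
#'   `sparsity`; a gene's own promoter element is always kept so no gene
#'   has an empty contact row).
#' @param sparsity keep-probability for `"random_sparse"` mode.
#' @param contact_noise_sd log-normal sdlog of contact noise.
#' @param depth_t target mean RNA-seq read count per gene (default 1000).
#' @param window contact distance window in bp (default 5e6).
#' @param model [power_law_model()] for contact decay.
#' @param seed integer seed fixing the entire dataset.
#' @param latent_overrides optional named list (`v`, `w`, `oP`, `oE`, `k`)
#'   of fixed latent values (scalars recycled) replacing the prior draws.
#' @return list of class `"sim_config"`.
#' @export
simulation_config <- function(n_genes, n_elements, chrom = "chrS",
                              chrom_length = n_elements * 30000,
                              hyper = hyperparameters(),
                              contact_mode = c("powerlaw", "random_sparse"),
                              sparsity = 0.2, contact_noise_sd = 0.25,
                              depth_t = 1000, window = 5e6,
                              model = power_law_model(), seed = 1,
                              latent_overrides = NULL) {
  contact_mode <- match.arg(contact_mode)
  if (n_genes < 1 || n_elements < n_genes)
    stop("need n_elements >= n_genes >= 1")
  structure(list(n_genes = n_genes, n_elements = n_elements, chrom = chrom,
                 chrom_length = chrom_length, hyper = hyper,
                 contact_mode = contact_mode, sparsity = sparsity,
                 contact_noise_sd = contact_noise_sd, depth_t = depth_t,
                 window = window, model = model, seed = seed,
                 latent_overrides = latent_overrides),
            class = "sim_config")
}

rlogunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Sample a synthetic dataset from the generative model
#'
#' Draws openness `oE ~ Gamma(alpha_o, beta_o)` per element (shared with the
#' promoter openness `oP` for promoter elements, since both views observe
#' the same genomic region), activities `v ~ Gamma(alpha_v,
#' alpha_v/(s oP))`, `w ~ Gamma(alpha_w, alpha_w/(lE oE))` and scale
#' `k ~ Gamma(alpha_k, beta_k)`; builds contacts from the configured mode;
#' sets `y_g = k v_g sum_r c_gr w_r` exactly; and draws counts
#' `t ~ Poisson(lT y)`, `x ~ Poisson(l o)` (one accessibility draw per
#' element, reused as `xP` for its gene).
#'
#' @param config a [simulation_config()].
#' @return list with the generated tables (`genes`, `expression`, `peaks`,
#'   `elements`, `promoters`, `burst_sizes`, `contacts`), the assembled
#'   `input` (an `inference_input`), and `truth` (per-gene `v`, `oP`, `y`;
#'   per-element `w`, `oE`; scalar `k`; per-pair `c` and `h`).
#' @export
sample_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  hy <- config$hyper
  G <- config$n_genes; R <- config$n_elements
  slot <- config$chrom_length / R
  if (slot < 2500) stop("chromosome too short for the element count")

  width <- round(rlogunif(R, 500, min(2000, slot - 500)))
  start <- round((seq_len(R) - 1) * slot + runif(R, 0, slot - width - 1))
  end <- start + width
  lE <- width / 1000

  ## genes: G elements spread along the chromosome serve as promoter
  ## elements, TSS at the element midpoint
  prom_elem <- sort(sample(R, G))
  tss <- (start[prom_elem] + end[prom_elem]) %/% 2
  strand <- sample(c("+", "-"), G, replace = TRUE)
  body_len <- round(rlogunif(G, 5000, 100000))
  gstart <- ifelse(strand == "+", tss, pmax(0, tss - body_len + 1))
  gend <- ifelse(strand == "+", pmin(config$chrom_length, tss + body_len),
                 tss + 1)

  ## latents
  ov <- function(name, default) {
    o <- config$latent_overrides[[name]]
    if (is.null(o)) default else rep_len(o, length(default))
  }
  oE <- ov("oE", rgamma(R, hy$alpha_o, rate = hy$beta_o))
  oP <- ov("oP", oE[prom_elem])
  s <- rlogunif(G, 0.5, 2)
  lT <- rlogunif(G, 0.5, 5)
  v <- ov("v", rgamma(G, hy$alpha_v, rate = hy$alpha_v / (s * oP)))
  w <- ov("w", rgamma(R, hy$alpha_w, rate = hy$alpha_w / (lE * oE)))
  k <- ov("k", rgamma(1, hy$alpha_k, rate = hy$beta_k))

  ## contacts on the in-window support
  mid <- (start + end) %/% 2
  pg <- rep(seq_len(G), each = R)
  pe <- rep(seq_len(R), times = G)
  d <- abs(tss[pg] - mid[pe])
  keep <- d <= config$window
  if (config$contact_mode == "random_sparse") {
    keep <- keep & (runif(length(d)) < config$sparsity | pe == prom_elem[pg])
  }
  pg <- pg[keep]; pe <- pe[keep]; d <- d[keep]
  c0 <- expected_contact(config$model, d) *
    rlnorm(length(d), 0, config$contact_noise_sd)
  sw0 <- as.numeric(rowsum(c0 * w[pe], pg))
  gamma_scale <- config$depth_t / mean(lT * k * v * sw0)
  cc <- c0 * gamma_scale
  y <- k * v * as.numeric(rowsum(cc * w[pe], pg))
  h <- cc * w[pe] / (y / (k * v))[pg]

  ## observed counts
  xE <- rpois(R, lE * oE)
  xP <- xE[prom_elem]
  t <- rpois(G, lT * y)

  gene_id <- sprintf("g%03d", seq_len(G))
  genes <- data.frame(gene_id = gene_id, symbol = gene_id,
                      chrom = config$chrom, strand = strand, tss = tss,
                      start = gstart, end = gend, stringsAsFactors = FALSE)
  elements <- data.frame(
    element_id = sprintf("%s:%d-%d", config$chrom, as.integer(start),
                         as.integer(end)),
    chrom = config$chrom, start = as.integer(start), end = as.integer(end),
    length_kb = lE, read_count = xE, stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = config$chrom, start = as.integer(start),
                      end = as.integer(end),
                      summit_offset = as.integer((end - start) %/% 2),
                      read_count = xE, stringsAsFactors = FALSE)
  expression <- compute_tpm(data.frame(
    gene_id = gene_id, read_count = t, effective_length_kb = lT,
    stringsAsFactors = FALSE))
  burst_sizes <- data.frame(gene_id = gene_id, s = s,
                            stringsAsFactors = FALSE)
  contacts <- data.frame(gene_id = gene_id[pg],
                         element_id = elements$element_id[pe],
                         distance_bp = d, contact = cc,
                         stringsAsFactors = FALSE)
  promoters <- data.frame(gene_id = gene_id,
                          length_kb = lE[prom_elem],
                          read_count = xP,
                          constituent_ids = elements$element_id[prom_elem],
                          stringsAsFactors = FALSE)
  truth <- list(v = v, oP = oP, y = y, w = w, oE = oE, k = k,
                pair_gene = pg, pair_elem = pe, c = cc, h = h,
                s = s, lT = lT, lE = lE)
  input <- assemble_inference_input(expression, promoters, elements,
                                    contacts, burst_sizes)
  list(config = config, genes = genes, expression = expression,
       peaks = peaks, elements = elements, promoters = promoters,
       burst_sizes = burst_sizes, contacts = contacts, truth = truth,
       input = input)
}

#' Redraw the observed counts of an existing dataset
#'
#' Keeps all latents and contacts fixed and redraws `t`, `xE` (and hence
#' `xP`) from their Poisson observation models; used to check the
#' observation layer's moments.
#'
#' @param dataset result of [sample_dataset()].
#' @param seed integer seed.
#' @return list with vectors `t` and `xE`.
#' @export
resample_observed <- function(dataset, seed) {
  set.seed(seed)
  tr <- dataset$truth
  list(t = rpois(length(tr$y), tr$lT * tr$y),
       xE = rpois(length(tr$oE), tr$lE * tr$oE))
}

#' Named test fixtures
#'
#' * `tiny`: 3 genes x 5 elements on a short chromosome, hand-checkable.
#' * `medium`: 200 genes x 600 elements, the parameter-recovery workload.
#' * `degenerate`: a zero-count gene, an element with no contacts, and a
#'   single-enhancer gene, exercising the boundary behaviour end-to-end.
#'
#' @param name fixture name.
#' @param seed integer seed (default 1).
#' @return a dataset as from [sample_dataset()].
#' @export
make_fixture <- function(name = c("tiny", "medium", "degenerate"), seed = 1) {
  name <- match.arg(name)
  if (name == "tiny") {
    return(sample_dataset(simulation_config(3, 5, chrom_length = 150000,
                                            seed = seed)))
  }
  if (name == "medium") {
    return(sample_dataset(simulation_config(200, 600, seed = seed)))
  }
  ## degenerate: edit a small sampled dataset
  ds <- sample_dataset(simulation_config(4, 8, chrom_length = 400000,
                                         seed = seed))
  ## gene 1: zero RNA-seq count
  ds$expression$read_count[1] <- 0
  ds$expression <- compute_tpm(ds$expression)
  ## element 8: remove all its contacts (stays in the universe)
  drop_elem <- ds$elements$element_id[8]
  ds$contacts <- ds$contacts[ds$contacts$element_id != drop_elem, ,
                             drop = FALSE]
  ## gene 4: keep only its single strongest contact
  g4 <- ds$contacts$gene_id == "g004"
  best <- which(g4)[which.max(ds$contacts$contact[g4])]
  ds$contacts <- ds$contacts[!g4 | seq_len(nrow(ds$contacts)) == best, ,
                             drop = FALSE]
  ds$input <- assemble_inference_input(ds$expression, ds$promoters,
                                       ds$elements, ds$contacts,
                                       ds$burst_sizes)
  ds
}
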