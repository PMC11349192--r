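## Mean-field variational inference for the gamma-Poisson bursting model.
##
## Observed data per gene g: RNA-seq count t_g with effective transcript
## length lT_g (kb), promoter accessibility count xP_g with promoter length
## lP_g (kb), sequence-based burst size s_g; per element r: accessibility
## count xE_r with length lE_r (kb); per pair: contact frequency c_gr.
##
## Latents: promoter activity v_g ~ Gamma(av, av/(s_g oP_g)), enhancer
## activity w_r ~ Gamma(aw, aw/(lE_r oE_r)), openness oP_g, oE_r ~
## Gamma(ao, bo), scale k ~ Gamma(ak, bk); t_g ~ Poisson(lT_g k v_g
## sum_r c_gr w_r), xP_g ~ Poisson(lP_g oP_g), xE_r ~ Poisson(lE_r oE_r).
##
## The variational posterior factorizes over families; activities and the
## scale stay gamma, openness becomes generalized inverse Gaussian.  The
## intractable E[log sum_r c_gr w_r] is lower-bounded via an auxiliary
## per-gene probability vector rho over the contact support.

#' Hyperparameters of the bursting model
#'
#' `alpha_v` and `alpha_w` are the gamma shape parameters of the promoter
#' and enhancer activity priors; their defaults (80 and 10) give the
#' enhancer prior a much larger coefficient of variation than the promoter
#' prior.  `alpha_o`/`beta_o` and `alpha_k`/`beta_k` are weakly informative
#' defaults for the openness and scale priors; posterior parameters are
#' data-dominated at realistic sequencing depths.
#'
#' @param alpha_v,alpha_w,alpha_o,beta_o,alpha_k,beta_k positive reals.
#' @param variant one of `"standard"`, `"no_sg"` (ignore the sequence-based
#'   burst size in the promoter-activity prior) or `"no_lE"` (ignore the
#'   element length in the enhancer-activity prior; the Poisson observation
#'   model keeps the true length).
#' @return list of class `"enhact_hyper"`.
#' @export
hyperparameters <- function(alpha_v = 80, alpha_w = 10,
                            alpha_o = 1, beta_o = 1e-3,
                            alpha_k = 1, beta_k = 1e-3,
                            variant = c("standard", "no_sg", "no_lE")) {
  variant <- match.arg(variant)
  vals <- c(alpha_v, alpha_w, alpha_o, beta_o, alpha_k, beta_k)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all hyperparameters must be positive")
  structure(list(alpha_v = alpha_v, alpha_w = alpha_w, alpha_o = alpha_o,
                 beta_o = beta_o, alpha_k = alpha_k, beta_k = beta_k,
                 variant = variant),
            class = "enhact_hyper")
}

#' Assemble the arrays consumed by the inference engine
#'
#' Aligns the per-gene tables (expression, promoter elements, burst sizes),
#' the element table, and the sparse contact pairs into indexed arrays.
#' Genes must have a promoter element, an expression record and at least one
#' contact; genes failing this are dropped with a message.  Contacts whose
#' gene or element is absent are dropped.
#'
#' @param expression data.frame `gene_id`, `read_count`,
#'   `effective_length_kb` (already expression-filtered if desired).
#' @param promoters promoter table from [build_promoter_elements()].
#' @param elements element table (the enhancer universe).
#' @param contacts data.frame `gene_id`, `element_id`, `contact` (positive),
#'   optionally `distance_bp`.
#' @param burst_sizes optional data.frame `gene_id`, `s`; genes absent from
#'   it get `default_s`.
#' @param default_s default burst size (1).
#' @return list of class `"inference_input"` with per-gene vectors `t`,
#'   `lT`, `s`, `xP`, `lP`, per-element `xE`, `lE`, id vectors, and the
#'   contact triplet (`ci_gene`, `ci_elem`, `c`) ordered by gene.
#' @export
assemble_inference_input <- function(expression, promoters, elements,
                                     contacts, burst_sizes = NULL,
                                     default_s = 1) {
  gene_ids <- intersect(expression$gene_id, promoters$gene_id)
  gene_ids <- intersect(gene_ids, unique(contacts$gene_id))
  dropped <- setdiff(union(expression$gene_id, promoters$gene_id), gene_ids)
  if (length(dropped))
    message(length(dropped),
            " gene(s) dropped (missing expression, promoter, or contacts)")
  if (!length(gene_ids)) stop("no genes left after alignment")
  ei <- match(contacts$element_id, elements$element_id)
  gi <- match(contacts$gene_id, gene_ids)
  ok <- !is.na(ei) & !is.na(gi)
  contacts <- contacts[ok, , drop = FALSE]
  gi <- gi[ok]; ei <- ei[ok]
  used_elem <- sort(unique(ei))
  elements <- elements[used_elem, , drop = FALSE]
  ei <- match(ei, used_elem)

  eidx <- match(gene_ids, expression$gene_id)
  pidx <- match(gene_ids, promoters$gene_id)
  s <- rep(default_s, length(gene_ids))
  if (!is.null(burst_sizes)) {
    m <- match(gene_ids, burst_sizes$gene_id)
    s[!is.na(m)] <- burst_sizes$s[m[!is.na(m)]]
  }
  inp <- structure(list(
    gene_id = gene_ids,
    t = as.numeric(expression$read_count[eidx]),
    lT = as.numeric(expression$effective_length_kb[eidx]),
    s = as.numeric(s),
    xP = as.numeric(promoters$read_count[pidx]),
    lP = as.numeric(promoters$length_kb[pidx]),
    element_id = elements$element_id,
    xE = as.numeric(elements$read_count),
    lE = as.numeric(elements$length_kb),
    ci_gene = gi, ci_elem = ei, c = as.numeric(contacts$contact)
  ), class = "inference_input")
  validate_inference_input(inp)
}

validate_inference_input <- function(inp) {
  with(inp, {
    if (any(lT <= 0) || any(lP <= 0) || any(lE <= 0) || any(s <= 0))
      stop("lengths and burst sizes must be strictly positive")
    if (any(t < 0) || any(xP < 0) || any(xE < 0))
      stop("counts must be non-negative")
    if (any(c <= 0)) stop("contacts must be strictly positive")
    if (!setequal(unique(ci_gene), seq_along(t)))
      stop("every gene needs at least one contact")
  })
  o <- order(inp$ci_gene, inp$ci_elem)
  inp$ci_gene <- inp$ci_gene[o]; inp$ci_elem <- inp$ci_elem[o]
  inp$c <- inp$c[o]
  inp
}

## --- sparse row/column helpers over the contact triplet ------------------

row_sum <- function(inp, x) {
  as.numeric(rowsum(x, inp$ci_gene, reorder = TRUE))
}

col_sum <- function(inp, x, n_elem) {
  out <- numeric(n_elem)
  cs <- rowsum(x, inp$ci_elem, reorder = TRUE)
  out[as.integer(rownames(cs))] <- cs
  out
}

## --- state initialization -------------------------------------------------

#' Initialize the variational state
#'
#' Moment-matched warm start: openness expectations are posterior means of
#' the openness given only its own accessibility count, activities start at
#' their prior means given that openness, and the scale matches total
#' observed expression.  Deterministic; the first action of a sweep is the
#' auxiliary-vector update.
#'
#' @param inp an `inference_input`.
#' @param hyper [hyperparameters()].
#' @return list of class `"inference_state"`.
#' @export
init_state <- function(inp, hyper) {
  G <- length(inp$t); R <- length(inp$xE)
  s_eff <- if (hyper$variant == "no_sg") rep(1, G) else inp$s
  EoP <- (inp$xP + hyper$alpha_o) / (inp$lP + hyper$beta_o)
  EoE <- (inp$xE + hyper$alpha_o) / (inp$lE + hyper$beta_o)
  Ev <- s_eff * EoP
  Ew <- inp$lE * EoE
  Sw <- row_sum(inp, inp$c * Ew[inp$ci_elem])
  state <- list(
    Ev = Ev, Elnv = log(Ev),
    Ew = Ew, Elnw = log(Ew),
    EoP = EoP, EioP = 1 / EoP, ElnoP = log(EoP),
    EoE = EoE, EioE = 1 / EoE, ElnoE = log(EoE),
    Ek = sum(inp$t) / sum(inp$lT * Ev * Sw), Elnk = NA_real_,
    rho = NULL,
    av = NULL, bv = NULL, aw = NULL, bw = NULL,
    lamP = NULL, chiP = NULL, psiP = NULL,
    lamE = NULL, chiE = NULL, psiE = NULL,
    ak = NULL, bk = NULL,
    elbo_trace = numeric(), iteration = 0L, converged = FALSE,
    max_rel_dw = NA_real_
  )
  state$Elnk <- log(state$Ek)
  class(state) <- "inference_state"
  state
}

## --- coordinate updates (each refreshes its cached expectations) ---------

#' Update the auxiliary contact-allocation probabilities
#'
#' `rho_r(g) = c_gr exp(E[log w_r]) / sum_r' c_gr' exp(E[log w_r'])` over
#' the contact support of gene g, evaluated with a per-gene log-sum-exp
#' shift so arbitrary magnitudes of `E[log w]` are safe.
#'
#' @param state inference state with `Elnw` cached.
#' @param inp inference input.
#' @return the state with `rho` set (sums to 1 within each gene row).
#' @export
update_rho <- function(state, inp) {
  z <- log(inp$c) + state$Elnw[inp$ci_elem]
  g <- inp$ci_gene
  mx <- tapply(z, g, max) # levels of factor(g) are 1..G in numeric order
  ez <- exp(z - as.numeric(mx)[g])
  den <- row_sum(inp, ez)
  state$rho <- ez / den[g]
  state
}

#' Update q(w), the enhancer-activity posteriors
#'
#' `aw_r = alpha_w + sum_g t_g rho_r(g)`;
#' `bw_r = (alpha_w / lE_r) E[1/oE_r] + E[k] sum_g lT_g E[v_g] c_gr`
#' (the `no_lE` variant drops the division by `lE_r` in the prior term).
#'
#' @param state,inp,hyper state, input, hyperparameters.
#' @return updated state with `Ew`, `Elnw` refreshed.
#' @export
update_q_w <- function(state, inp, hyper) {
  R <- length(inp$xE)
  lE_prior <- if (hyper$variant == "no_lE") rep(1, R) else inp$lE
  aw <- hyper$alpha_w +
    col_sum(inp, inp$t[inp$ci_gene] * state$rho, R)
  bw <- (hyper$alpha_w / lE_prior) * state$EioE +
    state$Ek * col_sum(inp, inp$lT[inp$ci_gene] * state$Ev[inp$ci_gene] * inp$c, R)
  state$aw <- aw; state$bw <- bw
  state$Ew <- aw / bw
  state$Elnw <- digamma(aw) - log(bw)
  state
}

#' Update q(v), the promoter-activity posteriors
#'
#' `av_g = alpha_v + t_g`;
#' `bv_g = (alpha_v / s_g) E[1/oP_g] + lT_g E[k] sum_r c_gr E[w_r]`
#' (the `no_sg` variant uses s_g = 1).
#'
#' @inheritParams update_q_w
#' @return updated state with `Ev`, `Elnv` refreshed.
#' @export
update_q_v <- function(state, inp, hyper) {
  s_eff <- if (hyper$variant == "no_sg") rep(1, length(inp$t)) else inp$s
  Sw <- row_sum(inp, inp$c * state$Ew[inp$ci_elem])
  av <- hyper$alpha_v + inp$t
  bv <- (hyper$alpha_v / s_eff) * state$EioP + inp$lT * state$Ek * Sw
  state$av <- av; state$bv <- bv
  state$Ev <- av / bv
  state$Elnv <- digamma(av) - log(bv)
  state
}

#' Update q(oE), the enhancer-openness GIG posteriors
#'
#' `lamE_r = alpha_o - alpha_w + xE_r`; `chiE_r = 2 alpha_w E[w_r] / lE_r`
#' (`no_lE`: no division); `psiE_r = 2 beta_o + 2 lE_r`.
#'
#' @inheritParams update_q_w
#' @param need_mean_log whether to refresh `ElnoE` (needed for the ELBO).
#' @return updated state with `EoE`, `EioE` (and optionally `ElnoE`)
#'   refreshed.
#' @export
update_q_oE <- function(state, inp, hyper, need_mean_log = TRUE) {
  R <- length(inp$xE)
  lE_prior <- if (hyper$variant == "no_lE") rep(1, R) else inp$lE
  state$lamE <- hyper$alpha_o - hyper$alpha_w + inp$xE
  state$chiE <- 2 * hyper$alpha_w * state$Ew / lE_prior
  state$psiE <- 2 * hyper$beta_o + 2 * inp$lE
  ex <- gig_expectations(gig_q(state$lamE, state$chiE, state$psiE))
  state$EoE <- ex$mean; state$EioE <- ex$inv_mean
  if (need_mean_log) state$ElnoE <- ex$mean_log
  state
}

#' Update q(oP), the promoter-openness GIG posteriors
#'
#' `lamP_g = alpha_o - alpha_v + xP_g`; `chiP_g = 2 alpha_v E[v_g] / s_g`
#' (`no_sg`: s_g = 1); `psiP_g = 2 beta_o + 2 lP_g`.
#'
#' @inheritParams update_q_oE
#' @return updated state with `EoP`, `EioP` (and optionally `ElnoP`)
#'   refreshed.
#' @export
update_q_oP <- function(state, inp, hyper, need_mean_log = TRUE) {
  s_eff <- if (hyper$variant == "no_sg") rep(1, length(inp$t)) else inp$s
  state$lamP <- hyper$alpha_o - hyper$alpha_v + inp$xP
  state$chiP <- 2 * hyper$alpha_v * state$Ev / s_eff
  state$psiP <- 2 * hyper$beta_o + 2 * inp$lP
  ex <- gig_expectations(gig_q(state$lamP, state$chiP, state$psiP))
  state$EoP <- ex$mean; state$EioP <- ex$inv_mean
  if (need_mean_log) state$ElnoP <- ex$mean_log
  state
}

#' Update q(k), the scale posterior
#'
#' `ak = alpha_k + sum_g t_g`;
#' `bk = beta_k + sum_g lT_g E[v_g] sum_r c_gr E[w_r]`.
#'
#' @inheritParams update_q_w
#' @return updated state with `Ek`, `Elnk` refreshed.
#' @export
update_q_k <- function(state, inp, hyper) {
  Sw <- row_sum(inp, inp$c * state$Ew[inp$ci_elem])
  state$ak <- hyper$alpha_k + sum(inp$t)
  state$bk <- hyper$beta_k + sum(inp$lT * state$Ev * Sw)
  state$Ek <- state$ak / state$bk
  state$Elnk <- digamma(state$ak) - log(state$bk)
  state
}

## --- ELBO -----------------------------------------------------------------

#' Evidence lower bound of the current state
#'
#' Computes the variational lower bound with the intractable
#' `E[log sum_r c_gr w_r]` replaced by its auxiliary-vector bound
#' `sum_r rho (log c + E[log w]) - sum_r rho log rho`.  Additive constants
#' that do not depend on the variational distribution (`log t_g!`,
#' `log xP_g!`, `log xE_r!`) are omitted, so values are comparable across
#' iterations but not across datasets.
#'
#' @param state a state in which all posterior families and `rho` are set
#'   (i.e. after at least one full sweep with mean-logs refreshed).
#' @param inp inference input.
#' @param hyper hyperparameters.
#' @return scalar lower-bound value.
#' @export
compute_elbo <- function(state, inp, hyper) {
  G <- length(inp$t); R <- length(inp$xE)
  s_eff <- if (hyper$variant == "no_sg") rep(1, G) else inp$s
  lE_prior <- if (hyper$variant == "no_lE") rep(1, R) else inp$lE
  av <- hyper$alpha_v; aw <- hyper$alpha_w
  ao <- hyper$alpha_o; bo <- hyper$beta_o
  akh <- hyper$alpha_k; bkh <- hyper$beta_k

  rho <- state$rho
  g <- inp$ci_gene
  Sw <- row_sum(inp, inp$c * state$Ew[inp$ci_elem])
  rlogr <- rho * log(rho)
  rlogr[rho == 0] <- 0
  t_obs <- sum(inp$t * (log(inp$lT) + state$Elnk + state$Elnv)) +
    sum(inp$t[g] * rho * (log(inp$c) + state$Elnw[inp$ci_elem])) -
    sum(inp$t[g] * rlogr) -
    state$Ek * sum(inp$lT * state$Ev * Sw)
  xP_obs <- sum(inp$xP * (log(inp$lP) + state$ElnoP) - inp$lP * state$EoP)
  xE_obs <- sum(inp$xE * (log(inp$lE) + state$ElnoE) - inp$lE * state$EoE)

  v_pri <- sum(av * (log(av) - log(s_eff)) - lgamma(av) - av * state$ElnoP +
                 (av - 1) * state$Elnv - (av / s_eff) * state$EioP * state$Ev)
  w_pri <- sum(aw * (log(aw) - log(lE_prior)) - lgamma(aw) -
                 aw * state$ElnoE +
                 (aw - 1) * state$Elnw - (aw / lE_prior) * state$EioE * state$Ew)
  oP_pri <- sum(ao * log(bo) - lgamma(ao) + (ao - 1) * state$ElnoP -
                  bo * state$EoP)
  oE_pri <- sum(ao * log(bo) - lgamma(ao) + (ao - 1) * state$ElnoE -
                  bo * state$EoE)
  k_pri <- akh * log(bkh) - lgamma(akh) + (akh - 1) * state$Elnk -
    bkh * state$Ek

  ent <- sum(gamma_entropy(state$av, state$bv)) +
    sum(gamma_entropy(state$aw, state$bw)) +
    gamma_entropy(state$ak, state$bk) +
    sum(gig_entropy(state$lamP, state$chiP, state$psiP,
                    list(mean = state$EoP, inv_mean = state$EioP,
                         mean_log = state$ElnoP))) +
    sum(gig_entropy(state$lamE, state$chiE, state$psiE,
                    list(mean = state$EoE, inv_mean = state$EioE,
                         mean_log = state$ElnoE)))

  terms <- c(t_obs = t_obs, xP_obs = xP_obs, xE_obs = xE_obs, v_pri = v_pri,
             w_pri = w_pri, oP_pri = oP_pri, oE_pri = oE_pri, k_pri = k_pri,
             entropy = ent)
  if (any(!is.finite(terms)))
    stop("non-finite ELBO term: ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "))
  sum(terms)
}

## --- main loop ------------------------------------------------------------

#' Run mean-field variational inference
#'
#' Repeats coordinate-ascent sweeps in the order rho, w, v, oE, oP, k
#' (cached expectations refreshed immediately after each family) until the
#' largest relative change of any posterior-mean enhancer activity drops
#' below `tol`, or `max_iter` sweeps.  Fully deterministic.
#'
#' @param inp an `inference_input` from [assemble_inference_input()].
#' @param hyper [hyperparameters()].
#' @param tol convergence tolerance on `max_r |dE[w_r]| / E[w_r]`
#'   (default 5e-3).
#' @param max_iter maximum number of sweeps (default 500).
#' @param elbo if `TRUE` (default), record the lower bound after every sweep
#'   in `elbo_trace`.
#' @param verbose print one line per sweep to stderr.
#' @return converged `inference_state`.
#' @export
run_inference <- function(inp, hyper = hyperparameters(), tol = 5e-3,
                          max_iter = 500, elbo = TRUE, verbose = FALSE) {
  stopifnot(inherits(inp, "inference_input"))
  state <- init_state(inp, hyper)
  for (it in seq_len(max_iter)) {
    ew_old <- state$Ew
    state <- update_rho(state, inp)
    state <- update_q_w(state, inp, hyper)
    state <- update_q_v(state, inp, hyper)
    state <- update_q_oE(state, inp, hyper, need_mean_log = elbo)
    state <- update_q_oP(state, inp, hyper, need_mean_log = elbo)
    state <- update_q_k(state, inp, hyper)
    state$iteration <- it
    rel <- abs(state$Ew - ew_old) / pmax(ew_old, 1e-12)
    state$max_rel_dw <- max(rel)
    if (elbo) {
      state$elbo_trace <- c(state$elbo_trace, compute_elbo(state, inp, hyper))
      if (verbose)
        message(sprintf("sweep %d  elbo %.6f  max_rel_dw %.3e", it,
                        state$elbo_trace[it], state$max_rel_dw))
    } else if (verbose) {
      message(sprintf("sweep %d  max_rel_dw %.3e", it, state$max_rel_dw))
    }
    if (state$max_rel_dw < tol) {
      state$converged <- TRUE
      break
    }
  }
  state
}

#' Derived quantities of a fitted state
#'
#' Point estimates and bursting decomposition: promoter activity `v`
#' (proportional to burst size), the contact-weighted activity sum
#' (proportional to burst frequency), and fitted expression
#' `y = E[k] v_g sum_r c_gr E[w_r]`.
#'
#' @param state fitted `inference_state`.
#' @param inp the matching `inference_input`.
#' @return data.frame per gene: `gene_id`, `v`, `burst_frequency`, `y`.
#' @export
fitted_expression <- function(state, inp) {
  Sw <- row_sum(inp, inp$c * state$Ew[inp$ci_elem])
  data.frame(gene_id = inp$gene_id, v = state$Ev, burst_frequency = Sw,
             y = state$Ek * state$Ev * Sw, stringsAsFactors = FALSE)
}
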