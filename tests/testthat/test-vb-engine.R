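# Variational engine: update arithmetic, ELBO behaviour, convergence,
# determinism, variants.

test_that("rho allocation is a normalized softmax over contacts", {
  inp <- toy_input(t = 10, xP = 5, xE = c(5, 5),
                   cmat = matrix(c(1, 1), 1, 2))
  st <- init_state(inp, hyperparameters())
  st$Elnw <- c(0, 0)
  st <- update_rho(st, inp)
  expect_equal(st$rho, c(0.5, 0.5))

  inp2 <- toy_input(t = 10, xP = 5, xE = c(5, 5),
                    cmat = matrix(c(2, 1), 1, 2))
  st2 <- init_state(inp2, hyperparameters())
  st2$Elnw <- c(0, 0)
  st2 <- update_rho(st2, inp2)
  expect_equal(st2$rho, c(2 / 3, 1 / 3))

  # extreme log activities: log-sum-exp contract, no overflow
  st2$Elnw <- c(700, -700)
  st2 <- update_rho(st2, inp2)
  expect_true(all(is.finite(st2$rho)))
  expect_equal(sum(st2$rho), 1, tolerance = 1e-12)

  # normalization on a larger random instance
  set.seed(4)
  cm <- matrix(runif(60) * (runif(60) < 0.7), 6, 10)
  cm[, 1] <- pmax(cm[, 1], 0.1) # no empty rows
  inp3 <- toy_input(t = rpois(6, 50), xP = rpois(6, 50), xE = rpois(10, 50),
                    cmat = cm)
  st3 <- init_state(inp3, hyperparameters())
  st3 <- update_rho(st3, inp3)
  rs <- rowsum(st3$rho, inp3$ci_gene)
  expect_equal(as.numeric(rs), rep(1, 6), tolerance = 1e-12)
})

test_that("posterior-shape updates follow the coordinate-ascent formulas", {
  hy <- hyperparameters() # alpha_v = 80, alpha_w = 10, alpha_o = 1
  inp <- toy_input(t = c(100, 0), xP = c(200, 3), xE = c(50, 0, 10),
                   cmat = matrix(c(1, 0.5, 2, 0, 0.25, 0), 2, 3),
                   lE = c(1, 0.5, 2), lP = c(1, 1))
  st <- init_state(inp, hy)
  st <- update_rho(st, inp)
  st <- update_q_w(st, inp, hy)
  st <- update_q_v(st, inp, hy)
  st <- update_q_oE(st, inp, hy)
  st <- update_q_oP(st, inp, hy)
  st <- update_q_k(st, inp, hy)

  expect_equal(st$av, c(80 + 100, 80 + 0))
  expect_equal(st$lamP, 1 - 80 + c(200, 3))
  expect_equal(st$psiP, rep(2 * 1e-3 + 2, 2))
  expect_equal(st$lamE, 1 - 10 + c(50, 0, 10))
  expect_true(st$lamE[2] == -9) # negative order is a valid GIG
  expect_equal(st$psiE, 2e-3 + 2 * inp$lE)
  expect_true(all(st$chiP > 0) && all(st$chiE > 0))
  expect_equal(st$ak, 1 + 100)
  # aw = alpha_w + sum_g t_g rho
  expect_equal(as.numeric(rowsum(inp$t[inp$ci_gene] * st$rho, inp$ci_elem)),
               st$aw[unique(inp$ci_elem)] - 10)

  # element contacted by no gene: pure prior
  cm <- matrix(c(1, 0), 1, 2)
  inp0 <- toy_input(t = 50, xP = 5, xE = c(5, 7), cmat = cm)
  # (the zero-contact element is dropped at assembly; emulate via direct
  #  manipulation: keep it by adding a tiny contact then zero rho weight)
  expect_equal(length(inp0$xE), 1)

  # single gene, rho = 1, t = 50: aw = 60
  inp1 <- toy_input(t = 50, xP = 5, xE = 8, cmat = matrix(1, 1, 1))
  s1 <- init_state(inp1, hy)
  s1 <- update_rho(s1, inp1)
  expect_equal(s1$rho, 1)
  s1 <- update_q_w(s1, inp1, hy)
  expect_equal(s1$aw, 60)
})

test_that("bv scales linearly in the contact row", {
  hy <- hyperparameters()
  inp <- toy_input(t = 100, xP = 50, xE = c(5, 9),
                   cmat = matrix(c(1, 2), 1, 2))
  inp2 <- inp
  inp2$c <- inp$c * 2
  st <- init_state(inp, hy)
  st2 <- init_state(inp2, hy)
  st2[c("Ew", "Elnw", "EioP", "Ek")] <- st[c("Ew", "Elnw", "EioP", "Ek")]
  a <- update_q_v(st, inp, hy)
  b <- update_q_v(st2, inp2, hy)
  prior_term <- (hy$alpha_v / inp$s) * st$EioP
  expect_equal(b$bv - prior_term, 2 * (a$bv - prior_term))
})

test_that("variant flags rewrite only the prior terms", {
  t <- c(60, 80); xP <- c(30, 40); xE <- c(20, 30, 10)
  cm <- matrix(c(1, 0.5, 0.2, 1, 0.3, 0.7), 2, 3)
  lE <- c(0.5, 2, 1)
  s <- c(2, 0.5)
  mk <- function(variant) {
    hy <- hyperparameters(variant = variant)
    inp <- toy_input(t, xP, xE, cm, lE = lE, s = s)
    st <- init_state(inp, hy)
    st <- update_rho(st, inp)
    st <- update_q_w(st, inp, hy)
    st <- update_q_oE(st, inp, hy)
    st <- update_q_oP(st, inp, hy)
    list(st = st, inp = inp, hy = hy)
  }
  std <- mk("standard")
  nle <- mk("no_lE")
  nsg <- mk("no_sg")

  # no_lE: chiE loses the division by lE; with lE = 0.5 the standard chi is
  # twice the variant's (same Ew enters both only approximately, so compare
  # the formulas at matched Ew)
  expect_equal(std$st$chiE, 2 * 10 * std$st$Ew / lE)
  expect_equal(nle$st$chiE, 2 * 10 * nle$st$Ew)
  # psiE keeps the observation-model lE in both variants
  expect_equal(nle$st$psiE, std$st$psiE)
  # no_sg: promoter prior uses s = 1
  expect_equal(nsg$st$chiP, 2 * 80 * nsg$st$Ev)
  expect_equal(std$st$chiP, 2 * 80 * std$st$Ev / s)
})

test_that("ak is data-determined and E[k] is inverse to the contact scale", {
  ds <- fixture("tiny")
  hy <- hyperparameters(beta_k = 1e-9)
  st <- run_inference(ds$input, hy, elbo = FALSE)
  inp10 <- ds$input
  inp10$c <- inp10$c * 10
  st10 <- run_inference(inp10, hy, elbo = FALSE)
  expect_equal(st10$ak, st$ak) # depends only on the data
  expect_equal(st$Ek / st10$Ek, 10, tolerance = 1e-3)
})

test_that("the ELBO increases along sweeps and is optimal in rho", {
  ds <- fixture("tiny")
  st <- fitted_fixture("tiny")
  tr <- st$elbo_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))

  # perturbing rho away from the softmax optimum lowers the bound
  hy <- hyperparameters()
  base <- compute_elbo(st, ds$input, hy)
  pert <- st
  set.seed(9)
  noise <- exp(0.3 * rnorm(length(pert$rho)))
  pert$rho <- pert$rho * noise
  den <- rowsum(pert$rho, ds$input$ci_gene)
  pert$rho <- pert$rho / den[ds$input$ci_gene]
  expect_lt(compute_elbo(pert, ds$input, hy), base)
})

test_that("converged ELBO matches a quadrature oracle on a 1x1 toy", {
  hy <- hyperparameters()
  inp <- toy_input(t = 30, xP = 20, xE = 15, cmat = matrix(0.5, 1, 1),
                   lT = 2, s = 1.5, lP = 0.8, lE = 1.2)
  st <- run_inference(inp, hy, tol = 1e-10, max_iter = 200)
  got <- compute_elbo(st, inp, hy)

  # independent evaluation: E over q(v) q(w) of all v/w-dependent bound
  # terms by nested quadrature, plus the remaining terms assembled from
  # quadrature-based GIG quantities
  av <- hy$alpha_v; aw <- hy$alpha_w
  gp <- oracle_gig(st$lamP, st$chiP, st$psiP)
  ge <- oracle_gig(st$lamE, st$chiE, st$psiE)
  A <- function(v, w) {
    inp$t * (log(inp$lT) + st$Elnk + log(v) + log(w) + log(inp$c)) -
      st$Ek * inp$lT * inp$c * v * w +
      av * (log(av) - log(inp$s)) - lgamma(av) - av * gp$mean_log +
      (av - 1) * log(v) - (av / inp$s) * gp$inv_mean * v +
      aw * (log(aw) - log(inp$lE)) - lgamma(aw) - aw * ge$mean_log +
      (aw - 1) * log(w) - (aw / inp$lE) * ge$inv_mean * w -
      dgamma(v, st$av, st$bv, log = TRUE) -
      dgamma(w, st$aw, st$bw, log = TRUE)
  }
  inner <- function(v) {
    vapply(v, function(vi) integrate(
      function(w) A(vi, w) * dgamma(w, st$aw, st$bw),
      0, Inf, rel.tol = 1e-10)$value, numeric(1))
  }
  Evw <- integrate(function(v) inner(v) * dgamma(v, st$av, st$bv),
                   0, Inf, rel.tol = 1e-9)$value
  gig_H <- function(q, lam, chi, psi)
    q$log_norm - (lam - 1) * q$mean_log +
      0.5 * (chi * q$inv_mean + psi * q$mean)
  rest <- inp$xP * (log(inp$lP) + gp$mean_log) - inp$lP * gp$mean +
    inp$xE * (log(inp$lE) + ge$mean_log) - inp$lE * ge$mean +
    2 * (hy$alpha_o * log(hy$beta_o) - lgamma(hy$alpha_o)) +
    (hy$alpha_o - 1) * (gp$mean_log + ge$mean_log) -
    hy$beta_o * (gp$mean + ge$mean) +
    hy$alpha_k * log(hy$beta_k) - lgamma(hy$alpha_k) +
    (hy$alpha_k - 1) * st$Elnk - hy$beta_k * st$Ek +
    st$ak - log(st$bk) + lgamma(st$ak) + (1 - st$ak) * digamma(st$ak) +
    gig_H(gp, st$lamP, st$chiP, st$psiP) +
    gig_H(ge, st$lamE, st$chiE, st$psiE)
  expect_equal(got, Evw + rest, tolerance = 1e-4)
})

test_that("inference is deterministic, stable at its fixed point, and
           exchangeable under element permutation", {
  ds <- fixture("tiny")
  s1 <- run_inference(ds$input)
  s2 <- run_inference(ds$input)
  expect_identical(s1, s2)
  expect_true(s1$converged)
  expect_lt(s1$iteration, 500)

  # one more sweep from the fixed point moves E[w] by < tol
  hy <- hyperparameters()
  st <- s1
  ew <- st$Ew
  st <- update_rho(st, ds$input)
  st <- update_q_w(st, ds$input, hy)
  expect_lt(max(abs(st$Ew - ew) / ew), 5e-3)

  # permuting elements permutes outputs identically
  inp <- ds$input
  set.seed(12)
  perm <- sample(length(inp$xE))
  pinp <- inp
  pinp$element_id <- inp$element_id[perm]
  pinp$xE <- inp$xE[perm]
  pinp$lE <- inp$lE[perm]
  pinp$ci_elem <- order(perm)[inp$ci_elem] # new position of each element
  pinp <- enhact:::validate_inference_input(pinp)
  sp <- run_inference(pinp)
  expect_equal(sp$Ew[match(inp$element_id, pinp$element_id)], s1$Ew,
               tolerance = 1e-12)
})

test_that("input validation enforces the model contracts", {
  expect_error(toy_input(t = -1, xP = 1, xE = 1, cmat = matrix(1, 1, 1)),
               "non-negative")
  expect_error(toy_input(t = 1, xP = 1, xE = 1, cmat = matrix(1, 1, 1),
                         lT = 0), "positive")
  # a gene whose contacts all vanish is rejected at assembly
  expr <- data.frame(gene_id = c("g1", "g2"), read_count = c(5, 5),
                     effective_length_kb = 1)
  prom <- data.frame(gene_id = c("g1", "g2"), length_kb = 1, read_count = 5,
                     constituent_ids = "")
  elem <- data.frame(element_id = "e1", chrom = "c", start = 0, end = 500,
                     length_kb = 0.5, read_count = 5)
  contacts <- data.frame(gene_id = "g1", element_id = "e1", contact = 1)
  expect_message(
    inp <- assemble_inference_input(expr, prom, elem, contacts),
    "dropped")
  expect_equal(inp$gene_id, "g1")
})
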