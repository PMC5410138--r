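test_that("forward and Viterbi agree with exhaustive path enumeration", {
  set.seed(20)
  cases <- 0L
  for (rep in 1:25) {
    M <- sample(1:3, 1)
    model <- rand_model(M, seed = 100 + rep)
    for (L in 1:4) {
      pep <- paste(sample(c(famscan:::AA_ALPHABET, "X"), L, TRUE,
                          prob = c(rep(1, 20), 2)), collapse = "")
      or <- oracle_scores(model, pep)
      expect_equal(forward_score(model, pep), or$forward, tolerance = 1e-9)
      expect_equal(viterbi_align(model, pep)$score, or$viterbi,
                   tolerance = 1e-9)
      cases <- cases + 1L
    }
  }
  expect_gte(cases, 100L)
})

test_that("forward dominates Viterbi and X-only peptides carry no signal", {
  m <- toy_model()
  set.seed(21)
  for (i in 1:20) {
    pep <- paste(sample(famscan:::AA_ALPHABET, sample(10:120, 1), TRUE),
                 collapse = "")
    expect_gte(forward_score(m, pep), viterbi_align(m, pep)$score)
  }
  for (L in c(1, 10, 200))
    expect_lte(forward_score(m, strrep("X", L)), 0)
})

test_that("the Viterbi path re-scores to the Viterbi score", {
  m <- toy_model()
  fam <- attr(m, "family")
  rescore <- function(model, pep, v) {
    code <- match(strsplit(pep, "")[[1]], model$alphabet)
    M <- model$M
    lo <- function(k, t, emit) if (is.na(code[t])) 0 else
      log(emit[k, code[t]] / model$background[code[t]])
    p <- v$path
    lw <- -log(nchar(pep) * M) + if (p[1, "state"] == 1)
      lo(p[1, "model_pos"], p[1, "pep_pos"], model$match_emit) else
        stop("path must enter at a match state")
    for (i in seq_len(nrow(p))[-1]) {
      a <- p[i - 1, ]; b <- p[i, ]
      type <- paste0(c("M", "I", "D")[a["state"]], c("M", "I", "D")[b["state"]])
      lt <- log(model$trans[a["model_pos"] + 1L, type])
      # core moves out of a match state are rescaled for the local exit
      if (a["state"] == 1)
        lt <- lt + log((M - a["model_pos"]) / (M - a["model_pos"] + 1))
      lw <- lw + lt
      if (b["state"] == 1) lw <- lw + lo(b["model_pos"], b["pep_pos"],
                                         model$match_emit)
      if (b["state"] == 2) lw <- lw + lo(b["model_pos"] + 1, b["pep_pos"],
                                         model$insert_emit)
    }
    last <- p[nrow(p), ]
    stopifnot(last["state"] == 1)
    (lw - log(M - last["model_pos"] + 1)) / log(2)
  }
  set.seed(22)
  for (i in 1:5) {
    pep <- diverge(fam$residues[i], 0.3, seed = 30 + i)
    v <- viterbi_align(m, pep)
    expect_equal(unname(rescore(m, pep, v)), v$score, tolerance = 1e-9)
    expect_lte(v$ali_end, nchar(pep))
    expect_gte(v$ali_start, 1)
    v2 <- viterbi_align(m, pep)
    expect_identical(v, v2)
  }
})

test_that("Gumbel E-values follow the closed form and its limits", {
  g <- gumbel_params(mu = 3, lambda = 0.7, n_calibration = 200)
  expect_equal(evalue_of(3, g, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(evalue_of(3, g, 500) / evalue_of(3, g, 1), 500)
  # strictly decreasing away from the saturation plateau at E ~ Z
  s <- seq(0, 400, by = 5)
  e <- evalue_of(s, g, 1000)
  expect_true(all(diff(e) < 0))
  expect_true(all(e > 0))
  # deep underflow still yields a positive E-value
  expect_lt(evalue_of(1e4, g, 1e6), 1e-300)
  expect_gt(evalue_of(1e4, g, 1e6), 0)
})

test_that("calibration is reproducible and matches Gumbel moments", {
  m0 <- toy_model()
  m1 <- calibrate_profile(m0, n_random = 400, length_mean = 60, seed = 77)
  m2 <- calibrate_profile(m0, n_random = 400, length_mean = 60, seed = 77)
  expect_identical(m1$calibration, m2$calibration)

  # full-sample ML fit reproduces the observed mean through the Gumbel
  # moment identity E[S] = mu + gamma / lambda
  scores <- forward_score(m0, famscan:::with_seed(
    77, famscan:::random_peptides(400, m0$background, 60, 4)))
  g <- gumbel_fit(scores, tail_fraction = 1)
  gumbel_mean <- g$mu + 0.57721566 / g$lambda
  se <- stats::sd(scores) / sqrt(length(scores))
  expect_lt(abs(gumbel_mean - mean(scores)), 3 * se)

  expect_error(gumbel_fit(rep(1, 200)), "degenerate")
})

test_that("the full-ML mu standard error shrinks roughly as 1/sqrt(n)", {
  m0 <- toy_model()
  mus <- function(n) vapply(1:8, function(s) {
    sc <- forward_score(m0, famscan:::with_seed(
      1000 + s, famscan:::random_peptides(n, m0$background, 40, 4)))
    gumbel_fit(sc, tail_fraction = 1)$mu
  }, numeric(1))
  ratio <- stats::sd(mus(150)) / stats::sd(mus(600))
  expect_gt(ratio, 1.1)   # ideal 2, allow wide stochastic slack
  expect_lt(ratio, 4)
})

test_that("search retains hits at or below the cutoff, sorted by E-value", {
  m <- toy_model()
  fam <- attr(m, "family")
  targets <- c(diverge(fam$residues[1], 0.25, seed = 3),
               diverge(fam$residues[2], 0.35, seed = 4),
               famscan:::with_seed(5, famscan:::random_peptides(
                 48, m$background, 60, 4)))
  names(targets) <- sprintf("t%02d", seq_along(targets))
  sc <- forward_score(m, targets)
  ev <- evalue_of(sc, m$calibration, length(targets))
  # boundary inclusive: cutoff equal to an observed E-value keeps that hit
  cut <- sort(ev)[2]
  hits <- profile_search(m, targets, search_config(evalue_cutoff = cut))
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$evalue <= cut))
  expect_equal(hits$evalue, sort(hits$evalue))
  # shrinking cutoff shrinks the hit list monotonically
  ns <- vapply(10^seq(-2, -40, by = -6), function(ct)
    nrow(profile_search(m, targets, search_config(evalue_cutoff = ct))),
    numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_equal(nrow(profile_search(m, character(0), search_config())), 0L)
})

test_that("homologs are detected and background decoys are not", {
  m <- toy_model(len = 120)
  fam <- attr(m, "family")
  homs <- vapply(1:20, function(i)
    diverge(attr(fam, "ancestor"), 0.4, seed = 500 + i), character(1))
  ev_h <- evalue_of(forward_score(m, homs), m$calibration, 10000)
  expect_true(all(ev_h <= 1e-5))
  decoys <- famscan:::with_seed(42, famscan:::random_peptides(
    3000, m$background, 60, 4))
  ev_d <- evalue_of(forward_score(m, decoys), m$calibration, 3000)
  expect_equal(sum(ev_d <= 1e-5), 0L)
  # in the calibrated tail region, E-values are roughly uniform: about a
  # fraction t of decoys fall at or below E = t * Z
  expect_gt(mean(ev_d <= 0.1 * 3000), 0.04)
  expect_lt(mean(ev_d <= 0.1 * 3000), 0.25)
})
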