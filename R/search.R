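# Log-odds scoring parameters shared by the forward and Viterbi kernels.
# Match/insert emissions become log-odds against the background (column 21
# is the unknown residue X, score-neutral); core transitions out of match
# state k are rescaled by (1 - 1/(M-k+1)) to fund the uniform local exit.
scoring_params <- function(model) {
  M <- model$M
  bg <- model$background
  lom <- cbind(log(model$match_emit / rep(bg, each = M)), 0)
  nI <- max(M - 1L, 0L)
  loi <- if (nI > 0)
    cbind(log(model$insert_emit[1L + seq_len(nI), , drop = FALSE] /
                rep(bg, each = nI)), 0)
  else matrix(0, 0, 21)
  tr <- model$trans
  k <- seq_len(nI)                          # core rows k = 1..M-1
  scale <- log((M - k) / (M - k + 1))
  list(lom = lom, loi = loi,
       lMM = log(tr[k + 1L, "MM"]) + scale,
       lMI = log(tr[k + 1L, "MI"]) + scale,
       lMD = log(tr[k + 1L, "MD"]) + scale,
       lIM = log(tr[k + 1L, "IM"]), lII = log(tr[k + 1L, "II"]),
       lDM = log(tr[k + 1L, "DM"]), lDD = log(tr[k + 1L, "DD"]),
       lexit = -log(M - seq_len(M) + 1))
}

# Encode peptides as 0-based integer codes; X and anything unknown -> 20.
encode_peptides <- function(peptides) {
  lapply(strsplit(peptides, ""), function(ch) {
    v <- match(ch, AA_ALPHABET)
    v[is.na(v)] <- 21L
    as.integer(v - 1L)
  })
}

#' Forward bit score of a peptide against a profile
#'
#' Log2 of the ratio between the summed probability of all local
#' alignments of the profile to the peptide and the i.i.d. background
#' null.  Entry is uniform over start positions and match states, exit
#' uniform over remaining positions; flanking residues are emitted by the
#' background and cancel against the null.
#'
#' @param model a `profile_hmm`.
#' @param peptide a character string over the amino-acid alphabet (X is
#'   score-neutral), or a character vector for several peptides.
#' @return numeric vector of bit scores.
#' @export
forward_score <- function(model, peptide) {
  if (any(!nzchar(peptide))) stop("empty peptide")
  sp <- scoring_params(model)
  .fwd_batch_cpp(encode_peptides(peptide), sp$lom, sp$loi, sp$lMM, sp$lMI,
                 sp$lMD, sp$lIM, sp$lII, sp$lDM, sp$lDD, sp$lexit) / log(2)
}

#' Viterbi local alignment of a peptide against a profile
#'
#' @inheritParams forward_score
#' @param peptide a single peptide string.
#' @return list with `score` (bits), `path` (matrix with columns `state`
#'   (1 = match, 2 = insert, 3 = delete), `model_pos`, `pep_pos`; deletes
#'   have `pep_pos = 0`), and `ali_start`/`ali_end` (1-based inclusive
#'   peptide coordinates of the aligned region).
#' @export
viterbi_align <- function(model, peptide) {
  stopifnot(length(peptide) == 1L)
  if (!nzchar(peptide)) stop("empty peptide")
  sp <- scoring_params(model)
  res <- .vit_align_cpp(encode_peptides(peptide)[[1L]], sp$lom, sp$loi,
                        sp$lMM, sp$lMI, sp$lMD, sp$lIM, sp$lII, sp$lDM,
                        sp$lDD, sp$lexit)
  res$score <- res$score / log(2)
  res
}

#' Gumbel calibration parameters
#'
#' @param mu location (bits).
#' @param lambda scale (per bit), > 0.
#' @param n_calibration number of random calibration sequences (>= 100).
#' @param seed RNG seed used for calibration.
#' @return a `gumbel_params` list.
#' @export
gumbel_params <- function(mu, lambda, n_calibration, seed = NA_integer_) {
  stopifnot(is.finite(mu), lambda > 0, n_calibration >= 100)
  structure(list(mu = mu, lambda = lambda,
                 n_calibration = as.integer(n_calibration),
                 seed = seed), class = "gumbel_params")
}

#' Gumbel fit of a score distribution
#'
#' E-values only depend on the upper tail of the random-score law, and the
#' forward-score tail decays more slowly than a whole-sample Gumbel fit
#' suggests, so the default fits the Gumbel's (asymptotically exponential)
#' tail to the exceedances above the `1 - tail_fraction` quantile by
#' maximum likelihood: `lambda = 1 / mean(excess)` and the location chosen
#' so the fitted law reproduces the observed exceedance fraction.  With
#' `tail_fraction = 1` the classical full-sample Gumbel ML fit is used
#' (lambda from the profile-likelihood equation via [uniroot()]).
#'
#' @param scores numeric vector of bit scores.
#' @param pin_lambda fix lambda at `log(2)` instead of fitting it.
#' @param tail_fraction upper-tail mass used for fitting, in (0, 1];
#'   default 0.02.
#' @return list with `mu` and `lambda`.
#' @export
gumbel_fit <- function(scores, pin_lambda = FALSE, tail_fraction = 0.02) {
  x <- scores[is.finite(scores)]
  if (length(x) < 10L || stats::sd(x) == 0)
    stop("calibration error: degenerate score distribution")
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  if (tail_fraction < 1) {
    k <- max(10L, as.integer(ceiling(tail_fraction * length(x))))
    if (k + 1L > length(x))
      stop("calibration error: too few scores for a tail fit")
    xs <- sort(x, decreasing = TRUE)
    s0 <- xs[k + 1L]
    excess <- xs[seq_len(k)] - s0
    if (mean(excess) == 0)
      stop("calibration error: degenerate score distribution")
    lambda <- if (pin_lambda) log(2) else 1 / mean(excess)
    mu <- s0 + log(k / length(x)) / lambda
    return(list(mu = mu, lambda = lambda))
  }
  y <- x - min(x)                 # keeps exp(-lambda * y) in (0, 1]
  if (pin_lambda) {
    lambda <- log(2)
  } else {
    f <- function(l) {
      w <- exp(-l * y)
      1 / l - mean(x) + sum(x * w) / sum(w)
    }
    lambda <- uniroot(f, lower = 1e-4, upper = 500, tol = 1e-10)$root
  }
  mu <- min(x) - log(mean(exp(-lambda * y))) / lambda
  list(mu = mu, lambda = lambda)
}

#' Calibrate a profile for E-value computation
#'
#' Scores `n_random` i.i.d. background-generated peptides (lengths drawn
#' from a gamma distribution with the given mean and shape, floored at 5)
#' and fits a Gumbel law to the score distribution with [gumbel_fit()]
#' (upper-tail fit by default).  Calibration accuracy in the deep tail
#' improves with `n_random`; 10,000 is a good choice when E-values near
#' 1e-5 must be trusted, the default is a compromise for interactive use.
#'
#' @param model a `profile_hmm`.
#' @param n_random number of random peptides (>= 100; default 2000).
#' @param length_mean,length_shape mean and gamma shape of the calibration
#'   peptide length distribution; match these to the lengths of the
#'   segments you will search.
#' @param seed RNG seed; calibration is reproducible given the seed.
#' @param score_kind `"forward"` (default) or `"viterbi"`.
#' @param pin_lambda,tail_fraction see [gumbel_fit()].
#' @return the model with its `calibration` field set.
#' @export
calibrate_profile <- function(model, n_random = 2000L, length_mean = 100,
                              length_shape = 4, seed = 1L,
                              score_kind = c("forward", "viterbi"),
                              pin_lambda = FALSE, tail_fraction = 0.02) {
  score_kind <- match.arg(score_kind)
  stopifnot(n_random >= 100L)
  peps <- with_seed(seed, random_peptides(n_random, model$background,
                                          length_mean, length_shape))
  scores <- if (score_kind == "forward") forward_score(model, peps)
  else vapply(peps, function(p) viterbi_align(model, p)$score, numeric(1))
  fit <- gumbel_fit(scores, pin_lambda, tail_fraction)
  model$calibration <- gumbel_params(fit$mu, fit$lambda, n_random, seed)
  model
}

# i.i.d. background peptides with gamma-distributed lengths (min 5).
random_peptides <- function(n, background, length_mean = 100,
                            length_shape = 4) {
  lens <- pmax(5L, as.integer(round(
    rgamma(n, shape = length_shape, rate = length_shape / length_mean))))
  vapply(lens, function(L) paste(
    sample(AA_ALPHABET, L, replace = TRUE, prob = background),
    collapse = ""), character(1))
}

#' E-value of a bit score
#'
#' `E = Z * (1 - exp(-exp(-lambda * (score - mu))))`, the expected number
#' of equal-or-better scores among Z random target segments.  Strictly
#' decreasing in the score and proportional to Z.  Values that would
#' underflow to zero are floored at 1e-320 so E-values stay positive.
#'
#' @param score bit score(s).
#' @param gumbel a [gumbel_params()].
#' @param Z effective database size (number of segments searched).
#' @return positive E-value(s).
#' @export
evalue_of <- function(score, gumbel, Z) {
  if (is.null(gumbel)) stop("model is not calibrated")
  stopifnot(Z >= 1)
  u <- exp(-gumbel$lambda * (score - gumbel$mu))
  e <- Z * ifelse(u < 1e-12, u, -expm1(-u))   # tail-accurate form
  pmax(e, 1e-320)
}

#' Search configuration
#'
#' @param evalue_cutoff retain hits with E-value at or below this
#'   (inclusive); default 1e-5.
#' @param Z effective database size; `NULL` (default) uses the number of
#'   segments actually searched, mimicking per-sample search runs.  Set a
#'   fixed value for cross-sample comparability.
#' @param score_kind `"forward"` (default) or `"viterbi"`.
#' @param seed seed for any calibration performed downstream.
#' @param min_peptide_len minimum translated segment length, in residues,
#'   passed to [six_frame_translate()] when nucleotide input is screened.
#' @return a `search_config` list.
#' @export
search_config <- function(evalue_cutoff = 1e-5, Z = NULL,
                          score_kind = c("forward", "viterbi"), seed = 1L,
                          min_peptide_len = 20L) {
  stopifnot(evalue_cutoff > 0, is.null(Z) || Z >= 1)
  structure(list(evalue_cutoff = evalue_cutoff, Z = Z,
                 score_kind = match.arg(score_kind), seed = seed,
                 min_peptide_len = as.integer(min_peptide_len)),
            class = "search_config")
}

#' Search peptides or translated segments with a calibrated profile
#'
#' Each target contributes its best-scoring local alignment; candidates
#' with E-value at or below the cutoff (inclusive, matching a significance
#' rule of E <= 1e-5) are retained and sorted by ascending E-value.
#'
#' @param model a calibrated `profile_hmm`.
#' @param targets a character vector of peptides, a protein sequence set
#'   (columns `id`, `residues`), or a translated-segment table from
#'   [six_frame_translate()] (provenance columns are copied into the hits).
#' @param config a [search_config()].
#' @return a hit `data.frame` with columns `model_name`, `target_id`,
#'   `bit_score`, `evalue`, `ali_start`, `ali_end`, `contig_id`, `frame`,
#'   `nt_start`, `nt_end`.
#' @export
profile_search <- function(model, targets, config = search_config()) {
  if (is.null(model$calibration)) stop("model is not calibrated")
  if (is.data.frame(targets) && "peptide" %in% names(targets)) {
    peptides <- targets$peptide
    ids <- targets$target_id %||% sprintf("target%d", seq_along(peptides))
    prov <- data.frame(contig_id = targets$contig_id %||% NA_character_,
                       frame = targets$frame %||% NA_integer_,
                       nt_start = targets$nt_start %||% NA_integer_,
                       nt_end = targets$nt_end %||% NA_integer_)
  } else if (is.data.frame(targets)) {
    peptides <- targets$residues
    ids <- targets$id
    prov <- NULL
  } else {
    peptides <- as.character(targets)
    ids <- names(targets) %||% sprintf("target%d", seq_along(peptides))
    prov <- NULL
  }
  if (length(peptides) == 0L) return(empty_hits(model$name))
  if (is.null(prov))
    prov <- data.frame(contig_id = rep(NA_character_, length(peptides)),
                       frame = NA_integer_, nt_start = NA_integer_,
                       nt_end = NA_integer_)
  scores <- if (config$score_kind == "forward")
    forward_score(model, peptides)
  else vapply(peptides, function(p) viterbi_align(model, p)$score,
              numeric(1), USE.NAMES = FALSE)
  Z <- config$Z %||% length(peptides)
  ev <- evalue_of(scores, model$calibration, Z)
  keep <- which(ev <= config$evalue_cutoff)
  if (length(keep) == 0L) return(empty_hits(model$name))
  ali <- t(vapply(keep, function(i) {
    v <- viterbi_align(model, peptides[i])
    c(v$ali_start, v$ali_end)
  }, numeric(2)))
  hits <- data.frame(model_name = model$name, target_id = ids[keep],
                     bit_score = scores[keep], evalue = ev[keep],
                     ali_start = as.integer(ali[, 1L]),
                     ali_end = as.integer(ali[, 2L]),
                     prov[keep, , drop = FALSE], stringsAsFactors = FALSE)
  hits <- hits[order(hits$evalue, -hits$bit_score), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function(model_name = character(0)) {
  data.frame(model_name = character(0), target_id = character(0),
             bit_score = numeric(0), evalue = numeric(0),
             ali_start = integer(0), ali_end = integer(0),
             contig_id = character(0), frame = integer(0),
             nt_start = integer(0), nt_end = integer(0))
}
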