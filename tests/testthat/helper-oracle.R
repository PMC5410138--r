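# Independent oracles used by the tests.  These share no code with the
# package's dynamic programming or test statistics: scores come from
# exhaustive enumeration of every admissible local alignment path, and
# Wilcoxon p-values from full enumeration of rank assignments.

logsumexp <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Exhaustive path-sum / path-max scores (bits) for small models.
# Local model: entry into match state k at any residue with weight
# 1/(L*M); exit from match state k with probability 1/(M-k+1), core moves
# out of a match state rescaled by (M-k)/(M-k+1); match and insert
# emissions scored as log-odds against the background; delete states are
# silent; X residues are score-neutral.
oracle_scores <- function(model, peptide) {
  M <- model$M
  ch <- strsplit(peptide, "")[[1L]]
  code <- match(ch, model$alphabet)   # NA = X / unknown
  L <- length(ch)
  bg <- model$background
  lom <- function(k, t) if (is.na(code[t])) 0 else
    log(model$match_emit[k, code[t]] / bg[code[t]])
  loi <- function(k, t) if (is.na(code[t])) 0 else
    log(model$insert_emit[k + 1L, code[t]] / bg[code[t]])
  tr <- model$trans
  scale_k <- function(k) (M - k) / (M - k + 1)
  exit_k <- function(k) 1 / (M - k + 1)
  weights <- numeric(0)
  rec <- function(type, k, t, lw) {
    if (type == "M") {
      weights <<- c(weights, lw + log(exit_k(k)))
      if (k < M) {
        if (t < L) {
          rec("M", k + 1L, t + 1L,
              lw + log(scale_k(k) * tr[k + 1L, "MM"]) + lom(k + 1L, t + 1L))
          rec("I", k, t + 1L,
              lw + log(scale_k(k) * tr[k + 1L, "MI"]) + loi(k, t + 1L))
        }
        rec("D", k + 1L, t, lw + log(scale_k(k) * tr[k + 1L, "MD"]))
      }
    } else if (type == "I") {
      if (t < L) {
        rec("M", k + 1L, t + 1L,
            lw + log(tr[k + 1L, "IM"]) + lom(k + 1L, t + 1L))
        rec("I", k, t + 1L, lw + log(tr[k + 1L, "II"]) + loi(k, t + 1L))
      }
    } else {
      if (k < M) {
        if (t < L)
          rec("M", k + 1L, t + 1L,
              lw + log(tr[k + 1L, "DM"]) + lom(k + 1L, t + 1L))
        rec("D", k + 1L, t, lw + log(tr[k + 1L, "DD"]))
      }
    }
  }
  for (t0 in seq_len(L)) for (k0 in seq_len(M))
    rec("M", k0, t0, -log(L * M) + lom(k0, t0))
  list(forward = logsumexp(weights) / log(2),
       viterbi = max(weights) / log(2))
}

# Fully random valid profile (random stochastic rows, unlike the peaked
# random_profile generator).
rand_model <- function(M, seed) {
  famscan::new_profile_hmm(
    name = paste0("rand", seed),
    match_emit = with_rng(seed, rdirich(M, 20)),
    insert_emit = with_rng(seed + 1L, rdirich(M + 1L, 20)),
    trans = with_rng(seed + 2L, {
      tr <- cbind(rdirich(M + 1L, 3), rdirich(M + 1L, 2), rdirich(M + 1L, 2))
      colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
      tr[M + 1L, "MD"] <- 0
      tr[M + 1L, c("MM", "MI")] <- tr[M + 1L, c("MM", "MI")] /
        sum(tr[M + 1L, c("MM", "MI")])
      tr[M + 1L, c("DM", "DD")] <- c(1, 0)
      tr
    }),
    background = with_rng(seed + 3L, as.numeric(rdirich(1, 20))))
}

rdirich <- function(n, k) {
  m <- matrix(rgamma(n * k, shape = 2), n, k)
  m / rowSums(m)
}

with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Exact two-sided Wilcoxon rank-sum p-value by enumeration of all
# C(nx+ny, nx) rank assignments (tie-free data), mirroring the two-sided
# doubling rule of the standard test.
exact_wilcox_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  mid <- nx * ny / 2
  p <- if (u_obs > mid) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(p, 1)
}

# Convenience: small calibrated model built from a synthetic family.
toy_model <- function(fam_seed = 5, len = 90, n = 30, div = 0.2,
                      calib_seed = 11, n_random = 500) {
  fam <- make_family(n, length = len, divergence = div, seed = fam_seed)
  m <- build_profile(family_alignment(fam), name = "toyfam")
  m <- calibrate_profile(m, n_random = n_random, length_mean = 60,
                         seed = calib_seed)
  attr(m, "family") <- fam
  m
}
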