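#' Build a profile HMM from a multiple sequence alignment
#'
#' Constructs a Plan-7-style profile with one match state per match column
#' (weighted occupancy rule of [assign_match_columns()]).  Match emissions
#' are weighted residue counts with background-proportional pseudocounts of
#' total mass `pseudocount_alpha`; insert emissions equal the background;
#' transitions are weighted counts of the observed match/insert/delete
#' moves along each sequence, with a Laplace-style pseudocount of
#' `alpha / 7` per transition type.  All probabilities are strictly
#' positive except the structurally impossible moves out of the last model
#' position (M->D and D->D), which are exact zeros.
#'
#' @param msa a `multiple_alignment`; if its weights are still unit weights
#'   and `weighting = "henikoff"`, position-based weighting is applied
#'   first.
#' @param config a [build_config()].
#' @param name model name (default: `"profile"`).
#' @param weighting `"henikoff"` (default) corrects for redundant,
#'   phylogenetically clustered training sets; use `"none"` (unit weights)
#'   when the training sequences are independent draws, e.g. simulated
#'   samples, since redundancy weighting deliberately inflates rare
#'   residues and would bias the recovered emissions.
#' @return a `profile_hmm` object.
#' @export
build_profile <- function(msa, config = build_config(), name = "profile",
                          weighting = c("henikoff", "none")) {
  weighting <- match.arg(weighting)
  if (weighting == "henikoff" && all(msa$weights == 1))
    msa <- position_weights(msa)
  labels <- assign_match_columns(msa, config)
  mat <- msa$mat
  w <- msa$weights
  n_cols <- msa$n_cols
  match_cols <- which(labels == "match")
  M <- length(match_cols)

  bg <- profile_background(config$background, mat, w)
  alpha <- config$pseudocount_alpha

  # --- match emissions -----------------------------------------------------
  match_emit <- matrix(0, M, 20, dimnames = list(NULL, AA_ALPHABET))
  for (m in seq_len(M)) {
    col <- mat[, match_cols[m]]
    keep <- col %in% AA_ALPHABET
    cnt <- vapply(AA_ALPHABET, function(a) sum(w[keep][col[keep] == a]),
                  numeric(1))
    match_emit[m, ] <- (cnt + alpha * bg) / (sum(cnt) + alpha)
  }
  insert_emit <- matrix(rep(bg, each = M + 1L), M + 1L, 20,
                        dimnames = list(NULL, AA_ALPHABET))

  # --- transitions ---------------------------------------------------------
  # Column -> match index mapping: match column j is match state k(j);
  # insert columns attach to the preceding match state.
  midx <- cumsum(labels == "match")
  types <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  cnt <- matrix(alpha / 7, M + 1L, 7L, dimnames = list(NULL, types))
  for (i in seq_len(nrow(mat))) {
    st <- "M"; sk <- 0L                       # begin state acts as M_0
    for (j in seq_len(n_cols)) {
      ch <- mat[i, j]
      if (labels[j] == "match") {
        nt <- if (ch == "-") "D" else "M"; nk <- midx[j]
      } else {
        if (ch == "-") next
        nt <- "I"; nk <- midx[j]
      }
      tt <- paste0(st, nt)
      # Plan 7 has no I->D / D->I moves; such adjacencies are not counted.
      if (tt %in% types) cnt[sk + 1L, tt] <- cnt[sk + 1L, tt] + w[i]
      st <- nt; sk <- nk
    }
    tt <- paste0(st, "M")                     # exit to the end state
    if (tt %in% types) cnt[sk + 1L, tt] <- cnt[sk + 1L, tt] + w[i]
  }
  cnt[M + 1L, c("MD", "DD")] <- 0             # no position M + 1 to delete to
  trans <- normalize_transitions(cnt)

  new_profile_hmm(name = name, match_emit = match_emit,
                  insert_emit = insert_emit, trans = trans, background = bg)
}

profile_background <- function(background, mat = NULL, w = NULL) {
  if (is.numeric(background)) return(setNames(background, AA_ALPHABET))
  if (identical(background, "flat"))
    return(setNames(rep(0.05, 20), AA_ALPHABET))
  stopifnot(!is.null(mat))
  cnt <- vapply(AA_ALPHABET, function(a) sum(w * rowSums(mat == a)),
                numeric(1))
  if (sum(cnt) <= 0) stop("empirical background: alignment has no residues")
  cnt / sum(cnt)
}

normalize_transitions <- function(cnt) {
  grp <- list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))
  for (g in grp) {
    s <- rowSums(cnt[, g, drop = FALSE])
    cnt[, g] <- cnt[, g] / s
  }
  cnt
}

#' Construct and validate a profile HMM object
#'
#' Low-level constructor; [build_profile()] is the usual entry point.
#'
#' @param name model name.
#' @param match_emit M x 20 row-stochastic matrix.
#' @param insert_emit (M+1) x 20 row-stochastic matrix; row k + 1 is the
#'   insert state after match position k (row 1 = N-terminal insert).
#' @param trans (M+1) x 7 matrix with columns MM, MI, MD, IM, II, DM, DD;
#'   row k + 1 holds the moves out of position k (row 1 = begin state).
#' @param background length-20 amino-acid background distribution.
#' @param calibration optional [gumbel_params()].
#' @return a `profile_hmm`.
#' @export
new_profile_hmm <- function(name, match_emit, insert_emit, trans,
                            background, calibration = NULL) {
  obj <- structure(list(name = name, M = nrow(match_emit),
                        alphabet = AA_ALPHABET,
                        match_emit = match_emit, insert_emit = insert_emit,
                        trans = trans, background = background,
                        calibration = calibration),
                   class = "profile_hmm")
  validate_profile(obj)
  obj
}

validate_profile <- function(m, tol = 1e-9) {
  M <- m$M
  stopifnot(M >= 1, nrow(m$insert_emit) == M + 1L, nrow(m$trans) == M + 1L,
            length(m$background) == 20L)
  if (any(abs(rowSums(m$match_emit) - 1) > tol) ||
      any(abs(rowSums(m$insert_emit) - 1) > tol))
    stop("profile invariant violated: emission row does not sum to 1")
  if (any(m$match_emit <= 0) || any(m$insert_emit <= 0))
    stop("profile invariant violated: zero emission probability")
  grp <- list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))
  for (g in grp)
    if (any(abs(rowSums(m$trans[, g, drop = FALSE]) - 1) > tol))
      stop("profile invariant violated: transition group does not sum to 1")
  tr <- m$trans
  tr[M + 1L, c("MD", "DD")] <- NA             # structural zeros are exempt
  if (any(tr <= 0, na.rm = TRUE))
    stop("profile invariant violated: zero transition probability")
  if (abs(sum(m$background) - 1) > max(tol, 1e-9) || any(m$background <= 0))
    stop("profile invariant violated: background is not a distribution")
  invisible(m)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm '", x$name, "': ", x$M, " match states\n", sep = "")
  if (!is.null(x$calibration))
    cat(sprintf("  calibrated: Gumbel mu=%.3f lambda=%.4f (n=%d)\n",
                x$calibration$mu, x$calibration$lambda,
                x$calibration$n_calibration))
  else cat("  uncalibrated (run calibrate_profile() before searching)\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# ASCII serialization, an HMMER3-style dialect: probabilities stored as
# negative natural logs, "*" marks the structural zeros of the last node.

fmt_nll <- function(p) ifelse(p == 0, "*", sprintf("%.6f", -log(p)))

parse_nll <- function(tok, line) {
  v <- ifelse(tok == "*", 0, exp(-suppressWarnings(as.numeric(tok))))
  if (anyNA(v)) stop("profile parse error at line ", line,
                     ": expected a number or '*'")
  v
}

#' Write / read a profile HMM
#'
#' ASCII serialization in an HMMER3-style dialect: a header (name, length,
#' alphabet, optional Gumbel calibration line), a background line, then one
#' match-emission, insert-emission and transition line per node, all as
#' negative natural-log probabilities, terminated by `//`.  Zero
#' probabilities are only legal at the structurally impossible last-node
#' M->D / D->D moves, written as `*`.  `read_profile(write_profile(m))`
#' reproduces every probability within 1e-6.
#'
#' @param model a `profile_hmm`.
#' @param path file path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a `profile_hmm`.
#' @export
write_profile <- function(model, path) {
  validate_profile(model, tol = 1e-6)
  M <- model$M
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("FAMSCAN1 [profile HMM, amino alphabet, -ln probabilities]")
  wl("NAME  ", model$name)
  wl("LENG  ", M)
  wl("ALPH  amino")
  if (!is.null(model$calibration)) {
    g <- model$calibration
    wl(sprintf("STATS GUMBEL %.6f %.6f %d %d", g$mu, g$lambda,
               g$n_calibration, g$seed %||% 0L))
  }
  wl("BG    ", paste(fmt_nll(model$background), collapse = " "))
  wl("HMM   ", paste(AA_ALPHABET, collapse = "      "))
  wl("      ", paste(colnames(model$trans), collapse = "      "))
  wl("      ", paste(fmt_nll(model$insert_emit[1L, ]), collapse = " "))
  wl("      ", paste(fmt_nll(model$trans[1L, ]), collapse = " "))
  for (k in seq_len(M)) {
    wl(sprintf("%-5d ", k), paste(fmt_nll(model$match_emit[k, ]),
                                  collapse = " "))
    wl("      ", paste(fmt_nll(model$insert_emit[k + 1L, ]), collapse = " "))
    wl("      ", paste(fmt_nll(model$trans[k + 1L, ]), collapse = " "))
  }
  wl("//")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 8L || !startsWith(lines[1L], "FAMSCAN1"))
    stop("profile parse error at line 1: missing FAMSCAN1 header")
  hdr <- function(key, n) {
    i <- grep(paste0("^", key, "\\b"), lines)[1L]
    if (is.na(i)) stop("profile parse error: missing ", key, " line")
    list(val = strsplit(trimws(sub(paste0("^", key), "", lines[i])),
                        "\\s+")[[1L]], line = i)
  }
  name <- hdr("NAME")$val[1L]
  M <- as.integer(hdr("LENG")$val[1L])
  if (is.na(M) || M < 1L) stop("profile parse error: bad LENG")
  bg_h <- hdr("BG")
  background <- setNames(parse_nll(bg_h$val, bg_h$line), AA_ALPHABET)
  calibration <- NULL
  si <- grep("^STATS GUMBEL", lines)
  if (length(si)) {
    v <- strsplit(trimws(sub("^STATS GUMBEL", "", lines[si[1L]])),
                  "\\s+")[[1L]]
    calibration <- gumbel_params(mu = as.numeric(v[1L]),
                                 lambda = as.numeric(v[2L]),
                                 n_calibration = as.integer(v[3L]),
                                 seed = as.integer(v[4L]))
  }
  hmm_i <- grep("^HMM\\b", lines)[1L]
  if (is.na(hmm_i)) stop("profile parse error: missing HMM block")
  body <- hmm_i + 2L                          # skip alphabet + column header
  need <- 2L + 3L * M
  toks <- lapply(seq_len(need), function(r) {
    i <- body + r - 1L
    if (i > length(lines)) stop("profile parse error: truncated at line ", i)
    strsplit(trimws(lines[i]), "\\s+")[[1L]]
  })
  insert_emit <- matrix(0, M + 1L, 20, dimnames = list(NULL, AA_ALPHABET))
  match_emit <- matrix(0, M, 20, dimnames = list(NULL, AA_ALPHABET))
  trans <- matrix(0, M + 1L, 7L,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                          "DM", "DD")))
  insert_emit[1L, ] <- parse_nll(toks[[1L]], body)
  trans[1L, ] <- parse_nll(toks[[2L]], body + 1L)
  for (k in seq_len(M)) {
    r <- 2L + 3L * (k - 1L)
    mt <- toks[[r + 1L]]
    if (mt[1L] != as.character(k))
      stop("profile parse error at line ", body + r,
           ": expected node index ", k)
    match_emit[k, ] <- parse_nll(mt[-1L], body + r)
    insert_emit[k + 1L, ] <- parse_nll(toks[[r + 2L]], body + r + 1L)
    trans[k + 1L, ] <- parse_nll(toks[[r + 3L]], body + r + 2L)
  }
  if (!any(grepl("^//", lines[(body + need):length(lines)])))
    stop("profile parse error: missing // terminator")
  obj <- structure(list(name = name, M = M, alphabet = AA_ALPHABET,
                        match_emit = match_emit, insert_emit = insert_emit,
                        trans = trans, background = background,
                        calibration = calibration),
                   class = "profile_hmm")
  validate_profile(obj, tol = 1e-4)           # 6-decimal -ln serialization
  obj
}
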