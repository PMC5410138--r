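#' Read an aligned FASTA multiple sequence alignment
#'
#' Records must be protein sequences of equal length; both `-` and `.` are
#' accepted as gap characters (normalised to `-`).  Sequences start with
#' unit weights; call [position_weights()] to apply Henikoff position-based
#' weighting.
#'
#' @param path path to an aligned FASTA file.
#' @return a `multiple_alignment`: list with `records` (sequence set),
#'   `mat` (n x n_cols character matrix), `n_cols`, and `weights`
#'   (length-n, summing to n).
#' @export
read_aligned_fasta <- function(path) {
  recs <- read_fasta(path, "protein", allow_gaps = TRUE)
  recs$residues <- chartr(".", "-", recs$residues)
  new_msa(recs)
}

new_msa <- function(recs, weights = NULL) {
  lens <- nchar(recs$residues)
  if (nrow(recs) < 2L)
    stop("an alignment needs at least 2 sequences")
  if (length(unique(lens)) != 1L) {
    bad <- recs$id[lens != lens[1L]][1L]
    stop("alignment error: record '", bad, "' has length ",
         lens[lens != lens[1L]][1L], ", expected ", lens[1L])
  }
  mat <- do.call(rbind, strsplit(recs$residues, ""))
  rownames(mat) <- recs$id
  structure(list(records = recs, mat = mat, n_cols = ncol(mat),
                 weights = weights %||% rep(1, nrow(recs))),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("multiple_alignment:", nrow(x$mat), "sequences x", x$n_cols,
      "columns\n")
  invisible(x)
}

#' Henikoff position-based sequence weights
#'
#' In each column with r distinct non-gap residue types, a residue carried
#' by s sequences contributes 1/(r*s) to each of those sequences.  Gap-only
#' columns are skipped and gap characters contribute nothing.  Per-sequence
#' sums are normalised so the weights total the number of sequences.
#'
#' @param msa a `multiple_alignment`.
#' @return the alignment with its `weights` replaced.
#' @export
position_weights <- function(msa) {
  mat <- msa$mat
  n <- nrow(mat)
  w <- numeric(n)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    res <- col != "-" & col != "X"
    if (!any(res)) next
    tab <- table(col[res])
    r <- length(tab)
    w[res] <- w[res] + 1 / (r * as.numeric(tab[col[res]]))
  }
  if (any(w <= 0))
    stop("position weighting failed: sequence '",
         msa$records$id[which(w <= 0)[1L]],
         "' has no residues in any counted column")
  msa$weights <- w * n / sum(w)
  msa
}

#' Assign match and insert columns
#'
#' A column becomes a match column when its weighted non-gap occupancy is
#' at least `occupancy_threshold` (boundary inclusive).
#'
#' @param msa a weighted `multiple_alignment`.
#' @param config a [build_config()].
#' @return character vector of length `n_cols` with values `"match"` /
#'   `"insert"`.
#' @export
assign_match_columns <- function(msa, config = build_config()) {
  occ <- apply(msa$mat != "-", 2, function(nz) sum(msa$weights[nz])) /
    sum(msa$weights)
  lab <- ifelse(occ >= config$occupancy_threshold, "match", "insert")
  if (sum(lab == "match") < config$min_match_states)
    stop("only ", sum(lab == "match"), " match columns at occupancy ",
         "threshold ", config$occupancy_threshold, " (need at least ",
         config$min_match_states, "); lower the threshold")
  lab
}

#' Profile build configuration
#'
#' @param occupancy_threshold weighted non-gap fraction at or above which a
#'   column becomes a match column; in (0, 1], default 0.5.
#' @param pseudocount_alpha total pseudocount mass per emission
#'   distribution, spread in proportion to the background; default 1.
#' @param background `"flat"` (0.05 per residue), `"empirical"` (training
#'   set frequencies), or a named 20-vector summing to 1.
#' @param min_match_states minimum acceptable number of match states.
#' @return a `build_config` list.
#' @export
build_config <- function(occupancy_threshold = 0.5, pseudocount_alpha = 1,
                         background = "flat", min_match_states = 5L) {
  stopifnot(occupancy_threshold > 0, occupancy_threshold <= 1,
            pseudocount_alpha > 0, min_match_states >= 1)
  if (is.numeric(background)) {
    stopifnot(length(background) == 20L,
              abs(sum(background) - 1) < 1e-9, all(background > 0))
    background <- setNames(as.numeric(background), AA_ALPHABET)
  } else stopifnot(background %in% c("flat", "empirical"))
  structure(list(occupancy_threshold = occupancy_threshold,
                 pseudocount_alpha = pseudocount_alpha,
                 background = background,
                 min_match_states = as.integer(min_match_states)),
            class = "build_config")
}
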