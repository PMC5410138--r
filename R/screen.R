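#' Recognised body-site labels
#'
#' The nine Human Microbiome Project body sites used for grouping: eight
#' oral sites plus stool.
#' @export
BODY_SITES <- c("Attached Keratinized Gingiva", "Buccal Mucosa",
                "Palatine Tonsils", "Saliva", "Stool", "Subgingival Plaque",
                "Supragingival Plaque", "Throat", "Tongue Dorsum")

#' Screen one assembly sample
#'
#' Six-frame translates the contigs, searches every translated segment with
#' the calibrated profile, and deduplicates hits whose nucleotide intervals
#' overlap (by at least 1 bp) on the same contig across frames, keeping the
#' lowest E-value.  The per-sample summary reports the hit count, assembly
#' size in Mb and the hits/Mb density.
#'
#' @param model a calibrated `profile_hmm`.
#' @param contigs a DNA sequence set (from [read_fasta()]) or a path to a
#'   nucleotide FASTA file.
#' @param sample_id sample identifier (defaults to the file base name).
#' @param site body-site label; see [BODY_SITES].
#' @param config a [search_config()].
#' @return list with `summary` (one-row `data.frame`: `sample_id`,
#'   `body_site`, `n_hits`, `assembly_mb`, `density`, `has_hit`) and `hits`.
#' @export
screen_sample <- function(model, contigs, sample_id = NULL, site = "Stool",
                          config = search_config()) {
  if (is.character(contigs)) {
    if (is.null(sample_id))
      sample_id <- sub("\\.(fa|fna|fasta)$", "", basename(contigs))
    contigs <- read_fasta(contigs, "dna")
  }
  if (is.null(sample_id)) sample_id <- "sample"
  if (nrow(contigs) == 0L)
    stop("empty assembly for sample '", sample_id, "'")
  frames <- six_frame_translate(contigs, config$min_peptide_len)
  hits <- profile_search(model, frames, config)
  hits <- dedup_hits(hits)
  mb <- sum(nchar(contigs$residues)) / 1e6
  summary <- data.frame(sample_id = sample_id, body_site = site,
                        n_hits = nrow(hits), assembly_mb = mb,
                        density = nrow(hits) / mb,
                        has_hit = nrow(hits) >= 1L,
                        stringsAsFactors = FALSE)
  list(summary = summary, hits = hits)
}

# Keep the lowest-E hit among same-contig hits whose nucleotide intervals
# share at least 1 bp (the same locus picked up in several frames).
dedup_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  hits <- hits[order(hits$evalue, -hits$bit_score), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    prev <- which(keep & hits$contig_id == hits$contig_id[i])
    clash <- any(hits$nt_start[prev] <= hits$nt_end[i] &
                   hits$nt_end[prev] >= hits$nt_start[i])
    keep[i] <- !isTRUE(clash)
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-site density table
#'
#' Aggregates per-sample summaries by body site: sample count, total hits,
#' mean hits/Mb density, and the percentage of samples with at least one
#' hit.  Unrecognised site labels raise a warning and are grouped under
#' `"other"`.
#'
#' @param summaries a `data.frame` of per-sample summaries
#'   (rbind of [screen_sample()] `$summary` rows).
#' @param pool_oral also report a pooled `"Oral"` row aggregating the eight
#'   non-stool sites.
#' @return a `data.frame` with columns `body_site`, `n_samples`,
#'   `total_hits`, `mean_density`, `pct_with_hit`.
#' @export
density_table <- function(summaries, pool_oral = FALSE) {
  stopifnot(nrow(summaries) > 0)
  site <- summaries$body_site
  unknown <- !(site %in% BODY_SITES)
  if (any(unknown)) {
    warning("unknown body site label(s): ",
            paste(unique(site[unknown]), collapse = ", "),
            "; grouped under 'other'")
    site[unknown] <- "other"
  }
  agg <- function(df, label) data.frame(
    body_site = label, n_samples = nrow(df), total_hits = sum(df$n_hits),
    mean_density = mean(df$density),
    pct_with_hit = 100 * mean(df$has_hit), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(unique(site), function(s)
    agg(summaries[site == s, , drop = FALSE], s)))
  if (pool_oral) {
    oral <- summaries[site != "Stool" & site != "other", , drop = FALSE]
    if (nrow(oral) > 0) out <- rbind(out, agg(oral, "Oral (pooled)"))
  }
  rownames(out) <- NULL
  out
}

#' Compare hit densities between two groups
#'
#' Two-sided Wilcoxon rank-sum (exact when the combined size is at most 10
#' and there are no ties, otherwise normal approximation with continuity
#' correction) or Welch's two-sample t-test.
#'
#' @param groupA,groupB numeric vectors of per-sample densities (each of
#'   length >= 2).
#' @param test `"wilcoxon_rank_sum"` or `"welch_t"`.
#' @param labels group labels for the report.
#' @return a `data.frame` with `test_name`, `statistic`, `p_value`,
#'   `group_labels`, `group_sizes`.
#' @export
compare_densities <- function(groupA, groupB,
                              test = c("wilcoxon_rank_sum", "welch_t"),
                              labels = c("A", "B")) {
  test <- match.arg(test)
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  if (length(unique(c(groupA, groupB))) == 1L)
    stop("degenerate data: all values identical in both groups")
  if (test == "wilcoxon_rank_sum") {
    n <- length(groupA) + length(groupB)
    ties <- anyDuplicated(c(groupA, groupB)) > 0
    ht <- suppressWarnings(wilcox.test(groupA, groupB,
                                       exact = (n <= 10 && !ties),
                                       correct = TRUE))
  } else {
    ht <- t.test(groupA, groupB, var.equal = FALSE)
  }
  data.frame(test_name = test, statistic = unname(ht$statistic),
             p_value = ht$p.value,
             group_labels = paste(labels, collapse = " vs "),
             group_sizes = paste(length(groupA), length(groupB), sep = ","),
             stringsAsFactors = FALSE)
}

#' Cross-method hit overlap (Venn region counts)
#'
#' Hits from different methods are considered the same locus when they lie
#' on the same sample and contig and their nucleotide intervals overlap by
#' at least 50% of the shorter interval.  Loci are single-linkage clusters
#' under that relation; each cluster is assigned to exactly one region (the
#' set of methods reporting it), so per-method region sums equal the
#' method's (deduplicated) hit count.
#'
#' @param hit_tables named list of 2 or 3 hit tables, each with columns
#'   `contig_id`, `nt_start`, `nt_end` and optionally `sample_id`.
#' @return a `method_overlap` object: list with `method_names` and
#'   `region_counts` (named integer vector, names like `"A"`, `"A&B"`).
#' @export
method_overlap <- function(hit_tables) {
  stopifnot(length(hit_tables) %in% c(2L, 3L), !is.null(names(hit_tables)))
  methods <- names(hit_tables)
  all_hits <- do.call(rbind, lapply(methods, function(m) {
    h <- hit_tables[[m]]
    if (nrow(h) == 0L)
      return(data.frame(method = character(0), sample_id = character(0),
                        contig_id = character(0), nt_start = integer(0),
                        nt_end = integer(0)))
    data.frame(method = m,
               sample_id = as.character(h$sample_id %||% "sample"),
               contig_id = h$contig_id, nt_start = h$nt_start,
               nt_end = h$nt_end, stringsAsFactors = FALSE)
  }))
  n <- nrow(all_hits)
  region_names <- unlist(lapply(seq_along(methods), function(k)
    utils::combn(methods, k, paste, collapse = "&", simplify = TRUE)))
  counts <- setNames(integer(length(region_names)), region_names)
  if (n > 0) {
    # single-linkage clusters over the >=50%-of-shorter overlap relation
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    key <- paste(all_hits$sample_id, all_hits$contig_id)
    for (g in split(seq_len(n), key)) {
      if (length(g) < 2L) next
      for (a in seq_along(g)) for (b in seq_len(a - 1L)) {
        i <- g[a]; j <- g[b]
        ov <- min(all_hits$nt_end[i], all_hits$nt_end[j]) -
          max(all_hits$nt_start[i], all_hits$nt_start[j]) + 1
        shorter <- min(all_hits$nt_end[i] - all_hits$nt_start[i],
                       all_hits$nt_end[j] - all_hits$nt_start[j]) + 1
        if (ov >= 0.5 * shorter) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
    dup <- FALSE
    for (cl in split(seq_len(n), root)) {
      ms <- all_hits$method[cl]
      if (anyDuplicated(ms)) dup <- TRUE
      region <- paste(methods[methods %in% ms], collapse = "&")
      counts[region] <- counts[region] + 1L
    }
    if (dup)
      warning("duplicate hits within one method collapsed to one locus")
  }
  structure(list(method_names = methods, region_counts = counts),
            class = "method_overlap")
}

#' @export
print.method_overlap <- function(x, ...) {
  cat("method_overlap of", paste(x$method_names, collapse = ", "), "\n")
  for (r in names(x$region_counts))
    cat(sprintf("  %-12s %d\n", r, x$region_counts[[r]]))
  invisible(x)
}

#' Per-method locus totals of an overlap partition
#'
#' @param overlap a `method_overlap`.
#' @return named integer vector: for each method, the sum of the regions
#'   that include it.
#' @export
overlap_totals <- function(overlap) {
  vapply(overlap$method_names, function(m) {
    inc <- vapply(strsplit(names(overlap$region_counts), "&", fixed = TRUE),
                  function(s) m %in% s, logical(1))
    sum(overlap$region_counts[inc])
  }, integer(1))
}

#' Screen a set of reference genomes
#'
#' As [screen_sample()] for each genome, but reporting one aggregate
#' density (total deduplicated hits over total megabases) instead of
#' per-site grouping.
#'
#' @param model a calibrated `profile_hmm`.
#' @param genomes a named list of DNA sequence sets or a character vector
#'   of FASTA paths.
#' @param config a [search_config()].
#' @return list with `hits` (all genomes, extra `genome` column),
#'   `n_hits`, `total_mb`, and `density` (hits/Mb).
#' @export
screen_genomes <- function(model, genomes, config = search_config()) {
  if (is.character(genomes))
    genomes <- setNames(lapply(genomes, read_fasta, alphabet = "dna"),
                        sub("\\.(fa|fna|fasta)$", "", basename(genomes)))
  if (is.null(names(genomes)))
    names(genomes) <- sprintf("genome%d", seq_along(genomes))
  all_hits <- list(); total_mb <- 0
  for (g in names(genomes)) {
    res <- screen_sample(model, genomes[[g]], sample_id = g,
                         site = "Stool", config = config)
    total_mb <- total_mb + res$summary$assembly_mb
    if (nrow(res$hits) > 0) all_hits[[g]] <- cbind(genome = g, res$hits)
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    cbind(genome = character(0), empty_hits())
  rownames(hits) <- NULL
  list(hits = hits, n_hits = nrow(hits), total_mb = total_mb,
       density = nrow(hits) / total_mb)
}

#' Screen many samples from a manifest
#'
#' @param model a calibrated `profile_hmm`.
#' @param manifest `data.frame` with columns `sample_id`, `body_site`,
#'   `fasta_path`, or a path to such a TSV.
#' @param config a [search_config()].
#' @return list with `summaries` (one row per sample) and `hits` (all
#'   samples, extra `sample_id` column).
#' @export
screen_manifest <- function(model, manifest, config = search_config()) {
  if (is.character(manifest))
    manifest <- read.delim(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "body_site", "fasta_path") %in%
                  names(manifest)))
  summaries <- list(); hits <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- screen_sample(model, manifest$fasta_path[i],
                         sample_id = manifest$sample_id[i],
                         site = manifest$body_site[i], config = config)
    summaries[[i]] <- res$summary
    if (nrow(res$hits) > 0)
      hits[[i]] <- cbind(sample_id = manifest$sample_id[i], res$hits)
  }
  list(summaries = do.call(rbind, summaries),
       hits = if (length(hits)) do.call(rbind, hits) else
         cbind(sample_id = character(0), empty_hits()))
}
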