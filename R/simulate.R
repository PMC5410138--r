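#' Random peaked profile HMM
#'
#' Generates a profile with one dominant residue per match state (drawn
#' uniformly) carrying `conservation` of the emission mass, the remainder
#' spread over the other residues; transitions favour match-to-match moves.
#' Useful as the known ground-truth model in parameter-recovery and oracle
#' experiments.
#'
#' @param M number of match states.
#' @param seed RNG seed.
#' @param conservation probability mass of the dominant residue per match
#'   state, in (0.05, 1).
#' @param t_mm probability of the match-to-match move (the remainder is
#'   split between match-to-insert and match-to-delete).
#' @return an uncalibrated `profile_hmm`.
#' @export
random_profile <- function(M, seed = 1L, conservation = 0.9, t_mm = 0.94) {
  stopifnot(M >= 1, conservation > 0.05, conservation < 1,
            t_mm > 0, t_mm < 1)
  with_seed(seed, {
    bg <- setNames(rep(0.05, 20), AA_ALPHABET)
    match_emit <- t(vapply(seq_len(M), function(k) {
      e <- rep((1 - conservation) / 19, 20)
      e[sample.int(20, 1)] <- conservation
      e
    }, numeric(20)))
    colnames(match_emit) <- AA_ALPHABET
    insert_emit <- matrix(rep(bg, each = M + 1L), M + 1L, 20,
                          dimnames = list(NULL, AA_ALPHABET))
    rest <- (1 - t_mm) / 2
    trans <- matrix(rep(c(t_mm, rest, rest, 0.9, 0.1, 0.9, 0.1), each = M + 1),
                    M + 1L, 7L,
                    dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                            "DM", "DD")))
    trans[M + 1L, c("MD", "DD")] <- 0
    trans <- normalize_transitions(trans)
    new_profile_hmm(name = sprintf("random_M%d_seed%d", M, seed),
                    match_emit = match_emit, insert_emit = insert_emit,
                    trans = trans, background = bg)
  })
}

#' Sample sequences from a profile HMM
#'
#' Draws i.i.d. state paths through the core model (begin through end) and
#' emits residues from the match/insert distributions.  The generating
#' paths are kept in the `"paths"` attribute so a ground-truth alignment
#' can be reconstructed with [sampled_alignment()].
#'
#' @param model a `profile_hmm`.
#' @param n number of sequences (>= 1).
#' @param seed RNG seed; fixed seed gives identical output.
#' @param indels if `FALSE`, paths are forced straight through all match
#'   states (gap-free homologs, trivially aligned).
#' @return a protein sequence set with attribute `"paths"`.
#' @export
sample_from_profile <- function(model, n, seed = 1L, indels = TRUE) {
  stopifnot(n >= 1)
  M <- model$M
  with_seed(seed, {
    paths <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      match_res <- rep("-", M)
      inserts <- rep("", M + 1L)              # inserts[k+1] follows match k
      if (indels) {
        type <- "M"; k <- 0L
        repeat {
          p <- model$trans[k + 1L, ]
          if (type == "M") {
            mv <- sample(c("M", "I", "D"), 1, prob = p[c("MM", "MI", "MD")])
          } else if (type == "I") {
            mv <- sample(c("M", "I"), 1, prob = p[c("IM", "II")])
          } else {
            mv <- sample(c("M", "D"), 1, prob = p[c("DM", "DD")])
          }
          if (mv == "I") {
            inserts[k + 1L] <- paste0(
              inserts[k + 1L],
              sample(AA_ALPHABET, 1, prob = model$insert_emit[k + 1L, ]))
            type <- "I"
          } else {
            k <- k + 1L
            if (k > M) break
            type <- mv
            if (mv == "M")
              match_res[k] <- sample(AA_ALPHABET, 1,
                                     prob = model$match_emit[k, ])
          }
        }
      } else {
        for (k in seq_len(M))
          match_res[k] <- sample(AA_ALPHABET, 1,
                                 prob = model$match_emit[k, ])
      }
      paths[[i]] <- list(match_res = match_res, inserts = inserts)
      pieces <- character(0)
      for (k in 0:M) {
        if (nzchar(inserts[k + 1L])) pieces <- c(pieces, inserts[k + 1L])
        if (k < M && match_res[k + 1L] != "-")
          pieces <- c(pieces, match_res[k + 1L])
      }
      seqs[i] <- paste(pieces, collapse = "")
    }
    out <- new_seq_set(sprintf("%s_s%04d", model$name, seq_len(n)), seqs,
                       alphabet = "protein")
    attr(out, "paths") <- paths
    out
  })
}

#' Ground-truth alignment of profile samples
#'
#' Reconstructs the multiple alignment implied by the generating state
#' paths of [sample_from_profile()]: one column per match state, plus
#' left-justified insert columns sized to the longest insert run observed
#' at each position.
#'
#' @param samples output of [sample_from_profile()].
#' @return a `multiple_alignment` with unit weights.
#' @export
sampled_alignment <- function(samples) {
  paths <- attr(samples, "paths")
  if (is.null(paths)) stop("samples carry no generating paths")
  M <- length(paths[[1L]]$match_res)
  ins_max <- vapply(0:M, function(k)
    max(vapply(paths, function(p) nchar(p$inserts[k + 1L]), integer(1))),
    integer(1))
  rows <- vapply(paths, function(p) {
    pieces <- character(0)
    for (k in 0:M) {
      if (ins_max[k + 1L] > 0)
        pieces <- c(pieces, formatC(p$inserts[k + 1L], flag = "-",
                                    width = ins_max[k + 1L]))
      if (k < M) pieces <- c(pieces, p$match_res[k + 1L])
    }
    gsub(" ", "-", paste(pieces, collapse = ""))
  }, character(1))
  new_msa(new_seq_set(samples$id, rows, alphabet = "protein"))
}

#' Point-substitute a protein at a fixed rate
#'
#' Each site is independently replaced, with probability `rate`, by a
#' uniformly chosen different residue, so the expected identity to the
#' input is 1 - rate.
#'
#' @param protein a protein string, or a sequence set (all rows diverged).
#' @param rate substitution probability per site, in \[0, 1).
#' @param seed RNG seed.
#' @return same type as the input.
#' @export
diverge <- function(protein, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (is.data.frame(protein)) {
    out <- protein
    out$residues <- with_seed(seed, vapply(protein$residues, diverge_one,
                                           character(1), rate = rate,
                                           USE.NAMES = FALSE))
    return(out)
  }
  with_seed(seed, diverge_one(protein, rate))
}

diverge_one <- function(s, rate) {
  ch <- strsplit(s, "")[[1L]]
  hit <- runif(length(ch)) < rate
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(a)
      sample(setdiff(AA_ALPHABET, a), 1), character(1))
  paste(ch, collapse = "")
}

#' Reverse-translate a protein into coding DNA
#'
#' Chooses a synonymous codon per residue with weights proportional to the
#' target GC content (each G/C base weighted `gc_content/2`, each A/T base
#' `(1-gc_content)/2`), and appends a stop codon.  Translating frame +1 of
#' the output regenerates the protein exactly.
#'
#' @param protein a protein string without X.
#' @param gc_content target GC fraction in (0, 1).
#' @param seed RNG seed.
#' @return a DNA string (coding sequence + stop codon).
#' @export
reverse_translate <- function(protein, gc_content = 0.5, seed = 1L) {
  stopifnot(gc_content > 0, gc_content < 1)
  if (grepl("X", protein, fixed = TRUE))
    stop("cannot reverse-translate X residues")
  code <- Biostrings::GENETIC_CODE
  with_seed(seed, {
    pick <- function(aa) {
      codons <- names(code)[code == aa]
      w <- vapply(codons, function(cd) {
        b <- strsplit(cd, "")[[1L]]
        prod(ifelse(b %in% c("G", "C"), gc_content / 2,
                    (1 - gc_content) / 2))
      }, numeric(1))
      sample(codons, 1, prob = w)
    }
    ch <- strsplit(protein, "")[[1L]]
    bad <- setdiff(ch, code)
    if (length(bad)) stop("no codon for residue ", bad[1L])
    paste0(paste(vapply(ch, pick, character(1)), collapse = ""), pick("*"))
  })
}

#' Simulation configuration for synthetic metagenomes
#'
#' @param seed master RNG seed.
#' @param n_contigs number of background contigs.
#' @param contig_length_mean,contig_length_dispersion negative-binomial
#'   mean and size of contig lengths (floored at 300 bp).
#' @param gc_content background GC fraction in (0, 1).
#' @param implants `data.frame` with columns `contig` (1-based index),
#'   `offset` (1-based position), `strand` (`"+"`/`"-"`), `member` (1-based
#'   index into the family).  `NULL` for no implants.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_contigs = 20L,
                       contig_length_mean = 5000,
                       contig_length_dispersion = 20,
                       gc_content = 0.45, implants = NULL) {
  stopifnot(n_contigs >= 1, contig_length_mean > 0, gc_content > 0,
            gc_content < 1)
  structure(list(seed = seed, n_contigs = as.integer(n_contigs),
                 contig_length_mean = contig_length_mean,
                 contig_length_dispersion = contig_length_dispersion,
                 gc_content = gc_content, implants = implants),
            class = "sim_config")
}

#' Synthetic protein family at controlled divergence
#'
#' Draws a random ancestor from the background amino-acid distribution and
#' derives `n` members by independent point substitution at `divergence`
#' per site, yielding a gap-free (hence trivially aligned) homolog family.
#'
#' @param n family size.
#' @param length protein length in residues.
#' @param divergence per-site substitution fraction from the ancestor.
#' @param seed RNG seed.
#' @param background amino-acid sampling weights (default flat).
#' @return a protein sequence set with attribute `"ancestor"`.
#' @export
make_family <- function(n, length = 300L, divergence = 0.2, seed = 1L,
                        background = rep(0.05, 20)) {
  stopifnot(n >= 2, length >= 10, divergence >= 0, divergence < 1)
  with_seed(seed, {
    ancestor <- paste(sample(AA_ALPHABET, length, replace = TRUE,
                             prob = background), collapse = "")
    members <- vapply(seq_len(n), function(i)
      diverge_one(ancestor, divergence), character(1))
    out <- new_seq_set(sprintf("fam%03d", seq_len(n)), members,
                       alphabet = "protein")
    attr(out, "ancestor") <- ancestor
    out
  })
}

#' Family sequence set as a multiple alignment
#'
#' Gap-free families from [make_family()] are already aligned; this wraps
#' them as a `multiple_alignment`.
#'
#' @param family a protein sequence set of equal-length sequences.
#' @return a `multiple_alignment`.
#' @export
family_alignment <- function(family) new_msa(family)

#' Generate a synthetic metagenome with implanted family genes
#'
#' Background contigs are i.i.d. nucleotides at the configured GC content;
#' each implant reverse-translates a family member (plus stop codon) and
#' splices it into its contig at the stated offset and strand.  The truth
#' table records every implant's forward-strand nucleotide interval.
#'
#' @param config a [sim_config()] with an `implants` table (or `NULL`).
#' @param family a protein sequence set supplying implant members.
#' @return list with `contigs` (DNA sequence set) and `truth`
#'   (`data.frame`: `contig_id`, `strand`, `nt_start`, `nt_end`,
#'   `member_id`).
#' @export
make_metagenome <- function(config, family = NULL) {
  with_seed(config$seed, {
    lens <- pmax(300L, stats::rnbinom(config$n_contigs,
                                      size = config$contig_length_dispersion,
                                      mu = config$contig_length_mean))
    gc <- config$gc_content
    contigs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = ""), character(1))
    ids <- sprintf("contig%03d", seq_len(config$n_contigs))
    truth <- data.frame(contig_id = character(0), strand = character(0),
                        nt_start = integer(0), nt_end = integer(0),
                        member_id = character(0))
    imp <- config$implants
    if (!is.null(imp) && nrow(imp) > 0) {
      stopifnot(!is.null(family), all(imp$member <= nrow(family)),
                all(imp$contig <= config$n_contigs))
      for (r in seq_len(nrow(imp))) {
        cds <- reverse_translate(family$residues[imp$member[r]], gc,
                                 seed = sample.int(1e6, 1))
        if (imp$strand[r] == "-")
          cds <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(cds)))
        ci <- imp$contig[r]
        s <- imp$offset[r]; e <- s + nchar(cds) - 1L
        if (s < 1L || e > nchar(contigs[ci]))
          stop("implant ", r, " does not fit in contig ", ci)
        clash <- truth$contig_id == ids[ci] & truth$nt_start <= e &
          truth$nt_end >= s
        if (any(clash)) stop("implant collision on contig ", ci)
        substr(contigs[ci], s, e) <- cds
        truth <- rbind(truth, data.frame(
          contig_id = ids[ci], strand = imp$strand[r], nt_start = s,
          nt_end = e, member_id = family$id[imp$member[r]],
          stringsAsFactors = FALSE))
      }
    }
    list(contigs = new_seq_set(ids, contigs, alphabet = "dna"),
         truth = truth)
  })
}
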