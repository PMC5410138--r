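# Synthetic producer/non-producer control strains: positives carry a true
# family gene implanted in background DNA, negatives carry a decoy diverged
# beyond recognition (90% per-site substitution from the ancestor).
make_synthetic_controls <- function(fam, n_pos = 9L, n_neg = 7L,
                                    seed = 900L) {
  neg_subclasses <- rep(c("LanM", "LanL", "LanKC", "none"),
                        length.out = n_neg)
  labels <- c(sprintf("producer_%02d", seq_len(n_pos)),
              sprintf("nonproducer_%02d", seq_len(n_neg)))
  controls <- data.frame(
    strain_label = labels,
    expected_subclass = c(rep("LanB", n_pos), neg_subclasses),
    stringsAsFactors = FALSE)
  anc <- attr(fam, "ancestor")
  seqsets <- vector("list", n_pos + n_neg)
  for (i in seq_len(n_pos + n_neg)) {
    prot <- if (i <= n_pos) fam$residues[i]
    else diverge(anc, 0.9, seed = seed + 50L + i)
    cfg <- sim_config(seed = seed + i, n_contigs = 2L,
                      contig_length_mean = 2500,
                      implants = data.frame(contig = 1, offset = 301,
                                            strand = "+", member = 1))
    member <- famscan:::new_seq_set("ctrl", prot, alphabet = "protein")
    seqsets[[i]] <- make_metagenome(cfg, member)$contigs
  }
  controls$sequences <- seqsets
  controls
}
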