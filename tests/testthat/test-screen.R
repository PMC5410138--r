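test_that("implanted family genes are recovered from synthetic contigs", {
  m <- toy_model(len = 120)
  fam <- attr(m, "family")
  cfg <- sim_config(seed = 31, n_contigs = 8, contig_length_mean = 4000,
                    implants = data.frame(contig = c(1, 3, 6),
                                          offset = c(501, 1201, 2001),
                                          strand = c("+", "-", "+"),
                                          member = c(1, 2, 3)))
  mg <- make_metagenome(cfg, fam)
  res <- screen_sample(m, mg$contigs, sample_id = "syn1", site = "Stool")
  expect_equal(res$summary$n_hits, 3L)
  expect_true(res$summary$has_hit)
  expect_equal(res$summary$density,
               3 / res$summary$assembly_mb, tolerance = 1e-12)
  # each hit overlaps a truth interval on its contig
  for (i in seq_len(nrow(res$hits))) {
    t <- mg$truth[mg$truth$contig_id == res$hits$contig_id[i], ]
    expect_true(any(t$nt_start <= res$hits$nt_end[i] &
                      t$nt_end >= res$hits$nt_start[i]))
  }
  expect_error(screen_sample(m, mg$contigs[0, ], sample_id = "bad"),
               "empty assembly.*bad")
})

test_that("overlapping same-contig hits collapse to the lowest E-value", {
  h <- famscan:::empty_hits()
  h <- rbind(h, data.frame(model_name = "m", target_id = c("a", "b", "c"),
                           bit_score = c(100, 20, 30),
                           evalue = c(1e-40, 1e-7, 1e-9),
                           ali_start = 1L, ali_end = 10L,
                           contig_id = c("c1", "c1", "c2"),
                           frame = c(1L, 2L, 1L),
                           nt_start = c(100L, 150L, 100L),
                           nt_end = c(400L, 430L, 400L)))
  d <- famscan:::dedup_hits(h)
  expect_equal(nrow(d), 2L)
  expect_equal(d$evalue[d$contig_id == "c1"], 1e-40)
})

test_that("density tables aggregate by site with inclusive percentages", {
  s <- data.frame(sample_id = c("a", "b", "c", "d"),
                  body_site = c("Stool", "Stool", "Stool", "Saliva"),
                  n_hits = c(4L, 1L, 0L, 10L),
                  assembly_mb = c(2, 1, 1, 2),
                  density = c(2, 1, 0, 5),
                  has_hit = c(TRUE, TRUE, FALSE, TRUE))
  dt <- density_table(s)
  stool <- dt[dt$body_site == "Stool", ]
  expect_equal(stool$n_samples, 3L)
  expect_equal(stool$total_hits, 5L)
  expect_equal(stool$pct_with_hit, 100 * 2 / 3)
  expect_equal(dt$mean_density[dt$body_site == "Saliva"], 5)

  # assembly of 2,000,000 bp with 10 hits -> density 5 hits/Mb
  expect_equal(10 / (2e6 / 1e6), 5)

  s2 <- rbind(s, data.frame(sample_id = "e", body_site = "Elbow",
                            n_hits = 0L, assembly_mb = 1, density = 0,
                            has_hit = FALSE))
  expect_warning(dt2 <- density_table(s2), "Elbow")
  expect_true("other" %in% dt2$body_site)

  oral_sites <- setdiff(BODY_SITES, "Stool")
  s3 <- data.frame(sample_id = sprintf("s%d", seq_along(BODY_SITES)),
                   body_site = BODY_SITES, n_hits = 1L, assembly_mb = 1,
                   density = 1, has_hit = TRUE)
  dt3 <- density_table(s3, pool_oral = TRUE)
  pooled <- dt3[dt3$body_site == "Oral (pooled)", ]
  expect_equal(pooled$n_samples, length(oral_sites))
})

test_that("seven hits over 1166.67 Mb give 0.006 hits/Mb", {
  s <- data.frame(sample_id = "hmrgd", body_site = "Stool", n_hits = 7L,
                  assembly_mb = 1166.67, density = 7 / 1166.67,
                  has_hit = TRUE)
  dt <- density_table(s)
  expect_equal(round(dt$mean_density, 3), 0.006)
})

test_that("rank-sum comparisons match exact enumeration and edge cases", {
  r <- compare_densities(c(1, 2), c(3, 4), "wilcoxon_rank_sum")
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$p_value, exact_wilcox_p(c(1, 2), c(3, 4)),
               tolerance = 1e-12)

  same <- compare_densities(c(1, 2, 3), c(1, 2, 3), "wilcoxon_rank_sum")
  expect_gte(same$p_value, 0.99)

  set.seed(11)
  jit <- rnorm(4, sd = 1e-9)
  w <- compare_densities(c(0, 0, 0, 0) + jit, c(1, 1, 1, 1) + rev(jit),
                         "welch_t")
  expect_lt(w$p_value, 1e-6)

  expect_error(compare_densities(c(2, 2), c(2, 2)), "degenerate")
})

test_that("wilcoxon p-values agree with full enumeration for n <= 8", {
  set.seed(12)
  for (na in 2:6) for (nb in 2:(8 - na)) {
    if (nb < 2) next
    vals <- sample(seq_len(20), na + nb)   # tie-free
    x <- vals[seq_len(na)]; y <- vals[-seq_len(na)]
    expect_equal(
      compare_densities(x, y, "wilcoxon_rank_sum")$p_value,
      exact_wilcox_p(x, y), tolerance = 1e-12,
      info = sprintf("na=%d nb=%d", na, nb))
  }
})

test_that("method overlap partitions loci and preserves per-method totals", {
  hit <- function(contig, s, e, sample = "smp")
    data.frame(sample_id = sample, contig_id = contig, nt_start = s,
               nt_end = e)
  h1 <- hit("c1", 100, 400); h2 <- hit("c2", 50, 350); h3 <- hit("c3", 1, 300)
  ov <- method_overlap(list(A = rbind(h1, h2), B = rbind(h2, h3)))
  expect_equal(unname(ov$region_counts[c("A", "B", "A&B")]), c(1L, 1L, 1L))
  expect_equal(unname(overlap_totals(ov)), c(2L, 2L))

  tabs <- list(A = rbind(h1, h2), B = rbind(h1, h2), C = rbind(h1, h2))
  ov3 <- method_overlap(tabs)
  expect_equal(unname(ov3$region_counts["A&B&C"]), 2L)
  expect_equal(sum(ov3$region_counts), 2L)

  dj <- method_overlap(list(A = h1, B = hit("c9", 1, 500)))
  expect_equal(unname(dj$region_counts[c("A", "B", "A&B")]), c(1L, 1L, 0L))

  # below 50%-of-shorter overlap the hits stay distinct loci
  near <- method_overlap(list(A = hit("c1", 1, 300),
                              B = hit("c1", 260, 1000)))
  expect_equal(unname(near$region_counts["A&B"]), 0L)
  over <- method_overlap(list(A = hit("c1", 1, 300),
                              B = hit("c1", 150, 1000)))
  expect_equal(unname(over$region_counts["A&B"]), 1L)
})

test_that("genome screening aggregates one density over all genomes", {
  m <- toy_model(len = 120)
  fam <- attr(m, "family")
  g1 <- make_metagenome(sim_config(seed = 61, n_contigs = 4,
                                   contig_length_mean = 3000,
                                   implants = data.frame(
                                     contig = 1, offset = 301, strand = "+",
                                     member = 1)), fam)
  g2 <- make_metagenome(sim_config(seed = 62, n_contigs = 4,
                                   contig_length_mean = 3000), fam)
  res <- screen_genomes(m, list(gA = g1$contigs, gB = g2$contigs))
  expect_equal(res$n_hits, 1L)
  expect_equal(res$density, 1 / res$total_mb)
  expect_equal(res$hits$genome, "gA")

  empty <- screen_genomes(m, list(g = g2$contigs))
  expect_equal(empty$n_hits, 0L)
  expect_equal(empty$density, 0)
})

test_that("manifest screening is deterministic end to end", {
  m <- toy_model(len = 90)
  fam <- attr(m, "family")
  dir <- tempfile(); dir.create(dir)
  paths <- character(2)
  for (i in 1:2) {
    mg <- make_metagenome(sim_config(seed = 70 + i, n_contigs = 3,
                                     contig_length_mean = 2000,
                                     implants = if (i == 1)
                                       data.frame(contig = 1, offset = 201,
                                                  strand = "+", member = 1)
                                     else NULL), fam)
    paths[i] <- file.path(dir, sprintf("s%d.fna", i))
    write_fasta(mg$contigs, paths[i])
  }
  man <- data.frame(sample_id = c("s1", "s2"),
                    body_site = c("Stool", "Saliva"), fasta_path = paths)
  r1 <- screen_manifest(m, man)
  r2 <- screen_manifest(m, man)
  expect_identical(r1, r2)
  expect_equal(r1$summaries$n_hits, c(1L, 0L))
  expect_equal(r1$hits$sample_id, "s1")
})
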