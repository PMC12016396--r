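test_that("latent factors have the configured shapes and are seeded", {
  cfg <- synth_config(n_circ = 5, n_mir = 3, rank = 2, seed = 4)
  f <- generate_latent_factors(cfg)
  expect_equal(dim(f$Z_circ), c(5L, 2L))
  expect_equal(dim(f$Z_mir), c(3L, 2L))
  expect_identical(f, generate_latent_factors(cfg))
  # CLT bound on column means at large n
  big <- synth_config(n_circ = 10000, n_mir = 10, rank = 3, seed = 5)
  Z <- generate_latent_factors(big)$Z_circ
  expect_true(all(abs(colMeans(Z)) < 4 / sqrt(10000)))
})

test_that("edge sampling hits the requested density without signal", {
  cfg <- synth_config(n_circ = 80, n_mir = 50, rank = 3,
                      edge_density = 0.2, signal_strength = 0, seed = 6)
  f <- generate_latent_factors(cfg)
  ints <- generate_interactions(f$Z_circ, f$Z_mir, cfg)
  n_pairs <- 80 * 50
  se <- sqrt(0.2 * 0.8 / n_pairs)
  expect_lt(abs(nrow(ints$table) / n_pairs - 0.2), 3 * se + 0.01 * 0.2)
  # with beta = 0 every pair has the same probability
  expect_lt(diff(range(ints$prob)), 1e-12)
})

test_that("planted signal makes the true factors near-Bayes-optimal", {
  cfg <- synth_config(n_circ = 120, n_mir = 90, rank = 4,
                      edge_density = 0.12, signal_strength = 5, seed = 7)
  f <- generate_latent_factors(cfg)
  ints <- generate_interactions(f$Z_circ, f$Z_mir, cfg)
  S <- tcrossprod(f$Z_circ, f$Z_mir)
  y <- as.integer(as.vector(ints$prob) > 0.5)  # not the labels; build them:
  lab <- matrix(0, 120, 90)
  idx <- cbind(match(ints$table$circRNA, rownames(ints$prob)),
               match(ints$table$miRNA, colnames(ints$prob)))
  lab[idx] <- 1
  expect_gt(roc_auc(as.vector(lab), as.vector(S)), 0.95)
})

test_that("null model scores at chance", {
  cfg <- synth_config(n_circ = 100, n_mir = 100, rank = 4,
                      edge_density = 0.15, signal_strength = 0, seed = 8)
  f <- generate_latent_factors(cfg)
  ints <- generate_interactions(f$Z_circ, f$Z_mir, cfg)
  lab <- matrix(0, 100, 100)
  idx <- cbind(match(ints$table$circRNA, rownames(ints$prob)),
               match(ints$table$miRNA, colnames(ints$prob)))
  lab[idx] <- 1
  S <- tcrossprod(f$Z_circ, f$Z_mir)
  expect_lt(abs(roc_auc(as.vector(lab), as.vector(S)) - 0.5), 0.02)
})

test_that("sequence composition follows the first factor", {
  cfg <- synth_config(n_circ = 200, n_mir = 50, seq_len_circ = c(50L, 60L),
                      signal_strength = 1, seed = 9)
  f <- generate_latent_factors(cfg)
  seqs <- generate_sequences(f$Z_circ, cfg, "circRNA")
  gc <- vapply(seqs$seq,
               function(s) mean(strsplit(s, "")[[1]] %in% c("G", "C")),
               numeric(1))
  # monotone link between z1 and GC fraction
  expect_gt(cor(f$Z_circ[, 1], gc), 0.7)
  hi <- gc[f$Z_circ[, 1] > 1]
  expect_true(mean(hi) > 0.5)
  # beta = 0: pooled base frequencies uniform within 3 SE
  cfg0 <- synth_config(n_circ = 100, n_mir = 10, seq_len_circ = c(50L, 60L),
                       signal_strength = 0, seed = 10)
  s0 <- generate_sequences(generate_latent_factors(cfg0)$Z_circ, cfg0,
                           "circRNA")
  bases <- unlist(strsplit(paste(s0$seq, collapse = ""), ""))
  freq <- table(factor(bases, levels = c("A", "C", "G", "U"))) / length(bases)
  se <- sqrt(0.25 * 0.75 / length(bases))
  expect_true(all(abs(freq - 0.25) < 3 * se + 0.01))
  expect_identical(generate_sequences(f$Z_circ, cfg, "circRNA")$seq,
                   seqs$seq)
})

test_that("generate_dataset composes and round-trips through the readers", {
  cfg <- synth_config(n_circ = 12, n_mir = 6, rank = 2, edge_density = 0.3,
                      seq_len_circ = c(10L, 15L), seq_len_mir = c(5L, 8L),
                      signal_strength = 2, seed = 11)
  dir <- tempfile()
  ds <- generate_dataset(cfg, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c("circ.fasta", "mir.fasta",
                                               "interactions.tsv",
                                               "truth.json")))))
  circ <- read_fasta(file.path(dir, "circ.fasta"), "circRNA")
  mir <- read_fasta(file.path(dir, "mir.fasta"), "miRNA")
  expect_equal(circ$seq, ds$sequences$seq[ds$sequences$kind == "circRNA"])
  tab <- read_interactions(file.path(dir, "interactions.tsv"),
                           circ$id, mir$id)
  expect_equal(tab$circRNA, ds$interactions$circRNA)
  expect_equal(tab$miRNA, ds$interactions$miRNA)
  # different seeds give different edge sets
  ds2 <- generate_dataset(synth_config(n_circ = 12, n_mir = 6, rank = 2,
                                       edge_density = 0.3,
                                       seq_len_circ = c(10L, 15L),
                                       seq_len_mir = c(5L, 8L),
                                       signal_strength = 2, seed = 12))
  expect_false(identical(ds$interactions$circRNA, ds2$interactions$circRNA))
})

test_that("default configuration lands near its expected pair count", {
  ds <- generate_dataset(synth_config(seed = 3))
  # 200 * 80 * 0.12 = 1920 expected positives
  expect_gt(nrow(ds$interactions), 1920 - 200)
  expect_lt(nrow(ds$interactions), 1920 + 200)
})
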