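test_that("generators are pure functions of their seed", {
  t1 <- make_toy_complex(seed = 4)
  t2 <- make_toy_complex(seed = 4)
  expect_identical(t1$structure$atoms, t2$structure$atoms)
  t3 <- make_toy_complex(seed = 5)
  expect_false(identical(t1$structure$atoms$x, t3$structure$atoms$x))

  c1 <- make_affinity_corpus(n_records = 50, seed = 9)
  c2 <- make_affinity_corpus(n_records = 50, seed = 9)
  expect_identical(c1$records, c2$records)

  tr1 <- make_trajectory(select_structure(t1$structure, "A"), n_frames = 5,
                         seed = 3)
  tr2 <- make_trajectory(select_structure(t1$structure, "A"), n_frames = 5,
                         seed = 3)
  expect_identical(tr1$trajectory$coords, tr2$trajectory$coords)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(make_toy_complex(seed = 1))
  invisible(make_affinity_corpus(n_records = 20, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("toy-complex geometry encodes the stated contact separations", {
  toy <- make_toy_complex(n_residues = 12, contact_patch = 5:7,
                          inter_chain_gap = 3.9, seed = 1)
  a <- toy$structure$atoms
  A <- a[a$chain == "A", ]; B <- a[a$chain == "B", ]
  dmat <- as.matrix(dist(rbind(cbind(A$x, A$y, A$z),
                               cbind(B$x, B$y, B$z))))
  cross <- dmat[seq_len(nrow(A)), nrow(A) + seq_len(nrow(B))]
  patch_B <- B$resseq %in% 5:7
  ## contact atoms within 4 A of the designated chain-A residues
  expect_lt(min(cross[A$resseq %in% 5:7, patch_B]), 4)
  ## every non-patch chain-B atom at least 10 A from chain A
  expect_gte(min(cross[, !patch_B]), 10)
  ## empty patch: chains fully separated, no interface
  none <- make_toy_complex(n_residues = 6, contact_patch = integer(0),
                           seed = 2)
  res <- structure_residues(select_structure(none$structure, "A"))
  rep <- delta_sasa(none$structure, "A", "B",
                    res[, c("chain", "resseq", "icode")])
  expect_equal(nrow(detect_interface(rep)), 0)
  expect_error(make_toy_complex(n_residues = 4, contact_patch = 3:9),
               "out of")
  expect_error(make_toy_complex(contact_patch = c(2, 5)), "contiguous")
})

test_that("affinity corpus carries a recoverable linear ground truth", {
  corpus <- make_affinity_corpus(n_records = 200, noise_sd = 0, seed = 4)
  X <- t(vapply(corpus$records$peptide_seq, conjoint_triad, numeric(343),
                normalize = "count"))
  recomputed <- drop(X %*% corpus$true_weights)
  recomputed <- recomputed - mean(recomputed) + mean(corpus$true_affinity)
  expect_equal(corpus$records$affinity, corpus$true_affinity)
  expect_equal(cor(recomputed, corpus$true_affinity), 1)
  expect_equal(corpus$true_ranking, order(corpus$true_affinity))
  ## all records are 1-2 substitutions from the parent
  parent <- strsplit(corpus$parent, "")[[1]]
  nmut <- vapply(corpus$records$peptide_seq, function(sq)
    sum(strsplit(sq, "")[[1]] != parent), 1)
  expect_true(all(nmut %in% 1:2))
})

test_that("zero-noise corpus gives ridge test R^2 >= 0.99", {
  corpus <- make_affinity_corpus(noise_sd = 0, seed = 1)
  res <- screen_affinity_table(corpus$records, "ridge", seed = 42,
                               normalize = "count")
  expect_gte(res$metrics$test$r2, 0.99)
})

test_that("10%-noise corpus keeps Spearman(truth, predicted) >= 0.95 at
           n = 300", {
  ref <- make_affinity_corpus(n_records = 300, noise_sd = 0, seed = 7)
  signal_sd <- sd(ref$true_affinity)
  corpus <- make_affinity_corpus(n_records = 300,
                                 noise_sd = 0.1 * signal_sd, seed = 7)
  res <- screen_affinity_table(corpus$records, "ridge", seed = 42,
                               normalize = "count")
  X <- encode_pairs(corpus$records$peptide_seq, corpus$records$target_seq,
                    "count")
  pred <- predict(res$model, X)
  expect_gte(cor(corpus$true_affinity, pred, method = "spearman"), 0.95)
})

test_that("harmonic trajectories honour their amplitude spec", {
  toy <- make_toy_complex(seed = 1)
  chain <- select_structure(toy$structure, "A")
  flat <- make_trajectory(chain, n_frames = 10, amplitudes = 0, seed = 1)
  expect_equal(max(abs(rmsd_series(flat$trajectory)$rmsd)), 0,
               tolerance = 1e-12)
  amps <- rep(0.2, 12); amps[9] <- 0.6
  tr <- make_trajectory(chain, n_frames = 300, amplitudes = amps, seed = 6)
  rf <- rmsf(tr$trajectory)
  expect_equal(which.max(rf$rmsf), 9)
})

test_that("hopping trajectories yield the stated number of clusters", {
  toy <- make_toy_complex(seed = 1)
  chain <- select_structure(toy$structure, "A")
  tr <- make_trajectory(chain, n_frames = 120, mode = "hopping",
                        n_states = 3, seed = 2)
  expect_equal(sort(unique(tr$state_labels)), 1:3)
  p <- traj_pca(tr$trajectory)
  expect_gt(mean_silhouette(p$projections, tr$state_labels), 0.5)
})
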