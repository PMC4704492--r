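test_that("per-TAD aggregation is the coverage-weighted mean", {
  tads <- tad_set(0, 4e4)
  # equal-width bins {2, 4} -> 3
  tr1 <- data.frame(start = c(0, 2e4), end = c(2e4, 4e4), value = c(2, 4))
  expect_equal(aggregate_feature_per_tad(tr1, tads), 3)
  # bins {2 (30 kb), 4 (10 kb)} -> 2.5
  tr2 <- data.frame(start = c(0, 3e4), end = c(3e4, 4e4), value = c(2, 4))
  expect_equal(aggregate_feature_per_tad(tr2, tads), 2.5)
  # constant track -> all TADs equal; uncovered TAD -> NA
  tads2 <- tad_set(c(0, 4e4, 8e4), c(4e4, 8e4, 12e4))
  tr3 <- data.frame(start = c(0, 4e4), end = c(4e4, 8e4), value = c(7, 7))
  expect_equal(aggregate_feature_per_tad(tr3, tads2), c(7, 7, NA))
})

test_that("correlation profiles behave on affine, random and planted values", {
  K <- 12
  tads <- tad_set((0:(K - 1)) * 5e5, (1:K) * 5e5)
  # affine values on the linear axis correlate perfectly at every offset
  p <- correlation_vs_distance(seq_len(K), "linear", tads)
  expect_true(all(abs(p$correlation - 1) < 1e-12))
  expect_true(all(p$n_pairs >= 2))
  # independent random values average to zero correlation (up to the
  # small negative finite-sample bias of lagged correlations)
  K2 <- 30
  tads30 <- tad_set((0:(K2 - 1)) * 5e5, (1:K2) * 5e5)
  mean_r <- rowMeans(vapply(1:200, function(s) {
    set.seed(s)
    pr <- correlation_vs_distance(rnorm(K2), "linear", tads30)
    pr$correlation[pr$distance %in% 1:3]
  }, numeric(3)))
  expect_true(all(abs(mean_r) < 0.1))
  # profiles are invariant under coordinate reversal (every unordered
  # pair keeps a consistent orientation)
  h <- plant_hierarchy(10, seed = 3)
  v <- simulate_feature_track(h, seed = 1)$tad_values
  td <- tree_distances(h$tree)
  p1 <- correlation_vs_distance(v, td, h$tads)
  perm <- 10:1
  tads_r <- tad_set(max(h$tads$end) - rev(h$tads$end),
                    max(h$tads$end) - rev(h$tads$start))
  p2 <- correlation_vs_distance(v[perm], td[perm, perm], tads_r)
  expect_equal(p1$correlation, p2$correlation)
  expect_equal(p1$mean_separation, p2$mean_separation)
  # tree-correlated track: tree-axis correlation beats linear at matched
  # mean separation (averaged over seeds)
  h16 <- plant_hierarchy(16, seed = 2, shape = "balanced")
  tdd <- tree_distances(h16$tree)
  diffs <- vapply(1:100, function(s) {
    vv <- simulate_feature_track(h16, seed = s)$tad_values
    pt <- correlation_vs_distance(vv, tdd, h16$tads)
    pl <- correlation_vs_distance(vv, "linear", h16$tads)
    ct <- correlation_length(pt, 0.2)
    cl <- correlation_length(pl, 0.2)
    as.numeric(ct) - as.numeric(cl)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("correlation length interpolates, censors and flags", {
  p <- structure(
    data.frame(distance = 1:2, correlation = c(1, 0),
               n_pairs = c(10, 10), mean_separation = c(1e6, 3e6)),
    class = c("correlation_profile", "data.frame"))
  r <- correlation_length(p, 0.2)
  expect_equal(as.numeric(r), 2.6e6)
  expect_equal(attr(r, "flag"), "ok")
  # never below threshold -> censored at max separation
  p$correlation <- c(0.5, 0.5)
  r2 <- correlation_length(p, 0.2)
  expect_equal(as.numeric(r2), 3e6)
  expect_equal(attr(r2, "flag"), "censored")
  # impossible threshold -> 0, flagged
  r3 <- correlation_length(p, 1.1)
  expect_equal(as.numeric(r3), 0)
  expect_equal(attr(r3, "flag"), "below_threshold")
})

test_that("random neighbour trees are structurally valid nulls", {
  ens <- random_neighbour_trees(10, 30, seed = 1)
  expect_length(ens, 30)
  for (tr in ens[1:5]) {
    expect_equal(tr$K, 10L)
    expect_equal(nrow(tr$merge), 9L)        # same node count
    expect_equal(tr$span[9, ], c(1L, 10L))  # root spans all, order kept
  }
  # ensemble visits more than one topology
  expect_gt(length(unique(vapply(ens, span_key, character(1)))), 1)
  # maximal observed correlation attains the smallest p-value wherever
  # the null cannot reach 1 (i.e. at distances with >= 3 pairs; with 2
  # pairs any correlation is exactly +-1)
  K <- 12
  h <- plant_hierarchy(K, seed = 2)
  set.seed(1)
  v <- rnorm(K)
  td <- tree_distances(h$tree)
  obs <- correlation_vs_distance(v, td, h$tads)
  obs$correlation[] <- 1  # by construction above any non-degenerate null
  ens2 <- random_neighbour_trees(K, 50, 3)
  pv <- correlation_pvalue(v, h$tads, obs, ens2)
  min_pairs <- vapply(pv$distance, function(d) {
    min(vapply(ens2, function(tr) {
      sum(tree_distances(tr) == d & upper.tri(td))
    }, numeric(1)))
  }, numeric(1))
  # no random tree can reach the observed value there, so p is at the
  # pseudocount floor 1/(n_valid_trees + 1)
  expect_true(all(pv$p[min_pairs >= 3] < 1 / 40))
})

test_that("PC1 compartments recover a planted checkerboard", {
  # two-block checkerboard on top of uniform decay
  nb <- 40
  lab <- rep(c("A", "B"), each = 4, length.out = nb)
  base <- outer(1:nb, 1:nb, function(i, j) 1 / (abs(i - j) + 1))
  chk <- outer(lab, lab, function(a, b) ifelse(a == b, 1.6, 0.6))
  m <- contact_matrix(base * chk, bin_size = 1e5)
  cp <- compartments_pc1(m, reference = as.numeric(lab == "A"))
  expect_equal(cp$label, lab)
  # flipping the phase flips labels, not scores' magnitude
  chk2 <- outer(lab, lab, function(a, b) ifelse(a == b, 0.6, 1.6))
  m2 <- contact_matrix(base * chk2, bin_size = 1e5)
  cp2 <- compartments_pc1(m2)
  expect_true(all(cp2$label == lab) || all(cp2$label == ifelse(lab == "A", "B", "A")))
  expect_equal(abs(cp2$score), abs(compartments_pc1(m2)$score))
  # uniform matrix: zero scores, labels flagged unreliable
  expect_warning(cpu <- compartments_pc1(contact_matrix(matrix(1, 10, 10),
                                                        bin_size = 1e5)),
                 "unreliable")
  expect_true(all(cpu$score == 0))
  expect_false(attr(cpu, "reliable"))
  # rank-0 matrix errors
  expect_error(compartments_pc1(contact_matrix(matrix(0, 10, 10),
                                               bin_size = 1e5)),
               "degenerate")
})

test_that("co-compartment frequency tracks labels along the tree", {
  h <- plant_hierarchy(8, seed = 1, shape = "balanced")
  # all-A: frequency 1 everywhere
  cc <- co_compartment_vs_tree(h$tree, rep("A", 8))
  expect_true(all(cc$freq_tree == 1, na.rm = TRUE))
  # alternating labels on a balanced tree: siblings always differ
  cc2 <- co_compartment_vs_tree(h$tree, rep(c("A", "B"), 4))
  expect_equal(cc2$freq_tree[cc2$distance == 1], 0)
  # random labels average to 0.5
  fr <- vapply(1:200, function(s) {
    set.seed(s)
    cc3 <- co_compartment_vs_tree(h$tree, sample(c("A", "B"), 8, TRUE))
    mean(cc3$freq_tree, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 0.05)
})

test_that("boundary profiles peak at planted boundary spikes", {
  h <- plant_hierarchy(24, seed = 4, mean_tad_size = 1e6)
  tr <- build_metatad_tree(
    tad_contact_matrix(simulate_contact_matrix(h), h$tads), tads = h$tads)
  bs <- h$bin_size
  nb <- max(h$tads$end) / bs
  track <- data.frame(chrom = "chrS", start = (0:(nb - 1)) * bs,
                      end = (1:nb) * bs, value = 0)
  # spike at every TAD boundary bin
  bnd_bins <- h$tads$start[-1] / bs
  track$value[c(bnd_bins, bnd_bins + 1)] <- 1
  bp <- boundary_profiles(track, h$tads, tr, flank = 4e5,
                          size_range = range(tr$d))
  tadp <- bp[bp$class == "TAD", ]
  expect_equal(tadp$mean[which.max(tadp$mean)],
               max(tadp$mean))
  inner <- abs(tadp$offset) < 1e5
  expect_true(all(tadp$mean[inner] >= max(tadp$mean[!inner])))
  # metaTAD boundaries are a subset of TAD boundaries
  meta_b <- unique(unlist(lapply(which(tr$d >= min(tr$d)), function(j) {
    c(h$tads$start[tr$span[j, 1]], h$tads$end[tr$span[j, 2]])
  })))
  expect_true(all(meta_b %in% c(h$tads$start, h$tads$end)))
  # constant track -> flat profile with shrinking CI
  track$value <- 5
  bp2 <- boundary_profiles(track, h$tads, tr, flank = 4e5,
                           size_range = range(tr$d))
  expect_true(all(bp2$mean == 5))
  expect_true(all(bp2$hi - bp2$lo == 0))
})

test_that("LAD-transition coincidence scores hits and calibrates p", {
  lads <- data.frame(start = c(1e6, 5e6), end = c(3e6, 8e6))
  trans <- c(1e6, 3e6, 5e6, 8e6)
  # boundaries exactly at transitions: fraction 1; with window 0 no
  # continuous circular shift can reproduce the alignment, so p is minimal
  r <- lad_transition_coincidence(trans, lads, chrom_length = 1e7,
                                  window = 0, n_perm = 200, seed = 1)
  expect_equal(r$fraction, 1)
  expect_equal(r$p, 1 / 201)
  # with a wide window, near-zero shifts keep the alignment and p grows
  rw <- lad_transition_coincidence(trans, lads, chrom_length = 1e7,
                                   window = 1e5, n_perm = 200, seed = 1)
  expect_equal(rw$fraction, 1)
  expect_lt(rw$p, 0.05)
  # window 0 with off-by-one boundaries: fraction 0
  r0 <- lad_transition_coincidence(trans + 5e4, lads, 1e7, window = 0,
                                   n_perm = 10, seed = 1)
  expect_equal(r0$fraction, 0)
  # no transitions
  r1 <- lad_transition_coincidence(trans, data.frame(start = numeric(),
                                                     end = numeric()), 1e7)
  expect_equal(r1$p, 1)
})
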