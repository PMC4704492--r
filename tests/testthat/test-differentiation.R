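test_that("cophenetic correlation matches hand and brute-force values", {
  # identical trees correlate perfectly
  h <- plant_hierarchy(12, seed = 1)
  expect_equal(cophenetic_correlation(h$tree, h$tree), 1.0)

  # 4-leaf hand example: ((1,2),(3,4)) vs (((1,2),3),4)
  ta <- metatad_tree(rbind(c(-1, -2), c(-3, -4), c(1, 2)))
  tb <- metatad_tree(rbind(c(-1, -2), c(1, -3), c(2, -4)))
  expect_equal(cophenetic_correlation(ta, tb), ref_cophenetic(ta, tb))
  expect_equal(cophenetic_correlation(ta, tb), 8 / sqrt(136))
  expect_equal(round(cophenetic_correlation(ta, tb), 2), 0.69)

  # symmetric in its arguments
  expect_equal(cophenetic_correlation(ta, tb),
               cophenetic_correlation(tb, ta))

  # exhaustive: all contiguous binary trees with <= 6 leaves against the
  # brute-force reference; correlation 1 iff identical topology
  for (K in c(4, 6)) {
    trees <- lapply(enumerate_contiguous_trees(K), metatad_tree)
    for (i in seq_along(trees)) {
      js <- if (K == 4) seq_along(trees) else
        unique(c(i, sample.int(length(trees), 6)))
      for (j in js) {
        r <- suppressWarnings(cophenetic_correlation(trees[[i]], trees[[j]]))
        expect_equal(r, suppressWarnings(ref_cophenetic(trees[[i]], trees[[j]])))
        if (!is.na(r)) {
          expect_equal(abs(r - 1) < 1e-12,
                       span_key(trees[[i]]) == span_key(trees[[j]]))
        }
      }
    }
  }

  # a tree against label-reshuffled copies scores below identity
  rt <- random_neighbour_trees(10, 1, seed = 5)[[1]]
  rs <- vapply(1:30, function(s) {
    other <- random_neighbour_trees(10, 1, seed = 100 + s)[[1]]
    cophenetic_correlation(rt, other)
  }, numeric(1))
  expect_lt(mean(rs), 1)
  expect_error(cophenetic_correlation(ta, tb,
               shared = data.frame(id_a = 1:2, id_b = 1:2)), "shared")
})

test_that("local tree change localizes a planted sibling swap", {
  # identical trees: raw 0 everywhere, degenerate z flagged
  h <- plant_hierarchy(8, seed = 2)
  expect_warning(ltc0 <- local_tree_change(h$tree, h$tree), "degenerate")
  expect_true(all(ltc0$raw == 0))

  # balanced 16-leaf tree with one rotated 4-leaf node
  hb <- plant_hierarchy(16, seed = 3, noise = "none", shape = "balanced")
  node <- which(hb$tree$n == 4)[1]
  pr <- simulate_timepoint_pair(hb, rewiring_plan(node), expr_noise_sd = 0)
  ltc <- local_tree_change(hb$tree, pr$hierarchy_b$tree)
  affected <- hb$tree$span[node, 1]:hb$tree$span[node, 2]
  expect_true(all(ltc$raw[affected] > 0))
  expect_true(all(ltc$raw[-affected] == 0))
  # z-scores standardized over the scored set
  expect_equal(mean(ltc$z), 0)
  expect_equal(sd(ltc$z), 1)
  expect_setequal(which(ltc$changed_z), affected)
})

test_that("expression change needs both fold and absolute criteria", {
  # background TADs pin the IQR of |diff| at 8, so that IQR/4 = 2
  bg_base <- c(rep(0, 10), rep(10, 8))
  bg_after <- c(rep(0, 10), rep(18, 8))
  base <- c(10, 0.1, 10, bg_base)
  after <- c(20, 0.3, 13, bg_after)
  calls <- classify_expression_change(base, after)
  expect_equal(attr(calls, "iqr_threshold"), 2)
  expect_equal(calls$class[1], "up")         # fold 2, diff 10: both pass
  expect_equal(calls$class[2], "unchanged")  # fold ~2.6 but diff 0.2 < 2
  expect_equal(calls$class[3], "unchanged")  # diff 3 > 2 but fold 1.3
  expect_equal(calls$class[4], "unchanged")  # 0 -> 0, both zero
  # down direction
  calls2 <- classify_expression_change(after, base)
  expect_equal(calls2$class[1], "down")
  expect_error(classify_expression_change(c(-1, 2), c(1, 2)))
})

test_that("jaccard index is exact, symmetric and fragmentation-invariant", {
  iv <- function(s, e, chrom = "chr1") data.frame(chrom = chrom, start = s,
                                                  end = e)
  a <- iv(0, 10); b <- iv(5, 15)
  expect_equal(jaccard_overlap(a, b), 5 / 15)
  expect_equal(jaccard_overlap(b, a), 5 / 15)
  expect_equal(jaccard_overlap(a, a), 1.0)
  expect_equal(jaccard_overlap(a, iv(20, 30)), 0.0)
  # fragmentation invariance
  a_frag <- iv(c(0, 3, 7), c(3, 7, 10))
  expect_equal(jaccard_overlap(a_frag, b), 5 / 15)
  # multi-chromosome accumulation
  a2 <- rbind(iv(0, 10), iv(0, 10, "chr2"))
  b2 <- rbind(iv(5, 15), iv(0, 10, "chr2"))
  expect_equal(jaccard_overlap(a2, b2), (5 + 10) / (15 + 10))
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  expect_warning(j0 <- jaccard_overlap(empty, empty), "empty")
  expect_true(is.na(j0))
})

test_that("circular permutation preserves coverage and calibrates p", {
  iv <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  lens <- c(chr1 = 100)
  a <- iv(c(0, 30, 60), c(10, 45, 80))
  # coverage and interval lengths preserved under wrapping shifts
  for (off in c(5, 55, 95)) {
    sh <- metatadr:::shift_intervals(a, off, 100)
    expect_equal(sum(sh$end - sh$start), sum(a$end - a$start))
  }
  # self-overlap at 50% coverage: no shift can beat it
  r <- circular_permutation_test(a, a, lens, n_perm = 200, seed = 1)
  expect_equal(r$jaccard, 1)
  expect_equal(r$p, 1 / 201)
  expect_true(all(r$null <= 1))
  expect_error(circular_permutation_test(a, a, lens, n_perm = 0), "n_perm")
})

test_that("change region sets combine the three call tracks", {
  tads <- tad_set((0:5) * 1e6, (1:6) * 1e6)
  ltc <- data.frame(id_a = 1:6, id_b = 1:6,
                    raw = c(2, 0, 0, 0, 1.5, 0),
                    z = c(2, -0.5, -0.5, -0.5, 1.2, -0.5),
                    changed_z = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
                    changed_raw = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expr <- data.frame(diff = c(5, -5, 0, 0, 1, 0), fold = c(2, 2, 1, 1, 3, 1),
                     class = c("up", "down", "unchanged", "unchanged",
                               "up", "unchanged"))
  comp_a <- c(0.8, 0.8, 0.2, 0.6, 0.4, NA)
  comp_b <- c(0.7, 0.2, 0.3, 0.7, 0.1, 0.5)
  rs <- change_region_sets(tads, ltc, expr, comp_a, comp_b)
  expect_equal(rs$tree_change$start, c(0e6, 4e6))
  expect_equal(nrow(rs$tree_conserved), 4)
  expect_equal(rs$expr_up$start, c(0e6, 4e6))
  # 0.8 -> 0.7 stays A (10% < 25%); 0.8 -> 0.2 transitions; NA excluded
  expect_equal(rs$stays_A$start, c(0e6, 3e6))
  expect_equal(rs$AB_transition$start, c(1e6, 4e6))
  expect_false(5e6 %in% c(rs$stays_A$start, rs$stays_B$start,
                          rs$AB_transition$start))
})

test_that("coherent-change enrichment detects planted coherence", {
  h <- plant_hierarchy(16, seed = 4, shape = "balanced")
  # all unchanged: coherence 1, null also 1, p ~ 1
  cls <- rep("unchanged", 16)
  ce <- coherent_change_enrichment(h$tree, h$tree, cls, n_perm = 50)
  expect_true(all(ce$coherent == 1))
  expect_true(all(ce$null_mean == 1))
  expect_true(all(ce$p > 0.9))
  # iid uniform labels: coherent fraction ~ 1/3 over seeds
  fr <- vapply(1:200, function(s) {
    set.seed(s)
    cl <- sample(c("up", "down", "unchanged"), 16, TRUE)
    ce2 <- coherent_change_enrichment(h$tree, h$tree, cl, n_perm = 1,
                                      seed = s)
    mean(ce2$coherent)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 1 / 3), 0.05)
  # planted coherent subtree: enrichment at distance 1, significant
  node <- which(h$tree$n == 8)[1]
  ids <- h$tree$span[node, 1]:h$tree$span[node, 2]
  set.seed(11)
  cl3 <- rep("unchanged", 16); cl3[ids] <- "up"
  cl3[setdiff(1:16, ids)] <- sample(c("up", "down", "unchanged"),
                                    16 - length(ids), TRUE)
  ce3 <- coherent_change_enrichment(h$tree, h$tree, cl3, n_perm = 200,
                                    seed = 1)
  expect_gt(ce3$coherent[ce3$distance == 1],
            ce3$null_mean[ce3$distance == 1])
})
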