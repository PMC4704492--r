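test_that("presets define the documented site layouts", {
  m_tad <- sbs_model("tad", n_beads = 100)
  expect_equal(sum(m_tad$pattern == 3), 0)          # no blue sites
  expect_equal(sum(m_tad$pattern == 1), 25)
  expect_equal(sum(m_tad$pattern == 2), 25)
  expect_true(all(which(m_tad$pattern == 1) <= 50))
  expect_equal(m_tad$binders[3], 0L)

  m_meta <- sbs_model("metatad", n_beads = 100)
  # blue present in both halves; red/green layout identical to TAD-only
  expect_gt(sum(m_meta$pattern[1:50] == 3), 0)
  expect_gt(sum(m_meta$pattern[51:100] == 3), 0)
  expect_identical(which(m_meta$pattern == 1), which(m_tad$pattern == 1))
  expect_identical(which(m_meta$pattern == 2), which(m_tad$pattern == 2))
  expect_error(sbs_model("tad", n_beads = 5000, box = 10), "box")

  # YAML round-trip of a model configuration
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("preset: metatad", "n_beads: 60", "box: 20",
               "binders: [5, 5, 8]", "energies: [2.0, 2.0, 3.0]",
               "seed: 3"), f)
  my <- sbs_model_from_yaml(f)
  expect_identical(my$pattern, sbs_model("metatad", n_beads = 60,
                                         box = 20)$pattern)
  expect_equal(my$binders, c(5L, 5L, 8L))
  writeLines(c("preset: tad", "bogus: 1"), f)
  expect_error(sbs_model_from_yaml(f), "unknown config")
})

test_that("trajectories are seed-deterministic", {
  m <- sbs_model("metatad", n_beads = 60, box = 16,
                 binders = c(10, 10, 10), seed = 3)
  t1 <- suppressWarnings(sbs_run(m, 2e5, sample_every = 2e4))
  t2 <- suppressWarnings(sbs_run(m, 2e5, sample_every = 2e4))
  expect_identical(t1$beads, t2$beads)
  expect_identical(t1$sample_energy, t2$sample_energy)
  t3 <- suppressWarnings(sbs_run(m, 2e5, sample_every = 2e4, seed = 99))
  expect_false(identical(t1$beads, t3$beads))
})

test_that("energy bookkeeping is exact against full recomputation", {
  for (s in 1:5) {
    m <- sbs_model("metatad", n_beads = 80, box = 16,
                   binders = c(15, 15, 15), energies = c(2.1, 1.7, 2.9),
                   seed = s)
    tr <- suppressWarnings(sbs_run(m, 5e5, sample_every = 5e4))
    expect_lt(abs(tr$final_energy_incremental - tr$final_energy_recomputed),
              1e-9)
    # independent R-visible oracle on the last sampled state
    k <- length(tr$beads)
    bcol <- rep.int(1:3, m$binders)
    e_ref <- metatadr:::cpp_energy_full(tr$beads[[k]], m$pattern,
                                        tr$binders[[k]], bcol, m$energies)
    expect_equal(tr$sample_energy[k], e_ref)
  }
})

test_that("geometric observables match closed forms on fixtures", {
  # straight rod: Rg^2 = (n^2 - 1) / 12
  n <- 25
  rod <- cbind(0:(n - 1), 0L, 0L)
  expect_equal(metatadr:::gyration_radius(rod), sqrt((n^2 - 1) / 12))
  # 3x3x3 bead cube occupies 27 hull sites
  cube <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  expect_equal(metatadr:::cpp_hull_sites(cube), 27)
  # hull from its 8 corners alone is identical
  corners <- as.matrix(expand.grid(c(0L, 2L), c(0L, 2L), c(0L, 2L)))
  expect_equal(metatadr:::cpp_hull_sites(corners), 27)
  # degenerate rank: rod hull is its own sites
  expect_equal(metatadr:::cpp_hull_sites(rod), n)
  # contact threshold below the minimum pair distance: empty matrix
  sparse <- cbind(seq(0, 40, by = 4), 0L, 0L)
  cm <- metatadr:::cpp_contact_matrix(sparse, 2^2)
  diag(cm) <- 0
  expect_true(all(cm == 0))
})

test_that("zero binders reproduce self-avoiding-walk statistics", {
  # Rg scaling over chain lengths: slope of log Rg^2 vs log N ~ 2 * 0.588
  lens <- c(40, 80, 160)
  rg2 <- vapply(lens, function(n) {
    m <- sbs_model("tad", n_beads = n, box = 64, binders = c(0, 0, 0),
                   seed = 1)
    tr <- suppressWarnings(sbs_run(m, 3e7, sample_every = 3e5))
    mean(vapply(tr$beads[tr$eq_samples],
                function(p) metatadr:::gyration_radius(p)^2, numeric(1)))
  }, numeric(1))
  slope <- coef(lm(log(rg2) ~ log(lens)))[2]
  expect_gt(slope, 2 * 0.588 - 0.12)
  expect_lt(slope, 2 * 0.588 + 0.12)
})

test_that("binding collapses the chain and E = 0 decouples binders", {
  base <- sbs_model("tad", n_beads = 80, box = 32, binders = c(0, 0, 0),
                    seed = 2)
  tr0 <- suppressWarnings(sbs_run(base, 1e7, sample_every = 1e5))
  rg0 <- mean(vapply(tr0$beads[tr0$eq_samples],
                     metatadr:::gyration_radius, numeric(1)))
  # strong single-colour binding: Rg drops below the unbound value
  strong <- sbs_model("tad", n_beads = 80, box = 32,
                      binders = c(60, 60, 0), energies = c(4, 4, 4),
                      seed = 2)
  tr1 <- suppressWarnings(sbs_run(strong, 2e7, sample_every = 2e5))
  rg1 <- mean(vapply(tr1$beads[tr1$eq_samples],
                     metatadr:::gyration_radius, numeric(1)))
  expect_lt(rg1, rg0 * 0.8)
  # E = 0 with binders: chain statistics match the zero-binder ensemble
  nul <- sbs_model("tad", n_beads = 80, box = 32, binders = c(30, 30, 0),
                   energies = c(0, 0, 0), seed = 2)
  tr2 <- suppressWarnings(sbs_run(nul, 1e7, sample_every = 1e5))
  rg2 <- mean(vapply(tr2$beads[tr2$eq_samples],
                     metatadr:::gyration_radius, numeric(1)))
  expect_lt(abs(rg2 - rg0) / rg0, 0.25)
  expect_equal(tr2$final_energy_incremental, 0)
})

test_that("toy chain samples the Boltzmann distribution over energy levels", {
  # 4-bead chain with one red site and one red binder in a 3^3 box:
  # enumerate every (chain, binder) state, compare MC energy-level
  # frequencies with exact Boltzmann weights
  L <- 3L
  E <- 1.3
  pattern <- c(0L, 1L, 0L, 0L)
  # --- exact enumeration (independent of the C++ engine) ---
  sites <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))
  nbr <- function(a, b) sum(abs(a - b)) == 1
  chains <- list()
  grow <- function(path) {
    if (length(path) == 4) {
      chains[[length(chains) + 1L]] <<- path
      return(invisible())
    }
    last <- sites[path[length(path)], ]
    for (s in seq_len(nrow(sites))) {
      if (s %in% path) next
      if (nbr(last, sites[s, ])) grow(c(path, s))
    }
  }
  for (s0 in seq_len(nrow(sites))) grow(s0)
  lev <- c(`0` = 0, `1` = 0)  # state counts by energy level (0 or -E)
  for (ch in chains) {
    bead2 <- sites[ch[2], ]
    free <- setdiff(seq_len(nrow(sites)), ch)
    for (b in free) {
      bound <- nbr(bead2, sites[b, ])
      w <- if (bound) exp(E) else 1
      lev[if (bound) "1" else "0"] <- lev[if (bound) "1" else "0"] + w
    }
  }
  p_bound_exact <- lev["1"] / sum(lev)
  # --- MC estimate ---
  m <- sbs_model("tad", n_beads = 4, box = L, binders = c(1, 0, 0),
                 energies = c(E, 0, 0), seed = 5)
  m$pattern <- pattern
  tr <- suppressWarnings(sbs_run(m, 4e6, sample_every = 400))
  p_bound_mc <- mean(tr$sample_energy[tr$eq_samples] < 0)
  expect_lt(abs(p_bound_mc - p_bound_exact), 0.02)
})

test_that("domain structure appears in both presets' contact maps", {
  ex <- suppressWarnings(sbs_metatad_experiment(
    n_beads = 100, box = 20, binders = c(30, 30, 30),
    energies = c(2.5, 2.5, 2.5), n_steps = 6e6, init = "saw", seed = 4))
  for (o in list(ex$tad, ex$metatad)) {
    # red and green blocks interact internally far above cross level
    expect_gt(o$cross_contact[1, 1], 5 * o$cross_contact[1, 2])
    expect_gt(o$cross_contact[2, 2], 5 * o$cross_contact[1, 2])
  }
  expect_true(is.finite(ex$percent_volume_reduction))
  expect_true(ex$blue_engaged_percent >= 0 && ex$blue_engaged_percent <= 100)
})
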