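#' Parameters for the membrane lattice simulation
#'
#' A conserved order-parameter 2D Ising model on an L x L square lattice
#' with periodic boundaries. Spins S = +1 mark components preferring
#' ordered membrane regions, S = -1 disordered ones. Most sites are
#' unspecified background; a few are labeled species: receptors and
#' kinases are ordered components (S = +1), phosphatases disordered
#' (S = -1). Dynamics are Metropolis spin exchanges (Kawasaki: the order
#' parameter and all species counts are conserved); an accepted exchange
#' can fire phosphorylation reactions on adjacent receptors. One pixel
#' represents a 2 nm x 2 nm membrane patch and one sweep (2 L^2 proposed
#' exchanges) roughly 1 us of diffusive time.
#'
#' @param L lattice side (default 256).
#' @param n_receptors,n_kinases,n_phosphatases labeled species counts
#'   (defaults 50, 100, 100).
#' @param ordered_fraction fraction of background sites assigned S = +1
#'   (default 0.5; 0 gives the uniform, all-disordered membrane).
#' @param t_ratio temperature as a multiple of the critical temperature
#'   `Tc = 2/ln(1+sqrt(2))` (default 1.05).
#' @param p_phos probability a receptor placed next to a kinase is
#'   phosphorylated (default 0.001).
#' @param p_dephos probability a receptor placed next to a phosphatase is
#'   dephosphorylated (default 1).
#' @param p_rbk probability a receptor placed next to a phosphorylated
#'   receptor is phosphorylated, when `rbk` is TRUE (default 0.001).
#' @param rbk enable receptor-bound-kinase positive feedback.
#' @param field `"none"`, `"receptor"` (strong circular field acting only
#'   on receptors; clusters them) or `"domain"` (weak circular field acting
#'   on all spins; stabilizes an ordered domain).
#' @param field_radius_px field disc radius (default 16 for the receptor
#'   field; use 24 or 48 for domain fields).
#' @param field_magnitude coupling-unit field strength inside the disc.
#'   The domain field uses 1 (a single interaction between components);
#'   the receptor field strength is only required to be "strong": the
#'   default 20 makes the field energy dominate the entropic cost of
#'   confinement (the outside/inside area ratio), keeping essentially all
#'   receptors inside the disc.
#' @param pixel_nm physical pixel size (2 nm).
#' @param sweep_time_s physical duration of one sweep (1e-6 s).
#' @return a `sim_params` list.
#' @export
sim_params <- function(L = 256, n_receptors = 50, n_kinases = 100,
                       n_phosphatases = 100, ordered_fraction = 0.5,
                       t_ratio = 1.05, p_phos = 0.001, p_dephos = 1,
                       p_rbk = 0.001, rbk = TRUE,
                       field = c("receptor", "none", "domain"),
                       field_radius_px = NULL, field_magnitude = NULL,
                       pixel_nm = 2, sweep_time_s = 1e-6) {
  field <- match.arg(field)
  if (is.null(field_radius_px))
    field_radius_px <- switch(field, receptor = 16, domain = 24, none = 0)
  if (is.null(field_magnitude))
    field_magnitude <- switch(field, receptor = 20, domain = 1, none = 0)
  probs <- c(p_phos, p_dephos, p_rbk)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (ordered_fraction < 0 || ordered_fraction > 1)
    stop("ordered_fraction must lie in [0, 1]")
  ns <- n_receptors + n_kinases + n_phosphatases
  if (ns > L^2) stop("species counts exceed the lattice size")
  structure(list(L = as.integer(L), n_receptors = as.integer(n_receptors),
                 n_kinases = as.integer(n_kinases),
                 n_phosphatases = as.integer(n_phosphatases),
                 ordered_fraction = ordered_fraction, t_ratio = t_ratio,
                 p_phos = p_phos, p_dephos = p_dephos, p_rbk = p_rbk,
                 rbk = rbk, field = field,
                 field_radius_px = field_radius_px,
                 field_magnitude = field_magnitude,
                 pixel_nm = pixel_nm, sweep_time_s = sweep_time_s),
            class = "sim_params")
}

#' Exact critical temperature of the square-lattice Ising model
#' @return `2 / log(1 + sqrt(2))` (coupling units, kB = J = 1).
#' @export
ising_tc <- function() 2 / log(1 + sqrt(2))

species_codes <- c(background = 0L, receptor = 1L, kinase = 2L,
                   phosphatase = 3L)

field_raster_ <- function(L, radius, magnitude) {
  if (radius <= 0 || magnitude == 0) return(matrix(0, L, L))
  ctr <- (L + 1) / 2
  d2 <- outer((seq_len(L) - ctr)^2, (seq_len(L) - ctr)^2, "+")
  matrix(ifelse(d2 <= radius^2, magnitude, 0), L, L)
}

#' Initialize a lattice state
#'
#' Species are placed uniformly at random; receptors and kinases carry
#' S = +1, phosphatases S = -1, and background spins are assigned so the
#' requested ordered background fraction holds exactly (up to rounding).
#' All receptors start dephosphorylated.
#'
#' @param params a [sim_params()].
#' @param seed integer seed (same seed, same initial state).
#' @return an `ising_state`: list with `spin` and `species` matrices,
#'   `phospho` flags (length L^2, TRUE only on receptor sites), `beta`,
#'   the `field` raster and `params`.
#' @export
init_state <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  L <- params$L
  N <- L^2
  nR <- params$n_receptors; nK <- params$n_kinases; nP <- params$n_phosphatases
  nbg <- N - nR - nK - nP
  n_up_bg <- round(params$ordered_fraction * nbg)
  sites <- sample.int(N)
  species <- integer(N)
  species[sites[seq_len(nR)]] <- species_codes[["receptor"]]
  species[sites[nR + seq_len(nK)]] <- species_codes[["kinase"]]
  species[sites[nR + nK + seq_len(nP)]] <- species_codes[["phosphatase"]]
  spin <- integer(N)
  spin[species == 1L | species == 2L] <- 1L
  spin[species == 3L] <- -1L
  bg <- sites[(nR + nK + nP + 1):N]
  spin[bg] <- c(rep(1L, n_up_bg), rep(-1L, nbg - n_up_bg))
  fld <- field_raster_(L, params$field_radius_px, params$field_magnitude)
  structure(list(spin = matrix(spin, L, L),
                 species = matrix(species, L, L),
                 phospho = rep(FALSE, N),
                 beta = 1 / (params$t_ratio * ising_tc()),
                 field = fld,
                 field_type = match(params$field,
                                    c("none", "receptor", "domain")) - 1L,
                 params = params),
            class = "ising_state")
}

#' Lattice Hamiltonian
#'
#' `H = -sum_<ij> S_i S_j - sum_i R_i Phi_i` (receptor field) or
#' `- sum_i S_i Phi_i` (domain field); nearest-neighbor bonds counted
#' once, periodic boundaries.
#'
#' @param state an [init_state()] result.
#' @return energy in coupling units.
#' @export
hamiltonian <- function(state) {
  stopifnot(inherits(state, "ising_state"))
  ising_energy_cpp(state$spin, state$species, state$field, state$field_type)
}

#' Advance a lattice state by Monte Carlo exchange sweeps
#'
#' Proposes `2 L^2` spin exchanges per sweep, either nonlocal (two random
#' distinct pixels; fast equilibration) or local (a pixel and a random
#' nearest neighbor; diffusive dynamics). Exchanges move spin, species
#' identity and phosphorylation flag together; acceptance is Metropolis
#' on the energy change. On accepted, state-changing moves the reaction
#' rules run on the exchanged sites and their neighborhoods (see
#' [sim_params()] probabilities).
#'
#' @param state an `ising_state`.
#' @param sweeps number of sweeps.
#' @param mode `"local"` or `"nonlocal"`.
#' @param reactions run phosphorylation reactions (default TRUE).
#' @param record_every record the phospho fraction (and energy) every this
#'   many sweeps (0 = no trace).
#' @param snapshot_every keep full lattice snapshots at this cadence
#'   (0 = none).
#' @param seed integer seed for the simulator's own RNG stream.
#' @return the updated `ising_state`, with `trace` (data.frame `sweep`,
#'   `phospho_fraction`, `energy`) and `snapshots` attached.
#' @export
mc_run <- function(state, sweeps, mode = c("local", "nonlocal"),
                   reactions = TRUE, record_every = 1, snapshot_every = 0,
                   seed = 1) {
  stopifnot(inherits(state, "ising_state"))
  mode <- match.arg(mode)
  p <- state$params
  out <- ising_run_cpp(state$spin, state$species, state$phospho,
                       state$beta, state$field, state$field_type,
                       p$p_phos, p$p_dephos, p$p_rbk, p$rbk, reactions,
                       as.integer(sweeps), mode == "local",
                       as.integer(record_every), as.integer(snapshot_every),
                       as.double(seed))
  state$spin <- out$spin
  state$species <- out$species
  state$phospho <- out$phospho
  if (record_every > 0) {
    sw <- seq(record_every, sweeps, by = record_every)
    state$trace <- data.frame(sweep = sw, phospho_fraction = out$trace_py,
                              energy = out$trace_energy)
  }
  state$snapshots <- out$snapshots
  state$accepted <- out$accepted
  state
}

#' Run the full simulation protocol
#'
#' Equilibrates the membrane (with any applied field already acting) using
#' fast nonlocal exchanges and no reactions, so that the receptor cluster
#' or stabilized domain is formed by t = 0 with all receptors
#' dephosphorylated. Production then runs diffusive (local) dynamics with
#' the reaction rules active, recording the receptor phosphorylation
#' fraction every sweep and lattice snapshots at the requested cadence.
#'
#' @param params a [sim_params()].
#' @param equil_sweeps nonlocal equilibration sweeps before t = 0.
#' @param sweeps production (local-move) sweeps.
#' @param snapshot_every snapshot cadence in sweeps (0 = none).
#' @param seed integer seed.
#' @return an `ising_state` after production, with `trace` and
#'   `snapshots`; `trace$time_s` gives physical time.
#' @export
run_simulation <- function(params, equil_sweeps = 1000, sweeps = 1000,
                           snapshot_every = 0, seed = 1) {
  state <- init_state(params, seed = seed)
  if (equil_sweeps > 0)
    state <- mc_run(state, equil_sweeps, mode = "nonlocal",
                    reactions = FALSE, record_every = 0, seed = seed * 2 + 1)
  state <- mc_run(state, sweeps, mode = "local", record_every = 1,
                  snapshot_every = snapshot_every, seed = seed * 2 + 2)
  state$trace$time_s <- state$trace$sweep * params$sweep_time_s
  state
}

#' Steady-state phosphorylation across membrane compositions
#'
#' Repeats [run_simulation()] for several ordered background fractions and
#' summarizes the steady-state receptor phosphorylation (mean over the
#' second half of the production trace), optionally with the
#' receptor/ordered-component cross-correlation of the final snapshot.
#'
#' @param params a [sim_params()] (its `ordered_fraction` is overridden).
#' @param fractions ordered background fractions to sweep.
#' @param seeds integer seeds; one run per seed per fraction.
#' @param equil_sweeps,sweeps as in [run_simulation()].
#' @param corr also compute the receptor vs ordered-spin correlation of
#'   the final state (logical).
#' @return data.frame with `fraction`, `seed`, `phospho_mean`, and (if
#'   `corr`) `c_receptor_ordered` (first-bin value).
#' @export
composition_sweep <- function(params, fractions = c(0.2, 0.5, 0.8),
                              seeds = 1:3, equil_sweeps = 1000,
                              sweeps = 1000, corr = FALSE) {
  rows <- list()
  for (fr in fractions) {
    pf <- params; pf$ordered_fraction <- fr
    feasible <- TRUE
    if (fr > 1 || fr < 0) feasible <- FALSE
    if (!feasible) { warning("infeasible fraction ", fr, "; skipped"); next }
    for (sd in seeds) {
      st <- run_simulation(pf, equil_sweeps = equil_sweeps, sweeps = sweeps,
                           seed = sd)
      tr <- st$trace$phospho_fraction
      half <- tr[(length(tr) %/% 2 + 1):length(tr)]
      row <- data.frame(fraction = fr, seed = sd, phospho_mean = mean(half))
      if (corr) {
        cc <- snapshot_crosscorr(list(st), "receptor", "ordered",
                                 r_max_nm = 40)
        row$c_receptor_ordered <- cc$C[1]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

species_raster_ <- function(snap, what) {
  if (what == "ordered") return((snap$spin + 1) / 2)
  if (what == "disordered") return((1 - snap$spin) / 2)
  code <- species_codes[[what]]
  (snap$species == code) * 1
}

#' Cross-correlation between species in simulation snapshots
#'
#' Rasters of two species (or spin classes) are cross-correlated with
#' periodic boundaries using the same radial machinery as the imaging
#' analysis, averaged over snapshots. To mimic finite optical resolution
#' the rasters can first be blurred with a Gaussian PSF, which is
#' equivalent to convolving the 2D correlation with the PSF
#' autocorrelation.
#'
#' @param snapshots list of snapshots (elements with `spin`, `species`), or
#'   of `ising_state`s (their final lattice is used).
#' @param what_a,what_b `"receptor"`, `"kinase"`, `"phosphatase"`,
#'   `"ordered"` or `"disordered"`.
#' @param blur_sigma_nm Gaussian PSF sd in nm (0 = unblurred).
#' @param dr_nm radial bin (default 2 nm = 1 pixel).
#' @param r_max_nm largest separation (default 100 nm).
#' @param pixel_nm lattice pixel size (default 2 nm).
#' @return a `corr_result` averaged over snapshots (counts and expected
#'   are summed; `C` is their ratio).
#' @export
snapshot_crosscorr <- function(snapshots, what_a = "receptor",
                               what_b = "kinase", blur_sigma_nm = 0,
                               dr_nm = 2, r_max_nm = 100, pixel_nm = 2) {
  snaps <- lapply(snapshots, function(s) {
    if (inherits(s, "ising_state")) list(spin = s$spin, species = s$species)
    else s
  })
  L <- nrow(snaps[[1]]$spin)
  mask <- roi_mask(matrix(TRUE, L, L), pixel_nm = pixel_nm)
  acc <- NULL
  for (s in snaps) {
    A <- species_raster_(s, what_a)
    B <- species_raster_(s, what_b)
    if (blur_sigma_nm > 0) {
      A <- blur_raster(A, blur_sigma_nm / pixel_nm, periodic = TRUE)
      B <- blur_raster(B, blur_sigma_nm / pixel_nm, periodic = TRUE)
    }
    imA <- structure(list(counts = A, pixel_nm = pixel_nm,
                          origin_nm = c(0, 0)), class = "recon_image")
    imB <- structure(list(counts = B, pixel_nm = pixel_nm,
                          origin_nm = c(0, 0)), class = "recon_image")
    cc <- crosscorr_fft(imA, imB, mask, dr_nm = dr_nm, r_max_nm = r_max_nm,
                        sigma_psf_nm = blur_sigma_nm, periodic = TRUE)
    if (is.null(acc)) {
      acc <- cc
    } else {
      acc$counts <- acc$counts + cc$counts
      acc$expected <- acc$expected + cc$expected
    }
  }
  acc$C <- acc$counts / acc$expected
  acc$dC_raw <- acc$dC_raw / sqrt(length(snaps))
  acc$dC1 <- acc$dC1 / sqrt(length(snaps))
  acc$meta$n_snapshots <- length(snaps)
  acc
}

#' Estimate the Ising critical temperature by Binder cumulant crossing
#'
#' Uses an auxiliary non-conserved single-spin-flip Metropolis sampler at
#' matched couplings: the magnetization Binder cumulant
#' `U_L = 1 - <m^4> / (3 <m^2>^2)` is computed on several small lattices
#' over a temperature grid, and the crossing points of successive
#' `U_L(T)` curves estimate the critical temperature, validating the
#' hard-coded [ising_tc()] constant.
#'
#' @param L_list lattice sides (default 16, 32, 64).
#' @param t_grid temperature grid spanning the transition.
#' @param equil_sweeps,meas_sweeps,thin sampling controls per (L, T).
#' @param seed integer seed.
#' @return list with `tc_hat` (mean of pairwise crossings), `crossings`,
#'   and `binder` (data.frame of U over the grid).
#' @export
estimate_tc <- function(L_list = c(16, 32, 64),
                        t_grid = seq(2.16, 2.38, by = 0.02),
                        equil_sweeps = 4000, meas_sweeps = 40000, thin = 2,
                        seed = 1) {
  rows <- list()
  for (L in L_list) {
    for (tt in t_grid) {
      r <- ising_binder_cpp(as.integer(L), tt, as.integer(equil_sweeps),
                            as.integer(meas_sweeps), as.integer(thin),
                            as.double(seed + 1000 * L + round(1e5 * tt)))
      rows[[length(rows) + 1]] <- data.frame(L = L, T = tt, m2 = r[1],
                                             m4 = r[2], U = r[3])
    }
  }
  binder <- do.call(rbind, rows)
  # Below the transition U_small < U_large (stronger finite-size
  # suppression of the cumulant on small lattices); above it the order
  # reverses as U -> 0 faster on large lattices. The crossing is the
  # negative-to-positive sign change of d(T) = U_small - U_large with the
  # steepest rise, located by linear interpolation inside that bracket.
  crossings <- numeric(0)
  for (i in seq_len(length(L_list) - 1)) {
    u1 <- binder[binder$L == L_list[i], ]
    u2 <- binder[binder$L == L_list[i + 1], ]
    d <- u1$U - u2$U
    tt <- u1$T
    br <- which(d[-length(d)] < 0 & d[-1] >= 0)
    if (!length(br)) {
      crossings <- c(crossings, tt[which.min(abs(d))])
      next
    }
    j <- br[which.max(d[br + 1] - d[br])]
    root <- tt[j] + (0 - d[j]) * (tt[j + 1] - tt[j]) / (d[j + 1] - d[j])
    crossings <- c(crossings, root)
  }
  list(tc_hat = mean(crossings), crossings = crossings, binder = binder)
}
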