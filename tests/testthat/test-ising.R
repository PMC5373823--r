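test_that("initial states have exact composition and reproduce by seed", {
  p <- sim_params(L = 64)
  st <- init_state(p, seed = 1)
  expect_equal(sum(st$species == 1), 50)
  expect_equal(sum(st$species == 2), 100)
  expect_equal(sum(st$species == 3), 100)
  # receptors/kinases ordered, phosphatases disordered
  expect_true(all(st$spin[st$species %in% 1:2] == 1))
  expect_true(all(st$spin[st$species == 3] == -1))
  # background split per the ordered fraction
  bg <- st$species == 0
  expect_equal(sum(st$spin[bg] == 1), round(0.5 * sum(bg)))
  expect_identical(init_state(p, seed = 1), st)
  expect_error(sim_params(L = 8, n_receptors = 100), "exceed")
  expect_error(sim_params(p_phos = 2), "probabilities")
})

test_that("the Hamiltonian reproduces closed-form energies", {
  p <- sim_params(L = 12, n_receptors = 0, n_kinases = 0,
                  n_phosphatases = 0, ordered_fraction = 1, field = "none")
  st <- init_state(p, seed = 1)
  expect_equal(hamiltonian(st), -2 * 12^2)   # ground state, 2 L^2 bonds
  st$spin <- outer(1:12, 1:12, function(i, j) ifelse((i + j) %% 2 == 0, 1L, -1L))
  expect_equal(hamiltonian(st), 2 * 12^2)    # checkerboard
  # a single receptor inside a field disc contributes -phi
  p2 <- sim_params(L = 12, n_receptors = 0, n_kinases = 0,
                   n_phosphatases = 0, ordered_fraction = 1,
                   field = "receptor", field_radius_px = 3,
                   field_magnitude = 7)
  st2 <- init_state(p2, seed = 1)
  base <- hamiltonian(st2)
  ctr <- (12 + 1) / 2
  st2$species[round(ctr), round(ctr)] <- 1L
  expect_equal(hamiltonian(st2), base - 7)
})

test_that("exchange dynamics conserve composition and magnetization", {
  p <- sim_params(L = 48, field = "receptor", field_radius_px = 8)
  st <- init_state(p, seed = 2)
  s0 <- sum(st$spin)
  for (mode in c("nonlocal", "local")) {
    out <- mc_run(st, 40, mode, seed = 3)
    expect_equal(sum(out$spin), s0)
    expect_equal(sum(out$species == 1), 50)
    expect_equal(sum(out$species == 2), 100)
    expect_equal(sum(out$species == 3), 100)
    # phospho flags live only on receptor sites
    expect_true(all(out$species[which(out$phospho)] == 1))
  }
  # determinism of the simulator stream
  expect_identical(mc_run(st, 25, "local", seed = 9)$spin,
                   mc_run(st, 25, "local", seed = 9)$spin)
})

test_that("reaction rules phosphorylate via kinases and clear via phosphatases", {
  # no kinases, no feedback: phosphorylation can only decay
  p <- sim_params(L = 32, n_receptors = 30, n_kinases = 0,
                  n_phosphatases = 60, rbk = FALSE, field = "none")
  st <- init_state(p, seed = 4)
  st$phospho[which(st$species == 1)] <- TRUE
  out <- mc_run(st, 100, "local", seed = 5)
  tr <- out$trace$phospho_fraction
  expect_true(all(diff(tr) <= 1e-12))
  expect_lt(tr[length(tr)], tr[1] + 1e-12)
  # kinases and no phosphatases with certain phosphorylation: all receptors
  # end up phosphorylated
  p2 <- sim_params(L = 32, n_receptors = 30, n_kinases = 60,
                   n_phosphatases = 0, p_phos = 1, rbk = FALSE,
                   field = "none")
  st2 <- init_state(p2, seed = 6)
  out2 <- mc_run(st2, 200, "local", seed = 7)
  expect_equal(tail(out2$trace$phospho_fraction, 1), 1)
  # p_phos = 0: nothing ever fires
  p3 <- sim_params(L = 32, p_phos = 0, p_rbk = 0, field = "none")
  out3 <- mc_run(init_state(p3, seed = 8), 50, "local", seed = 9)
  expect_true(all(out3$trace$phospho_fraction == 0))
})

test_that("kinase adjacency fires at the configured low probability", {
  # moderate-size run: the realized phosphorylation count over many
  # accepted receptor-kinase adjacencies should scale with p_phos
  p_lo <- sim_params(L = 48, n_receptors = 60, n_kinases = 200,
                     n_phosphatases = 0, p_phos = 0.0005, rbk = FALSE,
                     field = "none")
  p_hi <- p_lo; p_hi$p_phos <- 0.05
  n_lo <- sum(mc_run(init_state(p_lo, seed = 10), 30, "local",
                     seed = 11)$phospho)
  n_hi <- sum(mc_run(init_state(p_hi, seed = 10), 30, "local",
                     seed = 11)$phospho)
  expect_gt(n_hi, 3 * max(n_lo, 1))
})

test_that("local and nonlocal samplers draw from the same distribution", {
  # reaction-free dynamics at matched beta: energies after thinning agree
  p <- sim_params(L = 32, n_receptors = 0, n_kinases = 0,
                  n_phosphatases = 0, field = "none")
  sample_energy <- function(mode, seed) {
    st <- init_state(p, seed = seed)
    st <- mc_run(st, 800, mode, reactions = FALSE, record_every = 0,
                 seed = seed)
    e <- numeric(100)
    for (i in seq_along(e)) {
      st <- mc_run(st, 120, mode, reactions = FALSE, record_every = 0,
                   seed = seed + i)
      e[i] <- hamiltonian(st)
    }
    e
  }
  e_loc <- sample_energy("local", 21)
  e_non <- sample_energy("nonlocal", 22)
  expect_gt(stats::ks.test(e_loc, e_non)$p.value, 0.01)
})

test_that("the receptor field confines receptors and recruits kinases", {
  p <- sim_params(L = 96, field = "receptor")
  st <- run_simulation(p, equil_sweeps = 400, sweeps = 400, seed = 12)
  infield <- st$field != 0
  expect_gte(sum(st$species == 1 & infield) / 50, 0.9)
  # ordered components enrich inside the disc relative to the lattice mean
  frac_in <- mean(st$spin[infield] == 1)
  frac_all <- mean(st$spin == 1)
  expect_gt(frac_in, frac_all + 0.15)
})

test_that("snapshot correlations sort kinases in and phosphatases out", {
  p <- sim_params(L = 96, field = "receptor")
  st <- run_simulation(p, equil_sweeps = 400, sweeps = 600,
                       snapshot_every = 150, seed = 13)
  ck <- snapshot_crosscorr(st$snapshots, "receptor", "kinase",
                           r_max_nm = 40)
  cp <- snapshot_crosscorr(st$snapshots, "receptor", "phosphatase",
                           r_max_nm = 40)
  short <- 2:5   # 2-10 nm, skipping the excluded-volume zero bin
  expect_gt(mean(ck$C[short]), 1.2)
  expect_lt(mean(cp$C[short]), 0.8)
  # blur attenuates but preserves the sign
  ckb <- snapshot_crosscorr(st$snapshots, "receptor", "kinase",
                            blur_sigma_nm = 30, r_max_nm = 40)
  cpb <- snapshot_crosscorr(st$snapshots, "receptor", "phosphatase",
                            blur_sigma_nm = 30, r_max_nm = 40)
  expect_gt(mean(ckb$C[short]), 1)
  expect_lt(mean(ckb$C[short]), mean(ck$C[short]))
  expect_lt(mean(cpb$C[short]), 1)
  expect_gt(mean(cpb$C[short]), mean(cp$C[short]))
  # a species against itself at random placement: flat beyond exclusion
  p0 <- sim_params(L = 96, field = "none", t_ratio = 50)
  st0 <- run_simulation(p0, equil_sweeps = 50, sweeps = 50, seed = 14)
  c0 <- snapshot_crosscorr(list(st0), "kinase", "phosphatase",
                           r_max_nm = 40)
  expect_lt(abs(mean(c0$C[3:10], na.rm = TRUE) - 1), 0.25)
})

test_that("the composition sweep trends with ordered fraction", {
  p <- sim_params(L = 64, field = "receptor", field_radius_px = 12)
  sw <- composition_sweep(p, fractions = c(0.2, 0.8), seeds = 1:2,
                          equil_sweeps = 200, sweeps = 400)
  m <- tapply(sw$phospho_mean, sw$fraction, mean)
  expect_gt(m[["0.2"]], m[["0.8"]])
})
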