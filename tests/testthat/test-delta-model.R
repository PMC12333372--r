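models_under_test <- function() {
  list(
    mace = init_model("mace_like", tiny_mace_hp(), seed = 11,
                      species_codes = test_codes),
    dp = init_model("dp_like", tiny_dp_hp(), seed = 11,
                    species_codes = test_codes))
}

## exercise the full readout with non-trivial weights
energize <- function(model, scale = 0.5, seed = 3) {
  set.seed(seed)
  model$theta <- rnorm(length(model$theta), sd = scale)
  model
}

test_that("initialization is seed-deterministic with zero MM biases", {
  for (arch in c("mace_like", "dp_like")) {
    hp <- if (arch == "mace_like") tiny_mace_hp() else tiny_dp_hp()
    m1 <- init_model(arch, hp, seed = 7, species_codes = test_codes)
    m2 <- init_model(arch, hp, seed = 7, species_codes = test_codes)
    expect_identical(m1$theta, m2$theta)
    expect_identical(m1$fixed, m2$fixed)
    m3 <- init_model(arch, hp, seed = 8, species_codes = test_codes)
    expect_false(identical(m1$theta, m3$theta))
    b <- species_bias(m1)
    expect_equal(unname(b[c("51", "58")]), c(0, 0))
    expect_true(all(is.finite(unlist(m1$theta))))
  }
  expect_error(init_model("mace_like", tiny_dp_hp(), 1, test_codes),
               "requires mace_hyperparams")
})

test_that("isolated atoms contribute exactly their species bias", {
  for (mdl in models_under_test()) {
    mdl <- energize(mdl)
    ## QM atom + far MM atom (outside the cutoff): no edges at all
    conf <- atomic_configuration(c(15, 8), rbind(c(0, 0, 0), c(20, 0, 0)),
                                 c("QM", "MM"))
    se <- site_energies(mdl, conf)
    expect_equal(se[2], 0)                       # isolated MM atom
    expect_equal(se[1], unname(species_bias(mdl)["15"]))  # isolated QM atom
    ef <- delta_energy_forces(mdl, conf)
    expect_equal(max(abs(ef$forces)), 0)
  }
})

test_that("duplicated identical environments give identical site energies", {
  base <- rand_config(n_qm = 2, n_mm = 2, seed = 21, spread = 2.5)
  shift <- matrix(c(40, 0, 0), nrow(base$positions), 3, byrow = TRUE)
  dup <- atomic_configuration(
    c(base$species, base$species),
    rbind(base$positions, base$positions + shift),
    c(base$region, base$region))
  for (mdl in models_under_test()) {
    mdl <- energize(mdl)
    se <- site_energies(mdl, dup)
    n <- nrow(base$positions)
    expect_equal(se[seq_len(n)], se[n + seq_len(n)], tolerance = 1e-12)
  }
})

test_that("forces equal the negative analytic gradient (finite differences)", {
  conf <- rand_config(n_qm = 4, n_mm = 5, seed = 13)
  h <- 1e-4
  for (mdl in models_under_test()) {
    mdl <- energize(mdl)
    ef <- delta_energy_forces(mdl, conf)
    n <- nrow(conf$positions)
    for (i in sample(n, 4)) for (c3 in 1:3) {
      cp <- conf; cp$positions[i, c3] <- cp$positions[i, c3] + h
      cm <- conf; cm$positions[i, c3] <- cm$positions[i, c3] - h
      fd <- -(sum(site_energies(mdl, cp)) - sum(site_energies(mdl, cm))) / (2 * h)
      expect_lt(abs(fd - ef$forces[i, c3]), 1e-5)
    }
    ## net force vanishes
    expect_lt(max(abs(colSums(ef$forces))), 1e-8)
  }
})

test_that("energies are invariant and forces equivariant under rotation", {
  conf <- rand_config(n_qm = 3, n_mm = 5, seed = 17)
  R <- rand_rotation(3)
  for (mdl in models_under_test()) {
    mdl <- energize(mdl)
    ef <- delta_energy_forces(mdl, conf)
    conf2 <- conf
    conf2$positions <- conf$positions %*% t(R) +
      matrix(c(2, -1, 3), nrow(conf$positions), 3, byrow = TRUE)
    ef2 <- delta_energy_forces(mdl, conf2)
    expect_lt(abs(ef2$energy - ef$energy), 1e-8)
    expect_lt(max(abs(ef2$forces - ef$forces %*% t(R))), 1e-8)
  }
})

test_that("energy is continuous as an MM atom crosses the cutoff", {
  ## one MM atom walked through r_cut along x; E(r) must be continuous and
  ## exactly constant beyond the cutoff
  for (mdl in models_under_test()) {
    mdl <- energize(mdl)
    rcut <- mdl$hyperparams$basis$r_cut
    econf <- function(r) {
      conf <- atomic_configuration(
        c(8, 15, 8), rbind(c(0, 0, 0.5), c(0, 0, -0.5), c(r, 0, 0)),
        c("QM", "QM", "MM"))
      sum(site_energies(mdl, conf))
    }
    d <- 1e-4
    expect_lt(abs(econf(rcut - d) - econf(rcut + d)), 1e-8)
    ## dense scan around the cutoff: increments stay tiny (C1 smoothness)
    rs <- seq(rcut - 0.02, rcut + 0.02, by = 1e-3)
    es <- vapply(rs, econf, numeric(1))
    expect_lt(max(abs(diff(es))), 1e-6)
    ## identically constant outside
    expect_equal(econf(rcut + 0.5), econf(rcut + 2.0))
  }
})

test_that("MM atoms beyond every QM cutoff are inert (MM-MM locality)", {
  for (mdl in models_under_test()) {
    mdl <- energize(mdl)
    rcut <- mdl$hyperparams$basis$r_cut
    ## far MM atom has another MM atom nearby, but no QM path
    mk <- function(far_x) atomic_configuration(
      c(8, 15, 8, 8),
      rbind(c(0, 0, 0.8), c(0, 0, -0.8), c(far_x, 0, 0), c(far_x + 2, 0, 0)),
      c("QM", "QM", "MM", "MM"))
    e1 <- delta_energy_forces(mdl, mk(1.9 * rcut))
    e2 <- delta_energy_forces(mdl, mk(1.9 * rcut + 0.37))
    expect_equal(e1$energy, e2$energy)
    expect_equal(max(abs(e1$forces[3:4, ])), 0)
  }
})

test_that("message passing extends the receptive field only through QM atoms", {
  ## MACE with T = 2: an MM atom at 1.9 r_cut influences nothing when its
  ## only in-range neighbor is MM, but does when a QM atom bridges the gap
  hp <- tiny_mace_hp()
  mdl <- energize(init_model("mace_like", hp, 5, test_codes))
  rcut <- hp$basis$r_cut
  mk <- function(bridge_region, far_x) atomic_configuration(
    c(8, 15, 8, 8),
    rbind(c(0, 0, 0.8), c(0, 0, -0.8), c(far_x / 2, 0, 0), c(far_x, 0, 0)),
    c("QM", "QM", bridge_region, "MM"))
  far <- 1.9 * rcut
  ## MM bridge: perturbing the far atom changes nothing
  e_mm_1 <- delta_energy_forces(mdl, mk("MM", far))$energy
  conf2 <- mk("MM", far); conf2$positions[4, 2] <- 1.1
  expect_equal(delta_energy_forces(mdl, conf2)$energy, e_mm_1)
  ## QM bridge: the far MM atom now matters
  e_qm_1 <- delta_energy_forces(mdl, mk("QM", far))$energy
  conf3 <- mk("QM", far); conf3$positions[4, 2] <- 1.1
  expect_gt(abs(delta_energy_forces(mdl, conf3)$energy - e_qm_1), 1e-10)
})

test_that("correlation order nu = 1 yields pairwise-additive features", {
  hp <- mace_hyperparams(N = 4L, T_layers = 1L, nu = 1L, l_max = 2L,
                         readout_channels = 4L,
                         basis = radial_basis_spec(6, 4L, 5L))
  mdl <- init_model("mace_like", hp, 3, test_codes)
  mk <- function(neighbors) atomic_configuration(
    c(15, rep(8, length(neighbors))),
    rbind(c(0, 0, 0), do.call(rbind, neighbors)),
    rep("QM", 1 + length(neighbors)))
  phi_of <- function(conf)
    rcdmlp:::mace_forward_cache(mdl, conf)$layers[[1]]$phi[1, ]
  n1 <- list(c(1.7, 0, 0)); n2 <- list(c(0, 2.1, 0.4))
  expect_equal(phi_of(mk(c(n1, n2))), phi_of(mk(n1)) + phi_of(mk(n2)),
               tolerance = 1e-12)
  ## nu = 3 features are not additive (many-body)
  hp3 <- mace_hyperparams(N = 4L, T_layers = 1L, nu = 3L, l_max = 2L,
                          readout_channels = 4L,
                          basis = radial_basis_spec(6, 4L, 5L))
  mdl3 <- init_model("mace_like", hp3, 3, test_codes)
  phi3_of <- function(conf)
    rcdmlp:::mace_forward_cache(mdl3, conf)$layers[[1]]$phi[1, ]
  expect_gt(max(abs(phi3_of(mk(c(n1, n2))) - phi3_of(mk(n1)) - phi3_of(mk(n2)))),
            1e-8)
})

test_that("L = 0 models run and stay invariant; L > l_max is rejected", {
  hp0 <- mace_hyperparams(N = 4L, L = 0L, T_layers = 2L, nu = 2L, l_max = 2L,
                          readout_channels = 4L,
                          basis = radial_basis_spec(6, 4L, 5L))
  mdl <- energize(init_model("mace_like", hp0, 2, test_codes))
  conf <- rand_config(3, 3, seed = 8)
  R <- rand_rotation(2)
  conf2 <- conf; conf2$positions <- conf$positions %*% t(R)
  expect_lt(abs(delta_energy_forces(mdl, conf2)$energy -
                  delta_energy_forces(mdl, conf)$energy), 1e-10)
  expect_error(mace_hyperparams(L = 3L, l_max = 2L), "l_max")
})

test_that("site energies sum to the total and dispatch by architecture", {
  conf <- rand_config(3, 4, seed = 30)
  mdls <- models_under_test()
  m <- energize(mdls$mace); d <- energize(mdls$dp)
  expect_equal(sum(mace_forward(m, conf)),
               delta_energy_forces(m, conf)$energy, tolerance = 1e-12)
  expect_equal(sum(dp_forward(d, conf)),
               delta_energy_forces(d, conf)$energy, tolerance = 1e-12)
  expect_error(mace_forward(d, conf), "not mace_like")
  expect_error(dp_forward(m, conf), "not dp_like")
})

test_that("checkpoints round-trip through the JSON archive", {
  conf <- rand_config(3, 3, seed = 44)
  for (mdl in models_under_test()) {
    mdl <- energize(mdl)
    p <- tempfile(fileext = ".json")
    save_model(mdl, p)
    m2 <- load_model(p)
    expect_equal(m2$theta, mdl$theta, tolerance = 1e-15)
    expect_equal(site_energies(m2, conf), site_energies(mdl, conf),
                 tolerance = 1e-12)
    expect_identical(m2$architecture, mdl$architecture)
  }
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "not an rcdmlp checkpoint")
})

test_that("feature design matrices agree with direct evaluation", {
  conf <- rand_config(4, 4, seed = 50)
  for (mdl in models_under_test()) {
    mdl <- energize(mdl)
    d <- model_design(mdl, conf)
    ef <- delta_energy_forces(mdl, conf)
    expect_equal(sum(d$psi * mdl$theta), ef$energy, tolerance = 1e-10)
    fJ <- -matrix(as.numeric(t(d$J) %*% mdl$theta), ncol = 3, byrow = TRUE)
    expect_lt(max(abs(fJ - ef$forces)), 1e-10)
  }
})

test_that("higher correlation order gives lower held-out force error", {
  ## many-body (nu = 3) features fit the toy correction better than pure
  ## 2-body (nu = 1) features at equal channel count (seeded, directional)
  spec <- toy_system_spec("Nuc-EtO", n_mm = 4)
  sched <- make_window_schedule(-1.5, 1.5, 0.75, 40)
  dyn <- dynamics_spec(n_equil_steps = 100, n_prod_steps = 400,
                       samples_saved = 30)
  ds <- generate_reference_dataset("Nuc-EtO", sched, dyn, seed = 31, n_mm = 4)
  db <- unlist(ds[["Nuc-EtO"]], recursive = FALSE)
  set.seed(5)
  idx <- sample(length(db))
  train <- db[idx[1:100]]; held <- db[idx[101:150]]
  codes <- sort(unique(map_species(db[[1]]$config)))
  rmse_of <- function(nu) {
    mean(vapply(1:2, function(sd0) {
      m <- init_model("mace_like", mace_hyperparams(N = 8L, nu = nu), sd0,
                      codes)
      m <- train_model(m, training_design(m, train),
                       lr_schedule(n_steps = 1500L))
      com <- structure(list(models = list(m), seeds = sd0),
                       class = "committee")
      mean(vapply(held, function(s) force_rmse_filter(com, s)$max_rmse,
                  numeric(1)))
    }, numeric(1)))
  }
  expect_lt(rmse_of(3L), rmse_of(1L))
})
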