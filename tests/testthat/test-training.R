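test_that("learning-rate schedule hits its printed endpoints", {
  s <- lr_schedule(1e-3, 1e-5, 400000L)
  expect_equal(lr_at(s, 0), 1e-3)
  expect_equal(lr_at(s, 200000), 1e-4)     # geometric midpoint of the decay
  expect_equal(lr_at(s, 400000), 1e-5)
  expect_equal(lr_at(s, 500000), 1e-5)     # clamped beyond n_steps
  steps <- seq(0, 450000, length.out = 50)
  expect_true(all(diff(lr_at(s, steps)) <= 0))
})

test_that("energy-weight schedule ramps from 1 to 100 eV^-2", {
  s <- loss_schedule()
  expect_equal(p_e_at(s, 0), 1)
  expect_equal(p_e_at(s, 1), 100)
  expect_equal(p_e_at(s, 0.5), 10)
  expect_true(all(diff(p_e_at(s, seq(0, 1, 0.05))) >= 0))
  expect_equal(s$p_f, 100)
})

test_that("the loss vanishes for perfect predictions and errors on bad data", {
  mdl <- init_model("mace_like", tiny_mace_hp(), 5, test_codes)
  set.seed(1); mdl$theta <- rnorm(length(mdl$theta), sd = 0.3)
  confs <- lapply(1:3, function(s) rand_config(3, 3, seed = s))
  batch <- realizable_samples(mdl, confs)
  expect_equal(loss(mdl, batch, 0), 0, tolerance = 1e-18)
  expect_equal(loss(mdl, batch, 1), 0, tolerance = 1e-18)
  ## nonzero residual, p_e scaling visible
  batch2 <- batch
  batch2[[1]]$e_target <- batch2[[1]]$e_target + 0.1
  l0 <- loss(mdl, batch2, 0); l1 <- loss(mdl, batch2, 1)
  expect_equal(l1 / l0, 100, tolerance = 1e-8)
  expect_error(loss(mdl, list(), 0), "nonempty")
  bad <- batch[[1]]; bad$f_target <- bad$f_target[1:2, ]
  expect_error(loss(mdl, list(bad), 0), "atom count")
})

test_that("committee training is reproducible and loss decreases", {
  fx <- toy_small_db()
  db <- fx$db[1:16]
  codes <- sort(unique(map_species(db[[1]]$config)))
  lrs <- lr_schedule(n_steps = 300L)
  c1 <- train_committee(db, "mace_like", tiny_mace_hp(), codes,
                        seeds = 1:2, lr_sched = lrs)
  c2 <- train_committee(db, "mace_like", tiny_mace_hp(), codes,
                        seeds = 1:2, lr_sched = lrs)
  expect_identical(c1$models[[1]]$theta, c2$models[[1]]$theta)
  expect_false(identical(c1$models[[1]]$theta, c1$models[[2]]$theta))
  ## loss decreased relative to initialization at matched weights
  init <- init_model("mace_like", tiny_mace_hp(), 1, codes)
  expect_lt(loss(c1$models[[1]], db, 1), loss(init, db, 1))
  h <- c1$models[[1]]$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_error(train_committee(list(), "mace_like", tiny_mace_hp(), codes),
               "nonempty")
})

test_that("a realizable correction is learned below the filter threshold", {
  ## labels generated by a model of the same class: training must push the
  ## held-out committee force RMSE below the 0.08 eV/A filter
  truth <- init_model("mace_like", tiny_mace_hp(), 99, test_codes)
  set.seed(2); truth$theta <- rnorm(length(truth$theta), sd = 0.4)
  confs <- lapply(1:40, function(s) rand_config(3, 4, seed = 1000 + s))
  db <- realizable_samples(truth, confs)
  ## committee members share the model class (fixed features) of the truth
  ## but start from independently randomized readouts
  members <- lapply(1:2, function(sd0) {
    m <- truth
    set.seed(sd0); m$theta <- rnorm(length(m$theta), sd = 0.01)
    m
  })
  design <- training_design(members[[1]], db[1:30])
  com <- structure(list(
    models = lapply(members, train_model, design = design,
                    lr_sched = lr_schedule(n_steps = 1500L)),
    seeds = 1:2), class = "committee")
  held <- db[31:40]
  mx <- vapply(held, function(s) force_rmse_filter(com, s)$max_rmse, numeric(1))
  expect_lt(max(mx), 0.08)
})

test_that("the committee filter discards by maximum member force RMSE", {
  mdl <- init_model("mace_like", tiny_mace_hp(), 3, test_codes)
  set.seed(9); mdl$theta <- rnorm(length(mdl$theta), sd = 0.3)
  conf <- rand_config(3, 3, seed = 77)
  pred <- delta_energy_forces(mdl, conf)$forces
  mk_sample <- function(offset) labeled_sample(
    conf, 0, 0, matrix(0, nrow(pred), 3), pred + offset, 0)
  twin <- structure(list(models = list(mdl, mdl), seeds = c(3, 3)),
                    class = "committee")
  ## constant component offset d gives RMSE exactly d for both members
  expect_false(force_rmse_filter(twin, mk_sample(0.05))$keep)   # discard
  expect_true(force_rmse_filter(twin, mk_sample(0.09))$keep)
  expect_true(force_rmse_filter(twin, mk_sample(0.08))$keep)    # boundary kept
  ## the maximum across members governs: pair the model with a copy whose
  ## readout is rescaled so its residual exceeds the threshold
  m2 <- mdl; m2$theta <- mdl$theta * 20
  mixed <- structure(list(models = list(mdl, m2), seeds = c(3, 4)),
                     class = "committee")
  res <- force_rmse_filter(mixed, mk_sample(0.05))
  expect_gt(res$rmse[2], 0.08)   # second member is off by construction
  expect_true(res$keep)
  expect_equal(res$max_rmse, max(res$rmse))
})

test_that("simplify bookkeeping: partitions, caps and the 3-round bound", {
  fx <- toy_small_db()
  db <- fx$db[1:10]
  codes <- sort(unique(map_species(db[[1]]$config)))
  hp <- mace_hyperparams(N = 2L, T_layers = 1L, nu = 1L, l_max = 1L,
                         readout_channels = 2L,
                         basis = radial_basis_spec(6, 3L, 5L))
  run <- function(filter_fn) simplify_workflow(
    db, "mace_like", hp, codes,
    config = simplify_config(committee_size = 2L),
    seeds = 1:2, lr_sched = lr_schedule(n_steps = 5L),
    selection_seed = 7L, filter_fn = filter_fn)
  ## adversarial filter that never discards: maximal rounds
  worst <- run(function(com, s) TRUE)
  expect_equal(worst$n_rounds, 3L)
  sizes <- vapply(worst$history, function(h) length(h$train_ids), integer(1))
  expect_equal(sizes, c(5L, 3L, 2L))    # ceil(n/2), then 25% caps
  ## a perfect filter stops after one round
  best <- run(function(com, s) FALSE)
  expect_equal(best$n_rounds, 1L)
  ## assorted deterministic filter behaviors never exceed 3 rounds and keep
  ## the partitions disjoint
  rules <- list(function(com, s) s$xi > 0,
                function(com, s) abs(s$e_target - s$e_base) > 0.05,
                function(com, s) TRUE,
                function(com, s) runif(1) > 0.5)
  for (rule in rules) {
    set.seed(3)
    res <- run(rule)
    expect_lte(res$n_rounds, 3L)
    all_train <- unlist(lapply(res$history, `[[`, "train_ids"))
    expect_false(any(duplicated(all_train)))
    expect_true(all(all_train %in% seq_along(db)))
    for (h in res$history)
      expect_length(intersect(h$train_ids, h$test_ids), 0L)
  }
})

test_that("simplify reproduces the printed worst-case arithmetic", {
  ## 100 samples, filter never discards: rounds train 50, 25, 25
  fx <- toy_small_db()
  db <- rep(fx$db[1:10], 10)[1:100]
  codes <- sort(unique(map_species(db[[1]]$config)))
  hp <- mace_hyperparams(N = 2L, T_layers = 1L, nu = 1L, l_max = 1L,
                         readout_channels = 2L,
                         basis = radial_basis_spec(6, 3L, 5L))
  res <- simplify_workflow(db, "mace_like", hp, codes,
                           config = simplify_config(committee_size = 1L),
                           seeds = 1L, lr_sched = lr_schedule(n_steps = 2L),
                           selection_seed = 11L,
                           filter_fn = function(com, s) TRUE)
  expect_equal(res$n_rounds, 3L)
  expect_equal(vapply(res$history, function(h) length(h$train_ids), integer(1)),
               c(50L, 25L, 25L))
})

test_that("end-state augmentation respects the displacement rules", {
  fx <- toy_small_db()
  ens <- list(fx$db[1:20], fx$db[21:40])
  sp <- augment_spec(copies_per_ensemble = 12L)
  out <- augment_endstates(ens, sp, seed = 4)
  expect_length(out, 24L)   # copies x ensembles (e.g. 50 x 12 = 600 at scale)
  ## deterministic given the seed
  out2 <- augment_endstates(ens, sp, seed = 4)
  expect_equal(out, out2)
  ## statistical check over many draws: heavy displacement <= 0.15 A, MM
  ## atoms untouched, H bond lengths inside [0.7, 1.2]
  many <- augment_endstates(list(rep(fx$db[1], 60)),
                            augment_spec(copies_per_ensemble = 60L), seed = 9)
  orig <- fx$db[[1]]$config
  qm_heavy <- which(orig$region == "QM" & orig$species > 1)
  hyd <- which(orig$region == "QM" & orig$species == 1)
  mm <- which(orig$region == "MM")
  disp <- unlist(lapply(many, function(cfg)
    sqrt(rowSums((cfg$positions[qm_heavy, ] - orig$positions[qm_heavy, ])^2))))
  expect_lte(max(disp), 0.15)
  expect_gt(max(disp), 0.10)   # the full range is actually explored
  for (cfg in many[1:10])
    expect_equal(cfg$positions[mm, ], orig$positions[mm, ])
  blen <- vapply(many, function(cfg) {
    j <- rcdmlp:::find_bonded_heavy(cfg, hyd[1])
    sqrt(sum((cfg$positions[hyd[1], ] - cfg$positions[j, ])^2))
  }, numeric(1))
  expect_true(all(blen >= 0.7 & blen <= 1.2))
  ## degenerate H range pins the bond length exactly
  deg <- augment_endstates(list(fx$db[1:5]),
                           augment_spec(copies_per_ensemble = 2L,
                                        heavy_max_disp = 0,
                                        h_bond_range = c(0.95, 0.95)),
                           seed = 2)
  for (cfg in deg) {
    j <- rcdmlp:::find_bonded_heavy(cfg, hyd[1])
    expect_equal(sqrt(sum((cfg$positions[hyd[1], ] - cfg$positions[j, ])^2)),
                 0.95, tolerance = 1e-10)
  }
  expect_error(augment_endstates(list(fx$db[1:3]),
                                 augment_spec(copies_per_ensemble = 5L)),
               "at least")
})

test_that("fine-tuning restarts from existing parameters and improves fit", {
  fx <- toy_small_db()
  db <- fx$db[1:16]
  extra <- fx$db[33:44]
  codes <- sort(unique(map_species(db[[1]]$config)))
  com <- train_committee(db, "mace_like", tiny_mace_hp(), codes, seeds = 1:2,
                         lr_sched = lr_schedule(n_steps = 400L))
  ## empty extra data: parameters unchanged
  expect_identical(fine_tune(com, list())$models[[1]]$theta,
                   com$models[[1]]$theta)
  ft <- fine_tune(com, c(db, extra), lr_sched = lr_schedule(n_steps = 400L))
  expect_lte(loss(ft$models[[1]], extra, 1), loss(com$models[[1]], extra, 1))
})
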