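## shared fixtures: random configurations, rotations, tiny model settings

rand_config <- function(n_qm = 4, n_mm = 6, seed = 1, spread = 4,
                        qm_species = c(8, 15, 1), mm_species = c(8, 1)) {
  set.seed(seed)
  pos <- matrix(runif((n_qm + n_mm) * 3, -spread, spread), ncol = 3)
  pos[seq_len(n_qm), ] <- matrix(runif(n_qm * 3, -1.5, 1.5), ncol = 3)
  atomic_configuration(
    species = c(sample(qm_species, n_qm, TRUE), sample(mm_species, n_mm, TRUE)),
    positions = pos,
    region = c(rep("QM", n_qm), rep("MM", n_mm)))
}

rand_rotation <- function(seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

test_codes <- c(1L, 8L, 15L, 51L, 58L)

tiny_mace_hp <- function(...) {
  mace_hyperparams(N = 4L, T_layers = 2L, nu = 3L, l_max = 2L,
                   readout_channels = 4L,
                   basis = radial_basis_spec(6, 4L, 5L), ...)
}

tiny_dp_hp <- function() {
  dp_hyperparams(fitting_layers = c(8L, 8L), embedding_layers = c(4L, 8L),
                 axis_filters = 4L, basis = radial_basis_spec(6, 4L, 5L))
}

## labeled samples whose correction labels come from a "truth" model, so the
## correction is exactly realizable by the model class
realizable_samples <- function(truth, configs, rc = NULL) {
  lapply(configs, function(cfg) {
    ef <- delta_energy_forces(truth, cfg)
    n <- nrow(cfg$positions)
    xi <- if (is.null(rc)) 0 else compute_xi(cfg, rc)
    labeled_sample(cfg, e_base = 0, e_target = ef$energy,
                   f_base = matrix(0, n, 3), f_target = ef$forces, xi = xi)
  })
}

## small base-sampled toy dataset, memoized across tests in one run
.toy_db_cache <- new.env()
toy_small_db <- function() {
  if (is.null(.toy_db_cache$db)) {
    spec <- toy_system_spec("Nuc-EtO", n_mm = 4)
    sched <- make_window_schedule(-1.25, 1.25, 2.5, 40)  # two end windows
    dyn <- dynamics_spec(n_equil_steps = 100, n_prod_steps = 400,
                         samples_saved = 25)
    ds <- generate_reference_dataset("Nuc-EtO", sched, dyn, seed = 31,
                                     n_mm = 4)
    .toy_db_cache$db <- unlist(ds[["Nuc-EtO"]], recursive = FALSE)
    .toy_db_cache$spec <- spec
  }
  list(db = .toy_db_cache$db, spec = .toy_db_cache$spec)
}
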