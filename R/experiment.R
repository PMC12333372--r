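#' End-state transferability experiment
#'
#' The package's flagship validation: train a 4-member correction-model
#' committee ONLY on base-potential umbrella sampling of the reactant-like
#' and product-like end states (plus the 10% augmentation), run
#' umbrella sampling with base + Delta-MLP across the full window ladder,
#' estimate the target free-energy surface by pooled gwTP, and compare it
#' with direct target-potential umbrella sampling.  The target's metastable
#' intermediate lies entirely between the end states, so its recovery tests
#' the correction's transferability through the unseen transition region.
#'
#' Desk-scale defaults: 17 windows on xi in [-2, 2] A (0.25 A spacing,
#' k = 40 kcal mol^-1 A^-2), 8 MM particles, 100 saved frames per end-state
#' window, 50 per production window, 2000 Adam steps.  All stages derive
#' their RNG streams from `seed`.
#'
#' @param seed integer master seed.
#' @param variant toy reaction variant (see [toy_system_spec()]).
#' @param n_mm MM particle count.
#' @param architecture `"mace_like"` or `"dp_like"`.
#' @param n_channels embedding channels of the MACE-like model.
#' @param schedule window schedule for production sampling.
#' @param endstates numeric xi values of the two training windows.
#' @param bin_width FES histogram width (Angstrom).
#' @param n_steps Adam steps per training round.
#' @param dyn_ref,dyn_end,dyn_mlp dynamics specs for target reference
#'   sampling, end-state data generation, and Delta-MLP sampling.
#' @param committee_seeds seeds of the committee members.
#' @return list with `fes_ref` (direct target FES), `gwtp` (the pooled
#'   reweighting report), `mad_kcal` and `mad_kt` (mean absolute deviation
#'   over common occupied bins), `intermediate` (list: depths of the gwTP
#'   intermediate below its flanking barriers, in kT), `committee`,
#'   `simplify_rounds`.
#' @export
endstate_transfer_experiment <- function(
    seed = 1L,
    variant = "Nuc-EtO",
    n_mm = 8L,
    architecture = "mace_like",
    n_channels = 8L,
    schedule = make_window_schedule(-2.0, 2.0, 0.25, 40),
    endstates = c(-1.5, 1.5),
    bin_width = 0.25,
    n_steps = 2000L,
    dyn_ref = dynamics_spec(n_equil_steps = 300L, n_prod_steps = 1500L,
                            samples_saved = 60L),
    dyn_end = dynamics_spec(n_equil_steps = 300L, n_prod_steps = 1500L,
                            samples_saved = 100L),
    dyn_mlp = dynamics_spec(n_equil_steps = 200L, n_prod_steps = 900L,
                            samples_saved = 50L),
    committee_seeds = 1:4) {
  spec <- toy_system_spec(variant, n_mm = n_mm)
  masses <- toy_masses(spec)
  temp <- dyn_ref$temperature
  ## ---- direct target-potential umbrella sampling (reference) ----
  xi_t <- c(); ut_t <- c(); wof_t <- c()
  for (wi in seq_along(schedule$windows)) {
    win <- schedule$windows[[wi]]
    ws <- (seed * 887L + wi) %% 2147483647L
    ens <- run_umbrella_window(function(c) target_energy_forces(c, spec), win,
                               dyn_ref, ws,
                               toy_template_config(spec, win$center, ws),
                               spec$rc, masses)
    xi_t <- c(xi_t, ens$xi)
    ut_t <- c(ut_t, vapply(ens$frames, function(f)
      target_energy_forces(f, spec)$energy, numeric(1)))
    wof_t <- c(wof_t, rep(wi, length(ens$xi)))
  }
  inp_t <- reweight_input(xi_t, cbind(ut_t), ut_t, rep(1L, length(xi_t)),
                          wof_t, schedule$windows, temp)
  fes_ref <- mbar_fes(inp_t, bin_width)
  ## ---- end-state training database ----
  end_sched <- make_window_schedule(endstates[1], endstates[2],
                                    diff(endstates), schedule$force_constant)
  ds <- generate_reference_dataset(variant, end_sched, dyn_end,
                                   seed = seed + 5L, n_mm = n_mm)
  ensembles <- ds[[variant]]
  n_aug <- max(1L, round(0.1 * dyn_end$samples_saved))
  aug_cfgs <- augment_endstates(ensembles,
                                augment_spec(copies_per_ensemble = n_aug),
                                seed = seed + 17L)
  aug <- lapply(aug_cfgs, function(cfg) {
    eb <- base_energy_forces(cfg, spec)
    et <- target_energy_forces(cfg, spec)
    labeled_sample(cfg, eb$energy, et$energy, eb$forces, et$forces,
                   xi = compute_xi(cfg, spec$rc))
  })
  db <- c(unlist(ensembles, recursive = FALSE), aug)
  ## ---- committee training via the simplify workflow ----
  codes <- sort(unique(map_species(db[[1]]$config)))
  hp <- if (architecture == "mace_like") mace_hyperparams(N = n_channels)
        else dp_hyperparams()
  res <- simplify_workflow(db, architecture, hp, codes,
                           config = simplify_config(
                             committee_size = length(committee_seeds)),
                           seeds = committee_seeds,
                           lr_sched = lr_schedule(n_steps = n_steps),
                           selection_seed = seed + 101L)
  com <- res$committee
  ## ---- Delta-MLP umbrella sampling across all windows ----
  frames <- list(); model_of <- integer(0); window_of <- integer(0)
  for (mi in seq_along(com$models)) {
    mdl <- com$models[[mi]]
    pot <- function(cfg) {
      eb <- base_energy_forces(cfg, spec)
      dd <- delta_energy_forces(mdl, cfg)
      list(energy = eb$energy + dd$energy, forces = eb$forces + dd$forces)
    }
    for (wi in seq_along(schedule$windows)) {
      win <- schedule$windows[[wi]]
      ws <- (seed * 7919L + mi * 613L + wi) %% 2147483647L
      ens <- run_umbrella_window(pot, win, dyn_mlp, ws,
                                 toy_template_config(spec, win$center, ws),
                                 spec$rc, masses)
      frames <- c(frames, ens$frames)
      model_of <- c(model_of, rep(mi, length(ens$frames)))
      window_of <- c(window_of, rep(wi, length(ens$frames)))
    }
  }
  ## ---- pooled gwTP to the target potential ----
  xi <- vapply(frames, function(f) compute_xi(f, spec$rc), numeric(1))
  u_target <- vapply(frames, function(f)
    target_energy_forces(f, spec)$energy, numeric(1))
  eb_all <- vapply(frames, function(f)
    base_energy_forces(f, spec)$energy, numeric(1))
  u_models <- matrix(0.0, length(frames), length(com$models))
  for (mi in seq_along(com$models))
    u_models[, mi] <- eb_all + vapply(frames, function(f)
      sum(site_energies(com$models[[mi]], f)), numeric(1))
  ginp <- reweight_input(xi, u_models, u_target, model_of, window_of,
                         schedule$windows, temp)
  gw <- gwtp_estimate(ginp, smoothing_spec(), bin_width)
  ## ---- comparison ----
  idx <- match(round(gw$fes$centers / bin_width), round(fes_ref$centers / bin_width))
  ref_on <- fes_ref$values[idx]
  common <- !is.na(gw$fes$values) & !is.na(ref_on)
  kT_kcal <- kT(temp, "kcal")
  mad <- mean(abs(gw$fes$values[common] - ref_on[common]))
  inter <- fes_intermediate_depth(gw$fes, kT_kcal)
  inter_ref <- fes_intermediate_depth(fes_ref, kT_kcal)
  list(fes_ref = fes_ref, gwtp = gw, mad_kcal = mad, mad_kt = mad / kT_kcal,
       intermediate = inter, intermediate_ref = inter_ref,
       committee = com, simplify_rounds = res$n_rounds)
}

#' Depth of the central intermediate well of an FES
#'
#' Finds the minimum of the surface within |xi| <= 0.5 A and the flanking
#' maxima out to |xi| <= 1.25 A.
#'
#' @param fes an `fes` object.
#' @param kT_kcal thermal energy in kcal/mol used to express the depths.
#' @return list with `depth_left_kt`, `depth_right_kt`, `xi_min` (well
#'   position), or depths `-Inf` when no interior structure exists.
#' @export
fes_intermediate_depth <- function(fes, kT_kcal = kT(298, "kcal")) {
  cen <- fes$centers; vals <- fes$values
  mid <- which(abs(cen) <= 0.5 & !is.na(vals))
  if (length(mid) == 0L)
    return(list(depth_left_kt = -Inf, depth_right_kt = -Inf, xi_min = NA_real_))
  i0 <- mid[which.min(vals[mid])]
  lsel <- which(cen < cen[i0] & cen >= -1.25 & !is.na(vals))
  rsel <- which(cen > cen[i0] & cen <= 1.25 & !is.na(vals))
  lb <- if (length(lsel)) max(vals[lsel]) else -Inf
  rb <- if (length(rsel)) max(vals[rsel]) else -Inf
  list(depth_left_kt = (lb - vals[i0]) / kT_kcal,
       depth_right_kt = (rb - vals[i0]) / kT_kcal,
       xi_min = cen[i0])
}
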