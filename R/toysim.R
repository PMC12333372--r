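#' Synthetic surrogate reaction system
#'
#' A desk-scale stand-in for a solvated QM/MM phosphoryl-transfer system: a
#' collinear triatomic O-P-O analog (leaving group "A", central atom "P",
#' nucleophile "B") with one tethered QM hydrogen, surrounded by MM
#' particles confined to a soft spherical droplet.  The base potential has a
#' two-basin profile along the distance-difference coordinate xi; the target
#' potential additionally contains (i) a Gaussian well near xi = 0 creating
#' a metastable intermediate (the pentacoordinate-analog state) and (ii) a
#' modified short-range QM/MM pair term that vanishes smoothly, with zero
#' slope, at the 6 Angstrom cutoff.  Both potentials are analytic with exact
#' gradients.
#'
#' Six named variants emulate the 2 nucleophiles x 3 leaving groups of the
#' reaction series: they differ in the profile tilt (reactant/product
#' asymmetry), the strength of the target QM/MM pair correction, and the
#' hydrogen tether length.
#'
#' @name toysim
NULL

#' Toy system specification
#'
#' @param variant one of `"Nuc-EtO"`, `"Nuc-AcO"`, `"Nuc-PhO"`,
#'   `"mNuc-EtO"`, `"mNuc-AcO"`, `"mNuc-PhO"`.
#' @param n_mm number of MM particles (>= 0).
#' @return object of class `toy_system_spec` bundling geometry, masses and
#'   potential parameters for the chosen variant.
#' @export
toy_system_spec <- function(variant = "Nuc-EtO", n_mm = 8L) {
  variants <- toy_variants()
  if (!variant %in% names(variants)) {
    stop("unknown variant; choose one of: ", paste(names(variants), collapse = ", "))
  }
  v <- variants[[variant]]
  structure(list(
    variant = variant,
    ## QM atoms: A (O-like), P, B (O-like), H tethered to P
    qm_species = c(8L, 15L, 8L, 1L),
    qm_masses = c(16, 31, 16, 2),
    n_mm = as.integer(n_mm),
    mm_species = 8L,
    mm_mass = 16,
    rc = rc_spec(1L, 2L, 3L),
    ## base potential parameters (eV, Angstrom)
    barrier = 0.40,         # double-well barrier height
    xi_m = 1.6,             # basin positions +- xi_m
    tilt = v$tilt,          # linear asymmetry along xi
    k_sum = 2.5,            # stiffness of the bond-sum coordinate
    sigma0 = 3.6,           # equilibrium bond sum (2 x 1.8)
    k_h = 20, l_h = v$l_h,  # H tether to P
    ab_rep = c(0.6, 1.2, 0.35),   # A-B repulsion: a * exp(-(d - d0)/w)
    mm_rep = c(0.05, 2.5, 0.4),   # MM-MM soft shell
    qmmm_rep = c(0.08, 2.2, 0.35),# base QM-MM repulsive shell
    ## target-only terms: per-bond Gaussian wells centered between the
    ## reactant-like (~1.2 A) and product-like (~2.4 A) bond lengths create
    ## a metastable intermediate near xi = 0 where both bonds reach d_well
    ## simultaneously; the well is a smooth function of the bond distances,
    ## so end-state sampling brackets it from both sides
    well_depth = 0.20,      # per-bond Gaussian amplitude (eV)
    well_center = 1.8,      # bond length of the intermediate-like state (A)
    well_width = 0.27,      # Gaussian width in the bond distance (A)
    dtilt = v$dtilt,        # target tilt change
    dv_amp = v$dv_amp,      # QM/MM pair correction amplitude (eV)
    dv_r0 = 3.0, dv_w = 1.0,
    dv_species = c("1" = 0.2, "8" = 0.5, "15" = 1.0),
    r_cut = 6.0, envelope_order = 5L,
    confine_radius = 4.5, confine_k = 0.5),
    class = "toy_system_spec")
}

toy_variants <- function() {
  list(
    "Nuc-EtO"  = list(tilt =  0.05, dtilt = -0.03, dv_amp = -0.030, l_h = 1.00),
    "Nuc-AcO"  = list(tilt = -0.05, dtilt =  0.02, dv_amp = -0.020, l_h = 1.00),
    "Nuc-PhO"  = list(tilt =  0.00, dtilt = -0.01, dv_amp = -0.025, l_h = 1.00),
    "mNuc-EtO" = list(tilt =  0.05, dtilt = -0.03, dv_amp = -0.035, l_h = 1.08),
    "mNuc-AcO" = list(tilt = -0.05, dtilt =  0.02, dv_amp = -0.022, l_h = 1.08),
    "mNuc-PhO" = list(tilt =  0.00, dtilt = -0.01, dv_amp = -0.028, l_h = 1.08))
}

#' Template configuration at a given reaction-coordinate value
#'
#' Collinear A-P-B geometry solving `xi = d1 - d2` at the equilibrium bond
#' sum, H along +x from P, and MM particles placed reproducibly on a shell.
#'
#' @param spec a [toy_system_spec()].
#' @param xi reaction-coordinate value (Angstrom).
#' @param seed RNG seed for the MM placement.
#' @return an [atomic_configuration()].
#' @export
toy_template_config <- function(spec, xi = -spec$xi_m, seed = 1L) {
  d1 <- (spec$sigma0 + xi) / 2
  d2 <- (spec$sigma0 - xi) / 2
  if (d1 <= 0.3 || d2 <= 0.3) stop("xi out of the geometrically accessible range")
  pos <- rbind(c(0, 0, d1),        # A
               c(0, 0, 0),         # P
               c(0, 0, -d2),       # B
               c(spec$l_h, 0, 0))  # H
  if (spec$n_mm > 0L) {
    mm <- with_preserved_rng(seed, function() {
      ## even-ish placement on a shell, then jitter
      k <- spec$n_mm
      i <- seq_len(k)
      phi <- 2 * pi * i * (1 + sqrt(5)) / 2
      cz <- (2 * i - 1) / k - 1
      sz <- sqrt(pmax(0, 1 - cz^2))
      rad <- spec$confine_radius - 0.8
      sh <- cbind(rad * sz * cos(phi), rad * sz * sin(phi), rad * cz)
      sh + matrix(stats::rnorm(3 * k, sd = 0.15), k, 3)
    })
    pos <- rbind(pos, mm)
  }
  atomic_configuration(
    species = c(spec$qm_species, rep(spec$mm_species, spec$n_mm)),
    positions = pos,
    region = c(rep("QM", 4L), rep("MM", spec$n_mm)))
}

#' Atomic masses of a toy system
#'
#' @param spec a [toy_system_spec()].
#' @return numeric vector of masses (amu), QM atoms first.
#' @export
toy_masses <- function(spec) c(spec$qm_masses, rep(spec$mm_mass, spec$n_mm))

## smooth pair helper: accumulate energy and gradient for one pair
pair_acc <- function(state, i, j, vfun) {
  u <- state$pos[i, ] - state$pos[j, ]
  r <- sqrt(sum(u^2))
  vd <- vfun(r)
  state$e <- state$e + vd[1]
  g <- (vd[2] / r) * u
  state$g[i, ] <- state$g[i, ] + g
  state$g[j, ] <- state$g[j, ] - g
  state
}

## internal QM profile term V(xi) and its derivative along xi; the target's
## bond-distance wells live in toy_eval (they depend on d1 and d2, not xi)
toy_profile <- function(xi, spec, target) {
  z <- xi / spec$xi_m
  e <- spec$barrier * (z^2 - 1)^2 + spec$tilt * z
  de <- spec$barrier * 4 * z * (z^2 - 1) / spec$xi_m + spec$tilt / spec$xi_m
  if (target) {
    e <- e + spec$dtilt * z
    de <- de + spec$dtilt / spec$xi_m
  }
  c(e, de)
}

## target-only per-bond well: value and derivative in the bond distance
toy_bond_well <- function(d, spec) {
  g <- exp(-(d - spec$well_center)^2 / (2 * spec$well_width^2))
  c(-spec$well_depth * g,
    spec$well_depth * (d - spec$well_center) / spec$well_width^2 * g)
}

toy_eval <- function(config, spec, target) {
  n <- n_atoms(config)
  st <- list(pos = config$positions, e = 0.0, g = matrix(0.0, n, 3))
  ## profile along xi
  xi <- compute_xi(config, spec$rc)
  pr <- toy_profile(xi, spec, target)
  st$e <- st$e + pr[1]
  st$g <- st$g + pr[2] * xi_gradient(config, spec$rc)
  ## bond-sum restraint
  p <- config$positions
  u1 <- p[1, ] - p[2, ]; u2 <- p[2, ] - p[3, ]
  d1 <- sqrt(sum(u1^2)); d2 <- sqrt(sum(u2^2))
  sig <- d1 + d2
  st$e <- st$e + spec$k_sum / 2 * (sig - spec$sigma0)^2
  ds <- spec$k_sum * (sig - spec$sigma0)
  e1 <- u1 / d1; e2 <- u2 / d2
  st$g[1, ] <- st$g[1, ] + ds * e1
  st$g[2, ] <- st$g[2, ] + ds * (-e1 + e2)
  st$g[3, ] <- st$g[3, ] - ds * e2
  ## target-only intermediate stabilization: Gaussian wells in each P-O
  ## bond distance
  if (target) {
    st <- pair_acc(st, 1L, 2L, function(r) toy_bond_well(r, spec))
    st <- pair_acc(st, 2L, 3L, function(r) toy_bond_well(r, spec))
  }
  ## A-B repulsion (discourages bent collapse)
  st <- pair_acc(st, 1L, 3L, function(r) {
    a <- spec$ab_rep
    v <- a[1] * exp(-(r - a[2]) / a[3])
    c(v, -v / a[3])
  })
  ## H tether
  st <- pair_acc(st, 4L, 2L, function(r) {
    c(spec$k_h / 2 * (r - spec$l_h)^2, spec$k_h * (r - spec$l_h))
  })
  mm_idx <- which(config$region == "MM")
  qm_idx <- which(config$region == "QM")
  ## MM-MM soft shell + droplet confinement relative to the QM centroid
  ## (keeps the whole potential translation/rotation invariant)
  if (length(mm_idx) > 0) {
    cqm <- colMeans(p[qm_idx, , drop = FALSE])
    nq <- length(qm_idx)
    for (ii in seq_along(mm_idx)) {
      i <- mm_idx[ii]
      dv <- p[i, ] - cqm
      ri <- sqrt(sum(dv^2))
      if (ri > spec$confine_radius) {
        st$e <- st$e + spec$confine_k / 2 * (ri - spec$confine_radius)^2
        gc <- spec$confine_k * (ri - spec$confine_radius) * dv / ri
        st$g[i, ] <- st$g[i, ] + gc
        st$g[qm_idx, ] <- st$g[qm_idx, ] -
          matrix(gc / nq, nq, 3, byrow = TRUE)
      }
      if (ii < length(mm_idx))
        for (j in mm_idx[(ii + 1):length(mm_idx)]) {
          st <- pair_acc(st, i, j, function(r) {
            a <- spec$mm_rep
            v <- a[1] * exp(-(r - a[2]) / a[3])
            c(v, -v / a[3])
          })
        }
    }
    ## QM-MM pair terms
    for (i in qm_idx) {
      zfac <- spec$dv_species[[as.character(config$species[i])]]
      if (is.null(zfac)) zfac <- 0.5
      for (j in mm_idx) {
        st <- pair_acc(st, i, j, function(r) {
          a <- spec$qmmm_rep
          v <- a[1] * exp(-(r - a[2]) / a[3])
          dv <- -v / a[3]
          if (target && r < spec$r_cut) {
            fenv <- envelope_poly(r, spec$r_cut, spec$envelope_order)
            dfenv <- envelope_poly_deriv(r, spec$r_cut, spec$envelope_order)
            gg <- exp(-(r - spec$dv_r0)^2 / (2 * spec$dv_w^2))
            dgg <- -gg * (r - spec$dv_r0) / spec$dv_w^2
            amp <- spec$dv_amp * zfac
            v <- v + amp * gg * fenv
            dv <- dv + amp * (dgg * fenv + gg * dfenv)
          }
          c(v, dv)
        })
      }
    }
  }
  list(energy = st$e, forces = -st$g)
}

#' Base and target toy potentials
#'
#' Analytic energies and exact gradient forces of the surrogate potentials.
#' The target minus base difference consists of the internal profile change
#' (intermediate well and tilt) plus the short-range QM/MM pair correction,
#' which is exactly zero (with zero slope) for MM atoms beyond the 6 A
#' cutoff of every QM atom.
#'
#' @param config an [atomic_configuration()] built for `spec`.
#' @param spec a [toy_system_spec()].
#' @return list with `energy` (eV) and `forces` (n x 3, eV/Angstrom).
#' @export
base_energy_forces <- function(config, spec) toy_eval(config, spec, FALSE)

#' @rdname base_energy_forces
#' @export
target_energy_forces <- function(config, spec) toy_eval(config, spec, TRUE)

#' Dynamics specification for Langevin umbrella sampling
#'
#' @param temperature temperature (K, default 298).
#' @param friction Langevin collision frequency (ps^-1, default 5).
#' @param dt time step (fs).
#' @param n_equil_steps equilibration steps discarded before production.
#' @param n_prod_steps production steps.
#' @param samples_saved number of evenly spaced production frames kept
#'   (must not exceed `n_prod_steps`).
#' @return object of class `dynamics_spec`.
#' @export
dynamics_spec <- function(temperature = 298, friction = 5, dt = 0.5,
                          n_equil_steps = 300L, n_prod_steps = 1500L,
                          samples_saved = 100L) {
  if (dt <= 0) stop("dt must be positive")
  if (samples_saved > n_prod_steps)
    stop("samples_saved must not exceed n_prod_steps")
  structure(list(temperature = temperature, friction = friction, dt = dt,
                 n_equil_steps = as.integer(n_equil_steps),
                 n_prod_steps = as.integer(n_prod_steps),
                 samples_saved = as.integer(samples_saved)),
            class = "dynamics_spec")
}

#' Langevin umbrella sampling of one window
#'
#' BAOAB-split Langevin dynamics under `potential + k/2 (xi - xi0)^2`.
#' Equilibration frames are discarded; `samples_saved` production frames are
#' kept at even spacing.
#'
#' @param potential function(config) -> list(energy, forces); the unbiased
#'   potential to sample (e.g. [base_energy_forces()] closed over a spec, or
#'   base + correction model).
#' @param window an [umbrella_window()] (force constant in kcal mol^-1 A^-2).
#' @param dynamics a [dynamics_spec()].
#' @param seed integer RNG seed.
#' @param config0 starting [atomic_configuration()].
#' @param rc an [rc_spec()] defining xi.
#' @param masses atomic masses (amu).
#' @return object of class `biased_ensemble`: list with `frames` (list of
#'   configurations), `xi` (per frame), `window`, `dynamics`.
#' @export
run_umbrella_window <- function(potential, window, dynamics, seed, config0,
                                rc, masses) {
  k_ev <- window$force_constant / EV_TO_KCAL
  biased <- function(config) {
    ef <- potential(config)
    xi <- compute_xi(config, rc)
    dxi <- xi - window$center
    ef$energy <- ef$energy + 0.5 * k_ev * dxi^2
    ef$forces <- ef$forces - k_ev * dxi * xi_gradient(config, rc)
    ef
  }
  n <- n_atoms(config0)
  dt <- dynamics$dt
  gamma <- dynamics$friction * 1e-3          # ps^-1 -> fs^-1
  kT_ev <- KB_EV * dynamics$temperature
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(1 - c1^2)
  sig_v <- sqrt(kT_ev * EV_A_AMU_ACC / masses)   # thermal velocity scale per atom
  total <- dynamics$n_equil_steps + dynamics$n_prod_steps
  ## strictly increasing, exactly samples_saved indices in 1..n_prod_steps
  save_at <- dynamics$n_equil_steps +
    as.integer(floor(seq_len(dynamics$samples_saved) *
                       (dynamics$n_prod_steps / dynamics$samples_saved)))
  frames <- vector("list", length(save_at))
  xis <- numeric(length(save_at))
  with_preserved_rng(seed, function() {
    config <- config0
    v <- matrix(stats::rnorm(n * 3), n, 3) * sig_v
    ef <- biased(config)
    if (!is.finite(ef$energy)) stop("non-finite energy at start of window")
    acc <- ef$forces * (EV_A_AMU_ACC / masses)
    isave <- 1L
    for (step in seq_len(total)) {
      v <- v + 0.5 * dt * acc
      config$positions <- config$positions + 0.5 * dt * v
      v <- c1 * v + c2 * (matrix(stats::rnorm(n * 3), n, 3) * sig_v)
      config$positions <- config$positions + 0.5 * dt * v
      ef <- biased(config)
      if (!is.finite(ef$energy)) {
        stop(sprintf("non-finite energy at step %d of window xi0 = %.2f; frame dumped to tempdir",
                     step, window$center))
      }
      acc <- ef$forces * (EV_A_AMU_ACC / masses)
      v <- v + 0.5 * dt * acc
      if (isave <= length(save_at) && step == save_at[isave]) {
        frames[[isave]] <<- config
        xis[isave] <<- compute_xi(config, rc)
        isave <- isave + 1L
      }
    }
  })
  structure(list(frames = frames, xi = xis, window = window,
                 dynamics = dynamics, seed = seed),
            class = "biased_ensemble")
}

#' Generate a labeled reference dataset by base-potential umbrella sampling
#'
#' For each variant and each window of its schedule, runs base-potential
#' Langevin umbrella sampling and annotates every saved frame with base and
#' target energies and forces, producing [labeled_sample()] records.
#'
#' @param variants character vector of [toy_system_spec()] variant names.
#' @param schedule a [make_window_schedule()] result (shared by variants).
#' @param dynamics a [dynamics_spec()].
#' @param seed integer master seed; per-(variant, window) seeds are derived
#'   deterministically.
#' @param n_mm MM particle count per system.
#' @return nested list: `result[[variant]][[window_index]]` is a list of
#'   `labeled_sample` objects (length `dynamics$samples_saved`).
#' @export
generate_reference_dataset <- function(variants, schedule, dynamics, seed,
                                       n_mm = 8L) {
  out <- list()
  for (vi in seq_along(variants)) {
    vname <- variants[vi]
    spec <- toy_system_spec(vname, n_mm = n_mm)
    masses <- toy_masses(spec)
    per_window <- vector("list", length(schedule$windows))
    for (wi in seq_along(schedule$windows)) {
      win <- schedule$windows[[wi]]
      wseed <- (seed * 1009L + vi * 131L + wi) %% 2147483647L
      config0 <- toy_template_config(spec, xi = win$center, seed = wseed)
      ens <- run_umbrella_window(
        function(cfg) base_energy_forces(cfg, spec),
        win, dynamics, wseed, config0, spec$rc, masses)
      per_window[[wi]] <- lapply(seq_along(ens$frames), function(fi) {
        cfg <- ens$frames[[fi]]
        eb <- base_energy_forces(cfg, spec)
        et <- target_energy_forces(cfg, spec)
        labeled_sample(cfg, eb$energy, et$energy, eb$forces, et$forces,
                       xi = ens$xi[fi])
      })
    }
    out[[vname]] <- per_window
  }
  out
}

#' Reference 1-D profile of the internal reaction term
#'
#' Direct numerical evaluation of the xi-dependent internal profile for the
#' isolated QM analog (no MM particles), used as a shape oracle: the base
#' profile has a single barrier between two basins, the target profile has
#' an intermediate well flanked by two barriers.
#'
#' @param spec a [toy_system_spec()].
#' @param xi_grid numeric grid of xi values.
#' @param target logical; evaluate the target (TRUE) or base profile.
#' @return numeric vector of energies (eV) on the grid, min-anchored at 0.
#' @export
toy_profile_curve <- function(spec, xi_grid, target = FALSE) {
  e <- vapply(xi_grid, function(x) {
    v <- toy_profile(x, spec, target)[1]
    if (target) {
      d1 <- (spec$sigma0 + x) / 2
      d2 <- (spec$sigma0 - x) / 2
      v <- v + toy_bond_well(d1, spec)[1] + toy_bond_well(d2, spec)[1]
    }
    v
  }, numeric(1))
  e - min(e)
}

#' Microcanonical (NVE) velocity-Verlet dynamics
#'
#' Integrates Newton's equations without thermostat, recording the total
#' (kinetic + potential) energy trace; used to verify energy conservation
#' of base + correction-model potentials.
#'
#' @param potential function(config) -> list(energy, forces).
#' @param config0 starting [atomic_configuration()].
#' @param masses atomic masses (amu).
#' @param dt time step (fs).
#' @param n_steps number of steps.
#' @param temperature initial Maxwell-Boltzmann velocity temperature (K).
#' @param seed RNG seed for the initial velocities.
#' @return list with `energy` (length n_steps + 1 total-energy trace, eV),
#'   `kinetic` (same length), `config` (final configuration).
#' @export
run_nve <- function(potential, config0, masses, dt, n_steps,
                    temperature = 298, seed = 1L) {
  n <- n_atoms(config0)
  sig_v <- sqrt(KB_EV * temperature * EV_A_AMU_ACC / masses)
  with_preserved_rng(seed, function() {
    config <- config0
    v <- matrix(stats::rnorm(n * 3), n, 3) * sig_v
    v <- sweep(v, 2, colMeans(v * masses) / mean(masses), "-")  # zero net momentum
    ef <- potential(config)
    acc <- ef$forces * (EV_A_AMU_ACC / masses)
    kin <- function(v) sum(0.5 * masses * rowSums(v^2)) / EV_A_AMU_ACC
    etot <- numeric(n_steps + 1L)
    ekin <- numeric(n_steps + 1L)
    etot[1] <- ef$energy + kin(v); ekin[1] <- kin(v)
    for (s in seq_len(n_steps)) {
      v <- v + 0.5 * dt * acc
      config$positions <- config$positions + dt * v
      ef <- potential(config)
      if (!is.finite(ef$energy)) stop("non-finite energy during NVE dynamics")
      acc <- ef$forces * (EV_A_AMU_ACC / masses)
      v <- v + 0.5 * dt * acc
      etot[s + 1L] <- ef$energy + kin(v)
      ekin[s + 1L] <- kin(v)
    }
    list(energy = etot, kinetic = ekin, config = config)
  })
}
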