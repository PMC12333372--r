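#' Training: losses, schedules, committees, and data selection
#'
#' Correction models are fit to energy and force residuals of
#' (target - base) labels with Adam under an exponential learning-rate decay
#' and an exponentially increasing energy-loss weight.  Because site
#' energies are linear in the trainable parameters, each sample contributes
#' fixed design quantities (energy features, force Jacobian) that are
#' precomputed once; the quadratic loss and its exact gradient are then
#' evaluated from Gram matrices at negligible per-step cost.
#'
#' @name training
NULL

#' Loss-weight schedule
#'
#' The energy weight increases exponentially from `p_e_start` to
#' `p_e_limit` (eV^-2) over training; the force weight `p_f`
#' (A^2 eV^-2) is constant.
#'
#' @param p_e_start,p_e_limit energy-residual weights (eV^-2).
#' @param p_f force-residual weight (A^2 eV^-2).
#' @return object of class `loss_schedule`.
#' @export
loss_schedule <- function(p_e_start = 1, p_e_limit = 100, p_f = 100) {
  structure(list(p_e_start = p_e_start, p_e_limit = p_e_limit, p_f = p_f),
            class = "loss_schedule")
}

#' Energy weight at a training fraction
#'
#' `p_e(t) = p_e_start * (p_e_limit/p_e_start)^t` for t in [0, 1].
#'
#' @param schedule a [loss_schedule()].
#' @param frac training progress fraction in [0, 1] (clamped).
#' @return energy weight (eV^-2).
#' @export
p_e_at <- function(schedule, frac) {
  frac <- min(max(frac, 0), 1)
  schedule$p_e_start * (schedule$p_e_limit / schedule$p_e_start)^frac
}

#' Learning-rate schedule
#'
#' Exponential decay from `lr_start` to `lr_stop` over `n_steps`, clamped
#' at `lr_stop` afterwards.  The production-scale protocol uses 400,000
#' steps; the desk default is 2,000 steps with the same endpoint ratio.
#'
#' @param lr_start,lr_stop initial and final learning rates.
#' @param n_steps number of optimization steps.
#' @return object of class `lr_schedule`.
#' @export
lr_schedule <- function(lr_start = 1e-3, lr_stop = 1e-5, n_steps = 2000L) {
  if (lr_start <= 0 || lr_stop <= 0 || n_steps < 1) stop("invalid schedule")
  structure(list(lr_start = lr_start, lr_stop = lr_stop,
                 n_steps = as.integer(n_steps)),
            class = "lr_schedule")
}

#' Learning rate at a step
#'
#' `lr(step) = lr_start * (lr_stop/lr_start)^(min(step, n_steps)/n_steps)`;
#' monotone nonincreasing.
#'
#' @param schedule an [lr_schedule()].
#' @param step step index (>= 0).
#' @return learning rate.
#' @export
lr_at <- function(schedule, step) {
  t <- pmin(step, schedule$n_steps) / schedule$n_steps
  schedule$lr_start * (schedule$lr_stop / schedule$lr_start)^t
}

## residual labels of a sample: energy (eV) and flattened forces (eV/A)
sample_labels <- function(sample) {
  list(y_e = sample$e_target - sample$e_base,
       y_f = as.numeric(t(sample$f_target - sample$f_base)))
}

#' Training loss of a model on a batch
#'
#' Per sample: `p_e(t) (dE)^2 + p_f/(3N) sum |dF|^2`, averaged over the
#' batch, where dE and dF are residuals of the model's correction against
#' the (target - base) labels.
#'
#' @param model a `correction_model`.
#' @param batch list of [labeled_sample()] objects.
#' @param step_fraction training progress in [0, 1] (controls p_e).
#' @param schedule a [loss_schedule()].
#' @return scalar loss.
#' @export
loss <- function(model, batch, step_fraction = 0,
                 schedule = loss_schedule()) {
  if (length(batch) == 0L) stop("batch must be nonempty")
  p_e <- p_e_at(schedule, step_fraction)
  tot <- 0
  for (s in batch) {
    if (nrow(s$f_target) != n_atoms(s$config) ||
        !identical(dim(s$f_target), dim(s$f_base)))
      stop("force array does not match atom count")
    lab <- sample_labels(s)
    ef <- delta_energy_forces(model, s$config)
    dE <- ef$energy - lab$y_e
    dF <- as.numeric(t(ef$forces)) - lab$y_f
    tot <- tot + p_e * dE^2 + schedule$p_f * sum(dF^2) / length(dF)
  }
  tot / length(batch)
}

#' Precompute training design for a dataset
#'
#' Evaluates per-sample energy features and force Jacobians once and
#' accumulates the Gram matrices of the quadratic loss.
#'
#' @param model a `correction_model` (architecture/hyperparameters define
#'   the features; parameter values are irrelevant here).
#' @param samples list of [labeled_sample()] objects.
#' @return object of class `training_design`.
#' @export
training_design <- function(model, samples) {
  P <- length(model$theta)
  H_e <- matrix(0.0, P, P); b_e <- numeric(P)
  H_f <- matrix(0.0, P, P); b_f <- numeric(P)
  c_e <- 0; c_f <- 0
  n <- length(samples)
  designs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    d <- model_design(model, s$config)
    lab <- sample_labels(s)
    D3 <- length(lab$y_f)
    H_e <- H_e + tcrossprod(d$psi)
    b_e <- b_e + lab$y_e * d$psi
    c_e <- c_e + lab$y_e^2
    ## forces = -t(J) theta; residual r = -t(J)theta - y_f
    ## |r|^2/D3 = theta' (JJ'/D3) theta + 2 theta' J y_f / D3 + |y_f|^2/D3
    H_f <- H_f + tcrossprod(d$J) / D3
    b_f <- b_f - as.numeric(d$J %*% lab$y_f) / D3
    c_f <- c_f + sum(lab$y_f^2) / D3
    designs[[i]] <- list(psi = d$psi, J = d$J, y_e = lab$y_e, y_f = lab$y_f)
  }
  structure(list(H_e = H_e / n, b_e = b_e / n, c_e = c_e / n,
                 H_f = H_f / n, b_f = b_f / n, c_f = c_f / n,
                 n = n, P = P, designs = designs),
            class = "training_design")
}

## quadratic loss and gradient at theta given a design and weights
design_loss_grad <- function(des, theta, p_e, p_f) {
  rE <- des$H_e %*% theta - des$b_e
  rF <- des$H_f %*% theta - des$b_f
  l <- p_e * (as.numeric(theta %*% des$H_e %*% theta) -
                2 * sum(des$b_e * theta) + des$c_e) +
    p_f * (as.numeric(theta %*% des$H_f %*% theta) -
             2 * sum(des$b_f * theta) + des$c_f)
  g <- 2 * (p_e * as.numeric(rE) + p_f * as.numeric(rF))
  list(loss = l, grad = g)
}

#' Train a single model with Adam
#'
#' Full-batch Adam on the quadratic energy+force loss with the standard
#' constants (beta1 = 0.9, beta2 = 0.999, eps = 1e-8), the exponential
#' learning-rate decay of `lr_sched` and the energy-weight ramp of
#' `loss_sched`.  Deterministic given the model and data.
#'
#' @param model a `correction_model`.
#' @param design a [training_design()] built for `model`'s architecture, or
#'   a list of [labeled_sample()] (design computed internally).
#' @param lr_sched an [lr_schedule()]; its `n_steps` is the step count.
#' @param loss_sched a [loss_schedule()].
#' @param history_every record the loss every this many steps.
#' @return the trained model with attribute-free `history` element attached
#'   as `model$history` (data.frame: step, loss, lr, p_e).
#' @export
train_model <- function(model, design, lr_sched = lr_schedule(),
                        loss_sched = loss_schedule(), history_every = 100L) {
  if (!inherits(design, "training_design"))
    design <- training_design(model, design)
  theta <- model$theta
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- list()
  n_steps <- lr_sched$n_steps
  for (step in seq_len(n_steps)) {
    frac <- step / n_steps
    p_e <- p_e_at(loss_sched, frac)
    lg <- design_loss_grad(design, theta, p_e, loss_sched$p_f)
    if (!is.finite(lg$loss))
      stop(sprintf("divergent training loss at step %d (loss = %g)", step, lg$loss))
    g <- lg$grad
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^step); vh <- v / (1 - b2^step)
    theta <- theta - lr_at(lr_sched, step) * mh / (sqrt(vh) + eps)
    if (step %% history_every == 0L || step == 1L || step == n_steps)
      hist[[length(hist) + 1L]] <- data.frame(step = step, loss = lg$loss,
                                              lr = lr_at(lr_sched, step),
                                              p_e = p_e)
  }
  model$theta <- theta
  model$history <- do.call(rbind, hist)
  model
}

#' Train a committee of models
#'
#' Repeats the optimization once per seed (default committee size 4),
#' producing independently initialized parameter sets trained on the same
#' data.
#'
#' @param database list of [labeled_sample()] objects.
#' @param architecture `"mace_like"` or `"dp_like"`.
#' @param hyperparams matching hyperparameter object.
#' @param species_codes species table for [init_model()].
#' @param seeds integer vector of seeds (length = committee size).
#' @param lr_sched,loss_sched training schedules.
#' @return object of class `committee`: list with `models`, `seeds`.
#' @export
train_committee <- function(database, architecture, hyperparams,
                            species_codes, seeds = 1:4,
                            lr_sched = lr_schedule(),
                            loss_sched = loss_schedule()) {
  if (length(database) == 0L) stop("database must be nonempty")
  seeds <- as.integer(unlist(seeds))
  models <- vector("list", length(seeds))
  design <- NULL
  for (i in seq_along(seeds)) {
    mdl <- init_model(architecture, hyperparams, seeds[i], species_codes)
    if (is.null(design)) design <- training_design(mdl, database)
    models[[i]] <- train_model(mdl, design, lr_sched, loss_sched)
  }
  structure(list(models = models, seeds = seeds), class = "committee")
}

#' @export
print.committee <- function(x, ...) {
  cat(sprintf("<committee of %d %s models (seeds %s)>\n", length(x$models),
              x$models[[1]]$architecture, paste(x$seeds, collapse = ", ")))
  invisible(x)
}

#' Committee force-RMSE filter
#'
#' For each committee member, computes the root-mean-square error of the
#' predicted atomic force components against the sample's (target - base)
#' force labels; the sample is discarded when the maximum RMSE across
#' members is strictly below the threshold (i.e. every member already
#' predicts its forces well).
#'
#' @param committee a [train_committee()] result.
#' @param sample a [labeled_sample()].
#' @param threshold force RMSE threshold (eV/A, default 0.08).
#' @return list with `keep` (logical; FALSE = discard), `max_rmse`, `rmse`
#'   (per member).
#' @export
force_rmse_filter <- function(committee, sample, threshold = 0.08) {
  lab <- sample_labels(sample)
  rmse <- vapply(committee$models, function(mdl) {
    f <- as.numeric(t(delta_energy_forces(mdl, sample$config)$forces))
    sqrt(mean((f - lab$y_f)^2))
  }, numeric(1))
  mx <- max(rmse)
  list(keep = !(mx < threshold), max_rmse = mx, rmse = rmse)
}

#' Simplify-workflow configuration
#'
#' @param init_fraction fraction of the database trained in round 1.
#' @param round_cap_fraction cap on later rounds' training-set size as a
#'   fraction of the original database.
#' @param force_rmse_threshold committee filter threshold (eV/A).
#' @param committee_size number of committee members.
#' @return object of class `simplify_config`.
#' @export
simplify_config <- function(init_fraction = 0.5, round_cap_fraction = 0.25,
                            force_rmse_threshold = 0.08,
                            committee_size = 4L) {
  structure(list(init_fraction = init_fraction,
                 round_cap_fraction = round_cap_fraction,
                 force_rmse_threshold = force_rmse_threshold,
                 committee_size = as.integer(committee_size)),
            class = "simplify_config")
}

#' The "simplify" iterative data-selection workflow
#'
#' Round 1 trains a committee on a random 50% of the database; the
#' committee filters the remaining test samples by force RMSE, and samples
#' the committee already predicts well are discarded.  Each later round
#' re-trains (warm-started from the previous parameters) on the surviving
#' test set capped at 25% of the original database size and re-filters the
#' remainder.  The process stops when the surviving set is empty or all
#' samples have been used for training; with the default fractions it can
#' never exceed 3 rounds.
#'
#' @param database list of [labeled_sample()] objects.
#' @param architecture,hyperparams,species_codes model definition.
#' @param config a [simplify_config()].
#' @param seeds committee seeds (length `config$committee_size`).
#' @param lr_sched,loss_sched training schedules (per round).
#' @param selection_seed RNG seed for the random partitions (independent of
#'   the model-init seeds).
#' @param filter_fn optional override of the per-sample filter, a
#'   `function(committee, sample)` returning TRUE to keep; used for
#'   workflow-bookkeeping tests.
#' @return list with `committee` (final), `history` (per-round list with
#'   `train_ids`, `test_ids`, `kept_ids`), `n_rounds`.
#' @export
simplify_workflow <- function(database, architecture, hyperparams,
                              species_codes,
                              config = simplify_config(),
                              seeds = 1:4,
                              lr_sched = lr_schedule(),
                              loss_sched = loss_schedule(),
                              selection_seed = 12345L,
                              filter_fn = NULL) {
  n0 <- length(database)
  if (n0 == 0L) stop("database must be nonempty")
  seeds <- seeds[seq_len(config$committee_size)]
  ## ceiling sizes guarantee init + 2 caps >= n0, hence termination in <= 3
  ## rounds for any filter outcome
  cap <- max(1L, ceiling(config$round_cap_fraction * n0))
  if (is.null(filter_fn))
    filter_fn <- function(com, s)
      force_rmse_filter(com, s, config$force_rmse_threshold)$keep
  history <- list()
  committee <- NULL
  pool <- seq_len(n0)             # current database (indices into `database`)
  round <- 0L
  repeat {
    round <- round + 1L
    n_train <- if (round == 1L) max(1L, ceiling(config$init_fraction * n0))
               else min(cap, length(pool))
    train_ids <- with_preserved_rng(selection_seed + round, function()
      sort(pool[sample.int(length(pool), n_train)]))
    test_ids <- setdiff(pool, train_ids)
    train_set <- database[train_ids]
    if (is.null(committee)) {
      committee <- train_committee(train_set, architecture, hyperparams,
                                   species_codes, seeds, lr_sched, loss_sched)
    } else {
      committee <- fine_tune(committee, train_set, lr_sched, loss_sched)
    }
    kept_ids <- test_ids[vapply(test_ids, function(i)
      isTRUE(filter_fn(committee, database[[i]])), logical(1))]
    history[[round]] <- list(train_ids = train_ids, test_ids = test_ids,
                             kept_ids = kept_ids)
    pool <- kept_ids
    if (length(pool) == 0L) break
  }
  list(committee = committee, history = history, n_rounds = round)
}

#' End-state augmentation specification
#'
#' @param copies_per_ensemble samples drawn per ensemble (default 50).
#' @param heavy_max_disp maximum QM heavy-atom displacement (Angstrom).
#' @param h_bond_range range of hydrogen covalent-bond lengths sampled
#'   uniformly (Angstrom).
#' @return object of class `augment_spec`.
#' @export
augment_spec <- function(copies_per_ensemble = 50L, heavy_max_disp = 0.15,
                         h_bond_range = c(0.7, 1.2)) {
  if (heavy_max_disp < 0 || any(h_bond_range <= 0) ||
      h_bond_range[2] < h_bond_range[1])
    stop("invalid augmentation ranges")
  structure(list(copies_per_ensemble = as.integer(copies_per_ensemble),
                 heavy_max_disp = heavy_max_disp,
                 h_bond_range = h_bond_range),
            class = "augment_spec")
}

## nearest QM heavy atom within bonding distance of a hydrogen
find_bonded_heavy <- function(config, ih) {
  qm_heavy <- which(config$region == "QM" & config$species > 1L)
  if (length(qm_heavy) == 0L) stop("hydrogen has no identifiable bonded heavy atom")
  d <- sqrt(rowSums((config$positions[qm_heavy, , drop = FALSE] -
                       matrix(config$positions[ih, ], length(qm_heavy), 3,
                              byrow = TRUE))^2))
  j <- qm_heavy[which.min(d)]
  if (min(d) > 1.8) stop("hydrogen has no identifiable bonded heavy atom")
  j
}

#' End-state data augmentation by random QM displacements
#'
#' From each ensemble, selects `copies_per_ensemble` samples and perturbs
#' the QM atoms: every QM heavy atom moves by a uniformly random direction
#' with magnitude uniform in [0, heavy_max_disp]; every QM hydrogen is moved
#' along its covalent bond so the bond length becomes uniform in
#' `h_bond_range`.  MM atoms are untouched.
#'
#' @param ensembles list of ensembles, each a list of [labeled_sample()].
#' @param spec an [augment_spec()].
#' @param seed RNG seed.
#' @return list of new [atomic_configuration()] objects of length
#'   `copies_per_ensemble * length(ensembles)`.
#' @export
augment_endstates <- function(ensembles, spec = augment_spec(), seed = 1L) {
  for (ens in ensembles)
    if (length(ens) < spec$copies_per_ensemble)
      stop("each ensemble must have at least copies_per_ensemble samples")
  with_preserved_rng(seed, function() {
    out <- list()
    for (ens in ensembles) {
      pick <- sample(length(ens), spec$copies_per_ensemble)
      for (i in pick) {
        cfg <- ens[[i]]$config
        qm <- which(cfg$region == "QM")
        heavy <- qm[cfg$species[qm] > 1L]
        hyd <- qm[cfg$species[qm] == 1L]
        for (a in heavy) {
          dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
          cfg$positions[a, ] <- cfg$positions[a, ] +
            stats::runif(1, 0, spec$heavy_max_disp) * dir
        }
        for (a in hyd) {
          j <- find_bonded_heavy(cfg, a)
          u <- cfg$positions[a, ] - cfg$positions[j, ]
          r <- sqrt(sum(u^2))
          newlen <- stats::runif(1, spec$h_bond_range[1], spec$h_bond_range[2])
          cfg$positions[a, ] <- cfg$positions[j, ] + u / r * newlen
        }
        out[[length(out) + 1L]] <- cfg
      }
    }
    out
  })
}

#' Fine-tune a committee on additional data
#'
#' Restarts each member's optimization from its current parameters on the
#' provided database (e.g. the union of the end-state data and added
#' S:n window selections).
#'
#' @param committee a `committee`.
#' @param database list of [labeled_sample()] to train on.
#' @param lr_sched,loss_sched training schedules for the restart.
#' @return the fine-tuned `committee`.
#' @export
fine_tune <- function(committee, database, lr_sched = lr_schedule(),
                      loss_sched = loss_schedule()) {
  if (length(database) == 0L) return(committee)
  design <- training_design(committee$models[[1]], database)
  committee$models <- lapply(committee$models, function(mdl)
    train_model(mdl, design, lr_sched, loss_sched))
  committee
}
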