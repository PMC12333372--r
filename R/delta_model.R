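#' Range-corrected correction models
#'
#' A `correction_model` predicts the difference between a target and a base
#' potential (energy in eV, forces in eV/Angstrom) as a sum of atomic site
#' energies over the range-corrected graph.  Two architectures are provided:
#' a many-body message-passing model (`"mace_like"`, see [mace_hyperparams()])
#' and a two-body-descriptor baseline (`"dp_like"`, see [dp_hyperparams()]).
#' Both obey the range-correction contract: MM-MM pairs carry no edges, MM
#' species biases are pinned to zero, and every feature vanishes smoothly at
#' the radial cutoff, so the total energy is continuous as MM atoms cross it.
#'
#' @name delta_model
NULL

## run code under a temporary RNG seed, restoring the caller's RNG state
with_preserved_rng <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Initialize a correction model
#'
#' Fixed internal weights and the trainable readout vector are drawn
#' reproducibly from `seed`; the same seed always yields bit-identical
#' parameters.  Species biases exist only for QM codes; MM codes (> 50) are
#' structurally pinned to zero.
#'
#' @param architecture `"mace_like"` or `"dp_like"`.
#' @param hyperparams a [mace_hyperparams()] or [dp_hyperparams()] object
#'   matching the architecture.
#' @param seed integer RNG seed.
#' @param species_codes integer vector of all species codes the model may
#'   encounter (QM atomic numbers and MM codes Z + 50; see [map_species()]).
#' @return object of class `correction_model`.
#' @export
init_model <- function(architecture = c("mace_like", "dp_like"),
                       hyperparams, seed, species_codes) {
  architecture <- match.arg(architecture)
  species_codes <- sort(unique(as.integer(species_codes)))
  qm_codes <- species_codes[!is_mm_code(species_codes)]
  nsp <- length(species_codes)
  model <- with_preserved_rng(seed, function() {
    if (architecture == "mace_like") {
      if (!inherits(hyperparams, "mace_hyperparams"))
        stop("mace_like architecture requires mace_hyperparams")
      fixed <- mace_init_fixed(hyperparams, nsp)
      P <- length(qm_codes) + mace_theta_dim(hyperparams)
    } else {
      if (!inherits(hyperparams, "dp_hyperparams"))
        stop("dp_like architecture requires dp_hyperparams")
      fixed <- dp_init_fixed(hyperparams, nsp)
      P <- length(qm_codes) + nsp * dp_theta_dim_per_species(hyperparams)
    }
    theta <- stats::rnorm(P, sd = 1e-2)
    theta[seq_along(qm_codes)] <- 0.0   # biases start at zero
    list(fixed = fixed, theta = theta)
  })
  structure(list(architecture = architecture, hyperparams = hyperparams,
                 species_codes = species_codes, qm_codes = qm_codes,
                 fixed = model$fixed, theta = model$theta, seed = seed),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model: %s, %d trainable parameters, %d species codes, seed %s>\n",
              x$architecture, length(x$theta), length(x$species_codes),
              format(x$seed)))
  invisible(x)
}

#' Species biases of a model
#'
#' @param model a `correction_model`.
#' @return named numeric vector of per-species-code energy biases (eV);
#'   exactly zero for every MM code.
#' @export
species_bias <- function(model) {
  b <- stats::setNames(numeric(length(model$species_codes)),
                       model$species_codes)
  if (length(model$qm_codes) > 0)
    b[as.character(model$qm_codes)] <- model$theta[seq_along(model$qm_codes)]
  b
}

model_cache <- function(model, config) {
  if (model$architecture == "mace_like") mace_forward_cache(model, config)
  else dp_forward_cache(model, config)
}

model_site_features <- function(model, cache) {
  if (model$architecture == "mace_like") mace_site_features(model, cache)
  else dp_site_features(model, cache)
}

#' Per-atom site energies of the correction
#'
#' The total correction energy is the sum of site energies.  An atom with no
#' graph neighbors contributes exactly its species bias, which is zero for
#' MM atoms.
#'
#' @param model a `correction_model`.
#' @param config an [atomic_configuration()].
#' @return numeric vector of site energies in eV, one per atom.
#' @export
site_energies <- function(model, config) {
  cache <- model_cache(model, config)
  Psi <- model_site_features(model, cache)
  as.numeric(Psi %*% model$theta)
}

#' Correction energy and forces
#'
#' Analytic energy and forces of the correction model; forces are the exact
#' negative gradient of the energy.
#'
#' @param model a `correction_model`.
#' @param config an [atomic_configuration()].
#' @return list with `energy` (eV) and `forces` (n x 3, eV/Angstrom).
#' @export
delta_energy_forces <- function(model, config) {
  cache <- model_cache(model, config)
  Psi <- model_site_features(model, cache)
  energy <- sum(Psi %*% model$theta)
  g <- if (model$architecture == "mace_like")
    mace_energy_gradient(model, cache, model$theta)
  else dp_energy_gradient(model, cache, model$theta)
  list(energy = energy, forces = -g)
}

#' Energy/force design matrices for training
#'
#' Because site energies are linear in the trainable vector theta, a
#' configuration is summarized by its energy feature vector `psi`
#' (E = psi . theta) and force design matrix `Jf` (forces = -t(Jf) theta
#' when flattened atom-major).  These are computed once per sample and reused
#' across optimization steps.
#'
#' @param model a `correction_model`.
#' @param config an [atomic_configuration()].
#' @return list with `psi` (length P) and `J` (P x 3n Jacobian of psi).
#' @export
model_design <- function(model, config) {
  cache <- model_cache(model, config)
  Psi <- model_site_features(model, cache)
  J <- if (model$architecture == "mace_like")
    mace_feature_jacobian(model, cache)
  else dp_feature_jacobian(model, cache)
  list(psi = colSums(Psi), J = J)
}

#' MACE-like forward pass (site energies)
#'
#' Thin wrapper exposing the many-body architecture directly; equivalent to
#' [site_energies()] for a `mace_like` model.
#'
#' @param model a `correction_model` with `architecture == "mace_like"`.
#' @param config an [atomic_configuration()].
#' @return per-atom site energies (eV).
#' @export
mace_forward <- function(model, config) {
  if (model$architecture != "mace_like") stop("model is not mace_like")
  site_energies(model, config)
}

#' DP-like forward pass (site energies)
#'
#' @param model a `correction_model` with `architecture == "dp_like"`.
#' @param config an [atomic_configuration()].
#' @return per-atom site energies (eV).
#' @export
dp_forward <- function(model, config) {
  if (model$architecture != "dp_like") stop("model is not dp_like")
  site_energies(model, config)
}

## ---- checkpoint serialization (single-file JSON archive) ----

pack_numeric <- function(x) {
  if (is.list(x)) return(lapply(x, pack_numeric))
  if (is.matrix(x) || is.array(x))
    return(list(.arr = TRUE, dim = dim(x), data = as.numeric(x)))
  x
}

unpack_numeric <- function(x) {
  if (is.list(x)) {
    if (isTRUE(x$.arr)) {
      a <- array(as.numeric(x$data), dim = as.integer(x$dim))
      return(a)
    }
    return(lapply(x, unpack_numeric))
  }
  x
}

#' Save / load model checkpoints
#'
#' Checkpoints are single-file JSON archives containing the format version,
#' architecture, hyperparameters, species table, fixed weights, trainable
#' parameters and the MM-bias-zero flag.
#'
#' @param model a `correction_model`.
#' @param path file path for the checkpoint.
#' @return `load_model` returns the restored `correction_model`.
#' @export
save_model <- function(model, path) {
  hp <- unclass(model$hyperparams)
  hp$basis <- unclass(hp$basis)
  obj <- list(
    format = "rcdmlp-checkpoint", version = 1L,
    architecture = model$architecture,
    hyperparams_class = class(model$hyperparams)[1],
    hyperparams = hp,
    species_codes = model$species_codes,
    qm_codes = model$qm_codes,
    mm_bias_zero = TRUE,
    seed = model$seed,
    fixed = pack_numeric(model$fixed),
    theta = model$theta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "rcdmlp-checkpoint"))
    stop("not an rcdmlp checkpoint file")
  basis <- lapply(obj$hyperparams$basis, unlist)
  hp <- obj$hyperparams
  hp$basis <- NULL
  hp <- lapply(hp, unlist)
  for (f in intersect(names(hp), c("L", "T_layers", "nu", "N", "l_max",
                                   "readout_channels", "fitting_layers",
                                   "embedding_layers", "axis_filters")))
    hp[[f]] <- as.integer(hp[[f]])
  basis <- structure(list(r_cut = as.numeric(basis$r_cut),
                          n_bessel = as.integer(basis$n_bessel),
                          envelope_order = as.integer(basis$envelope_order)),
                     class = "radial_basis_spec")
  hp$basis <- basis
  hp <- structure(hp, class = obj$hyperparams_class)
  fixed <- unpack_json_fixed(obj$fixed)
  structure(list(architecture = obj$architecture, hyperparams = hp,
                 species_codes = as.integer(unlist(obj$species_codes)),
                 qm_codes = as.integer(unlist(obj$qm_codes)),
                 fixed = fixed, theta = as.numeric(unlist(obj$theta)),
                 seed = unlist(obj$seed)),
            class = "correction_model")
}

## rebuild numeric arrays from the {.arr, dim, data} records
unpack_json_fixed <- function(x) {
  rebuild <- function(node) {
    if (is.list(node) && isTRUE(unlist(node$.arr))) {
      return(array(as.numeric(unlist(node$data)),
                   dim = as.integer(unlist(node$dim))))
    }
    if (is.list(node)) {
      ## plain numeric vectors arrive as lists of scalars
      if (length(node) > 0L && !any(vapply(node, is.list, logical(1))))
        return(unlist(node))
      return(lapply(node, rebuild))
    }
    node
  }
  rebuild(x)
}
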