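#' Atomic configurations
#'
#' An `atomic_configuration` is the unit every stage of the package consumes:
#' atomic numbers, Cartesian coordinates in Angstrom, and a per-atom region
#' label (`"QM"` for the reactive solute treated at the corrected level,
#' `"MM"` for the surrounding environment).
#'
#' @param species integer vector of atomic numbers (> 0).
#' @param positions numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param region character vector, each element `"QM"` or `"MM"`.
#' @return An object of class `atomic_configuration` with elements
#'   `species`, `positions`, `region`.
#' @examples
#' conf <- atomic_configuration(
#'   species = c(8, 15, 8),
#'   positions = rbind(c(0, 0, 1.6), c(0, 0, 0), c(0, 0, -1.6)),
#'   region = c("QM", "QM", "QM"))
#' @export
atomic_configuration <- function(species, positions, region) {
  positions <- as.matrix(positions)
  if (is.null(dim(positions)) || ncol(positions) != 3L)
    stop("`positions` must be an n x 3 matrix")
  n <- nrow(positions)
  species <- as.integer(species)
  if (length(species) != n || length(region) != n)
    stop("`species`, `positions` and `region` must agree on the atom count")
  if (any(!is.finite(positions))) stop("positions must be finite")
  if (any(is.na(species)) || any(species <= 0L))
    stop("species must be positive integers (atomic numbers)")
  if (!all(region %in% c("QM", "MM")))
    stop("region labels must be \"QM\" or \"MM\"")
  if (!any(region == "QM"))
    stop("a configuration must contain at least one QM atom")
  structure(
    list(species = species, positions = positions, region = as.character(region)),
    class = "atomic_configuration")
}

#' @export
print.atomic_configuration <- function(x, ...) {
  cat(sprintf("<atomic_configuration: %d atoms (%d QM, %d MM)>\n",
              length(x$species), sum(x$region == "QM"), sum(x$region == "MM")))
  invisible(x)
}

n_atoms <- function(config) length(config$species)

#' Labeled training/reweighting sample
#'
#' Bundles a configuration with total energies and per-atom forces evaluated
#' at both the base (cheap) and target (expensive) levels, plus the value of
#' the reaction coordinate.
#'
#' @param config an [atomic_configuration()].
#' @param e_base,e_target total energies in eV.
#' @param f_base,f_target n x 3 force matrices in eV/Angstrom.
#' @param xi reaction-coordinate value in Angstrom (see [compute_xi()]).
#' @return object of class `labeled_sample`.
#' @export
labeled_sample <- function(config, e_base, e_target, f_base, f_target, xi) {
  f_base <- as.matrix(f_base); f_target <- as.matrix(f_target)
  n <- n_atoms(config)
  if (!identical(dim(f_base), c(n, 3L)) && !identical(dim(f_base), as.integer(c(n, 3))))
    stop("f_base must be an n x 3 matrix matching the atom count")
  if (nrow(f_target) != n || ncol(f_target) != 3L)
    stop("f_target must be an n x 3 matrix matching the atom count")
  structure(
    list(config = config, e_base = as.numeric(e_base),
         e_target = as.numeric(e_target),
         f_base = f_base, f_target = f_target, xi = as.numeric(xi)),
    class = "labeled_sample")
}

#' Reaction-coordinate specification
#'
#' The distance-difference coordinate of a phosphoryl-transfer-like process:
#' `xi = |R_a - R_p| - |R_p - R_b|`, where `a` is the leaving-group atom
#' (O5' analog), `p` the central atom (P analog) and `b` the nucleophile
#' (O2' analog).
#'
#' @param idx_O5,idx_P,idx_O2 1-based atom indices of the three atoms.
#' @return object of class `rc_spec`.
#' @export
rc_spec <- function(idx_O5, idx_P, idx_O2) {
  idx <- as.integer(c(idx_O5, idx_P, idx_O2))
  if (any(is.na(idx)) || any(idx < 1L)) stop("indices must be positive integers")
  if (length(unique(idx)) != 3L) stop("the three indices must be distinct")
  structure(list(idx_O5 = idx[1], idx_P = idx[2], idx_O2 = idx[3]),
            class = "rc_spec")
}

#' Distance-difference reaction coordinate
#'
#' Computes `xi = |R_O5' - R_P| - |R_P - R_O2'|` in Angstrom.  Negative values
#' correspond to the reactant side (nucleophile far), positive values to the
#' product side.  The coordinate is exactly invariant under rigid rotations
#' and translations of the configuration.
#'
#' @param config an [atomic_configuration()].
#' @param spec an [rc_spec()].
#' @return the coordinate value in Angstrom (scalar).
#' @export
compute_xi <- function(config, spec) {
  n <- n_atoms(config)
  idx <- c(spec$idx_O5, spec$idx_P, spec$idx_O2)
  if (any(idx > n)) stop("rc_spec index out of range for this configuration")
  p <- config$positions
  d1 <- sqrt(sum((p[spec$idx_O5, ] - p[spec$idx_P, ])^2))
  d2 <- sqrt(sum((p[spec$idx_P, ] - p[spec$idx_O2, ])^2))
  d1 - d2
}

## gradient of xi wrt all positions (n x 3); used by the umbrella bias force
xi_gradient <- function(config, spec) {
  p <- config$positions
  g <- matrix(0.0, n_atoms(config), 3L)
  u1 <- p[spec$idx_O5, ] - p[spec$idx_P, ]
  u2 <- p[spec$idx_P, ] - p[spec$idx_O2, ]
  r1 <- sqrt(sum(u1^2)); r2 <- sqrt(sum(u2^2))
  e1 <- u1 / r1; e2 <- u2 / r2
  g[spec$idx_O5, ] <- e1
  g[spec$idx_P, ] <- -e1 - e2
  g[spec$idx_O2, ] <- e2
  g
}

#' Umbrella window and window schedules
#'
#' An umbrella window is a harmonic bias `k/2 (xi - xi0)^2` restraining the
#' reaction coordinate near a center `xi0`.  A window schedule is the evenly
#' spaced ladder of windows spanning the coordinate range.
#'
#' @param center window center xi0 in Angstrom.
#' @param force_constant bias force constant k in kcal mol^-1 A^-2 (> 0).
#' @return object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_constant) {
  if (!is.finite(force_constant) || force_constant <= 0)
    stop("force_constant must be positive")
  structure(list(center = as.numeric(center),
                 force_constant = as.numeric(force_constant)),
            class = "umbrella_window")
}

#' Build an evenly spaced umbrella-window schedule
#'
#' Centers run from `xi_min` to `xi_max` inclusive in steps of `step`; the
#' canonical production schedule uses 64 windows from -3.3 to 3.0 Angstrom in
#' 0.1 Angstrom increments with k = 300 kcal mol^-1 A^-2.
#'
#' @param xi_min,xi_max range of window centers (Angstrom), `xi_max >= xi_min`.
#' @param step center spacing (Angstrom, > 0).
#' @param force_constant shared bias force constant (kcal mol^-1 A^-2).
#' @return object of class `window_schedule`: list with `windows` (list of
#'   [umbrella_window()]), `centers`, `xi_min`, `xi_max`, `step`,
#'   `force_constant`.
#' @examples
#' sched <- make_window_schedule(-3.3, 3.0, 0.1, 300)
#' length(sched$windows)  # 64
#' @export
make_window_schedule <- function(xi_min, xi_max, step, force_constant = 300) {
  if (!is.finite(step) || step <= 0) stop("step must be positive")
  if (xi_max < xi_min) stop("xi_max must be >= xi_min")
  n <- as.integer(round((xi_max - xi_min) / step)) + 1L
  centers <- xi_min + step * (seq_len(n) - 1L)
  windows <- lapply(centers, umbrella_window, force_constant = force_constant)
  structure(list(windows = windows, centers = centers,
                 xi_min = xi_min, xi_max = xi_max, step = step,
                 force_constant = force_constant),
            class = "window_schedule")
}

#' @export
print.window_schedule <- function(x, ...) {
  cat(sprintf("<window_schedule: %d windows, centers %.2f..%.2f A, k = %g kcal/mol/A^2>\n",
              length(x$windows), min(x$centers), max(x$centers), x$force_constant))
  invisible(x)
}

#' Stride through a window schedule
#'
#' Keeps every `stride`-th window starting at the first (most negative)
#' center, mirroring the S:n selections: stride 1 keeps all 64 windows,
#' stride 2 keeps 32 (last center 2.9 A), stride 4 keeps 16 (last 2.7 A),
#' stride 8 keeps 8 (last 2.3 A) on the canonical schedule.
#'
#' @param schedule a [make_window_schedule()] result.
#' @param stride positive integer.
#' @return a new `window_schedule` with the retained windows.
#' @export
stride_select <- function(schedule, stride) {
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be a positive integer")
  keep <- seq(1L, length(schedule$windows), by = stride)
  centers <- schedule$centers[keep]
  structure(list(windows = schedule$windows[keep], centers = centers,
                 xi_min = centers[1], xi_max = centers[length(centers)],
                 step = schedule$step * stride,
                 force_constant = schedule$force_constant),
            class = "window_schedule")
}

#' Select end-state windows across reactions
#'
#' Returns one (reaction, window) entry per reaction and requested endpoint,
#' e.g. the 12 end-state simulations of 6 reactions at xi = -2.0 and 3.0 A.
#'
#' @param schedules named list of `window_schedule`, one per reaction.
#' @param endpoints numeric vector of window centers (Angstrom); each must
#'   match an existing center within 1e-9 A.
#' @return data.frame with columns `reaction`, `endpoint`, `window_index`.
#' @export
select_endstate_windows <- function(schedules, endpoints) {
  if (is.null(names(schedules)))
    names(schedules) <- paste0("reaction", seq_along(schedules))
  out <- list()
  for (rn in names(schedules)) {
    centers <- schedules[[rn]]$centers
    for (ep in endpoints) {
      j <- which(abs(centers - ep) < 1e-9)
      if (length(j) != 1L)
        stop(sprintf("endpoint %.6g A is not a window center of reaction '%s'", ep, rn))
      out[[length(out) + 1L]] <- data.frame(
        reaction = rn, endpoint = ep, window_index = j,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write / read a window schedule as TSV
#'
#' @param schedule a `window_schedule`.
#' @param path file path.
#' @return `read_window_schedule` returns a `window_schedule`.
#' @export
write_window_schedule <- function(schedule, path) {
  df <- data.frame(center = schedule$centers,
                   force_constant = schedule$force_constant)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_window_schedule
#' @export
read_window_schedule <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  centers <- df$center
  step <- if (length(centers) > 1) centers[2] - centers[1] else 0.1
  make_window_schedule(centers[1], centers[length(centers)],
                       step = if (step > 0) step else 0.1,
                       force_constant = df$force_constant[1])
}
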