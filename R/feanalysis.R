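#' Free-energy estimation and reliability diagnostics
#'
#' Multistate Bennett acceptance ratio (MBAR) estimation over umbrella
#' windows, histogram free-energy surfaces (FES), weighted thermodynamic
#' perturbation to a target potential from one reference (wTP) or several
#' pooled references (gwTP), per-bin reweighting-entropy diagnostics, and
#' density-of-states smoothing of perturbation weights.
#'
#' @name feanalysis
NULL

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Solve the MBAR self-consistent equations
#'
#' Given the reduced-potential matrix `u_kn` (dimensionless, state k by
#' sample n) and per-state sample counts `N_k`, iterates
#' `f_k = -log sum_n exp(-u_kn) / D_n`, `D_n = sum_k N_k exp(f_k - u_kn)`
#' to self-consistency.  Free energies are anchored at `f_1 = 0`.
#'
#' @param u_matrix K x N matrix of reduced potentials beta*(U + bias).
#' @param N_k integer vector of per-state sample counts (sum = N).
#' @param tol relative tolerance on `f_k` (default 1e-10).
#' @param max_iter maximum iterations.
#' @return object of class `mbar_result`: `f_k` (dimensionless), `log_D`
#'   (per-sample log denominators), `n_iter`, `residual`.
#' @export
mbar_solve <- function(u_matrix, N_k, tol = 1e-10, max_iter = 100000L) {
  u_matrix <- as.matrix(u_matrix)
  K <- nrow(u_matrix); N <- ncol(u_matrix)
  if (length(N_k) != K) stop("length(N_k) must equal nrow(u_matrix)")
  if (sum(N_k) != N) stop("sum(N_k) must equal the number of samples")
  if (any(!is.finite(u_matrix))) stop("u_matrix must be finite")
  logN <- log(N_k)
  log_D_of <- function(f) {
    A <- (logN + f) - u_matrix                # K x N (column recycling)
    m <- apply(A, 2, max)
    m + log(colSums(exp(sweep(A, 2, m, "-"))))
  }
  scf_update <- function(f) {
    log_D <- log_D_of(f)
    Bm <- -u_matrix - matrix(log_D, K, N, byrow = TRUE)
    mm <- apply(Bm, 1, max)
    f_new <- -(mm + log(rowSums(exp(Bm - mm))))
    f_new - f_new[1]
  }
  ## stage 1: minimize the convex MBAR objective (Newton-type acceleration
  ## via BFGS with the analytic gradient), free energies relative to state 1
  negll <- function(fr) {
    f <- c(0, fr)
    sum(log_D_of(f)) - sum(N_k * f)
  }
  negll_grad <- function(fr) {
    f <- c(0, fr)
    log_D <- log_D_of(f)
    W <- exp((logN + f) - u_matrix - matrix(log_D, K, N, byrow = TRUE))
    (rowSums(W) - N_k)[-1]
  }
  f <- numeric(K)
  if (K > 1L) {
    opt <- stats::optim(numeric(K - 1L), negll, negll_grad, method = "BFGS",
                        control = list(maxit = 1000L, reltol = 1e-15))
    f <- c(0, opt$par)
  }
  ## stage 2: self-consistent polishing to the requested tolerance
  residual <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    f_new <- scf_update(f)
    residual <- max(abs(f_new - f) / pmax(1, abs(f_new)))
    f <- f_new
    if (residual < tol || iter >= max_iter) break
  }
  if (residual >= tol)
    stop(sprintf("MBAR failed to converge: residual %.3g after %d iterations",
                 residual, iter))
  log_D <- log_D_of(f)
  ## final denominators at converged f
  A <- (logN + f) - u_matrix
  m <- apply(A, 2, max)
  log_D <- m + log(colSums(exp(sweep(A, 2, m, "-"))))
  structure(list(f_k = f, log_D = log_D, n_iter = iter, residual = residual),
            class = "mbar_result")
}

#' Unbiased sample log-weights from an MBAR result
#'
#' `log w_n = -u0_n - log D_n` (unnormalized), where `u0_n` is the reduced
#' unbiased potential of the reweighting target evaluated at sample n.
#'
#' @param mbar an `mbar_result`.
#' @param u0 reduced unbiased potential per sample (dimensionless).
#' @return normalized weights summing to 1.
#' @export
mbar_weights <- function(mbar, u0) {
  lw <- -u0 - mbar$log_D
  w <- exp(lw - logsumexp(lw))
  w
}

## snap xi values to the histogram grid (bins centered on multiples of width)
xi_bin_center <- function(xi, bin_width) round(xi / bin_width) * bin_width

#' Histogram free-energy surface from sample weights
#'
#' `F(b) = -kT log sum_{n in b} w_n`, computed on a grid of bins of width
#' `bin_width` centered on integer multiples of the width (aligned with the
#' umbrella window centers), shifted so the minimum over occupied bins is 0.
#' Unoccupied bins are reported as `NA` and never interpolated.
#'
#' @param weights per-sample weights (need not be normalized).
#' @param xi per-sample reaction-coordinate values (Angstrom).
#' @param bin_width histogram spacing (Angstrom, default 0.1).
#' @param temperature temperature (K) used for kT.
#' @return object of class `fes`: list with `centers`, `values` (kcal/mol,
#'   min 0), `n_samples`, `bin_width`, `temperature`.
#' @export
fes_from_weights <- function(weights, xi, bin_width = 0.1, temperature = 298) {
  if (length(weights) != length(xi)) stop("weights and xi must align")
  w <- weights / sum(weights)
  bc <- xi_bin_center(xi, bin_width)
  grid <- seq(min(bc), max(bc), by = bin_width)
  ## match tolerance-robustly via integer indices
  idx <- as.integer(round((bc - grid[1]) / bin_width)) + 1L
  mass <- numeric(length(grid))
  cnt <- integer(length(grid))
  for (n in seq_along(idx)) {
    mass[idx[n]] <- mass[idx[n]] + w[n]
    cnt[idx[n]] <- cnt[idx[n]] + 1L
  }
  kT <- KB_KCAL * temperature
  vals <- ifelse(mass > 0, -kT * log(mass), NA_real_)
  vals <- vals - min(vals, na.rm = TRUE)
  structure(list(centers = grid, values = vals, n_samples = cnt,
                 bin_width = bin_width, temperature = temperature),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  occ <- sum(!is.na(x$values))
  cat(sprintf("<fes: %d bins (%d occupied), width %.3g A, max %.2f kcal/mol>\n",
              length(x$centers), occ, x$bin_width, max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Reweighting entropy of a weight set
#'
#' Normalized Shannon entropy `-sum w~ log w~ / log n` of the weights within
#' one histogram bin: 1 for uniform weights, approaching 0 when a few
#' samples dominate.  Requires n >= 2 samples.
#'
#' @param weights nonnegative weights, not all zero, length >= 2.
#' @return value in [0, 1].
#' @export
reweighting_entropy <- function(weights) {
  n <- length(weights)
  if (n < 2L) stop("reweighting entropy requires at least 2 samples")
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  w <- weights / s
  nz <- w > 0
  -sum(w[nz] * log(w[nz])) / log(n)
}

#' Density-of-states smoothing of perturbation energies
#'
#' Histograms the dimensionless perturbation energies `delta_u` of one
#' spatial bin into energy bins of width `energy_bin_width` (in kT) and
#' assigns every sample in an energy bin the identical weight factor: the
#' bin average of `exp(-delta_u)`.  Sharing the mean weight preserves each
#' energy bin's total weight mass, so the smoothing dampens outlier weights
#' within a spatial bin without ever decreasing the bin's reweighting
#' entropy; it never mixes information between spatial bins.
#'
#' @param delta_u dimensionless perturbation energies beta*(U_target-U_ref)
#'   of the samples in one spatial bin.
#' @param energy_bin_width energy histogram width in kT (default 0.2).
#' @return list with `factors` (per-sample weight factors) and
#'   `delta_u_smoothed` (per-sample effective energies, -log(factors)).
#' @export
dos_smoothing <- function(delta_u, energy_bin_width = 0.2) {
  if (length(delta_u) == 0L) stop("empty spatial bin")
  if (energy_bin_width <= 0) stop("energy_bin_width must be positive")
  eb <- floor((delta_u - min(delta_u)) / energy_bin_width)
  ## bin-shared mean weight, computed stably relative to the smallest energy
  ref <- min(delta_u)
  fac <- stats::ave(exp(-(delta_u - ref)), eb) * exp(-ref)
  list(factors = fac, delta_u_smoothed = -log(fac))
}

#' Smoothing specification
#'
#' @param energy_bin_width width of the perturbation-energy histogram in kT.
#' @return object of class `smoothing_spec`.
#' @export
smoothing_spec <- function(energy_bin_width = 0.2) {
  if (energy_bin_width <= 0) stop("energy_bin_width must be positive")
  structure(list(energy_bin_width = energy_bin_width), class = "smoothing_spec")
}

#' Assemble a reweighting input from labeled umbrella samples
#'
#' Collects pooled samples from one or more reference models into the form
#' consumed by [wtp_estimate()] and [gwtp_estimate()]: every reference
#' model's unbiased potential energy must be available for every pooled
#' sample, alongside the target potential energy.
#'
#' @param xi per-sample reaction-coordinate values (Angstrom).
#' @param u_models N x M matrix of unbiased reference energies (eV); column
#'   m is reference model m evaluated on all samples.
#' @param u_target per-sample target energies (eV).
#' @param model_of integer in 1..M: which model generated each sample.
#' @param window_of integer in 1..K: which umbrella window generated each
#'   sample.
#' @param windows list of [umbrella_window()] (shared across models).
#' @param temperature temperature (K).
#' @return object of class `reweight_input`.
#' @export
reweight_input <- function(xi, u_models, u_target, model_of, window_of,
                           windows, temperature = 298) {
  u_models <- as.matrix(u_models)
  N <- length(xi)
  if (nrow(u_models) != N || length(u_target) != N ||
      length(model_of) != N || length(window_of) != N)
    stop("per-sample inputs must align")
  if (any(model_of < 1L | model_of > ncol(u_models)))
    stop("model_of out of range")
  if (any(window_of < 1L | window_of > length(windows)))
    stop("window_of out of range")
  structure(list(xi = xi, u_models = u_models, u_target = as.numeric(u_target),
                 model_of = as.integer(model_of),
                 window_of = as.integer(window_of),
                 windows = windows, temperature = temperature),
            class = "reweight_input")
}

## pooled MBAR over all (model, window) states with nonzero counts
reweight_mbar <- function(input, tol = 1e-10) {
  beta <- 1 / (KB_EV * input$temperature)
  M <- ncol(input$u_models); K <- length(input$windows)
  N <- length(input$xi)
  ## bias energies per (window, sample)
  kcent <- vapply(input$windows, function(w) w$center, numeric(1))
  kfc <- vapply(input$windows, function(w) w$force_constant, numeric(1)) / EV_TO_KCAL
  states <- expand.grid(window = seq_len(K), model = seq_len(M))
  state_of_sample <- (input$model_of - 1L) * K + input$window_of
  N_k <- tabulate(state_of_sample, nbins = nrow(states))
  keep <- which(N_k > 0L)
  u <- matrix(0.0, length(keep), N)
  for (si in seq_along(keep)) {
    st <- keep[si]
    kw <- states$window[st]; km <- states$model[st]
    bias <- 0.5 * kfc[kw] * (input$xi - kcent[kw])^2
    u[si, ] <- beta * (input$u_models[, km] + bias)
  }
  ## remap sample states to kept indices for counting
  mb <- mbar_solve(u, N_k[keep], tol = tol)
  list(mbar = mb, beta = beta)
}

## shared wTP/gwTP engine
reweight_engine <- function(input, smoothing, bin_width) {
  rm_ <- reweight_mbar(input)
  beta <- rm_$beta
  mb <- rm_$mbar
  N <- length(input$xi)
  ## perturbation against each sample's own generating reference
  own_ref <- input$u_models[cbind(seq_len(N), input$model_of)]
  delta_u <- beta * (input$u_target - own_ref)
  ## per-spatial-bin weight factors (optionally DoS-smoothed)
  bc <- xi_bin_center(input$xi, bin_width)
  fac_log <- -delta_u
  if (!is.null(smoothing)) {
    for (b in unique(bc)) {
      sel <- which(abs(bc - b) < bin_width / 4)
      sm <- dos_smoothing(delta_u[sel], smoothing$energy_bin_width)
      fac_log[sel] <- -sm$delta_u_smoothed
    }
  }
  ## target weights: exp(-beta U_ref,own + fac_log - log D); with no
  ## smoothing fac_log = -delta_u, so the numerator is exp(-beta U_target)
  log_w <- -beta * own_ref - mb$log_D + fac_log
  w <- exp(log_w - logsumexp(log_w))
  fes <- fes_from_weights(w, input$xi, bin_width, input$temperature)
  ## per-bin reweighting entropy of the perturbation factors
  re <- rep(NA_real_, length(fes$centers))
  for (bi in seq_along(fes$centers)) {
    sel <- which(abs(bc - fes$centers[bi]) < bin_width / 4)
    if (length(sel) >= 2L) re[bi] <- reweighting_entropy(exp(fac_log[sel] - max(fac_log[sel])))
  }
  occ <- !is.na(re)
  structure(list(fes = fes, re_per_bin = re,
                 mean_re = mean(re[occ]), std_re = stats::sd(re[occ]),
                 mbar = mb, weights = w),
            class = "reweighting_report")
}

#' @export
print.reweighting_report <- function(x, ...) {
  cat(sprintf("<reweighting_report: %d bins, mean RE %.3f +/- %.3f>\n",
              length(x$re_per_bin), x$mean_re, x$std_re))
  invisible(x)
}

#' Weighted thermodynamic perturbation (wTP) from one reference model
#'
#' Reweights umbrella samples drawn from a single reference potential to
#' estimate the target potential's free-energy surface, with a per-bin
#' reweighting-entropy diagnostic.  When the target equals the reference the
#' result reproduces the reference MBAR FES exactly and every bin's
#' reweighting entropy is 1.
#'
#' @param input a [reweight_input()] with exactly one reference model.
#' @param smoothing a [smoothing_spec()] or `NULL` for no density-of-states
#'   smoothing.
#' @param bin_width spatial histogram width (Angstrom).
#' @return object of class `reweighting_report`: `fes`, `re_per_bin`,
#'   `mean_re`, `std_re`, plus the underlying `mbar` result and weights.
#' @export
wtp_estimate <- function(input, smoothing = NULL, bin_width = 0.1) {
  if (ncol(input$u_models) != 1L)
    stop("wtp_estimate expects a single reference model; use gwtp_estimate")
  reweight_engine(input, smoothing, bin_width)
}

#' Generalized weighted thermodynamic perturbation (gwTP)
#'
#' Pools the umbrella sampling of multiple reference models into a single
#' MBAR over all (model, window) states and reweights to the target
#' potential, producing one FES and reweighting-entropy report.  With a
#' single reference model this reduces exactly to [wtp_estimate()].
#'
#' @inheritParams wtp_estimate
#' @param input a [reweight_input()]; every reference model's energies must
#'   be present for every pooled sample.
#' @export
gwtp_estimate <- function(input, smoothing = NULL, bin_width = 0.1) {
  reweight_engine(input, smoothing, bin_width)
}

#' MBAR reference free-energy surface
#'
#' The FES of the reference sampling itself (no perturbation): unbiased
#' MBAR weights histogrammed on the xi grid.
#'
#' @param input a [reweight_input()] (single model or pooled).
#' @param bin_width spatial histogram width (Angstrom).
#' @return an `fes` object.
#' @export
mbar_fes <- function(input, bin_width = 0.1) {
  rm_ <- reweight_mbar(input)
  own_ref <- input$u_models[cbind(seq_along(input$xi), input$model_of)]
  w <- mbar_weights(rm_$mbar, rm_$beta * own_ref)
  fes_from_weights(w, input$xi, bin_width, input$temperature)
}

#' Average free-energy surfaces
#'
#' Per-bin arithmetic mean over surfaces defined on a common grid,
#' re-anchored so the minimum over occupied bins is zero.  Bins missing in
#' any surface are averaged over the surfaces that define them.
#'
#' @param surfaces list of `fes` objects on a common bin grid.
#' @return an `fes` object.
#' @export
average_surfaces <- function(surfaces) {
  if (length(surfaces) == 0L) stop("no surfaces to average")
  ## align on the union grid
  allc <- sort(unique(round(unlist(lapply(surfaces, `[[`, "centers")) /
                              surfaces[[1]]$bin_width)))
  bw <- surfaces[[1]]$bin_width
  grid <- allc * bw
  for (s in surfaces) {
    if (abs(s$bin_width - bw) > 1e-12)
      stop("surfaces use different bin widths")
  }
  acc <- matrix(NA_real_, length(surfaces), length(grid))
  cnt <- matrix(0L, length(surfaces), length(grid))
  for (si in seq_along(surfaces)) {
    s <- surfaces[[si]]
    idx <- match(round(s$centers / bw), allc)
    acc[si, idx] <- s$values
    cnt[si, idx] <- s$n_samples
  }
  vals <- colMeans(acc, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  vals <- vals - min(vals, na.rm = TRUE)
  structure(list(centers = grid, values = vals,
                 n_samples = as.integer(colSums(cnt)),
                 bin_width = bw, temperature = surfaces[[1]]$temperature),
            class = "fes")
}

#' Write an FES / reweighting report as TSV
#'
#' Columns: bin center, free energy (kcal/mol), reweighting entropy (if
#' available), sample count.
#'
#' @param report an `fes` or `reweighting_report`.
#' @param path output file path.
#' @export
write_fes_tsv <- function(report, path) {
  if (inherits(report, "reweighting_report")) {
    df <- data.frame(center = report$fes$centers, value = report$fes$values,
                     re = report$re_per_bin, n_samples = report$fes$n_samples)
  } else {
    df <- data.frame(center = report$centers, value = report$values,
                     n_samples = report$n_samples)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
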