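## DP-like two-body-descriptor correction model (DeepPot-SE family).
##
## Per atom: each neighbor within the range-corrected graph contributes a
## smooth scalar weight s(r) = f_env(r)/r (zero with zero slope at r_cut)
## and a coordinate-matrix row s(r) * (1, x/r, y/r, z/r).  A species-specific
## embedding network maps s(r) to an M-vector; the embedding matrix is
## contracted with the coordinate matrix and with its first `axis_filters`
## rows to form the symmetry-preserving feature matrix D = T T'^t, which a
## fitting network maps to the atomic site energy.  As in the MACE-like
## model the embedding and fitting hidden weights are fixed at seeded random
## values and the trainable parameters are per-species readout weights plus
## QM species biases (MM biases pinned to zero), so site energies are linear
## in the trainable vector.

DP_SCALE <- 0.25  # fixed normalization of the neighbor sum

#' DP-like hyperparameters
#'
#' @param fitting_layers hidden widths of the fitting network (desk default
#'   c(24, 24, 24); production scale c(240, 240, 240)).
#' @param embedding_layers widths of the per-species embedding network (desk
#'   default c(8, 16, 32); production scale c(25, 50, 100)).
#' @param axis_filters number of retained coordinate-matrix columns in the
#'   feature contraction (default 12).
#' @param basis a [radial_basis_spec()]; only `r_cut` and `envelope_order`
#'   are used by this architecture.
#' @return object of class `dp_hyperparams`.
#' @export
dp_hyperparams <- function(fitting_layers = c(24L, 24L, 24L),
                           embedding_layers = c(8L, 16L, 32L),
                           axis_filters = 12L,
                           basis = radial_basis_spec()) {
  if (any(fitting_layers < 1) || any(embedding_layers < 1))
    stop("all layer widths must be >= 1")
  M <- embedding_layers[length(embedding_layers)]
  if (axis_filters < 1 || axis_filters > M)
    stop("axis_filters must be between 1 and the embedding output width")
  structure(list(fitting_layers = as.integer(fitting_layers),
                 embedding_layers = as.integer(embedding_layers),
                 axis_filters = as.integer(axis_filters),
                 basis = basis),
            class = "dp_hyperparams")
}

dp_theta_dim_per_species <- function(hp) hp$fitting_layers[length(hp$fitting_layers)]

dp_init_fixed <- function(hp, n_species) {
  emb <- lapply(seq_len(n_species), function(s) {
    widths <- hp$embedding_layers
    W <- list(); b <- list()
    prev <- 1L
    for (k in seq_along(widths)) {
      W[[k]] <- matrix(stats::rnorm(widths[k] * prev, sd = 1 / sqrt(prev)),
                       widths[k], prev)
      b[[k]] <- stats::rnorm(widths[k], sd = 0.5)
      prev <- widths[k]
    }
    list(W = W, b = b)
  })
  M <- hp$embedding_layers[length(hp$embedding_layers)]
  Fdim <- M * hp$axis_filters
  fit <- list(W = list(), b = list())
  prev <- Fdim
  for (k in seq_along(hp$fitting_layers)) {
    w <- hp$fitting_layers[k]
    fit$W[[k]] <- matrix(stats::rnorm(w * prev, sd = 1 / sqrt(prev)), w, prev)
    fit$b[[k]] <- stats::rnorm(w, sd = 0.5)
    prev <- w
  }
  list(emb = emb, fit = fit)
}

## embedding net on a vector of scalar inputs: values (ne x M) and d/ds
dp_embed_eval <- function(net, s) {
  a <- matrix(s, length(s), 1)
  d <- matrix(1, length(s), 1)
  for (k in seq_along(net$W)) {
    z <- a %*% t(net$W[[k]])
    z <- sweep(z, 2, net$b[[k]], "+")
    t_ <- tanh(z)
    d <- (d %*% t(net$W[[k]])) * (1 - t_^2)
    a <- t_
  }
  list(G = a, dG = d)
}

## fitting net forward on one feature vector; returns value, per-layer
## activations (for backprop) and optionally the full input Jacobian
dp_fit_eval <- function(fit, f, jacobian = FALSE) {
  a <- as.numeric(f)
  acts <- list()
  J <- NULL
  if (jacobian) J <- diag(length(f))
  for (k in seq_along(fit$W)) {
    z <- as.numeric(fit$W[[k]] %*% a + fit$b[[k]])
    a <- tanh(z)
    acts[[k]] <- a
    if (jacobian) J <- ((1 - a^2) * fit$W[[k]]) %*% J
  }
  list(h = a, acts = acts, J = J)
}

## backward through the fitting net: adjoint of the input given g_h
dp_fit_back <- function(fit, acts, f, g_h) {
  g <- g_h
  for (k in rev(seq_along(fit$W))) {
    g <- g * (1 - acts[[k]]^2)
    g <- as.numeric(t(fit$W[[k]]) %*% g)
  }
  g
}

dp_forward_cache <- function(model, config) {
  hp <- model$hyperparams
  n <- n_atoms(config)
  codes <- map_species(config)
  sp_idx <- match(codes, model$species_codes)
  if (anyNA(sp_idx))
    stop("configuration contains species codes absent from the model's species table")
  edges <- build_edges(config, hp$basis$r_cut)
  ne <- length(edges$sender)
  M <- hp$embedding_layers[length(hp$embedding_layers)]
  Mp <- hp$axis_filters
  cache <- list(hp = hp, n = n, ne = ne, edges = edges, sp_idx = sp_idx,
                codes = codes, M = M, Mp = Mp)
  ## h0: fitting net at zero features (subtracted so empty environments give 0)
  f0 <- numeric(M * Mp)
  cache$h0 <- dp_fit_eval(model$fixed$fit, f0)$h
  if (ne > 0L) {
    r <- edges$distance
    p <- hp$basis$envelope_order; rc <- hp$basis$r_cut
    env <- envelope_poly(r, rc, p); denv <- envelope_poly_deriv(r, rc, p)
    s <- env / r
    dsdr <- (denv * r - env) / r^2
    uhat <- edges$displacement / r
    Rhat <- cbind(s, s * uhat)                      # ne x 4
    cache$s <- s; cache$dsdr <- dsdr; cache$uhat <- uhat; cache$Rhat <- Rhat
    ## species-resolved embedding
    G <- matrix(0.0, ne, M); dG <- matrix(0.0, ne, M)
    snd_sp <- sp_idx[edges$sender]
    for (sp in unique(snd_sp)) {
      sel <- which(snd_sp == sp)
      ev <- dp_embed_eval(model$fixed$emb[[sp]], s[sel])
      G[sel, ] <- ev$G; dG[sel, ] <- ev$dG
    }
    cache$G <- G; cache$dG <- dG
  }
  Tm <- vector("list", n); Dm <- vector("list", n)
  hvals <- matrix(0.0, n, dp_theta_dim_per_species(hp))
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    Ti <- matrix(0.0, M, 4)
    if (ne > 0L) {
      sel <- which(edges$receiver == i)
      if (length(sel) > 0L)
        Ti <- crossprod(cache$G[sel, , drop = FALSE],
                        cache$Rhat[sel, , drop = FALSE]) * DP_SCALE
    }
    Di <- Ti %*% t(Ti[seq_len(Mp), , drop = FALSE])  # M x Mp
    fe <- dp_fit_eval(model$fixed$fit, as.numeric(Di))
    Tm[[i]] <- Ti; Dm[[i]] <- Di
    hvals[i, ] <- fe$h - cache$h0
    fits[[i]] <- fe
  }
  cache$Tm <- Tm; cache$Dm <- Dm; cache$h <- hvals; cache$fits <- fits
  cache
}

## per-atom feature matrix: [qm bias indicators | per-species readout blocks]
dp_site_features <- function(model, cache) {
  hp <- cache$hp; n <- cache$n
  H <- dp_theta_dim_per_species(hp)
  nsp <- length(model$species_codes)
  nbias <- length(model$qm_codes)
  P <- nbias + nsp * H
  Psi <- matrix(0.0, n, P)
  if (nbias > 0L) {
    j <- match(cache$codes, model$qm_codes)
    ok <- !is.na(j)
    Psi[cbind(which(ok), j[ok])] <- 1.0
  }
  for (i in seq_len(n)) {
    sp <- cache$sp_idx[i]
    cols <- nbias + (sp - 1L) * H + seq_len(H)
    Psi[i, cols] <- cache$h[i, ]
  }
  Psi
}

## split theta into per-species readout vectors
dp_theta_split <- function(model, theta) {
  hp <- model$hyperparams
  H <- dp_theta_dim_per_species(hp)
  nbias <- length(model$qm_codes)
  nsp <- length(model$species_codes)
  lapply(seq_len(nsp), function(sp)
    theta[nbias + (sp - 1L) * H + seq_len(H)])
}

## reverse sweep: dE/dr (n x 3) for E = sum_i Psi[i,] . theta
dp_energy_gradient <- function(model, cache, theta) {
  n <- cache$n; ne <- cache$ne
  grad <- matrix(0.0, n, 3)
  if (ne == 0L) return(grad)
  hp <- cache$hp; M <- cache$M; Mp <- cache$Mp
  edges <- cache$edges
  th <- dp_theta_split(model, theta)
  for (i in seq_len(n)) {
    sel <- which(edges$receiver == i)
    if (length(sel) == 0L) next
    g_h <- th[[cache$sp_idx[i]]]
    g_f <- dp_fit_back(model$fixed$fit, cache$fits[[i]]$acts,
                       as.numeric(cache$Dm[[i]]), g_h)
    g_D <- matrix(g_f, M, Mp)
    Ti <- cache$Tm[[i]]
    Tp <- Ti[seq_len(Mp), , drop = FALSE]
    g_T <- g_D %*% Tp                                # M x 4
    g_T[seq_len(Mp), ] <- g_T[seq_len(Mp), ] + t(g_D) %*% Ti
    ## per-edge: T += DP_SCALE * G_e (x) Rhat_e
    for (e in sel) {
      Ge <- cache$G[e, ]; dGe <- cache$dG[e, ]
      uh <- cache$uhat[e, ]; se <- cache$s[e]; dse <- cache$dsdr[e]
      r <- edges$distance[e]
      g_G <- DP_SCALE * as.numeric(g_T %*% cache$Rhat[e, ])   # M
      g_R <- DP_SCALE * as.numeric(t(g_T) %*% Ge)             # 4
      ## ds contributions: G via dG*ds, Rhat row: (s, s*uhat)
      g_s <- sum(g_G * dGe) + g_R[1] + sum(g_R[2:4] * uh)
      g_u <- (g_s * dse) * uh
      ## uhat dependence of Rhat columns 2:4: d(s*uhat_c)/du = s*(e_c - uhat_c uhat)/r
      guh <- se * g_R[2:4]
      g_u <- g_u + (guh - sum(guh * uh) * uh) / r
      j <- edges$sender[e]
      grad[j, ] <- grad[j, ] + g_u
      grad[i, ] <- grad[i, ] - g_u
    }
  }
  grad
}

## forward sensitivity: J (P x 3n) of psi = colSums(Psi_atom)
dp_feature_jacobian <- function(model, cache) {
  hp <- cache$hp; n <- cache$n; ne <- cache$ne
  H <- dp_theta_dim_per_species(hp)
  nsp <- length(model$species_codes)
  nbias <- length(model$qm_codes)
  P <- nbias + nsp * H
  D <- 3L * n
  J <- matrix(0.0, P, D)
  if (ne == 0L) return(J)
  M <- cache$M; Mp <- cache$Mp
  edges <- cache$edges
  dof <- function(atom, c3) (atom - 1L) * 3L + c3
  for (i in seq_len(n)) {
    sel <- which(edges$receiver == i)
    if (length(sel) == 0L) next
    fe <- dp_fit_eval(model$fixed$fit, as.numeric(cache$Dm[[i]]), jacobian = TRUE)
    Jh <- fe$J                                       # H x (M*Mp)
    Ti <- cache$Tm[[i]]
    Tp <- Ti[seq_len(Mp), , drop = FALSE]
    dh <- matrix(0.0, H, D)
    for (e in sel) {
      Ge <- cache$G[e, ]; dGe <- cache$dG[e, ]
      uh <- cache$uhat[e, ]; se <- cache$s[e]; dse <- cache$dsdr[e]
      r <- edges$distance[e]
      Re <- cache$Rhat[e, ]
      j <- edges$sender[e]
      for (c3 in 1:3) {
        ## d s / d u_c, d uhat / d u_c
        ds_c <- dse * uh[c3]
        duh_c <- -uh * uh[c3] / r
        duh_c[c3] <- duh_c[c3] + 1 / r
        dR_c <- c(ds_c, ds_c * uh + se * duh_c)      # 4
        dG_c <- dGe * ds_c                           # M
        dT_c <- DP_SCALE * (outer(dG_c, Re) + outer(Ge, dR_c))
        dD_c <- dT_c %*% t(Tp) + Ti %*% t(dT_c[seq_len(Mp), , drop = FALSE])
        dh_c <- as.numeric(Jh %*% as.numeric(dD_c))  # H
        dh[, dof(j, c3)] <- dh[, dof(j, c3)] + dh_c
        dh[, dof(i, c3)] <- dh[, dof(i, c3)] - dh_c
      }
    }
    sp <- cache$sp_idx[i]
    rows <- nbias + (sp - 1L) * H + seq_len(H)
    J[rows, ] <- J[rows, ] + dh
  }
  J
}
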