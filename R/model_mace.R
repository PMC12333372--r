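## MACE-like many-body correction model.
##
## Architecture (invariant-readout ACE/MACE family):
##  * per edge: Bessel radial features under a polynomial envelope, real
##    spherical harmonics up to l_max on the edge direction;
##  * per layer t = 1..T: atomic basis A[i,k,lm] summed over graph neighbors
##    with channel-resolved radial weights and sender node scalars (layer 1
##    node scalars are species embeddings); for L >= 1 the l = 1 components
##    of A are carried between layers as equivariant vector features and
##    re-enter the next layer through invariant contractions with the edge
##    direction;
##  * invariant product basis per atom: power sums of A up to correlation
##    order nu (m1 = A_l0; m2_l = sum_m A_lm^2; m3_l = m1 * m2_l), i.e.
##    body orders up to nu + 1;
##  * readouts: linear in the product basis for layers t < T, a
##    readout_channels-wide perceptron gated by the sigmoid-linear-unit for
##    the final layer, plus per-species biases (pinned to zero for MM codes).
##
## All internal mixing weights are fixed at seed-controlled random values;
## the trainable parameters are the readout weights and QM species biases,
## so every site energy is linear in the trainable vector theta.  Forces are
## exact analytic gradients (reverse sweep); training uses the full feature
## Jacobian (forward sensitivity sweep).

MACE_MSG_SCALE <- 0.25  # fixed normalization of the neighbor sum

silu <- function(x) x / (1 + exp(-x))
silu_deriv <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

#' MACE-like hyperparameters
#'
#' @param L angular order of equivariant features communicated between
#'   message-passing layers (0 or 1 here; `L = 0` keeps all internal
#'   messages invariant).
#' @param T_layers number of message-passing layers (>= 1).
#' @param nu correlation order of the product basis (body order nu + 1);
#'   1, 2 or 3.
#' @param N number of embedding channels (desk default 16; production-scale
#'   128 remains configurable).
#' @param l_max spherical-harmonics expansion order (<= 3).
#' @param readout_channels width of the silu-gated final readout perceptron.
#' @param basis a [radial_basis_spec()].
#' @return object of class `mace_hyperparams`.
#' @export
mace_hyperparams <- function(L = 1L, T_layers = 2L, nu = 3L, N = 16L,
                             l_max = 3L, readout_channels = 16L,
                             basis = radial_basis_spec()) {
  if (L > l_max) stop("L must not exceed l_max")
  if (L > 1L) stop("equivariant message order L > 1 is not supported")
  if (nu < 1L) stop("nu must be >= 1")
  if (T_layers < 1L) stop("T_layers must be >= 1")
  if (N < 1L) stop("N must be >= 1")
  if (l_max > 3L) stop("l_max <= 3 supported")
  structure(list(L = as.integer(L), T_layers = as.integer(T_layers),
                 nu = as.integer(nu), N = as.integer(N),
                 l_max = as.integer(l_max),
                 readout_channels = as.integer(readout_channels),
                 basis = basis),
            class = "mace_hyperparams")
}

## dimension of the invariant product basis per atom
mace_phi_dim <- function(hp) {
  L1 <- hp$l_max + 1L
  hp$N * (1L + (hp$nu >= 2L) * L1 + (hp$nu >= 3L) * L1)
}

## total trainable dimension (excluding the bias block)
mace_theta_dim <- function(hp) {
  (hp$T_layers - 1L) * mace_phi_dim(hp) + hp$readout_channels
}

## initialize fixed random weights; RNG state is managed by the caller
mace_init_fixed <- function(hp, n_species) {
  K <- hp$N; L1 <- hp$l_max + 1L; nb <- hp$basis$n_bessel
  Pphi <- mace_phi_dim(hp)
  fixed <- list(embed = matrix(stats::rnorm(n_species * K), n_species, K))
  fixed$W <- lapply(seq_len(hp$T_layers), function(t)
    matrix(stats::rnorm(nb * K * L1, sd = 1 / sqrt(nb)), nb, K * L1))
  if (hp$L >= 1L && hp$T_layers > 1L) {
    fixed$Wv <- lapply(seq_len(hp$T_layers), function(t)
      if (t >= 2L) matrix(stats::rnorm(nb * K * L1, sd = 1 / sqrt(nb)), nb, K * L1) else NULL)
  }
  if (hp$T_layers > 1L) {
    fixed$U <- lapply(seq_len(hp$T_layers - 1L), function(t)
      matrix(stats::rnorm(Pphi * K, sd = 1 / sqrt(Pphi)), Pphi, K))
  }
  C <- hp$readout_channels
  fixed$a <- matrix(stats::rnorm(Pphi * C, sd = 1 / sqrt(Pphi)), Pphi, C)
  fixed$b <- stats::rnorm(C, sd = 0.5)
  fixed
}

## assemble the invariant product basis from A (n x K x nlm)
mace_invariants <- function(A, hp) {
  n <- dim(A)[1]; K <- hp$N; L1 <- hp$l_max + 1L
  lidx <- sph_l_of_index(hp$l_max)
  m1 <- A[, , 1, drop = FALSE]; dim(m1) <- c(n, K)
  blocks <- list(m1)
  m2 <- NULL
  if (hp$nu >= 2L) {
    m2 <- array(0.0, c(n, K, L1))
    for (lm in seq_along(lidx)) {
      l1 <- lidx[lm] + 1L
      Alm <- A[, , lm, drop = FALSE]; dim(Alm) <- c(n, K)
      m2[, , l1] <- m2[, , l1] + Alm^2
    }
    blocks <- c(blocks, list(matrix(m2, n, K * L1)))
  }
  if (hp$nu >= 3L) {
    m3 <- array(0.0, c(n, K, L1))
    for (l1 in seq_len(L1)) m3[, , l1] <- m1 * m2[, , l1]
    blocks <- c(blocks, list(matrix(m3, n, K * L1)))
  }
  list(phi = do.call(cbind, blocks), m1 = m1, m2 = m2)
}

## forward pass with cached intermediates; `config` must contain >= 1 QM atom
mace_forward_cache <- function(model, config) {
  hp <- model$hyperparams
  K <- hp$N; L1 <- hp$l_max + 1L
  lidx <- sph_l_of_index(hp$l_max)
  nlm <- length(lidx)
  n <- n_atoms(config)
  codes <- map_species(config)
  sp_idx <- match(codes, model$species_codes)
  if (anyNA(sp_idx))
    stop("configuration contains species codes absent from the model's species table")
  edges <- build_edges(config, hp$basis$r_cut)
  ne <- length(edges$sender)
  cache <- list(hp = hp, n = n, ne = ne, edges = edges, sp_idx = sp_idx,
                codes = codes, lidx = lidx, nlm = nlm)
  if (ne > 0L) {
    B <- radial_features(edges$distance, hp$basis)
    dB <- radial_features_deriv(edges$distance, hp$basis)
    Y <- sph_harmonics(edges$displacement, hp$l_max)
    Yg <- sph_harmonics_grad(edges$displacement, hp$l_max)
    uhat <- edges$displacement / edges$distance
    cache$B <- B; cache$dB <- dB; cache$Y <- Y; cache$Yg <- Yg
    cache$uhat <- uhat
    ## dense aggregation matrices: receiver-sum and sender-sum over edges
    Pr <- matrix(0.0, n, ne); Pr[cbind(edges$receiver, seq_len(ne))] <- 1
    Ps <- matrix(0.0, n, ne); Ps[cbind(edges$sender, seq_len(ne))] <- 1
    cache$Pr <- Pr; cache$Ps <- Ps
  }
  layers <- vector("list", hp$T_layers)
  s <- model$fixed$embed[sp_idx, , drop = FALSE]   # node scalars, layer 1
  V <- NULL                                        # vector features from prev layer
  for (t in seq_len(hp$T_layers)) {
    lay <- list(s = s, Vin = V)
    A <- array(0.0, c(n, K, nlm))
    if (ne > 0L) {
      Ra <- array(cache$B %*% model$fixed$W[[t]], c(ne, K, L1))
      dRa <- array(cache$dB %*% model$fixed$W[[t]], c(ne, K, L1))
      lay$Ra <- Ra; lay$dRa <- dRa
      sE <- s[edges$sender, , drop = FALSE]                 # (ne x K)
      omega <- array(0.0, c(ne, K, L1))
      for (l1 in seq_len(L1)) omega[, , l1] <- sE * Ra[, , l1]
      if (hp$L >= 1L && t >= 2L && !is.null(V)) {
        Rb <- array(cache$B %*% model$fixed$Wv[[t]], c(ne, K, L1))
        dRb <- array(cache$dB %*% model$fixed$Wv[[t]], c(ne, K, L1))
        lay$Rb <- Rb; lay$dRb <- dRb
        ## sv[e,k] = V[sender,k,] . uhat[e,]
        sv <- V[edges$sender, , 1] * cache$uhat[, 1] +
          V[edges$sender, , 2] * cache$uhat[, 2] +
          V[edges$sender, , 3] * cache$uhat[, 3]
        dim(sv) <- c(ne, K)
        lay$sv <- sv
        for (l1 in seq_len(L1)) omega[, , l1] <- omega[, , l1] + sv * Rb[, , l1]
      }
      lay$omega <- omega; lay$sE <- sE
      for (lm in seq_len(nlm)) {
        l1 <- lidx[lm] + 1L
        term <- omega[, , l1] * cache$Y[, lm]
        A[, , lm] <- (cache$Pr %*% term) * MACE_MSG_SCALE
      }
    }
    lay$A <- A
    inv <- mace_invariants(A, hp)
    lay$phi <- inv$phi; lay$m1 <- inv$m1; lay$m2 <- inv$m2
    ## vector features for the next layer (l = 1 components: x,y,z <-> lm 4,2,3)
    if (hp$L >= 1L && hp$l_max >= 1L) {
      V <- array(0.0, c(n, K, 3))
      V[, , 1] <- A[, , 4]; V[, , 2] <- A[, , 2]; V[, , 3] <- A[, , 3]
    } else V <- NULL
    lay$Vout <- V
    if (t < hp$T_layers) {
      pre <- lay$phi %*% model$fixed$U[[t]]
      s <- tanh(pre)
      lay$s_next <- s
    }
    layers[[t]] <- lay
  }
  ## final readout channels
  TT <- hp$T_layers
  z <- sweep(layers[[TT]]$phi %*% model$fixed$a, 2, model$fixed$b, "+")
  cache$z <- z
  cache$h <- silu(z) - matrix(silu(model$fixed$b), n, hp$readout_channels, byrow = TRUE)
  cache$layers <- layers
  cache
}

## per-atom feature matrix Psi (n x P); E_i = Psi[i, ] %*% theta_full where
## theta_full = [qm biases, layer readouts...]; bias columns are indicators
mace_site_features <- function(model, cache) {
  hp <- cache$hp; n <- cache$n
  nbias <- length(model$qm_codes)
  bias_block <- matrix(0.0, n, nbias)
  if (nbias > 0L) {
    j <- match(cache$codes, model$qm_codes)
    ok <- !is.na(j)
    bias_block[cbind(which(ok), j[ok])] <- 1.0
  }
  blocks <- list(bias_block)
  if (hp$T_layers > 1L)
    for (t in seq_len(hp$T_layers - 1L)) blocks <- c(blocks, list(cache$layers[[t]]$phi))
  blocks <- c(blocks, list(cache$h))
  do.call(cbind, blocks)
}

## reverse sweep: gradient of E = sum_i Psi[i,] . theta w.r.t. positions.
## returns dE/dr as an (n x 3) matrix.
mace_energy_gradient <- function(model, cache, theta) {
  hp <- cache$hp; n <- cache$n; ne <- cache$ne
  if (ne == 0L) return(matrix(0.0, n, 3))
  K <- hp$N; L1 <- hp$l_max + 1L; nlm <- cache$nlm
  lidx <- cache$lidx
  edges <- cache$edges
  Pphi <- mace_phi_dim(hp)
  nbias <- length(model$qm_codes)
  C <- hp$readout_channels
  ## split theta
  off <- nbias
  th_lin <- list()
  if (hp$T_layers > 1L)
    for (t in seq_len(hp$T_layers - 1L)) {
      th_lin[[t]] <- theta[(off + 1):(off + Pphi)]
      off <- off + Pphi
    }
  th_C <- theta[(off + 1):(off + C)]
  grad <- matrix(0.0, n, 3)
  ## adjoint of phi at the final layer via the silu readout
  sd_z <- silu_deriv(cache$z)                       # n x C
  g_phi <- (sd_z * matrix(th_C, n, C, byrow = TRUE)) %*% t(model$fixed$a)
  g_V_next <- NULL                                  # adjoint of Vout of layer t-1
  for (t in rev(seq_len(hp$T_layers))) {
    lay <- cache$layers[[t]]
    if (t < hp$T_layers) {
      ## phi_t read out linearly, plus chain through s_{t+1} = tanh(phi_t U_t)
      g_phi <- matrix(th_lin[[t]], n, Pphi, byrow = TRUE)
      g_pre <- g_s_next * (1 - lay$s_next^2)
      g_phi <- g_phi + g_pre %*% t(model$fixed$U[[t]])
    }
    ## phi -> A adjoint
    g_m1 <- g_phi[, 1:K, drop = FALSE]
    g_m2 <- NULL
    if (hp$nu >= 2L) {
      g_m2 <- array(g_phi[, (K + 1):(K + K * L1)], c(n, K, L1))
      if (hp$nu >= 3L) {
        g_m3 <- array(g_phi[, (K + K * L1 + 1):(K + 2 * K * L1)], c(n, K, L1))
        for (l1 in seq_len(L1)) {
          g_m1 <- g_m1 + g_m3[, , l1] * lay$m2[, , l1]
          g_m2[, , l1] <- g_m2[, , l1] + g_m3[, , l1] * lay$m1
        }
      }
    }
    g_A <- array(0.0, c(n, K, nlm))
    g_A[, , 1] <- g_m1
    if (hp$nu >= 2L)
      for (lm in seq_len(nlm)) {
        l1 <- lidx[lm] + 1L
        g_A[, , lm] <- g_A[, , lm] + 2 * lay$A[, , lm] * g_m2[, , l1]
      }
    ## Vout of this layer feeds layer t+1 (adjoint stashed from previous iter)
    if (!is.null(g_V_next)) {
      g_A[, , 4] <- g_A[, , 4] + g_V_next[, , 1]
      g_A[, , 2] <- g_A[, , 2] + g_V_next[, , 2]
      g_A[, , 3] <- g_A[, , 3] + g_V_next[, , 3]
      g_V_next <- NULL
    }
    ## A -> edges
    g_omega <- array(0.0, c(ne, K, L1))
    g_Y <- matrix(0.0, ne, nlm)
    for (lm in seq_len(nlm)) {
      l1 <- lidx[lm] + 1L
      gA_r <- g_A[, , lm][edges$receiver, , drop = FALSE] * MACE_MSG_SCALE
      g_omega[, , l1] <- g_omega[, , l1] + gA_r * cache$Y[, lm]
      g_Y[, lm] <- rowSums(gA_r * lay$omega[, , l1])
    }
    ## omega = sE * Ra (+ sv * Rb)
    g_sE <- matrix(0.0, ne, K)
    g_r <- numeric(ne)
    for (l1 in seq_len(L1)) {
      g_sE <- g_sE + g_omega[, , l1] * lay$Ra[, , l1]
      g_r <- g_r + rowSums(g_omega[, , l1] * lay$sE * lay$dRa[, , l1])
    }
    g_u <- matrix(0.0, ne, 3)
    if (!is.null(lay$sv)) {
      g_sv <- matrix(0.0, ne, K)
      for (l1 in seq_len(L1)) {
        g_sv <- g_sv + g_omega[, , l1] * lay$Rb[, , l1]
        g_r <- g_r + rowSums(g_omega[, , l1] * lay$sv * lay$dRb[, , l1])
      }
      ## sv = V[snd,k,] . uhat
      Vin <- lay$Vin
      g_V_prev <- array(0.0, c(n, K, 3))
      for (c3 in 1:3) {
        contrib <- g_sv * cache$uhat[, c3]
        g_V_prev[, , c3] <- cache$Ps %*% contrib
        ## uhat adjoint: g_uh[e,c] = sum_k g_sv * V[snd,k,c]
        g_uh_c <- rowSums(g_sv * Vin[edges$sender, , c3])
        ## d uhat / d u = (I - uhat uhat^T)/r
        g_u[, c3] <- g_u[, c3] + g_uh_c / edges$distance
      }
      proj <- rowSums(g_u * cache$uhat)  # includes only uhat-part so far
      g_u <- g_u - proj * cache$uhat / 1  # subtract (uhat.g) uhat
      ## note: g_u currently holds only the uhat-channel contribution;
      ## the projection above completes (I - uhat uhat^T)/r applied to g_uh
      g_V_next <- g_V_prev
    }
    ## radial part: dr/du = uhat
    g_u <- g_u + g_r * cache$uhat
    ## spherical harmonic gradients
    g_u[, 1] <- g_u[, 1] + rowSums(g_Y * cache$Yg$gx)
    g_u[, 2] <- g_u[, 2] + rowSums(g_Y * cache$Yg$gy)
    g_u[, 3] <- g_u[, 3] + rowSums(g_Y * cache$Yg$gz)
    ## u = r_sender - r_receiver
    grad <- grad + (cache$Ps - cache$Pr) %*% g_u
    ## node-scalar adjoint -> s chain
    if (t >= 2L) {
      g_s_next <- cache$Ps %*% g_sE  # adjoint of s at layer t
    } else {
      g_s_next <- NULL  # layer-1 node scalars are species embeddings
    }
  }
  grad
}

## forward sensitivity sweep: full Jacobian J (P x 3n) of the summed feature
## vector psi = colSums(Psi_atom) w.r.t. positions.  Used to build force
## design matrices for training.
mace_feature_jacobian <- function(model, cache) {
  hp <- cache$hp; n <- cache$n; ne <- cache$ne
  D <- 3L * n
  K <- hp$N; L1 <- hp$l_max + 1L; nlm <- cache$nlm
  lidx <- cache$lidx
  Pphi <- mace_phi_dim(hp)
  nbias <- length(model$qm_codes)
  C <- hp$readout_channels
  P <- nbias + (hp$T_layers - 1L) * Pphi + C
  J <- matrix(0.0, P, D)
  if (ne == 0L) return(J)
  edges <- cache$edges
  dof <- function(atom, c3) (atom - 1L) * 3L + c3
  ds <- NULL        # d s / d x : (n x K x D), NULL for layer 1
  dV <- NULL        # d Vin / d x
  off <- nbias
  for (t in seq_len(hp$T_layers)) {
    lay <- cache$layers[[t]]
    dA <- array(0.0, c(n, K, nlm, D))
    ## per-edge geometric contributions
    for (e in seq_len(ne)) {
      i <- edges$receiver[e]; j <- edges$sender[e]
      uh <- cache$uhat[e, ]
      ## d omega[e,k,l] / d u_c  (direct: radial part, and sv's uhat part)
      domega_u <- array(0.0, c(K, L1, 3))
      for (l1 in seq_len(L1)) {
        dr_term <- lay$sE[e, ] * lay$dRa[e, , l1]     # K
        if (!is.null(lay$sv)) dr_term <- dr_term + lay$sv[e, ] * lay$dRb[e, , l1]
        for (c3 in 1:3) domega_u[, l1, c3] <- dr_term * uh[c3]
      }
      if (!is.null(lay$sv)) {
        Vj <- lay$Vin[j, , ]                           # K x 3
        r <- edges$distance[e]
        ## d sv / d u = (V - (V.uhat) uhat)/r
        Vdotu <- as.numeric(Vj %*% uh)
        dsv_u <- (Vj - outer(Vdotu, uh)) / r           # K x 3
        for (l1 in seq_len(L1))
          for (c3 in 1:3)
            domega_u[, l1, c3] <- domega_u[, l1, c3] + dsv_u[, c3] * lay$Rb[e, , l1]
      }
      ## dA[i,k,lm] from omega and Y position dependence
      gadd <- array(0.0, c(K, nlm, 3))
      for (lm in seq_len(nlm)) {
        l1 <- lidx[lm] + 1L
        dY_u <- c(cache$Yg$gx[e, lm], cache$Yg$gy[e, lm], cache$Yg$gz[e, lm])
        for (c3 in 1:3)
          gadd[, lm, c3] <- (domega_u[, l1, c3] * cache$Y[e, lm] +
                               lay$omega[e, , l1] * dY_u[c3]) * MACE_MSG_SCALE
      }
      dj <- dof(j, 1:3); di <- dof(i, 1:3)
      dA[i, , , dj] <- dA[i, , , dj] + gadd
      dA[i, , , di] <- dA[i, , , di] - gadd
      ## chain through sender node scalars (layer >= 2)
      if (!is.null(ds)) {
        tmp <- ds[j, , ]                               # K x D
        RY <- matrix(0.0, K, nlm)
        for (lm in seq_len(nlm))
          RY[, lm] <- lay$Ra[e, , lidx[lm] + 1L] * cache$Y[e, lm] * MACE_MSG_SCALE
        ## dA[i,k,lm,d] += RY[k,lm] * tmp[k,d]
        contrib <- array(aperm(outer(tmp, rep(1, nlm)), c(1, 3, 2)), c(K, nlm, D)) *
          array(RY, c(K, nlm, D))
        dA[i, , , ] <- dA[i, , , ] + contrib
      }
      ## chain through sender vector features (L >= 1, layer >= 2)
      if (!is.null(lay$sv) && !is.null(dV)) {
        ## d sv[e,k]/dx via dV: sum_c dV[j,k,c,d] * uhat[c]
        dsv <- dV[j, , 1, ] * uh[1] + dV[j, , 2, ] * uh[2] + dV[j, , 3, ] * uh[3]
        dim(dsv) <- c(K, D)
        RYb <- matrix(0.0, K, nlm)
        for (lm in seq_len(nlm))
          RYb[, lm] <- lay$Rb[e, , lidx[lm] + 1L] * cache$Y[e, lm] * MACE_MSG_SCALE
        contrib <- array(aperm(outer(dsv, rep(1, nlm)), c(1, 3, 2)), c(K, nlm, D)) *
          array(RYb, c(K, nlm, D))
        dA[i, , , ] <- dA[i, , , ] + contrib
      }
    }
    ## invariants and their sensitivities
    m1 <- lay$m1; m2 <- lay$m2
    dm1 <- dA[, , 1, , drop = FALSE]; dim(dm1) <- c(n, K, D)
    dphi_blocks <- list(dm1)
    dm2 <- NULL
    if (hp$nu >= 2L) {
      dm2 <- array(0.0, c(n, K, L1, D))
      for (lm in seq_len(nlm)) {
        l1 <- lidx[lm] + 1L
        Alm <- lay$A[, , lm]
        dAlm <- dA[, , lm, , drop = FALSE]; dim(dAlm) <- c(n, K, D)
        dm2[, , l1, ] <- dm2[, , l1, ] + 2 * array(Alm, c(n, K, D)) * dAlm
      }
      dphi_blocks <- c(dphi_blocks, list(array(dm2, c(n, K * L1, D))))
    }
    if (hp$nu >= 3L) {
      dm3 <- array(0.0, c(n, K, L1, D))
      for (l1 in seq_len(L1))
        dm3[, , l1, ] <- array(m1, c(n, K, D)) * dm2[, , l1, ] +
          array(m2[, , l1], c(n, K, D)) * dm1
      dphi_blocks <- c(dphi_blocks, list(array(dm3, c(n, K * L1, D))))
    }
    ## dphi: n x Pphi x D
    dphi <- array(0.0, c(n, Pphi, D))
    pos <- 0L
    for (bl in dphi_blocks) {
      w <- dim(bl)[2]
      dphi[, (pos + 1):(pos + w), ] <- bl
      pos <- pos + w
    }
    if (t < hp$T_layers) {
      ## linear readout block: J rows are sums over atoms of dphi
      Jblock <- colSums(dphi)
      J[(off + 1):(off + Pphi), ] <- Jblock
      off <- off + Pphi
      ## next-layer node scalars: s = tanh(phi U)
      sech2 <- 1 - lay$s_next^2                       # n x K
      ds <- array(0.0, c(n, K, D))
      U <- model$fixed$U[[t]]
      for (d in seq_len(D))
        ds[, , d] <- sech2 * (dphi[, , d] %*% U)
    } else {
      ## final silu readout
      sd_z <- silu_deriv(cache$z)                     # n x C
      a <- model$fixed$a                              # Pphi x C
      Jblock <- matrix(0.0, C, D)
      for (d in seq_len(D)) {
        az <- dphi[, , d] %*% a                       # n x C
        Jblock[, d] <- colSums(sd_z * az)
      }
      J[(off + 1):(off + C), ] <- Jblock
      off <- off + C
    }
    ## vector-feature sensitivities for the next layer
    if (hp$L >= 1L && hp$l_max >= 1L && t < hp$T_layers) {
      dV <- array(0.0, c(n, K, 3, D))
      dV[, , 1, ] <- array(dA[, , 4, ], c(n, K, D))
      dV[, , 2, ] <- array(dA[, , 2, ], c(n, K, D))
      dV[, , 3, ] <- array(dA[, , 3, ], c(n, K, D))
    } else dV <- NULL
  }
  J
}
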