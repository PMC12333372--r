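#' Range-corrected graph construction
#'
#' The correction potential acts only on internal-QM and short-range QM/MM
#' interactions.  The graph over atoms therefore keeps an edge (i, j) only if
#' the pair is within the radial cutoff AND at least one of the two atoms is
#' a QM atom; MM-MM pairs never form edges.  MM atoms additionally use
#' species codes shifted by +50 so that an MM element can carry network
#' parameters distinct from the same QM element, and MM energy biases are
#' pinned to zero elsewhere so the total energy stays continuous as MM atoms
#' drift across the cutoff.
#'
#' @name rc_graph
NULL

## offset separating MM species codes from QM atomic numbers
MM_SPECIES_OFFSET <- 50L

#' Map atoms to species codes
#'
#' QM atoms keep their atomic number Z; MM atoms are coded Z + 50.
#'
#' @param config an [atomic_configuration()].
#' @return integer vector of species codes, one per atom.
#' @examples
#' conf <- atomic_configuration(c(8, 8), rbind(c(0,0,0), c(3,0,0)),
#'                              c("QM", "MM"))
#' map_species(conf)  # 8 58
#' @export
map_species <- function(config) {
  code <- config$species
  code[config$region == "MM"] <- code[config$region == "MM"] + MM_SPECIES_OFFSET
  as.integer(code)
}

is_mm_code <- function(code) code > MM_SPECIES_OFFSET

#' Build the range-corrected edge list
#'
#' Directed edges (sender -> receiver) for every ordered pair within
#' `r_cut` that contains at least one QM atom.  Both directions of each
#' retained pair are present; there are no self edges and no MM-MM edges.
#'
#' @param config an [atomic_configuration()].
#' @param r_cut cutoff radius in Angstrom (> 0).
#' @return list of class `edge_list` with `sender`, `receiver` (integer
#'   vectors), `displacement` (n_edges x 3, `r_sender - r_receiver`),
#'   `distance` (n_edges).
#' @export
build_edges <- function(config, r_cut) {
  if (!is.finite(r_cut) || r_cut <= 0) stop("r_cut must be positive")
  n <- n_atoms(config)
  qm <- config$region == "QM"
  p <- config$positions
  ## brute-force O(N^2); desk-scale systems are small clusters
  snd <- rep(seq_len(n), each = n)
  rcv <- rep(seq_len(n), times = n)
  keep <- snd != rcv & (qm[snd] | qm[rcv])
  snd <- snd[keep]; rcv <- rcv[keep]
  disp <- p[snd, , drop = FALSE] - p[rcv, , drop = FALSE]
  dist <- sqrt(rowSums(disp^2))
  keep2 <- dist <= r_cut
  structure(list(sender = snd[keep2], receiver = rcv[keep2],
                 displacement = disp[keep2, , drop = FALSE],
                 distance = dist[keep2], r_cut = r_cut, n_atoms = n),
            class = "edge_list")
}

#' Radial basis specification
#'
#' Bessel-type radial functions under a polynomial envelope that takes the
#' features (and their first derivatives) smoothly to zero at the cutoff.
#'
#' @param r_cut cutoff in Angstrom (default 6).
#' @param n_bessel number of Bessel functions (default 8).
#' @param envelope_order polynomial envelope order p (default 5, must be >= 2).
#' @return object of class `radial_basis_spec`.
#' @export
radial_basis_spec <- function(r_cut = 6, n_bessel = 8L, envelope_order = 5L) {
  if (r_cut <= 0) stop("r_cut must be positive")
  if (n_bessel < 1) stop("n_bessel must be >= 1")
  if (envelope_order < 2) stop("envelope_order must be >= 2")
  structure(list(r_cut = r_cut, n_bessel = as.integer(n_bessel),
                 envelope_order = as.integer(envelope_order)),
            class = "radial_basis_spec")
}

## polynomial envelope: u = r/r_cut,
## f(u) = 1 - (p+1)(p+2)/2 u^p + p(p+2) u^(p+1) - p(p+1)/2 u^(p+2), 0 for u>=1.
## f(0)=1, f(1)=0 with first p-1(+) derivatives vanishing at u=1.
envelope_poly <- function(r, r_cut, p) {
  u <- r / r_cut
  f <- 1 - ((p + 1) * (p + 2) / 2) * u^p + p * (p + 2) * u^(p + 1) -
    (p * (p + 1) / 2) * u^(p + 2)
  f[u >= 1] <- 0
  f
}

envelope_poly_deriv <- function(r, r_cut, p) {
  u <- r / r_cut
  df <- (-((p + 1) * (p + 2) / 2) * p * u^(p - 1) +
           p * (p + 2) * (p + 1) * u^p -
           (p * (p + 1) / 2) * (p + 2) * u^(p + 1)) / r_cut
  df[u >= 1] <- 0
  df
}

#' Bessel radial features
#'
#' `feature_n(r) = sqrt(2/r_cut) * sin(n pi r / r_cut) / r * f_env(r)` for
#' n = 1..n_bessel.  All features and their first derivatives vanish for
#' `r >= r_cut`, so any quantity built from them is C1-continuous as a
#' neighbor crosses the cutoff.
#'
#' @param distance numeric vector of distances (Angstrom, > 0).
#' @param spec a [radial_basis_spec()].
#' @return matrix `length(distance)` x `n_bessel` of features.
#' @export
radial_features <- function(distance, spec) {
  if (any(distance <= 0)) stop("distances must be positive")
  rc <- spec$r_cut; nb <- spec$n_bessel
  env <- envelope_poly(distance, rc, spec$envelope_order)
  n <- seq_len(nb)
  ## outer over (distance, n)
  arg <- outer(distance, n) * (pi / rc)
  feat <- sqrt(2 / rc) * sin(arg) / distance * env
  dimnames(feat) <- NULL
  feat
}

## d feature_n / d r, same shape as radial_features
radial_features_deriv <- function(distance, spec) {
  rc <- spec$r_cut; nb <- spec$n_bessel
  p <- spec$envelope_order
  env <- envelope_poly(distance, rc, p)
  denv <- envelope_poly_deriv(distance, rc, p)
  n <- seq_len(nb)
  arg <- outer(distance, n) * (pi / rc)
  s <- sin(arg); cs <- cos(arg)
  base <- sqrt(2 / rc) * s / distance
  dbase <- sqrt(2 / rc) * (cs * rep(n, each = length(distance)) * (pi / rc) / distance -
                             s / distance^2)
  dbase * env + base * denv
}
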