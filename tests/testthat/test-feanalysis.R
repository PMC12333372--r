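## exact 1-D Gaussian umbrella fixture: underlying spring K, bias springs k
## at several centers; the reduced free energies have a closed form
gaussian_umbrella <- function(seed = 1, K_spring = 1, kbias = 4,
                              centers = seq(-2, 2, 0.5), nper = 400) {
  set.seed(seed)
  xs <- unlist(lapply(centers, function(c0)
    rnorm(nper, kbias * c0 / (K_spring + kbias),
          sqrt(1 / (K_spring + kbias)))))
  K <- length(centers)
  u <- matrix(0, K, length(xs))
  for (k in seq_len(K))
    u[k, ] <- K_spring / 2 * xs^2 + kbias / 2 * (xs - centers[k])^2
  f_exact <- -(log(sqrt(2 * pi / (K_spring + kbias))) -
                 K_spring * kbias * centers^2 / (2 * (K_spring + kbias)))
  list(u = u, N_k = rep(nper, K), f_exact = f_exact - f_exact[1], xs = xs)
}

test_that("MBAR recovers closed-form harmonic free energies", {
  fx <- gaussian_umbrella(seed = 1)
  mb <- mbar_solve(fx$u, fx$N_k)
  ## 0.3 is ~3x the empirical seed-to-seed spread of this estimator at n=400
  expect_lt(max(abs(mb$f_k - fx$f_exact)), 0.3)
  ## two identical states have zero free-energy difference
  u2 <- rbind(fx$u[1, ], fx$u[1, ])
  n2 <- ncol(fx$u)
  mb2 <- mbar_solve(u2, c(n2 / 2, n2 / 2))
  expect_equal(mb2$f_k[2], 0, tolerance = 1e-12)
})

test_that("MBAR agrees with an independent self-consistent oracle", {
  set.seed(7)
  K <- 4; N <- 60
  u <- matrix(runif(K * N, 0, 3), K, N)
  N_k <- c(20, 10, 15, 15)
  mb <- mbar_solve(u, N_k)
  ## oracle: plain fixed-point iteration written directly from the
  ## defining equations, no shared code with the solver
  f <- rep(0, K)
  for (it in 1:5000) {
    D <- colSums(N_k * exp(f - u))
    f_new <- -log(rowSums(sweep(exp(-u), 2, D, "/")))
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f)) < 1e-13) { f <- f_new; break }
    f <- f_new
  }
  expect_lt(max(abs(mb$f_k - f)), 1e-6)
  ## weights from the denominators normalize to 1
  w <- mbar_weights(mb, u[1, ])
  expect_equal(sum(w), 1.0)
})

test_that("MBAR is invariant to constant shifts of one state's potentials", {
  fx <- gaussian_umbrella(seed = 3, centers = seq(-1, 1, 0.5), nper = 150)
  mb <- mbar_solve(fx$u, fx$N_k)
  u2 <- fx$u; u2[2, ] <- u2[2, ] + 5
  mb2 <- mbar_solve(u2, fx$N_k)
  expected <- mb$f_k; expected[2] <- expected[2] + 5
  expect_equal(mb2$f_k, expected, tolerance = 1e-8)
  expect_error(mbar_solve(fx$u, fx$N_k[-1]), "length")
})

test_that("histogram free energies follow -kT log of binned weights", {
  ## uniform weights in one bin: flat surface at zero
  set.seed(2)
  xi <- runif(50, -0.04, 0.04)
  f <- fes_from_weights(rep(1, 50), xi, 0.1, 298)
  occ <- !is.na(f$values)
  expect_true(all(abs(f$values[occ]) < 1e-12))
  ## two bins with weight ratio e^-1 differ by exactly kT
  xi2 <- c(rep(0, 10), rep(0.1, 10))
  w2 <- c(rep(1, 10), rep(exp(-1) / 1, 10))
  f2 <- fes_from_weights(w2, xi2, 0.1, 298)
  dF <- f2$values[f2$centers == 0.1] - f2$values[f2$centers == 0]
  expect_equal(dF, kT(298, "kcal"), tolerance = 1e-10)
  expect_equal(dF, 0.592, tolerance = 1e-3)
  ## bins align to the 0.1 A grid of window centers; empty bins are NA
  xi3 <- c(-0.2, 0.2)
  f3 <- fes_from_weights(c(1, 1), xi3, 0.1, 298)
  expect_equal(f3$centers, seq(-0.2, 0.2, 0.1), tolerance = 1e-9)
  expect_true(all(is.na(f3$values[2:4])))   # interior bins stay unoccupied
  expect_equal(sum(is.na(f3$values)), 3L)
})

test_that("reweighting entropy has the normalized-Shannon limits", {
  for (n in c(2L, 10L, 1000L))
    expect_equal(reweighting_entropy(rep(1 / n, n)), 1.0, tolerance = 1e-12)
  expect_equal(reweighting_entropy(c(1, 0, 0, 0)), 0.0)
  expect_equal(reweighting_entropy(c(0.5, 0.5, 0, 0)), log(2) / log(4))
  ## concentrating mass strictly decreases RE
  res <- vapply(c(0.25, 0.5, 0.8, 0.95), function(p)
    reweighting_entropy(c(p, rep((1 - p) / 3, 3))), numeric(1))
  expect_true(all(diff(res) < 0))
  expect_error(reweighting_entropy(1.0), "at least 2")
  expect_error(reweighting_entropy(c(0, 0)), "not all")
})

test_that("density-of-states smoothing dampens outlier weights", {
  ## all equal energies: factors are a common constant
  s <- dos_smoothing(rep(0.3, 8), 0.2)
  expect_true(all(s$factors == s$factors[1]))
  ## energies spanning less than one bin: single bin, identical factors
  s2 <- dos_smoothing(c(0.0, 0.05, 0.19), 0.2)
  expect_true(all(s2$factors == s2$factors[1]))
  ## one -10 kT outlier among near-zero energies: smoothing cannot lower RE
  set.seed(8)
  du <- c(rnorm(99, 0, 0.05), -10)
  before <- reweighting_entropy(exp(-du))
  after <- reweighting_entropy(dos_smoothing(du, 0.2)$factors)
  expect_gte(after, before)
})

## small base-potential umbrella fixture for the reweighting estimators
toy_reweight_fixture <- function(seed = 5, target = FALSE) {
  spec <- toy_system_spec("Nuc-EtO", n_mm = 4)
  sched <- make_window_schedule(-1.5, 1.5, 0.25, 40)
  dyn <- dynamics_spec(n_equil_steps = 80, n_prod_steps = 320,
                       samples_saved = 40)
  ds <- generate_reference_dataset("Nuc-EtO", sched, dyn, seed = seed,
                                   n_mm = 4)
  samp <- unlist(ds[["Nuc-EtO"]], recursive = FALSE)
  list(
    xi = vapply(samp, `[[`, numeric(1), "xi"),
    ub = vapply(samp, `[[`, numeric(1), "e_base"),
    ut = vapply(samp, `[[`, numeric(1), "e_target"),
    window_of = rep(seq_along(sched$windows), each = dyn$samples_saved),
    windows = sched$windows)
}

test_that("wTP with target == reference reproduces the MBAR FES with RE = 1", {
  fx <- toy_reweight_fixture()
  inp <- reweight_input(fx$xi, cbind(fx$ub), fx$ub, rep(1L, length(fx$xi)),
                        fx$window_of, fx$windows, 298)
  rep0 <- wtp_estimate(inp, smoothing = NULL, bin_width = 0.25)
  ref <- mbar_fes(inp, bin_width = 0.25)
  expect_identical(rep0$fes$values, ref$values)
  occ <- !is.na(rep0$re_per_bin)
  expect_true(all(abs(rep0$re_per_bin[occ] - 1) < 1e-12))
  ## with DoS smoothing the self-perturbation identity still holds
  rep1 <- wtp_estimate(inp, smoothing = smoothing_spec(), bin_width = 0.25)
  expect_equal(rep1$fes$values, ref$values, tolerance = 1e-12)
})

test_that("a dominating sample drives that bin's RE toward zero", {
  fx <- toy_reweight_fixture()
  kT_ev <- kT(298, "eV")
  ut <- fx$ub
  sel <- which(abs(fx$xi - fx$xi[1]) < 0.05)
  ut[sel[1]] <- ut[sel[1]] - 20 * kT_ev   # one -20 kT outlier in its bin
  inp <- reweight_input(fx$xi, cbind(fx$ub), ut, rep(1L, length(fx$xi)),
                        fx$window_of, fx$windows, 298)
  rep_ <- wtp_estimate(inp, smoothing = NULL, bin_width = 0.25)
  b <- which(abs(rep_$fes$centers - round(fx$xi[1] / 0.25) * 0.25) < 1e-9)
  expect_lt(rep_$re_per_bin[b], 0.05)
})

test_that("gwTP reduces to wTP for a single reference model", {
  fx <- toy_reweight_fixture()
  inp <- reweight_input(fx$xi, cbind(fx$ub), fx$ut, rep(1L, length(fx$xi)),
                        fx$window_of, fx$windows, 298)
  w <- wtp_estimate(inp, smoothing = smoothing_spec(), bin_width = 0.25)
  g <- gwtp_estimate(inp, smoothing = smoothing_spec(), bin_width = 0.25)
  expect_identical(g$fes$values, w$fes$values)
  expect_identical(g$re_per_bin, w$re_per_bin)
})

test_that("two bit-identical references pool like one reference", {
  fx <- toy_reweight_fixture()
  n <- length(fx$xi)
  half <- seq_len(n %/% 2)
  ## split the samples between two copies of the same reference potential
  model_of <- rep(2L, n); model_of[half] <- 1L
  inp2 <- reweight_input(fx$xi, cbind(fx$ub, fx$ub), fx$ut, model_of,
                         fx$window_of, fx$windows, 298)
  g2 <- gwtp_estimate(inp2, smoothing = NULL, bin_width = 0.25)
  inp1 <- reweight_input(fx$xi, cbind(fx$ub), fx$ut, rep(1L, n),
                         fx$window_of, fx$windows, 298)
  g1 <- gwtp_estimate(inp1, smoothing = NULL, bin_width = 0.25)
  ## identical states (same potential, same windows) double the state count
  ## but define the same mixture: the FES agrees bin by bin
  occ <- !is.na(g1$fes$values) & !is.na(g2$fes$values)
  expect_equal(g2$fes$values[occ], g1$fes$values[occ], tolerance = 1e-6)
})

test_that("surface averaging is offset-invariant on a common grid", {
  mk_fes <- function(vals, centers = seq(-0.2, 0.2, 0.1)) {
    structure(list(centers = centers, values = vals - min(vals, na.rm = TRUE),
                   n_samples = rep(10L, length(centers)), bin_width = 0.1,
                   temperature = 298), class = "fes")
  }
  f1 <- mk_fes(c(1, 0.2, 0, 0.5, 2))
  expect_equal(average_surfaces(list(f1, f1))$values, f1$values)
  ## constant offsets disappear after re-anchoring
  f2 <- mk_fes(c(1, 0.2, 0, 0.5, 2) + 3)
  av <- average_surfaces(list(f1, f2))
  expect_equal(av$values, f1$values, tolerance = 1e-12)
  expect_error(average_surfaces(list(f1, structure(
    modifyList(unclass(f1), list(bin_width = 0.2)), class = "fes"))),
    "different bin widths")
})
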