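# shared, lazily built model objects (expensive pieces built once per run)
.cache <- new.env(parent = emptyenv())

test_fixture <- function(seed = 1) {
  key <- paste0("fx", seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- generate_fixture(fixture_spec(seed = seed))
  .cache[[key]]
}

test_model <- function() {
  if (is.null(.cache$mdl)) .cache$mdl <- default_model(seed = 1)
  .cache$mdl
}

# single-active-loop toy: only one muscle (Delt Ant) and one DOF (SFE)
# are coupled, no delays; used for polynomial-root oracles
toy_single_loop <- function(g0 = 0.5, T1 = 0.035, T2 = 0.15,
                            Cf = 1000, Ma = 0.03,
                            Ij = 0.3, Dj = 2, Kj = 40) {
  n <- 15; m <- 7
  M <- matrix(0, m, n); M[1, 1] <- Ma
  params <- forward_params(T1 = rep(T1, n), T2 = rep(T2, n),
                           C = rep(Cf, n), M = M,
                           I = diag(Ij, m), D = diag(Dj, m),
                           K = diag(Kj, m))
  G <- matrix(NA_real_, 13, 13,
              dimnames = list(UL_MUSCLES_13, UL_MUSCLES_13))
  G["Delt Ant", "Delt Ant"] <- g0
  list(params = params, G = gain_matrix(G),
       delays = stats::setNames(rep(0, n), UL_MUSCLES_15),
       g0 = g0, T1 = T1, T2 = T2, Cf = Cf, Ma = Ma,
       Ij = Ij, Dj = Dj, Kj = Kj)
}

# independent oracle: largest stable c from the closed-form characteristic
# polynomial of the toy loop, located by bisection on polyroot
toy_cmax_polyroot <- function(toy, r = 0.1, tol = 1e-6) {
  # (T1 s + 1)(T2 s + 1)(I s^2 + D s + K) + c g0 M^2 C (1/r + s) = 0
  conv2 <- function(a, b) {           # ascending-coefficient product
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) for (j in seq_along(b))
      out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
    out
  }
  base <- conv2(conv2(c(1, toy$T1), c(1, toy$T2)),
                c(toy$Kj, toy$Dj, toy$Ij))
  fb <- toy$g0 * toy$Ma^2 * toy$Cf * c(1 / r, 1)
  maxre <- function(cc) {
    p <- base
    p[1:2] <- p[1:2] + cc * fb
    max(Re(polyroot(p)))
  }
  lo <- 0; hi <- 1
  while (maxre(hi) < 0) { lo <- hi; hi <- 2 * hi }
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (maxre(mid) < 0) lo <- mid else hi <- mid
  }
  lo
}
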