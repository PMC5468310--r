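## Independent reference implementations used as oracles.
##
## refStep/refSimulate re-derive the backward-Euler update with dense linear
## algebra (base R solve()) from the compartmental quantities, sharing no
## code with the compiled stepper. analytic2comp solves the 2-compartment
## passive ODE system exactly via matrix exponentials.

## gate curves evaluated straight from the kinetic-scheme list
refGateInf <- function(kin, g, v) 1 / (1 + exp((kin$vhalf[g] - v) / kin$k[g]))
refGateTau <- function(kin, g, v) {
  p <- kin$tau_params[g, ]
  if (kin$tau_type[g] == 0L) p[1]
  else p[1] + p[2] / (exp((v - p[3]) / p[4]) + exp(-(v - p[3]) / p[5]))
}

## dense backward-Euler simulation of a CompartmentalSystem
refSimulate <- function(system, v0, gates0, e_amp = 0, e_on = 0, e_off = Inf,
                        inj = NULL, dt, nsteps, phi = 0) {
  comp <- system@comp
  n <- nrow(comp)
  kin <- system@kin
  ngate <- length(kin$gate_channel)
  a <- pi / 180 * phi
  vext_u <- (comp$x * sin(a) + comp$y * cos(a)) / 1000

  ## symmetric axial conductance matrix from parent links
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    p <- comp$parent[i]
    if (p > 0) {
      G[i, p] <- G[i, p] + comp$g_axial[i]
      G[p, i] <- G[p, i] + comp$g_axial[i]
    }
  }
  gax_sum <- rowSums(G)
  fsrc <- as.vector(G %*% vext_u) - gax_sum * vext_u

  v <- v0
  x <- gates0
  vrec <- matrix(NA_real_, nsteps + 1L, n)
  vrec[1, ] <- v
  for (s in seq_len(nsteps)) {
    t1 <- s * dt
    if (ngate > 0) {
      for (g in seq_len(ngate)) {
        inf <- refGateInf(kin, g, v)
        tau <- vapply(v, function(vv) refGateTau(kin, g, vv), numeric(1))
        x[, g] <- inf + (x[, g] - inf) * exp(-dt / tau)
      }
    }
    gtot <- system@gleak
    gE <- system@gleak * system@eleak
    if (ngate > 0) {
      nchan <- length(system@erev)
      open <- matrix(1, n, nchan)
      for (g in seq_len(ngate)) {
        ci <- kin$gate_channel[g] + 1L
        open[, ci] <- open[, ci] * x[, g]^kin$power[g]
      }
      for (ci in seq_len(nchan)) {
        gc <- system@gbar[, ci] * open[, ci]
        gtot <- gtot + gc
        gE <- gE + gc * system@erev[ci]
      }
    }
    A <- -G
    diag(A) <- system@cm / dt + gtot + gax_sum
    b <- system@cm / dt * v + gE
    if (e_amp != 0 && t1 > e_on && t1 <= e_off) b <- b + e_amp * fsrc
    if (!is.null(inj) && t1 > inj$on && t1 <= inj$off) {
      b[inj$comp] <- b[inj$comp] + inj$amp
    }
    v <- solve(A, b)
    vrec[s + 1L, ] <- v
  }
  list(v = vrec, v_final = v, gates_final = x)
}

## exact solution of the 2-compartment passive system
##   C dv/dt = -gl (v - el) + G (v_other - v) + I(t)
## via eigen-decomposition of the constant-coefficient linear system
analytic2comp <- function(cm, gl, el, gax, v0, I = c(0, 0), t) {
  A <- rbind(c(-(gl[1] + gax) / cm[1], gax / cm[1]),
             c(gax / cm[2], -(gl[2] + gax) / cm[2]))
  b <- c((gl[1] * el + I[1]) / cm[1], (gl[2] * el + I[2]) / cm[2])
  vinf <- solve(-A, b)
  ev <- eigen(A)
  co <- solve(ev$vectors, v0 - vinf)
  vapply(t, function(tt) {
    Re(ev$vectors %*% (co * exp(ev$values * tt))) + vinf
  }, numeric(2))
}
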