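# Exact stochastic simulation (Gillespie direct method) of a reduced
# radical network, used as an independent oracle for the deterministic
# integrator. Species are molecule counts in a small reaction volume:
#   source:      0          -> LOO        rate a (1/s)
#   quenching:   LOO + QH2  -> 0          rate c2 * LOO * QH2
#   propagation: LOO        -> LOO + D    rate c3 * LOO   (LH clamped)
ssa_reduced_run <- function(a, c2, c3, qh2_0, t_end) {
  loo <- 0L; qh2 <- qh2_0; d <- 0L; t <- 0
  repeat {
    p1 <- a
    p2 <- c2 * loo * qh2
    p3 <- c3 * loo
    ptot <- p1 + p2 + p3
    t <- t + stats::rexp(1, ptot)
    if (t > t_end) break
    u <- stats::runif(1) * ptot
    if (u < p1) {
      loo <- loo + 1L
    } else if (u < p1 + p2) {
      loo <- loo - 1L; qh2 <- qh2 - 1L
    } else {
      d <- d + 1L
    }
  }
  c(LOO = loo, QH2 = qh2, D = d)
}

ssa_reduced_means <- function(a, c2, c3, qh2_0, t_end, n_runs) {
  out <- vapply(seq_len(n_runs),
                function(i) ssa_reduced_run(a, c2, c3, qh2_0, t_end),
                numeric(3))
  list(mean = rowMeans(out), se = apply(out, 1, stats::sd) / sqrt(n_runs))
}

ode_reduced_final <- function(a, c2, c3, qh2_0, t_end) {
  rhs <- function(t, y, p) {
    with(as.list(y), list(c(
      LOO = a - c2 * LOO * QH2,
      QH2 = -c2 * LOO * QH2,
      D = c3 * LOO
    )))
  }
  out <- deSolve::lsoda(c(LOO = 0, QH2 = qh2_0, D = 0), c(0, t_end), rhs,
                        NULL, rtol = 1e-10, atol = 1e-10)
  out[nrow(out), c("LOO", "QH2", "D")]
}
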