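# Independent oracles used across tests. Deliberately written with
# elementary arithmetic (explicit sums, loops) so they share no code path
# with the package implementation they check.

# Brute-force recomputation of the two scoring equations: per-metric
# standardisation with the sample SD, Euclidean distance from the reference
# point, and re-standardisation of the distances.
oracle_codrp <- function(auc, growth, reference_z = -4.5) {
  n <- length(auc)
  zs <- function(x) {
    m <- sum(x) / n
    s <- sqrt(sum((x - m)^2) / (n - 1))
    (x - m) / s
  }
  za <- zs(auc)
  zg <- zs(growth)
  d <- numeric(n)
  for (i in seq_len(n))
    d[i] <- sqrt((zg[i] - reference_z)^2 + (za[i] - reference_z)^2)
  list(distances = d, z = zs(d))
}

# Dense-trapezoid AUC of a fitted curve on the log10 axis, with clipping.
oracle_trapz_auc <- function(fit, cmin, cmax, npts = 10000) {
  x <- seq(log10(cmin), log10(cmax), length.out = npts)
  y <- pmin(pmax(predictViability(fit, 10^x), 0), 1)
  sum(diff(x) * (y[-1] + y[-npts]) / 2) / (log10(cmax) - log10(cmin))
}

# Convenience: a DoseResponseProfile with constant replicate counts.
make_profile <- function(concs, reps, dmso, id = "P1", drug = "d") {
  new("DoseResponseProfile", patientId = id, drug = drug,
      concentrations = concs, replicates = reps, dmsoReadouts = dmso)
}

fixture_cohort <- function() {
  loadCohort(codrpExample("clinical.csv"), codrpExample("screening.csv"))
}
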