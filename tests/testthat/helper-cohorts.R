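# Shared small fixtures, built in code. Kept deliberately small so the
# whole suite stays fast; larger cohorts are generated inside the tests
# that need them.

small_cohort <- function(seed = 7, n_probes = 2000, dmp = TRUE) {
  sim_config(
    n_fp = 12, n_sd = 10, n_probes = n_probes, n_plates = 2,
    dmp_spec = if (dmp) list(list(probes = 1:25, delta_beta = 0.12)) else list(),
    batch_effect_sd = 0.15, probe_fail_rate = 0.002, seed = seed
  ) |> generate_cohort()
}

# deterministic two-group matrix for panel/LDA tests
toy_groups <- function(n1 = 10, n2 = 10) rep(c("FP", "SD"), c(n1, n2))

random_candidates <- function(seed, n = 20, m = 10, sep = 0) {
  set.seed(seed)
  g <- rep(c("FP", "SD"), length.out = n)
  x <- matrix(stats::rnorm(n * m), n, m,
              dimnames = list(NULL, sprintf("p%02d", seq_len(m))))
  x[g == "FP", 1] <- x[g == "FP", 1] + sep
  list(x = x, groups = g)
}
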