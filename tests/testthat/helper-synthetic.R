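# Small synthetic datasets shared across tests. Grids are kept small so
# the per-test cost stays low; the acceptance tests use the full default
# conditions.

small_config <- function(n_hc = 80, n_bp = 0, n_sz = 0, dims = c(12, 14, 12),
                         seed = 7, ...) {
  generator_config(n_hc = n_hc, n_bp = n_bp, n_sz = n_sz, dims = dims,
                   seed = seed, ...)
}

small_dataset <- function(...) {
  cfg <- small_config(...)
  coh <- generate_cohort(cfg)
  vd <- generate_voxel_data(coh, cfg)
  list(cfg = cfg, cohort = coh, vs = vd$voxel_space, gm = vd$gm,
       truth = vd$truth)
}

# Hand-built prediction object for direct Z arithmetic checks.
fake_prediction <- function(mean, var_function, noise_var) {
  structure(list(mean = mean, var_function = var_function,
                 var_total = var_function + noise_var),
            class = "normative_prediction")
}
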