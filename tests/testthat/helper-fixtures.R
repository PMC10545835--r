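# shared small fixtures, built in code

quick_grid <- function(n = 486L) time_grid(0, 10.3, n)

quick_geom <- function(s = 51) slab_geometry(thickness_s = s)

# noiseless synthetic TRP: amplitude * (slab model (x) IRF)
quick_synthetic_trp <- function(mu_a = 0.010, mu_s = 0.60, s = 51,
                                amplitude = 5e4, grid = quick_grid(),
                                irf = make_gaussian_irf(quick_grid()),
                                meta = list(sample_id = "syn", day = 0,
                                            condition = "shelf")) {
  model <- transmittance_curve(grid_times(grid),
                               optical_properties(mu_a, mu_s),
                               slab_geometry(s))
  conv <- convolve_with_irf(model, irf, grid)
  trp(grid, amplitude * conv / max(conv), meta)
}

# small, fast study for structural tests
quick_study_config <- function(seed = 7L)
  study_config(n_samples = 3L, shelf_days = c(0, 4, 8, 13),
               cold_days = c(0, 14, 28, 49), total_counts = 2e5, seed = seed)
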