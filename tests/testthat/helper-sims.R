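# Session-level cache of simulator outputs so the default-scale fixtures are
# built once and shared across test files. Small-scale parameters for unit
# tests keep the ordinary suite fast; the acceptance file uses the defaults.

.tc_cache <- new.env(parent = emptyenv())

small_sim_params <- function(seed) {
  sim_params(width = 130, height = 130, n_cells = 45, n_frames = 16,
             n_divisions = 1, n_extrusions = 1, seed = seed)
}

cached <- function(key, expr) {
  if (!exists(key, envir = .tc_cache)) assign(key, expr, envir = .tc_cache)
  get(key, envir = .tc_cache)
}

get_small_sim <- function(seed) {
  cached(paste0("small_sim_", seed), simulate_epithelium(small_sim_params(seed)))
}

get_default_sim <- function(seed) {
  cached(paste0("sim_", seed), simulate_epithelium(sim_params(seed = seed)))
}

get_default_corrupt <- function(seed, cseed = 100 + seed) {
  cached(paste0("cor_", seed, "_", cseed), {
    sim <- get_default_sim(seed)
    corrupt_movie(sim$movie, sim$tracks, corruption_params(seed = cseed),
                  events = sim$events)
  })
}

get_corrupt_tracks <- function(seed, cseed = 100 + seed) {
  cached(paste0("trc_", seed, "_", cseed),
         build_tracks(get_default_corrupt(seed, cseed)$movie))
}
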