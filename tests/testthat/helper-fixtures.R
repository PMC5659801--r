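# Shared fixtures: built once per test run, all deterministic.

# representative single-cell parameter set at the generator's log-medians
paper_like_params <- function(variant = "ACD") {
  cfg <- generator_config()
  tab <- cfg$param_table
  p <- setNames(10^tab$log10_mean, tab$name)
  nm <- kinetic_param_names(variant, "epo")
  c(k_on_Epo = cfg$k_on_Epo, k_off_Epo = cfg$k_off_Epo,
    p[setdiff(nm, c("k_on_Epo", "k_off_Epo"))])
}

# small cached datasets so slow fixtures are built only once per run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

tiny_dataset <- function() cached("tiny", {
  cfg <- generator_config(n_epo_cells = 3, n_bleach_cells = 2,
                          n_chx_cells = 2, seed = 42)
  generate_dataset(cfg)
})

# one noise-free Epo cell from the basic variant, for recovery tests
noisefree_cell <- function() cached("noisefree", {
  cfg <- generator_config(n_epo_cells = 1, n_bleach_cells = 0,
                          n_chx_cells = 0, true_variant = "",
                          sigma_rel = 0, seed = 7)
  generate_dataset(cfg)
})
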