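# Shared fixtures: a small, fully specified model parameterisation built in
# code (independent of the shipped config) plus convenience accessors for
# the shipped placeholder configuration.

toy_geometry <- function(k_iw = c(root = 0.94, stem = 5, leaf = 1.75, grain = 100)) {
  list(
    root  = part_geometry("root",  area = 0.05,  water_content = 0.8,
                          k_iw = k_iw[["root"]]),
    stem  = part_geometry("stem",  area = 0.02,  water_content = 0.6,
                          k_iw = k_iw[["stem"]]),
    leaf  = part_geometry("leaf",  area = 0.06,  water_content = 0.7,
                          k_iw = k_iw[["leaf"]], permeability = 1e-4),
    grain = part_geometry("grain", area = 2e-4,  water_content = 0.12,
                          k_iw = k_iw[["grain"]], permeability = 5e-5)
  )
}

toy_env <- function(metal = "Cu", c_total = 22.1, frac_s = 0.05,
                    frac_t = 0.10, c_a = 5e-5, m_s = 2, k_sw = 9.5) {
  metal_environment(metal, c_total = c_total, c_s = frac_s * c_total,
                    c_t = frac_t * c_total, c_a = c_a, m_s = m_s, k_sw = k_sw)
}

toy_flux <- function() {
  list(q_up = c(root = 2, stem = 2, leaf = 1, grain = 2.3e-4),
       phloem_fraction = c(root = 0.2, stem = 0.3, leaf = 0.3, grain = 0))
}

toy_rt <- function() root_transport(q = 2, f_c = 1000, d_r = 1e-5)
toy_atm <- function() atmosphere_params(f_p = 0.5, v_dep = 17.3)

toy_simulation <- function(metal = "Cu", cfg = simulation_config(), ...) {
  simulate_accumulation(toy_env(metal, ...), toy_geometry(), toy_rt(),
                        toy_atm(), default_growth_params(), cfg,
                        flux = toy_flux())
}

shipped_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(load_config(default_config_path()))
    }
    cache
  }
})

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}
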