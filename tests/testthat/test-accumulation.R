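test_that("zero sources give identically zero concentrations", {
  res <- toy_simulation(c_total = 0, c_a = 0)
  expect_true(all(res$C == 0))
  expect_true(all(res$final == 0))
})

test_that("concentrations scale linearly with the source concentrations", {
  base <- toy_simulation()
  for (alpha in c(0.25, 3, 17.5)) {
    scaled <- simulate_accumulation(
      toy_env(c_total = alpha * 22.1, c_a = alpha * 5e-5),
      toy_geometry(), toy_rt(), toy_atm(), default_growth_params(),
      simulation_config(), flux = toy_flux()
    )
    rel <- abs(scaled$C - alpha * base$C) /
      pmax(abs(alpha * base$C), .Machine$double.eps)
    expect_lt(max(rel[base$C > 0]), 1e-9)
  }
})

test_that("reduced case (constant mass, zero loss) matches the linear closed form", {
  # near-constant masses: m0 within 1e-12 of mmax, so M(t) = mmax to double
  # precision; q_up = 0 removes every inter-part edge, hence k = 0 everywhere
  const_growth <- lapply(wheat_parts(), function(p) {
    mmax <- c(root = 0.25, stem = 0.45, leaf = 0.05, grain = 0.56)[[p]]
    growth_params(p, mmax * (1 - 1e-12), mmax, 0.1, emergence_day = 0)
  })
  names(const_growth) <- wheat_parts()
  env <- toy_env()
  geom <- toy_geometry()
  rt <- toy_rt()
  atm <- toy_atm()
  cfg <- simulation_config(t_end = 100, grain_emergence = 0)
  res <- simulate_accumulation(env, geom, rt, atm, const_growth, cfg,
                               flux = list(q_up = 0, phloem_fraction = 0))
  # closed form: C_i(t) = t * U_i / M_i with constant uptake U_i
  r_sr <- root_uptake_rate(rt, geom$root$area, env)
  u <- c(
    root  = r_sr * (env$c_s + env$c_t) * geom$root$water_content,
    stem  = 0,
    leaf  = atmos_rate(geom$leaf$area, geom$leaf$permeability, atm) * env$c_a,
    grain = atmos_rate(geom$grain$area, geom$grain$permeability, atm) * env$c_a
  )
  mmax <- c(root = 0.25, stem = 0.45, leaf = 0.05, grain = 0.56)
  for (p in c("root", "leaf", "grain")) {
    expected <- res$t * u[[p]] / mmax[[p]]
    rel <- abs(res$C[, p] - expected) / pmax(expected, .Machine$double.eps)
    expect_lt(max(rel[-1]), 1e-6)
  }
  expect_true(all(res$C[, "stem"] == 0))
})

test_that("grain stays at zero before emergence and trajectories stay non-negative", {
  res <- toy_simulation()
  expect_true(all(res$C[res$t < 50, "grain"] == 0))
  expect_true(any(res$C[res$t > 55, "grain"] > 0))
  expect_true(all(res$C >= 0))
})

test_that("halving the step leaves trajectories unchanged to 1e-4 relative", {
  # at dt = 0.125 d the integrator has resolved the startup boundary layer
  # (loss rates ~2/d in the fixture), so successive halvings agree everywhere
  coarse <- toy_simulation(cfg = simulation_config(dt = 0.125))
  fine <- toy_simulation(cfg = simulation_config(dt = 0.0625))
  idx <- match(round(coarse$t, 9), round(fine$t, 9))
  rel <- abs(fine$C[idx, ] - coarse$C) / pmax(abs(fine$C[idx, ]), 1e-12)
  expect_lt(max(rel[fine$C[idx, ] > 1e-12]), 1e-4)
})

test_that("euler and rk4 integrators agree at small steps", {
  rk <- toy_simulation(cfg = simulation_config(dt = 0.5))
  eu <- toy_simulation(cfg = simulation_config(dt = 0.05, integrator = "euler"))
  expect_equal(unname(eu$final), unname(rk$final), tolerance = 5e-3)
  expect_equal(eu$metadata$config$integrator, "euler")
})

test_that("long horizons converge to the plateau fixed point where loss > 0", {
  growth <- default_growth_params()
  ss <- steady_state_conc(toy_env(), toy_geometry(), toy_rt(), toy_atm(),
                          growth, flux = toy_flux())
  expect_true(ss$divergent[["grain"]])
  expect_false(any(ss$divergent[c("root", "stem", "leaf")]))
  res <- toy_simulation(cfg = simulation_config(t_end = 3000))
  for (p in c("root", "stem", "leaf")) {
    expect_equal(unname(res$final[p]), unname(ss$conc[p]), tolerance = 0.01)
  }
  # zero sources -> zero fixed point, nothing divergent
  ss0 <- steady_state_conc(toy_env(c_total = 0, c_a = 0), toy_geometry(),
                           toy_rt(), toy_atm(), growth, flux = toy_flux())
  expect_true(all(ss0$conc == 0))
  expect_false(any(ss0$divergent))
})

test_that("raising the soluble soil concentration never lowers any tissue concentration", {
  base <- toy_simulation()
  higher <- simulate_accumulation(
    metal_environment("Cu", 22.1, c_s = 2 * 1.105, c_t = 2.21, c_a = 5e-5,
                      m_s = 2, k_sw = 9.5),
    toy_geometry(), toy_rt(), toy_atm(), default_growth_params(),
    simulation_config(), flux = toy_flux()
  )
  expect_true(all(higher$C - base$C >= -1e-12))
})

test_that("final tables carry the per-metal columns and the shipped ordering", {
  cfg <- shipped_config()
  res <- lapply(stats::setNames(nm = names(cfg$metals)), function(m) {
    inp <- config_inputs(cfg, m)
    simulate_accumulation(inp$env, inp$geom, inp$rt, inp$atm, inp$growth,
                          inp$cfg, inp$flux)
  })
  tab <- final_table(res)
  expect_equal(tab$part, wheat_parts())
  expect_equal(names(tab), c("part", names(cfg$metals)))
  for (m in names(cfg$metals)) {
    conc <- stats::setNames(tab[[m]], tab$part)
    expect_gt(conc[["root"]], conc[["leaf"]])
    expect_gt(conc[["leaf"]], conc[["stem"]])
    expect_gt(conc[["root"]], conc[["grain"]])
  }
  expect_error(final_table(list()), "no simulation results")
})

test_that("simulation metadata echoes parameters and logged assumptions", {
  res <- toy_simulation()
  md <- res$metadata
  expect_s3_class(md$env, "metal_environment")
  expect_equal(md$dt_used, 0.5)
  expect_true(any(grepl("phloem", md$assumptions)))
  expect_true(any(grepl("tau", md$assumptions)))
  # trajectory export round-trips through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_result(res, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 4 * length(res$t))
  expect_equal(back$conc_mg_per_kg[back$part == "root"],
               unname(res$C[, "root"]))
})
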