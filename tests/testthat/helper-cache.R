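# Session-wide fixture cache: expensive simulations are computed once and
# shared across test files (testthat runs all files in one process).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

ref_elec <- function() electrolyte_reference()

# limit-cycle biomarkers at given electrolytes (40-beat CL-1000 pre-pacing)
lc_bm <- function(Ko = 4.5, Nao = 140, Cao = 1.8, fibrotic = FALSE) {
  key <- sprintf("bm_%g_%g_%g_%d", Ko, Nao, Cao, fibrotic)
  cached(key, {
    p <- if (fibrotic) apply_fibrosis_remodelling(crn_parameters())
         else crn_parameters()
    limit_cycle_biomarkers(p, electrolyte_set(Ko, Nao, Cao),
                           cl = 1000, n_prepace_beats = 40)
  })
}

# paced 1-cm strand runs at baseline (two beats; CV on the second)
healthy_strand <- function() cached("healthy_strand",
  strand_cv_protocol(crn_parameters(), ref_elec(), cl = 1000,
                     n_prepace_beats = 40, n_beats = 2))

fibrotic_strand <- function() cached("fibrotic_strand",
  strand_cv_protocol(apply_fibrosis_remodelling(crn_parameters()), ref_elec(),
                     cl = 1000, n_prepace_beats = 40, n_beats = 2))

# small desk substrate and its paced mapping run (also drives the
# single-stimulus screen)
tiny_config <- function() substrate_config(size = 1.0, dx = 500)

tiny_substrate <- function() cached("tiny_substrate",
  suppressWarnings(build_substrate(generate_iir_field(tiny_config(), seed = 3),
                                   tiny_config())))

tiny_mapping <- function() cached("tiny_mapping",
  mapping_run(tiny_substrate(), ref_elec(), n_prepace_beats = 20,
              dt = 0.05, extra_ms = 1600))

# desk-scale four-spiral induction episode: 6-cm sheet, 500-um spacing,
# halved conductivities (diffusely remodelled AF substrate), hyponatraemia
spiral_episode <- function() cached("spiral_episode", {
  icfg <- substrate_config(size = 6.0, dx = 500, sigma_scale = 0.5)
  sub <- suppressWarnings(build_substrate(generate_iir_field(icfg, seed = 11),
                                          icfg))
  e <- electrolyte_set(4.5, 105, 1.8)
  ic <- spiral_initial_condition(sub, e, n_prepace_beats = 30)
  res <- solve_monodomain(sub$geometry, sub$params, e, list(),
                          t_end = 2200, dt = 0.05, out_dt = 10,
                          initial_states = ic$states)
  list(episode = classify_episode(res, final_stim_time = 0),
       ic = ic, substrate = sub)
})
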