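# Shared fixtures: analytic test landscapes with known properties and a
# memoised cache of the full default pipeline runs reused across files.

# featureless surface: straight path, flat profile, negligible transverse
# stiffness -- the restraint is the only force
flat_landscape <- function() {
  landscape_spec(
    path_spec(data.frame(s = c(0, 1), phi = c(-170, 170), psi = c(0, 0)),
              data.frame(s = c(0, 1), F = c(0, 0)),
              profile_ends = "secant"),
    transverse_stiffness = 1e-9)
}

# exactly linear free energy F = a * phi (a in kJ/mol/rad) near the center
tilted_landscape <- function(a_rad = 5) {
  landscape_spec(
    path_spec(data.frame(s = c(0, 1), phi = c(-90, 90), psi = c(0, 0)),
              data.frame(s = c(0, 1), F = c(0, a_rad * pi)),
              profile_ends = "secant"),
    transverse_stiffness = 1e-9)
}

# symmetric 1-D double well along phi with stiff transverse confinement
doublewell_landscape <- function(barrier = 4, kt = 0.5) {
  landscape_spec(
    path_spec(data.frame(s = c(0, 1), phi = c(-60, 60), psi = c(0, 0)),
              data.frame(s = c(0, 0.5, 1), F = c(0, barrier, 0))),
    transverse_stiffness = kt)
}

# straight shallow valley whose analytic MFEP is the line psi = 0
valley_landscape <- function() {
  landscape_spec(
    path_spec(data.frame(s = c(0, 1), phi = c(-60, 60), psi = c(0, 0)),
              data.frame(s = c(0, 0.5, 1), F = c(0, 5, 0))),
    transverse_stiffness = 0.05)
}

.fixture_cache <- new.env(parent = emptyenv())

default_landscape_cached <- function() {
  if (is.null(.fixture_cache$landscape))
    .fixture_cache$landscape <- build_default_landscape()
  .fixture_cache$landscape
}

# one full pipeline run (20-image FTS + refined line-integral PMF),
# memoised by (seed, field)
default_pipeline_run <- function(seed, field = NULL) {
  key <- paste0("run_s", seed, "_",
                if (is.null(field)) "nofield"
                else paste0(field$axis, field$sign, "_", field$strength))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  ls <- default_landscape_cached()
  fts <- run_fts(ls, field, fts_config(), seed = seed)
  pmf <- pmf_from_fts(ls, fts, field)
  out <- list(fts = fts, pmf = pmf)
  assign(key, out, envir = .fixture_cache)
  out
}
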