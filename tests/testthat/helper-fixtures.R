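# Shared fixtures, memoised so expensive bundles are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one small family with a calibrated profile
small_family <- function() {
  memo("small_family", function() {
    fam <- gen_profile_family(fixture_spec(), 1)
    fam$calibrated <- calibrate_profile(fam$profile, n_random = 500, seed = 7)
    fam
  })
}

# compact pipeline world: 4 families, 400-structure library
small_world <- function() {
  memo("small_world", function() {
    spec <- fixture_spec(n_proteins = 6, n_families = 4, library_size = 400)
    b <- gen_fixture_bundle(spec)
    b$resources <- pipeline_resources(
      b$profiles, b$library, b$map, b$cdf,
      orthologs = b$orthologs, ortholog_seqs = b$ortholog_seqs,
      essentials = b$essentials)
    b
  })
}

# the reference study conditions (defaults), used by the acceptance tests
default_bundle <- function() {
  memo("default_bundle", function() gen_fixture_bundle(fixture_spec()))
}

tmp_file <- function(ext = "") {
  tempfile(fileext = ext)
}

random_id <- function(n = 8) {
  paste(sample(c(letters, LETTERS, 0:9), n, replace = TRUE), collapse = "")
}
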