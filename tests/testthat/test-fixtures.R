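# Synthetic generators: purity (seeded determinism), substitution-rate
# statistics, library/map construction, strict/relaxed engineering, and
# ground-truth bookkeeping.

test_that("generators are pure functions of their spec", {
  spec <- fixture_spec(n_families = 3, n_proteins = 4, library_size = 200)
  f1 <- gen_profile_family(spec, 2)
  f2 <- gen_profile_family(spec, 2)
  expect_identical(f1, f2)

  z1 <- gen_background_zscores(spec)
  z2 <- gen_background_zscores(spec)
  expect_identical(z1, z2)

  l1 <- gen_structure_library(spec, list(f1))
  l2 <- gen_structure_library(spec, list(f1))
  expect_identical(l1, l2)

  # different seed, different draws
  spec2 <- fixture_spec(seed = 2, n_families = 3, n_proteins = 4,
                        library_size = 200)
  expect_false(identical(gen_profile_family(spec2, 2)$consensus,
                         f1$consensus))
})

test_that("zero-divergence members equal the consensus; substitution rate tracks", {
  spec <- fixture_spec()
  fam <- gen_profile_family(spec, 1)
  zero <- fam$members[fam$members$divergence == 0, ]
  expect_true(all(zero$seq == fam$consensus))

  # binomial oracle: fraction of substituted sites within 3 sigma of rate
  set.seed(81)
  L <- 2000
  cons <- paste(sample(aa_alphabet(), L, TRUE), collapse = "")
  for (rate in c(0.1, 0.3, 0.6)) {
    mut <- mutate_seq(cons, rate)
    frac <- mean(strsplit(cons, "")[[1]] != strsplit(mut, "")[[1]])
    expect_lt(abs(frac - rate), 3 * sqrt(rate * (1 - rate) / L))
  }
})

test_that("the structure library links families to their own structures only", {
  spec <- fixture_spec(n_families = 3, library_size = 50)
  fams <- lapply(1:3, function(i) gen_profile_family(spec, i))
  lib <- gen_structure_library(spec, fams)
  expect_equal(nrow(lib$library), 50)
  expect_equal(sort(names(lib$map)), sort(sapply(fams, `[[`, "accession")))
  expect_equal(lengths(lib$map), setNames(rep(2L, 3), names(lib$map)))
  expect_false(any(duplicated(lib$library$structure_id)))
  expect_true(all(unlist(lib$map) %in% lib$library$structure_id))

  # decoy reference sequences are not close to any family consensus:
  # alignment-score separation against the mapped references
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  b62 <- env$BLOSUM62
  decoys <- lib$library[lib$library$fold_class == "decoy", ][1:10, ]
  for (f in fams) {
    mapped <- lib$library[lib$library$structure_id %in% lib$map[[f$accession]], ]
    self <- Biostrings::pairwiseAlignment(mapped$ref_seq[1], f$consensus,
                                          substitutionMatrix = b62,
                                          gapOpening = 11, gapExtension = 1,
                                          type = "local", scoreOnly = TRUE)
    dec <- max(vapply(decoys$ref_seq, function(d) {
      Biostrings::pairwiseAlignment(d, f$consensus,
                                    substitutionMatrix = b62,
                                    gapOpening = 11, gapExtension = 1,
                                    type = "local", scoreOnly = TRUE)
    }, numeric(1)))
    expect_gt(self, dec + 50)
  }

  expect_error(gen_structure_library(fixture_spec(n_families = 3,
                                                  library_size = 4), fams),
               "library_size")
})

test_that("background samples match the spec's model and count", {
  spec <- fixture_spec(background_n = 1e5)
  z <- gen_background_zscores(spec)
  expect_length(z, 1e5)
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(stats::sd(z) - 1), 0.02)
})

test_that("strict/relaxed pairs engineer the hide-and-seek contrast", {
  spec <- fixture_spec(n_families = 2, library_size = 100)
  fam <- gen_profile_family(spec, 1)
  pair <- gen_strict_relaxed_pair(spec, fam)
  expect_equal(pair$old$db_version, "synthetic-old")
  expect_equal(pair$new$db_version, "synthetic-new")

  score_vs <- function(profile, sq) {
    s <- remotethread:::.glocal_score_cpp(profile$match_scores,
                                          remotethread:::encode_seq(sq),
                                          2.5, 2.5, -0.5)
    spec$effective_db_size *
      exp(-profile$calibration$lambda * (s - profile$calibration$mu))
  }
  far <- pair$far_members$seq[1]
  e_old <- score_vs(pair$old, far)
  e_new <- score_vs(pair$new, far)
  expect_gt(e_old, 0.1)
  expect_lt(e_new, 0.1)
  expect_gte(e_old / e_new, 10)

  # near members stay significant on both releases
  near <- fam$members$seq[fam$members$divergence == 0.1][1]
  expect_lt(score_vs(pair$old, near), 1e-4)
  expect_lt(score_vs(pair$new, near), 1e-4)

  # with no far members the releases coincide
  pair0 <- gen_strict_relaxed_pair(spec, fam, far_seqs = list())
  expect_equal(pair0$old$match_scores, pair0$new$match_scores)
})

test_that("proteomes carry exactly the planted ground truth", {
  w <- small_world()
  spec <- w$spec
  expect_equal(nrow(w$truth), spec$n_proteins * spec$planted_per_protein)
  for (i in seq_len(nrow(w$truth))) {
    p <- w$proteome$seq[w$proteome$id == w$truth$protein_id[i]]
    expect_gte(w$truth$env_start[i], 0)
    expect_lte(w$truth$env_end[i], nchar(p))
  }
  # remote plants landed in the weak, reportable E band
  rem <- w$truth[w$truth$kind == "remote", ]
  expect_true(all(rem$evalue_planted > 0.1 & rem$evalue_planted < 50))

  # ortholog-vs-query identity ~ 1 - ortholog_divergence
  ids <- w$orthologs$ortholog_id[w$orthologs$query_id == w$proteome$id[1]]
  q <- strsplit(w$proteome$seq[1], "")[[1]]
  for (oid in ids) {
    o <- strsplit(w$ortholog_seqs$seq[w$ortholog_seqs$id == oid], "")[[1]]
    ident <- mean(q == o)
    expect_lt(abs(ident - (1 - spec$ortholog_divergence)),
              3 * sqrt(spec$ortholog_divergence / length(q)) + 0.01)
  }
  # one ortholog per species per query
  per <- table(w$orthologs$query_id)
  expect_true(all(per == spec$n_species))
})

test_that("essential-residue fixtures flag consensus positions in range", {
  w <- small_world()
  for (f in w$families) {
    ess <- w$essentials[w$essentials$profile_accession == f$accession, ]
    expect_equal(nrow(ess), 8)
    expect_true(all(ess$position >= 1 & ess$position <= nchar(f$consensus)))
    expect_equal(ess$residue,
                 substring(f$consensus, ess$position, ess$position))
  }
})

test_that("fixture bundles write and read back through the package formats", {
  w <- small_world()
  dir <- tempfile()
  write_fixtures(w[setdiff(names(w), "resources")], dir)
  prot <- read_fasta(file.path(dir, "proteome.fasta"))
  expect_equal(prot$id, w$proteome$id)
  expect_equal(prot$seq, w$proteome$seq)
  db <- read_profile_db(file.path(dir, "profiles.tsv"))
  expect_equal(names(db), names(w$profiles))
  lib <- read_structure_library(file.path(dir, "structures.tsv"),
                                file.path(dir, "structures.fasta"))
  expect_equal(lib, w$library)
  map <- read_structure_map(file.path(dir, "structmap.tsv"), lib)
  expect_equal(map[names(w$map)], lapply(w$map, unname))
  z <- read_background_zscores(file.path(dir, "background_z.txt"))
  expect_equal(as.numeric(z), as.numeric(w$background))
})
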