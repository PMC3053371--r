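# Deterministic generators for every input the pipeline and benchmark
# consume: domain families with mapped structures, remote members at
# engineered E-value bands, proteomes with planted domains and
# re-diverged orthologs, structure libraries with decoys, and background
# Z-score samples. Every generator is a pure function of its spec (seed
# included).

#' Fixture specification
#'
#' Defaults are the package's reference study conditions (rationale in
#' the methods vignette): 10 domain families of length 60-90, two
#' near-consensus structures per family in a 1000-structure library
#' (top window 5), 30 proteins each carrying one planted domain
#' (alternating exact and engineered-remote members), remote members
#' tuned into the E-value band (0.2, 10), orthologs in 3 species
#' re-diverged at rate 0.02, and a standard-normal background Z model
#' with 1e5 draws.
#'
#' @param seed Master seed; every generator derives its stream from it.
#' @param n_families Number of domain families.
#' @param profile_length Length range `c(min, max)` of family consensus.
#' @param n_structures_per_profile Structures mapped per family.
#' @param library_size Total structure library size (incl. decoys).
#' @param divergence_levels Substitution rates at which family members
#'   are generated.
#' @param n_members_per_level Members generated per divergence level.
#' @param n_proteins Proteome size.
#' @param planted_per_protein Planted domains per protein.
#' @param ortholog_divergence Whole-protein substitution rate for
#'   re-diverged orthologs.
#' @param n_species Validation species count (<= 3).
#' @param background_z_model Background Z distribution (only
#'   `"normal"` bundled).
#' @param background_n Background sample size.
#' @param flank_length Range of random flank lengths around planted
#'   domains.
#' @param remote_band Target E-value band `c(lo, hi)` for engineered
#'   remote members.
#' @param effective_db_size E-value scaling attached to generated profile
#'   databases (full domain-database scale; see [effective_db_size()]).
#' @param n_calibration Random sequences per profile calibration.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1,
                         n_families = 10,
                         profile_length = c(60, 90),
                         n_structures_per_profile = 2,
                         library_size = 1000,
                         divergence_levels = c(0, 0.1, 0.2, 0.3, 0.45),
                         n_members_per_level = 3,
                         n_proteins = 30,
                         planted_per_protein = 1,
                         ortholog_divergence = 0.02,
                         n_species = 3,
                         background_z_model = "normal",
                         background_n = 1e5,
                         flank_length = c(40, 80),
                         remote_band = c(0.2, 10),
                         effective_db_size = 10000,
                         n_calibration = 500) {
  stopifnot(seed == as.integer(seed), n_species <= 3,
            planted_per_protein == 1,
            all(divergence_levels >= 0 & divergence_levels <= 1),
            ortholog_divergence >= 0, ortholog_divergence <= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

# BLOSUM-conditioned substitution proposal: replacement for residue o is
# drawn with probability proportional to exp(B62[o, a] / 2) over a != o,
# so substitutions stay biochemically plausible and remote members remain
# fold-detectable by the surrogate (structure outlasting sequence).
substitution_proposals <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- blosum62()[aa_alphabet(), aa_alphabet()]
      w <- exp(b / 2)
      diag(w) <- 0
      cache <<- sweep(w, 1, rowSums(w), "/")
    }
    cache
  }
})

#' Mutate a sequence by i.i.d. per-site substitution
#'
#' Each site is replaced with probability `rate`; replacements are drawn
#' from the BLOSUM-conditioned proposal (never the original residue).
#' Uses the current RNG stream; wrap in a seeded context for
#' reproducibility.
#'
#' @param seq Residue string.
#' @param rate Substitution rate in \[0, 1\].
#' @return Mutated residue string.
#' @export
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate & chars %in% aa_alphabet())
  if (length(hit) > 0) {
    prop <- substitution_proposals()
    chars[hit] <- vapply(chars[hit], function(o) {
      sample(aa_alphabet(), 1, prob = prop[o, ])
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Generate one synthetic domain family
#'
#' Random consensus, members at each divergence level, and a profile
#' built from the near members (consensus plus members at divergence
#' <= 0.1) with pseudocounts.
#'
#' @param spec A [fixture_spec()].
#' @param family_index 1-based family number (drives accession and seed).
#' @return List: `profile` (uncalibrated), `consensus`, `members` tibble
#'   (`divergence`, `seq`), `accession`.
#' @export
gen_profile_family <- function(spec, family_index) {
  acc <- sprintf("PF%04d", family_index)
  with_seed(spec$seed + 1000L + family_index, {
    L <- sample(spec$profile_length[1]:spec$profile_length[2], 1)
    consensus <- random_seq(L)
    members <- bind_rows(lapply(spec$divergence_levels, function(d) {
      tibble(divergence = d,
             seq = vapply(seq_len(spec$n_members_per_level),
                          function(i) mutate_seq(consensus, d),
                          character(1)))
    }))
    near <- c(consensus, members$seq[members$divergence <= 0.1])
    profile <- build_profile(near, accession = acc,
                             name = paste0("fam_", family_index),
                             db_version = "synthetic-1")
    list(profile = profile, consensus = consensus, members = members,
         accession = acc)
  })
}

#' Generate the structure library and profile-to-structure map
#'
#' Each family receives `n_structures_per_profile` entries whose
#' reference sequences are near-consensus variants (5% divergence);
#' random decoy structures fill the library to `library_size`. The map
#' links each family profile to its own structures only.
#'
#' @param spec A [fixture_spec()].
#' @param families List of families from [gen_profile_family()].
#' @return List: `library` tibble (sorted by `structure_id`), `map`
#'   (named list accession -> structure ids).
#' @export
gen_structure_library <- function(spec, families) {
  n_mapped <- length(families) * spec$n_structures_per_profile
  if (spec$library_size < n_mapped) {
    abort("library_size smaller than total mapped structures")
  }
  with_seed(spec$seed + 2000L, {
    idx <- 0L
    rows <- list()
    map <- list()
    for (f in families) {
      ids <- character(spec$n_structures_per_profile)
      for (j in seq_len(spec$n_structures_per_profile)) {
        idx <- idx + 1L
        ids[j] <- sprintf("S%05d", idx)
        rows[[idx]] <- tibble(structure_id = ids[j],
                              fold_class = paste0("fold_", f$accession),
                              ref_seq = mutate_seq(f$consensus, 0.05))
      }
      map[[f$accession]] <- ids
    }
    lens <- vapply(families, function(f) nchar(f$consensus), integer(1))
    while (idx < spec$library_size) {
      idx <- idx + 1L
      rows[[idx]] <- tibble(structure_id = sprintf("S%05d", idx),
                            fold_class = "decoy",
                            ref_seq = random_seq(sample(lens, 1)))
    }
    library <- bind_rows(rows)
    library$length <- nchar(library$ref_seq)
    library <- arrange(select(library, "structure_id", "fold_class",
                              "length", "ref_seq"),
                       .data$structure_id)
    list(library = library, map = map)
  })
}

#' Generate a background Z-score sample
#'
#' Draws from the spec's background model (standard normal bundled),
#' seeded; at least the spec's `background_n` values.
#'
#' @param spec A [fixture_spec()].
#' @return Numeric vector with `source` attribute.
#' @export
gen_background_zscores <- function(spec) {
  if (!identical(spec$background_z_model, "normal")) {
    abort("only the standard-normal background model is bundled")
  }
  z <- with_seed(spec$seed + 3000L, rnorm(spec$background_n))
  attr(z, "source") <- paste0("synthetic-normal-seed", spec$seed)
  z
}

# Engineer a family member whose E-value against `profile` falls in
# `band` (bisection on the divergence rate; the E(divergence) relation is
# monotone in expectation). Returns the closest achieved member when the
# band is not hit exactly.
tune_member_evalue <- function(consensus, profile, db_size, band,
                               max_iter = 24) {
  target <- sqrt(band[1] * band[2])
  lo <- 0.05; hi <- 0.95
  best <- NULL
  for (it in seq_len(max_iter)) {
    d <- (lo + hi) / 2
    seq <- mutate_seq(consensus, d)
    s <- .glocal_score_cpp(profile$match_scores, encode_seq(seq),
                           .gap_ins, .gap_del, .x_score)
    ev <- evalue_from_score(s, profile$calibration, db_size)
    if (is.null(best) ||
        abs(log(ev) - log(target)) < abs(log(best$evalue) - log(target))) {
      best <- list(seq = seq, divergence = d, evalue = ev)
    }
    if (ev >= band[1] && ev <= band[2]) {
      return(list(seq = seq, divergence = d, evalue = ev))
    }
    if (ev < band[1]) lo <- d else hi <- d
  }
  best
}

#' Generate a strict/relaxed profile pair for the hide-and-seek benchmark
#'
#' The "old" profile is built from near members only; "far" members are
#' engineered so their E-value against the old profile falls in the
#' spec's remote band (weak but reportable); the "new" profile is built
#' from near plus far members, emulating a domain family that grew more
#' sensitive between releases.
#'
#' @param spec A [fixture_spec()].
#' @param family A family from [gen_profile_family()].
#' @param n_far Number of engineered far members (when `far_seqs` is not
#'   supplied).
#' @param db_size Effective database size used for the tuned E-values
#'   (default the spec's `effective_db_size`).
#' @param far_seqs Optional pre-engineered far member sequences (e.g.
#'   verified in their genomic context by the benchmark generator); when
#'   given they are used verbatim instead of tuning fresh ones.
#' @return List: `old` and `new` calibrated `domain_profile`s, and
#'   `far_members` tibble (`seq`, `divergence`, `evalue_old`).
#' @export
gen_strict_relaxed_pair <- function(spec, family, n_far = 1,
                                    db_size = spec$effective_db_size,
                                    far_seqs = NULL) {
  with_seed(spec$seed + 4000L + match(family$accession,
                                      sprintf("PF%04d", 1:10000)), {
    near <- c(family$consensus,
              family$members$seq[family$members$divergence <= 0.1])
    old <- build_profile(near, accession = family$accession,
                         name = family$profile$name,
                         db_version = "synthetic-old")
    old <- calibrate_profile(old, n_random = spec$n_calibration,
                             seed = spec$seed + 41L)
    far <- if (is.null(far_seqs)) {
      lapply(seq_len(n_far), function(i) {
        tune_member_evalue(family$consensus, old, db_size, spec$remote_band)
      })
    } else {
      lapply(far_seqs, function(fs) {
        s <- .glocal_score_cpp(old$match_scores, encode_seq(fs),
                               .gap_ins, .gap_del, .x_score)
        list(seq = fs, divergence = NA_real_,
             evalue = evalue_from_score(s, old$calibration, db_size))
      })
    }
    new <- build_profile(c(near, vapply(far, `[[`, character(1), "seq")),
                         accession = family$accession,
                         name = family$profile$name,
                         db_version = "synthetic-new")
    new <- calibrate_profile(new, n_random = spec$n_calibration,
                             seed = spec$seed + 42L)
    list(old = old, new = new,
         far_members = tibble(
           seq = vapply(far, `[[`, character(1), "seq"),
           divergence = vapply(far, `[[`, numeric(1), "divergence"),
           evalue_old = vapply(far, `[[`, numeric(1), "evalue")))
  })
}

# Assemble flank + member + flank and verify that a profile search of the
# assembled protein reports the planted region: E-value inside the
# verification band (weak but reportable) and envelope covering at least
# `min_cover` of the planted interval. Retries with fresh members and
# flanks; remote members are engineered by construction.
assemble_remote_protein <- function(spec, fam, profile, db_size,
                                    max_attempts = 25, min_cover = 0.6) {
  verify_band <- c(max(0.15, spec$remote_band[1] / 2),
                   min(20, spec$remote_band[2] * 2))
  best <- NULL
  for (a in seq_len(max_attempts)) {
    tuned <- tune_member_evalue(fam$consensus, profile, db_size,
                                spec$remote_band)
    fl1 <- random_seq(sample(spec$flank_length[1]:spec$flank_length[2], 1))
    fl2 <- random_seq(sample(spec$flank_length[1]:spec$flank_length[2], 1))
    pseq <- paste0(fl1, tuned$seq, fl2)
    start <- nchar(fl1); end <- start + nchar(tuned$seq)
    aln <- .glocal_align_cpp(profile$match_scores, encode_seq(pseq),
                             .gap_ins, .gap_del, .x_score)
    ev <- evalue_from_score(aln$score, profile$calibration, db_size)
    cover <- (min(aln$qend, end) - max(aln$qstart - 1L, start)) / (end - start)
    cand <- list(seq = pseq, env_start = start, env_end = end,
                 divergence = tuned$divergence, evalue = ev, cover = cover)
    ok_band <- ev >= verify_band[1] && ev <= verify_band[2]
    if (ok_band && cover >= min_cover) return(cand)
    if (is.null(best) || (ok_band && cover > best$cover)) best <- cand
  }
  best
}

#' Generate a proteome with planted domains and re-diverged orthologs
#'
#' Proteins alternate between an exact (divergence 0) planted member and
#' an engineered remote member tuned into the spec's E-value band against
#' the supplied calibrated database. Each protein gets one ortholog per
#' validation species: the whole protein re-diverged at the spec's
#' ortholog rate. Ground truth records every planted domain.
#'
#' @param spec A [fixture_spec()].
#' @param families Families from [gen_profile_family()].
#' @param db Calibrated `profile_db` the proteome will be searched with
#'   (used to tune remote members' E-values).
#' @return List: `proteome` (sequence tibble), `orthologs` (table),
#'   `ortholog_seqs` (sequence tibble), `truth` tibble (`protein_id`,
#'   `profile_accession`, `env_start`, `env_end`, `divergence`, `kind`,
#'   `evalue_planted`).
#' @export
gen_proteome_with_orthologs <- function(spec, families, db) {
  species <- c("mouse", "dog", "chicken")[seq_len(spec$n_species)]
  with_seed(spec$seed + 5000L, {
    prot <- list(); truth <- list(); orth <- list(); orth_seqs <- list()
    for (i in seq_len(spec$n_proteins)) {
      pid <- sprintf("prot%03d", i)
      fam <- families[[(i - 1L) %% length(families) + 1L]]
      kind <- if (i %% 2 == 1) "significant" else "remote"
      if (kind == "significant") {
        fl1 <- random_seq(sample(spec$flank_length[1]:spec$flank_length[2], 1))
        fl2 <- random_seq(sample(spec$flank_length[1]:spec$flank_length[2], 1))
        pseq <- paste0(fl1, fam$consensus, fl2)
        trow <- tibble(protein_id = pid, profile_accession = fam$accession,
                       env_start = nchar(fl1),
                       env_end = nchar(fl1) + nchar(fam$consensus),
                       divergence = 0, kind = kind,
                       evalue_planted = NA_real_)
      } else {
        asm <- assemble_remote_protein(spec, fam, db[[fam$accession]],
                                       effective_db_size(db))
        pseq <- asm$seq
        trow <- tibble(protein_id = pid, profile_accession = fam$accession,
                       env_start = asm$env_start, env_end = asm$env_end,
                       divergence = asm$divergence, kind = kind,
                       evalue_planted = asm$evalue)
      }
      prot[[i]] <- tibble(id = pid, desc = "", seq = pseq)
      truth[[i]] <- trow
      for (sp in species) {
        oid <- paste0(pid, "_", sp)
        orth[[length(orth) + 1]] <- tibble(query_id = pid, species = sp,
                                           ortholog_id = oid)
        orth_seqs[[length(orth_seqs) + 1]] <-
          tibble(id = oid, desc = "",
                 seq = mutate_seq(pseq, spec$ortholog_divergence))
      }
    }
    list(proteome = bind_rows(prot),
         orthologs = bind_rows(orth),
         ortholog_seqs = bind_rows(orth_seqs),
         truth = bind_rows(truth))
  })
}

#' Generate essential-residue annotations for the synthetic families
#'
#' Flags `n_flagged` random consensus positions per family with the
#' consensus residue as the expected functional residue.
#'
#' @param spec A [fixture_spec()].
#' @param families Families from [gen_profile_family()].
#' @param n_flagged Flagged positions per family.
#' @return Essential-residue tibble (`profile_accession`, `position`,
#'   `residue`).
#' @export
gen_essential_residues <- function(spec, families, n_flagged = 8) {
  with_seed(spec$seed + 6000L, {
    bind_rows(lapply(families, function(f) {
      L <- nchar(f$consensus)
      pos <- sort(sample(seq_len(L), min(n_flagged, L)))
      tibble(profile_accession = f$accession, position = pos,
             residue = substring(f$consensus, pos, pos))
    }))
  })
}

#' Generate the complete default fixture bundle
#'
#' Families, calibrated profile database, structure library and map,
#' background CDF, planted proteome with orthologs, ground truth and
#' essential residues — everything [run_proteome()] consumes.
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `spec`, `families`, `profiles`, `library`,
#'   `map`, `background`, `cdf`, `proteome`, `orthologs`,
#'   `ortholog_seqs`, `truth`, `essentials`.
#' @export
gen_fixture_bundle <- function(spec = fixture_spec()) {
  families <- lapply(seq_len(spec$n_families),
                     function(i) gen_profile_family(spec, i))
  profiles <- calibrate_db(
    profile_db(lapply(families, `[[`, "profile")),
    n_random = spec$n_calibration, seed = spec$seed + 7000L)
  effective_db_size(profiles) <- spec$effective_db_size
  lib <- gen_structure_library(spec, families)
  background <- gen_background_zscores(spec)
  cdf <- build_cdf(background)
  prot <- gen_proteome_with_orthologs(spec, families, profiles)
  essentials <- gen_essential_residues(spec, families)
  list(spec = spec, families = families, profiles = profiles,
       library = lib$library, map = lib$map,
       background = background, cdf = cdf,
       proteome = prot$proteome, orthologs = prot$orthologs,
       ortholog_seqs = prot$ortholog_seqs, truth = prot$truth,
       essentials = essentials)
}

#' Generate a paired-release benchmark fixture
#'
#' Builds a strict ("old") and relaxed ("new") profile database over the
#' spec's families, a proteome in which each family plants one engineered
#' far member (the known truth set: weak under old, significant under
#' new), one near member (significant under both) and random decoy
#' flanks, plus the structure library, map and background CDF needed to
#' run fold recognition on the old-release candidates.
#'
#' @param spec A [fixture_spec()] (benchmark runs are typically scaled
#'   down, e.g. `n_families = 6`, `library_size = 600`).
#' @return List: `old_db`, `new_db` (calibrated), `library`, `map`,
#'   `cdf`, `proteome`, `truth` (engineered far-member table with
#'   envelopes), `families`.
#' @export
gen_benchmark_fixture <- function(spec = fixture_spec(n_families = 6,
                                                      n_proteins = 12,
                                                      library_size = 600)) {
  families <- lapply(seq_len(spec$n_families),
                     function(i) gen_profile_family(spec, i))
  # per family: calibrated old profile, a far member verified in its
  # assembled protein context, then the relaxed pair including that member
  base_pairs <- lapply(families, function(f) gen_strict_relaxed_pair(spec, f))
  asms <- with_seed(spec$seed + 8000L, {
    lapply(seq_along(families), function(j) {
      assemble_remote_protein(spec, families[[j]], base_pairs[[j]]$old,
                              spec$effective_db_size)
    })
  })
  pairs <- lapply(seq_along(families), function(j) {
    member <- substr(asms[[j]]$seq, asms[[j]]$env_start + 1,
                     asms[[j]]$env_end)
    gen_strict_relaxed_pair(spec, families[[j]], far_seqs = list(member))
  })
  old_db <- new_profile_db(lapply(pairs, `[[`, "old"))
  new_db <- new_profile_db(lapply(pairs, `[[`, "new"))
  effective_db_size(old_db) <- spec$effective_db_size
  effective_db_size(new_db) <- spec$effective_db_size
  lib <- gen_structure_library(spec, families)
  cdf <- build_cdf(gen_background_zscores(spec))
  with_seed(spec$seed + 8500L, {
    prot <- list(); truth <- list()
    pi_ <- 0L
    for (j in seq_along(families)) {
      fam <- families[[j]]
      # far-member protein (truth entry), envelope verified at assembly
      pi_ <- pi_ + 1L
      pid <- sprintf("bprot%03d", pi_)
      prot[[pi_]] <- tibble(id = pid, desc = "", seq = asms[[j]]$seq)
      truth[[length(truth) + 1]] <-
        tibble(protein_id = pid, profile_accession = fam$accession,
               env_start = asms[[j]]$env_start,
               env_end = asms[[j]]$env_end,
               divergence = asms[[j]]$divergence,
               evalue_old = asms[[j]]$evalue)
      # near-member protein, significant under both releases
      pi_ <- pi_ + 1L
      pid <- sprintf("bprot%03d", pi_)
      fl1 <- random_seq(sample(spec$flank_length[1]:spec$flank_length[2], 1))
      fl2 <- random_seq(sample(spec$flank_length[1]:spec$flank_length[2], 1))
      prot[[pi_]] <- tibble(id = pid, desc = "",
                            seq = paste0(fl1, mutate_seq(fam$consensus, 0.05),
                                         fl2))
    }
    list(old_db = old_db, new_db = new_db, library = lib$library,
         map = lib$map, cdf = cdf, proteome = bind_rows(prot),
         truth = bind_rows(truth), families = families)
  })
}

#' Write a fixture bundle to disk in the package's text formats
#'
#' Emits every file the pipeline and benchmark commands consume:
#' proteome and ortholog FASTA, profile database, structure library
#' manifest + FASTA, structure map, ortholog table, essential residues,
#' background Z-scores, and the ground-truth table.
#'
#' @param bundle From [gen_fixture_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$proteome, file.path(dir, "proteome.fasta"))
  write_fasta(bundle$ortholog_seqs, file.path(dir, "orthologs.fasta"))
  write_profile_db(bundle$profiles, file.path(dir, "profiles.tsv"))
  write_structure_library(bundle$library,
                          file.path(dir, "structures.tsv"),
                          file.path(dir, "structures.fasta"))
  write_structure_map(bundle$map, file.path(dir, "structmap.tsv"))
  write_ortholog_table(bundle$orthologs, file.path(dir, "orthologs.tsv"))
  write_essential_residues(bundle$essentials,
                           file.path(dir, "essentials.tsv"))
  write_background_zscores(bundle$background,
                           file.path(dir, "background_z.txt"),
                           source = attr(bundle$background, "source"))
  readr::write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
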