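# Relaxed profile search: planted-consensus recovery, E-value
# calibration, deterministic ordering, overlap resolution, gating.

test_that("a planted consensus is the top hit with E far below 1e-04", {
  fam <- small_family()
  db <- profile_db(list(fam$calibrated))
  effective_db_size(db) <- 10000
  seqs <- tibble::tibble(id = "q1",
                         seq = paste0(strrep("G", 10), fam$consensus,
                                      strrep("S", 10)))
  hits <- search_domains(seqs, db)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$profile_accession[1], fam$accession)
  expect_lt(hits$evalue[1], 1e-4)
  # envelope covers the planted region
  expect_lte(abs(hits$env_start[1] - 10), 2)
  expect_lte(abs(hits$env_end[1] - (10 + nchar(fam$consensus))), 2)
  # alignment pairs strictly increasing and inside the envelope
  aln <- hits$alignment[[1]]
  expect_true(all(diff(aln$ppos) > 0))
  expect_true(all(diff(aln$qpos) > 0))
  expect_true(all(aln$qpos >= hits$env_start[1] + 1 &
                    aln$qpos <= hits$env_end[1]))
})

test_that("search rejects bad inputs per contract", {
  fam <- small_family()
  expect_error(search_domains(tibble::tibble(id = "q", seq = "ACDEFGHIKL"),
                              profile_db(list(fam$profile))),
               "uncalibrated")
  expect_error(profile_db(list()), "length")
  db <- profile_db(list(fam$calibrated))
  expect_warning(out <- search_domains(tibble::tibble(id = "q", seq = "ACD"),
                                       db),
                 "shorter than 5")
  expect_equal(nrow(out), 0)
})

test_that("calibration is deterministic, convergent and rejects degenerate profiles", {
  fam <- small_family()
  a <- calibrate_profile(fam$profile, 500, seed = 3)
  b <- calibrate_profile(fam$profile, 500, seed = 3)
  expect_identical(a$calibration, b$calibration)

  big <- calibrate_profile(fam$profile, 5000, seed = 4)
  small <- calibrate_profile(fam$profile, 500, seed = 5)
  expect_lt(abs(small$calibration$lambda / big$calibration$lambda - 1), 0.05)
  expect_lt(abs(small$calibration$mu / big$calibration$mu - 1), 0.05)

  expect_error(calibrate_profile(fam$profile, 100, seed = 1), ">= 200")

  flat <- fam$profile
  flat$match_scores[] <- 0
  expect_error(calibrate_profile(flat, 500, seed = 1), "degenerate")

  # length-1 profile: documented degenerate handling (finite calibration)
  one <- build_profile("W", accession = "PF_ONE", db_version = "synthetic-1")
  out <- calibrate_profile(one, 500, seed = 6)
  expect_true(is.finite(out$calibration$lambda))
})

test_that("E-values are calibrated: P(E <= e) tracks e for random queries", {
  # Monte-Carlo oracle: score i.i.d. random sequences against a 1-profile
  # database; under the Gumbel calibration the per-trial probability of
  # reporting E <= e is approximately e.
  fam <- small_family()
  pr <- calibrate_profile(fam$profile, 2000, seed = 5)
  db <- profile_db(list(pr))
  effective_db_size(db) <- 1
  len <- pr$calibration$random_length
  set.seed(77)
  seqs <- tibble::tibble(id = sprintf("r%04d", 1:1000),
                         seq = replicate(1000, paste(
                           sample(aa_alphabet(), len, replace = TRUE),
                           collapse = "")))
  cfg <- search_config(report_threshold = 1e6, significant_threshold = 1e-7,
                       weak_threshold = 1e-4)
  ev <- search_domains(seqs, db, cfg)$evalue
  for (e in c(0.02, 0.1, 0.3)) {
    tol <- 0.5 * e + 4 * sqrt(e * (1 - e) / 1000)
    expect_lt(abs(mean(ev <= e) - e), tol)
  }
})

test_that("hits are sorted by E-value with the accession/start tie-break", {
  w <- small_world()
  hits <- search_domains(w$proteome, w$profiles,
                         search_config(report_threshold = 1e5,
                                       significant_threshold = 1e-7,
                                       weak_threshold = 1e-4))
  key <- order(hits$evalue, hits$profile_accession, hits$env_start)
  expect_equal(key, seq_len(nrow(hits)))
})

test_that("resolve_overlaps keeps the best-scoring domain per region", {
  hits <- tibble::tibble(
    protein_id = "p",
    profile_accession = c("A", "B"),
    env_start = c(10L, 40L), env_end = c(60L, 90L),
    bit_score = c(50, 10), evalue = c(1e-6, 2),
    db_version = "v", alignment = list(NULL, NULL))
  kept <- resolve_overlaps(hits)
  expect_equal(kept$profile_accession, "A")

  disjoint <- hits
  disjoint$env_start <- c(10L, 70L); disjoint$env_end <- c(60L, 90L)
  expect_equal(nrow(resolve_overlaps(disjoint)), 2)
  # output sorted by envelope start
  expect_equal(resolve_overlaps(disjoint)$env_start, c(10L, 70L))
})

test_that("resolve_overlaps equals the brute-force greedy oracle on random hits", {
  greedy_oracle <- function(h, max_shared = 0) {
    ord <- order(h$evalue, h$profile_accession, h$env_start)
    kept <- integer(0)
    for (i in ord) {
      ok <- TRUE
      for (j in kept) {
        shared <- min(h$env_end[i], h$env_end[j]) -
          max(h$env_start[i], h$env_start[j])
        if (shared > max_shared) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, i)
    }
    h[sort(kept), , drop = FALSE]
  }
  set.seed(123)
  for (rep in 1:5) {
    n <- 50
    h <- tibble::tibble(
      protein_id = "p",
      profile_accession = sprintf("PF%03d", sample(1:20, n, TRUE)),
      env_start = as.integer(sample(0:300, n, TRUE)))
    h$env_end <- h$env_start + as.integer(sample(20:80, n, TRUE))
    h$evalue <- 10^runif(n, -8, 1.5)
    h$bit_score <- -log10(h$evalue)
    h$db_version <- "v"
    got <- resolve_overlaps(h)
    want <- greedy_oracle(h)
    want <- want[order(want$env_start), , drop = FALSE]
    expect_equal(got[order(got$env_start), ]$env_start, want$env_start)
    expect_equal(sort(got$evalue), sort(want$evalue))
    # kept hits are pairwise non-overlapping
    g <- got[order(got$env_start), ]
    if (nrow(g) > 1) {
      expect_true(all(g$env_start[-1] >= g$env_end[-nrow(g)]))
    }
    # every removed hit overlaps a kept hit with <= E-value
    removed <- h[!paste(h$env_start, h$evalue) %in%
                   paste(got$env_start, got$evalue), , drop = FALSE]
    for (i in seq_len(nrow(removed))) {
      overl <- pmin(got$env_end, removed$env_end[i]) -
        pmax(got$env_start, removed$env_start[i]) > 0
      expect_true(any(overl & got$evalue <= removed$evalue[i]))
    }
  }
})

test_that("gate_by_structure reflects map coverage exactly", {
  hits <- tibble::tibble(protein_id = "p",
                         profile_accession = sprintf("PF%02d", 1:20))
  map <- list(PF01 = "s1", PF03 = c("s2", "s3"), PF07 = "s4")
  gated <- gate_by_structure(hits, map)
  expect_equal(gated$structure_mapped,
               hits$profile_accession %in% names(map))
  expect_equal(sum(gated$structure_mapped), 3)
})

test_that("planted-domain recovery decays with divergence on average", {
  fam <- small_family()
  db <- profile_db(list(fam$calibrated))
  effective_db_size(db) <- 10000
  set.seed(9)
  mean_E <- vapply(c(0, 0.2, 0.4, 0.6), function(d) {
    evs <- replicate(5, {
      sq <- mutate_seq(fam$consensus, d)
      h <- search_domains(tibble::tibble(id = "m", seq = sq), db,
                          search_config(report_threshold = 1e30,
                                        significant_threshold = 1e-31,
                                        weak_threshold = 1e-30))
      h$evalue[1]
    })
    mean(log10(evs))
  }, numeric(1))
  expect_true(all(diff(mean_E) > 0))
  expect_lt(mean_E[1], -10)  # divergence 0 recovered far below 1e-04
})
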