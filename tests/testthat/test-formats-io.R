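# Readers/writers: normalization contracts, referential integrity,
# line-numbered errors, and round-trip identity on generated fixtures.

test_that("read_fasta returns records in order with normalized residues", {
  f <- tmp_file(".fasta")
  writeLines(c(">p1 first protein", "ACDE", ">p2", "GHIK"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("p1", "p2"))
  expect_equal(recs$desc, c("first protein", ""))
  expect_equal(recs$seq, c("ACDE", "GHIK"))
})

test_that("read_fasta drops a terminal stop and masks unknown letters, warning", {
  f <- tmp_file(".fasta")
  writeLines(c(">p1", "acde*"), f)
  expect_warning(recs <- read_fasta(f), "terminal stop")
  expect_equal(recs$seq, "ACDE")

  writeLines(c(">p2", "ACBZDE"), f)
  expect_warning(recs <- read_fasta(f), "normalized to X")
  expect_equal(recs$seq, "ACXXDE")
})

test_that("read_fasta rejects empty files, empty records and duplicate ids", {
  f <- tmp_file(".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "no records")
  writeLines(c(">p1", ""), f)
  expect_error(read_fasta(f), "p1")
  writeLines(c(">a", "ACDE", ">a", "GHIK"), f)
  expect_error(read_fasta(f), "duplicate")
})

test_that("FASTA write/read round-trips 50 random records", {
  set.seed(42)
  recs <- tibble::tibble(
    id = paste0("s", sprintf("%02d", 1:50), "_", replicate(50, random_id(4))),
    desc = "",
    seq = replicate(50, paste(sample(aa_alphabet(), sample(20:120, 1),
                                     replace = TRUE), collapse = "")))
  f <- tmp_file(".fasta")
  write_fasta(recs, f)
  expect_equal(read_fasta(f), recs)
})

test_that("structure map groups rows, enforces referential integrity, dedups", {
  lib <- tibble::tibble(structure_id = c("s1", "s2", "s3"),
                        fold_class = "f", length = 10L,
                        ref_seq = strrep("A", 10))
  f <- tmp_file(".tsv")
  writeLines(c("PF_A\ts1", "PF_A\ts2", "PF_B\ts3", "PF_A\ts2"), f)
  m <- read_structure_map(f, lib)
  expect_equal(m, list(PF_A = c("s1", "s2"), PF_B = "s3"))

  writeLines("PF_A\ts9", f)
  expect_error(read_structure_map(f, lib), "s9")
})

test_that("structure map round-trips a generated 200x1000 mapping", {
  set.seed(7)
  ids <- sprintf("S%04d", 1:1000)
  lib <- tibble::tibble(structure_id = ids, fold_class = "f",
                        length = 5L, ref_seq = strrep("A", 5))
  m <- lapply(setNames(seq_len(200), sprintf("PF%04d", 1:200)),
              function(i) sort(sample(ids, sample(1:6, 1))))
  f <- tmp_file(".tsv")
  write_structure_map(m, f)
  m2 <- read_structure_map(f, lib)
  expect_equal(m2[names(m)], m)
})

test_that("profile database round-trips through the native flat format", {
  fam <- small_family()
  db <- profile_db(list(fam$calibrated,
                        build_profile(c("ACDEFGHIKL", "ACDEFGHIKV"),
                                      accession = "PF9999", clan = "CL0001",
                                      db_version = "synthetic-1")))
  f <- tmp_file(".tsv")
  write_profile_db(db, f)
  db2 <- read_profile_db(f)
  expect_equal(names(db2), names(db))
  expect_equal(db2[[1]]$match_scores, db[[1]]$match_scores)
  expect_equal(db2[[1]]$calibration$lambda, db[[1]]$calibration$lambda)
  expect_equal(db2[[1]]$calibration$mu, db[[1]]$calibration$mu)
  expect_null(db2[[2]]$calibration)
  expect_equal(db2[[2]]$clan, "CL0001")
  expect_equal(db2[[2]]$length, 10L)
})

test_that("structure library reader validates manifests against the FASTA", {
  lib <- tibble::tibble(structure_id = c("s1", "s2"), fold_class = c("a", "b"),
                        length = c(4L, 6L), ref_seq = c("ACDE", "GHIKLM"))
  mf <- tmp_file(".tsv"); ff <- tmp_file(".fasta")
  write_structure_library(lib, mf, ff)
  expect_equal(read_structure_library(mf, ff), lib)

  bad <- lib; bad$length[1] <- 9L
  write_structure_library(bad, mf, ff)
  # manifest length must equal reference length
  writeLines(c("s1\ta\t9", "s2\tb\t6"), mf)
  expect_error(read_structure_library(mf, ff), "disagrees")
})

test_that("hits report writes headers, literal level tags, and round-trips", {
  f <- tmp_file(".tsv")
  write_hits_report(tibble::tibble(), f)
  lines <- readLines(f)
  expect_true(all(startsWith(lines, "#")))
  expect_true(any(grepl("1-based inclusive", lines)))
  expect_equal(nrow(read_hits_report(f)), 0)

  call <- tibble::tibble(
    protein_id = "p1", profile_accession = "PF0001",
    env_start = 9L, env_end = 40L, bit_score = 33.25, evalue = 2.5,
    p_cdf = 1e-4, p_hyper = 2e-3, p_combined = 2e-7, fold_accepted = TRUE,
    tier = "remote_validated", validation = "2-species",
    short_domain = FALSE, db_version = "synthetic-1")
  write_hits_report(call, f)
  body <- readLines(f)
  expect_true(any(grepl("\t2-species\t", body)))
  expect_true(any(grepl("\t10\t40\t", body)))  # 1-based inclusive coordinates
  expect_true(file.exists(paste0(f, ".json")))
  expect_equal(read_hits_report(f), call)
})

test_that("hits report round-trips 100 generated calls exactly", {
  set.seed(11)
  tiers <- c("significant", "confirmed_weak", "remote_validated",
             "remote_unvalidated", "rejected")
  calls <- tibble::tibble(
    protein_id = paste0("p", 1:100),
    profile_accession = sprintf("PF%04d", sample(1:30, 100, replace = TRUE)),
    env_start = as.integer(sample(0:200, 100, replace = TRUE)))
  calls$env_end <- calls$env_start + as.integer(sample(30:90, 100, TRUE))
  calls$bit_score <- rnorm(100, 50, 20)
  calls$evalue <- 10^runif(100, -30, 1.6)
  calls$p_cdf <- runif(100)
  calls$p_hyper <- runif(100)
  calls$p_combined <- calls$p_cdf * calls$p_hyper
  calls$fold_accepted <- sample(c(TRUE, FALSE, NA), 100, TRUE)
  calls$tier <- sample(tiers, 100, TRUE)
  calls$validation <- sample(c("0-species", "2-species", "no-data", "-"),
                             100, TRUE)
  calls$short_domain <- sample(c(TRUE, FALSE), 100, TRUE)
  calls$db_version <- "synthetic-1"
  f <- tmp_file(".tsv")
  write_hits_report(calls, f)
  expect_equal(read_hits_report(f), calls)
})

test_that("auxiliary tables validate and round-trip", {
  # ortholog table: duplicate (query, species) rejected with line numbers
  f <- tmp_file(".tsv")
  writeLines(c("q1\tmouse\tq1_m", "q1\tmouse\tq1_m2"), f)
  expect_error(read_ortholog_table(f), "line")
  orth <- tibble::tibble(query_id = c("q1", "q1"),
                         species = c("mouse", "dog"),
                         ortholog_id = c("q1_m", "q1_d"))
  write_ortholog_table(orth, f)
  expect_equal(read_ortholog_table(f), orth)

  # essential residues: invalid position rejected
  writeLines("PF0001\t0\tK", f)
  expect_error(read_essential_residues(f), "position")
  ess <- tibble::tibble(profile_accession = "PF0001",
                        position = c(3L, 9L), residue = c("K", "W"))
  write_essential_residues(ess, f)
  expect_equal(read_essential_residues(f), ess)

  # background z-scores
  z <- c(-1.5, 0, 2.25)
  write_background_zscores(z, f, source = "unit")
  z2 <- read_background_zscores(f)
  expect_equal(as.numeric(z2), z)
  expect_equal(attr(z2, "source"), "unit")

  # clan map
  write_clan_map(c(PF0001 = "CL1", PF0002 = "CL1"), f)
  expect_equal(read_clan_map(f), c(PF0001 = "CL1", PF0002 = "CL1"))
})

test_that("malformed rows are rejected with their line numbers", {
  f <- tmp_file(".tsv")
  writeLines(c("# header", "PF_A\ts1", "broken row"), f)
  lib <- tibble::tibble(structure_id = "s1", fold_class = "f",
                        length = 2L, ref_seq = "AC")
  expect_error(read_structure_map(f, lib), "3")
})
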