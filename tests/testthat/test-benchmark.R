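# Benchmark framework: truth-set predicate, confusion classification
# with clan exclusion, and metric parity with printed benchmark tables.

mk_hits <- function(df, version) {
  df$db_version <- version
  df
}

test_that("select_truth applies the three-way predicate", {
  old <- mk_hits(tibble::tibble(
    protein_id = c("p1", "p2", "p3"),
    profile_accession = c("A", "B", "C"),
    env_start = c(0L, 0L, 0L), env_end = c(50L, 50L, 50L),
    evalue = c(5, 0.5, 5)), "v-old")
  new <- mk_hits(tibble::tibble(
    protein_id = c("p1", "p2", "p3"),
    profile_accession = c("A", "B", "C"),
    env_start = c(5L, 5L, 5L), env_end = c(55L, 55L, 55L),
    evalue = c(0.01, 0.09, 0.6)), "v-new")
  ts <- select_truth(old, new)
  # p1: 5 -> 0.01 selected (ratio 500); p2: ratio 5.6 < 10; p3: E_new > 0.1
  expect_equal(ts$protein_id, "p1")
  expect_equal(attr(ts, "provenance"), c(old = "v-old", new = "v-new"))

  # boundary: ratio exactly 10 selected by default, excluded under strict
  old2 <- mk_hits(old[1, ], "v-old"); old2$evalue <- 0.5
  new2 <- mk_hits(new[1, ], "v-new"); new2$evalue <- 0.05
  expect_equal(nrow(select_truth(old2, new2)), 1)
  expect_equal(nrow(select_truth(old2, new2, strict = TRUE)), 0)

  expect_error(select_truth(mk_hits(old, "x"), mk_hits(new, "x")),
               "same db_version")
})

test_that("select_truth equals a brute-force filter on random E-value pairs", {
  set.seed(71)
  n <- 300
  base <- tibble::tibble(
    protein_id = paste0("p", 1:n),
    profile_accession = sprintf("PF%03d", sample(1:40, n, TRUE)),
    env_start = 0L, env_end = 60L)
  e_old <- 10^runif(n, -4, 1.7)
  e_new <- e_old / 10^runif(n, -1, 4)
  ts <- select_truth(mk_hits(dplyr::mutate(base, evalue = e_old), "old"),
                     mk_hits(dplyr::mutate(base, evalue = e_new), "new"))
  want <- base$protein_id[e_old > 0.1 & e_new < 0.1 & e_old / e_new >= 10]
  expect_setequal(ts$protein_id, want)
})

test_that("classification follows the four formulas with clan exclusion", {
  truth <- tibble::tibble(protein_id = "p1", profile_accession = "A",
                          env_start = 10L, env_end = 60L)
  cands <- tibble::tibble(
    protein_id = c("p1", "p1", "p1", "p1", "p2"),
    profile_accession = c("A", "A2", "B", "C", "D"),
    env_start = c(10L, 12L, 15L, 20L, 0L),
    env_end = c(60L, 58L, 62L, 55L, 50L),
    p_value = c(5e-4, 1e-5, 1e-4, 0.5, 0.9))
  clans <- c(A = "CL1", A2 = "CL1", B = "CL2")
  ct <- classify_candidates(cands, truth, clans)
  # A: truth member accepted -> TP; A2: clan-mate of truth -> excluded
  # B: accepted non-member -> FP; C: non-member not accepted -> TN
  # p2/D: no truth overlap, not accepted -> TN
  expect_equal(tidy(ct)$n, c(1L, 0L, 1L, 2L, 1L))
  expect_equal(ct$calls$class, c("TP", "excluded", "FP", "TN", "TN"))

  # truth member with p = 0.01 -> FN
  cands2 <- cands[1, ]; cands2$p_value <- 0.01
  expect_equal(classify_candidates(cands2, truth, clans)$calls$class, "FN")

  # presence/absence substitutes for engines without a p-value
  cands3 <- dplyr::mutate(cands[c(1, 4), ], detected = c(TRUE, FALSE),
                          p_value = NULL)
  ct3 <- classify_candidates(cands3, truth, clans)
  expect_equal(ct3$calls$class, c("TP", "TN"))
})

test_that("classification is invariant to candidate ordering", {
  set.seed(72)
  truth <- tibble::tibble(protein_id = paste0("p", 1:5),
                          profile_accession = "A",
                          env_start = 0L, env_end = 50L)
  cands <- tibble::tibble(
    protein_id = sample(paste0("p", 1:8), 40, TRUE),
    profile_accession = sample(c("A", "B"), 40, TRUE),
    env_start = 0L, env_end = 50L,
    p_value = 10^runif(40, -6, 0))
  a <- classify_candidates(cands, truth)
  b <- classify_candidates(cands[sample(40), ], truth)
  expect_equal(tidy(a), tidy(b))
})

test_that("metrics reproduce printed benchmark percentages after rounding", {
  # published comparison table, four methods (counts are inputs)
  new_hmt <- confusion_table(tp = 217, fn = 47, fp = 76, tn = 845)
  m <- confusion_metrics(new_hmt)
  expect_equal(m$percent[m$metric == "precision"], 74)
  expect_equal(m$percent[m$metric == "recall"], 82)
  expect_equal(m$percent[m$metric == "accuracy"], 90)
  expect_equal(m$percent[m$metric == "fpr"], 8)
  expect_equal(m$percent[m$metric == "fnr"], 18)

  old_hmt <- confusion_metrics(confusion_table(186, 197, 53, 781))
  expect_equal(old_hmt$percent[old_hmt$metric == "precision"], 78)
  expect_equal(old_hmt$percent[old_hmt$metric == "recall"], 49)
  expect_equal(old_hmt$percent[old_hmt$metric == "accuracy"], 79)
  expect_equal(old_hmt$percent[old_hmt$metric == "fnr"], 51)
  expect_equal(old_hmt$percent[old_hmt$metric == "fpr"], 6)

  gth <- confusion_metrics(confusion_table(121, 256, 5, 773))
  expect_equal(gth$percent[gth$metric == "precision"], 96)
  expect_equal(gth$percent[gth$metric == "recall"], 32)
  expect_equal(gth$percent[gth$metric == "accuracy"], 77)
  expect_equal(gth$percent[gth$metric == "fnr"], 68)

  sf <- confusion_metrics(confusion_table(271, 91, 29, 565))
  expect_equal(sf$percent[sf$metric == "precision"], 90)
  expect_equal(sf$percent[sf$metric == "recall"], 75)
  expect_equal(sf$percent[sf$metric == "accuracy"], 87)
  expect_equal(sf$percent[sf$metric == "fnr"], 25)
  expect_equal(sf$percent[sf$metric == "fpr"], 5)
})

test_that("degenerate denominators report undefined metrics, not zero", {
  m <- confusion_metrics(confusion_table(0, 0, 0, 10))
  expect_true(is.na(m$value[m$metric == "precision"]))
  expect_true(is.na(m$value[m$metric == "recall"]))
  expect_equal(m$percent[m$metric == "accuracy"], 100)
})

test_that("glance/tidy/autoplot cover the confusion table surface", {
  ct <- confusion_table(10, 2, 3, 85)
  g <- glance(ct)
  expect_equal(g$tp, 10L)
  expect_equal(g$precision, round(10 / 13 * 100))
  p <- autoplot(ct)
  expect_s3_class(p, "ggplot")
})
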