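# Cross-species ortholog validation and essential-residue validation for
# weak hits (E >= 0.1).

#' Re-detect and re-score a weak domain in one ortholog
#'
#' The ortholog sequence is searched for the same profile at the relaxed
#' ortholog ceiling (default E <= 100). "Same domain" means the same
#' profile accession with an envelope overlapping the query's mapped
#' region by at least one residue (when `region` is supplied). When found,
#' the ortholog region is pre-processed, threaded and scored with the
#' identical fold-recognition procedure used for the query.
#'
#' @param ortholog One-row sequence tibble (`id`, `seq`).
#' @param profile The query hit's `domain_profile` (calibrated).
#' @param library,map,cdf Fold-recognition resources (structure library,
#'   accession-to-structure map, background CDF).
#' @param cfg A [search_config()].
#' @param region Optional 0-based half-open interval `c(start, end)` in
#'   ortholog coordinates that the re-detected envelope must overlap.
#' @param backend Threading backend.
#' @param db_size Effective profile-database size for the ortholog
#'   E-value (default 10,000, full domain-database scale, so the E <= 100
#'   rule keeps its published stringency; see [effective_db_size()]).
#' @return One-row tibble: `found_domain`, `fold_accepted`, `evalue`.
#' @export
validate_in_ortholog <- function(ortholog, profile, library, map, cdf,
                                 cfg = search_config(), region = NULL,
                                 backend = surrogate_backend(),
                                 db_size = 10000) {
  stopifnot(is.data.frame(ortholog), nrow(ortholog) == 1)
  ortho_cfg <- cfg
  ortho_cfg$report_threshold <- cfg$ortholog_threshold
  single <- profile_db(list(profile))
  effective_db_size(single) <- db_size
  hits <- search_domains(ortholog, single, cfg = ortho_cfg)
  hits <- filter(hits, .data$evalue <= cfg$ortholog_threshold)
  if (!is.null(region) && nrow(hits) > 0) {
    keep <- pmin(hits$env_end, region[2]) - pmax(hits$env_start, region[1]) > 0
    hits <- hits[keep, , drop = FALSE]
  }
  if (nrow(hits) == 0) {
    return(tibble(found_domain = FALSE, fold_accepted = FALSE,
                  evalue = NA_real_))
  }
  hit <- hits[1, , drop = FALSE]  # best E-value
  expected <- map[[profile$accession]]
  if (is.null(expected) || length(expected) == 0) {
    return(tibble(found_domain = TRUE, fold_accepted = FALSE,
                  evalue = hit$evalue))
  }
  mseq <- preprocess(ortholog)
  region_rec <- extract_domain_region(mseq, hit)
  tr <- thread(list(id = region_rec$id[1], seq = region_rec$seq[1]),
               library, backend)
  fs <- score_threading(tr, expected, cdf,
                        window = top_window(nrow(library),
                                            cfg$window_fraction,
                                            cfg$window_floor),
                        alpha = cfg$alpha, method = cfg$combine_method)
  tibble(found_domain = TRUE, fold_accepted = fs$accepted,
         evalue = hit$evalue)
}

#' Validation level from per-species outcomes
#'
#' The level is the number of species in which the same domain was both
#' re-detected and accepted by fold recognition (0-3). Callers treat
#' level >= 2 as validated by default, the published operating point. An
#' empty per-species table yields level 0 with the `"no-data"` tag
#' (no validation data available).
#'
#' @param per_species Tibble with logical columns `found_domain` and
#'   `fold_accepted` (one row per species, at most 3).
#' @return List with `level` (integer) and `tag` (e.g. `"2-species"`,
#'   `"no-data"`).
#' @export
assign_level <- function(per_species) {
  if (is.null(per_species) || nrow(per_species) == 0) {
    return(list(level = 0L, tag = "no-data"))
  }
  if (nrow(per_species) > 3) abort("at most 3 validation species")
  lvl <- sum(per_species$found_domain & per_species$fold_accepted)
  list(level = as.integer(lvl), tag = paste0(lvl, "-species"))
}

#' Classify essential residues of a hit
#'
#' Each flagged consensus position of the profile is compared with the
#' query residue aligned to it: identity if equal, similarity if the
#' BLOSUM62 score of the pair is positive, otherwise null; consensus
#' positions not aligned to any query residue count as null. The hit
#' passes when `(identity + similarity) / evaluated >= threshold`
#' (default 25%). Profiles without annotation are reported not evaluable
#' (distinct from failing).
#'
#' @param alignment Tibble `(ppos, qpos)` of 1-based matched positions
#'   (profile consensus position, query position), as stored in the hits
#'   table.
#' @param query_seq Full query protein sequence.
#' @param essentials Tibble `(position, residue)` of flagged consensus
#'   positions for this profile, or `NULL`/empty when not annotated.
#' @param threshold Pass threshold on the identity+similarity fraction.
#' @return One-row tibble: `n_identity`, `n_similarity`, `n_null`,
#'   `n_evaluated`, `pass`, `evaluable`.
#' @export
classify_residues <- function(alignment, query_seq, essentials,
                              threshold = 0.25) {
  if (is.null(essentials) || nrow(essentials) == 0) {
    return(tibble(n_identity = NA_integer_, n_similarity = NA_integer_,
                  n_null = NA_integer_, n_evaluated = 0L,
                  pass = NA, evaluable = FALSE))
  }
  b62 <- blosum62()
  qchars <- strsplit(query_seq, "", fixed = TRUE)[[1]]
  ident <- 0L; simil <- 0L; nul <- 0L
  for (i in seq_len(nrow(essentials))) {
    p <- essentials$position[i]
    expected <- essentials$residue[i]
    j <- alignment$qpos[match(p, alignment$ppos)]
    if (is.na(j)) { nul <- nul + 1L; next }
    r <- qchars[j]
    if (!r %in% rownames(b62) || !expected %in% rownames(b62)) {
      nul <- nul + 1L
    } else if (r == expected) {
      ident <- ident + 1L
    } else if (b62[r, expected] > 0) {
      simil <- simil + 1L
    } else {
      nul <- nul + 1L
    }
  }
  n_eval <- ident + simil + nul
  tibble(n_identity = ident, n_similarity = simil, n_null = nul,
         n_evaluated = n_eval,
         pass = (ident + simil) / n_eval >= threshold,
         evaluable = TRUE)
}
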