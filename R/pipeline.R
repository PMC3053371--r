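# End-to-end orchestration per protein and per proteome: relaxed domain
# search -> structure gating -> pre-processing -> threading -> combined
# fold score -> (for weak hits) cross-species and essential-residue
# validation, with the tier decision table.

#' Bundle the resources a pipeline run needs
#'
#' @param profiles Calibrated `profile_db`.
#' @param library Structure library tibble.
#' @param map Accession-to-structure map (named list).
#' @param cdf `empirical_cdf` background (required whenever any hit needs
#'   threading).
#' @param orthologs Optional ortholog table (`query_id`, `species`,
#'   `ortholog_id`).
#' @param ortholog_seqs Optional sequence tibble holding the ortholog
#'   sequences named in `orthologs`.
#' @param essentials Optional essential-residue tibble
#'   (`profile_accession`, `position`, `residue`).
#' @param secondary Optional secondary-structure tibble (pass-through
#'   hook; the surrogate backend ignores it).
#' @param backend Threading backend, default [surrogate_backend()].
#' @return A `pipeline_resources` list.
#' @export
pipeline_resources <- function(profiles, library, map, cdf = NULL,
                               orthologs = NULL, ortholog_seqs = NULL,
                               essentials = NULL, secondary = NULL,
                               backend = surrogate_backend()) {
  structure(list(profiles = profiles, library = library, map = map,
                 cdf = cdf, orthologs = orthologs,
                 ortholog_seqs = ortholog_seqs, essentials = essentials,
                 secondary = secondary, backend = backend),
            class = "pipeline_resources")
}

#' Assign the decision tier of a call
#'
#' Implements the pipeline's branch structure as a total decision table:
#' \itemize{
#'   \item E below the significance threshold: `significant` (accepted
#'     without fold recognition).
#'   \item otherwise, no mapped structure or fold rejected: `rejected`.
#'   \item fold accepted and E below the weak threshold: `confirmed_weak`.
#'   \item fold accepted and E at/above the weak threshold:
#'     `remote_validated` when the validation level reaches
#'     `required_level`, else `remote_unvalidated`.
#' }
#'
#' @param evalue E-value(s).
#' @param structure_mapped Logical: profile has >= 1 mapped structure.
#' @param fold_accepted Logical: combined fold score accepted (`NA`
#'   allowed when not applicable).
#' @param validation_level Integer 0-3 (`NA` when not applicable).
#' @param cfg A [search_config()].
#' @return Character vector of tiers.
#' @export
assign_tier <- function(evalue, structure_mapped, fold_accepted,
                        validation_level, cfg = search_config()) {
  n <- length(evalue)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (evalue[i] < cfg$significant_threshold) {
      "significant"
    } else if (!isTRUE(structure_mapped[i]) || !isTRUE(fold_accepted[i])) {
      "rejected"
    } else if (evalue[i] < cfg$weak_threshold) {
      "confirmed_weak"
    } else if (!is.na(validation_level[i]) &&
               validation_level[i] >= cfg$required_level) {
      "remote_validated"
    } else {
      "remote_unvalidated"
    }
  }
  out
}

empty_calls <- function() {
  tibble(protein_id = character(0), profile_accession = character(0),
         env_start = integer(0), env_end = integer(0),
         bit_score = numeric(0), evalue = numeric(0),
         db_version = character(0), structure_mapped = logical(0),
         p_cdf = numeric(0), p_hyper = numeric(0), p_combined = numeric(0),
         fold_accepted = logical(0), k = integer(0), m = integer(0),
         n_window = integer(0), lib_size = integer(0),
         validation_level = integer(0), validation = character(0),
         n_identity = integer(0), n_similarity = integer(0),
         n_null = integer(0), residue_pass = logical(0),
         residue_evaluable = logical(0),
         tier = character(0), short_domain = logical(0))
}

#' Run the pipeline on one protein
#'
#' @param seq One-row sequence tibble (`id`, `seq`).
#' @param resources A [pipeline_resources()].
#' @param cfg A [search_config()].
#' @return A calls tibble, one row per (kept) domain hit, with fold-score
#'   fields, validation fields, the decision `tier` and the short-domain
#'   flag (profile shorter than 50 match positions).
#' @export
run_protein <- function(seq, resources, cfg = search_config()) {
  stopifnot(is.data.frame(seq), nrow(seq) == 1,
            inherits(resources, "pipeline_resources"))
  hits <- search_domains(seq, resources$profiles, cfg)
  if (cfg$overlap_mode == "top_hit_only") {
    hits <- resolve_overlaps(hits, cfg$max_shared_overlap)
    hits <- arrange(hits, .data$evalue, .data$profile_accession,
                    .data$env_start)
  }
  if (nrow(hits) == 0) return(empty_calls())
  hits <- gate_by_structure(hits, resources$map)
  needs_threading <- hits$evalue >= cfg$significant_threshold |
    cfg$thread_significant
  if (any(needs_threading & hits$structure_mapped) &&
      is.null(resources$cdf)) {
    abort("threading required but no background CDF supplied")
  }
  mseq <- NULL  # pre-process lazily, once per protein
  rows <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, , drop = FALSE]
    prof <- resources$profiles[[h$profile_accession]]
    fold <- list(p_cdf = NA_real_, p_hyper = NA_real_,
                 p_combined = NA_real_, accepted = NA,
                 params = list(N = NA_integer_, n = NA_integer_,
                               m = NA_integer_, k = NA_integer_))
    val_level <- NA_integer_
    val_tag <- "-"
    res_cls <- tibble(n_identity = NA_integer_, n_similarity = NA_integer_,
                      n_null = NA_integer_, n_evaluated = 0L,
                      pass = NA, evaluable = NA)
    if (needs_threading[i] && h$structure_mapped) {
      if (is.null(mseq)) {
        mseq <- preprocess(seq, secondary = resources$secondary)
      }
      region <- extract_domain_region(mseq, h)
      tr <- thread(list(id = region$id[1], seq = region$seq[1]),
                   resources$library, resources$backend)
      fs <- score_threading(tr, resources$map[[h$profile_accession]],
                            resources$cdf,
                            window = top_window(nrow(resources$library),
                                                cfg$window_fraction,
                                                cfg$window_floor),
                            alpha = cfg$alpha, method = cfg$combine_method)
      fold <- fs
      if (fs$accepted && h$evalue >= cfg$weak_threshold) {
        # cross-species validation + essential residues for weak hits
        per_species <- validate_hit_orthologs(h, prof, resources, cfg)
        lv <- assign_level(per_species)
        val_level <- lv$level
        val_tag <- lv$tag
        ess <- essentials_for(resources$essentials, h$profile_accession)
        res_cls <- classify_residues(h$alignment[[1]], seq$seq[1], ess)
      }
    }
    tier <- assign_tier(h$evalue, h$structure_mapped,
                        if (needs_threading[i]) isTRUE(fold$accepted) else NA,
                        val_level, cfg)
    rows[[i]] <- tibble(
      protein_id = h$protein_id, profile_accession = h$profile_accession,
      env_start = h$env_start, env_end = h$env_end,
      bit_score = h$bit_score, evalue = h$evalue,
      db_version = h$db_version, structure_mapped = h$structure_mapped,
      p_cdf = fold$p_cdf, p_hyper = fold$p_hyper,
      p_combined = fold$p_combined,
      fold_accepted = if (is.na(fold$p_combined)) NA else fold$accepted,
      k = fold$params$k, m = fold$params$m, n_window = fold$params$n,
      lib_size = fold$params$N,
      validation_level = val_level, validation = val_tag,
      n_identity = res_cls$n_identity, n_similarity = res_cls$n_similarity,
      n_null = res_cls$n_null, residue_pass = res_cls$pass,
      residue_evaluable = res_cls$evaluable,
      tier = tier,
      short_domain = prof$length < cfg$short_domain_length)
  }
  bind_rows(rows)
}

validate_hit_orthologs <- function(h, prof, resources, cfg) {
  orth <- resources$orthologs
  if (is.null(orth) || is.null(resources$ortholog_seqs)) return(NULL)
  mine <- orth[orth$query_id == h$protein_id, , drop = FALSE]
  if (nrow(mine) == 0) return(NULL)
  mine <- head(mine[order(mine$species), , drop = FALSE], 3)
  out <- lapply(seq_len(nrow(mine)), function(j) {
    oseq <- resources$ortholog_seqs[
      resources$ortholog_seqs$id == mine$ortholog_id[j], , drop = FALSE]
    if (nrow(oseq) == 0) return(NULL)
    res <- validate_in_ortholog(oseq[1, ], prof, resources$library,
                                resources$map, resources$cdf, cfg,
                                region = c(h$env_start, h$env_end),
                                backend = resources$backend,
                                db_size = effective_db_size(resources$profiles))
    mutate(res, species = mine$species[j])
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) NULL else out
}

essentials_for <- function(essentials, accession) {
  if (is.null(essentials)) return(NULL)
  ess <- essentials[essentials$profile_accession == accession, , drop = FALSE]
  if (nrow(ess) == 0) return(NULL)
  select(ess, "position", "residue")
}

#' Run the pipeline over a proteome
#'
#' @param seqs Sequence tibble (or path to a FASTA file).
#' @param resources A [pipeline_resources()].
#' @param cfg A [search_config()].
#' @param out_dir Optional directory; when given, the per-call report
#'   (`hits.tsv` + JSON twin) and summary (`summary.tsv`) are written.
#' @param continue_on_error Keep going when a protein fails, collecting
#'   the error messages (default `TRUE`).
#' @return List with `calls` (all per-protein calls), `summary` (one-row
#'   count table: total proteins, calls per tier, weak-call validation
#'   levels), and `errors` (named character vector, possibly empty).
#' @export
run_proteome <- function(seqs, resources, cfg = search_config(),
                         out_dir = NULL, continue_on_error = TRUE) {
  if (is.character(seqs)) seqs <- read_fasta(seqs)
  calls <- list()
  errors <- character(0)
  for (i in seq_len(nrow(seqs))) {
    res <- tryCatch(run_protein(seqs[i, ], resources, cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (!continue_on_error) {
        abort(paste0("protein ", seqs$id[i], ": ", conditionMessage(res)))
      }
      errors[seqs$id[i]] <- conditionMessage(res)
    } else {
      calls[[length(calls) + 1]] <- res
    }
  }
  calls <- if (length(calls) > 0) bind_rows(calls) else empty_calls()
  weak <- calls[!is.na(calls$evalue) &
                  calls$evalue >= cfg$weak_threshold &
                  calls$tier %in% c("remote_validated", "remote_unvalidated"), ,
                drop = FALSE]
  summary <- tibble(
    total_proteins = nrow(seqs),
    total_calls = nrow(calls),
    significant = sum(calls$tier == "significant"),
    confirmed_weak = sum(calls$tier == "confirmed_weak"),
    remote_calls = nrow(weak),
    validated_1 = sum(!is.na(weak$validation_level) &
                        weak$validation_level >= 1),
    validated_2 = sum(!is.na(weak$validation_level) &
                        weak$validation_level >= 2),
    validated_3 = sum(!is.na(weak$validation_level) &
                        weak$validation_level >= 3),
    rejected = sum(calls$tier == "rejected"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hits_report(calls, file.path(out_dir, "hits.tsv"))
    readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))
  }
  list(calls = calls, summary = summary, errors = errors)
}
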