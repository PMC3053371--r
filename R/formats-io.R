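# Readers and writers for every external artifact the pipeline touches.
# Conventions (stated in every written header): intervals are 0-based
# half-open internally and 1-based inclusive in written reports; all
# tables are tab-separated; '#' lines are comments.

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order as a tibble with one row per
#' sequence. Residues are uppercased, a single terminal stop (`*`) is
#' dropped, and any remaining non-standard letter (B, Z, U, O, J, `*`,
#' `-`, `.` or other unknowns) is normalized to the mask token `X` with a
#' warning naming the affected records.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(paste0("no records in ", path,
                                                   " (", conditionMessage(e), ")")))
  if (length(set) == 0) abort(paste0("no records in ", path))
  nm <- names(set)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  if (anyDuplicated(id)) {
    abort(paste0("duplicate sequence ids: ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  stops <- grepl("\\*$", seqs)
  if (any(stops)) {
    warn(paste0("terminal stop dropped in: ",
                paste(id[stops], collapse = ", ")))
    seqs <- sub("\\*$", "", seqs)
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0("empty sequence for record(s): ",
                 paste(id[empty], collapse = ", ")))
  }
  bad <- grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "X]"), seqs)
  if (any(bad)) {
    warn(paste0("non-standard residues normalized to X in: ",
                paste(id[bad], collapse = ", ")))
    seqs[bad] <- vapply(seqs[bad], function(s) {
      gsub(paste0("[^", paste(aa_alphabet(), collapse = ""), "X]"), "X", s)
    }, character(1))
  }
  tibble(id = unname(id), desc = unname(desc), seq = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Tibble with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  desc <- if ("desc" %in% names(seqs)) seqs$desc else rep("", nrow(seqs))
  nm <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  set <- Biostrings::BStringSet(setNames(seqs$seq, nm))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---- generic strict TSV helpers ------------------------------------------

read_tsv_strict <- function(path, n_cols, col_names, what) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0) abort(paste0("no records in ", path))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- keep[lengths(parts) != n_cols]
  if (length(bad) > 0) {
    abort(paste0("malformed ", what, " rows (expected ", n_cols,
                 " tab-separated fields) at line(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  out <- as_tibble(setNames(
    lapply(seq_len(n_cols), function(i) vapply(parts, `[[`, character(1), i)),
    col_names))
  out$.line <- keep
  out
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

# ---- profile database -----------------------------------------------------

#' Write a profile database to the native flat format
#'
#' The native on-disk format is a documented tab/flat text dialect: a
#' header comment, then per profile one `>` line
#' (`accession name clan length db_version lambda mu`, `-` for absent
#' clan/calibration) followed by `length` lines of 20 tab-separated
#' per-residue log-odds scores (bits) in [aa_alphabet()] column order.
#'
#' @param db A profile database (list of profiles, see [build_profile()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_db <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# remotethread profile-db v1",
               "# columns after '>': accession name clan length db_version lambda mu",
               "# score rows: 20 tab-separated bits in ACDEFGHIKLMNPQRSTVWY order"),
             con)
  for (p in db) {
    cal <- p$calibration
    writeLines(paste(">", paste(p$accession, p$name,
                                p$clan %||% "-", p$length,
                                p$db_version,
                                if (is.null(cal)) "-" else fmt_num(cal$lambda),
                                if (is.null(cal)) "-" else fmt_num(cal$mu),
                                sep = "\t"), sep = ""), con)
    writeLines(apply(p$match_scores, 1,
                     function(r) paste(fmt_num(r), collapse = "\t")), con)
  }
  invisible(path)
}

#' Read a profile database from the native flat format
#'
#' @param path Path written by [write_profile_db()].
#' @return A `profile_db` (named list of `domain_profile` objects).
#' @export
read_profile_db <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  idx <- which(startsWith(lines, ">"))
  if (length(idx) == 0) abort(paste0("no profiles in ", path))
  profiles <- list()
  for (h in seq_along(idx)) {
    i <- idx[h]
    f <- strsplit(sub("^>", "", lines[i]), "\t", fixed = TRUE)[[1]]
    if (length(f) != 7) {
      abort(paste0("malformed profile header at line ", i))
    }
    len <- as.integer(f[4])
    rows <- lines[(i + 1):(i + len)]
    mat <- do.call(rbind, lapply(seq_along(rows), function(r) {
      v <- suppressWarnings(as.numeric(strsplit(rows[r], "\t", fixed = TRUE)[[1]]))
      if (length(v) != 20 || anyNA(v)) {
        abort(paste0("malformed score row at line ", i + r))
      }
      v
    }))
    colnames(mat) <- aa_alphabet()
    cal <- if (f[6] == "-") NULL else list(lambda = as.numeric(f[6]),
                                           mu = as.numeric(f[7]))
    profiles[[f[1]]] <- new_domain_profile(
      accession = f[1], name = f[2],
      clan = if (f[3] == "-") NULL else f[3],
      match_scores = mat, db_version = f[5], calibration = cal)
  }
  new_profile_db(profiles)
}

# ---- structure library ----------------------------------------------------

#' Write a structure library (manifest + reference FASTA)
#'
#' @param library Tibble with columns `structure_id`, `fold_class`,
#'   `length`, `ref_seq`.
#' @param manifest_path Output TSV manifest path.
#' @param fasta_path Output FASTA path for reference sequences.
#' @return `manifest_path`, invisibly.
#' @export
write_structure_library <- function(library, manifest_path, fasta_path) {
  con <- file(manifest_path, "w")
  writeLines(c("# remotethread structure-library v1",
               "# columns: structure_id fold_class length"), con)
  writeLines(paste(library$structure_id, library$fold_class, library$length,
                   sep = "\t"), con)
  close(con)
  write_fasta(tibble(id = library$structure_id, seq = library$ref_seq),
              fasta_path)
  invisible(manifest_path)
}

#' Read a structure library (manifest + reference FASTA)
#'
#' @param manifest_path TSV with columns `structure_id`, `fold_class`,
#'   `length`.
#' @param fasta_path FASTA of reference sequences keyed by `structure_id`.
#' @return Tibble with columns `structure_id`, `fold_class`, `length`,
#'   `ref_seq`, sorted by `structure_id`.
#' @export
read_structure_library <- function(manifest_path, fasta_path) {
  tab <- read_tsv_strict(manifest_path, 3,
                         c("structure_id", "fold_class", "length"),
                         "structure library")
  if (anyDuplicated(tab$structure_id)) {
    abort(paste0("duplicate structure_id at line(s): ",
                 paste(tab$.line[duplicated(tab$structure_id)], collapse = ", ")))
  }
  seqs <- read_fasta(fasta_path)
  missing <- setdiff(tab$structure_id, seqs$id)
  if (length(missing) > 0) {
    abort(paste0("reference sequence missing for: ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble(structure_id = tab$structure_id,
                fold_class = tab$fold_class,
                length = as.integer(tab$length),
                ref_seq = seqs$seq[match(tab$structure_id, seqs$id)])
  bad <- which(out$length != nchar(out$ref_seq))
  if (length(bad) > 0) {
    abort(paste0("manifest length disagrees with reference sequence at line(s): ",
                 paste(tab$.line[bad], collapse = ", ")))
  }
  arrange(out, .data$structure_id)
}

# ---- structure map --------------------------------------------------------

#' Read a profile-to-structure map
#'
#' Tab-separated rows `(profile_accession, structure_id)` are grouped into
#' one structure-id set per accession (the PDBMAP-style lookup consulted
#' before threading). Rows naming structures absent from the library are
#' rejected with their line numbers; duplicate pairs are deduplicated
#' silently.
#'
#' @param path TSV path.
#' @param library Structure library tibble (see [read_structure_library()]).
#' @return Named list: accession -> character vector of structure ids.
#' @export
read_structure_map <- function(path, library) {
  tab <- read_tsv_strict(path, 2, c("profile_accession", "structure_id"),
                         "structure map")
  unknown <- !(tab$structure_id %in% library$structure_id)
  if (any(unknown)) {
    abort(paste0("structure map references unknown structure(s) ",
                 paste(unique(tab$structure_id[unknown]), collapse = ", "),
                 " at line(s): ", paste(tab$.line[unknown], collapse = ", ")))
  }
  tab <- distinct(tab, .data$profile_accession, .data$structure_id)
  split(tab$structure_id, tab$profile_accession)
}

#' Write a profile-to-structure map
#'
#' @param map Named list: accession -> character vector of structure ids.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_structure_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# remotethread structure-map v1",
               "# columns: profile_accession structure_id"), con)
  for (acc in names(map)) {
    writeLines(paste(acc, map[[acc]], sep = "\t"), con)
  }
  invisible(path)
}

#' Read a clan map
#'
#' @param path TSV with columns `(profile_accession, clan)`. Accessions
#'   absent from the file simply have no clan.
#' @return Named character vector: accession -> clan id.
#' @export
read_clan_map <- function(path) {
  tab <- read_tsv_strict(path, 2, c("profile_accession", "clan"), "clan map")
  setNames(tab$clan, tab$profile_accession)
}

#' Write a clan map
#' @param clans Named character vector: accession -> clan id.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clan_map <- function(clans, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# remotethread clan-map v1",
               "# columns: profile_accession clan"), con)
  writeLines(paste(names(clans), clans, sep = "\t"), con)
  invisible(path)
}

#' Read an ortholog table
#'
#' Ortholog relationships are consumed, never inferred: each row maps a
#' query protein to its ortholog's FASTA id in one validation species (at
#' most three species per query).
#'
#' @param path TSV with columns `(query_protein_id, species_tag,
#'   ortholog_fasta_id)`.
#' @return Tibble with columns `query_id`, `species`, `ortholog_id`.
#' @export
read_ortholog_table <- function(path) {
  tab <- read_tsv_strict(path, 3, c("query_id", "species", "ortholog_id"),
                         "ortholog table")
  dup <- duplicated(tab[, c("query_id", "species")])
  if (any(dup)) {
    abort(paste0("duplicate (query, species) pairs at line(s): ",
                 paste(tab$.line[dup], collapse = ", ")))
  }
  select(tab, -".line")
}

#' Write an ortholog table
#' @param orthologs Tibble with columns `query_id`, `species`, `ortholog_id`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(orthologs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# remotethread ortholog-table v1",
               "# columns: query_protein_id species_tag ortholog_fasta_id"), con)
  writeLines(paste(orthologs$query_id, orthologs$species,
                   orthologs$ortholog_id, sep = "\t"), con)
  invisible(path)
}

#' Read essential-residue annotations
#'
#' @param path TSV with columns `(profile_accession, consensus_position,
#'   expected_residue)`; positions are 1-based on the profile consensus.
#' @return Tibble with columns `profile_accession`, `position`, `residue`.
#' @export
read_essential_residues <- function(path) {
  tab <- read_tsv_strict(path, 3,
                         c("profile_accession", "position", "residue"),
                         "essential residues")
  pos <- suppressWarnings(as.integer(tab$position))
  bad <- which(is.na(pos) | pos < 1)
  if (length(bad) > 0) {
    abort(paste0("invalid consensus position at line(s): ",
                 paste(tab$.line[bad], collapse = ", ")))
  }
  tibble(profile_accession = tab$profile_accession,
         position = pos, residue = tab$residue)
}

#' Write essential-residue annotations
#' @param essentials Tibble with columns `profile_accession`, `position`,
#'   `residue`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_essential_residues <- function(essentials, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# remotethread essential-residues v1",
               "# columns: profile_accession consensus_position expected_residue"),
             con)
  writeLines(paste(essentials$profile_accession, essentials$position,
                   essentials$residue, sep = "\t"), con)
  invisible(path)
}

#' Read a background Z-score sample
#'
#' @param path File with `# source:` and `# count:` header comments and one
#'   Z-score per line.
#' @return Numeric vector with attribute `source`.
#' @export
read_background_zscores <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  src <- sub("^#\\s*source:\\s*", "", hdr[grepl("^#\\s*source:", hdr)])
  vals <- lines[nzchar(lines) & !startsWith(lines, "#")]
  z <- suppressWarnings(as.numeric(vals))
  if (anyNA(z)) {
    abort(paste0("non-numeric Z-score at line(s): ",
                 paste(which(lines %in% vals[is.na(z)])[1:min(5, sum(is.na(z)))],
                       collapse = ", ")))
  }
  attr(z, "source") <- if (length(src) > 0) src[1] else "unknown"
  z
}

#' Write a background Z-score sample
#' @param z Numeric vector of background Z-scores.
#' @param path Output path.
#' @param source Free-text provenance tag stored in the header.
#' @return `path`, invisibly.
#' @export
write_background_zscores <- function(z, path, source = "synthetic") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# source: ", source),
               paste0("# count: ", length(z))), con)
  writeLines(fmt_num(z), con)
  invisible(path)
}

# ---- hits report ----------------------------------------------------------

.report_cols <- c("protein_id", "profile_accession", "start", "end",
                  "bit_score", "evalue", "p_cdf", "p_hyper", "p_combined",
                  "fold_accepted", "tier", "validation", "short_domain",
                  "db_version")

#' Write a scored-calls report
#'
#' Emits one tab-separated row per call plus a commented header stating
#' column semantics and the 1-based inclusive coordinate convention, and a
#' machine-readable JSON twin (`<path>.json`) with identical content.
#' Validation levels are written as literal tags (`"2-species"`; `"no-data"`
#' when no ortholog was available, `"-"` when validation was not required).
#'
#' @param calls Calls tibble as produced by [run_protein()] (internal
#'   0-based half-open `env_start`/`env_end`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_report <- function(calls, path) {
  g <- function(nm, default) calls[[nm]] %||% default
  tab <- tibble(
    protein_id = as.character(g("protein_id", character(0))),
    profile_accession = as.character(g("profile_accession", character(0))),
    start = if (nrow(calls)) calls$env_start + 1L else integer(0),
    end = if (nrow(calls)) as.integer(calls$env_end) else integer(0),
    bit_score = as.numeric(g("bit_score", numeric(0))),
    evalue = as.numeric(g("evalue", numeric(0))),
    p_cdf = as.numeric(g("p_cdf", numeric(0))),
    p_hyper = as.numeric(g("p_hyper", numeric(0))),
    p_combined = as.numeric(g("p_combined", numeric(0))),
    fold_accepted = as.logical(g("fold_accepted", logical(0))),
    tier = as.character(g("tier", character(0))),
    validation = as.character(g("validation", character(0))),
    short_domain = as.logical(g("short_domain", logical(0))),
    db_version = as.character(g("db_version", character(0))))
  con <- file(path, "w")
  writeLines(c(
    "# remotethread hits-report v1",
    "# coordinates: 1-based inclusive (start, end)",
    paste0("# columns: ", paste(.report_cols, collapse = "\t")),
    "# validation: '<k>-species' tag, 'no-data' (no ortholog available), '-' (not required)"),
    con)
  if (nrow(tab) > 0) {
    num <- c("bit_score", "evalue", "p_cdf", "p_hyper", "p_combined")
    body <- do.call(paste, c(lapply(names(tab), function(cn) {
      v <- tab[[cn]]
      if (cn %in% num) fmt_num(v) else ifelse(is.na(v), "NA", as.character(v))
    }), sep = "\t"))
    writeLines(body, con)
  }
  close(con)
  jsonlite::write_json(tab, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a scored-calls report back into the internal representation
#'
#' @param path TSV written by [write_hits_report()].
#' @return Calls tibble with internal 0-based half-open coordinates.
#' @export
read_hits_report <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0) {
    return(tibble(protein_id = character(0), profile_accession = character(0),
                  env_start = integer(0), env_end = integer(0),
                  bit_score = numeric(0), evalue = numeric(0),
                  p_cdf = numeric(0), p_hyper = numeric(0),
                  p_combined = numeric(0), fold_accepted = logical(0),
                  tier = character(0), validation = character(0),
                  short_domain = logical(0), db_version = character(0)))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- keep[lengths(parts) != length(.report_cols)]
  if (length(bad) > 0) {
    abort(paste0("malformed report rows at line(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  g <- function(i) vapply(parts, `[[`, character(1), i)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  lgl <- function(x) as.logical(ifelse(x == "NA", NA, x))
  tibble(
    protein_id = g(1), profile_accession = g(2),
    env_start = as.integer(g(3)) - 1L, env_end = as.integer(g(4)),
    bit_score = num(g(5)), evalue = num(g(6)),
    p_cdf = num(g(7)), p_hyper = num(g(8)), p_combined = num(g(9)),
    fold_accepted = lgl(g(10)), tier = g(11), validation = g(12),
    short_domain = lgl(g(13)), db_version = g(14))
}
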