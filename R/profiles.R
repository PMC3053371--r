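# Per-position scoring profiles ("domain profiles") and profile databases.

new_domain_profile <- function(accession, name, clan, match_scores,
                               db_version, calibration = NULL) {
  stopifnot(is.matrix(match_scores), ncol(match_scores) == 20,
            nrow(match_scores) >= 1)
  if (!is.null(calibration)) {
    stopifnot(is.finite(calibration$lambda), calibration$lambda > 0)
  }
  structure(list(accession = accession, name = name, clan = clan,
                 length = nrow(match_scores), match_scores = match_scores,
                 calibration = calibration, db_version = db_version),
            class = "domain_profile")
}

#' Build a domain profile from aligned member sequences
#'
#' Members must be gap-free equal-length strings (the synthetic generators
#' produce fixed-length families; an import adapter for externally aligned
#' families can feed the same interface). Per-column residue probabilities
#' are estimated with a uniform Dirichlet pseudocount and converted to
#' log-odds bits against a background model.
#'
#' @param members Character vector of equal-length member sequences.
#' @param accession,name Profile identifiers.
#' @param clan Optional clan id (`NULL` for none).
#' @param db_version Database release tag.
#' @param pseudocount Dirichlet pseudocount added per residue per column.
#' @param background Background residue frequencies (default uniform).
#' @return A `domain_profile` object (uncalibrated).
#' @export
build_profile <- function(members, accession, name = accession, clan = NULL,
                          db_version = "synthetic-1",
                          pseudocount = 0.5, background = aa_background()) {
  stopifnot(length(members) >= 1)
  lens <- nchar(members)
  if (length(unique(lens)) != 1) {
    abort("profile members must be aligned to equal length")
  }
  L <- lens[1]
  codes <- lapply(members, encode_seq)
  counts <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, aa_alphabet()))
  for (cd in codes) {
    ok <- cd < 20L  # X contributes no count
    idx <- cbind(which(ok), cd[ok] + 1L)
    for (r in seq_len(nrow(idx))) {
      counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + 1
    }
  }
  probs <- (counts + pseudocount * rep(background, each = L)) /
    (rowSums(counts) + pseudocount)
  scores <- log2(sweep(probs, 2, background, "/"))
  new_domain_profile(accession, name, clan, scores, db_version)
}

#' Consensus sequence of a profile
#'
#' The highest-scoring residue at each match position (ties broken by
#' alphabet order).
#'
#' @param profile A `domain_profile`.
#' @return Character scalar of length `profile$length`.
#' @export
profile_consensus <- function(profile) {
  paste(aa_alphabet()[apply(profile$match_scores, 1, which.max)],
        collapse = "")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("<domain_profile> ", x$accession, " (", x$name, "), length ", x$length,
      if (!is.null(x$clan)) paste0(", clan ", x$clan) else "",
      if (is.null(x$calibration)) ", uncalibrated" else
        sprintf(", calibrated (lambda=%.3f, mu=%.2f)",
                x$calibration$lambda, x$calibration$mu),
      ", db ", x$db_version, "\n", sep = "")
  invisible(x)
}

new_profile_db <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  names(profiles) <- vapply(profiles, `[[`, character(1), "accession")
  structure(profiles, class = "profile_db")
}

#' Bundle domain profiles into a profile database
#'
#' @param ... `domain_profile` objects, or a single list of them.
#' @return A `profile_db` (named list keyed by accession).
#' @export
profile_db <- function(...) {
  args <- list(...)
  if (length(args) == 1 && !inherits(args[[1]], "domain_profile")) {
    args <- args[[1]]
  }
  new_profile_db(args)
}

#' @export
print.profile_db <- function(x, ...) {
  cat("<profile_db> ", length(x), " profiles: ",
      paste(head(names(x), 8), collapse = ", "),
      if (length(x) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
`[.profile_db` <- function(x, i) {
  new_profile_db(NextMethod())
}

#' Clan map of a profile database
#'
#' @param db A `profile_db`.
#' @return Named character vector accession -> clan (accessions without a
#'   clan are absent).
#' @export
db_clan_map <- function(db) {
  clans <- vapply(db, function(p) p$clan %||% NA_character_, character(1))
  clans[!is.na(clans)]
}
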