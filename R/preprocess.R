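# Pre-processing: low-complexity and coiled-coil masking, optional
# secondary-structure hook, collation into a masked sequence, and
# extraction of the domain region sent to threading. Mask intervals are
# 0-based half-open.

#' Detect low-complexity regions (two-threshold entropy masking)
#'
#' SEG-style algorithm: Shannon entropy (bits) over a sliding window;
#' windows below the trigger threshold `k1` seed a region, which extends
#' through contiguous windows below the extension threshold `k2`; the
#' residue span covered by each maximal run of windows becomes one mask
#' interval, and overlapping intervals are merged.
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @param window Window length (>= 4), default 12.
#' @param k1 Trigger entropy threshold (bits), default 2.2.
#' @param k2 Extension entropy threshold (bits), default 2.5.
#' @return Tibble of intervals: `protein_id`, `start`, `end`, `source`.
#' @export
mask_low_complexity <- function(seqs, window = 12, k1 = 2.2, k2 = 2.5) {
  if (window < 4) abort("window must be >= 4")
  out <- lapply(seq_len(nrow(seqs)), function(i) {
    iv <- seg_intervals(seqs$seq[i], window, k1, k2)
    if (nrow(iv) == 0) return(NULL)
    tibble(protein_id = seqs$id[i], start = iv$start, end = iv$end,
           source = "low_complexity")
  })
  as_mask_tbl(bind_rows(out))
}

as_mask_tbl <- function(x) {
  if (nrow(x) == 0) {
    return(tibble(protein_id = character(0), start = integer(0),
                  end = integer(0), source = character(0)))
  }
  x
}

seg_intervals <- function(seq, window, k1, k2) {
  n <- nchar(seq)
  if (n < window) return(tibble(start = integer(0), end = integer(0)))
  codes <- encode_seq(seq)
  nw <- n - window + 1
  ent <- window_entropy(codes, window)
  trigger <- ent < k1
  extend <- ent < k2
  if (!any(trigger)) return(tibble(start = integer(0), end = integer(0)))
  # maximal runs of extendable windows that contain >= 1 trigger window
  r <- rle(extend)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- list()
  for (j in which(r$values)) {
    if (any(trigger[starts[j]:ends[j]])) {
      iv[[length(iv) + 1]] <- c(starts[j] - 1L, ends[j] - 1L + window)
    }
  }
  if (length(iv) == 0) return(tibble(start = integer(0), end = integer(0)))
  m <- do.call(rbind, iv)
  merge_intervals(tibble(start = m[, 1], end = m[, 2]))
}

window_entropy <- function(codes, window) {
  n <- length(codes)
  nw <- n - window + 1
  counts <- integer(21)
  for (k in codes[1:window]) counts[k + 1L] <- counts[k + 1L] + 1L
  ent <- numeric(nw)
  entropy_of <- function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log2(p))
  }
  ent[1] <- entropy_of(counts)
  if (nw > 1) {
    for (j in 2:nw) {
      out <- codes[j - 1] + 1L
      inc <- codes[j + window - 1] + 1L
      counts[out] <- counts[out] - 1L
      counts[inc] <- counts[inc] + 1L
      ent[j] <- entropy_of(counts)
    }
  }
  ent
}

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- arrange(iv, .data$start, .data$end)
  starts <- iv$start[1]; ends <- iv$end[1]
  for (i in 2:nrow(iv)) {
    k <- length(starts)
    if (iv$start[i] <= ends[k]) {
      ends[k] <- max(ends[k], iv$end[i])
    } else {
      starts <- c(starts, iv$start[i]); ends <- c(ends, iv$end[i])
    }
  }
  tibble(start = as.integer(starts), end = as.integer(ends))
}

# Heptad-position propensity table for coiled-coil detection. Positions
# a-g; hydrophobics favored at the core positions a/d, charged/polar at
# the flanking positions. Proline is strongly disfavored everywhere.
# Bundled, versioned constant (v1); see the methods vignette for how the
# detection cutoff was fixed.
coil_propensities <- function() {
  pos <- c("a", "b", "c", "d", "e", "f", "g")
  m <- matrix(0.8, nrow = 20, ncol = 7, dimnames = list(aa_alphabet(), pos))
  core <- c("a", "d")
  outer_ <- c("b", "c", "f")
  inter <- c("e", "g")
  m["L", core] <- 5.0; m["M", core] <- 4.0; m["I", core] <- 3.5
  m["V", core] <- 2.5; m["A", core] <- 2.0; m["F", core] <- 1.8
  m[c("E", "K", "R", "N", "S", "T"), core] <- 0.5
  m["D", core] <- 0.3; m["Q", core] <- 0.6; m["H", core] <- 0.6
  m["E", outer_] <- 2.0; m["K", outer_] <- 2.0; m["Q", outer_] <- 1.8
  m["R", outer_] <- 1.6; m["A", outer_] <- 1.5; m["D", outer_] <- 1.2
  m[c("S", "N"), outer_] <- 1.0; m["T", outer_] <- 0.9
  m[c("L", "M"), outer_] <- 0.6; m[c("I", "V"), outer_] <- 0.5
  m["F", outer_] <- 0.4; m["W", outer_] <- 0.3; m["Y", outer_] <- 0.5
  m["E", inter] <- 2.5; m["K", inter] <- 2.5; m["R", inter] <- 2.0
  m["Q", inter] <- 1.8; m["A", inter] <- 1.2; m["D", inter] <- 0.8
  m["L", inter] <- 0.8; m[c("I", "V"), inter] <- 0.5
  m["G", ] <- 0.3
  m["P", ] <- 0.05
  m
}

# geometric-mean propensity cutoff; fixed so that an ideal heptad repeat
# scores well above it and proline/random sequence well below (v1)
.coil_cutoff <- 1.5

#' Detect coiled-coil regions (heptad sliding-window scoring)
#'
#' Every window is scored against the bundled heptad-position propensity
#' table under each of the 7 possible registers; the score is the
#' geometric mean propensity of the best register. Windows scoring above
#' the detection cutoff are merged into mask intervals.
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @param window Window length, one of 14, 21, 28 (default 28).
#' @param score_cutoff Geometric-mean propensity cutoff (default 1.5, the
#'   bundled constant).
#' @return Tibble of intervals: `protein_id`, `start`, `end`, `source`.
#' @export
mask_coiled_coils <- function(seqs, window = 28, score_cutoff = .coil_cutoff) {
  if (!window %in% c(14, 21, 28)) abort("window must be one of 14, 21, 28")
  prop <- coil_propensities()
  lp <- log(prop)
  out <- lapply(seq_len(nrow(seqs)), function(i) {
    sq <- seqs$seq[i]
    n <- nchar(sq)
    if (n < window) return(NULL)
    codes <- encode_seq(sq)
    # log-propensity per residue per register offset
    lmat <- matrix(log(0.8), nrow = n, ncol = 7)
    ok <- codes < 20L
    for (r in 0:6) {
      hep <- ((seq_len(n) - 1 + r) %% 7) + 1
      lmat[ok, r + 1] <- lp[cbind(codes[ok] + 1L, hep[ok])]
    }
    nw <- n - window + 1
    best <- rep(-Inf, nw)
    for (r in 1:7) {
      cs <- cumsum(c(0, lmat[, r]))
      wscore <- (cs[(window + 1):(n + 1)] - cs[1:nw]) / window
      best <- pmax(best, wscore)
    }
    hit <- which(exp(best) > score_cutoff)
    if (length(hit) == 0) return(NULL)
    iv <- merge_intervals(tibble(start = hit - 1L, end = hit - 1L + window))
    tibble(protein_id = seqs$id[i], start = iv$start, end = iv$end,
           source = "coiled_coil")
  })
  as_mask_tbl(bind_rows(out))
}

#' Collate mask intervals into masked sequences
#'
#' Applies the union of all mask intervals as `X` over each sequence,
#' retaining original residues elsewhere and preserving interval
#' provenance in a list column.
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @param masks Interval tibble (`protein_id`, `start`, `end`, `source`),
#'   e.g. rows from [mask_low_complexity()] and [mask_coiled_coils()]
#'   bound together. 0-based half-open.
#' @return Tibble: `protein_id`, `seq_masked`, `masks` (list column of the
#'   protein's intervals).
#' @export
collate <- function(seqs, masks = NULL) {
  masks <- masks %||% tibble(protein_id = character(0), start = integer(0),
                             end = integer(0), source = character(0))
  out <- lapply(seq_len(nrow(seqs)), function(i) {
    pid <- seqs$id[i]
    sq <- seqs$seq[i]
    mv <- masks[masks$protein_id == pid, , drop = FALSE]
    if (nrow(mv) > 0) {
      if (any(mv$start < 0 | mv$end > nchar(sq) | mv$start >= mv$end)) {
        abort(paste0("mask interval out of bounds for ", pid))
      }
      chars <- strsplit(sq, "", fixed = TRUE)[[1]]
      for (r in seq_len(nrow(mv))) {
        chars[(mv$start[r] + 1):mv$end[r]] <- "X"
      }
      sq <- paste(chars, collapse = "")
    }
    tibble(protein_id = pid, seq_masked = sq,
           masks = list(select(mv, "start", "end", "source")))
  })
  bind_rows(out)
}

#' Run the full pre-processing step on raw sequences
#'
#' Convenience wrapper: low-complexity masking, coiled-coil masking, and
#' collation. Secondary structure, when supplied via the optional hook, is
#' carried through untouched for backends that consume it (the bundled
#' surrogate threader does not).
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @param secondary Optional tibble (`protein_id`, `ss`) of 3-state
#'   H/E/C strings of matching length.
#' @return Masked-sequence tibble as from [collate()], plus an `ss` column
#'   when provided.
#' @export
preprocess <- function(seqs, secondary = NULL) {
  masks <- bind_rows(mask_low_complexity(seqs), mask_coiled_coils(seqs))
  out <- collate(seqs, masks)
  if (!is.null(secondary)) {
    out <- left_join(out, rename(secondary, protein_id = 1, ss = 2),
                     by = "protein_id")
  }
  out
}

#' Read an optional per-protein secondary-structure table
#'
#' @param path TSV with columns `(protein_id, ss)`, `ss` a 3-state H/E/C
#'   string of the protein's length.
#' @return Tibble (`protein_id`, `ss`).
#' @export
read_secondary_structure <- function(path) {
  tab <- read_tsv_strict(path, 2, c("protein_id", "ss"), "secondary structure")
  bad <- grepl("[^HEC]", tab$ss)
  if (any(bad)) {
    abort(paste0("non-HEC state at line(s): ",
                 paste(tab$.line[bad], collapse = ", ")))
  }
  select(tab, -".line")
}

#' Extract the masked domain region for threading
#'
#' Slices the masked residues over each hit's envelope. The region id is
#' composed as `protein/accession/start-end` with 1-based inclusive
#' coordinates. Fully masked regions are flagged with a warning.
#'
#' @param mseqs Masked-sequence tibble from [collate()]/[preprocess()].
#' @param hits Hits tibble (0-based half-open envelopes).
#' @return Sequence tibble: `id`, `seq`, `protein_id`, `profile_accession`,
#'   `env_start`, `env_end`, `all_masked`.
#' @export
extract_domain_region <- function(mseqs, hits) {
  out <- lapply(seq_len(nrow(hits)), function(i) {
    pid <- hits$protein_id[i]
    row <- which(mseqs$protein_id == pid)
    if (length(row) != 1) abort(paste0("no masked sequence for ", pid))
    sq <- mseqs$seq_masked[row]
    s <- hits$env_start[i]; e <- hits$env_end[i]
    if (s < 0 || e > nchar(sq) || s >= e) {
      abort(paste0("hit envelope out of bounds for ", pid))
    }
    sub <- substr(sq, s + 1, e)
    allx <- grepl("^X+$", sub)
    tibble(id = paste0(pid, "/", hits$profile_accession[i], "/",
                       s + 1, "-", e),
           seq = sub, protein_id = pid,
           profile_accession = hits$profile_accession[i],
           env_start = s, env_end = e, all_masked = allx)
  })
  res <- bind_rows(out)
  if (nrow(res) > 0 && any(res$all_masked)) {
    warn(paste0("fully masked region(s): ",
                paste(res$id[res$all_masked], collapse = ", ")))
  }
  res
}
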