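# Hide-and-seek benchmark framework: truth-set selection from paired
# profile-database releases, confusion classification with clan
# exclusion, and the derived precision/recall/accuracy metrics.

#' Select the remote-domain truth set from paired-release searches
#'
#' A candidate (protein, profile, region) belongs to the truth set when it
#' scored weakly under the old release and significantly under the new
#' one with a large E-value change: `E_old > 0.1`, `E_new < 0.1` and
#' `E_old / E_new >= min_ratio` (default 10; `strict = TRUE` uses a
#' strictly-greater ratio). Old and new hits are paired by protein and
#' accession with envelope overlap of at least one residue.
#'
#' @param old_hits,new_hits Hits tibbles from searches against the old and
#'   new profile releases (must carry distinct `db_version` tags).
#' @param weak_cut E-value boundary between weak and significant
#'   (default 0.1).
#' @param min_ratio Minimum old/new E-value ratio (default 10).
#' @param strict Require a strictly greater ratio.
#' @return Truth tibble: `protein_id`, `profile_accession`, `env_start`,
#'   `env_end` (old-hit envelope), `e_old`, `e_new`; attribute
#'   `provenance = c(old, new)` version tags.
#' @export
select_truth <- function(old_hits, new_hits, weak_cut = 0.1,
                         min_ratio = 10, strict = FALSE) {
  vo <- unique(old_hits$db_version)
  vn <- unique(new_hits$db_version)
  if (length(vo) == 1 && length(vn) == 1 && identical(vo, vn)) {
    abort("old and new hit sets carry the same db_version tag")
  }
  old <- select(old_hits, "protein_id", "profile_accession",
                "env_start", "env_end", e_old = "evalue")
  new <- select(new_hits, "protein_id", "profile_accession",
                new_start = "env_start", new_end = "env_end",
                e_new = "evalue")
  paired <- inner_join(old, new, by = c("protein_id", "profile_accession"),
                       relationship = "many-to-many")
  paired <- filter(paired,
                   pmin(.data$env_end, .data$new_end) -
                     pmax(.data$env_start, .data$new_start) > 0)
  # best (smallest) new E-value per old hit
  paired <- paired |>
    group_by(.data$protein_id, .data$profile_accession,
             .data$env_start, .data$env_end, .data$e_old) |>
    summarise(e_new = min(.data$e_new), .groups = "drop")
  ratio_ok <- if (strict) paired$e_old / paired$e_new > min_ratio
  else paired$e_old / paired$e_new >= min_ratio
  out <- paired[paired$e_old > weak_cut & paired$e_new < weak_cut &
                  ratio_ok, , drop = FALSE]
  out <- arrange(out, .data$protein_id, .data$profile_accession,
                 .data$env_start)
  attr(out, "provenance") <- c(old = vo[1], new = vn[1])
  out
}

#' Classify candidate predictions against a truth set
#'
#' Implements the four-way confusion rule on best-hit decisions per
#' candidate region: a truth member is TP when its decision statistic is
#' at or below `alpha` (or, for engines without a p-value, when
#' `detected` is `TRUE`), else FN; a non-member is FP when positive, else
#' TN — unless its profile shares a clan with the truth profile of an
#' overlapping truth region, in which case the candidate is excluded from
#' all counts.
#'
#' @param candidates Tibble with one row per candidate region:
#'   `protein_id`, `profile_accession`, `env_start`, `env_end`, and either
#'   `p_value` (numeric) or `detected` (logical) as the decision.
#' @param truth Truth tibble from [select_truth()] (or any tibble with
#'   `protein_id`, `profile_accession`, `env_start`, `env_end`).
#' @param clans Optional named character vector accession -> clan.
#' @param alpha Decision threshold on `p_value` (default 0.001).
#' @return A `confusion_table` object; its `$calls` tibble carries the
#'   per-candidate class (`TP`/`FN`/`FP`/`TN`/`excluded`).
#' @export
classify_candidates <- function(candidates, truth, clans = NULL,
                                alpha = 0.001) {
  stopifnot(is.data.frame(candidates), is.data.frame(truth))
  positive <- if ("p_value" %in% names(candidates)) {
    !is.na(candidates$p_value) & candidates$p_value <= alpha
  } else if ("detected" %in% names(candidates)) {
    isTRUE_v(candidates$detected)
  } else {
    abort("candidates need a `p_value` or `detected` column")
  }
  cls <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    trow <- truth[truth$protein_id == candidates$protein_id[i] &
                    pmin(truth$env_end, candidates$env_end[i]) -
                    pmax(truth$env_start, candidates$env_start[i]) > 0, ,
                  drop = FALSE]
    is_member <- any(trow$profile_accession == candidates$profile_accession[i])
    if (is_member) {
      cls[i] <- if (positive[i]) "TP" else "FN"
    } else {
      same_clan <- FALSE
      if (!is.null(clans) && nrow(trow) > 0) {
        c_cand <- clans[candidates$profile_accession[i]]
        c_truth <- clans[trow$profile_accession]
        same_clan <- !is.na(c_cand) && any(!is.na(c_truth) & c_truth == c_cand)
      }
      cls[i] <- if (same_clan) "excluded" else if (positive[i]) "FP" else "TN"
    }
  }
  calls <- mutate(candidates, class = cls)
  confusion_table(tp = sum(cls == "TP"), fn = sum(cls == "FN"),
                  fp = sum(cls == "FP"), tn = sum(cls == "TN"),
                  excluded = sum(cls == "excluded"), calls = calls)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Construct a confusion table
#'
#' @param tp,fn,fp,tn Confusion counts.
#' @param excluded Candidates excluded by the clan rule.
#' @param calls Optional per-candidate classification tibble.
#' @return A `confusion_table` object.
#' @export
confusion_table <- function(tp, fn, fp, tn, excluded = 0, calls = NULL) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 excluded = as.integer(excluded), calls = calls),
            class = "confusion_table")
}

#' Derived benchmark metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); Recall = TP/(TP+FN);
#' Precision = TP/(TP+FP); FPR = FP/(FP+TN); FNR = FN/(TP+FN).
#' Exact rational values plus percentages rounded half-up to integers for
#' parity with printed benchmark tables. Metrics with zero denominators
#' are reported as `NA` (undefined), never 0.
#'
#' @param ct A `confusion_table` (or anything with `tp`, `fn`, `fp`,
#'   `tn`).
#' @return Tibble: `metric`, `value` (proportion), `percent` (integer).
#' @export
confusion_metrics <- function(ct) {
  tp <- ct$tp; fn <- ct$fn; fp <- ct$fp; tn <- ct$tn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  vals <- c(precision = safe(tp, tp + fp),
            recall = safe(tp, tp + fn),
            accuracy = safe(tp + tn, tp + tn + fp + fn),
            fpr = safe(fp, fp + tn),
            fnr = safe(fn, tp + fn))
  tibble(metric = names(vals), value = unname(vals),
         percent = unname(ifelse(is.na(vals), NA_real_,
                                 round_half_up(vals * 100))))
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> TP=%d FN=%d FP=%d TN=%d (excluded=%d)\n",
              x$tp, x$fn, x$fp, x$tn, x$excluded))
  m <- confusion_metrics(x)
  cat(paste(sprintf("%s=%s%%", m$metric,
                    ifelse(is.na(m$percent), "NA", m$percent)),
            collapse = "  "), "\n")
  invisible(x)
}

#' Tidy a confusion table into count rows
#' @param x A `confusion_table`.
#' @param ... Unused.
#' @return Tibble `class`, `n`.
#' @export
tidy.confusion_table <- function(x, ...) {
  tibble(class = c("TP", "FN", "FP", "TN", "excluded"),
         n = c(x$tp, x$fn, x$fp, x$tn, x$excluded))
}

#' One-row metric summary of a confusion table
#' @param x A `confusion_table`.
#' @param ... Unused.
#' @return One-row tibble of counts and percent metrics.
#' @export
glance.confusion_table <- function(x, ...) {
  m <- confusion_metrics(x)
  out <- tibble(tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
                excluded = x$excluded)
  for (i in seq_len(nrow(m))) out[[m$metric[i]]] <- m$percent[i]
  out
}

#' Bar plot of confusion counts
#' @param object A `confusion_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "candidates", title = "Benchmark confusion")
}
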