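# Reference-standard aggregation: normalise each rater's differential, rank
# by confidence with inverse-rank weights, and fuse the three raters by
# summing weights per condition. Ambiguity is classified from top-1
# agreement: 3/3 unanimous, 2/3 intermediate, 0/3 disagreement.

#' Normalise a rater differential
#'
#' Drops entries that could not be mapped to the taxonomy (sentinel
#' condition `"UNMAPPED"`) and collapses duplicate mappings, keeping the
#' highest confidence per condition.
#'
#' @param diff A differential: data.frame with columns `condition` and
#'   `confidence` (and optionally `raw_label`).
#' @return data.frame with columns `condition`, `confidence`, one row per
#'   condition.
#' @export
normalise_rater <- function(diff) {
  stopifnot(is.data.frame(diff), all(c("condition", "confidence") %in% names(diff)))
  if (nrow(diff) == 0L) {
    return(data.frame(condition = character(0), confidence = numeric(0)))
  }
  if (any(diff$confidence < 1 | diff$confidence > 5)) {
    stopf("confidences must lie in [1, 5]")
  }
  keep <- diff$condition != "UNMAPPED"
  diff <- diff[keep, , drop = FALSE]
  if (nrow(diff) == 0L) {
    return(data.frame(condition = character(0), confidence = numeric(0)))
  }
  conf <- tapply(diff$confidence, diff$condition, max)
  data.frame(condition = names(conf), confidence = as.numeric(conf),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Inverse-rank weights for a normalised differential
#'
#' Ranks entries by descending confidence and assigns the weight 1/rank.
#' Ties in confidence break by higher mean confidence across the panel (when
#' supplied), then by lexicographic condition code, keeping the ranking
#' deterministic.
#'
#' @param entries Normalised differential (one row per condition).
#' @param panel_mean Optional named numeric vector of each condition's mean
#'   confidence across the panel, used as the first tie-break.
#' @return data.frame with columns `condition`, `confidence`, `rank`,
#'   `weight`, ordered by rank.
#' @export
weight_rater <- function(entries, panel_mean = NULL) {
  stopifnot(is.data.frame(entries))
  if (nrow(entries) == 0L) {
    return(data.frame(condition = character(0), confidence = numeric(0),
                      rank = integer(0), weight = numeric(0)))
  }
  pm <- if (is.null(panel_mean)) entries$confidence else
    as.numeric(panel_mean[entries$condition])
  ord <- order(-entries$confidence, -pm, entries$condition)
  out <- entries[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$weight <- 1 / out$rank
  rownames(out) <- NULL
  out
}

#' Fuse a three-rater panel into a reference standard
#'
#' Each rater's normalised differential is ranked with inverse-rank weights
#' and the weights are summed per condition across raters; the fused ranking
#' orders conditions by descending aggregate weight (ties by panel mean
#' confidence, then condition code). Top-1 agreement among the raters'
#' individual top choices yields the ambiguity class.
#'
#' @param panel List of exactly 3 rater differentials.
#' @return An object of class `reference_standard`: list with `ranked`
#'   (data.frame `condition`, `weight`), `top1`, `ambiguity` (one of
#'   `"unanimous"`, `"intermediate"`, `"disagreement"`), and `excluded`
#'   (`NA` or an exclusion reason; `"undiagnosable"` when all three
#'   differentials are empty after normalisation, in which case there is no
#'   ranking).
#' @export
fuse_panel <- function(panel) {
  if (!is.list(panel) || length(panel) != 3L) {
    stopf("panel must contain exactly 3 rater differentials")
  }
  norm <- lapply(panel, normalise_rater)
  if (all(vapply(norm, nrow, integer(1)) == 0L)) {
    return(structure(list(ranked = NULL, top1 = NA_character_,
                          ambiguity = NA_character_,
                          excluded = "undiagnosable"),
                     class = "reference_standard"))
  }
  all_conf <- do.call(rbind, norm)
  panel_mean <- tapply(all_conf$confidence, all_conf$condition, mean)

  weighted <- lapply(norm, weight_rater, panel_mean = panel_mean)
  agg_tab <- do.call(rbind, weighted)
  agg <- tapply(agg_tab$weight, agg_tab$condition, sum)
  conds <- names(agg)
  ord <- order(-as.numeric(agg), -as.numeric(panel_mean[conds]), conds)
  ranked <- data.frame(condition = conds[ord],
                       weight = as.numeric(agg)[ord],
                       row.names = NULL, stringsAsFactors = FALSE)

  votes <- unlist(lapply(weighted, function(w) {
    if (nrow(w)) w$condition[1L] else NULL
  }))
  n_agree <- if (length(votes)) max(table(votes)) else 0L
  ambiguity <- if (n_agree >= 3L) "unanimous"
    else if (n_agree == 2L) "intermediate"
    else "disagreement"

  structure(list(ranked = ranked, top1 = ranked$condition[1L],
                 ambiguity = ambiguity, excluded = NA_character_),
            class = "reference_standard")
}

#' @export
print.reference_standard <- function(x, ...) {
  if (!is.na(x$excluded)) {
    cat(sprintf("<reference_standard> excluded (%s)\n", x$excluded))
  } else {
    cat(sprintf("<reference_standard> top1 = %s (%s); %d ranked conditions\n",
                x$top1, x$ambiguity, nrow(x$ranked)))
  }
  invisible(x)
}

#' Build reference standards for every case in a set
#'
#' Applies [fuse_panel] per case and passes generator-injected exclusion
#' flags (multiple conditions, undiagnosable, unsupported) through; excluded
#' cases carry no ranking and must not reach evaluation. Adds `ref_top1` and
#' `ambiguity` columns to `cases$info` for convenience.
#'
#' @param cases A `case_set` with simulated panels ([simulate_panels]).
#' @return The `case_set` with a `reference` element (list of
#'   `reference_standard`) and augmented `info`.
#' @export
panel_reference <- function(cases) {
  if (is.null(cases$panel)) stopf("cases carry no rater panels; run simulate_panels() first")
  refs <- vector("list", n_cases(cases))
  for (i in seq_along(refs)) {
    flag <- cases$info$excluded[i]
    if (!is.na(flag)) {
      refs[[i]] <- structure(list(ranked = NULL, top1 = NA_character_,
                                  ambiguity = NA_character_, excluded = flag),
                             class = "reference_standard")
    } else {
      refs[[i]] <- fuse_panel(cases$panel[[i]])
    }
  }
  cases$reference <- refs
  cases$info$ref_top1 <- vapply(refs, function(r) r$top1, character(1))
  cases$info$ambiguity_class <- vapply(refs, function(r) r$ambiguity, character(1))
  cases$info$excluded <- vapply(refs, function(r) r$excluded, character(1))
  cases
}

#' Simulated in-house dermatologist arm
#'
#' A fourth independent simulated rater scored against the panel reference:
#' for each case one differential is simulated, normalised and ranked, and
#' the flag records whether the panel's top-1 diagnosis appears among the
#' rater's first three ranked conditions. This furnishes the
#' clinician-vs-model comparison structure without clinical data.
#'
#' @param cases A `case_set` processed by [panel_reference].
#' @param tax A `cond_taxonomy`.
#' @param rater_skill Skill of the simulated dermatologist in (0, 1].
#' @param seed Integer seed.
#' @return Integer vector of 0/1 top-3 agreement flags.
#' @export
derm_flags <- function(cases, tax, rater_skill = 0.95, seed = 1) {
  cat_members <- split(tax$conditions,
                       factor(tax$category_of, levels = tax$categories))
  info <- cases$info
  local_seed(derive_seed(seed, "derm"), {
    vapply(seq_len(nrow(info)), function(i) {
      diff <- simulate_rater(info$true_condition[i], info$ambiguity[i], tax,
                             cat_members, rater_skill)
      ranked <- weight_rater(normalise_rater(diff))
      top3 <- utils::head(ranked$condition, 3L)
      as.integer(!is.na(info$ref_top1[i]) && info$ref_top1[i] %in% top3)
    }, integer(1))
  })
}

#' Drop excluded cases
#'
#' Removes cases flagged for exclusion (multiple conditions, undiagnosable,
#' unsupported) so they never reach evaluation.
#'
#' @param cases A `case_set` processed by [panel_reference].
#' @export
drop_excluded <- function(cases) {
  keep <- is.na(cases$info$excluded)
  out <- subset_cases(cases, keep)
  if (!is.null(cases$reference)) out$reference <- cases$reference[keep]
  out
}
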