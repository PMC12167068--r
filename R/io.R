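# Plain-text exchange formats: cases as JSONL (one case per line) with
# embeddings in a long CSV keyed by case_id, taxonomy / policies /
# calibration models as JSON, generator parameters as YAML, results as CSV.

#' Write / read a taxonomy as JSON
#' @param tax A `cond_taxonomy`.
#' @param path File path.
#' @export
write_taxonomy_json <- function(tax, path) {
  x <- unclass(tax)
  # named vectors serialise as JSON objects so condition keys survive
  x$category_of <- as.list(x$category_of)
  x$subsample_rate <- as.list(x$subsample_rate)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_taxonomy_json
#' @export
read_taxonomy_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$category_of <- unlist(x$category_of)
  x$subsample_rate <- unlist(x$subsample_rate)
  x$seed <- as.integer(x$seed)
  structure(x, class = "cond_taxonomy")
}

#' Write / read cases as JSONL plus an embeddings CSV
#'
#' One JSON object per line per case (info fields, metadata, panel);
#' embeddings go to a separate long-format CSV (`case_id`, `image`, then
#' one column per dimension) referenced by case id.
#'
#' @param cases A `case_set`.
#' @param path JSONL path for the cases.
#' @param embeddings_path CSV path for the embeddings (default: `path`
#'   with extension `.embeddings.csv`).
#' @export
write_cases_jsonl <- function(cases, path,
                              embeddings_path = paste0(path, ".embeddings.csv")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_cases(cases))) {
    rec <- c(as.list(cases$info[i, ]),
             list(metadata = as.list(cases$metadata[i, ])))
    if (!is.null(cases$panel)) rec$panel <- cases$panel[[i]]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  emb <- do.call(rbind, lapply(seq_len(n_cases(cases)), function(i) {
    e <- cases$embeddings[[i]]
    cbind(data.frame(case_id = cases$info$case_id[i], image = seq_len(nrow(e))),
          as.data.frame(e))
  }))
  names(emb)[-(1:2)] <- sprintf("e%03d", seq_len(cases$d))
  utils::write.csv(emb, embeddings_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cases_jsonl
#' @export
read_cases_jsonl <- function(path,
                             embeddings_path = paste0(path, ".embeddings.csv")) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  meta <- do.call(rbind, lapply(recs, function(r) {
    as.data.frame(r$metadata, stringsAsFactors = FALSE)
  }))
  info_fields <- setdiff(names(recs[[1]]), c("metadata", "panel"))
  info <- do.call(rbind, lapply(recs, function(r) {
    as.data.frame(lapply(r[info_fields], function(v) v %||% NA),
                  stringsAsFactors = FALSE)
  }))
  emb_tab <- utils::read.csv(embeddings_path, stringsAsFactors = FALSE)
  d <- ncol(emb_tab) - 2L
  emb <- lapply(split(emb_tab, factor(emb_tab$case_id, levels = info$case_id)),
                function(x) unname(as.matrix(x[order(x$image), -(1:2)])))
  names(emb) <- NULL
  out <- list(info = info, metadata = meta, embeddings = emb, d = d)
  has_panel <- all(vapply(recs, function(r) !is.null(r$panel), logical(1)))
  if (has_panel) out$panel <- lapply(recs, function(r) {
    lapply(r$panel, function(p) as.data.frame(p, stringsAsFactors = FALSE))
  })
  structure(out, class = "case_set")
}

#' Write reference standards as JSONL
#'
#' One object per case: case id, ambiguity class, exclusion reason and the
#' fused ranking.
#'
#' @param cases A `case_set` processed by [panel_reference].
#' @param path File path.
#' @export
write_reference_jsonl <- function(cases, path) {
  if (is.null(cases$reference)) stopf("cases carry no reference standards")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(cases$reference)) {
    r <- cases$reference[[i]]
    rec <- list(case_id = cases$info$case_id[i], top1 = r$top1,
                ambiguity = r$ambiguity, excluded = r$excluded,
                ranked = r$ranked)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  invisible(path)
}

#' Write a variable-k policy (JSON) and prediction sets (CSV)
#'
#' @param policy A `variable_k_policy`.
#' @param path File path.
#' @export
write_policy_json <- function(policy, path) {
  jsonlite::write_json(unclass(policy), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_policy_json
#' @export
read_policy_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  variable_k_policy(x$threshold, x$k_min, x$k_max, x$calibration_report)
}

#' Write prediction sets as CSV
#'
#' Columns `case_id`, `k`, `conditions` (pipe-delimited, descending score).
#'
#' @param scores Score matrix.
#' @param policy A `variable_k_policy`.
#' @param path File path.
#' @export
write_prediction_sets_csv <- function(scores, policy, path) {
  sets <- lapply(seq_len(nrow(scores)), function(i) {
    variable_k_predict(scores[i, ], policy)
  })
  tab <- data.frame(
    case_id = rownames(scores),
    k = vapply(sets, function(s) s$k, integer(1)),
    conditions = vapply(sets, function(s) paste(s$conditions, collapse = "|"),
                        character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a calibration model as JSON
#' @param model A `calibration_model`.
#' @param path File path.
#' @export
write_calibration_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a score matrix as CSV
#'
#' Rows are cases (first column `case_id`), columns conditions.
#'
#' @param scores Score matrix from [predict_scores].
#' @param path File path.
#' @export
write_scores_csv <- function(scores, path) {
  tab <- cbind(data.frame(case_id = rownames(scores)), as.data.frame(scores))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a classifier checkpoint as JSON
#'
#' Parameters are stored as named flat arrays with dimensions, alongside
#' the model configuration, so checkpoints are diffable plain text.
#'
#' @param model A `shift_classifier`.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  x <- unclass(model)
  x$par <- lapply(x$par, function(p) {
    list(dim = dim(p) %||% length(p), values = as.numeric(p))
  })
  if (!is.null(x$cfg)) x$cfg <- unclass(x$cfg)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$par <- lapply(x$par, function(p) {
    if (length(p$dim) == 2L) matrix(p$values, p$dim[1], p$dim[2]) else p$values
  })
  x$conditions <- as.character(x$conditions)
  structure(x, class = "shift_classifier")
}

#' Write a training loss curve as CSV
#'
#' @param model A trained `shift_classifier` (uses its `history`).
#' @param path File path.
#' @export
write_training_csv <- function(model, path) {
  if (is.null(model$history)) stopf("model carries no training history")
  utils::write.csv(data.frame(step = seq_along(model$history),
                              loss = model$history),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a grid configuration from YAML
#'
#' The YAML file holds any subset of [grid_config]'s arguments (including
#' an explicit integer `seed`); unspecified values keep their defaults.
#'
#' @param path YAML path.
#' @return A `grid_config`.
#' @export
read_grid_config <- function(path) {
  args <- yaml::read_yaml(path)
  known <- names(formals(grid_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) {
    stopf("unknown grid_config fields in YAML: %s",
          paste(unknown, collapse = ", "))
  }
  do.call(grid_config, args)
}

#' Write grid results as CSV
#' @param results Output of [run_grid].
#' @param path File path.
#' @export
write_grid_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
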