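# Synthetic case generation: embeddings, metadata, covariates, rater panels.
#
# The embedding model is class-conditional Gaussian: each condition has a
# fixed centroid equal to its category's centroid plus a condition-specific
# offset, and each image adds isotropic noise scaled by the domain's
# noise_scale times a per-case ambiguity draw. Category separation exceeds
# condition separation, so embeddings cluster by category.

CAT_SD <- 1.5  # sd of category centroids
COND_SD <- 1   # sd of condition offsets around the category centroid
RATER_DECAY <- 0.12  # rater top-1 error growth per unit case ambiguity

# A fraction of conditions belong to cross-category look-alike clusters
# (infections presenting like inflammatory or contact eruptions, say):
# cluster members share a centroid up to a small offset, so the ranking
# within a cluster is driven by prior information rather than appearance.
MIMIC_RATE <- 0.6    # fraction of conditions in look-alike clusters
MIMIC_SIZE <- 10     # target cluster size
MIMIC_SD <- 0.1      # member offset around the cluster centroid

N_META_FIELDS <- 25L
META_LEVELS <- 4L

# Image-count distribution over 1..8: mode at 3-4, P(>6) = 0.04 < 0.05.
IMG_COUNT_PROBS <- c(0.08, 0.17, 0.27, 0.25, 0.12, 0.07, 0.025, 0.015)

ANATOMIC_LOCATIONS <- c(
  "Scalp", "Face and neck", "Mouth and tongue", "Arm", "Hand and palm",
  "Anterior torso", "Posterior torso", "Genitalia", "Buttocks", "Leg",
  "Dorsal foot", "Unspecified"
)
ANATOMIC_PROBS <- c(0.027, 0.28, 0.011, 0.17, 0.065, 0.15, 0.08, 0.048,
                    0.02, 0.2, 0.035, 0.064)

#' Condition centroids for a taxonomy
#'
#' Deterministic class-conditional Gaussian centroids: category centroids
#' with sd 1.5, condition offsets with sd 1, so embeddings cluster by
#' category more strongly than by condition. A fixed fraction (60%) of
#' conditions form cross-category look-alike clusters of about 10 members
#' whose centroids coincide up to a small offset (sd 0.1), reproducing the
#' visually-confusable condition groups (e.g. cutaneous infections vs
#' inflammatory eruptions) across which prior information must arbitrate.
#' Seeded from the taxonomy's own seed and the embedding dimension, so every
#' domain generated from the same taxonomy shares the same centroids.
#'
#' @param tax A `cond_taxonomy`.
#' @param d Embedding dimension.
#' @return A `length(tax$conditions)` x `d` matrix, rownames condition codes.
#' @export
taxonomy_centroids <- function(tax, d) {
  if (!is_count(d)) stopf("d must be a positive integer")
  K <- length(tax$categories)
  C <- length(tax$conditions)
  cluster <- mimic_clusters(tax)
  local_seed(derive_seed(tax$seed, paste0("centroids", d)), {
    cat_c <- matrix(stats::rnorm(K * d, sd = CAT_SD), K, d,
                    dimnames = list(tax$categories, NULL))
    off <- matrix(stats::rnorm(C * d, sd = COND_SD), C, d)
    m <- cat_c[tax$category_of, , drop = FALSE] + off
    n_clusters <- max(cluster)
    if (n_clusters > 0L) {
      centres <- matrix(stats::rnorm(n_clusters * d,
                                     sd = sqrt(CAT_SD^2 + COND_SD^2)),
                        n_clusters, d)
      members <- which(cluster > 0L)
      m[members, ] <- centres[cluster[members], , drop = FALSE] +
        matrix(stats::rnorm(length(members) * d, sd = MIMIC_SD),
               length(members), d)
    }
    rownames(m) <- tax$conditions
    m
  })
}

#' Look-alike cluster membership
#'
#' Deterministic (from the taxonomy seed alone) assignment of 60% of the
#' conditions to cross-category look-alike clusters of about 10 members.
#' Cluster members share an embedding centroid up to a small offset and
#' share a metadata profile, so within a cluster the classifier can only
#' rank members by prior information; look-alike structure is what makes
#' condition-distribution shift costly and prior-based adaptation useful.
#'
#' @param tax A `cond_taxonomy`.
#' @return Integer vector over conditions: 0 for unclustered conditions,
#'   otherwise the cluster index.
#' @export
mimic_clusters <- function(tax) {
  C <- length(tax$conditions)
  n_mimic <- round(MIMIC_RATE * C)
  cluster <- integer(C)
  if (n_mimic >= 2L) {
    n_clusters <- max(1L, round(n_mimic / MIMIC_SIZE))
    local_seed(derive_seed(tax$seed, "mimic"), {
      members <- sample.int(C, n_mimic)
      cluster[members] <- rep_len(seq_len(n_clusters), n_mimic)
    })
  }
  names(cluster) <- tax$conditions
  cluster
}

#' Generate synthetic cases for a domain
#'
#' Draws `profile$n_cases` cases: a true condition from the profile's
#' category prior and within-category prior, 1-8 image embeddings (mode 3-4,
#' fewer than 5% of cases exceed 6) around the condition centroid with noise
#' `noise_scale * ambiguity`, 25 categorical metadata fields informative of
#' the condition category with independent missingness, demographic and
#' image-quality covariates, and rare generator-injected exclusion flags
#' (multiple conditions / undiagnosable / unsupported) that downstream
#' evaluation must drop.
#'
#' @param tax A `cond_taxonomy`.
#' @param profile A `domain_profile`.
#' @param d Embedding dimension (default 64).
#' @param seed Integer seed; generation is deterministic given it.
#' @param meta_informativeness Probability that a metadata field takes its
#'   category-determined level rather than a uniform one (default 0.25).
#' @param meta_missing Independent per-field missingness probability
#'   (default 0.15).
#' @return A `case_set`: list with `info` (data.frame of per-case fields),
#'   `metadata` (data.frame with 25 categorical columns), `embeddings`
#'   (list of images x d matrices), `d`, and later `panel` (see
#'   [simulate_panels]).
#' @export
generate_cases <- function(tax, profile, d = 64, seed = 1,
                           meta_informativeness = 0.25, meta_missing = 0.15) {
  stopifnot(inherits(tax, "cond_taxonomy"), inherits(profile, "domain_profile"))
  if (!is_count(d)) stopf("d must be a positive integer")
  K <- length(tax$categories)
  if (length(profile$category_prior) != K) {
    stopf("profile category_prior must be defined over the taxonomy's %d categories", K)
  }
  n <- profile$n_cases
  centroids <- taxonomy_centroids(tax, d)
  cat_members <- split(tax$conditions, factor(tax$category_of, levels = tax$categories))

  local_seed(derive_seed(seed, paste0("cases", profile$name)), {
    cat_idx <- sample.int(K, n, replace = TRUE, prob = profile$category_prior)
    cond <- character(n)
    for (k in seq_len(K)) {
      idx <- which(cat_idx == k)
      if (!length(idx)) next
      within <- profile$condition_prior_within_category[[k]] %||%
        rep(1 / length(cat_members[[k]]), length(cat_members[[k]]))
      cond[idx] <- sample(cat_members[[k]], length(idx), replace = TRUE,
                          prob = within)
    }

    ambiguity <- profile$noise_scale * stats::runif(n, 0.4, 1.6)
    n_img <- sample.int(8L, n, replace = TRUE, prob = IMG_COUNT_PROBS)
    total <- sum(n_img)
    case_of_img <- rep.int(seq_len(n), n_img)
    noise <- matrix(stats::rnorm(total * d), total, d) * ambiguity[case_of_img]
    img <- centroids[cond[case_of_img], , drop = FALSE] + noise
    embeddings <- lapply(split.data.frame(img, case_of_img), function(m) {
      rownames(m) <- NULL
      m
    })
    names(embeddings) <- NULL

    # 25 categorical metadata fields: informative level is a deterministic
    # function of (category, field) -- or of (cluster, field) for look-alike
    # cluster members, which share presentation; otherwise uniform; then
    # missingness.
    cluster <- mimic_clusters(tax)
    grp_idx <- ifelse(cluster[cond] > 0L, K + cluster[cond], cat_idx)
    meta <- matrix("", n, N_META_FIELDS)
    lvls <- paste0("L", seq_len(META_LEVELS))
    for (f in seq_len(N_META_FIELDS)) {
      informative_lvl <- ((grp_idx + f) %% META_LEVELS) + 1L
      pick <- stats::runif(n) < meta_informativeness
      val <- ifelse(pick, informative_lvl,
                    sample.int(META_LEVELS, n, replace = TRUE))
      val <- lvls[val]
      val[stats::runif(n) < meta_missing] <- "unknown"
      meta[, f] <- val
    }
    metadata <- as.data.frame(meta, stringsAsFactors = FALSE)
    names(metadata) <- sprintf("q%02d", seq_len(N_META_FIELDS))

    age <- round(stats::runif(n, 18, 90))
    age_group <- cut(age, c(-Inf, 29, 39, 49, 59, Inf),
                     labels = c("<30", "30-39", "40-49", "50-59", ">=60"))
    efst <- sample(c("I/II", "III/IV", "V/VI", "unknown"), n, replace = TRUE,
                   prob = c(0.4, 0.33, 0.05, 0.22))
    sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.55, 0.45))
    location <- sample(ANATOMIC_LOCATIONS, n, replace = TRUE,
                       prob = ANATOMIC_PROBS)
    image_quality <- sample(c("ok", "non_skin_area", "blurry"), n,
                            replace = TRUE, prob = c(0.8, 0.1, 0.1))
    pre_covid <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.7, 0.3))

    excl_draw <- stats::runif(n)
    excluded <- rep(NA_character_, n)
    excluded[excl_draw < 0.008] <- "multiple_conditions"
    excluded[excl_draw >= 0.008 & excl_draw < 0.013] <- "undiagnosable"
    excluded[excl_draw >= 0.013 & excl_draw < 0.018] <- "unsupported"

    info <- data.frame(
      case_id = sprintf("%s-%06d", profile$name, seq_len(n)),
      domain = profile$name,
      true_condition = cond,
      true_category = tax$categories[cat_idx],
      ambiguity = ambiguity,
      n_images = n_img,
      age = age, age_group = as.character(age_group), sex = sex, efst = efst,
      anatomic_location = location, image_quality = image_quality,
      pre_covid = pre_covid, excluded = excluded,
      stringsAsFactors = FALSE
    )
    structure(list(info = info, metadata = metadata, embeddings = embeddings,
                   d = as.integer(d)),
              class = "case_set")
  })
}

#' @export
print.case_set <- function(x, ...) {
  cat(sprintf("<case_set> %d cases (domain %s), d = %d%s\n",
              nrow(x$info), paste(unique(x$info$domain), collapse = "/"),
              x$d, if (!is.null(x$panel)) ", with rater panels" else ""))
  invisible(x)
}

#' Number of cases in a case set
#' @param x A `case_set`.
#' @export
n_cases <- function(x) nrow(x$info)

#' Subset a case set by index
#'
#' Indices may repeat (sampling with replacement for training sets).
#'
#' @param x A `case_set`.
#' @param idx Integer or logical index into the cases.
#' @export
subset_cases <- function(x, idx) {
  if (is.logical(idx)) idx <- which(idx)
  out <- list(info = x$info[idx, , drop = FALSE],
              metadata = x$metadata[idx, , drop = FALSE],
              embeddings = x$embeddings[idx],
              d = x$d)
  rownames(out$info) <- rownames(out$metadata) <- NULL
  if (!is.null(x$panel)) out$panel <- x$panel[idx]
  if (!is.null(x$reference)) out$reference <- x$reference[idx]
  structure(out, class = "case_set")
}

#' Concatenate case sets
#' @param ... `case_set` objects with equal embedding dimension.
#' @export
bind_cases <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, logical(1), "case_set")))
  d <- unique(vapply(sets, function(s) s$d, integer(1)))
  if (length(d) != 1) stopf("case sets have differing embedding dimensions")
  all_cols <- Reduce(union, lapply(sets, function(s) names(s$info)))
  infos <- lapply(sets, function(s) {
    for (col in setdiff(all_cols, names(s$info))) s$info[[col]] <- NA
    s$info[all_cols]
  })
  out <- list(
    info = do.call(rbind, infos),
    metadata = do.call(rbind, lapply(sets, function(s) s$metadata)),
    embeddings = do.call(c, lapply(sets, function(s) s$embeddings)),
    d = d
  )
  rownames(out$info) <- rownames(out$metadata) <- NULL
  if (all(vapply(sets, function(s) !is.null(s$panel), logical(1)))) {
    out$panel <- do.call(c, lapply(sets, function(s) s$panel))
  }
  if (all(vapply(sets, function(s) !is.null(s$reference), logical(1)))) {
    out$reference <- do.call(c, lapply(sets, function(s) s$reference))
  }
  structure(out, class = "case_set")
}

#' Apply study sub-sampling to a case set
#'
#' Thins cases of each condition independently with the taxonomy's
#' `subsample_rate` (e.g. an eczema-like condition retained at 20%),
#' emulating the cohort's design; downstream accuracy estimates must then be
#' adjusted with inverse-probability weights ([sampling_weights]).
#'
#' @param cases A `case_set`.
#' @param tax The `cond_taxonomy` holding the rates.
#' @param seed Integer seed.
#' @return The thinned `case_set`.
#' @export
apply_subsampling <- function(cases, tax, seed = 1) {
  rate <- tax$subsample_rate[cases$info$true_condition]
  keep <- local_seed(derive_seed(seed, "subsample"),
                     stats::runif(n_cases(cases)) < rate)
  subset_cases(cases, keep)
}

# -- rater panel simulation --------------------------------------------------

# One simulated differential: data.frame(raw_label, condition, confidence).
# Top-1 is the true condition with probability rater_skill * exp(-0.25 *
# ambiguity); wrong picks fall mostly in the true category (plausible
# differentials). Occasional UNMAPPED entries and duplicate raw labels
# mapping to the same condition exercise the normalisation rules.
simulate_rater <- function(true_cond, ambiguity, tax, cat_members,
                           rater_skill) {
  p_top <- rater_skill * exp(-RATER_DECAY * ambiguity)
  m <- sample.int(5L, 1L, prob = c(0.15, 0.3, 0.3, 0.15, 0.1))
  true_cat <- tax$category_of[[true_cond]]
  members <- cat_members[[true_cat]]

  top <- if (stats::runif(1) < p_top) {
    true_cond
  } else if (stats::runif(1) < 0.75 && length(members) > 1L) {
    sample(setdiff(members, true_cond), 1L)
  } else {
    sample(tax$conditions, 1L)
  }
  rest <- character(0)
  if (m > 1L) {
    pool <- if (stats::runif(1) < 0.75) members else tax$conditions
    pool <- setdiff(pool, top)
    rest <- sample(pool, min(m - 1L, length(pool)))
  }
  conds <- c(top, rest)
  conf <- sort(sample(seq(1, 5, by = 0.5), length(conds), replace = TRUE),
               decreasing = TRUE)
  raw <- conds
  # duplicate-mapping label: a synonym of an already-listed condition
  if (stats::runif(1) < 0.05) {
    dup <- sample(seq_along(conds), 1L)
    raw <- c(raw, paste0(conds[dup], "~syn"))
    conds <- c(conds, conds[dup])
    conf <- c(conf, sample(seq(1, 5, by = 0.5), 1L))
  }
  if (stats::runif(1) < 0.05) {
    raw <- c(raw, "free-text finding")
    conds <- c(conds, "UNMAPPED")
    conf <- c(conf, sample(seq(1, 5, by = 0.5), 1L))
  }
  data.frame(raw_label = raw, condition = conds, confidence = conf,
             stringsAsFactors = FALSE)
}

#' Simulate a three-rater differential panel for one case
#'
#' Each of three independent raters emits 1-5 ranked diagnoses with
#' confidences in \[1, 5\]. The probability that a rater's top-1 equals the
#' true condition increases with `rater_skill` and decays with the case's
#' ambiguity (noise_scale times its per-case draw). Panels occasionally
#' contain unmappable labels (sentinel condition `"UNMAPPED"`) and duplicate
#' labels mapping to one condition.
#'
#' @param true_condition Condition code of the case.
#' @param ambiguity The case's ambiguity value (see [generate_cases]).
#' @param tax A `cond_taxonomy`.
#' @param rater_skill Skill in (0, 1].
#' @param seed Integer seed.
#' @return List of 3 differentials, each a data.frame with columns
#'   `raw_label`, `condition`, `confidence`.
#' @export
simulate_panel <- function(true_condition, ambiguity, tax, rater_skill = 0.9,
                           seed = 1) {
  if (!is.numeric(rater_skill) || rater_skill <= 0 || rater_skill > 1) {
    stopf("rater_skill must lie in (0, 1]")
  }
  if (!true_condition %in% tax$conditions) {
    stopf("case has no true condition in the taxonomy")
  }
  cat_members <- split(tax$conditions,
                       factor(tax$category_of, levels = tax$categories))
  local_seed(derive_seed(seed, paste0("panel", true_condition)), {
    lapply(1:3, function(r) {
      simulate_rater(true_condition, ambiguity, tax, cat_members, rater_skill)
    })
  })
}

#' Simulate rater panels for every case in a set
#'
#' @param cases A `case_set`.
#' @param tax A `cond_taxonomy`.
#' @param rater_skill Skill in (0, 1] shared by the three raters.
#' @param seed Integer seed.
#' @return The `case_set` with a `panel` element (list of 3-rater panels).
#' @export
simulate_panels <- function(cases, tax, rater_skill = 0.9, seed = 1) {
  if (!is.numeric(rater_skill) || rater_skill <= 0 || rater_skill > 1) {
    stopf("rater_skill must lie in (0, 1]")
  }
  cat_members <- split(tax$conditions,
                       factor(tax$category_of, levels = tax$categories))
  info <- cases$info
  cases$panel <- local_seed(derive_seed(seed, "panels"), {
    lapply(seq_len(nrow(info)), function(i) {
      lapply(1:3, function(r) {
        simulate_rater(info$true_condition[i], info$ambiguity[i], tax,
                       cat_members, rater_skill)
      })
    })
  })
  cases
}
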