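# Classifier on frozen synthetic embeddings: image pooling with a 6-image
# cap, one-hot metadata encoding, FiLM fusion, focal-loss training with Adam,
# and both end-to-end and head-only regimes.
#
# All maps are affine, so gradients are exact matrix expressions:
#   E_meta = X_meta M' + m0
#   alpha  = E_meta A' + a0,  beta = E_meta B' + b0
#   fused  = beta + alpha * E_image   (elementwise)
#   logits = fused W' + w0
# The loss is the mean focal loss over the batch.

#' Pool image embeddings for one case
#'
#' If a case has more than 6 images, 6 are selected uniformly without
#' replacement (seeded); the pooled embedding is the elementwise mean
#' (average-reduce) of the selected set.
#'
#' @param image_embeddings Matrix (images x d) or list of d-vectors.
#' @param seed Integer seed for the over-cap subsample.
#' @return Numeric vector of length d.
#' @export
pool_images <- function(image_embeddings, seed = 1) {
  if (is.list(image_embeddings)) {
    image_embeddings <- do.call(rbind, image_embeddings)
  }
  if (is.null(dim(image_embeddings))) {
    image_embeddings <- matrix(image_embeddings, nrow = 1L)
  }
  m <- nrow(image_embeddings)
  if (m == 0L) stopf("at least one image embedding is required")
  if (m > 6L) {
    pick <- local_seed(derive_seed(seed, "pool"), sample.int(m, 6L))
    image_embeddings <- image_embeddings[pick, , drop = FALSE]
  }
  colMeans(image_embeddings)
}

# Pooled embeddings for a whole case set, vectorised; cases over the 6-image
# cap are rare (<5%) and handled individually.
pooled_embeddings <- function(cases, seed = 1) {
  n <- n_cases(cases)
  out <- matrix(0, n, cases$d)
  over <- which(cases$info$n_images > 6L)
  seeds <- local_seed(derive_seed(seed, "poolset"),
                      sample.int(2147483646L, max(1L, length(over))))
  j <- 1L
  for (i in seq_len(n)) {
    e <- cases$embeddings[[i]]
    if (nrow(e) > 6L) {
      out[i, ] <- pool_images(e, seed = seeds[j])
      j <- j + 1L
    } else {
      out[i, ] <- colMeans(e)
    }
  }
  rownames(out) <- cases$info$case_id
  out
}

#' Apply metadata dropout
#'
#' Independently replaces each of the 25 categorical metadata fields with
#' `"unknown"` with probability `p` (training-time robustness to missing
#' metadata); age is untouched.
#'
#' @param metadata data.frame of categorical metadata fields.
#' @param p Replacement probability in \[0, 1\].
#' @param seed Integer seed.
#' @return The metadata data.frame with dropped fields set to `"unknown"`.
#' @export
apply_meta_dropout <- function(metadata, p = 0.25, seed = 1) {
  if (!is.numeric(p) || p < 0 || p > 1) stopf("p must lie in [0, 1]")
  if (p == 0) return(metadata)
  n <- nrow(metadata)
  local_seed(derive_seed(seed, "dropout"), {
    for (f in seq_along(metadata)) {
      hit <- stats::runif(n) < p
      metadata[[f]][hit] <- "unknown"
    }
  })
  metadata
}

# One-hot encode metadata (levels L1..L4 plus explicit unknown per field)
# concatenated with centred/scaled age. Returns n x (25*5 + 1).
encode_metadata <- function(metadata, age) {
  lvls <- c(paste0("L", seq_len(META_LEVELS)), "unknown")
  n <- nrow(metadata)
  blocks <- lapply(seq_along(metadata), function(f) {
    x <- matrix(0, n, length(lvls))
    m <- match(metadata[[f]], lvls)
    m[is.na(m)] <- length(lvls)
    x[cbind(seq_len(n), m)] <- 1
    x
  })
  cbind(do.call(cbind, blocks), (age - 50) / 25)
}

#' Focal loss
#'
#' `FL(p_t) = -alpha * (1 - p_t)^gamma * log(p_t)`, a scaled form of cross
#' entropy that down-weights easy examples; with `gamma = 0`, `alpha = 1` it
#' reduces to cross entropy.
#'
#' @param p_t Probability assigned to the true class, in (0, 1].
#' @param alpha Positive weighting factor.
#' @param gamma Nonnegative focusing exponent.
#' @return Nonnegative loss value(s).
#' @export
focal_loss <- function(p_t, alpha = 1, gamma = 0) {
  if (any(p_t <= 0)) stopf("p_t must be positive")
  if (alpha <= 0 || gamma < 0) stopf("alpha must be positive and gamma nonnegative")
  -alpha * (1 - p_t)^gamma * log(p_t)
}

#' FiLM fusion of an image embedding with metadata
#'
#' Feature-wise linear modulation: the metadata embedding is projected to a
#' scale and a shift and applied to the image embedding as
#' `beta(E_meta) + alpha(E_meta) * E_image` (elementwise product).
#'
#' @param e_image Image embedding vector (length d).
#' @param alpha,beta Scale and shift vectors of length d (already projected
#'   from the metadata embedding).
#' @return Fused embedding vector of length d.
#' @export
film_fuse <- function(e_image, alpha, beta) {
  if (length(alpha) != length(e_image) || length(beta) != length(e_image)) {
    stopf("alpha/beta dimension must equal the image embedding dimension")
  }
  beta + alpha * e_image
}

#' Loss and optimiser configuration
#'
#' @param focal_alpha Focal-loss weight (default 1).
#' @param focal_gamma Focal-loss focusing exponent (default 2).
#' @param meta_dropout_p Training-time metadata dropout probability
#'   (default 0.25).
#' @param train_steps Number of full-batch Adam steps (default 300).
#' @param learning_rate Constant Adam learning rate (default 0.1).
#' @param weight_decay Decoupled L2 weight decay per step (default 2e-3);
#'   regularises the bilinear FiLM interaction, which otherwise overfits
#'   small or heavily-duplicated training sets.
#' @param seed Integer seed for initialisation, dropout and pooling.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(focal_alpha = 1, focal_gamma = 2,
                        meta_dropout_p = 0.25, train_steps = 300,
                        learning_rate = 0.1, weight_decay = 2e-3, seed = 1) {
  if (meta_dropout_p < 0 || meta_dropout_p > 1) {
    stopf("meta_dropout_p must lie in [0, 1]")
  }
  structure(list(focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 meta_dropout_p = meta_dropout_p,
                 train_steps = as.integer(train_steps),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "loss_config")
}

#' Initialise a classifier model
#'
#' @param tax A `cond_taxonomy` (fixes the C-way output).
#' @param d Image-embedding dimension.
#' @param d_meta Metadata-embedding dimension (default 32).
#' @param use_metadata Logical; `FALSE` gives an image-only model (fused
#'   embedding = pooled image embedding, no FiLM).
#' @param seed Integer seed for the random initialisation.
#' @return An object of class `shift_classifier`.
#' @export
new_classifier <- function(tax, d, d_meta = 32, use_metadata = TRUE, seed = 1) {
  p_meta <- N_META_FIELDS * (META_LEVELS + 1L) + 1L
  C <- length(tax$conditions)
  local_seed(derive_seed(seed, "init"), {
    rn <- function(r, c, s) matrix(stats::rnorm(r * c, sd = s), r, c)
    par <- list(
      M = rn(d_meta, p_meta, 0.1), m0 = rep(0, d_meta),
      A = rn(d, d_meta, 0.05), a0 = rep(1, d),  # start near identity FiLM
      B = rn(d, d_meta, 0.05), b0 = rep(0, d),
      W = rn(C, d, 0.01), w0 = rep(0, C)
    )
    structure(list(par = par, d = as.integer(d), d_meta = as.integer(d_meta),
                   use_metadata = isTRUE(use_metadata),
                   conditions = tax$conditions, trained = FALSE),
              class = "shift_classifier")
  })
}

#' @export
print.shift_classifier <- function(x, ...) {
  cat(sprintf("<shift_classifier> %d conditions, d = %d, d_meta = %d, %s%s\n",
              length(x$conditions), x$d, x$d_meta,
              if (x$use_metadata) "FiLM-fused" else "image-only",
              if (x$trained) ", trained" else ""))
  invisible(x)
}

# Forward pass on precomputed features; returns logits plus intermediates.
forward_pass <- function(par, E_img, X_meta, use_metadata) {
  if (use_metadata) {
    E_meta <- X_meta %*% t(par$M)
    E_meta <- sweep(E_meta, 2L, par$m0, "+")
    alpha <- sweep(E_meta %*% t(par$A), 2L, par$a0, "+")
    beta <- sweep(E_meta %*% t(par$B), 2L, par$b0, "+")
    fused <- beta + alpha * E_img
  } else {
    E_meta <- alpha <- beta <- NULL
    fused <- E_img
  }
  logits <- sweep(fused %*% t(par$W), 2L, par$w0, "+")
  list(logits = logits, fused = fused, E_meta = E_meta, alpha = alpha)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train a classifier
#'
#' Minimises the mean focal loss with full-batch Adam at a constant learning
#' rate. In `"end_to_end"` mode every parameter (metadata encoder, FiLM
#' projections, head) is trained; in `"head_only"` mode the encoders and
#' FiLM projections are frozen at their current values and only the final
#' classification layer moves. Metadata dropout is re-drawn every step.
#' Training is deterministic given `cfg$seed`.
#'
#' @param cases A `case_set`.
#' @param labels Character vector of true condition codes (training labels).
#' @param model A `shift_classifier` (for `"head_only"`, typically an
#'   already-trained model being adapted).
#' @param cfg A [loss_config].
#' @param mode `"end_to_end"` or `"head_only"`.
#' @return The fitted `shift_classifier` (with a `history` of losses).
#' @export
train_classifier <- function(cases, labels, model,
                             cfg = loss_config(),
                             mode = c("end_to_end", "head_only")) {
  mode <- match.arg(mode)
  n <- n_cases(cases)
  if (n == 0L) stopf("training set is empty")
  if (length(labels) != n) stopf("labels must align with cases")
  t_idx <- match(labels, model$conditions)
  if (anyNA(t_idx)) stopf("labels must be conditions of the model's taxonomy")

  E_img <- pooled_embeddings(cases, seed = derive_seed(cfg$seed, "trainpool"))
  X_meta_clean <- encode_metadata(cases$metadata, cases$info$age)
  par <- model$par
  head_only <- mode == "head_only"
  trainable <- if (head_only) c("W", "w0") else names(par)

  adam_m <- lapply(par[trainable], function(x) x * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  a_f <- cfg$focal_alpha; g_f <- cfg$focal_gamma
  history <- numeric(cfg$train_steps)
  ii <- seq_len(n)

  local_seed(derive_seed(cfg$seed, "train"), {
    for (step in seq_len(cfg$train_steps)) {
      X_meta <- X_meta_clean
      if (model$use_metadata && cfg$meta_dropout_p > 0) {
        for (f in seq_len(N_META_FIELDS)) {
          hit <- stats::runif(n) < cfg$meta_dropout_p
          if (any(hit)) {
            cols <- ((f - 1L) * (META_LEVELS + 1L) + 1L):(f * (META_LEVELS + 1L))
            X_meta[hit, cols] <- 0
            X_meta[hit, cols[META_LEVELS + 1L]] <- 1
          }
        }
      }
      fw <- forward_pass(par, E_img, X_meta, model$use_metadata)
      P <- softmax_rows(fw$logits)
      p_t <- pmax(P[cbind(ii, t_idx)], 1e-12)
      u <- 1 - p_t
      history[step] <- mean(-a_f * u^g_f * log(p_t))

      # dL/dz_j = c_i * (delta_tj - p_j) with c_i = p_t * dL/dp_t
      dLdp <- a_f * (g_f * u^pmax(g_f - 1, 0) * log(p_t) - u^g_f / p_t)
      if (g_f == 0) dLdp <- -a_f / p_t
      ci <- dLdp * p_t / n
      dZ <- P * (-ci)
      dZ[cbind(ii, t_idx)] <- dZ[cbind(ii, t_idx)] + ci

      grad <- list(W = t(dZ) %*% fw$fused, w0 = colSums(dZ))
      if (!head_only && model$use_metadata) {
        dF <- dZ %*% par$W
        dAlpha <- dF * E_img
        dBeta <- dF
        dEm <- dAlpha %*% par$A + dBeta %*% par$B
        grad$A <- t(dAlpha) %*% fw$E_meta; grad$a0 <- colSums(dAlpha)
        grad$B <- t(dBeta) %*% fw$E_meta; grad$b0 <- colSums(dBeta)
        grad$M <- t(dEm) %*% X_meta; grad$m0 <- colSums(dEm)
      }
      wd <- cfg$weight_decay %||% 0
      for (nm in trainable) {
        if (is.null(grad[[nm]])) next
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grad[[nm]]
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grad[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1^step)
        vhat <- adam_v[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + wd * par[[nm]])
      }
    }
  })
  model$par <- par
  model$trained <- TRUE
  model$history <- history
  model$cfg <- cfg
  model
}

#' Predict condition scores
#'
#' Softmax probability vectors over the full taxonomy, one row per case
#' (each summing to 1). The pre-softmax logits are attached as the
#' `"logits"` attribute for temperature recalibration.
#'
#' @param cases A `case_set`.
#' @param model A fitted `shift_classifier`.
#' @param seed Integer seed for over-cap image pooling.
#' @return Matrix n x C of probabilities, rownames case ids, colnames
#'   condition codes, with attribute `"logits"`.
#' @export
predict_scores <- function(cases, model, seed = 1) {
  E_img <- pooled_embeddings(cases, seed = derive_seed(seed, "predpool"))
  X_meta <- if (model$use_metadata) {
    encode_metadata(cases$metadata, cases$info$age)
  } else NULL
  fw <- forward_pass(model$par, E_img, X_meta, model$use_metadata)
  logits <- fw$logits
  dimnames(logits) <- list(cases$info$case_id, model$conditions)
  P <- softmax_rows(logits)
  dimnames(P) <- dimnames(logits)
  attr(P, "logits") <- logits
  P
}
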