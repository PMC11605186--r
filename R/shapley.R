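#' Exact Shapley values by subset enumeration
#'
#' Computes, for every feature i, the exact Shapley value
#' `phi_i = sum over S not containing i of |S|! (F-|S|-1)! / F! *
#' (v(S + i) - v(S))`, where the value of a coalition S is the model output
#' with the features outside S replaced by background-row values, averaged
#' over the background set. All `2^F` coalition values are evaluated once
#' and reused across features, so the budget is `2^F * B` model
#' evaluations.
#'
#' @param value_fn function taking a numeric matrix (rows = inputs over the
#'   F features) and returning one model output per row.
#' @param x numeric vector of length F, the input being explained.
#' @param background B x F matrix of reference rows (training-split draws).
#' @param max_features complexity guard; exact mode refuses larger F.
#' @param chunk_size maximum rows per `value_fn` call.
#' @return list(phi, f_x = v(full set), background_value = v(empty set)).
#' @export
exact_shapley <- function(value_fn, x, background, max_features = 15L,
                          chunk_size = 50000L) {
  if (is.vector(background)) background <- matrix(background, nrow = 1L)
  f <- length(x)
  if (f > max_features)
    ecn_stop(sprintf(
      "exact Shapley enumerates 2^%d coalitions; use sampled_shapley()", f),
      "complexity_error")
  stopifnot(ncol(background) == f)
  b <- nrow(background)
  n_masks <- 2L^f
  masks <- 0:(n_masks - 1L)
  bits <- vapply(seq_len(f), function(i) bitwAnd(masks, 2L^(i - 1L)) > 0L,
                 logical(n_masks))
  pop <- rowSums(bits)
  # coalition values, chunked over masks
  v <- numeric(n_masks)
  masks_per_chunk <- max(1L, chunk_size %/% b)
  for (start in seq(1L, n_masks, by = masks_per_chunk)) {
    mi <- start:min(start + masks_per_chunk - 1L, n_masks)
    nm <- length(mi)
    Z <- background[rep(seq_len(b), nm), , drop = FALSE]
    for (i in seq_len(f)) {
      rows <- rep(bits[mi, i], each = b)
      if (any(rows)) Z[rows, i] <- x[i]
    }
    out <- value_fn(Z)
    v[mi] <- colMeans(matrix(out, nrow = b))
  }
  # Shapley weights by coalition size
  w <- exp(lgamma(0:(f - 1L) + 1) + lgamma(f - (0:(f - 1L))) - lgamma(f + 1))
  phi <- numeric(f)
  for (i in seq_len(f)) {
    no_i <- !bits[, i]
    s_masks <- masks[no_i]
    phi[i] <- sum(w[pop[no_i] + 1L] *
                    (v[s_masks + 2L^(i - 1L) + 1L] - v[s_masks + 1L]))
  }
  list(phi = phi, f_x = v[n_masks], background_value = v[1L])
}

#' Sampled Shapley values by permutation averaging
#'
#' Castro-style estimator: for each random feature ordering, features are
#' switched from their background values to the explained input one at a
#' time, and each feature is credited with its marginal change in the
#' coalition value. The estimate is the average over orderings; the same
#' masking rule as [exact_shapley()] is used, so the estimator converges to
#' the exact values. Each permutation's contributions telescope, so the
#' efficiency identity holds for the estimate as well.
#'
#' @param value_fn,x,background as in [exact_shapley()].
#' @param n_permutations number of sampled orderings (>= 1).
#' @param seed integer seed.
#' @return list(phi, f_x, background_value).
#' @export
sampled_shapley <- function(value_fn, x, background, n_permutations = 2000L,
                            seed = 1L) {
  if (n_permutations < 1L)
    ecn_stop("n_permutations must be >= 1", "contract_violation")
  if (is.vector(background)) background <- matrix(background, nrow = 1L)
  f <- length(x)
  b <- nrow(background)
  set.seed(stage_seed(seed, "shapley"))
  phi <- numeric(f)
  v0 <- NA_real_; vfull <- NA_real_
  for (r in seq_len(n_permutations)) {
    ord <- sample.int(f)
    # rows grouped by prefix length 0..f; prefix j has ord[1..j] set to x
    Z <- background[rep(seq_len(b), f + 1L), , drop = FALSE]
    for (j in seq_len(f)) {
      rows <- (j * b + 1L):((f + 1L) * b)
      Z[rows, ord[j]] <- x[ord[j]]
    }
    vp <- colMeans(matrix(value_fn(Z), nrow = b))
    phi[ord] <- phi[ord] + diff(vp)
    v0 <- vp[1L]; vfull <- vp[f + 1L]
  }
  list(phi = phi / n_permutations, f_x = vfull, background_value = v0)
}

#' Rank features by mean absolute Shapley value
#'
#' @param phi N x F matrix of per-sample Shapley values (columns named by
#'   feature).
#' @return list(mean_abs = named vector, ranking = feature names in
#'   descending mean |phi|, ties broken by column/schema order).
#' @export
rank_features <- function(phi) {
  if (!nrow(phi)) ecn_stop("phi must be nonempty", "contract_violation")
  mean_abs <- colMeans(abs(phi))
  ord <- order(-mean_abs, seq_along(mean_abs))
  nms <- colnames(phi) %||% as.character(seq_len(ncol(phi)))
  list(mean_abs = stats::setNames(mean_abs, nms), ranking = nms[ord])
}

#' Long-format table for beeswarm-style attribution plots
#'
#' One row per (sample, feature) with the Shapley value, the raw feature
#' value and a per-feature color rank in \[0,1\] (the normalized rank of
#' the feature value), plus a per-feature sign summary: the Pearson
#' correlation between feature value and Shapley value, positive when high
#' feature values push the prediction toward the positive class.
#'
#' @param phi N x F Shapley matrix.
#' @param feature_values N x F matrix of raw (unnormalized) feature values.
#' @return list(table = long data.frame(site, feature, phi, value,
#'   color_rank), sign_summary = data.frame(feature, sign_cor)).
#' @export
export_beeswarm_table <- function(phi, feature_values) {
  stopifnot(all(dim(phi) == dim(feature_values)))
  n <- nrow(phi); f <- ncol(phi)
  nms <- colnames(phi) %||% as.character(seq_len(f))
  color_rank <- apply(feature_values, 2L, function(v) {
    if (n == 1L) return(0.5)
    (rank(v, ties.method = "average") - 1) / (n - 1)
  })
  tab <- data.frame(
    site = rep(rownames(phi) %||% as.character(seq_len(n)), times = f),
    feature = rep(nms, each = n),
    phi = as.vector(phi),
    value = as.vector(feature_values),
    color_rank = as.vector(color_rank),
    stringsAsFactors = FALSE
  )
  sign_cor <- vapply(seq_len(f), function(j) {
    if (stats::sd(feature_values[, j]) == 0 || stats::sd(phi[, j]) == 0)
      return(0)
    stats::cor(feature_values[, j], phi[, j])
  }, numeric(1))
  list(table = tab,
       sign_summary = data.frame(feature = nms, sign_cor = sign_cor,
                                 stringsAsFactors = FALSE))
}

#' Attribute a trained model over the genomic features
#'
#' Computes per-sample Shapley values for the 52 genomic features with the
#' sequence block held at each sample's observed one-hot encoding (set
#' `whole_input = TRUE` to attribute over the full input instead). The
#' background set is drawn from the training split. Sampled mode is the
#' default; exact mode is only feasible for submodels within the
#' enumeration guard.
#'
#' @param trained a `trained_model` (integrated or genomic-only mode).
#' @param dataset the `encoded_dataset` it was trained on.
#' @param split which split to explain (default "test").
#' @param mode "sampled" or "exact".
#' @param n_permutations permutations per sample in sampled mode.
#' @param background_size rows drawn from the training split.
#' @param n_samples optional cap on explained samples (first n of split).
#' @param whole_input attribute sequence + genomic jointly when TRUE.
#' @param seed integer seed.
#' @return An `attribution_report`: list(site_ids, feature_names, phi,
#'   background_value, f_x, mean_abs, ranking, sign_summary, meta).
#' @export
attribute_model <- function(trained, dataset, split = "test",
                            mode = c("sampled", "exact"),
                            n_permutations = 20L, background_size = 100L,
                            n_samples = NULL, whole_input = FALSE,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (!trained$mode %in% c("integrated", "genomic_only"))
    ecn_stop("attribution expects an integrated or genomic-only model",
             "contract_violation")
  idx <- which(dataset$split == split)
  if (!is.null(n_samples)) idx <- idx[seq_len(min(n_samples, length(idx)))]
  tr_idx <- which(dataset$split == "train")
  set.seed(stage_seed(seed, "background"))
  bg_idx <- sample(tr_idx, min(background_size, length(tr_idx)))
  fn <- colnames(dataset$genomic) %||%
    paste0("g", seq_len(ncol(dataset$genomic)))
  n <- length(idx)
  f <- if (whole_input && trained$mode == "integrated")
    ncol(dataset$one_hot) + ncol(dataset$genomic) else ncol(dataset$genomic)
  phi <- matrix(0, n, f)
  bgv <- numeric(n); fx <- numeric(n)
  for (s in seq_len(n)) {
    i <- idx[s]
    if (trained$mode == "genomic_only") {
      value_fn <- function(G) dcn_predict(trained$model, G)
      x <- dataset$genomic[i, ]
      bg <- dataset$genomic[bg_idx, , drop = FALSE]
    } else if (whole_input) {
      value_fn <- function(Z) dcn_predict(trained$model, Z)
      x <- c(dataset$one_hot[i, ], dataset$genomic[i, ])
      bg <- cbind(dataset$one_hot, dataset$genomic)[bg_idx, , drop = FALSE]
    } else {
      oh_i <- dataset$one_hot[i, ]
      value_fn <- function(G) {
        dcn_predict(trained$model,
                    cbind(matrix(oh_i, nrow(G), length(oh_i), byrow = TRUE), G))
      }
      x <- dataset$genomic[i, ]
      bg <- dataset$genomic[bg_idx, , drop = FALSE]
    }
    res <- if (mode == "exact") exact_shapley(value_fn, x, bg)
           else sampled_shapley(value_fn, x, bg, n_permutations,
                                seed = stage_seed(seed, paste0("sample", s)))
    phi[s, ] <- res$phi
    bgv[s] <- res$background_value
    fx[s] <- res$f_x
  }
  colnames(phi) <- if (f == length(fn)) fn else c(
    colnames(dataset$one_hot) %||% paste0("s", seq_len(f - length(fn))), fn)
  rownames(phi) <- dataset$site_ids[idx] %||% as.character(idx)
  rk <- rank_features(phi)
  bs <- export_beeswarm_table(
    phi, if (trained$mode == "genomic_only" || !whole_input)
      dataset$genomic[idx, , drop = FALSE]
    else cbind(dataset$one_hot, dataset$genomic)[idx, , drop = FALSE])
  structure(list(site_ids = rownames(phi), feature_names = colnames(phi),
                 phi = phi, background_value = bgv, f_x = fx,
                 mean_abs = rk$mean_abs, ranking = rk$ranking,
                 sign_summary = bs$sign_summary,
                 meta = list(mode = mode, split = split,
                             n_permutations = n_permutations,
                             background_size = length(bg_idx), seed = seed)),
            class = "attribution_report")
}
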