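#' One-hot encode a 41-nt window
#'
#' Maps each base to the row A=\[1,0,0,0\], C=\[0,1,0,0\], G=\[0,0,1,0\],
#' U=\[0,0,0,1\]; T is treated as U and N becomes an all-zero row.
#'
#' @param window 41-character string over A/C/G/U/T/N.
#' @return A 41 x 4 binary matrix with columns A, C, G, U.
#' @export
one_hot_window <- function(window) {
  if (!is.character(window) || length(window) != 1L || nchar(window) != 41L)
    ecn_stop("window must be a single 41-character string",
             "contract_violation")
  chars <- strsplit(toupper(window), "")[[1]]
  chars[chars == "T"] <- "U"
  bad <- !chars %in% c(.rna_bases, "N")
  if (any(bad))
    ecn_stop(sprintf("invalid character(s) in window: %s",
                     paste(unique(chars[bad]), collapse = ",")),
             "contract_violation")
  m <- matrix(0L, nrow = 41L, ncol = 4L,
              dimnames = list(NULL, .rna_bases))
  idx <- match(chars, .rna_bases) # NA for N -> all-zero row
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1L
  m
}

#' Decode a one-hot matrix back to a window string
#'
#' @param mat 41 x 4 binary matrix as produced by [one_hot_window()];
#'   all-zero rows decode to N.
#' @return 41-character string.
#' @export
decode_window <- function(mat) {
  stopifnot(ncol(mat) == 4L)
  idx <- apply(mat, 1L, function(r) {
    w <- which(r == 1L)
    if (length(w) == 1L) w else NA_integer_
  })
  paste(ifelse(is.na(idx), "N", .rna_bases[idx]), collapse = "")
}

#' Stack one-hot windows into a flattened matrix
#'
#' Encodes every window and flattens position-major (columns are
#' pos1:A,C,G,U, pos2:A,C,G,U, ...), the layout assumed by the models.
#'
#' @param windows character vector of 41-nt windows.
#' @return N x 164 binary matrix.
#' @export
one_hot_matrix <- function(windows) {
  out <- matrix(0L, nrow = length(windows), ncol = 41L * 4L)
  for (i in seq_along(windows)) {
    out[i, ] <- as.integer(t(one_hot_window(windows[i])))
  }
  colnames(out) <- paste0("pos", rep(seq_len(41L), each = 4L), "_",
                          rep(.rna_bases, 41L))
  out
}

#' Metagene relative position
#'
#' The distance of a site to the 5' end of a region divided by the region
#' length, giving a fraction in \[0,1\] (0 = 5' end, 1 = 3' end).
#'
#' @param distance_to_5prime nonnegative integer distance in nt.
#' @param total_length positive region length in nt.
#' @return fraction in \[0,1\].
#' @export
relative_position <- function(distance_to_5prime, total_length) {
  if (any(total_length <= 0))
    ecn_stop("region length must be positive", "contract_violation")
  if (any(distance_to_5prime < 0 | distance_to_5prime > total_length))
    ecn_stop("distance must lie within [0, total_length]",
             "contract_violation")
  distance_to_5prime / total_length
}

#' Z-score continuous features using training-split statistics
#'
#' Continuous features (kinds count/fraction/score) are centered and scaled
#' by the mean and standard deviation of the training rows only; binary
#' features pass through untouched. Zero-variance features map to all
#' zeros with a warning.
#'
#' @param features a `feature_matrix`.
#' @param train_idx integer indices of the training rows used to fit the
#'   statistics; defaults to all rows.
#' @return The `feature_matrix` with normalized `values` and populated
#'   `normalization_stats` (per-feature mean/sd).
#' @export
normalize_features <- function(features, train_idx = seq_len(nrow(features$values))) {
  vals <- features$values
  sch <- features$schema
  mu <- rep(0, ncol(vals)); sdv <- rep(1, ncol(vals))
  cont <- sch$kind != "binary"
  for (j in which(cont)) {
    m <- mean(vals[train_idx, j])
    s <- stats::sd(vals[train_idx, j])
    if (!is.finite(s) || s == 0) {
      warning(sprintf("feature '%s' has zero variance on the training split; mapped to 0",
                      sch$name[j]))
      vals[, j] <- 0
      mu[j] <- m; sdv[j] <- 0
    } else {
      vals[, j] <- (vals[, j] - m) / s
      mu[j] <- m; sdv[j] <- s
    }
  }
  out <- features
  out$values <- vals
  out$normalization_stats <- data.frame(name = sch$name, mean = mu, sd = sdv,
                                        stringsAsFactors = FALSE)
  out
}

#' Assemble an encoded dataset with a stratified 8:1:1 split
#'
#' Combines the flattened one-hot block, the genomic feature block and the
#' labels, and assigns every sample to train/val/test in an 8:1:1 ratio,
#' stratified by class so the label ratio is preserved per split (within
#' one sample of rounding). Deterministic under `seed`.
#'
#' @param one_hot N x 164 binary matrix.
#' @param genomic N x 52 numeric matrix.
#' @param labels binary vector of length N.
#' @param seed integer seed.
#' @param site_ids optional character ids carried through.
#' @return An `encoded_dataset`: list(one_hot, genomic, labels, split
#'   (factor train/val/test), site_ids, seed).
#' @export
assemble_dataset <- function(one_hot, genomic, labels, seed = 1L,
                             site_ids = NULL) {
  n <- length(labels)
  if (nrow(one_hot) != n || nrow(genomic) != n)
    ecn_stop("one_hot, genomic and labels must share N", "contract_violation")
  if (n < 10L)
    ecn_stop("need at least 10 samples for an 8:1:1 split", "split_error")
  if (!all(labels %in% c(0L, 1L)))
    ecn_stop("labels must be binary", "contract_violation")
  set.seed(stage_seed(seed, "split"))
  split <- character(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    m <- length(idx)
    n_test <- round(m / 10)
    n_val <- round(m / 10)
    split[idx[seq_len(n_test)]] <- "test"
    split[idx[n_test + seq_len(n_val)]] <- "val"
    split[idx[(n_test + n_val + 1):m]] <- "train"
  }
  structure(list(one_hot = one_hot, genomic = genomic,
                 labels = as.integer(labels),
                 split = factor(split, levels = c("train", "val", "test")),
                 site_ids = site_ids, seed = as.integer(seed)),
            class = "encoded_dataset")
}

#' Build an encoded dataset from a catalog, features and a labeled set
#'
#' Convenience constructor for the standard path: subsets the catalog to
#' the labeled sites, one-hot encodes their windows, normalizes genomic
#' features on the training split and returns the assembled dataset.
#'
#' @param catalog a `site_catalog`.
#' @param features a `feature_matrix` aligned with the catalog.
#' @param labeled a `labeled_site_set`.
#' @param seed split seed.
#' @return An `encoded_dataset` with normalized genomic block.
#' @export
encode_labeled_dataset <- function(catalog, features, labeled, seed = 1L) {
  ids <- c(labeled$positives, labeled$negatives)
  labels <- c(rep(1L, length(labeled$positives)),
              rep(0L, length(labeled$negatives)))
  idx <- match(ids, catalog$sites$site_id)
  if (anyNA(idx))
    ecn_stop("labeled set contains site ids missing from the catalog",
             "contract_violation")
  oh <- one_hot_matrix(catalog$sites$window_seq[idx])
  fidx <- match(ids, features$site_ids)
  fsub <- features
  fsub$site_ids <- ids
  fsub$values <- features$values[fidx, , drop = FALSE]
  ds <- assemble_dataset(oh, fsub$values, labels, seed = seed, site_ids = ids)
  fnorm <- fsub
  fnorm$values <- ds$genomic
  fnorm <- normalize_features(fnorm, train_idx = which(ds$split == "train"))
  ds$genomic <- fnorm$values
  ds$normalization_stats <- fnorm$normalization_stats
  ds$schema <- features$schema
  ds
}
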