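# Gaussian naive Bayes ranking of candidate shapes.
#
# The user annotates candidate shapes as valid nuclei or invalid
# (internuclear gaps, merged pairs, noise); per-feature Gaussians per
# class plus class priors are enough to rank candidates, and the model
# round-trips through a plain TSV so it can be reused across images.

#' Train the shape classifier
#'
#' @param training_table data.frame of feature columns (see
#'   `FEATURE_NAMES`) plus a `label` column with values `"valid"` /
#'   `"invalid"`; at least 2 examples per class.
#' @param variance_floor per-feature variance floor, expressed as a
#'   fraction of the observed feature range (squared); guards against
#'   near-constant features in small training sets.
#' @return object of class `TrainedClassifier` with per-class means,
#'   variances, log-priors, feature names and resubstitution accuracy.
#' @export
train_classifier <- function(training_table, variance_floor = 1e-6) {
  stopifnot(is.data.frame(training_table), "label" %in% names(training_table))
  feats <- setdiff(names(training_table), "label")
  lab <- training_table$label
  classes <- c("valid", "invalid")
  if (!all(lab %in% classes))
    stopf("nucridge_bad_training", "labels must be 'valid' or 'invalid'")
  n_by <- table(factor(lab, classes))
  if (any(n_by < 2L))
    stopf("nucridge_bad_training", "need >= 2 examples per class (got %s)",
          paste(n_by, collapse = "/"))
  X <- as.matrix(training_table[feats])
  rng <- apply(X, 2L, function(v) diff(range(v)))
  # relative floor; a feature constant across training carries no
  # information and gets a huge variance so it cannot dominate
  floor_var <- ifelse(rng > 0, pmax(variance_floor * rng^2, 1e-300), 1e6)
  mu <- s2 <- matrix(0, 2L, length(feats), dimnames = list(classes, feats))
  for (ci in 1:2) {
    Xi <- X[lab == classes[ci], , drop = FALSE]
    mu[ci, ] <- colMeans(Xi)
    s2[ci, ] <- pmax(apply(Xi, 2L, stats::var), floor_var)
  }
  cl <- structure(list(features = feats, mu = mu, s2 = s2,
                       log_prior = log(as.numeric(n_by) / sum(n_by)),
                       n_train = as.integer(n_by)),
                  class = "TrainedClassifier")
  post <- apply(X, 1L, function(x) predict_valid(cl, x))
  cl$resubstitution_accuracy <-
    mean((post > 0.5) == (lab == "valid"))
  cl
}

#' Posterior probability that a feature vector is a valid nucleus shape
#'
#' @param classifier a [train_classifier()] model.
#' @param features named numeric vector covering the model's features.
#' @return P(valid | features) in `[0, 1]`.
#' @export
predict_valid <- function(classifier, features) {
  x <- as.numeric(features[classifier$features])
  ll <- numeric(2L)
  for (ci in 1:2) {
    ll[ci] <- classifier$log_prior[ci] +
      sum(stats::dnorm(x, classifier$mu[ci, ], sqrt(classifier$s2[ci, ]), log = TRUE))
  }
  m <- max(ll)
  exp(ll[1L] - m) / sum(exp(ll - m))
}

#' Serialise / load a trained classifier as TSV
#'
#' One row per feature with per-class mean and variance; priors and
#' training counts in a header comment. [read_classifier()] inverts
#' [write_classifier()] exactly.
#'
#' @param classifier a `TrainedClassifier`.
#' @param path TSV file.
#' @return `path` / a `TrainedClassifier`.
#' @export
write_classifier <- function(classifier, path) {
  df <- data.frame(feature = classifier$features,
                   mu_valid = classifier$mu["valid", ],
                   var_valid = classifier$s2["valid", ],
                   mu_invalid = classifier$mu["invalid", ],
                   var_invalid = classifier$s2["invalid", ])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# prior_valid=%.17g prior_invalid=%.17g n_valid=%d n_invalid=%d",
                     exp(classifier$log_prior[1L]), exp(classifier$log_prior[2L]),
                     classifier$n_train[1L], classifier$n_train[2L]), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  if (!file.exists(path)) stopf("nucridge_missing_file", "no such file: %s", path)
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.eE+]+", hdr))[[1]]
  vals <- as.numeric(sub("^[a-z_]+=", "", kv))
  names(vals) <- sub("=.*$", "", kv)
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  feats <- df$feature
  mu <- rbind(valid = df$mu_valid, invalid = df$mu_invalid)
  s2 <- rbind(valid = df$var_valid, invalid = df$var_invalid)
  colnames(mu) <- colnames(s2) <- feats
  structure(list(features = feats, mu = mu, s2 = s2,
                 log_prior = log(unname(vals[c("prior_valid", "prior_invalid")])),
                 n_train = as.integer(vals[c("n_valid", "n_invalid")])),
            class = "TrainedClassifier")
}

#' Build a training table from an intensity image and reference labels
#'
#' Runs the per-plane shape-candidate stages on the intensity volume and
#' labels every candidate by its Jaccard overlap with the reference 2D
#' areas: candidates matching a reference area (JI >= `ji_valid`) become
#' `valid` rows, candidates matching nothing (JI <= `ji_invalid`) become
#' `invalid` rows, and ambiguous candidates are dropped. This is how a
#' training set is bootstrapped from a small annotated (or synthetic)
#' image without an interactive painter.
#'
#' @param intensity an [intensity_volume()].
#' @param labels a [label_volume()] of reference instances.
#' @param params a [seg_params()].
#' @param n_per_class rows kept per class (highest/lowest JI first);
#'   `Inf` keeps everything.
#' @param ji_valid,ji_invalid JI cuts for the two labels.
#' @param planes optional subset of plane indices to scan.
#' @param augment_invalid when the scan yields fewer invalid candidates
#'   than `n_per_class` (sparse scenes produce almost none), valid
#'   contours are translated onto off-nucleus positions and re-measured
#'   there, giving genuine non-nucleus feature rows.
#' @return data.frame of feature columns plus `label`.
#' @export
make_training_table <- function(intensity, labels, params,
                                n_per_class = 20L,
                                ji_valid = 0.7, ji_invalid = 0.3,
                                planes = NULL, augment_invalid = TRUE) {
  nx <- intensity$shape[1]; ny <- intensity$shape[2]; nz <- intensity$shape[3]
  if (is.null(planes)) planes <- seq_len(nz)
  rows <- list(); jis <- numeric(0); labs <- character(0)
  wv <- working_volume(intensity, params)   # image the detector measures on
  iscale <- 1 / (2^intensity$bit_depth - 1)
  for (z in planes) {
    plane <- get_plane(intensity, z)
    fplane <- get_plane(wv, z) * iscale
    lab <- labels$data[, , z]
    ids <- setdiff(unique(as.vector(lab)), 0L)
    if (!length(ids)) next
    ref <- lapply(ids, function(id) which(lab == id))
    cands <- plane_candidates(plane, params, nx, ny,
                              plane_lo = get_plane(intensity, max(1L, z - 1L)),
                              plane_hi = get_plane(intensity, min(nz, z + 1L)),
                              iscale = 1 / (2^intensity$bit_depth - 1))
    best_ji <- function(px) {
      best <- 0
      for (rpx in ref) {
        inter <- length(intersect(px, rpx))
        if (inter > 0L)
          best <- max(best, inter / (length(px) + length(rpx) - inter))
      }
      best
    }
    for (cd in cands) {
      best <- best_ji(c(cd$outline, cd$interior))
      lb <- if (best >= ji_valid) "valid" else if (best <= ji_invalid) "invalid" else NA
      if (is.na(lb)) next
      rows[[length(rows) + 1L]] <- cd$features
      jis <- c(jis, best); labs <- c(labs, lb)
      if (augment_invalid && lb == "valid") {
        # the same contour measured away from any nucleus is an
        # off-target example of what the classifier must reject
        w <- diff(range(cd$contour[, 1L])) + 4L
        for (sh in list(c(w, 0L), c(-w, 0L), c(0L, w))) {
          ctr2 <- cbind(cd$contour[, 1L] + sh[1L], cd$contour[, 2L] + sh[2L])
          if (!all(in_bounds(ctr2, nx, ny))) next
          ras <- rasterize(ctr2, nx, ny)
          if (is.null(ras) || length(ras$interior) < 4L) next
          if (best_ji(c(ras$outline, ras$interior)) > ji_invalid) next
          sh_cd <- c(list(contour = ctr2), ras)
          rows[[length(rows) + 1L]] <- compute_features(sh_cd, fplane)
          jis <- c(jis, 0); labs <- c(labs, "invalid")
          break
        }
      }
    }
  }
  if (!length(rows)) stopf("nucridge_bad_training", "no usable candidates found")
  tab <- as.data.frame(do.call(rbind, rows))
  tab$label <- labs
  if (is.finite(n_per_class)) {
    keep <- integer(0)
    iv <- which(labs == "valid"); ii <- which(labs == "invalid")
    keep <- c(iv[order(-jis[iv])][seq_len(min(n_per_class, length(iv)))],
              ii[order(jis[ii])][seq_len(min(n_per_class, length(ii)))])
    tab <- tab[sort(keep), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}
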