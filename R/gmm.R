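#' Fit per-class Gaussian mixture models for activity recognition
#'
#' Fits one diagonal-covariance Gaussian mixture per activity class by
#' expectation-maximization, initialized with a seeded k-means pass, and
#' stores empirical class priors. Classification is the arg-max of the
#' prior-weighted class likelihood, with ties broken in the fixed class
#' order stationary < walking < running < driving.
#'
#' Training rows are canonically ordered (lexicographically by feature
#' value) before initialization, so the fitted model is invariant to the
#' order in which examples are supplied.
#'
#' @param features Data frame of feature rows (see [extract_features()])
#'   with a `label` column, or the columns named by `feature_cols()`.
#' @param k Number of mixture components per class.
#' @param seed Integer seed controlling k-means initialization.
#' @param max_iter,tol EM stopping rule: at most `max_iter` iterations or a
#'   log-likelihood improvement below `tol`.
#' @return An object of class `activity_gmm`.
#' @examples
#' tr <- simulate_accel_windows(20, seed = 1)
#' fit_activity_gmm(tr, k = 2, seed = 1)
#' @export
fit_activity_gmm <- function(features, k = 2, seed = 1,
                             max_iter = 200, tol = 1e-8) {
  if (!"label" %in% names(features)) {
    abort("`features` must contain a `label` column.")
  }
  cols <- feature_cols()
  missing <- setdiff(cols, names(features))
  if (length(missing)) {
    abort(sprintf(
      "Missing feature column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  counts <- table(features$label)
  if (any(counts < 2)) {
    abort(sprintf(
      "Class(es) with fewer than 2 examples: %s.",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  labels <- names(counts)[order(activity_rank(names(counts)))]
  x_all <- as.matrix(features[, cols])
  mixtures <- lapply(labels, function(lab) {
    x <- x_all[features$label == lab, , drop = FALSE]
    # canonical row order -> fit independent of input ordering
    x <- x[do.call(order, as.data.frame(x)), , drop = FALSE]
    fit_diag_gmm(x, k = min(k, nrow(x)), seed = seed, max_iter = max_iter,
                 tol = tol)
  })
  names(mixtures) <- labels
  structure(
    list(
      classes = labels,
      priors = as.numeric(counts[labels] / sum(counts)),
      mixtures = mixtures,
      feature_names = cols,
      k = k,
      seed = as.integer(seed),
      n_train = nrow(features)
    ),
    class = "activity_gmm"
  )
}

# Diagonal-covariance GMM via EM with seeded k-means initialization.
fit_diag_gmm <- function(x, k, seed, max_iter = 200, tol = 1e-8) {
  n <- nrow(x)
  d <- ncol(x)
  floor_v <- pmax(apply(x, 2, function(c) mean((c - mean(c))^2)) * 1e-6,
                  1e-10)
  if (k == 1L) {
    mu <- matrix(colMeans(x), 1, d)
    v <- matrix(pmax(apply(x, 2, function(c) mean((c - mean(c))^2)),
                     floor_v), 1, d)
    w <- 1
  } else {
    km <- with_seed(seed, kmeans(x, centers = k, nstart = 5, iter.max = 50))
    assign <- km$cluster
    w <- as.numeric(table(factor(assign, levels = seq_len(k))) / n)
    mu <- km$centers
    v <- t(vapply(seq_len(k), function(j) {
      xi <- x[assign == j, , drop = FALSE]
      if (nrow(xi) < 2) {
        pmax(floor_v, 1e-10)
      } else {
        pmax(apply(xi, 2, function(c) mean((c - mean(c))^2)), floor_v)
      }
    }, numeric(d)))
    # EM refinement
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      lp <- comp_logdens(x, w, mu, v) # n x k
      m <- apply(lp, 1, max)
      ll <- sum(m + log(rowSums(exp(lp - m))))
      resp <- exp(lp - m - log(rowSums(exp(lp - m))))
      nk <- colSums(resp)
      w <- nk / n
      mu <- t(vapply(seq_len(k), function(j) {
        colSums(resp[, j] * x) / nk[j]
      }, numeric(d)))
      v <- t(vapply(seq_len(k), function(j) {
        pmax(colSums(resp[, j] * (x - matrix(mu[j, ], n, d,
                                             byrow = TRUE))^2) / nk[j],
             floor_v)
      }, numeric(d)))
      if (is.finite(ll) && ll - ll_old < tol) break
      ll_old <- ll
    }
  }
  list(weights = w, means = mu, vars = v)
}

# n x k matrix of log(w_j) + log N(x | mu_j, diag(v_j))
comp_logdens <- function(x, w, mu, v) {
  n <- nrow(x)
  k <- length(w)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    out[, j] <- log(w[j]) - 0.5 * sum(log(2 * pi * v[j, ])) -
      0.5 * colSums((t(x) - mu[j, ])^2 / v[j, ])
  }
  out
}

mixture_loglik <- function(mix, x) {
  lp <- comp_logdens(x, mix$weights, mix$means, mix$vars)
  m <- apply(lp, 1, max)
  m + log(rowSums(exp(lp - m)))
}

#' Classify feature vectors with a fitted activity GMM
#'
#' @param model An `activity_gmm` from [fit_activity_gmm()].
#' @param features Data frame of feature rows.
#' @return Tibble with one row per input: predicted `label` plus one
#'   `loglik_<class>` column per class (log prior + log mixture density).
#' @export
classify <- function(model, features) {
  if (!inherits(model, "activity_gmm")) {
    abort("`model` must be an `activity_gmm`.")
  }
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing)) {
    abort(sprintf(
      "Feature dimensionality mismatch; missing: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  x <- as.matrix(features[, model$feature_names])
  ll <- vapply(seq_along(model$classes), function(i) {
    log(model$priors[i]) + mixture_loglik(model$mixtures[[i]], x)
  }, numeric(nrow(x)))
  ll <- matrix(ll, nrow = nrow(x))
  # classes are stored in fixed order, so the first max is the tie-break
  pick <- apply(ll, 1, which.max)
  out <- tibble(label = model$classes[pick])
  colnames(ll) <- paste0("loglik_", model$classes)
  dplyr::bind_cols(out, as_tibble(ll))
}

#' @export
predict.activity_gmm <- function(object, newdata, ...) {
  classify(object, newdata)
}

#' Per-second activity labels for a 1 Hz sensor stream
#'
#' Extracts features in consecutive windows (default 10 s) and broadcasts
#' each window's predicted label to its seconds, preserving the per-second
#' labeling cadence downstream stages expect.
#'
#' @param stream Tibble with `timestamp`, `ax`, `ay`, `az`.
#' @param model Fitted `activity_gmm`.
#' @param window_s Classification window, seconds.
#' @return Tibble `timestamp`, `label` with one row per input second.
#' @export
classify_stream <- function(stream, model, window_s = 10) {
  if (nrow(stream) == 0L) {
    return(tibble(timestamp = stream$timestamp, label = character()))
  }
  per <- max(1L, as.integer(window_s))
  feats <- window_features(stream, window_s = per, sample_rate_hz = 1)
  pred <- classify(model, feats)
  idx <- pmin((seq_len(nrow(stream)) - 1L) %/% per + 1L, nrow(feats))
  tibble(
    timestamp = stream$timestamp,
    label = pred$label[idx]
  )
}

#' @export
#' @method tidy activity_gmm
tidy.activity_gmm <- function(x, ...) {
  imap(x$mixtures, function(mix, cls) {
    k <- length(mix$weights)
    map(seq_len(k), function(j) {
      tibble(
        class = cls, component = j, weight = mix$weights[j],
        feature = x$feature_names,
        mean = mix$means[j, ], variance = mix$vars[j, ]
      )
    }) %>% list_rbind()
  }) %>% list_rbind()
}

#' @export
#' @method glance activity_gmm
glance.activity_gmm <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    components_per_class = x$k,
    n_features = length(x$feature_names),
    n_train = x$n_train,
    seed = x$seed
  )
}

#' @export
print.activity_gmm <- function(x, ...) {
  cat(sprintf(
    "<activity_gmm> %d classes (%s), k = %d, %d features, n_train = %d\n",
    length(x$classes), paste(x$classes, collapse = ", "),
    x$k, length(x$feature_names), x$n_train
  ))
  invisible(x)
}
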