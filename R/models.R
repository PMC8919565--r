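# Per-family classifier trios: negative subsampling (10 per negative
# family), 9:1 positive weighting, and three L2-regularized linear SVMs with
# squared hinge loss on the three feature subsets, each with a Platt-style
# sigmoid probability calibrator fit on internally held-out decision values.
#
# The squared-hinge objective
#   0.5 ||w||^2 + C * sum_i  w_i * max(0, 1 - y_i (x_i . w + b))^2
# is convex and continuously differentiable, so it is minimized directly by
# BFGS with the analytic gradient; training is deterministic.

#' Training specification for a family trio
#'
#' @param n_neg_per_family negatives sampled from each non-target family.
#' @param positive_weight,negative_weight per-example loss weights; the
#'   default 9:1 makes each member of the (rare) positive class count nine
#'   times as much as a negative.
#' @param C regularization trade-off of the squared-hinge loss.
#' @param seed integer seed controlling negative subsampling and the
#'   internal calibration split.
#' @return A `training_spec` list.
#' @export
training_spec <- function(n_neg_per_family = 10, positive_weight = 9,
                          negative_weight = 1, C = 1, seed = 1) {
  if (n_neg_per_family < 1) {
    stop("n_neg_per_family must be >= 1", call. = FALSE)
  }
  if (positive_weight <= 0 || negative_weight <= 0) {
    stop("weights must be > 0", call. = FALSE)
  }
  structure(list(n_neg_per_family = n_neg_per_family,
                 positive_weight = positive_weight,
                 negative_weight = negative_weight,
                 C = C, seed = seed),
            class = "training_spec")
}

#' Build the weighted training set for one family
#'
#' Positives are every training member of the target family (weight
#' `positive_weight`); negatives are `n_neg_per_family` sequences sampled
#' uniformly without replacement from each other family (all members when a
#' family is smaller), weight `negative_weight`. Subsampling negatives this
#' way shrinks the negative class from roughly `d * (N - 1)` examples to
#' `n_neg_per_family * (N - 1)`.
#'
#' @param target_family the family being modeled.
#' @param features feature matrix (rows = sequences, rownames = ids).
#' @param labels named character vector of family labels for the rows.
#' @param spec a [training_spec()].
#' @return List with `X` (matrix), `y` (+1/-1), `weights`, `ids`.
#' @export
sample_training_set <- function(target_family, features, labels, spec) {
  stopifnot(inherits(spec, "training_spec"))
  labels <- labels[rownames(features)]
  pos_ids <- rownames(features)[labels == target_family]
  if (length(pos_ids) == 0) {
    stop("no training members for family '", target_family, "'",
         call. = FALSE)
  }
  other <- setdiff(unique(labels), c(target_family, NOVEL_FAMILY))
  neg_ids <- with_seed(child_seed(spec$seed, 1L), {
    unlist(lapply(sort(other), function(fam) {
      ids <- rownames(features)[labels == fam]
      if (length(ids) <= spec$n_neg_per_family) ids
      else sample(ids, spec$n_neg_per_family)
    }))
  })
  ids <- c(pos_ids, neg_ids)
  list(
    X = features[ids, , drop = FALSE],
    y = c(rep(1, length(pos_ids)), rep(-1, length(neg_ids))),
    weights = c(rep(spec$positive_weight, length(pos_ids)),
                rep(spec$negative_weight, length(neg_ids))),
    ids = ids
  )
}

# Deterministic L2-regularized squared-hinge linear SVM with per-example
# weights. Returns weights on the standardized scale plus the
# standardization statistics.
fit_svm_sqhinge <- function(X, y, weights, C = 1, standardize = TRUE) {
  if (length(unique(y)) < 2) {
    stop("degenerate single-class training input", call. = FALSE)
  }
  X <- as.matrix(X)
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale < 1e-12] <- 1
  } else {
    center <- rep(0, ncol(X))
    scale <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  p <- ncol(Xs)
  obj <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1]
    m <- pmax(0, 1 - y * (drop(Xs %*% w) + b))
    0.5 * sum(w^2) + C * sum(weights * m^2)
  }
  grad <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1]
    m <- pmax(0, 1 - y * (drop(Xs %*% w) + b))
    gw <- w - 2 * C * drop(crossprod(Xs, weights * y * m))
    gb <- -2 * C * sum(weights * y * m)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1],
       center = center, scale = scale, converged = fit$convergence == 0)
}

svm_decision <- function(model, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
  drop(Xs %*% model$w) + model$b
}

# Platt-style sigmoid p = 1 / (1 + exp(A * d + B)) with A < 0 (so p is
# increasing in the decision value d), fit by cross-entropy on Platt's
# prior-smoothed targets to stay finite on separable data.
fit_platt <- function(decisions, y) {
  n_pos <- sum(y > 0); n_neg <- sum(y <= 0)
  t_pos <- (n_pos + 1) / (n_pos + 2)
  t_neg <- 1 / (n_neg + 2)
  targets <- ifelse(y > 0, t_pos, t_neg)
  nll <- function(theta) {
    a <- -exp(theta[1]); b <- theta[2]
    z <- a * decisions + b
    # log(p) = -log1p(exp(z)), log(1-p) = z - log1p(exp(z))
    lse <- ifelse(z > 30, z, log1p(exp(z)))
    -sum(targets * (-lse) + (1 - targets) * (z - lse))
  }
  fit <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  list(A = -exp(fit$par[1]), B = fit$par[2])
}

platt_probability <- function(calibrator, decisions) {
  1 / (1 + exp(calibrator$A * decisions + calibrator$B))
}

#' Train the three-classifier trio for one family
#'
#' Fits, on the weighted training set from [sample_training_set()], one
#' linear squared-hinge SVM per feature subset (full vector; target triple
#' plus profile block; target triple only). Each model's probability
#' calibrator is fit on decision values from an internal 3-fold split (fit
#' on 2/3, score the held-out 1/3) so calibration never uses a model's own
#' training points; the final model is refit on the full set.
#'
#' @param target_family the family being modeled.
#' @param features feature matrix (training rows).
#' @param labels named family labels for the rows.
#' @param spec a [training_spec()].
#' @param family_order,profile_order block orders used at assembly time.
#' @return An object of class `family_trio`: per-model weight vector,
#'   intercept, standardization statistics, feature indices and Platt
#'   calibrator, plus training metadata.
#' @export
train_trio <- function(target_family, features, labels, spec,
                       family_order = attr(features, "family_order"),
                       profile_order = attr(features, "profile_order")) {
  ts <- sample_training_set(target_family, features, labels, spec)
  n <- nrow(ts$X)
  cal_folds <- with_seed(child_seed(spec$seed, 2L), {
    sample(rep_len(1:3, n))
  })
  models <- lapply(1:3, function(k) {
    Xk <- subset_for_model(ts$X, target_family, k, family_order,
                           profile_order)
    held_d <- numeric(n)
    for (f in 1:3) {
      tr <- cal_folds != f
      if (length(unique(ts$y[tr])) < 2) {
        stop("calibration split left a single-class fold; need more ",
             "training members", call. = FALSE)
      }
      sub <- fit_svm_sqhinge(Xk[tr, , drop = FALSE], ts$y[tr],
                             ts$weights[tr], C = spec$C)
      held_d[!tr] <- svm_decision(sub, Xk[!tr, , drop = FALSE])
    }
    calibrator <- fit_platt(held_d, ts$y)
    final <- fit_svm_sqhinge(Xk, ts$y, ts$weights, C = spec$C)
    c(final, list(calibrator = calibrator,
                  feature_index = model_feature_index(target_family, k,
                                                      family_order,
                                                      profile_order)))
  })
  structure(
    list(family = target_family, models = models,
         family_order = family_order, profile_order = profile_order,
         spec = spec,
         positive_ids = ts$ids[ts$y > 0], negative_ids = ts$ids[ts$y < 0]),
    class = "family_trio"
  )
}

#' @export
print.family_trio <- function(x, ...) {
  cat("family_trio for '", x$family, "': ",
      length(x$positive_ids), " positives, ",
      length(x$negative_ids), " sampled negatives\n", sep = "")
  invisible(x)
}

# Decision values (d1, d2, d3) of the trio on assembled feature rows.
trio_decisions <- function(trio, v) {
  m <- if (is.matrix(v)) v else matrix(v, nrow = 1,
                                       dimnames = list(NULL, names(v)))
  expected <- feature_names(trio$family_order, trio$profile_order)
  if (!is.null(colnames(m)) && !identical(colnames(m), expected)) {
    stop("feature-order mismatch for trio '", trio$family, "'",
         call. = FALSE)
  }
  vapply(trio$models, function(mod) {
    svm_decision(mod, m[, mod$feature_index, drop = FALSE])
  }, numeric(nrow(m)))
}

#' Calibrated probabilities of the three base classifiers
#'
#' @param trio a [train_trio()] result.
#' @param v assembled feature vector (or matrix of rows).
#' @return Numeric vector `(p1, p2, p3)` (or an `n x 3` matrix), each in
#'   `(0, 1)`; the binary vote of classifier k is `sign(decision_k)`.
#' @export
classifier_probability <- function(trio, v) {
  d <- trio_decisions(trio, v)
  d <- if (is.matrix(d)) d else matrix(d, nrow = 1)
  p <- vapply(1:3, function(k) {
    platt_probability(trio$models[[k]]$calibrator, d[, k])
  }, numeric(nrow(d)))
  p <- if (is.matrix(p)) p else matrix(p, nrow = 1)
  colnames(p) <- c("p1", "p2", "p3")
  if (nrow(p) == 1 && !is.matrix(v)) p[1, ] else p
}

#' Persist or load a trained trio as JSON
#'
#' @param trio a [train_trio()] result.
#' @param path JSON file path.
#' @return `write_trio` returns `path` invisibly; `read_trio` the trio.
#' @export
write_trio <- function(trio, path) {
  payload <- list(
    family = trio$family,
    family_order = trio$family_order,
    profile_order = trio$profile_order,
    spec = unclass(trio$spec),
    positive_ids = trio$positive_ids,
    negative_ids = trio$negative_ids,
    models = lapply(trio$models, function(m) {
      list(w = m$w, b = m$b, center = m$center, scale = m$scale,
           A = m$calibrator$A, B = m$calibrator$B,
           feature_index = m$feature_index)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trio
#' @export
read_trio <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(seq_len(3), function(k) {
    m <- if (is.data.frame(x$models)) as.list(x$models[k, ]) else
      x$models[[k]]
    list(w = as.numeric(unlist(m$w)), b = as.numeric(m$b),
         center = as.numeric(unlist(m$center)),
         scale = as.numeric(unlist(m$scale)),
         calibrator = list(A = as.numeric(m$A), B = as.numeric(m$B)),
         feature_index = as.integer(unlist(m$feature_index)))
  })
  structure(
    list(family = x$family, models = models,
         family_order = as.character(x$family_order),
         profile_order = as.character(x$profile_order %||% character(0)),
         spec = do.call(training_spec, as.list(x$spec)),
         positive_ids = as.character(x$positive_ids),
         negative_ids = as.character(x$negative_ids)),
    class = "family_trio"
  )
}
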