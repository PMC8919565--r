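# Ensemble combination: majority vote of the three base classifiers decides
# family membership; the closed-form ensemble probability (the probability
# that at least two of three independent base classifiers fire) is the score
# used for ROC analysis.

#' Majority vote of three binary classifiers
#'
#' @param c1,c2,c3 logical (or 0/1) votes; vectorized.
#' @return Logical: `TRUE` when at least two of the three votes are
#'   positive (with three binary voters the mode, and no tie is possible).
#' @export
vote <- function(c1, c2, c3) {
  stopifnot(all(c1 %in% c(0, 1, TRUE, FALSE)),
            all(c2 %in% c(0, 1, TRUE, FALSE)),
            all(c3 %in% c(0, 1, TRUE, FALSE)))
  (as.integer(c1) + as.integer(c2) + as.integer(c3)) >= 2
}

#' Closed-form ensemble probability
#'
#' Probability that at least two of three independent Bernoulli events with
#' success probabilities `p1, p2, p3` occur:
#' `p1 p2 p3 + p1 p2 q3 + p1 q2 p3 + q1 p2 p3` with `q_i = 1 - p_i`. High
#' only when at least two of the base probabilities are high.
#'
#' @param p1,p2,p3 probabilities in `[0, 1]`; vectorized.
#' @return Numeric in `[0, 1]`.
#' @export
ensemble_probability <- function(p1, p2, p3) {
  if (any(c(p1, p2, p3) < 0) || any(c(p1, p2, p3) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  q1 <- 1 - p1; q2 <- 1 - p2; q3 <- 1 - p3
  p1 * p2 * p3 + p1 * p2 * q3 + p1 * q2 * p3 + q1 * p2 * p3
}

#' Predict family membership for assembled feature rows
#'
#' Runs every family's trio on the feature rows: each trio votes by the
#' sign of its three decision values, a family is predicted iff the
#' majority vote is positive, and every (sequence, family) pair gets the
#' ensemble probability for ROC analysis. `pred_count` is the number of
#' families voted positive for a sequence; 0 flags a sequence matching no
#' known family (novel / unassignable).
#'
#' @param features assembled feature matrix (rows = sequences).
#' @param trios named list of [train_trio()] results, one per family.
#' @return An object of class `family_predictions`: list with `scores`
#'   (sequences x families matrix of ensemble probabilities), `votes`
#'   (logical matrix), `pred_count` (named integer vector) and
#'   `predictions` (long data frame `seq_id`, `family`, `pr_ensemble` of
#'   the positive votes, sorted by descending probability within each
#'   sequence).
#' @export
predict_families <- function(features, trios) {
  stopifnot(is.matrix(features), length(trios) > 0)
  fams <- vapply(trios, `[[`, character(1), "family")
  names(trios) <- fams
  n <- nrow(features)
  scores <- matrix(NA_real_, n, length(fams),
                   dimnames = list(rownames(features), fams))
  votes <- matrix(NA, n, length(fams),
                  dimnames = list(rownames(features), fams))
  for (f in fams) {
    d <- trio_decisions(trios[[f]], features)
    d <- if (is.matrix(d)) d else matrix(d, nrow = 1)
    p <- vapply(1:3, function(k) {
      platt_probability(trios[[f]]$models[[k]]$calibrator, d[, k])
    }, numeric(n))
    p <- if (is.matrix(p)) p else matrix(p, nrow = 1)
    votes[, f] <- vote(d[, 1] > 0, d[, 2] > 0, d[, 3] > 0)
    scores[, f] <- ensemble_probability(p[, 1], p[, 2], p[, 3])
  }
  pred_count <- rowSums(votes)
  long <- do.call(rbind, lapply(seq_len(n), function(i) {
    hit <- which(votes[i, ])
    if (length(hit) == 0) return(NULL)
    o <- hit[order(-scores[i, hit], fams[hit])]
    data.frame(seq_id = rownames(features)[i], family = fams[o],
               pr_ensemble = scores[i, o], stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  if (is.null(long)) {
    long <- data.frame(seq_id = character(0), family = character(0),
                       pr_ensemble = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(scores = scores, votes = votes,
                 pred_count = stats::setNames(pred_count,
                                              rownames(features)),
                 predictions = long),
            class = "family_predictions")
}

#' @export
print.family_predictions <- function(x, ...) {
  cat("family_predictions:", nrow(x$scores), "sequences x",
      ncol(x$scores), "families;",
      sum(x$pred_count == 0), "with no predicted family\n")
  invisible(x)
}

#' Propagate leaf-level predictions up a family hierarchy
#'
#' For hierarchically organized families (leaf sub-subfamily -> subfamily
#' -> family), models are built at the leaves and predictions propagated
#' bottom-up: a parent is predicted iff any of its leaves is, with
#' probability the maximum over contributing leaves.
#'
#' @param predictions a [predict_families()] result (leaf level).
#' @param hierarchy data frame with columns `family` (leaf), `subfamily`,
#'   `superfamily`.
#' @return List of long data frames `leaf`, `subfamily`, `superfamily`,
#'   each with `seq_id`, `label`, `pr_ensemble`.
#' @export
propagate_hierarchy <- function(predictions, hierarchy) {
  stopifnot(inherits(predictions, "family_predictions"),
            all(c("family", "subfamily", "superfamily") %in%
                  names(hierarchy)))
  leaf <- predictions$predictions
  unmapped <- setdiff(unique(leaf$family), hierarchy$family)
  if (length(unmapped) > 0) {
    stop("leaf '", unmapped[1], "' missing from hierarchy", call. = FALSE)
  }
  lift <- function(level) {
    if (nrow(leaf) == 0) {
      return(data.frame(seq_id = character(0), label = character(0),
                        pr_ensemble = numeric(0), stringsAsFactors = FALSE))
    }
    parent <- hierarchy[[level]][match(leaf$family, hierarchy$family)]
    agg <- stats::aggregate(leaf$pr_ensemble,
                            by = list(seq_id = leaf$seq_id, label = parent),
                            FUN = max)
    names(agg)[3] <- "pr_ensemble"
    agg[order(agg$seq_id, -agg$pr_ensemble, agg$label), , drop = FALSE]
  }
  list(
    leaf = data.frame(seq_id = leaf$seq_id, label = leaf$family,
                      pr_ensemble = leaf$pr_ensemble,
                      stringsAsFactors = FALSE),
    subfamily = lift("subfamily"),
    superfamily = lift("superfamily")
  )
}

#' Write predictions as TSV
#'
#' One row per sequence: `seq_id`, `pred_count`, and the predicted
#' families as semicolon-joined `family:probability` pairs (empty for
#' sequences with no predicted family).
#'
#' @param predictions a [predict_families()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  ids <- rownames(predictions$scores)
  joined <- vapply(ids, function(i) {
    rows <- predictions$predictions[predictions$predictions$seq_id == i, ]
    paste(sprintf("%s:%.6g", rows$family, rows$pr_ensemble),
          collapse = ";")
  }, character(1))
  utils::write.table(
    data.frame(seq_id = ids, pred_count = predictions$pred_count[ids],
               predicted = joined, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
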