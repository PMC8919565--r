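# Evaluation protocols: identity of test sequences to the training set
# (with the minimum-alignment-length rule), accuracy stratified by
# prediction count and identity bin (with the optional "more than five
# predictions counts as wrong" discard rule), per-family ROC/AUC, and the
# novel-family rejection protocol.

#' Identity of a test sequence to the training set
#'
#' Aligns the test sequence against every training sequence (and any
#' profile seed sequences) and returns the percent identity of the best
#' (highest raw score) hit whose alignment length is at least
#' `min_aln_len`; `NA` when no alignment qualifies. The length rule
#' prevents short high-identity local alignments from masquerading as
#' homology.
#'
#' @param test_seq character residues or one-row data frame.
#' @param training_seqs data frame with `id`/`residues` columns.
#' @param seed_seqs optional extra sequences (profile seeds) in the same
#'   shape.
#' @param min_aln_len minimum qualifying alignment length (residue
#'   columns); the conventional rule of thumb is 100.
#' @param matrix,gap_open,gap_extend alignment scoring parameters.
#' @return Percent identity in `(0, 100]`, or `NA` if unassigned.
#' @export
identity_to_training <- function(test_seq, training_seqs, seed_seqs = NULL,
                                 min_aln_len = 100, matrix = "BLOSUM62",
                                 gap_open = 11, gap_extend = 1) {
  refs <- rbind(training_seqs[, c("id", "residues")],
                if (!is.null(seed_seqs)) seed_seqs[, c("id", "residues")])
  stopifnot(nrow(refs) > 0)
  qres <- if (is.data.frame(test_seq)) test_seq$residues else test_seq
  ss <- Biostrings::AAStringSet(refs$residues)
  names(ss) <- refs$id
  hits <- sw_batch(qres, ss, aa_submatrix(matrix), gap_open, gap_extend)
  hits <- hits[hits$aln_length >= min_aln_len & hits$raw_score > 0, ,
               drop = FALSE]
  if (nrow(hits) == 0) return(NA_real_)
  hits$identity_pct[which.max(hits$raw_score)]
}

#' Identity map for a whole test set
#'
#' @param test_seqs data frame of test sequences (`id`, `residues`).
#' @param training_seqs,seed_seqs,min_aln_len,matrix,gap_open,gap_extend
#'   passed to [identity_to_training()].
#' @return Named numeric vector of identities (NA = unassigned).
#' @export
identity_map <- function(test_seqs, training_seqs, seed_seqs = NULL,
                         min_aln_len = 100, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  stats::setNames(
    vapply(seq_len(nrow(test_seqs)), function(i) {
      identity_to_training(test_seqs[i, , drop = FALSE], training_seqs,
                           seed_seqs, min_aln_len, matrix, gap_open,
                           gap_extend)
    }, numeric(1)),
    test_seqs$id
  )
}

#' Assign identity bins
#'
#' Half-open bins `(0,30]`, `(30,40]`, `(40,70]`, `(70,100]`; `NA`
#' identities map to `"unassigned"`. The two lowest bins form the twilight
#' zone.
#'
#' @param identity numeric identities (possibly NA).
#' @param edges increasing bin edges.
#' @return Character vector of bin labels.
#' @export
assign_identity_bin <- function(identity, edges = c(0, 30, 40, 70, 100)) {
  labels <- paste0("(", utils::head(edges, -1), ",", edges[-1], "]")
  out <- as.character(cut(identity, breaks = edges, labels = labels,
                          right = TRUE))
  out[is.na(out)] <- "unassigned"
  out
}

#' Accuracy stratified by prediction count (and identity bin)
#'
#' A sequence is counted correct iff its true family is among its predicted
#' families; it is assigned to the bin of its own prediction count (bins
#' `1..5` and `>5`; `pred_count = 0` is always wrong for a non-novel truth
#' and tabulated in its own `0` bin). When `discard_over` is set,
#' sequences with more than that many predictions are counted wrong
#' regardless of content (the "more than five predictions are useless"
#' rule for small hierarchical datasets).
#'
#' @param predictions a [predict_families()] result.
#' @param truth named character vector of true family labels.
#' @param identity_bins optional named character vector of identity-bin
#'   labels per sequence (see [assign_identity_bin()]).
#' @param discard_over integer or `NULL`.
#' @return List with `overall` accuracy, `correct` (named logical),
#'   `by_predcount` (data frame bin / n / accuracy), and, when identity
#'   bins are supplied, `by_identity` and `by_identity_predcount` tables.
#' @export
accuracy_by_predcount <- function(predictions, truth, identity_bins = NULL,
                                  discard_over = NULL) {
  stopifnot(inherits(predictions, "family_predictions"))
  ids <- rownames(predictions$scores)
  missing <- setdiff(ids, names(truth))
  if (length(missing) > 0) {
    stop("missing truth label for '", missing[1], "'", call. = FALSE)
  }
  truth <- truth[ids]
  pc <- predictions$pred_count[ids]
  predicted_sets <- split(predictions$predictions$family,
                          predictions$predictions$seq_id)
  correct <- vapply(ids, function(i) {
    truth[[i]] %in% predicted_sets[[i]]
  }, logical(1))
  if (!is.null(discard_over)) {
    correct[pc > discard_over] <- FALSE
  }
  pc_bin <- ifelse(pc > 5, ">5", as.character(pc))
  bin_levels <- c("0", "1", "2", "3", "4", "5", ">5")
  by_pc <- do.call(rbind, lapply(bin_levels, function(b) {
    sel <- pc_bin == b
    data.frame(pred_count = b, n = sum(sel),
               accuracy = if (any(sel)) mean(correct[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- list(overall = mean(correct), correct = correct,
              by_predcount = by_pc)
  if (!is.null(identity_bins)) {
    ib <- identity_bins[ids]
    out$by_identity <- do.call(rbind, lapply(sort(unique(ib)), function(b) {
      sel <- ib == b
      data.frame(identity_bin = b, n = sum(sel),
                 accuracy = mean(correct[sel]), stringsAsFactors = FALSE)
    }))
    tab <- expand.grid(identity_bin = sort(unique(ib)),
                       pred_count = bin_levels,
                       stringsAsFactors = FALSE)
    tab$n <- mapply(function(b, p) sum(ib == b & pc_bin == p),
                    tab$identity_bin, tab$pred_count)
    tab$accuracy <- mapply(function(b, p) {
      sel <- ib == b & pc_bin == p
      if (any(sel)) mean(correct[sel]) else NA_real_
    }, tab$identity_bin, tab$pred_count)
    out$by_identity_predcount <- tab
  }
  out
}

#' ROC curve and AUC for one family's scores
#'
#' Sweeps the unique scores as thresholds (equal scores grouped into one
#' step), computes `TPR = TP / P` and `FPR = FP / N` at each, and
#' integrates by the trapezoidal rule -- which equals the Mann-Whitney
#' concordance probability with half credit for ties.
#'
#' @param scores numeric scores (higher = more family-like).
#' @param labels binary labels (1/TRUE = member).
#' @return List with `curve` (data frame `threshold`, `tpr`, `fpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  P <- sum(labels); N <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / N, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr),
                      fpr = c(0, fpr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Per-family AUC over a test set
#'
#' One-vs-rest AUC of each family's ensemble-probability column; families
#' with a single class in the test set are skipped.
#'
#' @param predictions a [predict_families()] result.
#' @param truth named character vector of true labels.
#' @return Named numeric vector of AUCs.
#' @export
per_family_auc <- function(predictions, truth) {
  ids <- rownames(predictions$scores)
  truth <- truth[ids]
  fams <- colnames(predictions$scores)
  aucs <- vapply(fams, function(f) {
    lab <- truth == f
    if (!any(lab) || all(lab)) return(NA_real_)
    roc_auc(predictions$scores[, f], lab)$auc
  }, numeric(1))
  aucs[!is.na(aucs)]
}

#' Novel-family rejection protocol
#'
#' For each trained family, scores its positive test sequences together
#' with all novel-family sequences (which the models should reject) and
#' reports the AUC of member vs novel. Families without positive test
#' sequences are skipped with a warning.
#'
#' @param novel_features assembled feature matrix of NOVEL-labeled
#'   sequences (same column order as training features).
#' @param test_features assembled feature matrix of the main test split.
#' @param test_labels named true labels for `test_features` rows.
#' @param trios named list of [train_trio()] results.
#' @return Named numeric vector: per-family AUC.
#' @export
novel_family_eval <- function(novel_features, test_features, test_labels,
                              trios) {
  if (is.null(novel_features) || nrow(novel_features) == 0) {
    stop("novel set is empty", call. = FALSE)
  }
  test_labels <- test_labels[rownames(test_features)]
  out <- numeric(0)
  for (trio in trios) {
    f <- trio$family
    pos <- rownames(test_features)[test_labels == f]
    if (length(pos) == 0) {
      warning("family '", f, "' has no positive test sequences; skipped")
      next
    }
    X <- rbind(test_features[pos, , drop = FALSE], novel_features)
    p <- classifier_probability(trio, X)
    pr <- ensemble_probability(p[, 1], p[, 2], p[, 3])
    lab <- c(rep(TRUE, length(pos)), rep(FALSE, nrow(novel_features)))
    out[f] <- roc_auc(pr, lab)$auc
  }
  out
}
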