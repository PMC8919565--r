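test_that("identity to training obeys the alignment-length rule", {
  train <- data.frame(id = "t1", residues = random_protein(200))
  # identical sequence: full-length alignment at 100%
  expect_equal(identity_to_training(train$residues[1], train,
                                    min_aln_len = 100), 100)
  # alignments shorter than the cutoff leave the sequence unassigned
  short_train <- data.frame(id = "t2", residues = substr(train$residues, 1,
                                                         40))
  expect_true(is.na(identity_to_training(short_train$residues[1], train,
                                         min_aln_len = 100)))
  expect_equal(identity_to_training(short_train$residues[1], train,
                                    min_aln_len = 30), 100)
})

test_that("heavily mutated members land in the twilight bins", {
  prof <- sample_profile(150, c(1, 1), seed = 71)
  train <- do.call(rbind, lapply(1:5, function(j) {
    emit_member(prof, divergence_spec(0.05, 0), seed = 700 + j,
                id = paste0("tr", j))
  }))
  test <- emit_member(prof, divergence_spec(0.65, 0), seed = 720)
  id <- identity_to_training(test$residues, train, min_aln_len = 60)
  expect_false(is.na(id))
  expect_lte(id, 40)
  expect_gt(id, 0)
})

test_that("identity bins are half-open on the printed edges", {
  got <- assign_identity_bin(c(30, 30.0001, 40, 40.5, 70, 100, NA, 12))
  expect_equal(got, c("(0,30]", "(30,40]", "(30,40]", "(40,70]", "(40,70]",
                      "(70,100]", "unassigned", "(0,30]"))
})

test_that("predCount accuracy counts set-membership, with discard rule", {
  fams <- sprintf("F%d", 1:8)
  mk_pred <- function(sets, scores) {
    ids <- names(sets)
    votes <- t(vapply(sets, function(s) fams %in% s, logical(8)))
    dimnames(votes) <- list(ids, fams)
    sc <- matrix(0.1, length(ids), 8, dimnames = list(ids, fams))
    for (i in ids) sc[i, sets[[i]]] <- scores[[i]]
    long <- do.call(rbind, lapply(ids, function(i) {
      if (length(sets[[i]]) == 0) return(NULL)
      data.frame(seq_id = i, family = sets[[i]],
                 pr_ensemble = scores[[i]], stringsAsFactors = FALSE)
    }))
    structure(list(scores = sc, votes = votes,
                   pred_count = stats::setNames(lengths(sets), ids),
                   predictions = long), class = "family_predictions")
  }
  sets <- list(q1 = c("F1", "F2"),           # truth F1 -> correct, bin 2
               q2 = character(0),            # truth F1 -> wrong, bin 0
               q3 = fams[1:7],               # truth F1, predCount 7
               q4 = "F2")                    # truth F1 -> wrong
  scores <- list(q1 = c(0.9, 0.5), q2 = numeric(0), q3 = rep(0.8, 7),
                 q4 = 0.7)
  truth <- c(q1 = "F1", q2 = "F1", q3 = "F1", q4 = "F1")
  pred <- mk_pred(sets, scores)
  rep1 <- accuracy_by_predcount(pred, truth)
  expect_equal(unname(rep1$correct), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rep1$overall, 0.5)
  tab <- rep1$by_predcount
  expect_equal(tab$accuracy[tab$pred_count == "2"], 1)
  expect_equal(tab$accuracy[tab$pred_count == ">5"], 1)
  expect_equal(sum(tab$n), 4)  # bins partition the test set
  # the discard rule turns predCount > 5 into wrong regardless of content
  rep2 <- accuracy_by_predcount(pred, truth, discard_over = 5)
  expect_false(rep2$correct[["q3"]])
  expect_equal(rep2$overall, 0.25)
  expect_error(accuracy_by_predcount(pred, truth[1:3]), "q4")
})

test_that("accuracy tables stratify by identity bin", {
  run <- small_run()
  ids <- rownames(run$test_features)
  bins <- stats::setNames(rep(c("(40,70]", "(70,100]"),
                              length.out = length(ids)), ids)
  rep <- accuracy_by_predcount(run$predictions, run$truth,
                               identity_bins = bins)
  expect_true(all(c("by_identity", "by_identity_predcount") %in%
                    names(rep)))
  expect_equal(sum(rep$by_identity$n), length(ids))
  expect_equal(sum(rep$by_identity_predcount$n), length(ids))
})

test_that("ROC/AUC matches hand cases and the concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.3, 0.9), c(1, 0))$auc, 0)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 1, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  set.seed(91)
  for (i in 1:60) {
    n <- sample(6:25, 1)
    scores <- round(stats::runif(n), 2)  # rounding forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_concordance_oracle(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("ROC curves are monotone with valid rates", {
  set.seed(92)
  scores <- stats::runif(50)
  labels <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  curve <- roc_auc(scores, labels)$curve
  expect_true(all(diff(curve$tpr) >= 0))
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(curve$tpr >= 0 & curve$tpr <= 1))
  expect_true(all(curve$fpr >= 0 & curve$fpr <= 1))
})

test_that("ROC/AUC agrees with pROC on random score sets", {
  skip_if_not_installed("pROC")
  set.seed(93)
  for (i in 1:20) {
    scores <- stats::runif(30)
    labels <- sample(c(0, 1), 30, replace = TRUE)
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("per-family AUC is perfect on the separable benchmark", {
  run <- small_run()
  aucs <- per_family_auc(run$predictions, run$truth)
  expect_length(aucs, 6)
  expect_true(all(aucs >= 0.99))
})

test_that("novel-family rejection scores near 1, self-copies near 0.5", {
  run <- small_run()
  aucs <- run$novel_auc
  expect_length(aucs, 6)
  expect_true(all(aucs >= 0.95))
  # adversarial misuse: using a family's own members as the "novel" set
  fam <- names(aucs)[1]
  own <- run$test_features[run$truth[rownames(run$test_features)] == fam, ,
                           drop = FALSE]
  adv <- novel_family_eval(own, run$test_features, run$truth,
                           run$trios[fam])
  expect_equal(unname(adv[fam]), 0.5, tolerance = 0.15)
  expect_error(novel_family_eval(own[0, ], run$test_features, run$truth,
                                 run$trios), "empty")
})
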