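# End-to-end convenience wrappers tying the modules together: profiles from
# seed alignments, trios for every family, and a complete benchmark run
# (simulate -> fold -> featurize -> train -> predict -> evaluate).

#' Build and calibrate profiles from seed alignments
#'
#' @param seed_alignments named list of character vectors of aligned rows.
#' @param pseudocount,background passed to [build_profile()].
#' @param n_shuffles,seq_length null-calibration settings.
#' @param seed integer seed for the calibration draws.
#' @return Named list of calibrated `profile_model`s.
#' @export
build_profile_set <- function(seed_alignments, pseudocount = 1,
                              background = rep(1 / 20, 20),
                              n_shuffles = 300, seq_length = 150,
                              seed = 1) {
  out <- lapply(seq_along(seed_alignments), function(m) {
    p <- build_profile(seed_alignments[[m]], pseudocount, background,
                       id = names(seed_alignments)[m])
    calibrate_null(p, n_shuffles = n_shuffles,
                   seed = child_seed(seed, 9000L + m),
                   seq_length = seq_length)
  })
  names(out) <- names(seed_alignments)
  out
}

#' Train a classifier trio for every family
#'
#' @param features training feature matrix (with order attributes).
#' @param labels named family labels for the rows.
#' @param spec a [training_spec()]; each family's trio gets a seed derived
#'   from `spec$seed` and the family's rank, so runs are reproducible.
#' @param families families to model (default: all in the feature order).
#' @return Named list of `family_trio` objects.
#' @export
train_all_trios <- function(features, labels, spec,
                            families = attr(features, "family_order")) {
  out <- lapply(seq_along(families), function(i) {
    fam_spec <- spec
    fam_spec$seed <- child_seed(spec$seed, 100000L + i)
    train_trio(families[i], features, labels, fam_spec)
  })
  names(out) <- families
  out
}

#' Run a complete synthetic benchmark
#'
#' Generates families, assigns stratified folds, holds out one fold as the
#' test split, builds the reference database and calibrated profiles,
#' featurizes all splits, trains one trio per family, predicts on the test
#' split (and the novel set, if any) and evaluates accuracy, per-family
#' AUC and -- optionally -- identity bins and the novel-family protocol.
#'
#' @param n_families,members_per_family,divergence_bins,n_novel_families,
#'   n_profile_models,overlap_fraction,length_range,conservation_range
#'   passed to [generate_benchmark()].
#' @param k folds for the stratified split; fold `test_fold` is the test
#'   set.
#' @param test_fold fold index held out for testing.
#' @param n_ref references per family for the database.
#' @param spec a [training_spec()] (its seed is re-derived from `seed`).
#' @param min_aln_len qualifying alignment length for identity binning;
#'   `NULL` skips identity binning.
#' @param seed master seed.
#' @return List with the generated data, fitted artifacts, predictions and
#'   an evaluation report (`accuracy`, `family_auc`, optionally
#'   `identity`, `novel_auc`).
#' @export
run_benchmark <- function(n_families = 20, members_per_family = 60,
                          divergence_bins = default_divergence_bins(),
                          n_novel_families = 0, n_profile_models = 5,
                          overlap_fraction = 0.2,
                          length_range = c(120, 160),
                          conservation_range = c(0.7, 0.98),
                          k = 3, test_fold = 1, n_ref = 10,
                          spec = training_spec(), min_aln_len = NULL,
                          seed = 1) {
  bench <- generate_benchmark(
    n_families = n_families, members_per_family = members_per_family,
    divergence_bins = divergence_bins,
    n_novel_families = n_novel_families,
    n_profile_models = n_profile_models,
    overlap_fraction = overlap_fraction, length_range = length_range,
    conservation_range = conservation_range, seed = seed
  )
  ds <- make_folds(bench$dataset, k, seed = child_seed(seed, 11L))
  splits <- split_by_fold(ds, test_fold)
  db <- build_reference_db(splits$train, n_ref = n_ref,
                           seed = child_seed(seed, 12L))
  profiles <- build_profile_set(bench$seed_alignments,
                                seq_length = round(mean(length_range)),
                                seed = child_seed(seed, 13L))
  train_X <- featurize(splits$train$sequences, db, profiles)
  test_X <- featurize(splits$test$sequences, db, profiles)
  spec$seed <- child_seed(seed, 14L)
  labels <- stats::setNames(splits$train$sequences$family,
                            splits$train$sequences$id)
  trios <- train_all_trios(train_X, labels, spec)
  pred <- predict_families(test_X, trios)
  truth <- stats::setNames(splits$test$sequences$family,
                           splits$test$sequences$id)
  id_bins <- NULL
  if (!is.null(min_aln_len)) {
    seed_df <- data.frame(
      id = paste0("seed_", seq_along(unlist(bench$seed_alignments))),
      residues = unlist(bench$seed_alignments), stringsAsFactors = FALSE
    )
    ids <- identity_map(splits$test$sequences, splits$train$sequences,
                        seed_df, min_aln_len = min_aln_len)
    id_bins <- stats::setNames(assign_identity_bin(ids), names(ids))
  }
  report <- accuracy_by_predcount(pred, truth, identity_bins = id_bins)
  out <- list(benchmark = bench, splits = splits, db = db,
              profiles = profiles, train_features = train_X,
              test_features = test_X, trios = trios, predictions = pred,
              truth = truth, identity_bins = id_bins,
              accuracy = report, family_auc = per_family_auc(pred, truth))
  if (n_novel_families > 0) {
    novel_X <- featurize(bench$novel$sequences, db, profiles)
    out$novel_features <- novel_X
    out$novel_auc <- novel_family_eval(novel_X, test_X, truth, trios)
  }
  out
}
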