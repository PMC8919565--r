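# Sequence and label input/output, and stratified cross-validation folds.

#' Construct a labeled family dataset
#'
#' A `family_dataset` bundles amino-acid sequences with their family labels.
#' The ordered vector of family identifiers defines the column order of every
#' downstream feature block, so it is fixed (lexicographic) at construction
#' and persisted alongside any feature matrix. Sequences labeled with the
#' sentinel `"NOVEL"` belong to held-out families that are never listed in
#' `families` and never used for training.
#'
#' @param sequences data frame with columns `id`, `residues`, `family`.
#' @param hierarchy optional data frame with columns `family`, `subfamily`,
#'   `superfamily` mapping each leaf family to its ancestors.
#' @param folds optional named integer vector mapping sequence id to fold.
#' @return An object of class `family_dataset`: a list with elements
#'   `sequences`, `families`, `hierarchy`, `folds`.
#' @export
family_dataset <- function(sequences, hierarchy = NULL, folds = NULL) {
  stopifnot(is.data.frame(sequences),
            all(c("id", "residues", "family") %in% names(sequences)))
  sequences <- data.frame(
    id = as.character(sequences$id),
    residues = toupper(as.character(sequences$residues)),
    family = as.character(sequences$family),
    stringsAsFactors = FALSE
  )
  dup <- sequences$id[duplicated(sequences$id)]
  if (length(dup) > 0) {
    stop("duplicate sequence id: '", dup[1], "'", call. = FALSE)
  }
  for (i in seq_len(nrow(sequences))) {
    check_residues(sequences$residues[i], sequences$id[i])
  }
  fams <- sort(unique(sequences$family[sequences$family != NOVEL_FAMILY]))
  structure(
    list(sequences = sequences, families = fams,
         hierarchy = hierarchy, folds = folds),
    class = "family_dataset"
  )
}

#' @export
print.family_dataset <- function(x, ...) {
  cat("family_dataset:", nrow(x$sequences), "sequences,",
      length(x$families), "families")
  n_novel <- sum(x$sequences$family == NOVEL_FAMILY)
  if (n_novel > 0) cat(",", n_novel, "novel")
  if (!is.null(x$folds)) cat(",", length(unique(x$folds)), "folds")
  cat("\n")
  invisible(x)
}

#' Read labeled sequences from FASTA
#'
#' Labels come from a sidecar two-column TSV (`sequence_id<TAB>family_id`, no
#' header) when `labels` is given, otherwise from the header itself: the
#' family identifier is the token after the final `'|'` in each header.
#'
#' @param fasta_path path to a protein FASTA file.
#' @param labels optional path to the labels TSV.
#' @return A [family_dataset()].
#' @export
read_labeled_fasta <- function(fasta_path, labels = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  residues <- as.character(seqs)
  if (!is.null(labels)) {
    lab <- utils::read.delim(labels, header = FALSE, sep = "\t",
                             colClasses = "character")
    if (ncol(lab) < 2) stop("labels TSV must have two columns", call. = FALSE)
    label_map <- stats::setNames(lab[[2]], lab[[1]])
    missing <- ids[!(ids %in% names(label_map))]
    if (length(missing) > 0) {
      stop("no label for sequence id '", missing[1], "'", call. = FALSE)
    }
    fam <- unname(label_map[ids])
  } else {
    has_pipe <- grepl("|", names(seqs), fixed = TRUE)
    if (any(!has_pipe)) {
      stop("header '", names(seqs)[which(!has_pipe)[1]],
           "' has no '|' family token and no labels TSV was given",
           call. = FALSE)
    }
    fam <- sub("^.*\\|", "", names(seqs))
  }
  family_dataset(data.frame(id = ids, residues = residues, family = fam,
                            stringsAsFactors = FALSE))
}

#' Write a dataset as FASTA plus labels TSV
#'
#' @param dataset a [family_dataset()].
#' @param fasta_path output FASTA path.
#' @param labels_path optional output path for the two-column labels TSV.
#' @return Invisibly, `fasta_path`.
#' @export
write_labeled_fasta <- function(dataset, fasta_path, labels_path = NULL) {
  stopifnot(inherits(dataset, "family_dataset"))
  x <- Biostrings::AAStringSet(dataset$sequences$residues)
  names(x) <- dataset$sequences$id
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(labels_path)) {
    utils::write.table(dataset$sequences[, c("id", "family")], labels_path,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}

#' Assign stratified cross-validation folds
#'
#' Each family's members are spread as evenly as possible across `k` folds
#' (stratified per family), so every family has both training and test
#' members in every fold -- a requirement of per-family evaluation.
#'
#' @param dataset a [family_dataset()].
#' @param k number of folds.
#' @param seed integer seed controlling the within-family shuffle.
#' @return The dataset with `folds` set: a named integer vector (values in
#'   `1:k`) over all sequence ids.
#' @export
make_folds <- function(dataset, k, seed) {
  stopifnot(inherits(dataset, "family_dataset"), k >= 2)
  counts <- table(dataset$sequences$family)
  small <- names(counts)[counts < k]
  if (length(small) > 0) {
    stop("families with fewer than k=", k, " members: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  folds <- with_seed(seed, {
    out <- integer(0)
    for (fam in sort(unique(dataset$sequences$family))) {
      ids <- dataset$sequences$id[dataset$sequences$family == fam]
      ids <- sample(ids)
      f <- rep_len(seq_len(k), length(ids))
      out <- c(out, stats::setNames(f, ids))
    }
    out
  })
  dataset$folds <- folds[dataset$sequences$id]
  names(dataset$folds) <- dataset$sequences$id
  dataset
}

#' Persist or load a fold map
#'
#' @param folds named integer vector as produced by [make_folds()].
#' @param path TSV path (`id<TAB>fold`, no header).
#' @return `write_fold_map` returns `path` invisibly; `read_fold_map` the
#'   named integer vector.
#' @export
write_fold_map <- function(folds, path) {
  utils::write.table(data.frame(id = names(folds), fold = unname(folds)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fold_map
#' @export
read_fold_map <- function(path) {
  x <- utils::read.delim(path, header = FALSE, sep = "\t",
                         colClasses = c("character", "integer"))
  stats::setNames(x[[2]], x[[1]])
}

#' Split a dataset by fold membership
#'
#' @param dataset a folded [family_dataset()].
#' @param test_fold fold index used as the test split.
#' @return List with `train` and `test` datasets (family order inherited
#'   from `dataset`).
#' @export
split_by_fold <- function(dataset, test_fold) {
  stopifnot(!is.null(dataset$folds))
  is_test <- dataset$folds[dataset$sequences$id] == test_fold
  train <- dataset
  train$sequences <- dataset$sequences[!is_test, , drop = FALSE]
  train$folds <- dataset$folds[!is_test]
  test <- dataset
  test$sequences <- dataset$sequences[is_test, , drop = FALSE]
  test$folds <- dataset$folds[is_test]
  # family order (and hence feature columns) stays that of the full dataset
  train$families <- dataset$families
  test$families <- dataset$families
  list(train = train, test = test)
}
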