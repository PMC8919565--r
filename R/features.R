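# Assemble fixed-length feature vectors: per family the alignment triple
# (bit-score, -log10 E-value, identity%) and per profile the pair
# (bit-score, -log10 E-value), concatenated in a fixed, persisted order so
# vectors are comparable across sequences and runs.

E_VALUE_FLOOR <- 1e-180

neglog_evalue <- function(e_value, floor = E_VALUE_FLOOR) {
  -log10(pmax(e_value, floor))
}

#' Feature column names for a given family/profile order
#'
#' @param family_order,profile_order character vectors fixing block order.
#' @return Character vector of `3N + 2M` column names
#'   (`family:bit|neglog_e|identity`, then `profile:bit|neglog_e`).
#' @export
feature_names <- function(family_order, profile_order = character(0)) {
  c(as.vector(t(outer(family_order, c("bit", "neglog_e", "identity"),
                      paste, sep = ":"))),
    if (length(profile_order) > 0) {
      as.vector(t(outer(profile_order, c("bit", "neglog_e"),
                        paste, sep = ":")))
    })
}

#' Assemble one feature vector
#'
#' Builds the length `3N + 2M` vector for a sequence from its per-family
#' best alignment hits and per-profile hits. E-values enter as
#' `-log10(max(e, 1e-180))`; a family with no passing hit contributes
#' `(0, 0, 0)` and a profile with no hit `(0, 0)` -- the natural
#' "no similarity" point (bit 0, E-value 1 or worse, identity 0).
#'
#' @param seq_id sequence identifier.
#' @param family_hits data frame as from [search_reference_db()] (or
#'   [reduce_best_per_family()] over parsed BLAST rows) for this sequence.
#' @param profile_hits data frame as from [score_profiles()] for this
#'   sequence (may be `NULL` when no profiles are used).
#' @param family_order,profile_order character vectors fixing block order.
#' @return Named numeric vector of length `3 * length(family_order) +
#'   2 * length(profile_order)`.
#' @export
assemble <- function(seq_id, family_hits, profile_hits,
                     family_order, profile_order = character(0)) {
  v <- stats::setNames(numeric(3 * length(family_order) +
                                 2 * length(profile_order)),
                       feature_names(family_order, profile_order))
  if (!is.null(family_hits) && nrow(family_hits) > 0) {
    unknown <- setdiff(family_hits$subject_family, family_order)
    if (length(unknown) > 0) {
      stop("hit for family '", unknown[1], "' not in family_order",
           call. = FALSE)
    }
    i <- match(family_hits$subject_family, family_order)
    v[(i - 1) * 3 + 1] <- family_hits$bit_score
    v[(i - 1) * 3 + 2] <- neglog_evalue(family_hits$e_value)
    v[(i - 1) * 3 + 3] <- family_hits$identity_pct
  }
  if (!is.null(profile_hits) && nrow(profile_hits) > 0) {
    unknown <- setdiff(profile_hits$profile, profile_order)
    if (length(unknown) > 0) {
      stop("hit for profile '", unknown[1], "' not in profile_order",
           call. = FALSE)
    }
    j <- match(profile_hits$profile, profile_order)
    off <- 3 * length(family_order)
    v[off + (j - 1) * 2 + 1] <- profile_hits$bit_score
    v[off + (j - 1) * 2 + 2] <- neglog_evalue(profile_hits$e_value)
  }
  attr(v, "seq_id") <- seq_id
  v
}

#' Column indices of one model's feature subset
#'
#' Model 1 uses the full `2M + 3N` vector; model 2 the target family's
#' alignment triple plus all `2M` profile features (`2M + 3`); model 3 only
#' the target family's triple (3).
#'
#' @param target_family family the trio is being built for.
#' @param model_id 1, 2 or 3.
#' @param family_order,profile_order character vectors fixing block order.
#' @return Integer vector of column indices into the assembled vector.
#' @export
model_feature_index <- function(target_family, model_id,
                                family_order, profile_order = character(0)) {
  i <- match(target_family, family_order)
  if (is.na(i)) {
    stop("target family '", target_family, "' not in family_order",
         call. = FALSE)
  }
  triple <- (i - 1) * 3 + 1:3
  profile_block <- 3 * length(family_order) +
    seq_len(2 * length(profile_order))
  switch(as.character(model_id),
         "1" = seq_len(3 * length(family_order) + 2 * length(profile_order)),
         "2" = c(triple, profile_block),
         "3" = triple,
         stop("unknown model_id: ", model_id, call. = FALSE))
}

#' Slice one model's feature subset from an assembled vector or matrix
#'
#' @param v assembled feature vector (or matrix with feature columns).
#' @param target_family family the trio is being built for.
#' @param model_id 1, 2 or 3.
#' @param family_order,profile_order character vectors fixing block order.
#' @return Numeric vector (or matrix) restricted to the model's features.
#' @export
subset_for_model <- function(v, target_family, model_id,
                             family_order, profile_order = character(0)) {
  idx <- model_feature_index(target_family, model_id, family_order,
                             profile_order)
  if (is.matrix(v)) v[, idx, drop = FALSE] else v[idx]
}

#' Assemble the feature matrix for a whole dataset
#'
#' Runs every sequence through the reference-database search and the
#' profile scorers and stacks the assembled vectors.
#'
#' @param sequences data frame with `id` and `residues` columns (e.g.
#'   `dataset$sequences`).
#' @param db a [build_reference_db()] result.
#' @param profiles named list of calibrated [build_profile()] models (may
#'   be empty).
#' @param family_order family order (defaults to the database's families).
#' @return Numeric matrix, one row per sequence (rownames = ids), with
#'   attributes `family_order` and `profile_order`.
#' @export
featurize <- function(sequences, db, profiles = list(),
                      family_order = db$families) {
  profile_order <- names(profiles)
  rows <- lapply(seq_len(nrow(sequences)), function(i) {
    fh <- search_reference_db(sequences[i, , drop = FALSE], db)
    ph <- if (length(profiles) > 0) {
      score_profiles(sequences[i, , drop = FALSE], profiles)
    } else NULL
    assemble(sequences$id[i], fh, ph, family_order, profile_order)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- sequences$id
  attr(m, "family_order") <- family_order
  attr(m, "profile_order") <- profile_order
  m
}

#' Persist or load a feature matrix
#'
#' The matrix is written as a TSV (first column `id`, then one column per
#' feature) with a sidecar JSON recording `family_order`, `profile_order`
#' and the E-value transform, without which the columns are meaningless.
#'
#' @param m matrix from [featurize()].
#' @param path output TSV path; the sidecar is `path` + `.json`.
#' @return `write_features` returns `path` invisibly; `read_features` the
#'   matrix with order attributes restored.
#' @export
write_features <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(family_order = attr(m, "family_order"),
         profile_order = attr(m, "profile_order"),
         evalue_transform = "neglog10", evalue_floor = E_VALUE_FLOOR),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing feature-order sidecar '", sidecar,
         "'; rerun featurization", call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  attr(m, "family_order") <- as.character(meta$family_order)
  attr(m, "profile_order") <- as.character(meta$profile_order %||%
                                             character(0))
  m
}
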