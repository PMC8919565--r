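# Per-family alignment similarity features: Smith-Waterman local alignment
# against a small per-family reference database, Karlin-Altschul bit-score /
# E-value statistics, and a parser for precomputed BLAST tabular output.
#
# The local aligner is Biostrings' affine-gap Smith-Waterman (a gap of
# length k costs gap_open + k * gap_extend, the BLAST convention); raw DP
# scores are converted to bit-scores and E-values here because the search
# space of the internal reference database is known exactly.

#' Resolve a substitution matrix
#'
#' Accepts a matrix directly, the name of a matrix shipped with Biostrings
#' (`"BLOSUM62"`, `"BLOSUM45"`, `"BLOSUM50"`, `"BLOSUM80"`, `"BLOSUM100"`,
#' `"PAM30"`, `"PAM40"`, `"PAM70"`, `"PAM120"`, `"PAM250"`), or a path to a
#' matrix in NCBI text format.
#'
#' @param matrix matrix, name, or file path.
#' @return A numeric substitution matrix with residue dimnames.
#' @export
aa_submatrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  stopifnot(is.character(matrix), length(matrix) == 1)
  if (file.exists(matrix)) return(read_ncbi_matrix(matrix))
  env <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = env)
  get(matrix, envir = env)
}

#' Read a substitution matrix in NCBI text format
#'
#' The format used by NCBI BLAST matrix files: `#` comment lines, a header
#' row of column residues, then one row per residue starting with its label.
#'
#' @param path matrix file path.
#' @return Numeric matrix with residue dimnames.
#' @export
read_ncbi_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(cols))))
  dimnames(m) <- list(vapply(rows, `[[`, character(1), 1), cols)
  m
}

# Align one query against a set of subjects; returns one row per subject
# with the local-alignment raw score, identity and alignment length.
# Subjects whose optimal local score is <= 0 (empty alignment) are no-hits.
sw_batch <- function(query_residues, subject_set, matrix, gap_open,
                     gap_extend) {
  aln <- Biostrings::pairwiseAlignment(
    subject_set, Biostrings::AAString(query_residues), type = "local",
    substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  len <- Biostrings::nchar(aln)
  data.frame(
    subject_id = names(subject_set),
    raw_score = Biostrings::score(aln),
    aln_length = len,
    identity_pct = ifelse(len > 0, 100 * Biostrings::nmatch(aln) / len, 0),
    stringsAsFactors = FALSE
  )
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' Optimal local alignment under affine gap costs (a gap of length `k`
#' costs `gap_open + k * gap_extend`). Identity is
#' `100 * matching columns / alignment length`, the alignment length
#' counting gap columns.
#'
#' @param query,subject character residues, or one-row data frames with
#'   `id`/`residues` columns.
#' @param matrix substitution matrix (see [aa_submatrix()]).
#' @param gap_open,gap_extend nonnegative gap penalties.
#' @return A one-row data frame with columns `query_id`, `subject_id`,
#'   `raw_score`, `identity_pct`, `aln_length`, or `NULL` when the optimal
#'   local score is not positive (no hit).
#' @export
smith_waterman <- function(query, subject, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  if (gap_open < 0 || gap_extend < 0) {
    stop("gap penalties must be >= 0", call. = FALSE)
  }
  qid <- if (is.data.frame(query)) query$id else "query"
  sid <- if (is.data.frame(subject)) subject$id else "subject"
  qres <- if (is.data.frame(query)) query$residues else query
  sres <- if (is.data.frame(subject)) subject$residues else subject
  stopifnot(nzchar(qres), nzchar(sres))
  ss <- Biostrings::AAStringSet(sres)
  names(ss) <- sid
  hit <- sw_batch(qres, ss, aa_submatrix(matrix), gap_open, gap_extend)
  if (hit$raw_score <= 0) return(NULL)
  cbind(data.frame(query_id = qid, stringsAsFactors = FALSE), hit)
}

#' Karlin-Altschul alignment statistics
#'
#' Converts a raw local-alignment score into a bit-score and E-value:
#' `bit = (lambda * raw - ln K) / ln 2` and
#' `E = m * n * 2^(-bit)` with `m` the query length and `n` the total
#' residue count of the searched database. The defaults are the standard
#' gapped BLOSUM62 (open 11 / extend 1) parameters.
#'
#' @param raw_score integer raw score(s), >= 1.
#' @param query_len query length in residues.
#' @param db_residues total residues in the searched database.
#' @param lambda,K Karlin-Altschul parameters, > 0.
#' @return List with numeric vectors `bit_score` and `e_value`.
#' @export
score_statistics <- function(raw_score, query_len, db_residues,
                             lambda = 0.267, K = 0.041) {
  if (lambda <= 0 || K <= 0) stop("lambda and K must be > 0", call. = FALSE)
  stopifnot(all(raw_score >= 1), query_len >= 1, db_residues >= 1)
  bit <- (lambda * raw_score - log(K)) / log(2)
  list(bit_score = bit, e_value = query_len * db_residues * 2^(-bit))
}

#' Build a per-family reference database
#'
#' Samples `n_ref` sequences from every family of the training data (so a
#' dataset of N families yields a database of `n_ref * N` sequences) and
#' records the scoring parameters used for all searches against it. The
#' sampled ids are recorded; they remain part of the training set.
#'
#' @param dataset a [family_dataset()] (training portion).
#' @param n_ref references per family (default 10).
#' @param seed integer seed for the per-family sample.
#' @param matrix,gap_open,gap_extend,lambda,K,e_threshold scoring parameters
#'   stored with the database.
#' @return An object of class `reference_db`: list with `sequences` (data
#'   frame id/residues/family), `params`, `db_residues` and `families`.
#' @export
build_reference_db <- function(dataset, n_ref = 10, seed = 1,
                               matrix = "BLOSUM62", gap_open = 11,
                               gap_extend = 1, lambda = 0.267, K = 0.041,
                               e_threshold = 10) {
  stopifnot(inherits(dataset, "family_dataset"))
  seqs <- dataset$sequences[dataset$sequences$family != NOVEL_FAMILY, ]
  counts <- table(seqs$family)
  small <- names(counts)[counts < n_ref]
  if (length(small) > 0) {
    stop("families with fewer than n_ref=", n_ref, " members: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  picked <- with_seed(seed, {
    unlist(lapply(sort(unique(seqs$family)), function(fam) {
      ids <- seqs$id[seqs$family == fam]
      sample(ids, n_ref)
    }))
  })
  refs <- seqs[match(picked, seqs$id), , drop = FALSE]
  rownames(refs) <- NULL
  structure(
    list(sequences = refs,
         families = sort(unique(refs$family)),
         params = list(matrix = if (is.matrix(matrix)) "custom" else matrix,
                       matrix_values = aa_submatrix(matrix),
                       gap_open = gap_open, gap_extend = gap_extend,
                       lambda = lambda, K = K, e_threshold = e_threshold),
         db_residues = sum(nchar(refs$residues))),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  cat("reference_db:", nrow(x$sequences), "sequences over",
      length(x$families), "families (", x$db_residues, "residues )\n")
  invisible(x)
}

#' Reduce alignment hits to the best hit per family
#'
#' Keeps, for every (query, family) pair, the hit with the highest
#' bit-score; ties broken by lower E-value, then by lexicographically
#' smallest subject id, so the reduction is deterministic and
#' order-independent.
#'
#' @param hits data frame with at least `query_id`, `subject_family`,
#'   `bit_score`, `e_value`, `subject_id`.
#' @return Data frame with one row per (query, family).
#' @export
reduce_best_per_family <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$query_id, hits$subject_family, -hits$bit_score,
             hits$e_value, hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  keep <- !duplicated(hits[, c("query_id", "subject_family")])
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search a query against the reference database
#'
#' Aligns the query against every reference sequence, applies the E-value
#' reporting threshold, and keeps at most one hit per family (the
#' maximum-bit-score hit among that family's references). Families with no
#' passing hit are absent from the result.
#'
#' @param query character residues or a one-row data frame with
#'   `id`/`residues`.
#' @param db a [build_reference_db()] result.
#' @param e_threshold E-value cutoff (defaults to the one stored in `db`).
#' @return Data frame with columns `query_id`, `subject_family`,
#'   `subject_id`, `raw_score`, `bit_score`, `e_value`, `identity_pct`,
#'   `aln_length`; zero rows if nothing passes.
#' @export
search_reference_db <- function(query, db, e_threshold = NULL) {
  stopifnot(inherits(db, "reference_db"))
  e_threshold <- e_threshold %||% db$params$e_threshold
  qid <- if (is.data.frame(query)) query$id else "query"
  qres <- if (is.data.frame(query)) query$residues else query
  ss <- Biostrings::AAStringSet(db$sequences$residues)
  names(ss) <- db$sequences$id
  hits <- sw_batch(qres, ss, db$params$matrix_values,
                   db$params$gap_open, db$params$gap_extend)
  hits$subject_family <- db$sequences$family
  hits <- hits[hits$raw_score >= 1, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(empty_hits_frame())
  }
  st <- score_statistics(hits$raw_score, nchar(qres), db$db_residues,
                         db$params$lambda, db$params$K)
  hits$bit_score <- st$bit_score
  hits$e_value <- st$e_value
  hits$query_id <- qid
  hits <- hits[hits$e_value <= e_threshold, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits_frame())
  reduce_best_per_family(hits[, c("query_id", "subject_family", "subject_id",
                                  "raw_score", "bit_score", "e_value",
                                  "identity_pct", "aln_length")])
}

empty_hits_frame <- function() {
  data.frame(query_id = character(0), subject_family = character(0),
             subject_id = character(0), raw_score = numeric(0),
             bit_score = numeric(0), e_value = numeric(0),
             identity_pct = numeric(0), aln_length = integer(0),
             stringsAsFactors = FALSE)
}

#' Parse BLAST tabular output (outfmt 6, default columns)
#'
#' Expects the default 12-column order `qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`. Rows are returned as
#' alignment hits; apply [reduce_best_per_family()] to obtain the per-family
#' best-hit map used for features.
#'
#' @param path BLAST tabular file.
#' @param family_of_subject named character vector mapping subject id to
#'   family.
#' @return Data frame in the same shape as [search_reference_db()] output
#'   (with `raw_score = NA`, which BLAST tabular does not report).
#' @export
parse_blast_tabular <- function(path, family_of_subject) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 12)
  if (length(bad) > 0) {
    stop("line ", bad[1], ": expected 12 tab-separated columns, got ",
         length(fields[[bad[1]]]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  unmapped <- setdiff(unique(m[, 2]), names(family_of_subject))
  if (length(unmapped) > 0) {
    stop("no family mapping for subject id '", unmapped[1], "'",
         call. = FALSE)
  }
  data.frame(
    query_id = m[, 1],
    subject_family = unname(family_of_subject[m[, 2]]),
    subject_id = m[, 2],
    raw_score = NA_real_,
    bit_score = as.numeric(m[, 12]),
    e_value = as.numeric(m[, 11]),
    identity_pct = as.numeric(m[, 3]),
    aln_length = as.integer(m[, 4]),
    stringsAsFactors = FALSE
  )
}
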