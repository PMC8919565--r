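# Position-specific profile scoring: the M per-profile (bit-score, E-value)
# features. Profiles are ungapped position-specific log-odds models built
# from seed alignments; a sequence's bit-score is the best placement of the
# full profile along the sequence, and E-values come from an exponential
# tail fit to a shuffled-sequence null. An adapter parses HMMER hmmscan
# domain tables so externally computed profile scores can be used instead.

#' Build a position-specific profile from a seed alignment
#'
#' Columns with more than 50% gap characters are dropped; the remaining
#' columns become match positions with log-odds scores
#' `log2((count(a) + pseudocount * background(a)) / (total + pseudocount)
#' / background(a))`, so a residue emitted at background frequency scores 0.
#'
#' @param seed_alignment character vector of equal-length aligned rows
#'   (gaps as `-` or `.`), or an `AAStringSet`.
#' @param pseudocount total pseudocount mass added per column, split
#'   according to the background.
#' @param background length-20 residue distribution (named or in the
#'   standard alphabet order); uniform by default.
#' @param id profile identifier.
#' @return An object of class `profile_model` with elements `id`, `length`,
#'   `match_log_odds` (length x 20 matrix), `background` and
#'   `null_calibration` (`NULL` until [calibrate_null()] is run).
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          background = rep(1 / 20, 20), id = "P1") {
  rows <- toupper(as.character(seed_alignment))
  if (length(rows) < 1) stop("seed alignment needs >= 1 row", call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    stop("ragged seed alignment: row lengths ",
         paste(unique(widths), collapse = ", "), call. = FALSE)
  }
  if (abs(sum(background) - 1) > 1e-9) {
    stop("background must sum to 1", call. = FALSE)
  }
  if (is.null(names(background))) names(background) <- AA_ALPHABET20
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  chars[chars == "."] <- "-"
  gap_frac <- colMeans(chars == "-")
  keep <- which(gap_frac <= 0.5)
  if (length(keep) == 0) stop("all columns are majority-gap", call. = FALSE)
  counts <- vapply(keep, function(j) {
    col <- chars[, j]
    col <- col[col != "-" & col != "X"]
    tabulate(match(col, AA_ALPHABET20), nbins = 20)
  }, numeric(20))
  counts <- t(counts)  # positions x 20
  totals <- rowSums(counts)
  bg <- background[AA_ALPHABET20]
  freq <- sweep(counts + pseudocount * rep(bg, each = nrow(counts)),
                1, totals + pseudocount, "/")
  lod <- log2(sweep(freq, 2, bg, "/"))
  colnames(lod) <- AA_ALPHABET20
  structure(
    list(id = id, length = nrow(lod), match_log_odds = lod,
         background = bg, null_calibration = NULL),
    class = "profile_model"
  )
}

#' @export
print.profile_model <- function(x, ...) {
  cat("profile_model '", x$id, "': ", x$length, " match positions",
      if (!is.null(x$null_calibration)) " (calibrated)" else "",
      "\n", sep = "")
  invisible(x)
}

# Best placement score of the profile along a residue string: local in the
# sequence, global in the profile; sequences shorter than the profile are
# scored over their best contiguous placement within the profile.
profile_window_score <- function(residues, profile) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_ALPHABET20)  # NA for 'X'
  n <- length(idx)
  L <- profile$length
  lod <- profile$match_log_odds
  persite <- function(offset, span) {
    # profile positions offset + (1:span) against sequence start..span
    pos <- offset + seq_len(span)
    r <- idx[seq_len(span)]
    s <- lod[cbind(pos, r)]
    s[is.na(s)] <- 0  # 'X' scores 0 everywhere
    sum(s)
  }
  if (n >= L) {
    scores <- vapply(0:(n - L), function(shift) {
      r <- idx[shift + seq_len(L)]
      s <- lod[cbind(seq_len(L), r)]
      s[is.na(s)] <- 0
      sum(s)
    }, numeric(1))
  } else {
    scores <- vapply(0:(L - n), function(offset) persite(offset, n),
                     numeric(1))
  }
  max(scores)
}

#' Score a sequence against a profile
#'
#' The bit-score is the best sum of per-position log-odds over all ungapped
#' placements of the full profile along the sequence. When the profile has
#' been calibrated, the E-value is
#' `n_models_equiv * exp(-(bit - mu) / beta)` under the fitted exponential
#' tail; otherwise it is `NA`.
#'
#' @param sequence character residues or a one-row data frame with
#'   `id`/`residues`.
#' @param profile a [build_profile()] result.
#' @param n_models_equiv effective number of models searched (scales the
#'   E-value linearly).
#' @return One-row data frame with columns `profile`, `bit_score`,
#'   `e_value`.
#' @export
score_profile <- function(sequence, profile, n_models_equiv = 1) {
  stopifnot(inherits(profile, "profile_model"))
  res <- if (is.data.frame(sequence)) sequence$residues else sequence
  stopifnot(nzchar(res))
  bit <- profile_window_score(toupper(res), profile)
  ev <- NA_real_
  cal <- profile$null_calibration
  if (!is.null(cal)) {
    ev <- max(0, n_models_equiv * exp(-(bit - cal$mu) / cal$beta))
  }
  data.frame(profile = profile$id, bit_score = bit, e_value = ev,
             stringsAsFactors = FALSE)
}

#' Calibrate a profile's score null distribution
#'
#' Scores `n_shuffles` random sequences drawn from the profile background
#' and fits an exponential to the upper tail of the score distribution
#' (exceedances over the `1 - tail_fraction` quantile), giving the
#' `(mu, beta)` parameters used by [score_profile()]'s E-value.
#'
#' @param profile a [build_profile()] result.
#' @param n_shuffles number of null sequences (>= 100).
#' @param seed integer seed.
#' @param seq_length length of each null sequence.
#' @param tail_fraction upper-tail mass used for the fit.
#' @return The profile with `null_calibration = list(mu, beta, tau,
#'   tail_fraction)` set.
#' @export
calibrate_null <- function(profile, n_shuffles = 1000, seed = 1,
                           seq_length = 300, tail_fraction = 0.05) {
  stopifnot(inherits(profile, "profile_model"))
  if (n_shuffles < 100) stop("n_shuffles must be >= 100", call. = FALSE)
  scores <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      res <- paste(sample(AA_ALPHABET20, seq_length, replace = TRUE,
                          prob = profile$background), collapse = "")
      profile_window_score(res, profile)
    }, numeric(1))
  })
  tau <- stats::quantile(scores, 1 - tail_fraction, names = FALSE)
  exceed <- scores[scores > tau] - tau
  if (length(exceed) < 3 || stats::sd(scores) < 1e-12 ||
      mean(exceed) < 1e-12) {
    stop("degenerate null score distribution; increase n_shuffles ",
         "or sequence length", call. = FALSE)
  }
  beta <- mean(exceed)
  # e_value(bit) = exp(-(bit - mu)/beta) with e_value(tau) = tail_fraction
  mu <- tau + beta * log(tail_fraction)
  profile$null_calibration <- list(mu = mu, beta = beta, tau = tau,
                                   tail_fraction = tail_fraction)
  profile
}

#' Score many sequences against many profiles
#'
#' @param sequences data frame with `id` and `residues` columns.
#' @param profiles named list of calibrated [build_profile()] models.
#' @param n_models_equiv effective number of models searched.
#' @return Data frame with columns `query_id`, `profile`, `bit_score`,
#'   `e_value` (one row per sequence x profile).
#' @export
score_profiles <- function(sequences, profiles, n_models_equiv = 1) {
  do.call(rbind, lapply(seq_len(nrow(sequences)), function(i) {
    hits <- do.call(rbind, lapply(profiles, function(p) {
      score_profile(sequences$residues[i], p, n_models_equiv)
    }))
    cbind(data.frame(query_id = sequences$id[i], stringsAsFactors = FALSE),
          hits)
  }))
}

#' Parse HMMER hmmscan domain table output
#'
#' Reads a `--domtblout` file and returns one hit per (query, model),
#' keeping the full-sequence bit-score (column 8) and full-sequence E-value
#' (column 7); multiple domains of the same model on one query collapse to
#' that single full-sequence record.
#'
#' @param path domain table file.
#' @return Data frame with columns `query_id`, `profile`, `bit_score`,
#'   `e_value`.
#' @export
parse_hmmscan_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(query_id = character(0), profile = character(0),
                      bit_score = numeric(0), e_value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) < 23)
  if (length(bad) > 0) {
    stop("line ", bad[1], ": malformed domtblout record (fewer than 23 ",
         "fields)", call. = FALSE)
  }
  hits <- data.frame(
    query_id = vapply(fields, `[[`, character(1), 4),
    profile = vapply(fields, `[[`, character(1), 1),
    bit_score = as.numeric(vapply(fields, `[[`, character(1), 8)),
    e_value = as.numeric(vapply(fields, `[[`, character(1), 7)),
    stringsAsFactors = FALSE
  )
  o <- order(hits$query_id, hits$profile, -hits$bit_score, hits$e_value)
  hits <- hits[o, , drop = FALSE]
  out <- hits[!duplicated(hits[, c("query_id", "profile")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
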