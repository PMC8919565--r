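# Shared internal helpers.

# 20 standard amino acids plus the ambiguity code X.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED <- c(AA_ALPHABET20, "X")

# Sentinel family label for sequences from families excluded from training.
NOVEL_FAMILY <- "NOVEL"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded package operations never perturb the
#' caller's random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_residues <- function(residues, id = "<sequence>") {
  if (!nzchar(residues)) {
    stop("sequence '", id, "' is empty", call. = FALSE)
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALLOWED))
  if (length(bad) > 0) {
    stop("sequence '", id, "' has invalid residue '", chars[bad[1]],
         "' at position ", bad[1], call. = FALSE)
  }
  invisible(TRUE)
}

# Derive a reproducible child seed from a base seed and a stream index,
# staying inside the 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 8191) %% 2147483647)
}
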