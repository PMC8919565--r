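# Synthetic family benchmark generator.
#
# Families are defined by randomized position-specific emission profiles (a
# stand-in for the common ancestor implied by homology); members are drawn
# from the profile and then mutated by a substitution/indel process whose
# rate controls how far they drift from the family consensus. Tuning the
# substitution rate targets the realized test-vs-training identity bins
# (<=30%, 30-40%, >40%) that define the twilight zone.

#' Sample a random family profile
#'
#' Each position gets a conservation weight drawn uniformly from
#' `conservation_range`; its emission distribution is the mixture
#' `c * point-mass(preferred residue) + (1 - c) * Dirichlet(1)` over the 20
#' amino acids, so fully conserved positions (`c = 1`) are degenerate and
#' unconserved positions (`c = 0`) are flat-Dirichlet draws.
#'
#' @param length number of profile positions.
#' @param conservation_range length-2 interval in `[0, 1]`.
#' @param seed integer seed.
#' @param family family identifier attached to the profile.
#' @return An object of class `family_profile` with elements `family`,
#'   `length`, `emission` (length x 20 matrix, rows summing to 1) and
#'   `conservation`.
#' @export
sample_profile <- function(length, conservation_range = c(0.7, 0.98),
                           seed, family = "F1") {
  if (length < 1) stop("profile length must be >= 1", call. = FALSE)
  if (length(conservation_range) != 2 ||
      any(!is.finite(conservation_range)) ||
      conservation_range[1] > conservation_range[2] ||
      conservation_range[1] < 0 || conservation_range[2] > 1) {
    stop("conservation_range must be an interval within [0, 1]",
         call. = FALSE)
  }
  with_seed(seed, {
    cons <- stats::runif(length, conservation_range[1], conservation_range[2])
    g <- matrix(stats::rgamma(length * 20, shape = 1), nrow = length)
    dir <- g / rowSums(g)
    preferred <- sample.int(20, length, replace = TRUE)
    emission <- (1 - cons) * dir
    emission[cbind(seq_len(length), preferred)] <-
      emission[cbind(seq_len(length), preferred)] + cons
    colnames(emission) <- AA_ALPHABET20
    structure(
      list(family = family, length = length, emission = emission,
           conservation = cons),
      class = "family_profile"
    )
  })
}

#' Consensus sequence of a profile
#'
#' @param profile a [sample_profile()] result.
#' @return Single string: the modal residue at every position.
#' @export
profile_consensus <- function(profile) {
  stopifnot(inherits(profile, "family_profile"))
  paste(AA_ALPHABET20[max.col(profile$emission, ties.method = "first")],
        collapse = "")
}

#' Specify a member divergence process
#'
#' @param substitution_rate per-site substitution probability in `[0, 1]`;
#'   substituted sites are replaced uniformly by one of the 19 other residues.
#' @param indel_rate per-site probability of an indel event.
#' @param max_indel_len cap on the geometric indel length.
#' @return A `divergence_spec` list.
#' @export
divergence_spec <- function(substitution_rate, indel_rate = 0,
                            max_indel_len = 4) {
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (substitution_rate + indel_rate > 1) {
    stop("substitution_rate + indel_rate must be <= 1", call. = FALSE)
  }
  if (max_indel_len < 1) stop("max_indel_len must be >= 1", call. = FALSE)
  structure(list(substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 max_indel_len = max_indel_len),
            class = "divergence_spec")
}

#' Emit one mutated family member
#'
#' Draws a sequence position-wise from the profile emission, substitutes each
#' site with probability `substitution_rate` (uniform over the other 19
#' residues), then applies indels: at each site, with probability
#' `indel_rate`, a deletion or an insertion (equiprobable) of geometric
#' length capped at `max_indel_len`.
#'
#' @param profile a [sample_profile()] result.
#' @param div a [divergence_spec()].
#' @param seed integer seed.
#' @param id sequence identifier.
#' @param family label to attach (defaults to the profile's family).
#' @return One-row data frame with columns `id`, `residues`, `family`.
#' @export
emit_member <- function(profile, div, seed, id = "seq1",
                        family = profile$family) {
  stopifnot(inherits(profile, "family_profile"),
            inherits(div, "divergence_spec"))
  with_seed(seed, {
    n <- profile$length
    res <- vapply(seq_len(n), function(i) {
      sample(AA_ALPHABET20, 1, prob = profile$emission[i, ])
    }, character(1))
    sub_mask <- stats::runif(n) < div$substitution_rate
    if (any(sub_mask)) {
      res[sub_mask] <- vapply(res[sub_mask], function(r) {
        sample(setdiff(AA_ALPHABET20, r), 1)
      }, character(1))
    }
    if (div$indel_rate > 0) {
      out <- character(0)
      i <- 1
      while (i <= length(res)) {
        if (stats::runif(1) < div$indel_rate) {
          len <- min(1 + stats::rgeom(1, prob = 0.5), div$max_indel_len)
          if (stats::runif(1) < 0.5) {
            i <- i + len  # deletion
            next
          } else {
            out <- c(out, sample(AA_ALPHABET20, len, replace = TRUE))
          }
        }
        out <- c(out, res[i])
        i <- i + 1
      }
      res <- out
    }
    if (length(res) == 0) res <- sample(AA_ALPHABET20, 1)
    data.frame(id = id, residues = paste(res, collapse = ""),
               family = family, stringsAsFactors = FALSE)
  })
}

#' Default divergence mixture
#'
#' Four divergence regimes mixed so the realized identity of test members to
#' their family's training members populates the easy (>40%), borderline and
#' twilight (<=40%, including <=30%) bins, with 12% of the mass on
#' substitution rates >= 0.6 (the twilight-bound regimes).
#'
#' @return Data frame with columns `substitution_rate`, `indel_rate`,
#'   `max_indel_len`, `weight` (weights summing to 1).
#' @export
default_divergence_bins <- function() {
  data.frame(
    substitution_rate = c(0.05, 0.22, 0.42, 0.62, 0.75),
    indel_rate        = c(0.01, 0.01, 0.02, 0.02, 0.03),
    max_indel_len     = 4,
    weight            = c(0.40, 0.28, 0.20, 0.07, 0.05)
  )
}

#' Generate a synthetic family benchmark
#'
#' Produces (a) a labeled main dataset of `n_families` families whose members
#' are drawn with divergence sampled from `divergence_bins`; (b) a dataset of
#' sequences from `n_novel_families` additional families, labeled `"NOVEL"`,
#' generated from profiles disjoint from the main families; and (c)
#' `n_profile_models` seed alignments for profile construction, of which a
#' fraction `overlap_fraction` derive from main-dataset family profiles (the
#' deliberate slight overlap between external profile models and the target
#' families) and the rest from independent profiles.
#'
#' @param n_families number of main families.
#' @param members_per_family members per main family (>= 13 so that a
#'   10-sequence reference sample and 3-fold cross-validation are both
#'   satisfiable).
#' @param divergence_bins data frame as in [default_divergence_bins()].
#' @param n_novel_families held-out families never used in training.
#' @param novel_members_per_family members per novel family.
#' @param n_profile_models number of seed alignments to emit.
#' @param overlap_fraction fraction of profile models derived from main
#'   families, in `[0, 1]`.
#' @param length_range profile length interval (residues).
#' @param conservation_range per-position conservation interval.
#' @param seed integer master seed; all internal draws derive from it.
#' @return List with elements `dataset` (a [family_dataset()]), `novel` (a
#'   [family_dataset()] of NOVEL-labeled sequences, or one with zero rows),
#'   `seed_alignments` (named list of character vectors of equal-length
#'   aligned rows) and `profiles` (the generating [sample_profile()]
#'   objects, kept so realized divergence can be audited).
#' @export
generate_benchmark <- function(n_families = 20, members_per_family = 60,
                               divergence_bins = default_divergence_bins(),
                               n_novel_families = 0,
                               novel_members_per_family = 12,
                               n_profile_models = 5,
                               overlap_fraction = 0.2,
                               length_range = c(120, 160),
                               conservation_range = c(0.7, 0.98),
                               seed = 1) {
  if (members_per_family < 13) {
    stop("members_per_family must be >= 13 (10 references + 3-fold CV)",
         call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (n_profile_models < 1) {
    stop("n_profile_models must be >= 1", call. = FALSE)
  }
  stopifnot(is.data.frame(divergence_bins),
            all(c("substitution_rate", "indel_rate", "max_indel_len",
                  "weight") %in% names(divergence_bins)))

  fam_ids <- sprintf("F%03d", seq_len(n_families))
  novel_ids <- sprintf("NF%03d", seq_len(n_novel_families))

  emit_family <- function(fam, profile, n_members, stream) {
    bins <- with_seed(child_seed(seed, stream), {
      sample.int(nrow(divergence_bins), n_members, replace = TRUE,
                 prob = divergence_bins$weight)
    })
    do.call(rbind, lapply(seq_len(n_members), function(j) {
      b <- divergence_bins[bins[j], ]
      div <- divergence_spec(b$substitution_rate, b$indel_rate,
                             b$max_indel_len)
      emit_member(profile, div, child_seed(seed, stream + j),
                  id = sprintf("%s_m%03d", fam, j), family = fam)
    }))
  }

  profiles <- lapply(seq_len(n_families), function(i) {
    len <- with_seed(child_seed(seed, 1000L + i), {
      sample(seq(length_range[1], length_range[2]), 1)
    })
    sample_profile(len, conservation_range,
                   seed = child_seed(seed, 2000L + i), family = fam_ids[i])
  })
  names(profiles) <- fam_ids

  main <- do.call(rbind, lapply(seq_len(n_families), function(i) {
    emit_family(fam_ids[i], profiles[[i]], members_per_family,
                stream = 10000L + i * 1000L)
  }))
  dataset <- family_dataset(main)

  if (n_novel_families > 0) {
    novel_profiles <- lapply(seq_len(n_novel_families), function(i) {
      len <- with_seed(child_seed(seed, 3000L + i), {
        sample(seq(length_range[1], length_range[2]), 1)
      })
      sample_profile(len, conservation_range,
                     seed = child_seed(seed, 4000L + i),
                     family = novel_ids[i])
    })
    novel_seqs <- do.call(rbind, lapply(seq_len(n_novel_families),
                                        function(i) {
      emit_family(novel_ids[i], novel_profiles[[i]],
                  novel_members_per_family, stream = 500000L + i * 1000L)
    }))
    novel_seqs$family <- NOVEL_FAMILY
    novel <- family_dataset(novel_seqs)
  } else {
    novel <- family_dataset(data.frame(id = character(0),
                                       residues = character(0),
                                       family = character(0)))
  }

  # Seed alignments: members emitted without indels are already column
  # aligned to the profile, so each seed is a gap-free aligned FASTA block.
  n_overlap <- round(overlap_fraction * n_profile_models)
  seed_div <- divergence_spec(0.15, 0, 1)
  seed_alignments <- lapply(seq_len(n_profile_models), function(m) {
    if (m <= n_overlap) {
      src <- profiles[[((m - 1L) %% n_families) + 1L]]
    } else {
      len <- with_seed(child_seed(seed, 6000L + m), {
        sample(seq(length_range[1], length_range[2]), 1)
      })
      src <- sample_profile(len, conservation_range,
                            seed = child_seed(seed, 7000L + m),
                            family = sprintf("EXT%02d", m))
    }
    vapply(seq_len(8), function(r) {
      emit_member(src, seed_div, child_seed(seed, 800000L + m * 100L + r),
                  id = sprintf("s%d", r))$residues
    }, character(1))
  })
  names(seed_alignments) <- sprintf("P%02d", seq_len(n_profile_models))

  list(dataset = dataset, novel = novel, seed_alignments = seed_alignments,
       profiles = profiles)
}
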