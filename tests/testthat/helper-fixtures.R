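# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small, well-separated trained benchmark reused by ensemble and
# evaluation tests: 6 families x 18 members at low divergence, 2 novel
# families, 3 profile models.
small_run <- function() {
  cached("small_run", function() {
    run_benchmark(
      n_families = 6, members_per_family = 18,
      divergence_bins = data.frame(substitution_rate = 0.08,
                                   indel_rate = 0.01, max_indel_len = 4,
                                   weight = 1),
      n_novel_families = 2, n_profile_models = 3, seed = 42
    )
  })
}

# A linearly separable two-family toy feature set (no alignment involved):
# family "A" clusters at +2 on its own similarity block, "B" at -2.
toy_features <- function(n_per = 12, shift = 2, noise = 0.3, seed = 5,
                         n_profiles = 2) {
  fams <- c("A", "B")
  profs <- paste0("P", seq_len(n_profiles))
  set.seed(seed)
  rows <- lapply(seq_len(2 * n_per), function(i) {
    fam <- fams[1 + (i > n_per)]
    sgn <- if (fam == "A") 1 else -1
    v <- stats::setNames(stats::rnorm(3 * 2 + 2 * n_profiles, sd = noise),
                         feature_names(fams, profs))
    v[1:3] <- v[1:3] + sgn * shift       # A block
    v[4:6] <- v[4:6] - sgn * shift       # B block
    v
  })
  X <- do.call(rbind, rows)
  rownames(X) <- sprintf("t%03d", seq_len(nrow(X)))
  attr(X, "family_order") <- fams
  attr(X, "profile_order") <- profs
  labels <- stats::setNames(rep(fams, each = n_per), rownames(X))
  list(X = X, labels = labels, family_order = fams, profile_order = profs)
}
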