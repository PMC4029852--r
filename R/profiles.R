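#' The default catalog of model expression profiles
#'
#' Sixteen integer shape vectors over three ordered conditions, each anchored
#' at 0 in the reference condition, covering the qualitative trajectories a
#' three-point series can take (up/down at the middle point, sustained,
#' transient, reversing). Shape 15 is (0,0,1): the one sustained-late-up
#' trajectory, distinct from shape 14's (0,0,-1).
#'
#' @param n_conditions series length; the shipped catalog is for 3 conditions.
#'   Other lengths must come from [read_profiles()].
#' @return Tibble with integer column `profile` and list-column `shape`.
#' @export
default_profiles <- function(n_conditions = 3) {
  if (n_conditions != 3) {
    abort("the shipped profile catalog is for 3 conditions; supply a profile table for other lengths.")
  }
  shapes <- list(
    c(0, 1, 2),   c(0, 2, 3),   c(0, 1, 1),   c(0, -1, -2),
    c(0, 2, 1),   c(0, -1, 0),  c(0, -2, -3), c(0, -2, -1),
    c(0, -1, -3), c(0, -1, 1),  c(0, 1, 3),   c(0, 1, 0),
    c(0, -1, -1), c(0, 0, -1),  c(0, 0, 1),   c(0, 1, -1))
  profiles <- tibble::tibble(profile = seq_along(shapes), shape = shapes)
  validate_profiles(profiles)
}

validate_profiles <- function(profiles, max_step = 2) {
  stopifnot(all(c("profile", "shape") %in% names(profiles)))
  purrr::walk2(profiles$profile, profiles$shape, function(id, s) {
    if (s[1] != 0) abort(sprintf("profile %d must be anchored at 0", id))
    if (all(s == 0)) abort(sprintf("profile %d is constant", id))
    if (any(abs(diff(s)) > max_step)) {
      abort(sprintf("profile %d has a step larger than %d", id, max_step))
    }
  })
  keys <- vapply(profiles$shape, paste, character(1), collapse = ",")
  if (anyDuplicated(keys)) abort("duplicate profile shapes.")
  profiles
}

#' Read a model-profile table
#'
#' TSV with columns `profile` (integer id) and `shape` (comma-separated
#' integers, first 0).
#'
#' @param path path to the TSV.
#' @return Validated profile tibble as from [default_profiles()].
#' @export
read_profiles <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  shapes <- purrr::map(strsplit(as.character(tab$shape), ","), as.numeric)
  validate_profiles(tibble::tibble(profile = as.integer(tab$profile), shape = shapes))
}

#' Anchored log2-ratio vectors for a gene set
#'
#' Converts per-condition mean log2 signals into trajectories relative to the
#' reference condition: v\[t\] = mean log2 signal at condition t minus mean
#' log2 signal at the reference, so v\[1\] is identically 0.
#'
#' @param x an [expr_matrix()].
#' @param genes probe ids to convert (default: all).
#' @return Tibble with `probe` and list-column `v` (numeric, length =
#'   number of conditions, first element 0).
#' @export
log2_ratio_vectors <- function(x, genes = rownames(x$signals)) {
  means <- condition_log2_means(x, genes)
  m <- as.matrix(means[, -1, drop = FALSE])
  v <- m - m[, 1]
  tibble::tibble(probe = means$probe,
                 v = purrr::map(seq_len(nrow(v)), function(i) unname(v[i, ])))
}

# correlation-based best profile for a matrix of ratio vectors (rows);
# flat rows get NA. ties -> lowest profile id.
best_profile <- function(vmat, profiles) {
  shapes <- vapply(profiles$shape, identity, numeric(length(profiles$shape[[1]])))
  flat <- apply(vmat, 1, function(r) stats::sd(r) == 0)
  out <- rep(NA_integer_, nrow(vmat))
  if (any(!flat)) {
    cors <- stats::cor(t(vmat[!flat, , drop = FALSE]), shapes)
    pick <- apply(cors, 1, which.max)  # which.max takes the first (lowest id) on ties
    out[!flat] <- profiles$profile[pick]
  }
  out
}

#' Assign ratio vectors to model profiles
#'
#' Each gene is assigned to the profile maximizing the Pearson correlation
#' between its ratio vector and the integer profile shape. Flat
#' (zero-variance) vectors are unassigned; correlation ties break to the
#' lowest profile id.
#'
#' @param vectors tibble from [log2_ratio_vectors()].
#' @param profiles profile catalog, default [default_profiles()].
#' @param min_corr minimum correlation with the best profile; below it the
#'   gene is left unassigned (default 0 = only flat vectors unassigned).
#' @return The input tibble with added columns `profile` (integer or NA) and
#'   `corr` (correlation with the assigned profile).
#' @export
assign_profiles <- function(vectors, profiles = default_profiles(), min_corr = 0) {
  if (nrow(profiles) == 0) abort("empty profile set.")
  if (nrow(vectors) == 0) {
    return(dplyr::mutate(vectors, profile = integer(), corr = numeric()))
  }
  vmat <- do.call(rbind, vectors$v)
  prof <- best_profile(vmat, profiles)
  shapes <- vapply(profiles$shape, identity, numeric(ncol(vmat)))
  corr <- rep(NA_real_, nrow(vmat))
  ok <- !is.na(prof)
  if (any(ok)) {
    idx <- match(prof[ok], profiles$profile)
    corr[ok] <- vapply(which(ok), function(i) {
      stats::cor(vmat[i, ], shapes[, match(prof[i], profiles$profile)])
    }, numeric(1))
  }
  drop <- ok & corr < min_corr
  prof[drop] <- NA_integer_
  corr[drop] <- NA_real_
  dplyr::mutate(vectors, profile = prof, corr = corr)
}

# all permutations of 1..n (n small), identity first
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  perms <- list()
  for (p in all_perms(n - 1)) {
    for (pos in n:1) perms <- c(perms, list(append(p, n, after = pos - 1)))
  }
  perms[order(vapply(perms, paste, character(1), collapse = ","))]
}

#' Permutation-expected profile counts
#'
#' The null for profile significance: for every permutation of the condition
#' positions (all n! orderings, identity included), each gene's ratio vector
#' is permuted, re-anchored to 0 at its new first position, and re-assigned;
#' the expected count of a profile is the mean count over the permutations.
#' With 3 conditions every expected count is therefore a multiple of 1/6, and
#' the expected counts sum exactly to the assigned counts (flatness is
#' permutation-invariant).
#'
#' @inheritParams assign_profiles
#' @return Tibble with `profile` and `expected`, one row per catalog profile.
#' @export
expected_counts <- function(vectors, profiles = default_profiles(), min_corr = 0) {
  if (nrow(profiles) == 0) abort("empty profile set.")
  k <- length(profiles$shape[[1]])
  perms <- all_perms(k)
  counts <- stats::setNames(numeric(nrow(profiles)), profiles$profile)
  if (nrow(vectors) > 0) {
    vmat <- do.call(rbind, vectors$v)
    for (perm in perms) {
      pv <- vmat[, perm, drop = FALSE]
      pv <- pv - pv[, 1]
      assigned <- assign_profiles(
        tibble::tibble(probe = vectors$probe,
                       v = purrr::map(seq_len(nrow(pv)), function(i) pv[i, ])),
        profiles, min_corr = min_corr)$profile
      tab <- table(factor(assigned, levels = profiles$profile))
      counts <- counts + as.numeric(tab)
    }
  }
  tibble::tibble(profile = profiles$profile, expected = unname(counts) / length(perms))
}

#' Exact binomial upper-tail significance of a profile count
#'
#' P(X >= assigned) for X ~ Binomial(total, expected / total), accumulated in
#' log space so tails far below double underflow (1e-300) are representable.
#' An observed count at or below expectation is simply non-significant (p
#' near or above 0.5); counts far above expectation give the extreme tails.
#'
#' @param assigned observed number of genes in the profile (integer).
#' @param expected permutation-expected number (real, >= 0).
#' @param total number of genes entered into the clustering.
#' @return The upper-tail p-value.
#' @examples
#' profile_significance(864, 483.67, 5127)
#' @export
profile_significance <- function(assigned, expected, total) {
  stopifnot(length(assigned) == 1, length(expected) == 1, length(total) == 1)
  if (assigned < 0 || assigned > total) abort("need 0 <= assigned <= total.")
  if (expected < 0 || expected > total) abort("need 0 <= expected <= total.")
  if (assigned == 0) return(1.0)
  if (expected == 0) {
    warn("expected = 0 with assigned > 0; returning p = 0 by convention")
    return(0.0)
  }
  prob <- expected / total
  # log-space sum of the exact binomial pmf over assigned..total
  log_terms <- dbinom(seq(assigned, total), total, prob, log = TRUE)
  mx <- max(log_terms)
  exp(mx + log(sum(exp(log_terms - mx)))) |> min(1.0)
}

#' Profile assignment statistics
#'
#' Combines observed counts, permutation-expected counts and binomial tail
#' p-values into one per-profile table.
#'
#' @inheritParams assign_profiles
#' @return A `profile_stats` tibble: `profile`, `shape` (printed form),
#'   `assigned`, `expected`, `p`.
#' @export
profile_stats <- function(vectors, profiles = default_profiles(), min_corr = 0) {
  assigned_tbl <- assign_profiles(vectors, profiles, min_corr)
  tab <- table(factor(assigned_tbl$profile, levels = profiles$profile))
  expected <- expected_counts(vectors, profiles, min_corr)
  total <- nrow(vectors)
  out <- tibble::tibble(
    profile = profiles$profile,
    shape = vapply(profiles$shape, function(s) paste0("(", paste(s, collapse = ","), ")"),
                   character(1)),
    assigned = as.integer(tab),
    expected = expected$expected) |>
    dplyr::mutate(p = purrr::map2_dbl(.data$assigned, .data$expected,
                                      profile_significance, total = total))
  class(out) <- c("profile_stats", class(out))
  out
}

#' Significant profiles at a level alpha
#'
#' @param stats a `profile_stats` tibble (or any tibble with `profile`, `p`).
#' @param alpha significance level (exclusive).
#' @return Integer profile ids with p < alpha, ordered by ascending p.
#' @export
significant_profiles <- function(stats, alpha = 0.05) {
  hit <- stats[stats$p < alpha, ]
  hit$profile[order(hit$p)]
}
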