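test_that("the default profile catalog is valid, complete and unique", {
  prof <- default_profiles()
  expect_equal(nrow(prof), 16)
  expect_true(all(vapply(prof$shape, function(s) s[1] == 0, logical(1))))
  expect_false(any(vapply(prof$shape, function(s) all(s == 0), logical(1))))
  expect_true(all(vapply(prof$shape, function(s) max(abs(diff(s))), numeric(1)) <= 2))
  keys <- vapply(prof$shape, paste, character(1), collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  # the two late-change shapes are distinct: (0,0,-1) vs (0,0,1)
  expect_false(identical(prof$shape[[14]], prof$shape[[15]]))
  expect_equal(prof$shape[[15]], c(0, 0, 1))
})

test_that("profile tables read from TSV and reject invalid shapes", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("profile\tshape", "1\t0,1,2", "2\t0,-1,0"), tsv)
  prof <- read_profiles(tsv)
  expect_equal(prof$shape[[2]], c(0, -1, 0))
  writeLines(c("profile\tshape", "1\t1,1,2"), tsv)
  expect_error(read_profiles(tsv), "anchored at 0")
  writeLines(c("profile\tshape", "1\t0,0,0"), tsv)
  expect_error(read_profiles(tsv), "constant")
  writeLines(c("profile\tshape", "1\t0,3,0"), tsv)
  expect_error(read_profiles(tsv), "step larger")
})

test_that("log2 ratio vectors anchor at the reference condition", {
  em <- tiny_matrix(list(pA = log2(c(100, 200, 50)), pB = log2(c(7, 7, 7))))
  vec <- log2_ratio_vectors(em)
  expect_equal(vec$v[[1]], c(0, 1, -1))
  expect_equal(vec$v[[2]], c(0, 0, 0))
  expect_error(log2_ratio_vectors(em, "nope"), "unknown probe")
})

test_that("ratio vectors match a brute-force recomputation from replicates", {
  sim <- generate_expression(synth_config(n_genes = 100, seed = 15))
  vec <- log2_ratio_vectors(sim$matrix)
  lg <- log2(sim$matrix$signals)
  cond <- sim$matrix$sample_sheet$condition
  for (i in sample(100, 20)) {
    means <- vapply(c("T0", "T1", "T2"), function(cc) mean(lg[i, cond == cc]),
                    numeric(1))
    expect_equal(vec$v[[i]], unname(means - means[1]), tolerance = 1e-12)
  }
})

test_that("profile assignment maximizes correlation with the shape", {
  prof <- default_profiles()
  vec <- tibble::tibble(probe = c("a", "b", "c"),
                        v = list(c(0, 1, 0), c(0, 0.8, 1.7), c(0, 0, 0)))
  got <- assign_profiles(vec, prof)
  expect_equal(got$profile[1], 12)       # exact match, r = 1
  expect_equal(got$corr[1], 1)
  # brute-force oracle over all 16 shapes for the interior case
  brute <- which.max(vapply(prof$shape, function(s) cor(c(0, 0.8, 1.7), s),
                            numeric(1)))
  expect_equal(got$profile[2], prof$profile[brute])
  expect_equal(got$profile[2], 1)        # rises toward (0,1,2)
  expect_true(is.na(got$profile[3]))     # flat vectors stay unassigned
})

test_that("assignment is invariant to positive rescaling of the vector", {
  prof <- default_profiles()
  set.seed(21)
  for (i in 1:50) {
    v <- c(0, rnorm(2))
    if (sd(v) == 0) next
    scale <- runif(1, 0.1, 10)
    a1 <- assign_profiles(tibble::tibble(probe = "x", v = list(v)), prof)$profile
    a2 <- assign_profiles(tibble::tibble(probe = "x", v = list(v * scale)), prof)$profile
    expect_equal(a1, a2)
  }
})

test_that("expected counts enumerate all six condition permutations", {
  prof <- default_profiles()
  vec <- tibble::tibble(probe = "g", v = list(c(0, 1, 0)))
  ex <- expected_counts(vec, prof)
  # the 6 permutations of (0,1,0), re-anchored, are (0,1,0) x2, (0,0,1) x2,
  # (0,-1,-1) x2 -> expected 1/3 for profiles 12, 15, 13 and 0 elsewhere
  want <- setNames(rep(0, 16), 1:16)
  want[c("12", "15", "13")] <- 1 / 3
  expect_equal(ex$expected, unname(want[as.character(ex$profile)]))
})

test_that("expected counts conserve the assigned total and use 1/6 granularity", {
  prof <- default_profiles()
  set.seed(31)
  for (i in 1:5) {
    n <- sample(10:80, 1)
    vec <- tibble::tibble(
      probe = paste0("g", seq_len(n)),
      v = purrr::map(seq_len(n), ~ c(0, round(rnorm(2), 2))))
    assigned <- assign_profiles(vec, prof)
    ex <- expected_counts(vec, prof)
    expect_equal(sum(ex$expected), sum(!is.na(assigned$profile)), tolerance = 1e-9)
    expect_equal(ex$expected * 6, round(ex$expected * 6), tolerance = 1e-9)
  }
})

test_that("flat vectors contribute nothing to any expected count", {
  prof <- default_profiles()
  ex <- expected_counts(tibble::tibble(probe = "flat", v = list(c(0, 0, 0))), prof)
  expect_equal(ex$expected, rep(0, 16))
})

test_that("binomial profile significance matches enumeration and conventions", {
  # exhaustive oracle: P(X >= 8), X ~ Bin(10, 1/2) = (45 + 10 + 1)/1024
  expect_equal(profile_significance(8, 5, 10), 56 / 1024, tolerance = 1e-12)
  expect_equal(profile_significance(0, 3, 10), 1.0)
  expect_warning(p0 <- profile_significance(2, 0, 10), "expected = 0")
  expect_equal(p0, 0)
  # agreement with an independent tail implementation across magnitudes
  set.seed(55)
  for (i in 1:25) {
    total <- sample(50:5000, 1)
    expected <- runif(1, 0.5, total / 3)
    assigned <- sample(seq_len(total), 1)
    mine <- profile_significance(assigned, expected, total)
    ref <- pbinom(assigned - 1, total, expected / total, lower.tail = FALSE)
    if (ref > 0) {
      expect_equal(log(mine), log(ref), tolerance = 1e-8)
    } else {
      expect_lt(mine, 1e-300)
    }
  }
})

test_that("log-space accumulation survives tails far below double underflow", {
  p <- profile_significance(5000, 100, 5127)
  expect_gte(p, 0)
  expect_lt(p, 1e-300)
})

test_that("significant profiles are ordered by ascending p", {
  tab <- series_profile_table()
  stats <- dplyr::mutate(tab, p = purrr::map2_dbl(assigned, expected,
                                                  profile_significance,
                                                  total = 5127))
  sel <- significant_profiles(stats, 0.05)
  expect_equal(sel, c(12, 16, 10, 6, 5))
  expect_equal(sel, stats$profile[order(stats$p)][1:5])
  expect_equal(significant_profiles(stats, 0), integer(0))
})

test_that("profile statistics integrate assignment, expectation and significance", {
  sim <- generate_expression(synth_config(n_genes = 2000, seed = 91))
  de <- sim$truth$genes$gene[sim$truth$genes$is_de]
  ps <- profile_stats(log2_ratio_vectors(sim$matrix, de))
  expect_equal(sum(ps$assigned), length(de))
  expect_equal(sum(ps$expected), sum(ps$assigned), tolerance = 1e-9)
  expect_true(all(ps$p >= 0 & ps$p <= 1))
  # planted profiles must dominate their permutation expectation
  planted <- sort(unique(sim$truth$genes$profile[sim$truth$genes$is_de]))
  expect_true(all(ps$p[ps$profile %in% planted] < 0.05))
})
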