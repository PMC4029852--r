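#' Fit the randomized variance model prior
#'
#' Under the randomized variance model each gene's residual precision
#' 1/sigma^2 is Gamma(shape a, scale b). Marginally the residual mean square
#' s^2 then satisfies s^2 * a * b ~ F(m, 2a), where m is the residual degrees
#' of freedom (common across genes in a balanced, complete design). The prior
#' (a, b) is fitted by maximizing the summed log marginal density of the
#' observed per-gene s^2 values, optimizing over (log a, log b) from a
#' moment-based start so positivity is structural and the fit deterministic.
#'
#' @param x an [expr_matrix()]. Signals are log2-transformed before the
#'   within-condition residual mean squares are computed.
#' @param s2_floor values of s^2 below this floor are raised to it, with a
#'   warning (an exactly-zero residual has measure zero under the model).
#' @return An object of class `rvm_prior`: list with `a`, `b`, `m` (residual
#'   df), `loglik`, and `n_genes`.
#' @examples
#' sim <- generate_expression(synth_config(n_genes = 300, seed = 42))
#' fit_rvm_prior(sim$matrix)
#' @export
fit_rvm_prior <- function(x, s2_floor = 1e-12) {
  stopifnot(inherits(x, "expr_matrix"))
  rs <- residual_stats(x)
  s2 <- rs$s2
  m <- rs$m
  if (max(s2) - min(s2) < 1e-14) {
    abort("prior degenerate (a -> infinity): all residual mean squares identical.")
  }
  if (any(s2 < s2_floor)) {
    warn(sprintf("%d residual mean square(s) below %g floored", sum(s2 < s2_floor), s2_floor))
    s2 <- pmax(s2, s2_floor)
  }

  # log marginal density of one s2: ab * f_F(s2 * ab; m, 2a)
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(df(s2 * a * b, m, 2 * a, log = TRUE) + log(a * b))
  }
  # moment start: E[s2] = 1/(b(a-1)) for a > 1; start a at 3
  a0 <- 3
  b0 <- 1 / (mean(s2) * (a0 - 1))
  fit <- optim(log(c(a0, b0)), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  if (fit$convergence != 0) {
    abort("RVM prior fit did not converge.")
  }
  structure(list(a = exp(fit$par[1]), b = exp(fit$par[2]), m = m,
                 loglik = -fit$value, n_genes = length(s2)),
            class = "rvm_prior")
}

#' @export
print.rvm_prior <- function(x, ...) {
  cat(sprintf("<rvm_prior> a = %.3f, b = %.3f, m = %d df, %d genes, logLik = %.2f\n",
              x$a, x$b, x$m, x$n_genes, x$loglik))
  invisible(x)
}

#' @rdname fit_rvm_prior
#' @param x an `rvm_prior`.
#' @param ... unused.
#' @export
glance.rvm_prior <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, m = x$m, df2 = x$m + 2 * x$a,
                 loglik = x$loglik, n_genes = x$n_genes)
}

# per-gene within-condition residual mean square on log2 signals, plus
# between-condition mean square, for a balanced complete layout
residual_stats <- function(x) {
  lg <- log2(x$signals)
  cond <- x$sample_sheet$condition[match(colnames(lg), x$sample_sheet$sample_id)]
  conds <- x$condition_order
  k <- length(conds)
  n_tot <- ncol(lg)
  if (any(!is.finite(lg))) abort("missing or non-finite log2 signals are not supported.")
  m <- n_tot - k
  if (m < 1) abort("no residual degrees of freedom (need replicates).")

  group_means <- vapply(conds, function(cc) rowMeans(lg[, cond == cc, drop = FALSE]),
                        numeric(nrow(lg)))
  if (nrow(lg) == 1L) group_means <- matrix(group_means, 1, k, dimnames = list(rownames(lg), conds))
  n_per <- vapply(conds, function(cc) sum(cond == cc), integer(1))
  fitted <- group_means[, match(cond, conds), drop = FALSE]
  ss_within <- rowSums((lg - fitted)^2)
  grand <- rowMeans(lg)
  ss_between <- as.numeric(group_means^2 %*% n_per) - n_tot * grand^2
  list(s2 = unname(ss_within) / m, ms_between = unname(ss_between) / (k - 1),
       group_means = group_means, m = m, k = k)
}

#' Moderated F-test under the randomized variance model
#'
#' The residual variance is shrunk toward the prior,
#' sigma_tilde^2 = (m s^2 + 2/b) / (m + 2a), and the moderated statistic
#' F = MS_between / sigma_tilde^2 is referred to F(k - 1, m + 2a): the prior
#' adds 2a denominator degrees of freedom, which is what rescues power with
#' triplicate designs.
#'
#' @param x an [expr_matrix()].
#' @param prior an `rvm_prior`, typically fitted on the same matrix.
#' @return A tibble with one row per probe: per-condition mean log2 signals
#'   (`mean_<condition>`), `s2`, `s2_tilde`, `f_mod`, `df1`, `df2`, `p`, `q`
#'   (Benjamini-Hochberg adjusted).
#' @export
rvm_f_test <- function(x, prior) {
  stopifnot(inherits(x, "expr_matrix"), inherits(prior, "rvm_prior"))
  rs <- residual_stats(x)
  if (rs$m != prior$m) {
    abort(sprintf("prior was fitted with m = %d residual df but matrix has m = %d",
                  prior$m, rs$m))
  }
  s2_tilde <- (rs$m * rs$s2 + 2 / prior$b) / (rs$m + 2 * prior$a)
  f_mod <- pmax(rs$ms_between, 0) / s2_tilde
  df1 <- rs$k - 1
  df2 <- rs$m + 2 * prior$a
  p <- pf(f_mod, df1, df2, lower.tail = FALSE)
  means <- tibble::as_tibble(rs$group_means)
  names(means) <- paste0("mean_", x$condition_order)
  dplyr::bind_cols(tibble::tibble(probe = rownames(x$signals)), means) |>
    dplyr::mutate(s2 = rs$s2, s2_tilde = s2_tilde, f_mod = f_mod,
                  df1 = df1, df2 = df2, p = p, q = bh_fdr(p))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, clipped to 1, monotone in p-rank.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    abort("p-values must be finite and within [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed genes
#'
#' Applies the conjunction of a raw p-value threshold and an FDR threshold.
#'
#' @param results tibble from [rvm_f_test()].
#' @param p_max raw p-value cutoff (exclusive).
#' @param q_max FDR cutoff (exclusive).
#' @return Character vector of selected probe ids.
#' @export
select_degs <- function(results, p_max = 0.05, q_max = 0.05) {
  stopifnot(all(c("probe", "p", "q") %in% names(results)))
  results$probe[results$p < p_max & results$q < q_max]
}

#' One-way ANOVA with Fisher's least-significant-difference test
#'
#' Classic one-way ANOVA followed by all pairwise LSD comparisons,
#' LSD = t(1 - alpha/2, df_within) * sqrt(MSW (1/n_i + 1/n_j)), and a
#' compact-letter display (groups sharing a letter do not differ at `alpha`).
#'
#' @param groups named list of numeric vectors (one per group, >= 2 values
#'   each), or a data frame with columns `group` and `value`.
#' @param alpha significance level.
#' @return An `anova_lsd` list: `f`, `p`, `df1`, `df2`, `msw`, `pairwise`
#'   tibble (group_i, group_j, diff, lsd, significant) and `letters` tibble
#'   (group, mean, letters).
#' @examples
#' one_way_anova_lsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova_lsd <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2) abort("need >= 2 groups.")
  if (any(lengths(groups) < 2)) abort("every group needs >= 2 values.")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))

  dat <- tibble::tibble(
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups)),
    value = unlist(groups, use.names = FALSE))
  fit <- aov(value ~ group, data = dat)
  atab <- summary(fit)[[1]]
  f <- atab[["F value"]][1]
  p <- atab[["Pr(>F)"]][1]
  df2 <- atab[["Df"]][2]
  msw <- atab[["Mean Sq"]][2]

  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  combos <- utils::combn(names(groups), 2)
  pairwise <- purrr::map2(combos[1, ], combos[2, ], function(i, j) {
    lsd <- qt(1 - alpha / 2, df2) * sqrt(msw * (1 / ns[[i]] + 1 / ns[[j]]))
    tibble::tibble(group_i = i, group_j = j, diff = means[[i]] - means[[j]],
                   lsd = lsd, significant = abs(means[[i]] - means[[j]]) > lsd)
  }) |> dplyr::bind_rows()

  structure(list(f = f, p = p, df1 = atab[["Df"]][1], df2 = df2, msw = msw,
                 pairwise = pairwise,
                 letters = lsd_letters(means, pairwise)),
            class = "anova_lsd")
}

# insert-and-absorb compact letter display from a pairwise significance table
lsd_letters <- function(means, pairwise) {
  ord <- names(sort(means, decreasing = TRUE))
  differ <- function(i, j) {
    hit <- pairwise[(pairwise$group_i == i & pairwise$group_j == j) |
                      (pairwise$group_i == j & pairwise$group_j == i), ]
    nrow(hit) > 0 && hit$significant[1]
  }
  sets <- list()
  for (g in ord) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(vapply(sets[[s]], function(o) differ(g, o), logical(1)))) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  labels <- vapply(ord, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  tibble::tibble(group = ord, mean = unname(means[ord]), letters = unname(labels))
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("<anova_lsd> F(%d, %d) = %.3f, p = %.4g\n", x$df1, x$df2, x$f, x$p))
  print(x$letters)
  invisible(x)
}

#' @rdname one_way_anova_lsd
#' @param x an `anova_lsd` object.
#' @param ... unused.
#' @export
tidy.anova_lsd <- function(x, ...) x$pairwise

#' @rdname one_way_anova_lsd
#' @export
glance.anova_lsd <- function(x, ...) {
  tibble::tibble(f = x$f, p = x$p, df1 = x$df1, df2 = x$df2, msw = x$msw)
}
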