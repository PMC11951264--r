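#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres the squared distance matrix (`G = -C (D*D/2) C` with
#' `C = I - 11'/n`), eigendecomposes it, and returns sample coordinates on
#' the axes with positive eigenvalues, scaled by the square root of the
#' eigenvalue. Negative eigenvalues (from non-Euclidean distances such as
#' Bray-Curtis) are reported as-is; no correction is applied by default.
#' For a Euclidean input matrix the embedded pairwise distances reproduce
#' the input exactly.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return object of class `"hfa_pcoa"`: list with `coordinates` (samples x
#'   positive axes), `eigenvalues` (all, descending) and
#'   `proportion_explained` (per positive axis, relative to the positive
#'   eigenvalue total).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-10))
    value_error("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12))
    value_error("distance matrix must have a zero diagonal")
  A <- -0.5 * d^2
  G <- A - matrix(rowMeans(A), n, n) -
    matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  pos <- which(e$values > max(e$values[1], 0) * 1e-10 & e$values > 0)
  coords <- if (length(pos) > 0)
    e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                            length(pos)) else
    matrix(0, n, 0)
  rownames(coords) <- rownames(d)
  if (ncol(coords) > 0)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    eigenvalues = e$values,
    proportion_explained = if (length(pos) > 0)
      e$values[pos] / sum(e$values[pos]) else numeric()
  ), class = "hfa_pcoa")
}

# all permutations of 1..n as rows (n! x n); recursive construction
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# hat matrix for a model matrix via QR
hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Permutational multivariate analysis of variance
#'
#' Partitions a distance matrix among factors by sequential (Type I) sums of
#' squares on the Gower-centred inner-product matrix, with significance from
#' free permutation of sample labels: per factor, pseudo-F is
#' `(SS_f / df_f) / (SS_res / df_res)` and
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`. Sequential R-squared per
#' factor plus the residual sums to 1.
#'
#' @param d symmetric distance matrix, samples in the same order as `factors`.
#' @param factors data.frame of grouping factors (one column per term).
#' @param terms character vector giving the sequential term order; defaults
#'   to the column order of `factors`.
#' @param n_perm number of permutations (999 by default).
#' @param seed integer seed for the permutations (required for
#'   reproducibility; the session RNG is untouched).
#' @param exact enumerate all `n!` label permutations instead of sampling
#'   (only sensible for n <= 8); the p-value is then
#'   `#[F_perm >= F_obs] / n!`, the identity permutation included.
#' @return object of class `"hfa_permanova"`: list with `table` (term, df,
#'   sum_sq, r_squared, pseudo_f, p_value; plus Residual and Total rows),
#'   `n_perm`, `seed`.
#' @export
permanova <- function(d, factors, terms = names(factors), n_perm = 999,
                      seed = NULL, exact = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  factors <- as.data.frame(factors)
  if (nrow(factors) != n)
    value_error("factors must have one row per sample")
  if (n_perm < 1) value_error("n_perm must be >= 1")
  for (trm in terms) {
    f <- factors[[trm]]
    if (length(unique(f)) < 2L)
      degenerate_factor_error(sprintf("factor '%s' is constant", trm))
  }
  A <- -0.5 * d^2
  G <- A - matrix(rowMeans(A), n, n) -
    matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  ss_total <- sum(diag(G))
  # cumulative hat matrices over the sequential model
  X <- matrix(1, n, 1)
  hats <- list(); dfs <- integer(length(terms))
  rank_prev <- 1L
  for (i in seq_along(terms)) {
    X <- cbind(X, stats::model.matrix(~f, data.frame(f = factor(factors[[terms[i]]])))[, -1, drop = FALSE])
    q <- qr(X)
    dfs[i] <- q$rank - rank_prev
    rank_prev <- q$rank
    hats[[i]] <- hat_matrix(X)
  }
  df_res <- n - rank_prev
  if (df_res < 1)
    insufficient_data_error("no residual degrees of freedom")
  H0 <- matrix(1 / n, n, n)
  stat <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss <- diff(c(sum(H0 * Gp), tr))
    ss_res <- sum(diag(Gp)) - tr[length(tr)] + sum(H0 * Gp)
    list(ss = ss, ss_res = ss_res,
         f = (ss / dfs) / (ss_res / df_res))
  }
  obs <- stat(G)
  exceed <- rep(0L, length(terms))
  if (exact) {
    if (n > 8L) value_error("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    for (b in seq_len(nrow(perms))) {
      p <- perms[b, ]
      f_perm <- stat(G[p, p])$f
      exceed <- exceed + (f_perm >= obs$f - 1e-12)
    }
    pvals <- exceed / nrow(perms)
    n_perm <- nrow(perms)
  } else {
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        p <- sample.int(n)
        f_perm <- stat(G[p, p])$f
        exceed <- exceed + (f_perm >= obs$f - 1e-12)
      }
      exceed
    }) -> exceed
    pvals <- (1 + exceed) / (1 + n_perm)
  }
  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    sum_sq = c(obs$ss, obs$ss_res, ss_total),
    r_squared = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    pseudo_f = c(obs$f, NA, NA),
    p_value = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab, n_perm = n_perm, seed = seed),
            class = "hfa_permanova")
}

#' @export
print.hfa_permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS,", x$n_perm, "permutations)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# compact letter display: groups sharing a letter are not significantly
# different. Insert-and-absorb over the significant-pair constraints.
compact_letters <- function(group_names, sig_pairs) {
  sets <- list(group_names)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$a[k]; b <- sig_pairs$b[k]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) for (j in seq_along(new_sets))
      if (i != j && keep[i] && keep[j] &&
          all(new_sets[[i]] %in% new_sets[[j]]) &&
          length(new_sets[[i]]) < length(new_sets[[j]]))
        keep[i] <- FALSE
    sets <- unique(new_sets[keep])
  }
  letters_out <- stats::setNames(rep("", length(group_names)), group_names)
  for (i in seq_along(sets))
    for (g in sets[[i]])
      letters_out[g] <- paste0(letters_out[g], letters[i])
  # order letters within each group label
  vapply(strsplit(letters_out, ""), function(ch)
    paste(sort(ch), collapse = ""), character(1))
}

#' One-way ANOVA with Bonferroni post-hoc letters
#'
#' Omnibus one-way ANOVA followed by all pairwise comparisons (pooled-SD
#' t-tests) with Bonferroni adjustment, summarised as a compact letter
#' display in which groups sharing a letter do not differ at `alpha`.
#'
#' @param values numeric response.
#' @param groups grouping vector, same length.
#' @param alpha significance level for the letter display.
#' @return list with `f` (omnibus F), `df`, `p_value`, `pairwise`
#'   (data.frame `a`, `b`, `p_adjusted`) and `letters` (named by group,
#'   ordered by decreasing group mean).
#' @export
one_way_anova_bonferroni <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  tabn <- table(groups)
  if (length(tabn) < 2L)
    insufficient_data_error("need at least two groups")
  if (any(tabn < 2L))
    insufficient_data_error(sprintf("group(s) with fewer than 2 values: %s",
                                    paste(names(tabn)[tabn < 2], collapse = ", ")))
  fit <- stats::aov(values ~ factor(groups))
  an <- stats::anova(fit)
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  pm <- pw$p.value
  pairs <- do.call(rbind, lapply(rownames(pm), function(r)
    do.call(rbind, lapply(colnames(pm), function(c)
      if (!is.na(pm[r, c]))
        data.frame(a = r, b = c, p_adjusted = pm[r, c],
                   stringsAsFactors = FALSE)))))
  rownames(pairs) <- NULL
  means <- tapply(values, groups, mean)
  ord <- names(sort(means, decreasing = TRUE))
  sig <- pairs[pairs$p_adjusted < alpha, , drop = FALSE]
  letts <- compact_letters(ord, sig)
  list(f = an[["F value"]][1], df = an[["Df"]],
       p_value = an[["Pr(>F)"]][1], pairwise = pairs, letters = letts)
}

#' Two-sample t-test
#'
#' Welch (default) or Student two-sample t-test. When both sides have zero
#' variance and equal means the statistic is taken as 0 with p = 1, by
#' convention, with a message.
#'
#' @param a,b numeric samples (>= 2 values each).
#' @param variant `"welch"` or `"student"`.
#' @return list with `t`, `df`, `p_value`, `mean_difference`.
#' @export
two_sample_t <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    insufficient_data_error("need at least two values per sample")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      message("both samples constant and equal; t = 0, p = 1 by convention")
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                  mean_difference = 0))
    }
    value_error("both samples constant with different means: t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "student"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(a) - mean(b))
}

#' Normality and variance-homogeneity gate
#'
#' Runs a Shapiro-Wilk test on the within-group residuals and Levene's test
#' across groups; if either fails at `alpha`, applies `transform` (default
#' `log(x + 1)`, appropriate for positive-skew data) and re-tests. The
#' returned values are the ones downstream tests should use.
#'
#' @param values numeric response.
#' @param groups grouping vector.
#' @param alpha gate level (0.05).
#' @param transform transformation applied on failure.
#' @return list: `normality_p`, `levene_p`, `transformed` (logical),
#'   `normality_p_after`, `levene_p_after` (NA if no transform), `values`
#'   (possibly transformed), `degenerate` (TRUE when the tests are
#'   undefined, e.g. constant data).
#' @export
assumption_gate <- function(values, groups, alpha = 0.05,
                            transform = function(x) log(x + 1)) {
  if (length(values) < 3L)
    insufficient_data_error("need at least three values")
  groups <- factor(groups)
  run_tests <- function(v) {
    res <- v - stats::ave(v, groups)
    sw <- tryCatch(stats::shapiro.test(res)$p.value,
                   error = function(e) NA_real_)
    lv <- if (nlevels(groups) >= 2L && all(table(groups) >= 2L))
      tryCatch(car::leveneTest(v ~ groups)[1, "Pr(>F)"],
               error = function(e) NA_real_) else NA_real_
    c(sw = sw, lv = lv)
  }
  p0 <- run_tests(values)
  degenerate <- all(is.na(p0))
  fail <- !degenerate && any(p0 < alpha, na.rm = TRUE)
  out <- list(normality_p = unname(p0["sw"]), levene_p = unname(p0["lv"]),
              transformed = FALSE, normality_p_after = NA_real_,
              levene_p_after = NA_real_, values = values,
              degenerate = degenerate)
  if (fail) {
    tv <- transform(values)
    if (any(!is.finite(tv))) {
      warning("transform produced non-finite values; raw values retained",
              call. = FALSE)
      return(out)
    }
    p1 <- run_tests(tv)
    out$transformed <- TRUE
    out$normality_p_after <- unname(p1["sw"])
    out$levene_p_after <- unname(p1["lv"])
    out$values <- tv
  }
  out
}

#' Simple linear regression of mean HFA on a predictor
#'
#' Ordinary least squares of the response on one predictor, reporting the
#' slope, intercept, R-squared and the slope's two-sided p-value.
#'
#' @param y response (e.g. per-pair mean HFA, percent).
#' @param x predictor (e.g. Bray-Curtis or dissimilarity abundance).
#' @return object of class `"hfa_linkage"`: list with `coefficients`
#'   (intercept, slope), `r_squared`, `p_value`, `n`.
#' @export
simple_linkage <- function(y, x) {
  ok <- stats::complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3L)
    insufficient_data_error("need at least three paired observations")
  if (stats::sd(x) == 0)
    degenerate_predictor_error("predictor is constant")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(coefficients = stats::coef(fit),
                 r_squared = s$r.squared,
                 p_value = s$coefficients["x", "Pr(>|t|)"],
                 n = length(y)),
            class = "hfa_linkage")
}

#' @export
print.hfa_linkage <- function(x, ...) {
  cat(sprintf("Linear linkage: slope %.4g, R^2 = %.3f, p = %.4g, n = %d\n",
              x$coefficients[2], x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Multiple regression of mean HFA on per-taxon dissimilarities
#'
#' Two-step procedure: a full multiple OLS of the response on the per-taxon
#' dissimilarity predictors; taxa whose coefficients are significant at
#' `alpha` are flagged, and each flagged taxon is then refit alone with
#' [simple_linkage()]. No multiple-testing correction is applied across the
#' refits by default; `holm = TRUE` applies a Holm correction to the
#' full-model coefficient p-values before flagging.
#'
#' @param y response vector.
#' @param predictors data.frame or matrix of per-taxon predictors (columns
#'   named by taxon).
#' @param alpha flagging level.
#' @param holm apply Holm correction before flagging?
#' @return list with `full` (data.frame taxon, estimate, p_value),
#'   `r_squared`, `n`, `flagged` (character), `refits` (named list of
#'   `"hfa_linkage"`).
#' @export
multi_taxon_linkage <- function(y, predictors, alpha = 0.05, holm = FALSE) {
  X <- as.data.frame(predictors)
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n < p + 1L)
    insufficient_data_error("fewer observations than coefficients")
  if (n < p + 2L)
    warning("no residual degrees of freedom to spare: coefficient tests are unreliable",
            call. = FALSE)
  mm <- scale(as.matrix(X))
  kappa_x <- kappa(cbind(1, as.matrix(X)), exact = TRUE)
  if (is.finite(kappa_x) && kappa_x > 1e8)
    warning(sprintf("predictors nearly collinear (condition number %.3g); pivoted fit",
                    kappa_x), call. = FALSE)
  dat <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = dat)
  s <- summary(fit)
  cf <- s$coefficients
  taxa <- names(X)
  rows <- match(make.names(taxa), rownames(cf))
  if (anyNA(rows)) rows <- match(taxa, rownames(cf))
  pvals <- cf[rows, "Pr(>|t|)"]
  if (holm) pvals <- stats::p.adjust(pvals, "holm")
  full <- data.frame(taxon = taxa, estimate = cf[rows, "Estimate"],
                     p_value = pvals, stringsAsFactors = FALSE)
  rownames(full) <- NULL
  flagged <- taxa[!is.na(pvals) & pvals < alpha]
  refits <- stats::setNames(
    lapply(flagged, function(tx) simple_linkage(y, X[[tx]])), flagged)
  list(full = full, r_squared = s$r.squared, n = n,
       flagged = flagged, refits = refits)
}
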