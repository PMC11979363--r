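#' Normalize daily survival proportions to day 1
#'
#' Adds `prop = n_alive / n_plated` and `norm_prop = prop / prop(day 1)` per
#' genotype x replicate series. The day-1 normalized value is exactly 1;
#' later values may exceed 1 because later-day counts can beat day 1 by
#' sampling.
#'
#' @param table survival table with columns genotype, replicate, day,
#'   n_plated, n_alive (day 1 present per series with `n_alive > 0`).
#' @return the table with `prop` and `norm_prop` columns added.
#' @export
normalize_day1 <- function(table) {
  assert_columns(table, c("genotype", "replicate", "day", "n_plated", "n_alive"),
                 "survival table")
  if (any(table$n_alive > table$n_plated))
    stop("n_alive exceeds n_plated")
  table$prop <- table$n_alive / table$n_plated
  key <- interaction(table$genotype, table$replicate, drop = TRUE)
  out <- lapply(split(table, key), function(s) {
    d1 <- s[s$day == 1, , drop = FALSE]
    if (nrow(d1) == 0L)
      stop(sprintf("no day-1 row for series %s / %s", s$genotype[1],
                   s$replicate[1]))
    if (d1$prop[1] == 0)
      stop(sprintf("day-1 proportion is zero for series %s / %s",
                   s$genotype[1], s$replicate[1]))
    s$norm_prop <- s$prop / d1$prop[1]
    s
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Quasi-binomial logistic fit of one survival series
#'
#' Fits a logit-link, binomial-variance quasi-likelihood model of the day-1
#' normalized proportion alive against days of starvation (IRLS via
#' [stats::glm()]), with prior weights equal to the number of animals plated.
#' Normalized proportions are clipped into (0, 1) only for the link
#' evaluation. The half-life is the day at which the fitted curve crosses
#' 0.5: `-beta0 / beta1`, defined only for a negative slope.
#'
#' @param series data.frame for one genotype x replicate with columns day,
#'   n_plated and norm_prop (or raw n_alive, in which case [normalize_day1()]
#'   is applied first); >= 3 distinct days.
#' @param weighted weight observations by `n_plated` (default `TRUE`).
#' @param clip clipping bound for proportions inside the link (default 1e-6).
#' @return object of class `"survival_fit"`: genotype, replicate, beta0,
#'   beta1, dispersion (Pearson chi-square / df), half_life (`NA` and flagged
#'   when the slope is non-negative), converged, and the underlying `glm`.
#' @export
fit_survival <- function(series, weighted = TRUE, clip = 1e-6) {
  assert_columns(series, c("day", "n_plated"), "survival series")
  if (!"norm_prop" %in% names(series)) series <- normalize_day1(series)
  if (length(unique(series$day)) < 3L)
    stop("need at least 3 distinct days to fit a survival curve")
  y <- pmin(pmax(series$norm_prop, clip), 1 - clip)
  w <- if (weighted) series$n_plated else rep(1, nrow(series))
  fit <- suppressWarnings(glm(y ~ day, data = cbind(series, y = y),
                              family = quasibinomial(),
                              weights = w,
                              control = glm.control(epsilon = 1e-8,
                                                    maxit = 100)))
  b <- coef(fit)
  disp <- sum(residuals(fit, type = "pearson")^2) / fit$df.residual
  half_life_defined <- is.finite(b[2]) && b[2] < 0
  structure(list(
    genotype = if ("genotype" %in% names(series)) series$genotype[1] else NA,
    replicate = if ("replicate" %in% names(series)) series$replicate[1] else NA,
    beta0 = unname(b[1]), beta1 = unname(b[2]), dispersion = disp,
    half_life = if (half_life_defined) unname(-b[1] / b[2]) else NA_real_,
    half_life_defined = half_life_defined,
    converged = fit$converged, model = fit), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("survival fit (%s / %s): logit p = %.3f %+.3f * day\n",
              x$genotype, x$replicate, x$beta0, x$beta1))
  cat(sprintf("  half-life: %s days   dispersion: %.3f   converged: %s\n",
              if (x$half_life_defined) sprintf("%.2f", x$half_life) else
                "undefined (non-negative slope)",
              x$dispersion, x$converged))
  invisible(x)
}

#' @export
coef.survival_fit <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1)
}

#' @export
predict.survival_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object$model))
  plogis(object$beta0 + object$beta1 * newdata$day)
}

#' @export
plot.survival_fit <- function(x, ...) {
  d <- x$model$data
  plot(d$day, d$y, xlab = "days of starvation",
       ylab = "normalized proportion alive", ylim = c(0, max(1, d$y)), ...)
  grid_days <- seq(min(d$day), max(d$day), length.out = 100)
  lines(grid_days, plogis(x$beta0 + x$beta1 * grid_days))
  if (x$half_life_defined) abline(v = x$half_life, lty = 2)
  invisible(x)
}

#' Fit every genotype x replicate survival series
#'
#' @param table raw survival table (see [normalize_day1()]).
#' @param normalize normalize proportions to day 1 before fitting (the assay
#'   convention; default `TRUE`). With `FALSE` the raw proportion alive is
#'   fitted, which estimates the generating curve's half-life directly — the
#'   right choice for parameter-recovery experiments on simulated data, where
#'   day-1 normalization would rescale the estimand whenever day-1 survival
#'   is below 1.
#' @inheritParams fit_survival
#' @return data.frame with one row per series: genotype, replicate, beta0,
#'   beta1, dispersion, half_life, converged.
#' @export
fit_survival_all <- function(table, weighted = TRUE, normalize = TRUE) {
  table <- normalize_day1(table)
  if (!normalize) table$norm_prop <- table$prop
  key <- interaction(table$genotype, table$replicate, drop = TRUE)
  rows <- lapply(split(table, key), function(s) {
    f <- fit_survival(s, weighted = weighted)
    data.frame(genotype = f$genotype, replicate = f$replicate,
               beta0 = f$beta0, beta1 = f$beta1, dispersion = f$dispersion,
               half_life = f$half_life, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @noRd
levene_p <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- factor(groups)
  centers <- tapply(values, groups, if (center == "median") median else mean)
  z <- abs(values - centers[groups])
  if (all(z == z[1])) return(1)
  fit <- lm(z ~ groups)
  stats::anova(fit)[["Pr(>F)"]][1]
}

#' Compare half-lives of two genotypes with a variance-gated t test
#'
#' Runs the chosen variance-homogeneity test (Bartlett, or Brown-Forsythe
#' Levene with median centering) across the two groups, then a two-tailed
#' unpaired t test: variance-pooled when the homogeneity p-value is at least
#' `pool_alpha`, Welch otherwise.
#'
#' @param group_a,group_b numeric vectors of replicate half-lives (>= 2 each).
#' @param variance_test `"bartlett"` or `"levene"`.
#' @param pool_alpha pooling gate on the homogeneity p-value (default 0.05).
#' @param levene_center centering for Levene's test.
#' @return list with variance_test, variance_p, t, df, p, pooled.
#' @export
compare_halflives <- function(group_a, group_b,
                              variance_test = c("bartlett", "levene"),
                              pool_alpha = 0.05,
                              levene_center = c("median", "mean")) {
  variance_test <- match.arg(variance_test)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 replicates")
  values <- c(group_a, group_b)
  groups <- rep(c("a", "b"), c(length(group_a), length(group_b)))
  var_p <- if (var(group_a) == 0 && var(group_b) == 0) {
    1 # no variance anywhere: trivially homogeneous
  } else if (variance_test == "bartlett") {
    bartlett.test(list(group_a, group_b))$p.value
  } else {
    levene_p(values, groups, center = match.arg(levene_center))
  }
  pooled <- var_p >= pool_alpha
  if (var(values) == 0) {
    # identical constant groups: no evidence of a difference
    tt <- list(statistic = c(t = 0), parameter = c(df = length(values) - 2),
               p.value = 1)
  } else {
    tt <- t.test(group_a, group_b, var.equal = pooled)
  }
  list(variance_test = variance_test, variance_p = var_p,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, pooled = pooled)
}

#' Two-way fixed-effects ANOVA with interaction on half-lives
#'
#' Classical two-way ANOVA of `value ~ A * B` assessing additivity of two
#' mutations' effects: a significant interaction term indicates nonadditivity
#' (dependence). Sums of squares are Type II (computed by model comparison),
#' which reduces to the textbook decomposition for the balanced designs used
#' here.
#'
#' @param values numeric response (e.g. replicate half-lives).
#' @param factor_a,factor_b two-level factors (e.g. loss of each gene); all
#'   four combinations must be present with >= 2 replicates each.
#' @return data.frame with one row per term (A, B, A:B, Residuals): df,
#'   sumsq, meansq, F, p. The interaction p-value is the nonadditivity test.
#' @export
interaction_anova <- function(values, factor_a, factor_b) {
  A <- factor(factor_a); B <- factor(factor_b)
  cells <- table(A, B)
  if (any(cells == 0)) stop("empty factor combination")
  if (any(cells < 2)) stop("each factor combination needs >= 2 replicates")
  d <- data.frame(y = values, A = A, B = B)
  rss <- function(f) sum(residuals(lm(f, data = d))^2)
  rss_full <- rss(y ~ A * B)
  rss_add <- rss(y ~ A + B)
  ss <- c(A = rss(y ~ B) - rss_add,
          B = rss(y ~ A) - rss_add,
          `A:B` = rss_add - rss_full)
  df_terms <- c(A = nlevels(A) - 1L, B = nlevels(B) - 1L,
                `A:B` = (nlevels(A) - 1L) * (nlevels(B) - 1L))
  df_res <- length(values) - nlevels(A) * nlevels(B)
  ms_res <- rss_full / df_res
  ms <- ss / df_terms
  Fstat <- ms / ms_res
  p <- pf(Fstat, df_terms, df_res, lower.tail = FALSE)
  data.frame(term = c(names(ss), "Residuals"),
             df = c(df_terms, df_res),
             sumsq = c(ss, rss_full),
             meansq = c(ms, ms_res),
             F = c(Fstat, NA), p = c(p, NA),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aligned-rank-transform nonparametric two-way ANOVA
#'
#' Nonparametric factorial ANOVA for one effect at a time: the response is
#' aligned for the requested effect (residuals from cell means plus the
#' effect's estimated contribution — marginal means minus the grand mean for
#' main effects, cell mean minus both marginals plus the grand mean for the
#' interaction), ranked with average ranks for ties, and the classical
#' factorial ANOVA is run on the ranks. Only the requested effect's test is
#' returned.
#'
#' @param values numeric response (e.g. proportions).
#' @param factor_a,factor_b factors of the full factorial design (all cells
#'   must be occupied).
#' @param effect which term to test: `"interaction"`, `"a"` or `"b"`.
#' @return list with F, df (numerator, denominator) and p.
#' @export
art_anova <- function(values, factor_a, factor_b,
                      effect = c("interaction", "a", "b")) {
  effect <- match.arg(effect)
  A <- factor(factor_a); B <- factor(factor_b)
  if (any(table(A, B) == 0)) stop("empty cell in the factorial design")
  grand <- mean(values)
  cell <- tapply(values, list(A, B), mean)
  ma <- tapply(values, A, mean)
  mb <- tapply(values, B, mean)
  cell_of <- cell[cbind(as.integer(A), as.integer(B))]
  resid_cell <- values - cell_of
  contribution <- switch(effect,
    a = ma[A] - grand,
    b = mb[B] - grand,
    interaction = cell_of - ma[A] - mb[B] + grand)
  aligned <- resid_cell + contribution
  r <- rank(aligned)
  if (all(aligned == aligned[1])) {
    # all aligned responses tied: no evidence for the effect
    return(list(F = 0,
                df = c(switch(effect,
                              a = nlevels(A) - 1L, b = nlevels(B) - 1L,
                              interaction = (nlevels(A) - 1L) * (nlevels(B) - 1L)),
                       length(values) - nlevels(A) * nlevels(B)),
                p = 1))
  }
  tab <- interaction_anova_ranks(r, A, B)
  term <- switch(effect, a = "A", b = "B", interaction = "A:B")
  row <- tab[tab$term == term, ]
  Fval <- row$F
  if (!is.finite(Fval) || row$sumsq <= 1e-12 * sum(tab$sumsq)) {
    Fval <- if (row$sumsq <= 1e-12 * sum(tab$sumsq)) 0 else Fval
  }
  pval <- if (Fval == 0) 1 else row$p
  list(F = Fval, df = c(row$df, tab$df[tab$term == "Residuals"]), p = pval)
}

#' @noRd
interaction_anova_ranks <- function(r, A, B) {
  d <- data.frame(y = r, A = A, B = B)
  rss <- function(f) sum(residuals(lm(f, data = d))^2)
  rss_full <- rss(y ~ A * B)
  rss_add <- rss(y ~ A + B)
  ss <- c(A = rss(y ~ B) - rss_add, B = rss(y ~ A) - rss_add,
          `A:B` = rss_add - rss_full)
  df_terms <- c(A = nlevels(A) - 1L, B = nlevels(B) - 1L,
                `A:B` = (nlevels(A) - 1L) * (nlevels(B) - 1L))
  df_res <- length(r) - nlevels(A) * nlevels(B)
  ms_res <- rss_full / max(df_res, 1L)
  Fstat <- (ss / df_terms) / ms_res
  p <- pf(Fstat, df_terms, df_res, lower.tail = FALSE)
  data.frame(term = c(names(ss), "Residuals"), df = c(df_terms, df_res),
             sumsq = c(ss, rss_full), F = c(Fstat, NA), p = c(p, NA),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kruskal-Wallis rank-sum test
#'
#' Nonparametric one-way ANOVA with tie correction (delegated to
#' [stats::kruskal.test()]); the degenerate all-identical case returns
#' `H = 0, p = 1`.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 non-empty groups).
#' @return list with H (the chi-squared statistic), df and p.
#' @export
kruskal_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L)) stop("empty group")
  if (all(values == values[1]))
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Earliest common hatching plateau
#'
#' Returns the earliest timepoint at which every genotype's proportion
#' hatched equals its own maximum (within `tol`) — the timepoint at which all
#' genotypes have reached maximal hatching efficiency, used to stage sample
#' collection.
#'
#' @param hatching data.frame with columns genotype, time, prop_hatched
#'   (>= 2 timepoints per genotype).
#' @param tol tolerance for "equals the maximum".
#' @return the plateau time (`NA` with a warning if no common plateau time
#'   exists).
#' @export
hatch_plateau <- function(hatching, tol = 1e-9) {
  assert_columns(hatching, c("genotype", "time", "prop_hatched"), "hatching")
  if (any(table(hatching$genotype) < 2L))
    stop("need at least 2 timepoints per genotype")
  times <- sort(unique(hatching$time))
  maxima <- tapply(hatching$prop_hatched, hatching$genotype, max)
  for (t in times) {
    at_t <- hatching[hatching$time == t, ]
    if (!setequal(at_t$genotype, names(maxima))) next
    if (all(at_t$prop_hatched >= maxima[at_t$genotype] - tol)) return(t)
  }
  warning("no common timepoint at which all genotypes are at their maximum")
  NA_real_
}
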