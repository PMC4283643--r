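# Repeated-measures ANOVA machinery used for all regional and group
# contrasts: one-way within-subject ANOVA, the split-plot (mixed) two-way
# design with a between-subject injection-group factor, and Bonferroni
# post-hoc paired comparisons. Classical uncorrected sums-of-squares
# decompositions (the source analyses report uncorrected degrees of
# freedom); a Greenhouse-Geisser correction is available behind a flag.

#' A repeated-measures design
#'
#' @param data Numeric matrix or data frame, subjects in rows, within-
#'   subject levels (regions) in columns. Complete (no missing cells).
#' @param groups Optional between-subject factor (length = subjects; at
#'   least 2 groups with at least 2 subjects each).
#' @param alpha Significance threshold.
#' @return A list of class `"rm_design"`.
#' @export
rm_design <- function(data, groups = NULL, alpha = 0.05) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_cf("design data must be numeric")
  if (anyNA(data)) stop_cf("design has missing cells; incomplete designs are rejected")
  if (ncol(data) < 2) stop_cf("need >= 2 within-subject levels")
  if (nrow(data) < 2) stop_cf("need >= 2 subjects")
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (length(groups) != nrow(data)) {
      stop_cf("groups length %d != number of subjects %d",
              length(groups), nrow(data))
    }
    if (nlevels(groups) < 2) stop_cf("need >= 2 between-subject groups")
    if (any(table(groups) < 2)) {
      stop_cf("every group needs >= 2 subjects (sizes: %s)",
              paste(table(groups), collapse = ", "))
    }
  }
  check_number(alpha, "alpha", min = 1e-12, max = 1)
  if (is.null(colnames(data))) {
    colnames(data) <- sprintf("L%02d", seq_len(ncol(data)))
  }
  structure(list(data = data, groups = groups, alpha = alpha),
            class = "rm_design")
}

anova_table <- function(effect, ss, df1, ss_err, df2) {
  mse <- ss_err / df2
  # a literally zero effect SS is reported as F = 0 even when the error
  # stratum is also degenerate (0/0 would otherwise give NaN)
  f <- if (ss <= 1e-300) 0 else (ss / df1) / mse
  tibble::tibble(
    effect = effect, ss = ss, df_num = as.integer(df1),
    ss_error = ss_err, df_den = as.integer(df2),
    F = f, p = pf(f, df1, df2, lower.tail = FALSE)
  )
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition of a subjects x regions matrix:
#' `SS_total = SS_subject + SS_region + SS_error`, with
#' `F = MS_region / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom.
#'
#' @param design An [rm_design()] without a between factor.
#' @param gg Apply the Greenhouse-Geisser sphericity correction to the
#'   degrees of freedom and p-value (off by default; the defaults mirror
#'   uncorrected reporting).
#' @return A list of class `"rm_anova"` with the effect `table`
#'   (tibble: effect, SS, df, F, p) and the full sums-of-squares
#'   decomposition.
#' @export
one_way_rm_anova <- function(design, gg = FALSE) {
  stopifnot(inherits(design, "rm_design"))
  if (!is.null(design$groups)) {
    stop_cf("design has a between factor; use two_way_rm_anova()")
  }
  y <- design$data
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_region <- n * sum((colMeans(y) - grand)^2)
  ss_err <- ss_total - ss_subj - ss_region
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  tab <- anova_table("region", ss_region, df1, ss_err, df2)
  if (gg) {
    eps <- gg_epsilon(y)
    tab$gg_epsilon <- eps
    tab$p <- pf(tab$F, eps * df1, eps * df2, lower.tail = FALSE)
  }
  structure(list(
    table = tab,
    ss = c(total = ss_total, subject = ss_subj, region = ss_region,
           error = ss_err),
    n_subjects = n, n_levels = k, alpha = design$alpha
  ), class = "rm_anova")
}

# Greenhouse-Geisser epsilon from the sample covariance of the within-
# subject measures.
gg_epsilon <- function(y) {
  S <- stats::cov(y)
  k <- ncol(S)
  dbar <- mean(diag(S)); sbar <- mean(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * sbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' Two-way (split-plot) repeated-measures ANOVA
#'
#' Mixed design with a between-subject group factor (injection location
#' class) and a within-subject region factor. Between-subject stratum:
#' `F_group = MS_group / MS_subjects-within-groups` on
#' `(g - 1, N - g)` df. Within-subject stratum: region and the group x
#' region interaction are tested against the within error on
#' `(k - 1, (k - 1)(N - g))` and `((g - 1)(k - 1), (k - 1)(N - g))` df.
#'
#' @param design An [rm_design()] with a `groups` factor.
#' @return A list of class `"rm_anova"`; `table` has rows `group`,
#'   `region`, `group:region`.
#' @export
two_way_rm_anova <- function(design) {
  stopifnot(inherits(design, "rm_design"))
  if (is.null(design$groups)) {
    stop_cf("design has no between factor; use one_way_rm_anova()")
  }
  y <- design$data
  g <- design$groups
  N <- nrow(y); k <- ncol(y); ng <- nlevels(g)
  n_per <- as.vector(table(g))
  grand <- mean(y)

  subj_means <- rowMeans(y)
  group_means <- tapply(subj_means, g, mean)
  level_means <- colMeans(y)
  # cell means: group x level
  cell_means <- rowsum(y, g) / n_per

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(n_per * (group_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group

  ss_region <- N * sum((level_means - grand)^2)
  ss_cells <- sum(n_per * rowSums((cell_means - grand)^2))
  ss_interaction <- ss_cells - ss_group - ss_region
  ss_within <- ss_total - ss_between_subj
  ss_err_within <- ss_within - ss_region - ss_interaction

  tab <- dplyr::bind_rows(
    anova_table("group", ss_group, ng - 1, ss_subj_within, N - ng),
    anova_table("region", ss_region, k - 1, ss_err_within, (k - 1) * (N - ng)),
    anova_table("group:region", ss_interaction, (ng - 1) * (k - 1),
                ss_err_within, (k - 1) * (N - ng))
  )
  structure(list(
    table = tab,
    ss = c(total = ss_total, group = ss_group,
           subj_within_group = ss_subj_within, region = ss_region,
           interaction = ss_interaction, error_within = ss_err_within),
    n_subjects = N, n_levels = k, n_groups = ng, alpha = design$alpha
  ), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> %d subjects x %d levels%s\n", x$n_subjects,
              x$n_levels,
              if (!is.null(x$n_groups)) sprintf(" x %d groups", x$n_groups)
              else ""))
  df <- as.data.frame(x$table)
  df$F <- signif(df$F, 4); df$p <- signif(df$p, 4)
  print(df[, c("effect", "df_num", "df_den", "F", "p")], row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected post-hoc paired comparisons
#'
#' Paired t-tests between within-subject levels; each raw p-value is
#' multiplied by the number of comparisons actually tested (capped at 1).
#'
#' @param design An [rm_design()].
#' @param pairs List of length-2 character/integer vectors naming the
#'   level pairs to test, or `"all"` for every pair.
#' @return A tibble of class `"posthoc_table"`: `level_a`, `level_b`,
#'   `t`, `df`, `p_raw`, `p_adj`, `significant` (at the design alpha).
#' @export
bonferroni_posthoc <- function(design, pairs = "all") {
  stopifnot(inherits(design, "rm_design"))
  y <- design$data
  lev <- colnames(y)
  if (identical(pairs, "all")) {
    cmb <- utils::combn(lev, 2, simplify = FALSE)
  } else {
    if (length(pairs) == 0) stop_cf("empty pair list")
    cmb <- lapply(pairs, function(p) {
      if (length(p) != 2) stop_cf("each pair must have exactly 2 levels")
      if (is.numeric(p)) p <- lev[p]
      if (!all(p %in% lev)) {
        stop_cf("unknown level(s): %s", paste(setdiff(p, lev), collapse = ", "))
      }
      p
    })
  }
  m <- length(cmb)
  rows <- lapply(cmb, function(p) {
    tt <- t.test(y[, p[1]], y[, p[2]], paired = TRUE)
    tibble::tibble(level_a = p[1], level_b = p[2],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- pmin(1, out$p_raw * m)
  out$significant <- out$p_adj < design$alpha
  class(out) <- c("posthoc_table", class(out))
  out
}
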