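## The engagement model: a linear mixed-effects model predicting windowed
## ISC from the movement category of the stimulus, the viewer's age group,
## their interaction, and the ALD visual-dynamics covariate, with a random
## intercept per subject,
##
##     ISC ~ group * movement + ALD + (1 | subject),
##
## reference levels: movement = "neither", group = "adults".  Post-hoc,
## per-subject condition means are compared with paired Wilcoxon
## signed-rank tests within each (group, ALD-level) panel, Bonferroni-
## corrected, with ALD binarized at its sample median.

GROUP_LEVELS <- c("adults", "children")

#' Assemble the window-level design table
#'
#' One row per subject x retained window, joining the three window-grid-
#' aligned series.  All three inputs must carry the same grid (same
#' starts, same drops); rows are restricted to windows retained by every
#' series.
#'
#' @param isc An `isc_series` from [time_resolved_isc()].
#' @param moves A `movement_series` from [window_categories()].
#' @param ald An `ald_series` from [downsample_ald()].
#' @param groups Named character vector mapping subject IDs to
#'   `"children"` / `"adults"`.
#' @param layout Optional [clip_layout()] used to attach a block ID.
#' @return A `design_table` data.frame with columns `subject`, `window`,
#'   `start`, `isc`, `group`, `movement`, `ald` (and `block` if a layout
#'   is given).
#' @export
build_design <- function(isc, moves, ald, groups, layout = NULL) {
  stopifnot(inherits(isc, "isc_series"))
  g_isc <- isc$grid
  same_grid <- function(g) nrow(g) == nrow(g_isc) &&
    max(abs(g$start - g_isc$start)) <= 1e-9
  if (!same_grid(attr(moves, "grid")) || !same_grid(attr(ald, "grid")))
    stop("window grids do not match: stages must share one grid")
  win_isc <- g_isc$window[g_isc$retained]
  common <- Reduce(intersect, list(win_isc, moves$window, ald$window))
  if (length(common) == 0) stop("no windows shared by all three series")
  subjects <- rownames(isc$windows)
  if (is.null(names(groups)) || !all(subjects %in% names(groups)))
    stop("groups must be a named vector covering every subject")
  if (!all(groups %in% GROUP_LEVELS))
    stop("groups must be 'children' or 'adults'")
  isc_cols <- match(common, win_isc)
  mv <- moves[match(common, moves$window), ]
  al <- ald[match(common, ald$window), ]
  rows <- lapply(seq_along(subjects), function(k)
    data.frame(subject = subjects[k], window = common,
               start = g_isc$start[common],
               isc = isc$windows[k, isc_cols],
               group = unname(groups[subjects[k]]),
               movement = as.character(mv$category), ald = al$ald))
  out <- do.call(rbind, rows)
  out$subject <- factor(out$subject)
  out$group <- factor(out$group, levels = GROUP_LEVELS)
  out$movement <- factor(out$movement, levels = MOVEMENT_LEVELS)
  if (!is.null(layout)) out$block <- layout_block_at(layout, out$start)
  rownames(out) <- NULL
  stopifnot(!anyNA(out$isc))
  class(out) <- c("design_table", "data.frame")
  out
}

#' Fit the engagement mixed-effects model
#'
#' REML fit of `isc ~ group * movement + ald + (1 | subject)` with
#' Satterthwaite (default) or residual degrees of freedom for the
#' fixed-effect t-tests.  Movement levels absent from the data are
#' dropped from the factor (with a note in the fit metadata); a rank-
#' deficient design is an error naming the aliased columns.
#'
#' @param tab A `design_table` from [build_design()].
#' @param df_method `"satterthwaite"` (default) or `"residual"`.
#' @param standardize_ald Z-score the ALD covariate before fitting
#'   (default `FALSE`; the covariate enters on its native scale).
#' @return An `engagement_fit`: list with `coefficients` (data.frame:
#'   estimate, se, t, df, p), `ranef_var`, `resid_var`, `converged`,
#'   `df_method`, `model` (the underlying `lmerMod`).
#' @export
fit_engagement_model <- function(tab, df_method = c("satterthwaite",
                                                    "residual"),
                                 standardize_ald = FALSE) {
  df_method <- match.arg(df_method)
  stopifnot(inherits(tab, "design_table"))
  if (any(table(unique(tab[c("subject", "group")])$group) < 2))
    warning("fewer than 2 subjects in a group; group effects unreliable")
  tab$movement <- droplevels(tab$movement)
  if (standardize_ald) tab$ald <- as.numeric(scale(tab$ald))
  mm <- model.matrix(~ group * movement + ald, tab)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- lme4::lmer(isc ~ group * movement + ald + (1 | subject),
                    data = tab, REML = TRUE)
  converged <- length(fit@optinfo$conv$lme4) == 0 &&
    fit@optinfo$conv$opt == 0
  if (!converged) warning("mixed-model optimizer did not converge cleanly")
  beta <- lme4::fixef(fit)
  used_method <- df_method
  if (df_method == "satterthwaite") {
    sw <- satterthwaite_df(fit)
    if (!sw$ok) {
      warning("Satterthwaite approximation unavailable (singular fit?); ",
              "falling back to residual df")
      used_method <- "residual"
    }
  }
  if (used_method == "residual") {
    df <- rep(nrow(tab) - length(beta) - nlevels(tab$subject) + 1L,
              length(beta))
    V <- as.matrix(stats::vcov(fit))
  } else {
    df <- sw$df
    V <- sw$vcov
  }
  se <- sqrt(diag(V))
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  coefs <- data.frame(effect = names(beta), estimate = unname(beta),
                      se = se, t = tval, df = df, p = pval,
                      row.names = NULL)
  structure(list(coefficients = coefs,
                 ranef_var = vc$vcov[vc$grp == "subject"],
                 resid_var = vc$vcov[vc$grp == "Residual"],
                 converged = converged, df_method = used_method,
                 model = fit),
            class = "engagement_fit")
}

#' @export
print.engagement_fit <- function(x, ...) {
  cat("Linear mixed-effects model for windowed ISC",
      sprintf("(random intercept per subject; %s df)\n", x$df_method))
  tab <- x$coefficients
  cat(sprintf("%-28s %9s %9s %8s %11s %9s\n",
              "Effect", "Est.", "S.E.", "t", "d.f.", "p"))
  for (i in seq_len(nrow(tab)))
    cat(sprintf("%-28s %9.4f %9.4f %8.3f %11.3f %9.2g\n",
                tab$effect[i], tab$estimate[i], tab$se[i], tab$t[i],
                tab$df[i], tab$p[i]))
  cat(sprintf("Random-intercept variance: %.5g; residual variance: %.5g\n",
              x$ranef_var, x$resid_var))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' Post-hoc Wilcoxon comparisons of per-subject condition means
#'
#' The continuous ALD covariate is binarized at its sample median (over
#' retained windows); within each (group, ALD-level) panel the ISC is
#' averaged per subject and movement condition, and every pair of
#' movement conditions is compared with a paired Wilcoxon signed-rank
#' test (exact null for n <= 25 paired subjects, normal approximation
#' with continuity correction above).  P-values are Bonferroni-corrected
#' over all reported comparisons; each cell also gets a Shapiro-Wilk
#' normality check (the rationale for rank tests over t-tests).
#'
#' @param tab A `design_table` from [build_design()].
#' @param ald_split Cut point for the ALD binarization; defaults to the
#'   median ALD over unique retained windows.
#' @return A `posthoc_table`: list with `comparisons` (data.frame),
#'   `cells` (per-subject condition means), `normality` (Shapiro-Wilk per
#'   cell), `ald_split`, `n_comparisons`.
#' @export
posthoc_wilcoxon <- function(tab, ald_split = NULL) {
  stopifnot(inherits(tab, "design_table"))
  if (is.null(ald_split))
    ald_split <- median(tab$ald[!duplicated(tab$window)])
  tab$ald_level <- factor(ifelse(tab$ald > ald_split, "high", "low"),
                          levels = c("low", "high"))
  cells <- stats::aggregate(isc ~ subject + group + ald_level + movement,
                            data = tab, FUN = mean)
  norm <- do.call(rbind, lapply(
    split(cells, list(cells$group, cells$ald_level, cells$movement),
          drop = TRUE),
    function(d) data.frame(group = d$group[1], ald_level = d$ald_level[1],
                           movement = d$movement[1], n = nrow(d),
                           shapiro_p = if (nrow(d) >= 3 && sd(d$isc) > 0)
                             shapiro.test(d$isc)$p.value else NA_real_)))
  rownames(norm) <- NULL
  pairs <- utils::combn(levels(droplevels(tab$movement)), 2)
  res <- list()
  for (g in levels(droplevels(tab$group))) for (a in levels(tab$ald_level)) {
    panel <- cells[cells$group == g & cells$ald_level == a, ]
    for (j in seq_len(ncol(pairs))) {
      c1 <- pairs[1, j]; c2 <- pairs[2, j]
      m1 <- panel[panel$movement == c1, c("subject", "isc")]
      m2 <- panel[panel$movement == c2, c("subject", "isc")]
      common <- intersect(m1$subject, m2$subject)
      n <- length(common)
      if (n < 1) next
      d1 <- m1$isc[match(common, m1$subject)]
      d2 <- m2$isc[match(common, m2$subject)]
      if (all(d1 == d2)) {
        # no non-zero differences: the signed-rank test is maximally
        # non-significant (wilcox.test would error after dropping zeros)
        stat <- 0; pv <- 1
      } else {
        wt <- suppressWarnings(wilcox.test(
          d1, d2, paired = TRUE, exact = n <= 25, correct = TRUE))
        stat <- unname(wt$statistic); pv <- wt$p.value
      }
      res[[length(res) + 1L]] <- data.frame(
        group = g, ald_level = a, cond1 = c1, cond2 = c2, n = n,
        mean1 = mean(d1), mean2 = mean(d2),
        statistic = stat, p = pv,
        underpowered = n < 6)
    }
  }
  comp <- do.call(rbind, res)
  m <- nrow(comp)
  comp$p_bonferroni <- pmin(1, comp$p * m)
  structure(list(comparisons = comp, cells = cells, normality = norm,
                 ald_split = ald_split, n_comparisons = m),
            class = "posthoc_table")
}

#' @export
print.posthoc_table <- function(x, ...) {
  cat(sprintf(
    "Post-hoc paired Wilcoxon tests (ALD split at %.4g; Bonferroni m = %d)\n",
    x$ald_split, x$n_comparisons))
  print(x$comparisons, digits = 3)
  invisible(x)
}
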