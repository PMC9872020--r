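# Builders for window-grid-aligned series and design tables.
toy_grid <- function(duration = 12) window_grid(duration, 1.5, 0.3)

toy_isc <- function(vals, grid, subjects = rownames(vals)) {
  structure(list(global = rowMeans(vals), windows = vals, grid = grid,
                 window_len = 1.5, hop = 0.3, K = 3L), class = "isc_series")
}
toy_moves <- function(categories, grid) {
  w <- grid$window[grid$retained]
  structure(data.frame(window = w, start = grid$start[w],
                       category = factor(categories,
                                         levels = iscpipe:::MOVEMENT_LEVELS),
                       arm = categories %in% c("arm", "both"),
                       leg = categories %in% c("leg", "both")),
            grid = grid, class = c("movement_series", "data.frame"))
}
toy_ald <- function(vals, grid) {
  w <- grid$window[grid$retained]
  structure(data.frame(window = w, start = grid$start[w], ald = vals),
            grid = grid, class = c("ald_series", "data.frame"))
}

# A design table with known generative effects, iid noise.
make_design <- function(n_sub = 8L, n_win = 60L, beta_both = 0.02,
                        beta_arm = 0.01, beta_leg = 0.01, sd_sub = 0.005,
                        sd_eps = 0.01, seed = 1L) {
  iscpipe:::with_seed(seed, {
    subjects <- sprintf("s%02d", seq_len(n_sub))
    group <- setNames(rep(c("children", "adults"), each = n_sub / 2), subjects)
    movement <- sample(iscpipe:::MOVEMENT_LEVELS, n_win, replace = TRUE)
    ald <- runif(n_win, 0, 2)
    u <- rnorm(n_sub, sd = sd_sub)
    eff <- c(neither = 0, arm = beta_arm, leg = beta_leg, both = beta_both)
    rows <- do.call(rbind, lapply(seq_len(n_sub), function(k)
      data.frame(subject = subjects[k], window = seq_len(n_win),
                 start = (seq_len(n_win) - 1) * 0.3,
                 isc = 0.01 + unname(eff[movement]) + 0.005 * ald + u[k] +
                   rnorm(n_win, sd = sd_eps),
                 group = unname(group[subjects[k]]), movement = movement,
                 ald = ald)))
    rows$subject <- factor(rows$subject)
    rows$group <- factor(rows$group, levels = iscpipe:::GROUP_LEVELS)
    rows$movement <- factor(rows$movement, levels = iscpipe:::MOVEMENT_LEVELS)
    rownames(rows) <- NULL
    class(rows) <- c("design_table", "data.frame")
    rows
  })
}

test_that("build_design joins aligned series into a long table", {
  grid <- toy_grid(3)   # 6 windows
  vals <- matrix(seq_len(12) / 10, 2, 6,
                 dimnames = list(c("s1", "s2"), NULL))
  isc <- toy_isc(vals, grid)
  mv <- toy_moves(rep(c("neither", "arm", "both"), 2), grid)
  al <- toy_ald(seq(0.1, 0.6, by = 0.1), grid)
  groups <- c(s1 = "children", s2 = "adults")
  tab <- build_design(isc, mv, al, groups)
  expect_equal(nrow(tab), 12)
  expect_identical(levels(tab$movement)[1], "neither")
  expect_identical(levels(tab$group)[1], "adults")
  expect_equal(tab$isc[tab$subject == "s2" & tab$window == 3],
               unname(vals[2, 3]))
  # a window dropped from one series is absent from the table
  mv2 <- mv[-2, ]
  attr(mv2, "grid") <- attr(mv, "grid")
  tab2 <- build_design(isc, mv2, al, groups)
  expect_equal(nrow(tab2), 10)
  expect_false(2 %in% tab2$window)
  # mismatched grids are rejected
  isc_bad <- toy_isc(vals[, -6, drop = FALSE], toy_grid(2.8))
  expect_error(build_design(isc_bad, mv, al, groups), "grids do not match")
  expect_error(build_design(isc, mv, al, c(s1 = "children")), "every subject")
})

test_that("design from the synthetic pipeline matches ground-truth categories", {
  cfg <- small_cfg(seed = 51L)
  sim <- generate_eeg(cfg)
  track <- movement_track(cfg)
  excised <- excise_onsets(sim$recording, 5)
  flt <- fit_corrca(compute_covariances(sim$recording, excised), gamma = 0.1)
  ts <- time_resolved_isc(sim$recording, flt, excised = excised)
  n_fr <- length(track$category)
  fl <- data.frame(transition = seq_len(n_fr - 1L),
                   arm = track$arm[-1], leg = track$leg[-1])
  spans <- mask_to_spans(excised, cfg$fs)
  mv <- window_categories(fl, ts$grid, cfg$fps, spans)
  al <- toy_ald(rep(0.5, sum(ts$grid$retained)), ts$grid)
  groups <- setNames(rep(c("children", "adults"), each = 3),
                     sim$recording$subjects)
  tab <- build_design(ts, mv, al, groups, layout = sim$recording$layout)
  # movement column equals the ground-truth-derived window categories
  per_win <- mv$category[match(tab$window, mv$window)]
  expect_identical(as.character(tab$movement), as.character(per_win))
  expect_true(all(tab$block %in% sim$recording$layout$block))
})

test_that("the mixed model recovers known effects with calibrated CIs", {
  tab <- make_design(beta_both = 0.02, seed = 5L)
  fit <- fit_engagement_model(tab)
  expect_true(fit$converged)
  co <- fit$coefficients
  b <- co[co$effect == "movementboth", ]
  expect_gt(b$estimate, 0)
  expect_gt(b$estimate - qt(0.975, b$df) * b$se, 0)  # CI excludes 0
  expect_true(all(co$p >= 0 & co$p <= 1))
  expect_true(all(co$df > 0))
  expect_identical(fit$df_method, "satterthwaite")
})

test_that("row order never changes the fit (reference-level contract)", {
  tab <- make_design(seed = 7L)
  fit1 <- fit_engagement_model(tab, df_method = "residual")
  perm <- iscpipe:::with_seed(8L, sample(nrow(tab)))
  tab2 <- tab[perm, ]
  class(tab2) <- class(tab)
  fit2 <- fit_engagement_model(tab2, df_method = "residual")
  expect_equal(fit2$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("duplicating rows keeps estimates but shrinks SEs (df accounting)", {
  tab <- make_design(seed = 9L)
  fit1 <- fit_engagement_model(tab, df_method = "residual")
  tab2 <- rbind(tab, tab)
  class(tab2) <- class(tab)
  fit2 <- fit_engagement_model(tab2, df_method = "residual")
  expect_equal(fit2$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 1e-6)
  expect_true(all(fit2$coefficients$se < fit1$coefficients$se))
  expect_true(all(fit2$coefficients$df > fit1$coefficients$df))
})

test_that("Satterthwaite df matches the classical balanced-design value", {
  # balanced two-group design, between-subject effect: classical df = m - 2
  m <- 12L; k <- 6L
  d <- iscpipe:::with_seed(42L, {
    d <- data.frame(s = factor(rep(seq_len(m), each = k)),
                    g = rep(c("a", "b"), each = m / 2 * k))
    d$y <- rnorm(m, sd = 1)[as.integer(d$s)] +
      rnorm(nrow(d), sd = 0.5) + (d$g == "b") * 0.5
    d
  })
  fit <- lme4::lmer(y ~ g + (1 | s), data = d, REML = TRUE)
  sw <- satterthwaite_df(fit)
  expect_true(sw$ok)
  expect_equal(sw$df[2], m - 2, tolerance = 0.01)
  expect_equal(sqrt(diag(sw$vcov)),
               unname(sqrt(diag(as.matrix(vcov(fit))))), tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with the aliased column named", {
  tab <- make_design(seed = 11L)
  tab$ald <- 1   # constant covariate aliases the intercept
  expect_error(fit_engagement_model(tab), "aliased.*ald")
})

test_that("posthoc: identical condition means give maximal p", {
  tab <- make_design(seed = 13L)
  # make every subject's ISC identical across movement conditions
  tab$isc <- ave(tab$isc, tab$subject, FUN = mean)
  ph <- posthoc_wilcoxon(tab)
  expect_true(all(ph$comparisons$p == 1))
})

test_that("posthoc signed-rank equals the exact enumeration oracle", {
  # 8 children, conditions neither/arm, all differences positive
  subjects <- sprintf("s%d", 1:8)
  base <- seq(0.01, 0.08, by = 0.01)
  tab <- data.frame(
    subject = factor(rep(subjects, 2)),
    window = rep(1:2, each = 8),
    start = rep(c(0, 0.3), each = 8),
    isc = c(base, base + seq(0.001, 0.008, by = 0.001)),
    group = factor("children", levels = iscpipe:::GROUP_LEVELS),
    movement = factor(rep(c("neither", "arm"), each = 8),
                      levels = iscpipe:::MOVEMENT_LEVELS),
    ald = 0.5)
  class(tab) <- c("design_table", "data.frame")
  ph <- posthoc_wilcoxon(tab)
  cmp <- ph$comparisons
  expect_equal(nrow(cmp), 1)
  # neither - arm differences are all negative: all ranks on the other
  # side, V = 0 (equivalently 36 for arm - neither)
  expect_equal(cmp$statistic, 0)
  # oracle: exhaustive enumeration of the 2^8 sign patterns
  ranks <- 1:8
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  w_null <- as.matrix(signs) %*% ranks
  p_exact <- 2 * mean(w_null <= 0)
  expect_equal(cmp$p, p_exact)
  expect_true(cmp$underpowered == FALSE)
  expect_equal(cmp$p_bonferroni, pmin(1, cmp$p * nrow(cmp)))
})

test_that("posthoc splits ALD at the median and applies Bonferroni", {
  tab <- make_design(n_sub = 8L, n_win = 80L, seed = 15L)
  ph <- posthoc_wilcoxon(tab)
  expect_equal(ph$ald_split, median(tab$ald[!duplicated(tab$window)]))
  cmp <- ph$comparisons
  expect_true(all(cmp$p_bonferroni >= cmp$p))
  expect_true(all(cmp$p_bonferroni <= 1))
  expect_true(all(cmp$p_bonferroni[cmp$p * ph$n_comparisons >= 1] == 1))
  expect_true(all(c("low", "high") %in% cmp$ald_level))
  # normality report covers the cells
  expect_true(nrow(ph$normality) > 0)
  expect_true(all(ph$normality$shapiro_p >= 0 | is.na(ph$normality$shapiro_p)))
})

test_that("subjects lacking a condition are dropped from that comparison", {
  tab <- make_design(n_sub = 6L, n_win = 40L, seed = 17L)
  drop_idx <- tab$subject == "s01" & tab$movement == "both"
  tab2 <- tab[!drop_idx, ]
  class(tab2) <- class(tab)
  ph <- posthoc_wilcoxon(tab2)
  cmp <- ph$comparisons
  with_both <- cmp[cmp$cond1 == "both" | cmp$cond2 == "both", ]
  expect_true(all(with_both$n <= 6))
})
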