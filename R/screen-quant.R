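#' @title Modifier-screen quantification
#' @description
#' Quantifies suppression and enhancement from screen tables: eye-surface
#' suppression percentage relative to the tester-vs-control eye-size
#' reduction, eclosion-based viability ratios and normalized lethality,
#' climbing curves, per-time-point group comparisons and the
#' modifier-strength classification.
#' @name screen-quant
NULL

#' Eye-surface suppression percentage
#'
#' Expresses a modifier's mean eye area as the percentage of the eye-size
#' reduction (control minus tester) that it restores: 0 when the modifier
#' equals the tester, 100 when it equals the control, linear in between.
#' Values outside \[0, 100\] (overshoot past the control, or worsening past
#' the tester) are reported unclamped, with an `out_of_range` attribute.
#'
#' @param mean_mod mean eye area with the modifier in trans.
#' @param mean_tester mean eye area of the tester line.
#' @param mean_control mean eye area of the driver-only control.
#' @return suppression percentage (numeric scalar).
#' @export
suppression_percent <- function(mean_mod, mean_tester, mean_control) {
  stopifnot(is.finite(mean_mod), is.finite(mean_tester),
            is.finite(mean_control))
  if (mean_control == mean_tester) {
    mn_degenerate_error(
      "degenerate baseline: control and tester mean areas are equal")
  }
  pct <- 100 * (mean_mod - mean_tester) / (mean_control - mean_tester)
  attr(pct, "out_of_range") <- pct < 0 || pct > 100
  pct
}

#' Viability ratio
#'
#' Observed eclosed flies of the tracked class over the Mendelian-expected
#' count.
#'
#' @param observed observed count (>= 0).
#' @param expected Mendelian-expected count (> 0).
#' @return V = observed/expected, unclamped.
#' @export
viability_ratio <- function(observed, expected) {
  stopifnot(is.finite(observed), is.finite(expected), observed >= 0)
  if (expected <= 0) mn_data_error("expected count must be positive")
  observed / expected
}

#' Normalized lethality percentage
#'
#' `(1 - V_enh / V_tes) * 100`: 0 when the enhancer leaves viability at the
#' tester level, 100 at complete lethality. Negative values (viability
#' improvement) are reported unclamped with an `improved` attribute.
#'
#' @param v_enh viability ratio of the tester with the enhancer in trans.
#' @param v_tes viability ratio of the tester line alone (> 0).
#' @return lethality percentage.
#' @export
normalized_lethality <- function(v_enh, v_tes) {
  stopifnot(is.finite(v_enh), is.finite(v_tes), v_enh >= 0)
  if (v_tes <= 0) mn_data_error("tester viability V_tes must be positive")
  pct <- (1 - v_enh / v_tes) * 100
  attr(pct, "improved") <- pct < 0
  pct
}

#' Climbing curve
#'
#' Per-genotype, per-time-point mean climb fraction with its standard
#' error over trials. The climb fraction of one trial is `n_above /
#' n_total` — flies above the 8 cm mark within 15 s; 10 trials are run
#' every 48 h.
#'
#' @param records data.frame with columns `genotype`, `time_point`,
#'   `trial`, `n_above`, `n_total`.
#' @return data.frame `genotype`, `time_point`, `n_trials`, `fraction`,
#'   `sem` (variance with n - 1 denominator).
#' @export
climbing_curve <- function(records) {
  check_cols(records, c("genotype", "time_point", "trial",
                        "n_above", "n_total"), "climbing table")
  if (any(records$n_above > records$n_total)) {
    mn_data_error("n_above exceeds n_total in climbing records")
  }
  if (any(records$n_total <= 0)) {
    mn_data_error("n_total must be positive in climbing records")
  }
  frac <- records$n_above / records$n_total
  key <- interaction(records$genotype, records$time_point, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_along(frac), key), function(idx) {
    f <- frac[idx]
    data.frame(genotype = records$genotype[idx[1]],
               time_point = records$time_point[idx[1]],
               n_trials = length(f),
               fraction = mean(f),
               sem = if (length(f) > 1) stats::sd(f) / sqrt(length(f)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$genotype, agg$time_point), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Classify modifier strength from per-time-point significance
#'
#' Applies the star-convention rule over the five climbing time points:
#' \describe{
#'   \item{strong}{suppressing direction with p < 0.001 at >= 3 time points.}
#'   \item{intermediate}{suppressing with p < 0.05 at exactly 2 time points
#'     (and not meeting the strong rule).}
#'   \item{weak}{suppressing with p < 0.001 at exactly 1 time point, or
#'     p < 0.05 at exactly 2 with neither below 0.01.}
#'   \item{enhancer}{worsening direction meeting any of the above patterns.}
#'   \item{none}{otherwise.}
#' }
#' Precedence is strong > intermediate > weak; suppressor classes are
#' evaluated before the enhancer rule. Exactly one class is returned.
#'
#' @param pvals numeric vector of 5 per-time-point p-values.
#' @param directions length-5 vector of effect directions: positive numbers
#'   or `"suppression"` for improvement over the tester, negative or
#'   `"enhancement"` for worsening.
#' @return character scalar, one of
#'   `c("strong", "intermediate", "weak", "enhancer", "none")`.
#' @export
classify_modifier_strength <- function(pvals, directions) {
  if (length(pvals) != 5L || length(directions) != 5L) {
    mn_data_error("classification requires exactly 5 time points")
  }
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    mn_data_error("p-values must lie in [0, 1]")
  }
  dir <- if (is.character(directions)) {
    if (!all(directions %in% c("suppression", "enhancement"))) {
      mn_data_error("directions must be 'suppression' or 'enhancement'")
    }
    ifelse(directions == "suppression", 1, -1)
  } else {
    sign(as.numeric(directions))
  }

  class_for <- function(sig) {
    # sig: logical mask of time points in the tested direction
    n001 <- sum(sig & pvals < 0.001)
    n05 <- sum(sig & pvals < 0.05)
    n01 <- sum(sig & pvals < 0.01)
    if (n001 >= 3) return("strong")
    if (n05 == 2) return("intermediate")
    if (n001 == 1 || (n05 == 2 && n01 == 0)) return("weak")
    "none"
  }

  sup <- class_for(dir > 0)
  if (sup != "none") return(sup)
  if (class_for(dir < 0) != "none") return("enhancer")
  "none"
}

#' Compare genotype groups (one-way or two-way design)
#'
#' One-way: omnibus one-way ANOVA with Tukey's HSD post hoc; with exactly
#' two groups, falls back to a two-tailed unpaired Student's t-test.
#' Two-way (genotype x time): two-way ANOVA omnibus (interaction model)
#' with per-time-point pairwise Welch t-tests, Bonferroni-adjusted across
#' time points within each genotype pair.
#'
#' @param data data.frame with columns `value`, `group`, and for the
#'   two-way design `time`.
#' @param design `"one_way"` or `"two_way"`.
#' @param alpha significance level for post-hoc flags.
#' @return list with `design`, `method`, `omnibus_p` and `pairwise`
#'   (data.frame of adjusted pairwise p-values and significance flags).
#' @export
group_compare <- function(data, design = c("one_way", "two_way"),
                          alpha = 0.05) {
  design <- match.arg(design)
  check_cols(data, c("value", "group"), "group_compare input")
  data$group <- as.character(data$group)
  counts <- table(data$group)
  if (length(counts) < 2L) mn_data_error("need at least 2 groups")
  if (any(counts < 2L)) mn_data_error("need >= 2 samples per group")

  if (design == "one_way") {
    if (length(counts) == 2L) {
      gs <- names(counts)
      tt <- stats::t.test(data$value[data$group == gs[1]],
                          data$value[data$group == gs[2]],
                          var.equal = TRUE)
      pair <- data.frame(group1 = gs[1], group2 = gs[2],
                         p_adj = tt$p.value,
                         significant = tt$p.value <= alpha,
                         stringsAsFactors = FALSE)
      return(list(design = design, method = "t_test",
                  omnibus_p = tt$p.value, pairwise = pair))
    }
    fit <- stats::aov(value ~ group, data = data)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pair <- data.frame(group1 = pairs[, 2], group2 = pairs[, 1],
                       p_adj = tk[, "p adj"],
                       significant = tk[, "p adj"] <= alpha,
                       stringsAsFactors = FALSE)
    rownames(pair) <- NULL
    return(list(design = design, method = "anova_tukey",
                omnibus_p = omnibus_p, pairwise = pair))
  }

  check_cols(data, "time", "two-way group_compare input")
  fit <- stats::aov(value ~ group * factor(time), data = data)
  tab <- summary(fit)[[1]]
  omnibus_p <- tab[["Pr(>F)"]][1]  # genotype main effect
  times <- sort(unique(data$time))
  gs <- names(counts)
  combs <- utils::combn(gs, 2)
  rows <- list()
  for (ci in seq_len(ncol(combs))) {
    g1 <- combs[1, ci]; g2 <- combs[2, ci]
    p_raw <- vapply(times, function(tp) {
      x <- data$value[data$group == g1 & data$time == tp]
      y <- data$value[data$group == g2 & data$time == tp]
      if (length(x) < 2 || length(y) < 2) return(NA_real_)
      stats::t.test(x, y)$p.value
    }, numeric(1))
    p_adj <- pmin(1, p_raw * length(times))  # Bonferroni across time points
    rows[[ci]] <- data.frame(group1 = g1, group2 = g2, time = times,
                             p_raw = p_raw, p_adj = p_adj,
                             significant = !is.na(p_adj) & p_adj <= alpha,
                             stringsAsFactors = FALSE)
  }
  pair <- do.call(rbind, rows)
  rownames(pair) <- NULL
  list(design = design, method = "two_way_anova_bonferroni",
       omnibus_p = omnibus_p, pairwise = pair)
}

#' Tally screen outcomes
#'
#' Integer arithmetic over the primary screen: total modifiers and the hit
#' rate among tested lines.
#'
#' @param n_suppressors,n_enhancers,n_tested integer counts.
#' @return list with `n_modifiers` and `hit_rate_pct` (= 100 * modifiers /
#'   tested).
#' @export
screen_tally <- function(n_suppressors, n_enhancers, n_tested) {
  n_suppressors <- check_count(n_suppressors, "n_suppressors")
  n_enhancers <- check_count(n_enhancers, "n_enhancers")
  n_tested <- check_count(n_tested, "n_tested", min = 1L)
  n_mod <- n_suppressors + n_enhancers
  list(n_modifiers = n_mod, hit_rate_pct = 100 * n_mod / n_tested)
}

#' Quantify all modifiers in a screen
#'
#' Joins the three screen tables: every genotype other than the control
#' and the tester is treated as a modifier. Eye areas give the suppression
#' percentage; viability gives the normalized lethality (relative to the
#' tester); climbing gives per-time-point Welch t-tests of the modifier's
#' trial fractions against the tester's, whose p-values and effect
#' directions feed the strength classification.
#'
#' @param eye,viability,climbing screen tables (see
#'   [generate_screen_table()] for the column contracts); `viability` and
#'   `climbing` may be `NULL`.
#' @param control,tester genotype labels of the driver-only control and the
#'   tester line.
#' @return data.frame, one row per modifier genotype: `gene`, `mean_mod`,
#'   `mean_tester`, `mean_control`, `suppression_pct`, `out_of_range`,
#'   `v_mod`, `v_tester`, `lethality_pct`, `p_t1`..`p_t5`, `strength_class`.
#' @export
quantify_modifiers <- function(eye, viability = NULL, climbing = NULL,
                               control = "control", tester = "tester") {
  check_cols(eye, c("genotype", "fly_id", "area"), "eye table")
  if (any(eye$area < 0)) mn_data_error("eye areas must be >= 0")
  gts <- unique(eye$genotype)
  if (!all(c(control, tester) %in% gts)) {
    mn_data_error("eye table must contain the control and tester genotypes")
  }
  mods <- setdiff(gts, c(control, tester))
  means <- tapply(eye$area, eye$genotype, mean)
  m_con <- means[[control]]; m_tes <- means[[tester]]

  v_tes <- NA_real_
  if (!is.null(viability)) {
    check_cols(viability, c("genotype", "observed", "expected"),
               "viability table")
    vrow <- viability[viability$genotype == tester, , drop = FALSE]
    if (nrow(vrow) == 1L) {
      v_tes <- viability_ratio(vrow$observed, vrow$expected)
    }
  }

  cc <- NULL
  if (!is.null(climbing)) cc <- climbing_curve(climbing)

  rows <- lapply(mods, function(g) {
    sp <- suppression_percent(means[[g]], m_tes, m_con)
    v_mod <- NA_real_; leth <- NA_real_
    if (!is.null(viability)) {
      vrow <- viability[viability$genotype == g, , drop = FALSE]
      if (nrow(vrow) == 1L && !is.na(v_tes)) {
        v_mod <- viability_ratio(vrow$observed, vrow$expected)
        leth <- as.numeric(normalized_lethality(v_mod, v_tes))
      }
    }
    pv <- rep(NA_real_, 5L); cls <- NA_character_
    if (!is.null(climbing) &&
        all(c(g, tester) %in% unique(climbing$genotype))) {
      dirs <- numeric(5L)
      for (tp in 1:5) {
        x <- climbing[climbing$genotype == g &
                        climbing$time_point == tp, , drop = FALSE]
        y <- climbing[climbing$genotype == tester &
                        climbing$time_point == tp, , drop = FALSE]
        if (nrow(x) >= 2 && nrow(y) >= 2) {
          fx <- x$n_above / x$n_total
          fy <- y$n_above / y$n_total
          pv[tp] <- if (stats::sd(fx) == 0 && stats::sd(fy) == 0) {
            if (mean(fx) == mean(fy)) 1 else 0
          } else stats::t.test(fx, fy)$p.value
          dirs[tp] <- mean(fx) - mean(fy)
        } else {
          pv[tp] <- 1; dirs[tp] <- 0
        }
      }
      cls <- classify_modifier_strength(pv, dirs)
    }
    data.frame(gene = g, mean_mod = means[[g]], mean_tester = m_tes,
               mean_control = m_con, suppression_pct = as.numeric(sp),
               out_of_range = isTRUE(attr(sp, "out_of_range")),
               v_mod = v_mod, v_tester = v_tes, lethality_pct = leth,
               p_t1 = pv[1], p_t2 = pv[2], p_t3 = pv[3], p_t4 = pv[4],
               p_t5 = pv[5], strength_class = cls,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene = character(), mean_mod = numeric(),
               mean_tester = numeric(), mean_control = numeric(),
               suppression_pct = numeric(), out_of_range = logical(),
               v_mod = numeric(), v_tester = numeric(),
               lethality_pct = numeric(), p_t1 = numeric(),
               p_t2 = numeric(), p_t3 = numeric(), p_t4 = numeric(),
               p_t5 = numeric(), strength_class = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
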