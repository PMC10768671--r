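#' One-way ANOVA of a metric across cenocrons, with Tukey HSD letters
#'
#' Fits a one-way ANOVA of `value ~ group`, reports eta-squared
#' (`SS_between / SS_total`) with the conventional effect-size labels
#' (small/medium/large at 0.01/0.06/0.14), and compresses Tukey HSD pairwise
#' tests into compact letter groups: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param data tibble with a numeric `value` column and a `group` column
#'   (or supply column names via `value`/`group`).
#' @param value,group column names (strings).
#' @param alpha significance level for the Tukey letters (default 0.05).
#' @param metric optional metric name carried into the result.
#' @return a `metric_anova` object; `tidy()` gives per-group letters,
#'   `glance()` the F, df, p, eta-squared and label.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   value = c(1, 2, 3, 2, 3, 4, 6, 7, 8),
#'   group = rep(c("a", "b", "c"), each = 3)
#' )
#' glance(metric_anova(d))
metric_anova <- function(data, value = "value", group = "group",
                         alpha = 0.05, metric = value) {
  df <- data.frame(value = data[[value]], group = factor(data[[group]]))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  counts <- table(df$group)
  if (length(counts) < 2) stop("at least 2 groups are required", call. = FALSE)
  if (any(counts < 2)) {
    stop("every group needs >= 2 values; too small: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- stats::anova(fit)
  ss_between <- an$`Sum Sq`[1]
  ss_total <- sum(an$`Sum Sq`)
  eta_sq <- if (ss_total > 0) ss_between / ss_total else 0
  tukey <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  letters <- tukey_letters(rownames(tukey), tukey[, "p adj"],
                           levels(df$group), alpha)
  structure(
    list(metric = metric, F = an$`F value`[1],
         df_between = an$Df[1], df_within = an$Df[2],
         p = an$`Pr(>F)`[1], eta_squared = eta_sq,
         effect_label = effect_label(eta_sq),
         tukey = tibble::as_tibble(tukey, rownames = "contrast"),
         tukey_groups = letters, alpha = alpha),
    class = "metric_anova"
  )
}

effect_label <- function(eta_sq) {
  if (eta_sq >= 0.14) "large" else if (eta_sq >= 0.06) "medium"
  else if (eta_sq >= 0.01) "small" else "negligible"
}

# Compact letter display by insert-absorb: start from one letter covering all
# groups; every significant pair must not share a letter, so split the
# violated letter-sets, then drop letter-sets contained in others.
tukey_letters <- function(contrasts, p_adj, groups, alpha) {
  pairs <- strsplit(contrasts, "-", fixed = TRUE)
  sig <- p_adj < alpha
  sets <- list(groups)
  for (k in which(sig)) {
    a <- pairs[[k]][1]; b <- pairs[[k]][2]
    newsets <- list()
    for (s in sets) {
      if (all(c(a, b) %in% s)) {
        newsets <- c(newsets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        newsets <- c(newsets, list(s))
      }
    }
    # absorb: drop sets that are subsets of another
    keep <- rep(TRUE, length(newsets))
    for (i in seq_along(newsets)) {
      for (j in seq_along(newsets)) {
        if (i != j && keep[j] &&
            all(newsets[[i]] %in% newsets[[j]]) &&
            (length(newsets[[i]]) < length(newsets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- newsets[keep]
  }
  lab <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) lab[g] <- paste0(lab[g], letters[i])
  }
  lab
}

#' @export
print.metric_anova <- function(x, ...) {
  cat(sprintf(
    "<metric_anova> %s: F(%d, %d) = %.4g, p = %.3g, eta^2 = %.3g (%s)\n",
    x$metric, x$df_between, x$df_within, x$F, x$p, x$eta_squared,
    x$effect_label
  ))
  cat("Tukey letters:",
      paste(sprintf("%s=%s", names(x$tukey_groups), x$tukey_groups),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.metric_anova <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    group = names(x$tukey_groups),
    letters = unname(x$tukey_groups)
  )
}

#' @export
glance.metric_anova <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, F = x$F, df_between = x$df_between,
    df_within = x$df_within, p = x$p, eta_squared = x$eta_squared,
    effect_label = x$effect_label
  )
}

#' Pearson correlations of assemblage metrics with environmental variables
#'
#' One record per stratum x metric x variable, computed at the sampled
#' sites with nodata pairs excluded pairwise. Records with fewer than 3
#' valid pairs, or a zero-variance series, are flagged invalid (`r` is `NA`).
#' p-values are naive (two-sided, no spatial-autocorrelation correction,
#' no multiple-testing adjustment).
#'
#' @param assemblage an `assemblage_result` from [compute_assemblage()].
#' @param env the environmental `grid_stack`.
#' @param metrics metric columns to correlate (default all six).
#' @param variables environmental layers to use (default all).
#' @param alpha significance level (default 0.05).
#' @return a tibble of correlation records: `cenocron`, `metric`, `variable`,
#'   `r`, `p`, `n`, `significant`, `valid`.
#' @export
correlation_table <- function(assemblage, env,
                              metrics = c("richness", "mean_age", "mean_nodes",
                                          "weighted_endemism", "pd", "ses_pd"),
                              variables = names(env), alpha = 0.05) {
  stopifnot(inherits(assemblage, "assemblage_result"),
            inherits(env, "grid_stack"))
  sites <- assemblage$sites
  cell <- cbind(sites$row, sites$col)
  env_at_sites <- lapply(env$layers[variables], function(m) m[cell])
  purrr::imap_dfr(assemblage$strata, function(st, stratum) {
    purrr::map_dfr(metrics, function(met) {
      y <- st$site_metrics[[met]]
      purrr::map_dfr(variables, function(v) {
        x <- env_at_sites[[v]]
        ok <- !is.na(x) & !is.na(y)
        n <- sum(ok)
        if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
          return(tibble::tibble(
            cenocron = stratum, metric = met, variable = v,
            r = NA_real_, p = NA_real_, n = n,
            significant = FALSE, valid = FALSE
          ))
        }
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        tibble::tibble(
          cenocron = stratum, metric = met, variable = v,
          r = unname(ct$estimate), p = ct$p.value, n = n,
          significant = ct$p.value < alpha, valid = TRUE
        )
      })
    })
  })
}

#' Heat map of metric-environment correlation coefficients
#'
#' @param records tibble from [correlation_table()].
#' @return a ggplot object (panels per cenocron; non-significant cells
#'   hollowed out).
#' @export
plot_correlations <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(
    x = .data$variable, y = .data$metric, fill = .data$r
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, sprintf("%.2f", .data$r), "")
    ), size = 2.5) +
    ggplot2::facet_wrap(~cenocron) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Niche conservatism / convergence verdict per cenocron
#'
#' Formalizes the qualitative reading of the correlation table: a cenocron is
#' called `conserved` when its mean absolute correlation with the
#' environment is high (>= `threshold_high`) *and* at least half of the
#' predicted correlation signs match; `convergent` when the mean absolute
#' correlation is low (<= `threshold_low`); otherwise `indeterminate`. The
#' mean is taken over significant records (all records, with a warning, when
#' none is significant). The rule and thresholds are echoed in the output so
#' every report states the formalization explicitly.
#'
#' @param records correlation records (tibble from [correlation_table()]),
#'   typically pre-filtered to the metric(s) of interest.
#' @param predictions tibble `cenocron`, `variable`, `expected_sign`
#'   (+1 / -1). Cenocrons without predictions are judged on magnitude alone.
#' @param metrics metric(s) the verdict is based on (default `"richness"`).
#' @param variables environmental variables the verdict is evaluated on.
#'   Default: the variables named in `predictions` (the candidate
#'   niche-driver axes the hypothesis is about), or every variable when no
#'   predictions are supplied.
#' @param threshold_high,threshold_low mean-|r| cutoffs (defaults 0.5 / 0.3).
#' @return a `regime_verdicts` object: tibble `cenocron`, `mean_abs_r`,
#'   `n_records`, `sign_match_frac`, `verdict`, with an `evidence` attribute
#'   (per-record detail) and a `rule` attribute describing the rule applied.
#' @export
regime_verdict <- function(records, predictions = NULL,
                           metrics = "richness", variables = NULL,
                           threshold_high = 0.5, threshold_low = 0.3) {
  predictions <- if (is.null(predictions)) {
    tibble::tibble(cenocron = character(), variable = character(),
                   expected_sign = numeric())
  } else {
    tibble::as_tibble(predictions)
  }
  variables <- variables %||%
    (if (nrow(predictions) > 0) unique(predictions$variable)
     else unique(records$variable))
  rec <- dplyr::filter(tibble::as_tibble(records),
                       .data$metric %in% metrics,
                       .data$variable %in% variables, .data$valid)
  if (nrow(rec) == 0) stop("no valid correlation records", call. = FALSE)
  out <- rec |>
    dplyr::group_by(.data$cenocron) |>
    dplyr::group_modify(function(d, key) {
      use <- d[d$significant, , drop = FALSE]
      warned <- FALSE
      if (nrow(use) == 0) {
        use <- d
        warned <- TRUE
      }
      pred <- predictions[predictions$cenocron == key$cenocron, , drop = FALSE]
      ev <- dplyr::left_join(use, pred[, c("variable", "expected_sign")],
                             by = "variable")
      ev$sign_match <- sign(ev$r) == ev$expected_sign
      matches <- ev$sign_match[!is.na(ev$sign_match)]
      tibble::tibble(
        mean_abs_r = mean(abs(use$r)),
        n_records = nrow(use),
        used_all_records = warned,
        sign_match_frac = if (length(matches) > 0) mean(matches) else NA_real_
      )
    }) |>
    dplyr::ungroup()
  if (any(out$used_all_records)) {
    warning("no significant records for: ",
            paste(out$cenocron[out$used_all_records], collapse = ", "),
            "; verdict computed from all records", call. = FALSE)
  }
  out$verdict <- dplyr::case_when(
    out$mean_abs_r >= threshold_high &
      (is.na(out$sign_match_frac) | out$sign_match_frac >= 0.5) ~ "conserved",
    out$mean_abs_r <= threshold_low ~ "convergent",
    TRUE ~ "indeterminate"
  )
  rule <- sprintf(
    paste0("conserved if mean |r| over significant records >= %.2f and >= half ",
           "of predicted signs match; convergent if mean |r| <= %.2f; ",
           "otherwise indeterminate (metrics: %s; variables: %s)"),
    threshold_high, threshold_low, paste(metrics, collapse = ", "),
    paste(variables, collapse = ", ")
  )
  structure(dplyr::select(out, -"used_all_records"),
            class = c("regime_verdicts", class(out)),
            rule = rule,
            evidence = dplyr::left_join(
              rec, predictions[, c("cenocron", "variable", "expected_sign")],
              by = c("cenocron", "variable")
            ))
}

#' @export
print.regime_verdicts <- function(x, ...) {
  cat("<regime_verdicts>\n")
  cat("rule:", attr(x, "rule"), "\n")
  print(tibble::as_tibble(unclass(x)[names(x)]))
  invisible(x)
}

#' Run the full diagnostic stage
#'
#' ANOVAs (per metric, across cenocron strata), the correlation table, and
#' regime verdicts in one call.
#'
#' @inheritParams correlation_table
#' @inheritParams regime_verdict
#' @param verdict_metrics metric(s) the verdict uses (default `"richness"`).
#' @return list with `anovas` (named list of `metric_anova`), `correlations`
#'   (tibble), `verdicts` (`regime_verdicts`).
#' @export
diagnose_regimes <- function(assemblage, env, predictions = NULL,
                             metrics = c("richness", "mean_age", "mean_nodes",
                                         "weighted_endemism", "pd", "ses_pd"),
                             variables = names(env), alpha = 0.05,
                             verdict_metrics = "richness",
                             threshold_high = 0.5, threshold_low = 0.3) {
  long <- tidy(assemblage)
  strata <- setdiff(names(assemblage$strata), "total")
  anovas <- lapply(stats::setNames(metrics, metrics), function(met) {
    d <- dplyr::filter(long, .data$metric == met, .data$cenocron %in% strata,
                       !is.na(.data$value))
    metric_anova(d, value = "value", group = "cenocron", alpha = alpha,
                 metric = met)
  })
  correlations <- correlation_table(assemblage, env, metrics = metrics,
                                    variables = variables, alpha = alpha)
  verdicts <- regime_verdict(
    dplyr::filter(correlations, .data$cenocron != "Unassigned"),
    predictions = predictions, metrics = verdict_metrics,
    threshold_high = threshold_high, threshold_low = threshold_low
  )
  list(anovas = anovas, correlations = correlations, verdicts = verdicts)
}
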