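#' Accuracy metrics for trait recovery
#'
#' The coefficient of determination is computed literally as
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` (residuals about the
#' observed mean, not a squared correlation, so it can be negative for bad
#' predictors), the root mean square error as `sqrt(mean((y - yhat)^2))`, and
#' the relative RMSE as `100 * RMSE / mean(y)` (percent). `y` holds the
#' observed (reference) values and `yhat` the extracted predictions.
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @return A scalar.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' rmse(c(1, 2, 3), c(1, 2, 4))      # sqrt(1/3)
#' @export
r_squared <- function(y, yhat) {
  check_pairs(y, yhat, min_n = 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("y is constant: R2 undefined")
  1 - sum((y - yhat)^2) / ss_tot
}

#' @rdname r_squared
#' @export
rmse <- function(y, yhat) {
  check_pairs(y, yhat, min_n = 1)
  sqrt(mean((y - yhat)^2))
}

#' @rdname r_squared
#' @export
rrmse <- function(y, yhat) {
  check_pairs(y, yhat, min_n = 1)
  if (mean(y) == 0) abort("mean(y) is zero: relative RMSE undefined")
  100 * rmse(y, yhat) / mean(y)
}

check_pairs <- function(y, yhat, min_n) {
  if (length(y) != length(yhat)) abort("y and yhat must have equal length")
  if (length(y) < min_n) abort(paste0("need at least ", min_n, " pairs"))
  if (any(!is.finite(y)) || any(!is.finite(yhat))) abort("non-finite values")
  invisible(TRUE)
}

#' One-way analysis of variance with significance stars
#'
#' Classical equal-variance one-way ANOVA (`F = MS_between / MS_within`, p
#' from the F distribution via `stats::anova`); significance stars follow the
#' convention `"**"` for p <= 0.01, `"*"` for p <= 0.05, `"ns"` otherwise.
#' If the within-group variance is exactly zero while group means differ, the
#' result is flagged degenerate with `F = Inf`, `p = 0`.
#'
#' @param groups A list of numeric vectors (>= 2 groups, each with >= 2
#'   values), or a data frame together with `value` and `group` column names.
#' @param value,group Column names when `groups` is a data frame.
#' @return A `wheat_anova` object; see [tidy()] and [glance()] methods.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova <- function(groups, value = "value", group = "group") {
  if (is.data.frame(groups)) {
    groups <- split(groups[[value]], groups[[group]])
  }
  if (!is.list(groups) || length(groups) < 2) abort("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) {
    abort("every group needs at least 2 values")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  n <- length(v)
  k <- nlevels(g)
  means <- vapply(groups, mean, 0)
  ssw <- sum((v - means[as.integer(g)])^2)
  degenerate <- FALSE
  if (ssw == 0) {
    if (max(means) - min(means) == 0) {
      Fstat <- 0; p <- 1
    } else {
      Fstat <- Inf; p <- 0; degenerate <- TRUE
    }
    tab <- NULL
  } else {
    tab <- anova(lm(v ~ g))
    Fstat <- tab$`F value`[1]
    p <- tab$`Pr(>F)`[1]
  }
  structure(list(F = Fstat, df_between = k - 1L, df_within = n - k, p = p,
                 group_means = means, stars = p_stars(p),
                 degenerate = degenerate, table = tab),
            class = "wheat_anova")
}

p_stars <- function(p) {
  if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
}

#' @export
print.wheat_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g %s%s\n",
              x$df_between, x$df_within, x$F, x$p, x$stars,
              if (x$degenerate) " (degenerate: zero within-group variance)" else ""))
  invisible(x)
}

#' @param x A `wheat_anova` object.
#' @param ... Unused.
#' @rdname one_way_anova
#' @export
tidy.wheat_anova <- function(x, ...) {
  tibble(term = c("between", "within"),
         df = c(x$df_between, x$df_within),
         statistic = c(x$F, NA),
         p.value = c(x$p, NA))
}

#' @rdname one_way_anova
#' @export
glance.wheat_anova <- function(x, ...) {
  tibble(statistic = x$F, df_between = x$df_between, df_within = x$df_within,
         p.value = x$p, stars = x$stars, degenerate = x$degenerate)
}

#' Validate extracted traits against reference values
#'
#' Joins a reference table (ground truth or manual measurements) with an
#' extraction table on the given keys and computes per-trait paired metrics
#' (n, R2, RMSE, relative RMSE in percent). Unmatched rows on either side are
#' reported, not silently dropped.
#'
#' @param truth,extracted Data frames sharing the join keys and one or more
#'   numeric trait columns with identical names (reference values in
#'   `truth`).
#' @param by Join keys (default: the shared columns among `plant_id`,
#'   `leaf_id`, `seed`, `stage`, `cultivar`).
#' @param traits Trait columns to compare (default: shared numeric columns).
#' @return A `trait_metrics` object: `$metrics` (per-trait tibble), `$pairs`
#'   (long paired values), `$orphans` (unmatched rows).
#' @export
validate_traits <- function(truth, extracted, by = NULL, traits = NULL) {
  stopifnot(is.data.frame(truth), is.data.frame(extracted))
  by <- by %||% intersect(c("plant_id", "leaf_id", "seed", "stage", "cultivar"),
                          intersect(names(truth), names(extracted)))
  if (!length(by)) abort("no join keys shared between truth and extracted")
  shared <- setdiff(intersect(names(truth), names(extracted)), by)
  traits <- traits %||% shared[vapply(shared, function(cc)
    is.numeric(truth[[cc]]) && is.numeric(extracted[[cc]]), TRUE)]
  if (!length(traits)) abort("no shared numeric trait columns")
  joined <- dplyr::inner_join(truth, extracted, by = by,
                              suffix = c("_true", "_extracted"))
  if (!nrow(joined)) abort("zero matched rows between truth and extracted")
  orphans <- list(
    truth = dplyr::anti_join(truth, extracted, by = by),
    extracted = dplyr::anti_join(extracted, truth, by = by)
  )
  pairs <- purrr::map_dfr(traits, function(tr) {
    tibble(trait = tr,
           y = joined[[paste0(tr, "_true")]],
           yhat = joined[[paste0(tr, "_extracted")]])
  })
  metrics <- pairs |>
    dplyr::filter(is.finite(.data$y) & is.finite(.data$yhat)) |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      n = dplyr::n(),
      r_squared = tryCatch(r_squared(.data$y, .data$yhat),
                           error = function(e) NA_real_),
      rmse = rmse(.data$y, .data$yhat),
      rrmse = tryCatch(rrmse(.data$y, .data$yhat),
                       error = function(e) NA_real_),
      .groups = "drop")
  structure(list(metrics = metrics, pairs = pairs, orphans = orphans, by = by),
            class = "trait_metrics")
}

#' @export
print.trait_metrics <- function(x, ...) {
  cat("<trait_metrics> joined on", paste(x$by, collapse = ", "), "\n")
  print(x$metrics)
  no <- vapply(x$orphans, nrow, 1L)
  if (any(no > 0)) {
    cat("unmatched rows: truth", no[["truth"]], "/ extracted",
        no[["extracted"]], "\n")
  }
  invisible(x)
}

#' @param x A `trait_metrics` object.
#' @param ... Unused.
#' @rdname validate_traits
#' @export
tidy.trait_metrics <- function(x, ...) x$metrics

#' @rdname validate_traits
#' @export
glance.trait_metrics <- function(x, ...) {
  tibble(n_traits = nrow(x$metrics),
         n_pairs = sum(x$metrics$n),
         n_orphans = sum(vapply(x$orphans, nrow, 1L)))
}

#' Growth dynamics summary across stages and cultivars
#'
#' Per cultivar-by-stage means and standard deviations of the requested
#' traits, plus, for every stage and trait, a one-way ANOVA across cultivars
#' and uncorrected pairwise two-group comparisons with significance stars
#' (an optional Bonferroni correction multiplies the pairwise p-values by
#' the number of pairs).
#'
#' @param data A phenotype table with one row per plant.
#' @param traits Trait column names to summarise.
#' @param stage,cultivar Names of the stage and cultivar columns.
#' @param stage_order Optional explicit stage ordering; stages listed here
#'   but absent from the data are reported in `$gaps`.
#' @param bonferroni Apply a Bonferroni correction to the pairwise p-values?
#' @return A `growth_dynamics` object with `$summary`, `$anova`, `$pairwise`
#'   and `$gaps`.
#' @export
growth_dynamics <- function(data, traits, stage = "stage",
                            cultivar = "cultivar", stage_order = NULL,
                            bonferroni = FALSE) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(traits, stage, cultivar), names(data))
  if (length(miss)) abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  stage_order <- stage_order %||% unique(data[[stage]])
  gaps <- setdiff(stage_order, unique(data[[stage]]))
  dd <- tibble(stage = factor(data[[stage]], levels = stage_order),
               cultivar = as.character(data[[cultivar]]))
  dd <- dplyr::bind_cols(dd, data[traits])
  long <- tidyr::pivot_longer(dd, dplyr::all_of(traits), names_to = "trait",
                              values_to = "value")
  summary <- long |>
    dplyr::group_by(.data$cultivar, .data$stage, .data$trait) |>
    dplyr::summarise(n = sum(is.finite(.data$value)),
                     mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  cultivars <- sort(unique(dd$cultivar))
  anova_tab <- tibble()
  pairwise <- tibble()
  if (length(cultivars) >= 2) {
    cells <- long |>
      dplyr::filter(is.finite(.data$value)) |>
      dplyr::group_by(.data$stage, .data$trait)
    keys <- dplyr::group_keys(cells)
    splits <- dplyr::group_split(cells)
    for (i in seq_along(splits)) {
      sp <- splits[[i]]
      gl <- split(sp$value, sp$cultivar)
      gl <- gl[vapply(gl, length, 1L) >= 2]
      if (length(gl) < 2) next
      an <- one_way_anova(gl)
      anova_tab <- dplyr::bind_rows(anova_tab, dplyr::bind_cols(
        keys[i, ], glance(an)))
      prs <- utils::combn(names(gl), 2, simplify = FALSE)
      for (pr in prs) {
        a2 <- one_way_anova(gl[pr])
        p <- a2$p * if (bonferroni) length(prs) else 1
        p <- min(1, p)
        pairwise <- dplyr::bind_rows(pairwise, dplyr::bind_cols(
          keys[i, ],
          tibble(group1 = pr[1], group2 = pr[2], statistic = a2$F,
                 p.value = p, stars = p_stars(p))))
      }
    }
  }
  structure(list(summary = summary, anova = anova_tab, pairwise = pairwise,
                 gaps = gaps, traits = traits),
            class = "growth_dynamics")
}

#' @export
print.growth_dynamics <- function(x, ...) {
  cat("<growth_dynamics>\n")
  print(x$summary)
  if (nrow(x$anova)) {
    cat("per-stage ANOVA across cultivars:\n")
    print(x$anova)
  }
  if (length(x$gaps)) cat("missing stages:", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

#' @param x A `growth_dynamics` object.
#' @param ... Unused.
#' @rdname growth_dynamics
#' @export
tidy.growth_dynamics <- function(x, ...) x$summary
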