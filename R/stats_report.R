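#' Aggregate object-level measurements to one value per animal
#'
#' Implements the fixed aggregation order object -> animal -> group: each
#' animal contributes the mean over its objects, and group means +/- SEM are
#' computed across animals, so N is always the number of animals.
#'
#' @param df Data frame with one row per object.
#' @param value Name of the value column.
#' @param animal Name of the animal id column.
#' @param group_vars Character vector of grouping columns (may be empty).
#' @return A `grouped_measure`: list with `per_animal` (one row per animal),
#'   `group` (mean, SEM — `NA` for single-animal groups — and `n_animals`),
#'   and the column names used.
#' @examples
#' df <- data.frame(animal_id = c("a", "a", "b"), v = c(1, 3, 5))
#' per_animal_aggregate(df, "v")$group
#' @export
per_animal_aggregate <- function(df, value, animal = "animal_id",
                                 group_vars = character()) {
  stopifnot(value %in% names(df), animal %in% names(df))
  ok <- !is.na(df[[value]])
  if (any(!ok)) {
    bad <- unique(df[[animal]][!ok])
    df <- df[ok, , drop = FALSE]
    dropped <- setdiff(bad, unique(df[[animal]]))
    if (length(dropped)) {
      warn(sprintf("animal(s) with no usable objects excluded: %s",
                   paste(dropped, collapse = ", ")))
    }
  }
  per_animal <- df |>
    group_by(dplyr::across(dplyr::all_of(c(group_vars, animal)))) |>
    summarise(value = mean(.data[[value]]), n_objects = dplyr::n(),
              .groups = "drop")
  group <- per_animal |>
    group_by(dplyr::across(dplyr::all_of(group_vars))) |>
    summarise(mean = mean(.data$value),
              sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else
                NA_real_,
              n_animals = dplyr::n(), .groups = "drop")
  structure(list(per_animal = per_animal, group = group, value = value,
                 animal = animal, group_vars = group_vars),
            class = "grouped_measure")
}

#' @export
print.grouped_measure <- function(x, ...) {
  cat(sprintf("<grouped_measure> '%s', N in animals\n", x$value))
  print(x$group)
  invisible(x)
}

#' @export
tidy.grouped_measure <- function(x, ...) x$per_animal

#' @export
glance.grouped_measure <- function(x, ...) x$group

#' Significance stars
#'
#' Figure-legend convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param p P-values (vectorized).
#' @return Character vector of stars (`"ns"` when p >= 0.05).
#' @export
significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Compare groups on per-animal values
#'
#' Runs the test on animal-level values: an unpaired two-tailed t-test for
#' two groups, or a one-/two-way ANOVA followed by Tukey's post hoc test for
#' multiple comparisons. For two-way movement-class panels, all class x
#' group comparisons enter the Tukey adjustment but by default only the
#' stationary between-group comparisons are flagged for display
#' (`highlight`), matching the convention of showing only the stationary
#' contrasts.
#'
#' @param gm A `grouped_measure` from [per_animal_aggregate()], or a data
#'   frame of per-animal values.
#' @param design `"ttest"`, `"anova1_tukey"` or `"anova2_tukey"`.
#' @param group Column with the primary grouping factor (default: the
#'   grouped measure's first group variable).
#' @param factor2 Second factor for the two-way design (e.g. movement
#'   class).
#' @param value Value column when `gm` is a plain data frame.
#' @param highlight_level Level of `factor2` whose between-group contrasts
#'   are highlighted (default `"stationary"`).
#' @return A `comparison_result`: list with `test`, `statistic`, `p_value`
#'   (omnibus), `comparisons` (per-contrast tibble with adjusted p-values
#'   and stars), and the fitted object.
#' @export
compare_groups <- function(gm, design = c("ttest", "anova1_tukey",
                                          "anova2_tukey"),
                           group = NULL, factor2 = NULL, value = "value",
                           highlight_level = "stationary") {
  design <- match.arg(design)
  df <- if (inherits(gm, "grouped_measure")) gm$per_animal else as_tibble(gm)
  if (is.null(group)) {
    group <- if (inherits(gm, "grouped_measure") && length(gm$group_vars))
      gm$group_vars[1] else "group"
  }
  stopifnot(group %in% names(df), value %in% names(df))
  df[[group]] <- factor(df[[group]])
  if (nlevels(df[[group]]) < 2) abort("at least 2 groups are required")

  if (design == "ttest") {
    if (nlevels(df[[group]]) != 2) abort("t-test requires exactly 2 groups")
    sp <- split(df[[value]], df[[group]])
    ht <- t.test(sp[[1]], sp[[2]], var.equal = FALSE)
    comparisons <- tibble(
      contrast = paste(levels(df[[group]]), collapse = " - "),
      estimate = unname(diff(rev(ht$estimate))),
      p_adj = ht$p.value, stars = significance_stars(ht$p.value),
      highlight = TRUE)
    return(structure(list(test = "unpaired two-tailed t-test",
                          statistic = unname(ht$statistic),
                          p_value = ht$p.value, comparisons = comparisons,
                          fit = ht), class = "comparison_result"))
  }

  if (design == "anova1_tukey") {
    fml <- stats::as.formula(paste(value, "~", group))
    fit <- aov(fml, data = df)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)[[group]]
    comparisons <- tibble(contrast = rownames(tk),
                          estimate = tk[, "diff"], p_adj = tk[, "p adj"],
                          stars = significance_stars(tk[, "p adj"]),
                          highlight = TRUE)
    return(structure(list(test = "one-way ANOVA + Tukey HSD",
                          statistic = an$`F value`[1],
                          p_value = an$`Pr(>F)`[1], comparisons = comparisons,
                          fit = fit), class = "comparison_result"))
  }

  stopifnot(!is.null(factor2), factor2 %in% names(df))
  df[[factor2]] <- factor(df[[factor2]])
  cells <- table(df[[group]], df[[factor2]])
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("empty cell in two-way design: %s x %s",
                  rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }
  fml <- stats::as.formula(paste(value, "~", group, "*", factor2))
  fit <- aov(fml, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)[[paste0(group, ":", factor2)]]
  cmp <- tibble(contrast = rownames(tk), estimate = tk[, "diff"],
                p_adj = tk[, "p adj"],
                stars = significance_stars(tk[, "p adj"]))
  # highlight between-group contrasts within the chosen factor2 level
  lv <- paste0(":", highlight_level)
  parts <- strsplit(cmp$contrast, "-")
  cmp$highlight <- vapply(parts, function(p) all(endsWith(trimws(p), lv)),
                          logical(1))
  structure(list(test = "two-way ANOVA + Tukey HSD",
                 statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1],
                 comparisons = cmp, fit = fit),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: omnibus p = %.4g\n", x$test,
              x$p_value))
  print(x$comparisons)
  invisible(x)
}

#' @export
tidy.comparison_result <- function(x, ...) x$comparisons

#' @export
glance.comparison_result <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         n_comparisons = nrow(x$comparisons))
}
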