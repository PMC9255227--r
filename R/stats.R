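#' One-way ANOVA for treatment groups
#'
#' Classical equal-variance one-way analysis of variance, F = MSB/MSE with
#' the p value from the F distribution (via [stats::aov()]). Degenerate
#' inputs are handled explicitly: all values identical gives F = 0 and p = 1
#' (flagged); perfectly separated groups with zero within-group variance give
#' an infinite F and p = 0 (flagged `"degenerate"`).
#'
#' @param value Numeric response.
#' @param group Grouping factor (>= 2 levels, each with n >= 2).
#' @return A list with `F`, `p`, `MSE`, `df_err`, `MSB`, `df_between` and
#'   `flag` (`NULL` when clean).
#' @examples
#' one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(value, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("every group needs n >= 2")
  if (anyNA(value)) stop("value contains NA")
  df_b <- nlevels(group) - 1L
  df_e <- length(value) - nlevels(group)
  # detect degenerate variance structure before handing off to aov, whose
  # mean squares are only zero up to floating-point cancellation noise
  gmeans <- tapply(value, group, mean)
  SSW <- sum((value - gmeans[group])^2)
  SST <- sum((value - mean(value))^2)
  tol <- 1e-12 * (SST + sum(value^2) + 1)
  if (SST <= tol)
    return(list(F = 0, p = 1, MSE = 0, df_err = df_e, MSB = 0,
                df_between = df_b, flag = "no variance"))
  if (SSW <= tol)
    return(list(F = Inf, p = 0, MSE = 0, df_err = df_e,
                MSB = (SST - SSW) / df_b, df_between = df_b,
                flag = "degenerate"))
  ss <- summary(stats::aov(value ~ group))[[1]]
  list(F = ss[["F value"]][1], p = ss[["Pr(>F)"]][1],
       MSE = ss[["Mean Sq"]][2], df_err = df_e, MSB = ss[["Mean Sq"]][1],
       df_between = df_b, flag = NULL)
}

#' LSD post-hoc compact letter display
#'
#' Least-significant-difference pairwise comparison after one-way ANOVA.
#' The threshold is
#' \deqn{LSD = t_{1-\alpha/2,\,df_{err}} \sqrt{2\,MSE/n}}
#' with the harmonic mean of the group sizes when n is unequal (flagged).
#' Letters are assigned greedily by descending mean: a group joins the
#' current letter when its mean is within LSD of that letter's leading
#' (largest) mean, otherwise it starts a new letter. Groups sharing a letter
#' are not significantly different.
#'
#' By default the test is Fisher-protected: when the ANOVA F is not
#' significant at `alpha`, all groups share the letter "a". Unprotected LSD
#' (every pair tested regardless) is anti-conservative for more than two
#' groups; set `protected = FALSE` to get it anyway.
#'
#' @param value Numeric response.
#' @param group Grouping factor.
#' @param alpha Significance level.
#' @param anova Optional precomputed [one_way_anova()] result.
#' @param protected Gate letter differences on the ANOVA F test (default).
#' @return A tibble with columns `group`, `n`, `mean`, `sd`, `letter`,
#'   ordered by descending mean, with attributes `LSD` and `flag`.
#' @export
lsd_posthoc <- function(value, group, alpha = 0.05, anova = NULL,
                        protected = TRUE) {
  group <- factor(group)
  if (is.null(anova)) anova <- one_way_anova(value, group)
  if (anova$df_err < 1) stop("df_err < 1: LSD undefined")
  ns <- tapply(value, group, length)
  means <- tapply(value, group, mean)
  sds <- tapply(value, group, sd)
  flag <- NULL
  n_eff <- if (length(unique(ns)) == 1) ns[[1]] else {
    flag <- "unequal n: harmonic mean used"
    length(ns) / sum(1 / ns)
  }
  LSD <- qt(1 - alpha / 2, anova$df_err) * sqrt(2 * anova$MSE / n_eff)
  ord <- order(means, decreasing = TRUE)
  letters_out <- character(length(means))
  if (protected && is.finite(anova$p) && anova$p >= alpha) {
    letters_out[] <- "a"
  } else {
    li <- 1L
    leader <- means[ord[1]]
    letters_out[ord[1]] <- letters[li]
    for (k in seq_along(ord)[-1]) {
      m <- means[ord[k]]
      if (leader - m < LSD) {
        letters_out[ord[k]] <- letters[li]
      } else {
        li <- li + 1L
        leader <- m
        letters_out[ord[k]] <- letters[li]
      }
    }
  }
  out <- tibble::tibble(group = names(means)[ord],
                        n = as.integer(ns[ord]),
                        mean = as.numeric(means[ord]),
                        sd = as.numeric(sds[ord]),
                        letter = letters_out[ord])
  attr(out, "LSD") <- LSD
  attr(out, "flag") <- c(anova$flag, flag)
  out
}

#' Percent change of group means versus a control
#'
#' 100 (mean_group - mean_control) / mean_control per parameter; decreases
#' are negative and the control is 0 by construction.
#'
#' @param table A tidy `TreatmentTable`
#'   (`sample_id, group, replicate, parameter, value`).
#' @param control Name of the control group (present in `table`).
#' @return A tibble `parameter, group, n, mean, percent_change` (with
#'   `percent_change` `NA` and a flag when the control mean is 0).
#' @export
percent_change <- function(table, control = "CK") {
  if (!control %in% table$group)
    stop("control group '", control, "' not present")
  means <- table |>
    dplyr::group_by(.data$parameter, .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value), .groups = "drop")
  ctrl <- means |>
    dplyr::filter(.data$group == control) |>
    dplyr::select("parameter", control_mean = "mean")
  out <- means |>
    dplyr::left_join(ctrl, by = "parameter") |>
    dplyr::mutate(percent_change = ifelse(.data$control_mean == 0, NA_real_,
                                          100 * (.data$mean - .data$control_mean) /
                                            .data$control_mean)) |>
    dplyr::select(-"control_mean")
  if (anyNA(out$percent_change))
    warning("control mean is 0 for some parameter(s); percent change unset")
  out
}

#' Group summary: ANOVA, LSD letters and percent change per parameter
#'
#' The full treatment-comparison report: for each parameter in a tidy
#' `TreatmentTable`, a one-way ANOVA across groups, the (protected) LSD
#' compact letter display, and the percent change of every group mean versus
#' the control. No correction is applied across parameters, matching the
#' per-parameter LSD reporting convention of stress-physiology studies; see
#' the vignette for the caveat.
#'
#' @inheritParams percent_change
#' @param alpha Significance level for ANOVA and LSD.
#' @param protected Fisher-protect the LSD letters (default).
#' @return A tibble with one row per parameter and group: `parameter`,
#'   `group`, `n`, `mean`, `sd`, `letter`, `F`, `p`, `percent_change`.
#' @export
group_summary <- function(table, control = "CK", alpha = 0.05,
                          protected = TRUE) {
  if (!control %in% table$group)
    stop("control group '", control, "' not present")
  if (length(unique(table$group)) < 2)
    stop("need at least 2 groups to compare")
  pc <- percent_change(table, control)
  parts <- lapply(split(table, table$parameter), function(df) {
    aov_res <- one_way_anova(df$value, df$group)
    lsd <- lsd_posthoc(df$value, df$group, alpha = alpha, anova = aov_res,
                       protected = protected)
    lsd$parameter <- df$parameter[1]
    lsd$F <- aov_res$F
    lsd$p <- aov_res$p
    lsd
  })
  dplyr::bind_rows(parts) |>
    dplyr::left_join(pc |> dplyr::select("parameter", "group", "percent_change"),
                     by = c("parameter", "group")) |>
    dplyr::select("parameter", "group", "n", "mean", "sd", "letter",
                  "F", "p", "percent_change")
}
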