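#' Balanced two-way factorial dataset
#'
#' Container for a 2 x 2 factorial experiment with equal replication, as
#' used for the grain-size (fine/coarse) by moisture (dry/humid) study of
#' acidity. Exactly two levels per factor and at least two replicates per
#' cell are required.
#'
#' @param factor_a,factor_b Factor level labels per observation (character
#'   or factor; exactly two distinct levels each).
#' @param response Numeric response per observation (e.g. moisture-corrected
#'   acidity).
#' @param factor_a_name,factor_b_name Display names for the two factors.
#' @param response_scale Multiplier applied to the response for display
#'   tables and plots only (e.g. 100 to show acidity in hundredths); the
#'   decomposition and ANOVA always use the raw response.
#' @return A `factorial_dataset`: a tibble with columns `a`, `b`,
#'   `replicate`, `response`, plus attributes for names and scale.
#' @export
#' @examples
#' d <- factorial_dataset(
#'   factor_a = rep(c("fine", "coarse"), each = 4),
#'   factor_b = rep(c("dry", "humid"), times = 4),
#'   response = c(0.6, 1.1, 0.7, 1.2, 0.8, 1.5, 0.7, 1.4)
#' )
#' factorial_anova(decompose_factorial(d))
factorial_dataset <- function(factor_a, factor_b, response,
                              factor_a_name = "grain size",
                              factor_b_name = "moisture",
                              response_scale = 1) {
  a <- as.character(factor_a)
  b <- as.character(factor_b)
  y <- as.numeric(response)
  if (length(a) != length(y) || length(b) != length(y)) {
    stop("Factor labels and responses must have equal length.")
  }
  if (anyNA(a) || anyNA(b) || anyNA(y)) {
    stop("Missing values are not supported in a factorial dataset.")
  }
  la <- sort(unique(a))
  lb <- sort(unique(b))
  if (length(la) != 2 || length(lb) != 2) {
    stop("Unsupported design: exactly two levels per factor are required.")
  }
  counts <- table(a, b)
  r <- counts[1, 1]
  if (any(counts != r)) {
    stop("Unsupported design: cells are unbalanced (unequal replication).")
  }
  if (r < 2) {
    stop("Unsupported design: at least two replicates per cell are required.")
  }
  out <- tibble::tibble(a = a, b = b, response = y) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::mutate(replicate = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("a", "b", "replicate", "response")
  structure(out,
            class = c("factorial_dataset", class(out)),
            factor_a_name = factor_a_name,
            factor_b_name = factor_b_name,
            levels_a = la, levels_b = lb, replication = as.integer(r),
            response_scale = response_scale)
}

#' Decompose a balanced 2 x 2 dataset into effects
#'
#' Least-squares decomposition by cell and marginal means: every observation
#' is written as grand mean + factor-A effect + factor-B effect +
#' interaction + residual. Effects sum to zero over the levels of their
#' factor, interaction terms sum to zero along each row and column, and
#' residuals sum to zero within each cell, so the reconstruction is exact.
#'
#' @param data A [factorial_dataset()].
#' @return A `factorial_decomposition` list: `grand_mean`, `effect_a` and
#'   `effect_b` (named per level), `interaction` (2 x 2 matrix), `fitted`
#'   and `residuals` per observation, and the input `data`.
#' @export
decompose_factorial <- function(data) {
  stopifnot(inherits(data, "factorial_dataset"))
  la <- attr(data, "levels_a")
  lb <- attr(data, "levels_b")
  grand <- mean(data$response)
  mean_a <- tapply(data$response, data$a, mean)[la]
  mean_b <- tapply(data$response, data$b, mean)[lb]
  cell <- tapply(data$response, list(data$a, data$b), mean)[la, lb]
  eff_a <- stats::setNames(as.numeric(mean_a - grand), la)
  eff_b <- stats::setNames(as.numeric(mean_b - grand), lb)
  inter <- cell - outer(eff_a, eff_b, `+`) - grand
  fitted <- cell[cbind(data$a, data$b)]
  structure(
    list(
      grand_mean = grand,
      effect_a = eff_a,
      effect_b = eff_b,
      interaction = inter,
      cell_means = cell,
      fitted = unname(fitted),
      residuals = data$response - unname(fitted),
      data = data
    ),
    class = "factorial_decomposition"
  )
}

#' Two-way ANOVA table from a factorial decomposition
#'
#' Sums of squares are the squared decomposition components summed over all
#' observations; F statistics are mean squares over the error mean square,
#' with p-values from the F distribution (df 1, 1, 1 and 4(r-1)). A
#' `probability` column reports the significance probability 100(1 - p) in
#' percent, the complement-form in which factorial screening results are
#' often quoted.
#'
#' @param dec A [decompose_factorial()] result.
#' @return A tibble with one row per source (A, B, A:B, Residuals) and
#'   columns `term`, `df`, `sumsq`, `meansq`, `statistic`, `p.value`,
#'   `probability`.
#' @export
factorial_anova <- function(dec) {
  stopifnot(inherits(dec, "factorial_decomposition"))
  data <- dec$data
  r <- attr(data, "replication")
  n <- nrow(data)
  ss_a <- sum((dec$effect_a[data$a])^2)
  ss_b <- sum((dec$effect_b[data$b])^2)
  ss_ab <- sum((dec$interaction[cbind(data$a, data$b)])^2)
  ss_e <- sum(dec$residuals^2)
  df <- c(1, 1, 1, 4 * (r - 1))
  ss <- c(ss_a, ss_b, ss_ab, ss_e)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA_real_)
  if (ms[4] == 0) {
    # degenerate: no residual variation
    f[1:3] <- ifelse(ms[1:3] > 0, Inf, NaN)
  }
  p <- c(stats::pf(f[1:3], 1, df[4], lower.tail = FALSE), NA_real_)
  tibble::tibble(
    term = c(attr(data, "factor_a_name"), attr(data, "factor_b_name"),
             paste(attr(data, "factor_a_name"), attr(data, "factor_b_name"),
                   sep = ":"),
             "Residuals"),
    df = df,
    sumsq = ss,
    meansq = ms,
    statistic = f,
    p.value = p,
    probability = 100 * (1 - p)
  )
}

#' Cell, marginal and grand means for the interaction graph
#'
#' @param data A [factorial_dataset()].
#' @return A list with `cell_means` (tibble: one row per factor-level
#'   combination), `marginal_a`, `marginal_b` (named vectors) and
#'   `grand_mean`. Means are consistent with the decomposition:
#'   cell mean = grand + effect_a + effect_b + interaction.
#' @export
grouped_means <- function(data) {
  stopifnot(inherits(data, "factorial_dataset"))
  la <- attr(data, "levels_a")
  lb <- attr(data, "levels_b")
  cell <- tapply(data$response, list(data$a, data$b), mean)[la, lb]
  cells <- tidyr::expand_grid(a = la, b = lb)
  cells$mean <- cell[cbind(cells$a, cells$b)]
  list(
    cell_means = cells,
    marginal_a = tapply(data$response, data$a, mean)[la],
    marginal_b = tapply(data$response, data$b, mean)[lb],
    grand_mean = mean(data$response)
  )
}

#' Interaction graph of grouped averages
#'
#' Plots the four cell means with one line per level of factor A across the
#' levels of factor B; parallel lines indicate additivity (no interaction).
#'
#' @param data A [factorial_dataset()].
#' @return A ggplot object.
#' @export
plot_interaction <- function(data) {
  stopifnot(inherits(data, "factorial_dataset"))
  gm <- grouped_means(data)
  scale <- attr(data, "response_scale")
  df <- gm$cell_means
  df$mean <- df$mean * scale
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$mean,
                                   group = .data$a, colour = .data$a)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = attr(data, "factor_b_name"),
                  colour = attr(data, "factor_a_name"),
                  y = "grouped average response") +
    ggplot2::theme_minimal()
}
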