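#' Coefficient of variation in percent
#'
#' `100 * sd / mean`, with the n-1 denominator for the SD. Scale-invariant
#' under positive rescaling.
#'
#' @param x Numeric values; mean must be nonzero.
#' @param na.rm Drop missing values first.
#' @return CV in percent.
#' @examples
#' cv_percent(c(8, 12)) # ~28.28
#' @export
cv_percent <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  m <- mean(x)
  if (m == 0) abort("CV is undefined for values with zero mean.")
  100 * sd(x) / m
}

#' Per-genotype trait summaries (means, standard errors, n)
#'
#' Collapses a per-fruit derived-trait table to the genotype level — the
#' unit of the statistical layer. Every numeric column is summarised as
#' arithmetic mean, standard error (absent when n = 1) and n.
#'
#' The log10-permeance trait is added at the genotype-mean level:
#' `log10(mean(permeance))`, computed over fruits with positive permeance
#' only. Fruits flagged with negative permeance (net mass loss during the
#' assay) contribute to the plain permeance mean but are excluded from the
#' log trait; the number excluded is reported in the `n_excluded_log`
#' attribute and via a message.
#'
#' @param data Per-fruit table with a `genotype` column (plus optional
#'   `collection`, `season`) and numeric trait columns, e.g. the output of
#'   [derive_uptake()] joined with [fit_ws_courses()].
#' @param traits Character vector of trait columns to summarise; default
#'   all numeric columns.
#' @return A tidy tibble with columns `genotype` (+ `collection`,
#'   `season` when present), `trait`, `mean`, `se`, `n`.
#' @export
summarize_genotypes <- function(data, traits = NULL) {
  if (nrow(data) == 0L) abort("Cannot summarise an empty per-fruit table.")
  if (!"genotype" %in% names(data)) abort("data must contain a 'genotype' column.")
  id_cols <- intersect(c("genotype", "collection", "season"), names(data))
  if (is.null(traits)) {
    traits <- names(data)[vapply(data, is.numeric, logical(1))]
    traits <- setdiff(traits, id_cols)
  }
  long <- data |>
    dplyr::select(dplyr::all_of(c(id_cols, traits))) |>
    tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(id_cols, "trait")))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = dplyr::if_else(dplyr::n() > 1L, sd(.data$value) / sqrt(dplyr::n()), NA_real_),
      n = dplyr::n(), .groups = "drop"
    )

  n_excl <- 0L
  if ("permeance_m_s" %in% traits) {
    pos <- data |>
      dplyr::filter(!is.na(.data$permeance_m_s)) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
      dplyr::summarise(
        n_pos = sum(.data$permeance_m_s > 0),
        n_neg = sum(.data$permeance_m_s <= 0),
        mean_pos = mean(.data$permeance_m_s[.data$permeance_m_s > 0]),
        .groups = "drop"
      )
    n_excl <- sum(pos$n_neg)
    if (n_excl > 0L) {
      message(n_excl, " fruit with non-positive permeance excluded from the log10-permeance trait.")
    }
    logp <- pos |>
      dplyr::filter(.data$n_pos > 0L) |>
      dplyr::transmute(dplyr::across(dplyr::all_of(id_cols)),
                       trait = "log10_permeance",
                       mean = log10(.data$mean_pos), se = NA_real_,
                       n = .data$n_pos)
    long <- dplyr::bind_rows(long, logp)
  }
  attr(long, "n_excluded_log") <- n_excl
  long
}

#' Wide genotype-by-trait matrix of means
#'
#' Pivots a [summarize_genotypes()] result to one row per genotype with a
#' column per trait mean — the shape the correlation and regression layer
#' consumes.
#'
#' @param summary A [summarize_genotypes()] tibble.
#' @return A wide tibble of genotype trait means.
#' @export
genotype_trait_matrix <- function(summary) {
  id_cols <- intersect(c("genotype", "collection", "season"), names(summary))
  summary |>
    dplyr::select(dplyr::all_of(id_cols), "trait", "mean") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "mean")
}

#' Frequency distribution, quantiles and normal-probability pairs
#'
#' Builds the material for a distribution panel: fixed-width histogram
#' bins, empirical quantiles, and normal-probability (QQ) pairs using the
#' plotting positions \eqn{(i - 0.5)/n} against the standard normal.
#'
#' @param x Numeric values, length >= 5.
#' @param binwidth Histogram bin width; default spans the data in
#'   `bins` equal bins.
#' @param bins Number of bins when `binwidth` is not given.
#' @param probs Quantile probabilities to report.
#' @return An object of class `distribution_report`: list with tibbles
#'   `histogram` (`lower`, `upper`, `mid`, `count`), `quantiles`
#'   (`prob`, `value`), `qq` (`theoretical`, `sample`), and `n`. Histogram
#'   counts always sum to `n`. Has an [autoplot()] method.
#' @export
distribution_report <- function(x, binwidth = NULL, bins = 10,
                                probs = c(0, 0.25, 0.5, 0.75, 1)) {
  x <- x[!is.na(x)]
  if (length(x) < 5L) abort("distribution_report needs at least 5 values.")
  rng <- range(x)
  if (is.null(binwidth)) {
    binwidth <- if (diff(rng) == 0) 1 else diff(rng) / bins
  }
  lower0 <- rng[1]
  idx <- pmin(floor((x - lower0) / binwidth), ceiling(diff(rng) / binwidth - 1))
  idx[diff(rng) == 0] <- 0
  idx <- pmax(idx, 0)
  counts <- table(factor(idx, levels = 0:max(idx)))
  hist_tbl <- tibble::tibble(
    lower = lower0 + as.integer(names(counts)) * binwidth,
    upper = lower0 + (as.integer(names(counts)) + 1) * binwidth,
    count = as.integer(counts)
  ) |> dplyr::mutate(mid = (.data$lower + .data$upper) / 2)
  n <- length(x)
  pp <- (seq_len(n) - 0.5) / n
  out <- list(
    histogram = hist_tbl,
    quantiles = tibble::tibble(prob = probs, value = unname(quantile(x, probs))),
    qq = tibble::tibble(theoretical = qnorm(pp), sample = sort(x)),
    n = n, mean = mean(x), sd = sd(x)
  )
  class(out) <- "distribution_report"
  out
}

#' @export
print.distribution_report <- function(x, ...) {
  cat(sprintf("Distribution report: n = %d, mean = %.4g, sd = %.4g, %d bins\n",
              x$n, x$mean, x$sd, nrow(x$histogram)))
  invisible(x)
}
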