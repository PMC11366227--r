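#' Significance star codes for p-values
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, `ns`
#' otherwise.
#'
#' @param p P-values; vectorised.
#' @return Character vector of star codes.
#' @export
star_code <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Pearson correlation table with significance stars
#'
#' Genotype-level Pearson correlations between trait means, per group
#' (e.g. per collection x season) and pooled across all rows (the "grand
#' mean" block, computed on all genotype-season rows together). Constant
#' traits yield an undefined correlation, reported as `NA`.
#'
#' @param data Wide genotype-by-trait tibble of means, e.g. from
#'   [genotype_trait_matrix()].
#' @param traits Character vector of trait columns to correlate.
#' @param by Optional character vector of grouping columns; each group
#'   must keep >= 3 complete genotypes. A pooled block labelled
#'   `"grand mean"` is always appended when `by` is given.
#' @return A tibble with `group`, `trait_x`, `trait_y`, `r`, `p`, `stars`,
#'   `n`. The table is symmetric with a unit diagonal.
#' @export
correlation_matrix <- function(data, traits, by = NULL) {
  miss <- setdiff(traits, names(data))
  if (length(miss)) abort(paste0("Missing trait column(s): ", paste(miss, collapse = ", ")))
  one_block <- function(d, label) {
    cmb <- expand.grid(trait_x = traits, trait_y = traits,
                       stringsAsFactors = FALSE)
    purrr::pmap_dfr(cmb, function(trait_x, trait_y) {
      x <- d[[trait_x]]; y <- d[[trait_y]]
      ok <- complete.cases(x, y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      if (n < 3L) abort(paste0("Correlation group '", label, "' has fewer than 3 complete genotypes."))
      if (sd(x) == 0 || sd(y) == 0) {
        return(tibble::tibble(group = label, trait_x = trait_x,
                              trait_y = trait_y, r = NA_real_, p = NA_real_,
                              stars = NA_character_, n = n))
      }
      if (identical(trait_x, trait_y)) {
        return(tibble::tibble(group = label, trait_x = trait_x,
                              trait_y = trait_y, r = 1, p = 0, stars = "***",
                              n = n))
      }
      ct <- cor.test(x, y, method = "pearson")
      tibble::tibble(group = label, trait_x = trait_x, trait_y = trait_y,
                     r = unname(ct$estimate), p = ct$p.value,
                     stars = star_code(ct$p.value), n = n)
    })
  }
  if (is.null(by)) return(one_block(data, "pooled"))
  groups <- data |> dplyr::group_by(dplyr::across(dplyr::all_of(by)))
  keys <- dplyr::group_keys(groups)
  labels <- apply(keys, 1, paste, collapse = "/")
  blocks <- dplyr::group_split(groups)
  out <- purrr::map2_dfr(blocks, labels, one_block)
  dplyr::bind_rows(out, one_block(data, "grand mean"))
}

#' Regress the water-soaking index on log10 skin permeance
#'
#' Ordinary least squares of the genotype-mean water-soaking index at the
#' index time on genotype-level log10 permeance — the headline
#' relationship of the analysis (the share of water-soaking variability
#' accounted for by skin permeance).
#'
#' @param data Wide genotype trait-mean tibble containing the two columns.
#' @param ws_col,logp_col Column names for the response and predictor.
#' @return An object of class `ws_permeance_fit` wrapping the `lm`, with
#'   `slope`, `intercept`, `r_squared`, `r_squared_pct`, `p_value`, `n`.
#'   Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
regress_ws_on_log_permeance <- function(data, ws_col = "ws_index",
                                        logp_col = "log10_permeance") {
  miss <- setdiff(c(ws_col, logp_col), names(data))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  d <- tibble::tibble(ws = data[[ws_col]], logp = data[[logp_col]])
  d <- d[complete.cases(d), ]
  if (nrow(d) < 3L) abort("The regression needs at least 3 genotypes.")
  fit <- lm(ws ~ logp, data = d)
  sm <- summary(fit)
  p <- if (nrow(d) > 2 && sm$fstatistic[1] > 0) {
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  } else NA_real_
  structure(list(fit = fit, data = d,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared, r_squared_pct = 100 * sm$r.squared,
                 p_value = unname(p), n = nrow(d)),
            class = "ws_permeance_fit")
}

#' @export
print.ws_permeance_fit <- function(x, ...) {
  cat("Water soaking ~ log10(permeance)\n")
  cat(sprintf("  slope = %.3f rating per log10 unit, intercept = %.3f\n",
              x$slope, x$intercept))
  cat(sprintf("  R^2 = %.3f (%.1f%%), p = %.3g, n = %d genotypes\n",
              x$r_squared, x$r_squared_pct, x$p_value, x$n))
  invisible(x)
}

#' Group comparisons with letters or stars
#'
#' The three group-comparison conventions of the genotype tables:
#' \describe{
#'   \item{`"tukey"`}{One-way ANOVA followed by Tukey's Studentized range
#'     test on all pairs; groups sharing no letter differ at `alpha`.}
#'   \item{`"mann_whitney"`}{Pairwise two-sided Mann-Whitney U tests
#'     (unadjusted by default, matching the convention for ordinal scores;
#'     set `p_adjust` for Holm/Bonferroni), summarised as letters.}
#'   \item{`"dunnett"`}{Dunnett's many-to-one comparison against a named
#'     control, via the multivariate-t distribution with the
#'     equal-correlation structure; reported as star codes per group.}
#' }
#' Letter displays use the insert-absorb algorithm and are self-audited
#' on every call: letters are checked against their own p-values (shared
#' letter implies p > alpha, no shared letter implies p <= alpha).
#'
#' @param data Data frame with one observation per row.
#' @param value,group Column names of the response and the grouping
#'   factor.
#' @param method `"tukey"`, `"mann_whitney"` or `"dunnett"`.
#' @param control Control group label, required for `"dunnett"`.
#' @param alpha Significance level for letter separation.
#' @param p_adjust Multiplicity adjustment for the pairwise Mann-Whitney
#'   p-values (default `"none"`).
#' @return A tibble with `group`, `n`, `mean`, `se` and `letters` (or
#'   `p_vs_control` + `stars` for Dunnett), ordered by decreasing mean.
#'   The pairwise p-value matrix is attached as attribute `"p_matrix"`.
#' @export
compare_groups <- function(data, value, group,
                           method = c("tukey", "mann_whitney", "dunnett"),
                           control = NULL, alpha = 0.05, p_adjust = "none") {
  method <- match.arg(method)
  miss <- setdiff(c(value, group), names(data))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  d <- tibble::tibble(value = data[[value]], group = as.character(data[[group]]))
  d <- d[complete.cases(d), ]
  counts <- table(d$group)
  if (length(counts) < 2L) abort("compare_groups needs at least 2 groups.")
  if (any(counts < 2L)) abort("Every group needs at least 2 observations.")

  summ <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean))

  if (method == "dunnett") {
    if (is.null(control)) abort("Dunnett's test needs a named control group.")
    if (!control %in% d$group) abort(paste0("Control group '", control, "' not found."))
    d$group <- stats::relevel(factor(d$group), ref = control)
    fit <- aov(value ~ group, data = d)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(gl)
    comp <- names(sm$test$coefficients)
    pvals <- setNames(as.numeric(sm$test$pvalues), sub(" - .*$", "", comp))
    out <- summ |>
      dplyr::mutate(
        p_vs_control = dplyr::if_else(.data$group == control, NA_real_,
                                      unname(pvals[.data$group])),
        stars = dplyr::if_else(.data$group == control, "control",
                               star_code(.data$p_vs_control))
      )
    attr(out, "p_matrix") <- pvals
    return(out)
  }

  pm <- if (method == "tukey") {
    fit <- aov(value ~ factor(group), data = d)
    tk <- TukeyHSD(fit)[[1]]
    pairs_to_matrix(rownames(tk), tk[, "p adj"], unique(d$group))
  } else {
    pw <- suppressWarnings(pairwise.wilcox.test(d$value, d$group,
                                                p.adjust.method = p_adjust,
                                                exact = FALSE))
    lower_to_matrix(pw$p.value, unique(d$group))
  }
  letters <- cld_insert_absorb(pm, summ$group, alpha = alpha)
  out <- summ |> dplyr::mutate(letters = unname(letters[.data$group]))
  audit_letter_display(out$letters, out$group, pm, alpha)
  attr(out, "p_matrix") <- pm
  out
}

# "B-A" style pair names + p values -> symmetric matrix
pairs_to_matrix <- function(pair_names, p, groups) {
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  parts <- strsplit(pair_names, "-", fixed = TRUE)
  for (k in seq_along(parts)) {
    a <- parts[[k]][1]; b <- parts[[k]][2]
    m[a, b] <- m[b, a] <- p[k]
  }
  diag(m) <- 1
  m
}

lower_to_matrix <- function(pmat, groups) {
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (r in rownames(pmat)) for (c in colnames(pmat)) {
    if (!is.na(pmat[r, c])) m[r, c] <- m[c, r] <- pmat[r, c]
  }
  diag(m) <- 1
  m
}

#' Compact letter display by insert-absorb
#'
#' Assigns letters to groups from a symmetric pairwise p-value matrix so
#' that two groups share a letter if and only if they are not
#' significantly different at `alpha`. Columns (letters) are ordered by
#' the best-ranked group they contain, with group rank given by
#' decreasing mean (ties broken by the supplied order).
#'
#' @param p_matrix Symmetric matrix of pairwise p-values with group
#'   dimnames.
#' @param group_order Groups ordered by decreasing mean.
#' @param alpha Significance level.
#' @return Named character vector of letter strings.
#' @export
cld_insert_absorb <- function(p_matrix, group_order, alpha = 0.05) {
  stopifnot(all(group_order %in% rownames(p_matrix)))
  cols <- list(group_order)
  n <- length(group_order)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      gi <- group_order[i]; gj <- group_order[j]
      pij <- p_matrix[gi, gj]
      if (is.na(pij) || pij > alpha) next
      new_cols <- list()
      for (col in cols) {
        if (gi %in% col && gj %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, gj)), list(setdiff(col, gi)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  rank_of <- setNames(seq_along(group_order), group_order)
  cols <- cols[order(vapply(cols, function(cl) min(rank_of[cl]), numeric(1)))]
  lab <- letters[seq_along(cols)]
  out <- setNames(vapply(group_order, function(g) {
    paste0(lab[vapply(cols, function(cl) g %in% cl, logical(1))], collapse = "")
  }, character(1)), group_order)
  out
}

audit_letter_display <- function(letters, groups, p_matrix, alpha) {
  share <- function(a, b) {
    any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
  }
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i >= j) next
      p <- p_matrix[groups[i], groups[j]]
      if (is.na(p)) next
      sh <- share(letters[i], letters[j])
      if (sh && p <= alpha) {
        abort("Letter-display self-audit failed: groups sharing a letter differ significantly.")
      }
      if (!sh && p > alpha) {
        abort("Letter-display self-audit failed: separated groups do not differ significantly.")
      }
    }
  }
  invisible(TRUE)
}
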