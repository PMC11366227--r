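# a reduced three-collection panel for tests that do not need the full
# 172-genotype layout
small_panel_config <- function(seed = 42, ...) {
  cols <- default_collections()
  cols$n_genotypes <- c(12L, 14L, 8L)
  cols$fruit_per_genotype <- 5L
  panel_config(collections = cols, seed = seed, ...)
}

# independent letter-sharing checker used to audit compare_groups output
letters_consistent <- function(tbl, alpha = 0.05) {
  pm <- attr(tbl, "p_matrix")
  share <- function(a, b) any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
  for (i in seq_len(nrow(tbl))) {
    for (j in seq_len(nrow(tbl))) {
      if (i >= j) next
      p <- pm[tbl$group[i], tbl$group[j]]
      if (is.na(p)) next
      sh <- share(tbl$letters[i], tbl$letters[j])
      if (sh && p <= alpha) return(FALSE)
      if (!sh && p > alpha) return(FALSE)
    }
  }
  TRUE
}
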