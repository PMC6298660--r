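#' Descriptive statistics for a network-behavior panel
#'
#' Per wave: number of participating actors, mean and SD of within-panel
#' out-degree over participating actors, mean and SD of raw BMI (when the
#' panel carries raw values; otherwise of the category codes), and the count
#' per behavior category.  Across the first and last wave (actors observed at
#' both): the percentage whose category increased, stayed the same, or
#' decreased.
#'
#' @param panel a [wave_panel()].
#' @return list with elements `per_wave` (data frame) , `category_counts`
#'   (matrix, categories x waves) and `transition` (named percentages
#'   `increase`, `same`, `decrease` summing to 100).
#' @export
panel_descriptives <- function(panel) {
  validate_wave_panel(panel)
  M <- length(panel$waves)
  per_wave <- do.call(rbind, lapply(seq_len(M), function(m) {
    w <- panel$waves[[m]]
    part <- w$participating
    od <- rowSums(w$adjacency)[part]
    bmi <- if (!is.null(w$bmi)) w$bmi[part] else w$behavior[part]
    data.frame(wave = m, n_participating = sum(part),
               outdegree_mean = mean(od), outdegree_sd = sd(od),
               bmi_mean = mean(bmi, na.rm = TRUE),
               bmi_sd = sd(bmi, na.rm = TRUE))
  }))
  counts <- sapply(panel$waves, function(w)
    tabulate(w$behavior[w$participating], nbins = panel$n_categories))
  rownames(counts) <- bmi_category_labels()[seq_len(panel$n_categories)]
  colnames(counts) <- paste0("T", seq_len(M))

  z1 <- panel$waves[[1]]$behavior
  zM <- panel$waves[[M]]$behavior
  both <- !is.na(z1) & !is.na(zM)
  if (!any(both)) stop("no actor observed at both the first and last wave")
  d <- zM[both] - z1[both]
  transition <- 100 * c(increase = mean(d > 0), same = mean(d == 0),
                        decrease = mean(d < 0))
  list(per_wave = per_wave, category_counts = counts, transition = transition)
}
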