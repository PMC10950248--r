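# Group-comparison protocol: one-way ANOVA gate, then pairwise two-sided
# Welch t-tests.

significanceStars <- function(p) {
  ifelse(p < 1e-4, "****",
    ifelse(p < 1e-3, "***",
      ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
    )
  )
}

#' Compare a quantity between neuron classes
#'
#' With more than two groups, a one-way ANOVA gates (at `gate`) a round of
#' pairwise two-sided Welch t-tests; with exactly two groups the Welch
#' test is performed directly. Stars follow the usual convention
#' (ns, * p<0.05, ** p<0.01, *** p<0.001, **** p<0.0001).
#'
#' @param values numeric vector.
#' @param labels group labels (same length).
#' @param gate ANOVA significance gate for running the pairwise tests.
#' @return list: `anova` (data.frame `F`, `p`, or `NULL` for two groups),
#'   `gated` (logical: were pairwise tests run), `pairwise` (data.frame
#'   `groupA`, `groupB`, `t`, `p`, `stars`).
#' @export
compareClasses <- function(values, labels, gate = 0.01) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  groups <- levels(labels)
  if (length(groups) < 2) stop("at least two groups are required")
  sizes <- table(labels)
  if (any(sizes < 2)) {
    stop(
      "every group needs at least two members; offending: ",
      paste(names(sizes)[sizes < 2], collapse = ", ")
    )
  }
  anovaTab <- NULL
  runPairs <- TRUE
  if (length(groups) > 2) {
    fit <- aov(values ~ labels)
    s <- summary(fit)[[1]]
    anovaTab <- data.frame(F = s[["F value"]][1], p = s[["Pr(>F)"]][1])
    runPairs <- anovaTab$p < gate
  }
  pairwise <- NULL
  if (runPairs) {
    combos <- utils::combn(groups, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
      a <- combos[1, i]
      b <- combos[2, i]
      tt <- t.test(values[labels == a], values[labels == b],
        var.equal = FALSE, alternative = "two.sided"
      )
      data.frame(
        groupA = a, groupB = b,
        t = unname(tt$statistic), p = tt$p.value,
        stars = significanceStars(tt$p.value),
        stringsAsFactors = FALSE
      )
    }))
  }
  list(anova = anovaTab, gated = runPairs, pairwise = pairwise)
}
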