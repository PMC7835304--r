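#' Assemble the per-region results report
#'
#' Mirrors the study's results table: per-region mean +/- SD of SUVR and
#' SPIO-Vol by group with two-sided Mann-Whitney group comparisons, plus
#' pooled (both groups together) Spearman correlations of each metric with
#' the clinical score and between SUVR and SPIO-Vol. Region-wise p-values
#' are reported uncorrected by default, matching common practice for small
#' exploratory cohorts; a Holm adjustment is available. Note that pooling
#' groups inflates rank correlations under group separation — this is the
#' convention being reproduced, not a recommendation.
#'
#' @param suvr region table containing metric `SUVR` (columns `animal_id`,
#'   `region`, `metric`, `value`).
#' @param spiovol region table containing metric `SPIO_Vol_pct`.
#' @param cohort cohort metadata data frame with `animal_id`, `group`
#'   (`"EAE"`/`"CTR"`) and `cs`.
#' @param alpha significance threshold (default 0.05).
#' @param holm apply a Holm correction across regions within each metric.
#' @return a `results_report`: list with `group_stats`, `correlations`,
#'   `alpha`.
#' @export
build_results <- function(suvr, spiovol, cohort, alpha = 0.05, holm = FALSE) {
  tab <- rbind(suvr[suvr$metric == "SUVR", ],
               spiovol[spiovol$metric == "SPIO_Vol_pct", ])
  missing_animals <- setdiff(unique(tab$animal_id), cohort$animal_id)
  if (length(missing_animals))
    stop("animals in the measurement tables but not in the cohort: ",
         paste(missing_animals, collapse = ", "))
  tab$group <- cohort$group[match(tab$animal_id, cohort$animal_id)]
  tab$cs <- cohort$cs[match(tab$animal_id, cohort$animal_id)]

  rows <- list(); crows <- list()
  for (metric in unique(tab$metric)) {
    for (region in unique(tab$region[tab$metric == metric])) {
      d <- tab[tab$metric == metric & tab$region == region, ]
      eae <- d$value[d$group == "EAE"]
      ctr <- d$value[d$group == "CTR"]
      mw <- if (length(eae) && length(ctr)) mann_whitney(eae, ctr) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, region = region,
        n_eae = length(eae), n_ctr = length(ctr),
        mean_eae = if (length(eae)) mean(eae) else NA_real_,
        sd_eae = if (length(eae) > 1) stats::sd(eae) else NA_real_,
        mean_ctr = if (length(ctr)) mean(ctr) else NA_real_,
        sd_ctr = if (length(ctr) > 1) stats::sd(ctr) else NA_real_,
        U = if (is.null(mw)) NA_real_ else mw$statistic,
        p_value = if (is.null(mw)) NA_real_ else mw$p_value,
        method = if (is.null(mw)) NA_character_ else mw$method)
      if (nrow(d) >= 3) {
        sp <- spearman_rank(d$value, d$cs)
        crows[[length(crows) + 1L]] <- data.frame(
          comparison = "vs_CS", metric = metric, region = region,
          rho = sp$statistic, p_value = sp$p_value, n = sp$n)
      }
    }
  }
  # SUVR vs SPIO-Vol, matched by animal within each region
  sv <- tab[tab$metric == "SUVR", ]
  sp_ <- tab[tab$metric == "SPIO_Vol_pct", ]
  for (region in intersect(unique(sv$region), unique(sp_$region))) {
    a <- sv[sv$region == region, ]
    b <- sp_[sp_$region == region, ]
    ids <- intersect(a$animal_id, b$animal_id)
    if (length(ids) >= 3) {
      r <- spearman_rank(a$value[match(ids, a$animal_id)],
                         b$value[match(ids, b$animal_id)])
      crows[[length(crows) + 1L]] <- data.frame(
        comparison = "SUVR_vs_SPIO", metric = "SUVR~SPIO_Vol_pct",
        region = region, rho = r$statistic, p_value = r$p_value, n = r$n)
    }
  }
  group_stats <- do.call(rbind, rows)
  if (holm)
    for (metric in unique(group_stats$metric)) {
      i <- group_stats$metric == metric
      group_stats$p_value[i] <- stats::p.adjust(group_stats$p_value[i], "holm")
    }
  group_stats$significant <- !is.na(group_stats$p_value) &
    group_stats$p_value < alpha
  correlations <- if (length(crows)) do.call(rbind, crows) else
    data.frame(comparison = character(), metric = character(),
               region = character(), rho = numeric(), p_value = numeric(),
               n = integer())
  structure(list(group_stats = group_stats, correlations = correlations,
                 alpha = alpha),
            class = "results_report")
}

#' @export
print.results_report <- function(x, ...) {
  cat("<results_report> group contrasts (alpha =", x$alpha, "):\n")
  print(x$group_stats[, c("metric", "region", "mean_eae", "sd_eae",
                          "mean_ctr", "sd_ctr", "p_value", "significant")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a results report to CSV and a markdown summary
#'
#' @param report a `results_report` from [build_results()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "group_stats.csv")
  p2 <- file.path(dir, "correlations.csv")
  p3 <- file.path(dir, "summary.md")
  utils::write.csv(report$group_stats, p1, row.names = FALSE)
  utils::write.csv(report$correlations, p2, row.names = FALSE)
  gs <- report$group_stats
  lines <- c("# Per-region results", "",
             sprintf("Significance threshold: p < %g (uncorrected unless noted).",
                     report$alpha), "",
             "| metric | region | EAE mean ± SD | CTR mean ± SD | p | sig |",
             "|---|---|---|---|---|---|",
             sprintf("| %s | %s | %.2f ± %.2f | %.2f ± %.2f | %.4f | %s |",
                     gs$metric, gs$region, gs$mean_eae, gs$sd_eae,
                     gs$mean_ctr, gs$sd_ctr, gs$p_value,
                     ifelse(gs$significant, "*", "")))
  cr <- report$correlations
  if (nrow(cr))
    lines <- c(lines, "", "## Pooled Spearman correlations", "",
               "| comparison | region | rho | p |", "|---|---|---|---|",
               sprintf("| %s | %s | %.3f | %.4f |", cr$comparison, cr$region,
                       cr$rho, cr$p_value))
  writeLines(lines, p3)
  invisible(c(p1, p2, p3))
}
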