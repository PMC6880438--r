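#' Identity-by-state similarity between a target and every panel sample
#'
#' Similarity is `1 - mean(|d_target - g_panel|) / 2` over the comparison
#' sites at which the target has data, where `d_target` is the target's
#' expected alternate-allele dosage and `g_panel` the panel sample's
#' genotype. Values lie in `[0, 1]`; 1 means identical, 0 maximal allele
#' distance at every site.
#'
#' @param target_dosages Numeric vector over all panel sites with the
#'   target's expected dosages (`NA` where the target has no data). With
#'   low-coverage data these are genotype-likelihood posterior means under
#'   a uniform prior.
#' @param panel A `haplotype_panel`.
#' @param comparison_sites Integer site indices to compare at (e.g. the
#'   target's densest-covered decile, standing in for regions consistently
#'   sequenced at high depth).
#' @return Named numeric vector of similarities, one per panel sample.
#' @export
ibs_similarity <- function(target_dosages, panel, comparison_sites) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (length(comparison_sites) == 0L) stop("`comparison_sites` is empty")
  d <- target_dosages[comparison_sites]
  avail <- !is.na(d)
  if (mean(avail) < 0.5)
    stop(sprintf(paste0("target has data at only %.0f%% of the %d comparison ",
                        "sites (>= 50%% required)"),
                 100 * mean(avail), length(comparison_sites)))
  use <- comparison_sites[avail]
  d <- d[avail]
  G <- haps_to_genotypes(panel$haplotypes[, use, drop = FALSE])
  sim <- 1 - colMeans(abs(t(G) - d)) / 2
  stats::setNames(as.numeric(sim), panel$sample_ids)
}

# default comparison sites: the densest-covered decile of sites for this
# sample (ties broken by site order)
densest_decile <- function(depth) {
  n <- length(depth)
  k <- max(1L, floor(n / 10))
  order(depth, seq_len(n), decreasing = TRUE)[seq_len(k)]
}

#' Select a per-sample custom reference panel by IBS similarity
#'
#' Picks the `panel_size` most similar eligible panel samples. The target
#' itself (if present in the panel) and every sample in its pedigree set of
#' first/second-degree relatives are never selected, regardless of
#' similarity. Ties are broken by lexicographic sample id so selection is
#' invariant to panel ordering.
#'
#' @param similarities Named similarity vector from [ibs_similarity()].
#' @param panel A `haplotype_panel`.
#' @param target_id Sample id of the target.
#' @param panel_size Number of samples to select (default 250, the
#'   accuracy/run-time sweet spot for custom panels).
#' @param exclude Additional sample ids to exclude (e.g. known relatives of
#'   a target that is not itself a panel member).
#' @return A `custom_panel`: list with `target`, `selected` (ordered ids),
#'   `similarity` (aligned to `selected`), `panel_size`.
#' @export
select_custom_panel <- function(similarities, panel, target_id,
                                panel_size = 250L, exclude = character(0)) {
  stopifnot(inherits(panel, "haplotype_panel"))
  stop_if_not_scalar(panel_size, "panel_size", lower = 1)
  ped <- unlist(panel$pedigree[intersect(target_id, names(panel$pedigree))],
                use.names = FALSE)
  # pedigree is symmetric: also exclude panel samples listing the target
  ped2 <- names(Filter(function(v) target_id %in% v, panel$pedigree))
  banned <- unique(c(target_id, ped, ped2, exclude))
  eligible <- setdiff(names(similarities), banned)
  if (length(eligible) == 0L) stop("no eligible panel samples after exclusions")
  s <- similarities[eligible]
  ord <- order(-s, eligible)
  take <- ord[seq_len(min(panel_size, length(eligible)))]
  structure(list(target = target_id, selected = eligible[take],
                 similarity = as.numeric(s[take]),
                 panel_size = as.integer(panel_size)),
            class = "custom_panel")
}

#' Write a custom-panel selection report
#'
#' Tab-separated columns `target panel_sample rank similarity`.
#'
#' @param custom A `custom_panel`.
#' @param path Output path.
#' @export
write_selection_report <- function(custom, path) {
  df <- data.frame(target = custom$target, panel_sample = custom$selected,
                   rank = seq_along(custom$selected),
                   similarity = sprintf("%.6f", custom$similarity))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
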