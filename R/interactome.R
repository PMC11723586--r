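#' Ligand-receptor pair lineage specificity and age disruption
#'
#' Calls lineage-specific ligand-receptor pairs (LRPs) from young-cohort
#' lineage DE and detects pairs disrupted in the older cohort when a
#' lineage-specific member no longer passes the specificity thresholds.
#'
#' @name interactome
NULL

#' Read a ligand-receptor pair table
#'
#' Two-column tab-separated file (ligand, receptor) with a header row.
#' Rows with missing symbols are skipped (with a message); duplicated
#' pairs are removed; symbols are upper-cased.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `ligand` and `receptor`.
#' @export
load_lrp_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("LRP table needs two columns (ligand, receptor)")
  tab <- data.frame(ligand = toupper(trimws(raw[[1]])),
                    receptor = toupper(trimws(raw[[2]])),
                    stringsAsFactors = FALSE)
  bad <- tab$ligand == "" | tab$receptor == "" | is.na(tab$ligand) |
    is.na(tab$receptor)
  if (any(bad)) message(sum(bad), " malformed LRP rows skipped")
  tab <- tab[!bad, , drop = FALSE]
  tab <- unique(tab)
  if (!nrow(tab)) warning("LRP table is empty")
  rownames(tab) <- NULL
  tab
}

#' Write a ligand-receptor pair table
#'
#' @param lrp Data frame with `ligand` and `receptor` columns.
#' @param path Output TSV path.
#' @export
write_lrp_table <- function(lrp, path) {
  utils::write.table(lrp[, c("ligand", "receptor")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

# Lineages in which a gene is taken to be expressed: a lineage-specific
# gene only in its own lineage, a non-specific gene in both.
expressed_in <- function(spec) {
  switch(spec, LEP = "LEP", MEP = "MEP", c("LEP", "MEP"))
}

#' Call lineage-specific ligand-receptor pairs
#'
#' A pair is lineage-specific when its ligand and/or receptor is LEP- or
#' MEP-specific in the young cohort (adj p < `p_thr`, |lfc| >= `lfc_thr`).
#' Signalling channels (source lineage of the ligand crossed with target
#' lineage of the receptor) are enumerated from the specificity-based
#' expression rule.  Pairs whose genes are absent from the DE universe are
#' dropped and counted.
#'
#' @param lrp LRP table ([load_lrp_table()]).
#' @param de_young Young-cohort MEP-vs-LEP `DEResult`.
#' @param p_thr,lfc_thr Specificity thresholds (defaults 0.001 and 1).
#' @return Data frame per retained pair: ligand, receptor, ligand_spec,
#'   receptor_spec, lineage_specific, channels (comma-joined
#'   "src>tgt" strings); attribute `n_dropped` counts pairs with genes
#'   missing from the universe.
#' @export
call_lineage_lrps <- function(lrp, de_young, p_thr = 0.001, lfc_thr = 1) {
  spec <- classify_specificity(de_young, p_thr, lfc_thr)
  present <- lrp$ligand %in% names(spec) & lrp$receptor %in% names(spec)
  dropped <- sum(!present)
  lrp <- lrp[present, , drop = FALSE]
  ls <- unname(spec[lrp$ligand])
  rs <- unname(spec[lrp$receptor])
  channels <- mapply(function(a, b) {
    paste(as.vector(outer(expressed_in(a), expressed_in(b), paste,
                          sep = ">")), collapse = ",")
  }, ls, rs)
  out <- data.frame(
    ligand = lrp$ligand, receptor = lrp$receptor,
    ligand_spec = ls, receptor_spec = rs,
    lineage_specific = ls != "none" | rs != "none",
    channels = unname(channels),
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- dropped
  attr(out, "thresholds") <- c(p_thr = p_thr, lfc_thr = lfc_thr)
  out
}

#' Find age-disrupted ligand-receptor pairs
#'
#' Re-evaluates every lineage-specific member of each pair against the
#' old-cohort thresholds; a pair is disrupted when any specific member no
#' longer passes (reason: ligand_lost, receptor_lost or both_lost).
#'
#' @param calls Output of [call_lineage_lrps()].
#' @param de_old Old-cohort MEP-vs-LEP `DEResult`.
#' @param p_thr,lfc_thr Old-cohort thresholds (defaults 0.001 and 1).
#' @return `calls` with `disrupted` (logical) and `reason` columns added.
#' @export
find_disrupted_lrps <- function(calls, de_old, p_thr = 0.001, lfc_thr = 1) {
  spec_old <- classify_specificity(de_old, p_thr, lfc_thr)
  member_lost <- function(gene, spec) {
    spec != "none" & unname(spec_old[gene]) != spec
  }
  lig_lost <- member_lost(calls$ligand, calls$ligand_spec)
  rec_lost <- member_lost(calls$receptor, calls$receptor_spec)
  disrupted <- calls$lineage_specific & (lig_lost | rec_lost)
  reason <- rep(NA_character_, nrow(calls))
  reason[disrupted & lig_lost & !rec_lost] <- "ligand_lost"
  reason[disrupted & rec_lost & !lig_lost] <- "receptor_lost"
  reason[disrupted & lig_lost & rec_lost] <- "both_lost"
  calls$disrupted <- disrupted
  calls$reason <- reason
  calls
}
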