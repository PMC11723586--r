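#' Lineage-fidelity strata and attribution framework
#'
#' Lineage-specificity calls per age cohort, transition strata
#' (maintained / lost / gained), fold-change-distribution shift statistics,
#' attribution of fidelity loss to directional (DE) versus variance (DV)
#' mechanisms, and direction-of-change summaries.
#'
#' @name fidelity
NULL

#' Lineage-specificity call from a lineage contrast
#'
#' MEP-specific when adj p < `p_thr` and lfc >= `lfc_thr`; LEP-specific
#' when adj p < `p_thr` and lfc <= -`lfc_thr`; otherwise none.
#'
#' @param de `DEResult` from a MEP-vs-LEP contrast.
#' @param p_thr Adjusted p-value threshold (default 0.001).
#' @param lfc_thr Absolute log2 fold-change threshold (default 1).
#' @return Character vector (`"LEP"`, `"MEP"` or `"none"`) named by gene.
#' @export
classify_specificity <- function(de, p_thr = 0.001, lfc_thr = 1) {
  ctr <- attr(de, "contrast")
  if (!is.null(ctr) && !grepl("^MEPvsLEP", ctr) && ctr != "custom") {
    stop("specificity calls require a MEP-vs-LEP contrast")
  }
  call <- rep("none", nrow(de))
  sig <- !is.na(de$adj_p) & de$adj_p < p_thr
  call[sig & de$lfc >= lfc_thr] <- "MEP"
  call[sig & de$lfc <= -lfc_thr] <- "LEP"
  stats::setNames(call, de$gene)
}

#' Strata of lineage-specificity transitions across age
#'
#' Combines young- and old-cohort specificity calls into per-gene
#' transition labels: maintained (same non-none call in both cohorts),
#' lost (young call, none in old), gained (none in young, old call),
#' none otherwise.  A switch of lineage (LEP young, MEP old) is labelled
#' lost-and-gained as `"switched"` and counted with lost.
#'
#' @param de_young,de_old `DEResult`s for the MEP-vs-LEP contrast per
#'   cohort (shared gene universe; mismatches are intersected with a
#'   warning).
#' @param p_thr,lfc_thr Thresholds passed to [classify_specificity()].
#' @return List: `table` (gene, specificity_young, specificity_old,
#'   transition, lfc_young, lfc_old) and `counts` (named integer vector:
#'   maintained, lost, gained, none, plus young_lep / young_mep shares).
#' @export
build_strata <- function(de_young, de_old, p_thr = 0.001, lfc_thr = 1) {
  genes <- intersect(de_young$gene, de_old$gene)
  if (length(genes) < max(nrow(de_young), nrow(de_old))) {
    warning("gene universes differ; intersecting")
  }
  dy <- de_young[match(genes, de_young$gene), ]
  do <- de_old[match(genes, de_old$gene), ]
  sy <- classify_specificity(dy, p_thr, lfc_thr)
  so <- classify_specificity(do, p_thr, lfc_thr)
  transition <- ifelse(sy != "none" & so == sy, "maintained",
                ifelse(sy != "none" & so == "none", "lost",
                ifelse(sy == "none" & so != "none", "gained",
                ifelse(sy != "none" & so != "none", "switched", "none"))))
  tab <- data.frame(gene = genes, specificity_young = unname(sy),
                    specificity_old = unname(so), transition = transition,
                    lfc_young = dy$lfc, lfc_old = do$lfc,
                    row.names = genes, stringsAsFactors = FALSE)
  young_spec <- sum(sy != "none")
  counts <- c(maintained = sum(transition == "maintained"),
              lost = sum(transition %in% c("lost", "switched")),
              gained = sum(transition == "gained"),
              none = sum(transition == "none"),
              young_specific = young_spec,
              old_specific = sum(so != "none"),
              young_lep = sum(sy == "LEP"),
              young_mep = sum(sy == "MEP"))
  list(table = tab, counts = counts)
}

#' Fold-change-shift statistics between cohorts
#'
#' Over a specificity class of genes, compares the young and old
#' lineage-lfc distributions (two-sample KS), reports the fraction of
#' genes whose |lfc| is larger in young, and a one-sided paired t-test
#' that mean(|lfc_young| - |lfc_old|) > 0.
#'
#' @param de_young,de_old Lineage `DEResult`s on a shared universe.
#' @param gene_subset Genes to analyse (e.g. one specificity class).
#' @param strata Optional [build_strata()] output; when supplied with
#'   `maintained_only = TRUE`, restricts to genes whose specificity is
#'   maintained with age.
#' @param maintained_only Restrict to maintained genes (default FALSE).
#' @return List: `ks` (test result or NULL), `frac_larger_young`,
#'   `t_p` (one-sided paired t p-value or NA), `n`.
#' @export
lfc_shift_report <- function(de_young, de_old, gene_subset,
                             strata = NULL, maintained_only = FALSE) {
  genes <- intersect(gene_subset, intersect(de_young$gene, de_old$gene))
  if (maintained_only) {
    if (is.null(strata)) stop("maintained_only requires a strata table")
    keep <- strata$table$gene[strata$table$transition == "maintained"]
    genes <- intersect(genes, keep)
  }
  if (!length(genes)) stop("empty gene subset")
  ly <- de_young$lfc[match(genes, de_young$gene)]
  lo <- de_old$lfc[match(genes, de_old$gene)]
  frac <- mean(abs(ly) > abs(lo))
  if (length(genes) < 3L) {
    message("fewer than 3 genes in subset; KS and t statistics skipped")
    return(list(ks = NULL, frac_larger_young = frac, t_p = NA_real_,
                n = length(genes)))
  }
  ks <- ks_two_sample(ly, lo)
  d <- abs(ly) - abs(lo)
  t_p <- if (stats::sd(d) == 0) {
    if (mean(d) > 0) 0 else 1
  } else {
    stats::t.test(d, mu = 0, alternative = "greater")$p.value
  }
  list(ks = ks, frac_larger_young = frac, t_p = t_p, n = length(genes))
}

#' Attribution of fidelity loss to directional and variance mechanisms
#'
#' Over the lost-gene stratum: `via_sig_DE` is the fraction with
#' significant age DE (adj p < `p_sig`) in either lineage; `via_2fold_DE`
#' the fraction with |age lfc| >= log2(`de_fold`) in either lineage
#' (magnitude-only by default; `require_nominal_p` additionally asks for
#' nominal p < `p_sig`); `via_2fold_DV` the fraction with a between-subject
#' variance fold >= `dv_fold` in either lineage; `overlap` the fraction
#' meeting both two-fold criteria, and `unexplained` the remainder.
#'
#' @param strata [build_strata()] output.
#' @param de_age_lep,de_age_mep Age (old vs young) `DEResult`s per lineage.
#' @param varratio_lep,varratio_mep [variance_ratio()] outputs per lineage.
#' @param p_sig Significance threshold for age DE (default 0.05).
#' @param de_fold,dv_fold Fold thresholds (default 2).
#' @param require_nominal_p Also require nominal age-DE p < `p_sig` for the
#'   two-fold DE criterion (default FALSE).
#' @return List of attribution fractions plus `n_lost`; fractions are NA
#'   when no genes were lost.
#' @export
attribute_loss <- function(strata, de_age_lep, de_age_mep,
                           varratio_lep, varratio_mep,
                           p_sig = 0.05, de_fold = 2, dv_fold = 2,
                           require_nominal_p = FALSE) {
  lost <- strata$table$gene[strata$table$transition %in% c("lost", "switched")]
  if (!length(lost)) {
    return(list(n_lost = 0L, via_sig_DE = NA_real_, via_2fold_DE = NA_real_,
                via_2fold_DV = NA_real_, overlap = NA_real_,
                unexplained = NA_real_))
  }
  pick <- function(tab, col) tab[[col]][match(lost, tab$gene)]
  sig_de <- (pick(de_age_lep, "adj_p") < p_sig) %in% TRUE |
            (pick(de_age_mep, "adj_p") < p_sig) %in% TRUE
  de_lep_hit <- (abs(pick(de_age_lep, "lfc")) >= log2(de_fold)) %in% TRUE
  de_mep_hit <- (abs(pick(de_age_mep, "lfc")) >= log2(de_fold)) %in% TRUE
  if (require_nominal_p) {
    de_lep_hit <- de_lep_hit & (pick(de_age_lep, "p") < p_sig) %in% TRUE
    de_mep_hit <- de_mep_hit & (pick(de_age_mep, "p") < p_sig) %in% TRUE
  }
  fold_de <- de_lep_hit | de_mep_hit
  fold_dv <- (pick(varratio_lep, "fold") >= dv_fold) %in% TRUE |
             (pick(varratio_mep, "fold") >= dv_fold) %in% TRUE
  list(n_lost = length(lost),
       via_sig_DE = mean(sig_de),
       via_2fold_DE = mean(fold_de),
       via_2fold_DV = mean(fold_dv),
       overlap = mean(fold_de & fold_dv),
       unexplained = mean(!fold_de & !fold_dv))
}

#' Direction of age-dependent change relative to the opposite lineage
#'
#' Among significant age-DE genes of one lineage, counts up/down changes
#' and the fraction moving toward the opposite lineage's expression level:
#' for LEP, sign(age lfc) = sign(young MEP-LEP lfc); for MEP, the opposite
#' sign.
#'
#' @param de_age Age `DEResult` for one lineage (old vs young).
#' @param de_lineage_young Young-cohort MEP-vs-LEP `DEResult`.
#' @param lineage `"LEP"` or `"MEP"` (defaults from the contrast
#'   descriptor when available).
#' @param p_sig Adjusted-p threshold for age DE (default 0.05).
#' @return List: `n_up`, `n_down`, `frac_toward_opposite` (NA when no
#'   significant genes).
#' @export
direction_summary <- function(de_age, de_lineage_young,
                              lineage = NULL, p_sig = 0.05) {
  if (is.null(lineage)) {
    ctr <- attr(de_age, "contrast")
    lineage <- if (!is.null(ctr) && grepl("MEP$", ctr)) "MEP" else "LEP"
  }
  sig <- !is.na(de_age$adj_p) & de_age$adj_p < p_sig
  if (!any(sig)) {
    return(list(n_up = 0L, n_down = 0L, frac_toward_opposite = NA_real_))
  }
  genes <- de_age$gene[sig]
  dl <- de_age$lfc[sig]
  bl <- de_lineage_young$lfc[match(genes, de_lineage_young$gene)]
  toward <- if (lineage == "LEP") sign(dl) == sign(bl) else sign(dl) == -sign(bl)
  list(n_up = sum(dl > 0), n_down = sum(dl < 0),
       frac_toward_opposite = mean(toward, na.rm = TRUE))
}
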