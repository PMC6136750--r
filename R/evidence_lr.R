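#' The seven evidence categories
#'
#' FAA (frequency/association), COC (co-occurrence), CSG (co-segregation),
#' FHX (personal/family history), FUN (functional validation, including
#' mutational hotspot), STR (structural) and OTH (other supporting
#' evidence).
#'
#' @return Character vector of length 7.
#' @export
evidence_categories <- function() {
  c("FAA", "COC", "CSG", "FHX", "FUN", "STR", "OTH")
}

#' Qualitative evidence levels and their (p_cut, p_frac) parameters
#'
#' Seven graded effect levels. `p_cut` is the target-class probability
#' threshold the evidence points at (0.99 pathogenic, 0.95 likely
#' pathogenic, 0.05 likely benign, 0.001 benign) and `p_frac` the fraction
#' of the required evidence a single item supplies (1, 1/4 or 1/2),
#' mirroring "one item of P-1 or four items of P-4" style grading.
#'
#' @return data.frame with columns `level`, `p_cut`, `p_frac`, `lr`.
#' @export
evidence_level_map <- function() {
  m <- data.frame(
    level  = c("P-1", "P-4", "LP-1", "LP-4", "LB-1", "LB-2", "B-1"),
    p_cut  = c(0.99, 0.99, 0.95, 0.95, 0.05, 0.05, 0.001),
    p_frac = c(1, 0.25, 1, 0.25, 1, 0.5, 1),
    stringsAsFactors = FALSE
  )
  m$lr <- qualitative_lr(m$p_cut, m$p_frac)
  m
}

#' Likelihood ratio of a qualitative evidence item
#'
#' Under a null probability of 0.5 an item pointing at target-class
#' probability `p_cut` with evidence fraction `p_frac` carries
#' `LR = (p_cut / (1 - p_cut)) ^ p_frac`.
#'
#' @param p_cut Threshold probability in (0, 1).
#' @param p_frac Evidence fraction in (0, 1\].
#' @return Positive likelihood ratio(s).
#' @examples
#' qualitative_lr(0.99, 1)     # 99
#' qualitative_lr(0.05, 0.5)   # 0.2294
#' @export
qualitative_lr <- function(p_cut, p_frac) {
  if (any(!is.finite(p_cut)) || any(p_cut <= 0) || any(p_cut >= 1))
    stop("p_cut must lie strictly in (0, 1)")
  if (any(!is.finite(p_frac)) || any(p_frac <= 0) || any(p_frac > 1))
    stop("p_frac must lie in (0, 1]")
  (p_cut / (1 - p_cut))^p_frac
}

#' Likelihood ratio of a graded evidence level code
#'
#' @param level Character vector of level codes (`P-1`, `P-4`, `LP-1`,
#'   `LP-4`, `LB-1`, `LB-2`, `B-1`).
#' @param map Level map, see [evidence_level_map()]; override to change
#'   the grading calibration.
#' @return Numeric likelihood ratio(s).
#' @examples
#' level_lr("LP-4")  # 19^0.25 = 2.0878
#' @export
level_lr <- function(level, map = evidence_level_map()) {
  i <- match(level, map$level)
  if (anyNA(i))
    stop("unknown evidence level code(s): ",
         paste(unique(level[is.na(i)]), collapse = ", "))
  qualitative_lr(map$p_cut[i], map$p_frac[i])
}

#' Combine two correlated likelihood ratios
#'
#' Two LR statistics from correlated sources within one evidence category
#' are not multiplied naively: if both point the same way the stronger one
#' is kept (`max` if both > 1, `min` if both < 1); only when they point in
#' different directions (or either is neutral) is the product taken.
#'
#' @param lr1,lr2 Positive likelihood ratios (vectorised).
#' @return Combined likelihood ratio(s).
#' @export
combine_correlated_lr <- function(lr1, lr2) {
  if (any(!is.finite(lr1)) || any(!is.finite(lr2)) ||
      any(lr1 <= 0) || any(lr2 <= 0))
    stop("likelihood ratios must be positive and finite")
  out <- lr1 * lr2
  both_up <- lr1 > 1 & lr2 > 1
  both_dn <- lr1 < 1 & lr2 < 1
  out[both_up] <- pmax(lr1, lr2)[both_up]
  out[both_dn] <- pmin(lr1, lr2)[both_dn]
  out
}

#' Build an evidence profile
#'
#' An evidence profile is a named numeric vector over the 7 categories;
#' missing evidence is the neutral `LR = 1`.
#'
#' @param ... Named category values, e.g. `FAA = 19, FUN = 3.15`.
#' @return Named numeric vector of length 7 with class `evidence_profile`.
#' @export
evidence_profile <- function(...) {
  vals <- c(...)
  prof <- setNames(rep(1, 7), evidence_categories())
  if (length(vals)) {
    bad <- setdiff(names(vals), evidence_categories())
    if (length(bad)) stop("unknown evidence categories: ", paste(bad, collapse = ", "))
    if (any(!is.finite(vals)) || any(vals <= 0))
      stop("likelihood ratios must be positive and finite")
    prof[names(vals)] <- vals
  }
  structure(prof, class = "evidence_profile")
}

#' Total likelihood ratio of an evidence profile
#'
#' Product of the 7 category LRs under the assumption that the categories
#' are statistically independent. A profile with every category at the
#' missing-evidence value 1 returns 1 with attribute `no_evidence = TRUE`.
#'
#' @param profile Named numeric vector over the 7 categories (extra to
#'   the [evidence_profile()] class is tolerated).
#' @return Positive scalar with attribute `no_evidence`.
#' @export
total_lr <- function(profile) {
  prof <- unclass(profile)
  if (!all(evidence_categories() %in% names(prof)))
    stop("profile must carry all 7 evidence categories")
  prof <- prof[evidence_categories()]
  if (any(!is.finite(prof)) || any(prof <= 0))
    stop("likelihood ratios must be positive and finite")
  structure(prod(prof), no_evidence = all(prof == 1))
}

#' Mutational hotspot indicator
#'
#' A variant sits in a mutational hotspot when at least one *other*
#' variant of consensus class `pathogenic` occupies the same amino-acid
#' residue of the same gene. Hotspot status feeds the FUN evidence
#' category at a configurable level (default `P-4`).
#'
#' @param panel Variant data.frame with `variant_id`, `gene`, `residue`
#'   and `consensus_class` columns.
#' @return Logical vector along the panel rows; `NA` where the residue is
#'   missing.
#' @export
hotspot_indicator <- function(panel) {
  stopifnot(all(c("variant_id", "gene", "residue", "consensus_class") %in% names(panel)))
  n <- nrow(panel)
  out <- rep(FALSE, n)
  path <- panel$consensus_class == "pathogenic" & !is.na(panel$residue)
  key <- paste(panel$gene, panel$residue)
  for (i in seq_len(n)) {
    if (is.na(panel$residue[i])) { out[i] <- NA; next }
    hit <- path & key == key[i] & panel$variant_id != panel$variant_id[i]
    out[i] <- any(hit)
  }
  out
}

#' Assemble per-variant evidence profiles from a long evidence table
#'
#' The long table carries one evidence item per row: `variant_id`,
#' `category` and either a numeric `lr_value` (auto-computed evidence) or
#' a qualitative `level_code` translated through `map`. Multiple items in
#' the same category for the same variant are treated as correlated and
#' folded left-to-right with [combine_correlated_lr()].
#'
#' @param evidence Long-format data.frame.
#' @param variant_ids Variant identifiers to build profiles for (profiles
#'   default to all-missing evidence, LR = 1).
#' @param map Level map for qualitative codes.
#' @return data.frame with `variant_id` plus the 7 category LR columns.
#' @export
build_evidence_profiles <- function(evidence, variant_ids,
                                    map = evidence_level_map()) {
  prof <- matrix(1, nrow = length(variant_ids), ncol = 7,
                 dimnames = list(NULL, evidence_categories()))
  if (!is.null(evidence) && nrow(evidence)) {
    stopifnot(all(c("variant_id", "category") %in% names(evidence)))
    bad <- setdiff(unique(evidence$category), evidence_categories())
    if (length(bad)) stop("unknown evidence categories: ", paste(bad, collapse = ", "))
    lr <- rep(NA_real_, nrow(evidence))
    if ("lr_value" %in% names(evidence)) lr <- as.numeric(evidence$lr_value)
    if ("level_code" %in% names(evidence)) {
      use_lvl <- is.na(lr) & !is.na(evidence$level_code) & nzchar(evidence$level_code)
      lr[use_lvl] <- level_lr(evidence$level_code[use_lvl], map = map)
    }
    if (anyNA(lr)) stop("evidence rows need either lr_value or level_code")
    keep <- evidence$variant_id %in% variant_ids
    ev <- evidence[keep, , drop = FALSE]
    lr <- lr[keep]
    for (r in seq_len(nrow(ev))) {
      i <- match(ev$variant_id[r], variant_ids)
      j <- match(ev$category[r], evidence_categories())
      prof[i, j] <- combine_correlated_lr(prof[i, j], lr[r])
    }
  }
  data.frame(variant_id = variant_ids, prof, stringsAsFactors = FALSE)
}

#' Add hotspot evidence to assembled profiles
#'
#' Folds a hotspot item (default level `P-4`) into the FUN category of
#' every variant flagged by [hotspot_indicator()].
#'
#' @param profiles Output of [build_evidence_profiles()].
#' @param panel Variant panel used for the hotspot scan.
#' @param level Evidence level the hotspot contributes.
#' @param map Level map.
#' @return Updated profiles data.frame.
#' @export
add_hotspot_evidence <- function(profiles, panel, level = "P-4",
                                 map = evidence_level_map()) {
  hs <- hotspot_indicator(panel)
  lr <- level_lr(level, map = map)
  idx <- match(panel$variant_id[which(hs)], profiles$variant_id)
  idx <- idx[!is.na(idx)]
  profiles$FUN[idx] <- combine_correlated_lr(profiles$FUN[idx], rep(lr, length(idx)))
  profiles
}
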