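# Seven-category rare/abundant taxon classification. Each OTU is placed by
# its minimum and maximum per-sample relative abundance against two cuts:
# rare_cut (default 0.01% = 1e-4) and abundant_cut (default 1% = 1e-2).
#
# Decision tree (boundaries follow the printed inequalities: ">=" at the
# abundant and lower-rare bounds, strict "<" for the rare conditions):
#   max >= abundant_cut:  AAT  if min >= abundant_cut
#                         CAT  if min >= rare_cut
#                         CRAT otherwise
#   max <  abundant_cut:  MT   if min >= rare_cut
#                         ART  if max <  rare_cut
#                         CRT  otherwise
# Coarse roll-up: AT = {AAT, CAT, CRAT, MT}; RT = {ART, CRT}.

ABUNDANCE_CATEGORIES <- c("AAT", "CAT", "CRAT", "MT", "ART", "CRT")
AT_CATEGORIES <- c("AAT", "CAT", "CRAT", "MT")
RT_CATEGORIES <- c("ART", "CRT")

#' Classify one OTU from its min and max relative abundance
#'
#' Categories: AAT (always abundant, >= 1% everywhere), CAT (conditionally
#' abundant, >= 0.01% everywhere and >= 1% somewhere), CRAT (conditionally
#' rare and abundant, spanning < 0.01% and >= 1%), MT (moderate, between
#' 0.01% and 1% everywhere), ART (always rare, < 0.01% everywhere), CRT
#' (conditionally rare, < 1% everywhere and < 0.01% somewhere).
#'
#' @param min_ra,max_ra minimum and maximum relative abundance across
#'   samples, as fractions.
#' @param rare_cut rare threshold (fraction), default 1e-4 (0.01%).
#' @param abundant_cut abundant threshold (fraction), default 1e-2 (1%).
#' @return one of `"AAT"`, `"CAT"`, `"CRAT"`, `"MT"`, `"ART"`, `"CRT"`.
#' @export
#' @examples
#' classify_otu(0.02, 0.05)   # AAT
#' classify_otu(5e-5, 0.005)  # CRT
classify_otu <- function(min_ra, max_ra, rare_cut = 1e-4, abundant_cut = 1e-2) {
  stopifnot(length(min_ra) == 1L, length(max_ra) == 1L)
  if (min_ra > max_ra) stop("min_ra > max_ra")
  if (min_ra < 0 || max_ra > 1) stop("relative abundances must lie in [0, 1]")
  if (max_ra >= abundant_cut) {
    if (min_ra >= abundant_cut) "AAT"
    else if (min_ra >= rare_cut) "CAT"
    else "CRAT"
  } else {
    if (min_ra >= rare_cut) "MT"
    else if (max_ra < rare_cut) "ART"
    else "CRT"
  }
}

#' Classify every OTU of a relative-abundance table
#'
#' Applies [classify_otu()] to each OTU's min/max relative abundance over
#' samples. OTUs absent everywhere (all-zero rows) come out ART (min = max
#' = 0 < rare_cut) and are flagged.
#'
#' @param relabund a [relative_abundance()] object.
#' @inheritParams classify_otu
#' @return object of class `abundance_classification`: data.frame `otus`
#'   with columns `otu_id`, `min_ra`, `max_ra`, `category`, `coarse`
#'   (AT/RT), `all_zero`; `summary` table of per-category counts;
#'   `thresholds`.
#' @export
classify_all <- function(relabund, rare_cut = 1e-4, abundant_cut = 1e-2) {
  stopifnot(inherits(relabund, "rel_abundance"))
  v <- relabund$values
  min_ra <- apply(v, 1, min)
  max_ra <- apply(v, 1, max)
  category <- vapply(seq_along(min_ra), function(i) {
    classify_otu(min_ra[i], max_ra[i], rare_cut, abundant_cut)
  }, character(1))
  category <- factor(category, levels = ABUNDANCE_CATEGORIES)
  coarse <- factor(ifelse(category %in% AT_CATEGORIES, "AT", "RT"),
                   levels = c("AT", "RT"))
  all_zero <- max_ra == 0
  if (any(all_zero)) {
    warning(sprintf("%d all-zero OTUs classified ART", sum(all_zero)))
  }
  otus <- data.frame(
    otu_id = relabund$otu_ids, min_ra = unname(min_ra),
    max_ra = unname(max_ra), category = category, coarse = coarse,
    all_zero = unname(all_zero), stringsAsFactors = FALSE
  )
  structure(
    list(
      otus = otus,
      summary = table(category),
      thresholds = c(rare_cut = rare_cut, abundant_cut = abundant_cut)
    ),
    class = "abundance_classification"
  )
}

#' @export
print.abundance_classification <- function(x, ...) {
  cat("abundance_classification:", nrow(x$otus), "OTUs\n")
  print(x$summary)
  invisible(x)
}

#' Subset a community table by abundance category
#'
#' Restricts the table to OTUs in the requested categories (or coarse
#' classes `"AT"` / `"RT"`). Counts are unchanged; no renormalization
#' happens at this step.
#'
#' @param table a [community_table()].
#' @param classification an [classify_all()] result computed on the same
#'   table.
#' @param classes character vector of categories and/or `"AT"`, `"RT"`.
#' @return the restricted [community_table()].
#' @export
subset_by_class <- function(table, classification, classes) {
  stopifnot(inherits(classification, "abundance_classification"))
  classes <- unique(unlist(lapply(classes, function(cl) {
    switch(cl, AT = AT_CATEGORIES, RT = RT_CATEGORIES, cl)
  })))
  unknown <- setdiff(classes, ABUNDANCE_CATEGORIES)
  if (length(unknown) > 0) {
    stop("unknown classes: ", paste(unknown, collapse = ", "),
         " (valid: ", paste(c(ABUNDANCE_CATEGORIES, "AT", "RT"),
                            collapse = ", "), ")")
  }
  keep <- classification$otus$otu_id[
    classification$otus$category %in% classes
  ]
  keep <- intersect(table$otu_ids, keep)
  if (length(keep) == 0) {
    stop("no OTUs in classes ", paste(classes, collapse = ", "),
         "; try different classes")
  }
  community_table(table$counts[keep, , drop = FALSE],
                  table$sample_groups, table$env)
}
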