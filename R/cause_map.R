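#' Cause map: 20 mutually exclusive NCD cause groups
#'
#' The analysis partitions all NCD deaths into 20 mutually exclusive and
#' collectively exhaustive cause groups: 16 named leading causes (or
#' aetiologically related groups) plus exactly 4 residual groups — other
#' circulatory diseases, other malignant neoplasms, other neuropsychiatric
#' conditions, and other NCDs. A cause map assigns every detailed cause
#' code in the input data to exactly one group, and tags each group with
#' its membership in the SDG target 3.4 cause superset (cancers,
#' cardiovascular diseases, chronic respiratory diseases, diabetes).
#'
#' @param groups a data.frame with columns `group_id` (character), `kind`
#'   (`"named"` or `"residual"`), `sdg` (logical) and a list-column
#'   `codes` of detailed cause codes per group.
#'
#' @return An object of class `cause_map`.
#' @export
cause_map <- function(groups) {
  stopifnot(is.data.frame(groups))
  need <- c("group_id", "kind", "sdg", "codes")
  if (!all(need %in% names(groups))) {
    stop("groups must have columns group_id, kind, sdg, codes")
  }
  if (nrow(groups) != 20L) {
    stop(sprintf("a cause map must have exactly 20 groups, got %d", nrow(groups)))
  }
  if (anyDuplicated(groups$group_id)) stop("duplicate group_id in cause map")
  if (!all(groups$kind %in% c("named", "residual"))) {
    stop("group kind must be 'named' or 'residual'")
  }
  if (sum(groups$kind == "residual") != 4L) {
    stop("a cause map must have exactly 4 residual groups")
  }
  codes <- unlist(groups$codes, use.names = FALSE)
  if (length(codes) == 0L) stop("cause map has no member codes")
  dup <- unique(codes[duplicated(codes)])
  if (length(dup)) {
    stop("cause codes mapped to more than one group: ", paste(dup, collapse = ", "))
  }
  structure(
    list(
      groups = data.frame(
        group_id = as.character(groups$group_id),
        kind = as.character(groups$kind),
        sdg = as.logical(groups$sdg),
        stringsAsFactors = FALSE
      ),
      codes = stats::setNames(
        rep(as.character(groups$group_id), lengths(groups$codes)),
        as.character(codes)
      )
    ),
    class = "cause_map"
  )
}

#' Default 20-group NCD cause map
#'
#' Sixteen named groups — ischaemic heart disease, stroke, ten
#' site-specific cancers, COPD, diabetes (including chronic kidney disease
#' due to diabetes), kidney diseases, liver cirrhosis, Alzheimer disease
#' and other dementias, and alcohol use disorders — plus the four residual
#' groups. The member codes are synthetic placeholders;
#' real analyses supply their own map via [read_cause_map()] because the
#' detailed code assignment is a property of the upstream cause list, not
#' of this package.
#'
#' @return A [cause_map()].
#' @export
default_cause_map <- function() {
  g <- function(id, kind, sdg, codes) {
    data.frame(group_id = id, kind = kind, sdg = sdg,
               codes = I(list(codes)), stringsAsFactors = FALSE)
  }
  groups <- rbind(
    g("ischaemic_heart_disease", "named", TRUE,  c("cvd_ihd")),
    g("stroke",                  "named", TRUE,  c("cvd_stroke_isch", "cvd_stroke_hem")),
    g("lung_cancer",             "named", TRUE,  c("ca_lung")),
    g("stomach_cancer",          "named", TRUE,  c("ca_stomach")),
    g("colorectal_cancer",       "named", TRUE,  c("ca_colon", "ca_rectum")),
    g("breast_cancer",           "named", TRUE,  c("ca_breast")),
    g("cervical_cancer",         "named", TRUE,  c("ca_cervix")),
    g("prostate_cancer",         "named", TRUE,  c("ca_prostate")),
    g("pancreatic_cancer",       "named", TRUE,  c("ca_pancreas")),
    g("liver_cancer",            "named", TRUE,  c("ca_liver")),
    g("copd",                    "named", TRUE,  c("resp_copd")),
    g("diabetes_ckd",            "named", TRUE,  c("dm_diabetes", "dm_ckd_diabetes")),
    g("kidney_diseases",         "named", FALSE, c("gu_kidney")),
    g("liver_cirrhosis",         "named", FALSE, c("dig_cirrhosis")),
    g("alzheimer_dementias",     "named", FALSE, c("neuro_dementia")),
    g("alcohol_use_disorders",   "named", FALSE, c("mental_alcohol")),
    g("other_circulatory",       "residual", TRUE,
      c("cvd_htn_heart", "cvd_cardiomyopathy", "cvd_other")),
    g("other_malignant",         "residual", TRUE,
      c("ca_oesophagus", "ca_lip_oral", "ca_larynx", "ca_lymphoma",
        "ca_myeloma", "ca_leukaemia", "ca_ovary", "ca_other")),
    g("other_neuropsychiatric",  "residual", FALSE,
      c("neuro_parkinson", "neuro_epilepsy", "mental_drug", "neuro_other")),
    g("other_ncd",               "residual", FALSE,
      c("congenital", "endocrine_other", "dig_other", "resp_other",
        "musculo", "skin", "ncd_other"))
  )
  cause_map(groups)
}

#' @export
print.cause_map <- function(x, ...) {
  cat(sprintf("<cause_map> %d groups (%d named, %d residual), %d detailed codes\n",
              nrow(x$groups), sum(x$groups$kind == "named"),
              sum(x$groups$kind == "residual"), length(x$codes)))
  invisible(x)
}

#' Group ids of a cause map
#'
#' @param map a [cause_map()].
#' @param sdg_only if `TRUE`, only groups tagged as part of the SDG 3.4
#'   cause superset.
#' @return Character vector of group ids, in map order.
#' @export
cause_groups <- function(map, sdg_only = FALSE) {
  stopifnot(inherits(map, "cause_map"))
  g <- map$groups
  if (sdg_only) g <- g[g$sdg, , drop = FALSE]
  g$group_id
}

#' Map detailed cause codes to group ids
#'
#' @param map a [cause_map()].
#' @param codes character vector of detailed cause codes.
#' @return Character vector of group ids; unmapped codes are a hard error
#'   naming the offending codes.
#' @export
map_cause_codes <- function(map, codes) {
  stopifnot(inherits(map, "cause_map"))
  codes <- as.character(codes)
  out <- unname(map$codes[codes])
  if (anyNA(out)) {
    bad <- unique(codes[is.na(out)])
    stop("cause codes not present in the cause map: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L) else "")
  }
  out
}

#' Read / write a cause map as YAML
#'
#' The YAML layout is a `groups` list whose entries carry `group_id`,
#' `kind`, `sdg` and `codes`. All [cause_map()] invariants (20 groups,
#' 4 residuals, disjoint codes) are enforced on read.
#'
#' @param path file path.
#' @return [read_cause_map()] returns a [cause_map()];
#'   [write_cause_map()] returns `path` invisibly.
#' @export
read_cause_map <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$groups)) stop("cause map YAML must have a top-level 'groups' list")
  groups <- do.call(rbind, lapply(y$groups, function(e) {
    data.frame(group_id = e$group_id, kind = e$kind, sdg = isTRUE(e$sdg),
               codes = I(list(as.character(unlist(e$codes)))),
               stringsAsFactors = FALSE)
  }))
  cause_map(groups)
}

#' @param map a [cause_map()].
#' @rdname read_cause_map
#' @export
write_cause_map <- function(map, path) {
  stopifnot(inherits(map, "cause_map"))
  entries <- lapply(seq_len(nrow(map$groups)), function(i) {
    id <- map$groups$group_id[i]
    list(group_id = id,
         kind = map$groups$kind[i],
         sdg = map$groups$sdg[i],
         codes = as.list(unname(names(map$codes)[map$codes == id])))
  })
  yaml::write_yaml(list(groups = entries), path)
  invisible(path)
}
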