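#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates (repeated rows per sample x assay) are averaged
#' first. Per sample and target assay, dCt = Ct(target) - Ct(reference);
#' ddCt subtracts the calibrator group's mean dCt for that assay; relative
#' expression is 2^-ddCt. The calibrator group's relative expression has
#' geometric mean 1 by construction.
#'
#' @param table data.frame with columns `sample_id`, `group`, `assay`, `ct`.
#' @param reference_assay internal-control assay id (the U6 role).
#' @param calibrator_group group used as the ddCt baseline (default the
#'   second sorted group label, i.e. the adult-like group "B").
#' @return data.frame: `sample_id`, `group`, `assay`, `dct`, `ddct`,
#'   `rel_expr`.
#' @export
ddct <- function(table, reference_assay = "U6", calibrator_group = NULL) {
  stopifnot(all(c("sample_id", "group", "assay", "ct") %in% names(table)))
  if (any(table$ct <= 0)) stop("Ct values must be positive")
  # average technical replicates
  agg <- stats::aggregate(ct ~ sample_id + group + assay, data = table,
                          FUN = mean)
  ref <- agg[agg$assay == reference_assay, c("sample_id", "ct")]
  tgt <- agg[agg$assay != reference_assay, , drop = FALSE]
  if (nrow(tgt) == 0) stop("no target assay rows found")
  miss <- setdiff(unique(tgt$sample_id), ref$sample_id)
  if (length(miss) > 0)
    stop("missing reference-assay (", reference_assay, ") measurement for ",
         "sample(s): ", paste(miss, collapse = ", "))
  tgt$dct <- tgt$ct - ref$ct[match(tgt$sample_id, ref$sample_id)]
  groups <- sort(unique(tgt$group))
  if (is.null(calibrator_group))
    calibrator_group <- groups[length(groups)]
  if (!calibrator_group %in% groups) stop("calibrator group not in the table")
  out <- do.call(rbind, lapply(split(tgt, tgt$assay), function(d) {
    cal <- mean(d$dct[d$group == calibrator_group])
    d$ddct <- d$dct - cal
    d$rel_expr <- 2^(-d$ddct)
    d
  }))
  rownames(out) <- NULL
  out[, c("sample_id", "group", "assay", "dct", "ddct", "rel_expr")]
}

#' Normality-screened two-group comparison of relative expression
#'
#' Shapiro-Wilk normality is tested per group (P > 0.05 read as normal).
#' When both groups pass, the groups are compared by a two-sided Welch
#' t-test. When a group fails and both groups have n >= 4, a two-sided
#' Wilcoxon rank-sum test is used instead. At n = 3 per group an exact rank
#' test cannot reach P < 0.05 at all (its smallest two-sided p is 0.1), so
#' with any group of size 3 the Welch t-test is used regardless and the
#' method is reported as `"welch_t_nonnormal"` — the normality screen is
#' then advisory. Relative expression is usually compared on the log2 scale
#' (pass `log2(rel_expr)`), where qPCR noise is closest to Gaussian.
#' Significance is flagged at P < 0.05.
#'
#' @param rel_expr numeric vector of (optionally log-transformed) relative
#'   expression values.
#' @param groups character vector of group labels (two groups, >= 3 each —
#'   Shapiro-Wilk needs n >= 3).
#' @return List: `normality_p` (named per group), `method` ("welch_t",
#'   "wilcoxon", "welch_t_nonnormal" or "degenerate"), `p`, `significant`.
#' @export
group_compare <- function(rel_expr, groups) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups are required")
  xs <- split(rel_expr, factor(groups, levels = lev))
  if (any(vapply(xs, length, 1L) < 3L))
    stop("Shapiro-Wilk needs >= 3 values per group")
  norm_p <- vapply(xs, function(x) {
    if (length(unique(x)) == 1L) return(0)  # degenerate: treat as non-normal
    shapiro.test(x)$p.value
  }, numeric(1))
  if (length(unique(rel_expr)) == 1L) {
    # all values identical in both groups: no evidence of any difference
    return(list(normality_p = norm_p, method = "degenerate", p = 1,
                significant = FALSE))
  }
  if (all(norm_p > 0.05)) {
    method <- "welch_t"
    p <- t.test(xs[[1]], xs[[2]], var.equal = FALSE)$p.value
  } else if (all(vapply(xs, length, 1L) >= 4L)) {
    method <- "wilcoxon"
    p <- wilcox.test(xs[[1]], xs[[2]], exact = FALSE)$p.value
  } else {
    method <- "welch_t_nonnormal"
    p <- t.test(xs[[1]], xs[[2]], var.equal = FALSE)$p.value
  }
  list(normality_p = norm_p, method = method, p = p, significant = p < 0.05)
}
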