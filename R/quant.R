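# ---------------------------------------------------------------------------
# Quantification: total-spectra normalization, differential expression,
# volcano table, spectra-per-kDa abundance index, ddCt helper
# ---------------------------------------------------------------------------

#' Normalize spectral counts to the mean sample total
#'
#' Each count is multiplied by the ratio of the average per-sample total
#' spectrum count to the total of its own sample:
#' `n_ij = s_ij * mean_j(S_j) / S_j`. Afterwards every sample's column
#' total equals the mean raw total, removing library-size differences
#' while keeping the overall scale of the experiment.
#'
#' @param x a [spectral_count_table()].
#' @return object of class `normalized_table`: list with `values` (numeric
#'   matrix, same dimnames as the counts), `groups`, `unique_peptides`,
#'   `sample_totals` and `mean_total`.
#' @export
normalize_spectra <- function(x) {
  stopifnot(inherits(x, "spectral_count_table"))
  totals <- colSums(x$counts)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0)
    stop("sample(s) with zero total spectra: ", paste(zero, collapse = ", "))
  mean_total <- mean(totals)
  values <- sweep(x$counts, 2, mean_total / totals, `*`)
  structure(list(values = values, groups = x$groups,
                 unique_peptides = x$unique_peptides,
                 sample_totals = totals, mean_total = mean_total),
            class = "normalized_table")
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("normalized_table: %d proteins x %d samples (mean total %.1f)\n",
              nrow(x$values), ncol(x$values), x$mean_total))
  invisible(x)
}

# vectorized pooled-variance (or Welch) two-sided t-test over matrix rows
.row_ttest <- function(a, b, var_equal = TRUE) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, var); v2 <- apply(b, 1, var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- (m2 - m1) / se
  p <- 2 * pt(-abs(t_stat), df)
  list(t = t_stat, p = p, df = df, mean1 = m1, mean2 = m2, se = se)
}

#' Per-protein differential expression by unpaired two-tailed t-test
#'
#' Runs an unpaired two-tailed t-test (pooled-variance Student by default;
#' Welch via `var_equal = FALSE`) on the normalized spectra of every
#' protein, case group versus control group. The fold change is computed
#' on group means with a pseudocount: `FC = (mean_case + eps) /
#' (mean_control + eps)`. Proteins are flagged by the inclusion filter
#' (at least two unique peptides in some sample); filtered-out proteins
#' carry `NA` p-values. Proteins whose two groups are constant and equal
#' are flagged degenerate and reported with p = 1. A Benjamini-Hochberg
#' column over the filter-passing tests is attached for information only;
#' significance tiers follow the raw p-value at 0.05 and 0.01 (boundary
#' inclusive).
#'
#' @param norm a `normalized_table` from [normalize_spectra()].
#' @param case,control group labels; the fold change is case over control.
#' @param eps pseudocount added to both group means (must be >= 0).
#' @param var_equal pooled-variance Student t when `TRUE` (default), Welch
#'   when `FALSE`.
#' @return data.frame of class `differential_result` with columns
#'   accession, mean_control, mean_case, fold_change, log2_fc, t_stat,
#'   p_value, p_adjust_bh, passed_filter, degenerate, tier.
#' @export
differential_expression <- function(norm, case = "injured",
                                    control = "control", eps = 0.5,
                                    var_equal = TRUE) {
  stopifnot(inherits(norm, "normalized_table"))
  if (eps < 0) stop("eps must be non-negative")
  grp <- norm$groups
  if (!all(c(case, control) %in% grp))
    stop("groups '", case, "' and '", control, "' must both be present")
  a <- norm$values[, grp == control, drop = FALSE]
  b <- norm$values[, grp == case, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    stop("each group needs at least 2 samples")
  tt <- .row_ttest(a, b, var_equal = var_equal)
  fc <- (tt$mean2 + eps) / (tt$mean1 + eps)
  degenerate <- !is.finite(tt$t)
  p <- tt$p
  # both groups constant: equal means -> no evidence, p = 1; unequal
  # constant means -> infinite t, p = 0 (still flagged)
  p[degenerate & tt$mean1 == tt$mean2] <- 1
  p[degenerate & tt$mean1 != tt$mean2] <- 0
  passed <- apply(norm$unique_peptides, 1, max) >= 2
  p[!passed] <- NA_real_
  tier <- rep("ns", length(p))
  tier[!is.na(p) & p <= 0.05] <- "p05"
  tier[!is.na(p) & p <= 0.01] <- "p01"
  bh <- rep(NA_real_, length(p))
  bh[passed] <- p.adjust(p[passed], method = "BH")
  out <- data.frame(accession = rownames(norm$values),
                    mean_control = unname(tt$mean1),
                    mean_case = unname(tt$mean2),
                    fold_change = unname(fc),
                    log2_fc = unname(log2(fc)),
                    t_stat = unname(tt$t),
                    p_value = unname(p),
                    p_adjust_bh = unname(bh),
                    passed_filter = unname(passed),
                    degenerate = unname(degenerate),
                    tier = tier,
                    stringsAsFactors = FALSE)
  if (any(degenerate))
    message(sum(degenerate), " protein(s) with zero pooled variance flagged degenerate")
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Volcano-plot table
#'
#' One row per filter-passing protein: the log2 fold change, `-log10` of
#' the raw p-value, the significance tier (`ns`, `p05`, `p01`, boundaries
#' inclusive) and the regulation direction (`up` for FC > 1, `down` for
#' FC < 1, `flat` at 1).
#'
#' @param de a `differential_result`.
#' @return data.frame with columns accession, log2_fc, neg_log10_p, tier,
#'   direction.
#' @export
volcano_table <- function(de) {
  stopifnot(inherits(de, "differential_result"))
  d <- de[de$passed_filter & !is.na(de$p_value), , drop = FALSE]
  data.frame(accession = d$accession,
             log2_fc = d$log2_fc,
             neg_log10_p = -log10(d$p_value),
             tier = d$tier,
             direction = ifelse(d$fold_change > 1, "up",
                                ifelse(d$fold_change < 1, "down", "flat")),
             stringsAsFactors = FALSE)
}

#' Spectra-per-kilodalton relative abundance index
#'
#' Divides an aggregate spectrum count per protein by its molecular mass
#' in kDa. Because spectral counts scale with the number of observable
#' peptides and hence with protein size, this ratio is a within-sample
#' proxy for relative molar abundance. Aggregation modes: `mean_all`
#' (default; mean across all samples), `sum_all`, or `mean_group` for the
#' samples of one group.
#'
#' @param x a [spectral_count_table()] or `normalized_table`.
#' @param meta [protein_meta()] supplying `mass_kda` for every requested
#'   protein.
#' @param mode aggregation mode.
#' @param group group label, required for `mode = "mean_group"`.
#' @param proteins optional accession subset (default: all rows of `x`).
#' @return data.frame of class `abundance_index`, sorted by descending
#'   ratio, with columns accession, gene_symbol, aggregate, mass_kda,
#'   ratio and dense rank (rank 1 = highest ratio).
#' @export
abundance_index <- function(x, meta, mode = c("mean_all", "sum_all", "mean_group"),
                            group = NULL, proteins = NULL) {
  mode <- match.arg(mode)
  vals <- if (inherits(x, "spectral_count_table")) x$counts
          else if (inherits(x, "normalized_table")) x$values
          else stop("x must be a spectral_count_table or normalized_table")
  grp <- x$groups
  if (is.null(proteins)) proteins <- rownames(vals)
  miss <- setdiff(proteins, rownames(vals))
  if (length(miss) > 0)
    stop("protein(s) not in table: ", paste(miss, collapse = ", "))
  vals <- vals[proteins, , drop = FALSE]
  agg <- switch(mode,
    mean_all = rowMeans(vals),
    sum_all = rowSums(vals),
    mean_group = {
      if (is.null(group) || !group %in% grp)
        stop("mode 'mean_group' needs a valid group label")
      rowMeans(vals[, grp == group, drop = FALSE])
    })
  m <- match(proteins, meta$accession)
  mass <- meta$mass_kda[m]
  no_mass <- proteins[is.na(m) | is.na(mass)]
  if (length(no_mass) > 0)
    stop("missing molecular mass for: ", paste(no_mass, collapse = ", "))
  ratio <- agg / mass
  out <- data.frame(accession = proteins,
                    gene_symbol = meta$gene_symbol[m],
                    aggregate = unname(agg),
                    mass_kda = mass,
                    ratio = unname(ratio),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ratio, out$accession), , drop = FALSE]
  out$rank <- match(out$ratio, sort(unique(out$ratio), decreasing = TRUE))
  rownames(out) <- NULL
  class(out) <- c("abundance_index", "data.frame")
  out
}

#' qPCR fold change by the delta-delta-Ct method
#'
#' `FC = 2^-[(Ct_target_case - Ct_ref_case) - (Ct_target_control -
#' Ct_ref_control)]`, the relative expression of a target gene against a
#' housekeeping reference and a control condition.
#'
#' @param ct_target_case,ct_ref_case,ct_target_control,ct_ref_control
#'   positive cycle-threshold values (vectorized).
#' @return fold change(s).
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts) | cts <= 0)) stop("Ct values must be positive")
  ddct <- (ct_target_case - ct_ref_case) -
          (ct_target_control - ct_ref_control)
  2 ^ (-ddct)
}
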