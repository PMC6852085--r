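#' Relative expression by the delta-delta-Ct method
#'
#' Normalizes target-gene threshold cycles against a reference-gene
#' panel and calibrates to the control group. Per sample,
#' `dCt = Ct_target - mean(Ct_ref)` (the arithmetic mean of reference
#' Cts, equivalent to geometric-mean normalization of reference
#' expression); per gene, `ddCt = dCt - mean(dCt of calibrator group)`;
#' relative expression is `efficiency^(-ddCt)`. With this calibration
#' the geometric mean of calibrator-group expression is 1 for every
#' gene.
#'
#' Samples missing any reference Ct are excluded entirely; samples
#' missing a target Ct are dropped for that gene only, with a message
#' giving the count.
#'
#' @param records data frame with columns `sample_id`, `group`, `gene`,
#'   `ct` (one row per well mean); an optional `tissue` column is
#'   carried through and normalization is done within tissue.
#' @param ref_genes character vector of reference gene names (default
#'   three-gene panel beta-actin / GAPDH / cyclophilin as "actb",
#'   "gapdh", "ppia"); all must be present for every retained sample.
#' @param calibrator_group group used as calibrator (default
#'   "control"); needs at least 2 samples per gene.
#' @param efficiency amplification efficiency (fold per cycle),
#'   default 2.
#' @return data frame of relative expression: `sample_id`, `group`,
#'   (`tissue`,) `gene`, `dct`, `ddct`, `rel`.
#' @export
normalize_ddct <- function(records, ref_genes = c("actb", "gapdh", "ppia"),
                           calibrator_group = "control",
                           efficiency = 2) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "group", "gene", "ct") %in% names(records)),
            efficiency > 1)
  has_tissue <- "tissue" %in% names(records)
  recs <- records
  if (!has_tissue) recs$tissue <- "all"
  if (any(!is.finite(recs$ct)))
    recs <- recs[is.finite(recs$ct), , drop = FALSE]
  out_of_range <- recs$ct < 10 | recs$ct > 40
  if (any(out_of_range))
    warning(sprintf("%d Ct values outside the typical 10-40 cycle range",
                    sum(out_of_range)))

  res <- lapply(split(recs, recs$tissue), function(rt) {
    key <- rt$sample_id
    ref <- rt[rt$gene %in% ref_genes, , drop = FALSE]
    n_ref <- tapply(ref$gene, ref$sample_id,
                    function(g) length(unique(g)))
    complete <- names(n_ref)[n_ref == length(ref_genes)]
    dropped <- setdiff(unique(key), complete)
    if (length(dropped))
      warning(sprintf(
        "excluding %d sample(s) missing reference-gene Cts: %s",
        length(dropped), paste(dropped, collapse = ", ")))
    rt <- rt[rt$sample_id %in% complete, , drop = FALSE]
    ref_mean <- tapply(ref$ct[ref$sample_id %in% complete],
                       ref$sample_id[ref$sample_id %in% complete], mean)
    tg <- rt[!(rt$gene %in% ref_genes), , drop = FALSE]
    tg$dct <- tg$ct - as.numeric(ref_mean[tg$sample_id])

    per_gene <- lapply(split(tg, tg$gene), function(g) {
      cal <- g$dct[g$group == calibrator_group]
      if (length(cal) < 2)
        stop(sprintf(
          "gene %s has %d calibrator sample(s); at least 2 required",
          g$gene[1], length(cal)))
      g$ddct <- g$dct - mean(cal)
      g$rel <- efficiency^(-g$ddct)
      g
    })
    do.call(rbind, per_gene)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  n_expected <- length(unique(paste(recs$sample_id, recs$tissue))) *
    length(setdiff(unique(recs$gene), ref_genes))
  if (nrow(out) < n_expected)
    message(sprintf("%d sample x gene combination(s) dropped for missing target Ct",
                    n_expected - nrow(out)))
  keep <- c("sample_id", "group", if (has_tissue) "tissue", "gene",
            "dct", "ddct", "rel")
  out[, keep]
}

#' Group summary of relative expression (mean +/- SEM and p-value)
#'
#' Per gene: mean, SEM (= SD/sqrt(n)) and n per group, plus a two-sided
#' p-value from [two_group_compare()]. Output order follows `categories`
#' when supplied (a named vector gene -> category label).
#'
#' @param rel output of [normalize_ddct()].
#' @param groups the two group labels to compare, default
#'   c("control", "CTEPH").
#' @param method p-value method passed to [two_group_compare()].
#' @param categories optional named character vector assigning genes to
#'   display categories; genes are ordered by category then name.
#' @param ... further arguments (e.g. `n_perm`, `seed`) for
#'   [two_group_compare()].
#' @return data frame: `gene` (+ `category` if given), per-group `mean`,
#'   `sem`, `n`, and `p`. SEM is NA (with a warning) for groups of one.
#' @export
summarize_expression <- function(rel, groups = c("control", "CTEPH"),
                                 method = c("welch", "permutation"),
                                 categories = NULL, ...) {
  stopifnot(is.data.frame(rel),
            all(c("gene", "group", "rel") %in% names(rel)))
  method <- match.arg(method)
  res <- lapply(split(rel, rel$gene), function(g) {
    a <- g$rel[g$group == groups[1]]
    b <- g$rel[g$group == groups[2]]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("gene %s: a group has fewer than 2 samples; SEM/p undefined",
                      g$gene[1]))
      p <- NA_real_
    } else {
      p <- two_group_compare(a, b, method = method, ...)
    }
    sem <- function(x) if (length(x) >= 2)
      stats::sd(x) / sqrt(length(x)) else NA_real_
    data.frame(gene = g$gene[1],
               mean_1 = mean(a), sem_1 = sem(a), n_1 = length(a),
               mean_2 = mean(b), sem_2 = sem(b), n_2 = length(b),
               p = p)
  })
  out <- do.call(rbind, res)
  names(out) <- c("gene",
                  paste0(c("mean_", "sem_", "n_"), groups[1]),
                  paste0(c("mean_", "sem_", "n_"), groups[2]), "p")
  if (!is.null(categories)) {
    out$category <- unname(categories[out$gene])
    out <- out[order(match(out$category, unique(categories)), out$gene), ]
    out <- out[, c("gene", "category", setdiff(names(out),
                                               c("gene", "category")))]
  }
  rownames(out) <- NULL
  out
}
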