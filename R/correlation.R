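#' Spearman correlation matrix between metabolites and property items
#'
#' Rank correlation (Pearson correlation of mid-ranks) is used because
#' several measurement items do not follow a normal distribution. Pairs with
#' fewer than 3 complete paired observations are set to `NA` and logged via a
#' warning.
#'
#' @param m a [metabolite_table()] (non-detects already resolved) or a
#'   numeric samples x metabolites matrix.
#' @param p a [property_table()] or numeric samples x items matrix.
#' @return metabolites x items matrix of Spearman coefficients in [-1, 1].
#' @export
spearman_matrix <- function(m, p) {
  X <- if (inherits(m, "metabolite_table")) m$values else as.matrix(m)
  Y <- if (inherits(p, "property_table")) p$values else as.matrix(p)
  if (inherits(m, "metabolite_table") && inherits(p, "property_table"))
    check_same_samples(m, p)
  if (nrow(X) != nrow(Y)) stop("sample counts differ between tables")
  rho <- suppressWarnings(
    stats::cor(X, Y, method = "spearman", use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(X), !is.na(Y))
  if (any(npair < 3L)) {
    rho[npair < 3L] <- NA_real_
    warning(sum(npair < 3L), " metabolite-item pairs had <3 complete ",
            "observations; their coefficients are missing")
  }
  rho
}

#' Hierarchical clustering of a correlation matrix axis
#'
#' Rows (or columns) are clustered with distance 1 - Pearson correlation
#' between their coefficient profiles and average linkage — the common
#' correlation-heatmap convention. Missing coefficients are imputed as 0
#' (neutral correlation) for distance computation only; the matrix itself is
#' never altered. Cutting the tree at `k = 2` yields the two major groups.
#'
#' @param rho coefficient matrix.
#' @param axis `"rows"` or `"cols"`.
#' @param k number of groups to cut (default 2).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return list with `order` (leaf order, a permutation), `tree` (hclust),
#'   `groups` (cut labels at `k`).
#' @export
hierarchical_cluster <- function(rho, axis = c("rows", "cols"), k = 2L,
                                 linkage = "average") {
  axis <- match.arg(axis)
  M <- if (axis == "rows") rho else t(rho)
  if (nrow(M) < 2L) stop("need at least 2 rows to cluster")
  M[is.na(M)] <- 0
  cc <- suppressWarnings(stats::cor(t(M)))
  cc[is.na(cc)] <- 0                      # constant profiles: neutral
  d <- stats::as.dist(1 - cc)
  tree <- stats::hclust(d, method = linkage)
  list(order = tree$order, tree = tree,
       groups = stats::cutree(tree, k = min(k, nrow(M))))
}

#' Kruskal-Wallis contrast of one metabolite's correlations across property
#' groups
#'
#' Tests whether the metabolite's correlation coefficients differ between the
#' vulcanization, tensile, and heat-aging groups. The statistic is the
#' tie-corrected H with an upper-tail chi-square p (the test is inherently
#' one-sided toward large H).
#'
#' @param rho_row numeric vector of coefficients for one metabolite.
#' @param groups character vector of the same length, group of each item.
#' @return list with `H` and `p`.
#' @export
kruskal_wallis_groups <- function(rho_row, groups) {
  ok <- !is.na(rho_row)
  g <- factor(groups[ok])
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("need at least 2 groups with at least 2 members")
  v <- rho_row[ok]
  if (length(unique(v)) == 1L)          # all tied: no evidence by convention
    return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(v, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Metabolite-property correlation analysis
#'
#' Computes the Spearman matrix on standardized tables, clusters both axes,
#' runs the per-metabolite Kruskal-Wallis contrast across property groups,
#' and re-clusters the significant metabolites into two major groups.
#'
#' @param m a [metabolite_table()] with non-detects resolved.
#' @param p a [property_table()] with empty items dropped.
#' @param alpha significance level for the Kruskal-Wallis contrast.
#' @return object of class `correlation_result`: `rho`, `row_order`,
#'   `col_order`, `kw` (data.frame metabolite/H/p), `significant_ids`,
#'   `significant_groups` (2-cut labels over significant metabolites, when
#'   at least two are significant).
#' @export
correlate_properties <- function(m, p, alpha = 0.05) {
  check_same_samples(m, p)
  Xs <- standardize(m$values)
  Ys <- standardize(p$values)
  rho <- spearman_matrix(Xs, Ys)
  rows <- hierarchical_cluster(rho, "rows")
  cols <- hierarchical_cluster(rho, "cols")
  kw <- do.call(rbind, lapply(seq_len(nrow(rho)), function(i) {
    res <- kruskal_wallis_groups(rho[i, ], p$groups)
    data.frame(metabolite_id = rownames(rho)[i], H = res$H, p = res$p,
               stringsAsFactors = FALSE)
  }))
  sig <- kw$metabolite_id[kw$p < alpha]
  sg <- if (length(sig) >= 2L)
    hierarchical_cluster(rho[sig, , drop = FALSE], "rows", k = 2L)$groups
  else NULL
  structure(list(rho = rho, row_order = rows$order, col_order = cols$order,
                 kw = kw, significant_ids = sig, significant_groups = sg,
                 alpha = alpha),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> ", nrow(x$rho), " metabolites x ", ncol(x$rho),
      " items; ", length(x$significant_ids),
      " metabolites differ across property groups at alpha ", x$alpha,
      "\n", sep = "")
  invisible(x)
}
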