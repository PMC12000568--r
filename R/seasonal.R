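#' Detection accounting across samples and seasons
#'
#' Counts detected metabolites per sample, plus the season-level summaries
#' used to describe a monthly sampling campaign: detected in at least one
#' sample (union), detected throughout each season (every sample of that
#' season), detected in all samples, and detected in only one season
#' (at least one sample of that season and none of the other).
#'
#' @param t a [metabolite_table()].
#' @return list with `per_sample` (named integer vector) and `summary`
#'   (named integer vector with elements `union`, `throughout_rainy`,
#'   `throughout_dry`, `all_samples`, `only_rainy`, `only_dry`).
#' @export
detection_counts <- function(t) {
  stopifnot(inherits(t, "metabolite_table"))
  d <- t$detected
  rainy <- t$seasons == "rainy"; dry <- t$seasons == "dry"
  any_rainy <- colSums(d[rainy, , drop = FALSE]) > 0L
  any_dry <- colSums(d[dry, , drop = FALSE]) > 0L
  list(per_sample = setNames(rowSums(d), t$sample_ids),
       summary = c(
         union = sum(any_rainy | any_dry),
         throughout_rainy = sum(colSums(d[rainy, , drop = FALSE]) == sum(rainy)),
         throughout_dry = sum(colSums(d[dry, , drop = FALSE]) == sum(dry)),
         all_samples = sum(colSums(d) == nrow(d)),
         only_rainy = sum(any_rainy & !any_dry),
         only_dry = sum(any_dry & !any_rainy)))
}

#' Concordance of detected-metabolite sets between two samples
#'
#' Jaccard index of the detection sets: `|D_i & D_j| / |D_i | D_j|`. The
#' overlap coefficient (`|D_i & D_j| / min(|D_i|, |D_j|)`) is available as an
#' alternative.
#'
#' @param t a [metabolite_table()].
#' @param i,j sample indices or ids.
#' @param method `"jaccard"` (default) or `"overlap"`.
#' @return scalar in [0, 1]; symmetric in `i`, `j`.
#' @export
concordance_rate <- function(t, i, j, method = c("jaccard", "overlap")) {
  stopifnot(inherits(t, "metabolite_table"))
  method <- match.arg(method)
  if (is.character(i)) i <- match(i, t$sample_ids)
  if (is.character(j)) j <- match(j, t$sample_ids)
  if (is.na(i) || is.na(j) || i == j) stop("i and j must be distinct valid samples")
  di <- t$detected[i, ]; dj <- t$detected[j, ]
  inter <- sum(di & dj)
  denom <- if (method == "jaccard") sum(di | dj) else min(sum(di), sum(dj))
  if (denom == 0L) stop("both detection sets are empty: concordance undefined")
  inter / denom
}

#' Pairwise concordance matrix
#'
#' @inheritParams concordance_rate
#' @return symmetric matrix with unit diagonal.
#' @export
concordance_matrix <- function(t, method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  n <- length(t$sample_ids)
  m <- diag(1, n)
  dimnames(m) <- list(t$sample_ids, t$sample_ids)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- concordance_rate(t, i, j, method)
  m
}

#' One-tailed Mann-Whitney U test
#'
#' The U statistic counts pairs where a `y` value exceeds an `x` value (ties
#' count one half). For small problems (`length(x) + length(y) <= 18`) the
#' p-value is exact, by enumeration of all assignments of the pooled
#' mid-ranks to the two groups, which remains exact under ties; larger
#' problems use the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y numeric vectors (each nonempty).
#' @param alternative `"greater"` tests whether `y` tends to exceed `x`;
#'   `"less"` the opposite.
#' @return list with `U` (for the tested direction) and `p`.
#' @export
mann_whitney_one_tailed <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be nonempty")
  if (any(is.na(c(x, y)))) stop("missing values not allowed")
  if (alternative == "less") { tmp <- x; x <- y; y <- tmp }
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))                     # mid-ranks
  Ry <- sum(r[(m + 1L):N])
  U <- Ry - n * (n + 1) / 2              # pairs where y beats x (ties = 1/2)
  if (N <= 18L) {
    sets <- combn(N, n)
    stats <- colSums(matrix(r[sets], nrow = n)) - n * (n + 1) / 2
    p <- mean(stats >= U - 1e-9)
  } else {
    ties <- table(r)
    muU <- m * n / 2
    sigU <- sqrt(m * n / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1))))
    if (sigU == 0) return(list(U = U, p = 1))
    p <- pnorm((U - 0.5 - muU) / sigU, lower.tail = FALSE)
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  list(U = U, p = p)
}

#' Rainy-vs-dry seasonal fold-change screen
#'
#' Per metabolite: season means (after the configured non-detect policy),
#' dry/rainy fold change, direction flags at the threshold (`up` if
#' fold >= threshold, `down` if <= 1/threshold), and a one-tailed
#' Mann-Whitney p-value testing the observed direction. Metabolites detected
#' in only one season get an infinite or zero fold change and are flagged
#' `presence_only` rather than treated as quantitative.
#'
#' @param t a [metabolite_table()].
#' @param threshold fold-change threshold (default 2).
#' @param policy non-detect policy (see [apply_nondetect_policy()]).
#' @return object of class `seasonal_screen` with elements `table`
#'   (per-metabolite data.frame), `n_up`, `n_down`, `detection`
#'   (from [detection_counts()]), `concordance` (pairwise matrix).
#' @export
seasonal_screen <- function(t, threshold = 2, policy = "zero") {
  stopifnot(inherits(t, "metabolite_table"))
  if (!all(c("rainy", "dry") %in% t$seasons)) stop("both seasons required")
  rainy <- t$seasons == "rainy"; dry <- t$seasons == "dry"
  if (sum(rainy) < 2L || sum(dry) < 2L)
    warning("a season has fewer than 2 samples: p-values unreliable")
  imp <- apply_nondetect_policy(t, policy)
  v <- imp$values
  mean_rainy <- colMeans(v[rainy, , drop = FALSE])
  mean_dry <- colMeans(v[dry, , drop = FALSE])
  fc <- mean_dry / mean_rainy
  fc[mean_rainy == 0 & mean_dry == 0] <- NA_real_
  presence_only <- (mean_rainy == 0) != (mean_dry == 0)
  # presence/absence metabolites are flagged, not counted as quantitative
  # fold changes (a fully season-absent metabolite would otherwise always
  # pass any finite threshold)
  direction <- ifelse(is.na(fc) | presence_only, "none",
                      ifelse(fc >= threshold, "up",
                             ifelse(fc <= 1 / threshold, "down", "none")))
  U <- p <- rep(NA_real_, ncol(v))
  for (j in seq_len(ncol(v))) {
    alt <- if (!is.na(fc[j]) && fc[j] < 1) "less" else "greater"
    res <- mann_whitney_one_tailed(v[rainy, j], v[dry, j], alt)
    U[j] <- res$U; p[j] <- res$p
  }
  tab <- data.frame(metabolite_id = t$metabolite_ids,
                    mean_rainy = mean_rainy, mean_dry = mean_dry,
                    fold_change = fc, direction = direction,
                    presence_only = presence_only,
                    u_statistic = U, p_one_tailed = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 n_up = sum(direction == "up"),
                 n_down = sum(direction == "down"),
                 threshold = threshold,
                 detection = detection_counts(t),
                 concordance = concordance_matrix(t)),
            class = "seasonal_screen")
}

#' @export
print.seasonal_screen <- function(x, ...) {
  cat("<seasonal_screen> threshold ", x$threshold, "x: ", x$n_up,
      " up, ", x$n_down, " down (dry vs rainy) of ",
      nrow(x$table), " metabolites\n", sep = "")
  invisible(x)
}

#' Tally chemical classes and pathways over a set of metabolites
#'
#' Counts non-missing class and pathway labels; metabolites without a label
#' are reported separately, and an exclusion list removes implausible
#' pathways from the tally.
#'
#' @param a annotation data.frame (see [read_annotation_table()]).
#' @param ids metabolite ids to tally (default: all in `a`).
#' @param exclude_pathways pathway labels to drop from the pathway tally.
#' @return list with `class_counts`, `pathway_counts` (named integer vectors,
#'   decreasing), `n_unclassified`, `n_no_pathway`.
#' @export
summarize_annotations <- function(a, ids = a$metabolite_id,
                                  exclude_pathways = character(0)) {
  sel <- a[a$metabolite_id %in% ids, ]
  cls <- sel$chem_class[!is.na(sel$chem_class)]
  pw <- sel$pathway[!is.na(sel$pathway)]
  pw <- pw[!pw %in% exclude_pathways]
  list(class_counts = sort(table(cls), decreasing = TRUE),
       pathway_counts = sort(table(pw), decreasing = TRUE),
       n_unclassified = sum(is.na(sel$chem_class)),
       n_no_pathway = sum(is.na(sel$pathway)))
}
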