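#' Synthetic study scenario
#'
#' Describes a simulated latex-sampling campaign with the statistical
#' structure the analysis assumes: monthly samples over two seasons,
#' log-normal (multiplicative-noise) relative abundances, planted seasonal
#' fold changes, per-cell detection dropout, and property items generated as
#' sparse linear functions of standardized planted metabolites plus Gaussian
#' noise.
#'
#' Defaults mirror the reference study design: 9 monthly samples
#' (May-January, i.e. 6 rainy + 3 dry), ~400 metabolites, 22 metabolites
#' planted up and 4 down in the dry season, and 30/14/34 measurement items
#' across the vulcanization / tensile / heat-aging groups. `dropout_rate`
#' defaults to 0.075, which makes roughly half of all metabolites miss at
#' least one of 9 samples (0.925^9 ~ 0.5), the detection pattern typical of
#' such campaigns. `cv` is the per-cell coefficient of variation of the
#' multiplicative noise (default 10%); `effect_fold` the planted dry/rainy
#' mean ratio (default 3 — a "more than two-fold" seasonal effect planted
#' with margin, so a 2x screen on observed means can recover it rather than
#' sit on its own decision boundary).
#'
#' @param n_samples,n_metabolites design size.
#' @param months calendar month per sample; seasons derive from them.
#' @param n_seasonal_up,n_seasonal_down planted dry-season effects.
#' @param effect_fold planted mean ratio for seasonal effects (>= 1).
#' @param cv per-cell coefficient of variation of abundances.
#' @param dropout_rate per-cell non-detect probability, in [0, 1).
#' @param n_items_per_group items in the vulcanization / tensile / heat-aging
#'   groups.
#' @param support_size metabolites per planted property support.
#' @param group_pool_size metabolites in each group's driver pool; items of a
#'   group draw their supports from that shared pool, so measurement items
#'   within a group are redundant the way real characterization tests are,
#'   and pool metabolites acquire group-differential correlations.
#' @param noise_sd property noise SD (response is on the standardized scale).
#' @param rng_seed integer seed; everything downstream is reproducible from
#'   it.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_samples = 9L, n_metabolites = 400L,
                               months = c(5:12, 1L)[seq_len(n_samples)],
                               n_seasonal_up = 22L, n_seasonal_down = 4L,
                               effect_fold = 3, cv = 0.1,
                               dropout_rate = 0.075,
                               n_items_per_group = c(vulcanization = 30L,
                                                     tensile = 14L,
                                                     heat_aging = 34L),
                               support_size = 3L, group_pool_size = 8L,
                               noise_sd = 0.1, rng_seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (effect_fold < 1) stop("effect_fold must be >= 1")
  if (n_seasonal_up + n_seasonal_down > n_metabolites)
    stop("more planted effects than metabolites")
  if (length(months) != n_samples) stop("months must have length n_samples")
  seasons <- season_from_month(months)
  if (length(unique(seasons)) < 2L)
    stop("scenario must contain both seasons")
  structure(list(n_samples = as.integer(n_samples),
                 n_metabolites = as.integer(n_metabolites),
                 months = as.integer(months), seasons = seasons,
                 n_seasonal_up = as.integer(n_seasonal_up),
                 n_seasonal_down = as.integer(n_seasonal_down),
                 effect_fold = effect_fold, cv = cv,
                 dropout_rate = dropout_rate,
                 n_items_per_group = n_items_per_group,
                 support_size = as.integer(support_size),
                 group_pool_size = as.integer(group_pool_size),
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "synthetic_scenario")
}

# deterministic per-stage seed derived from the scenario master seed, so
# adding a stage never perturbs earlier stages' randomness
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Generate a synthetic metabolite table
#'
#' Abundances are log-normal around metabolite-specific baselines; planted
#' "up" metabolites have a dry-season mean `effect_fold` times the rainy
#' mean in expectation (and symmetrically for "down"). Dropout is applied
#' per cell. The first `n_seasonal_up` metabolites are the planted up set,
#' the next `n_seasonal_down` the down set (recorded in the attributes
#' `planted_up` / `planted_down`).
#'
#' @param s a [synthetic_scenario()].
#' @return a [metabolite_table()] with planted-truth attributes.
#' @export
generate_metabolite_matrix <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  set.seed(stage_seed(s$rng_seed, "metabolites"))
  n <- s$n_samples; p <- s$n_metabolites
  sdlog <- sqrt(log(1 + s$cv^2))            # lognormal sd giving the target CV
  base <- runif(p, log(10), log(1000))      # baseline log-mean per metabolite
  up <- seq_len(s$n_seasonal_up)
  down <- s$n_seasonal_up + seq_len(s$n_seasonal_down)
  eff <- rep(0, p)
  eff[up] <- log(s$effect_fold)
  eff[down] <- -log(s$effect_fold)
  dry <- s$seasons == "dry"
  logmu <- outer(as.numeric(dry), eff) + matrix(base, n, p, byrow = TRUE)
  vals <- exp(logmu + matrix(rnorm(n * p, 0, sdlog), n, p)) /
    exp(sdlog^2 / 2)                        # mean-preserving noise
  detected <- matrix(runif(n * p) >= s$dropout_rate, n, p)
  dimnames(vals) <- list(sprintf("S%02d_m%02d", seq_len(n), s$months),
                         sprintf("met%03d", seq_len(p)))
  dimnames(detected) <- dimnames(vals)
  out <- metabolite_table(vals, s$months, s$seasons, detected)
  attr(out, "planted_up") <- colnames(vals)[up]
  attr(out, "planted_down") <- colnames(vals)[down]
  out
}

#' Generate synthetic property measurements from planted supports
#'
#' Each measurement item is a linear combination of `support_size`
#' standardized planted metabolites plus Gaussian noise, so the true model
#' complexity of every item is known. Each property group owns a disjoint
#' driver pool of `group_pool_size` metabolites (drawn from those not
#' carrying planted seasonal effects) and every item of the group samples
#' its support from that pool — characterization items within a family are
#' redundant, so the same metabolites recur across a group's items (which is
#' what overlap counting and the group-contrast test measure). Coefficients
#' have magnitude in [1, 2] with random sign. Group sizes follow the
#' scenario (30/14/34 by default).
#'
#' @param t a [metabolite_table()] from [generate_metabolite_matrix()].
#' @param s the same [synthetic_scenario()].
#' @return a [property_table()]; attribute `planted_supports` records, per
#'   item, the support metabolite ids and coefficients.
#' @export
generate_properties <- function(t, s) {
  stopifnot(inherits(t, "metabolite_table"), inherits(s, "synthetic_scenario"))
  set.seed(stage_seed(s$rng_seed, "properties"))
  k <- s$support_size
  if (k >= s$n_samples)
    warning("support size >= n_samples: perfect interpolation regime")
  imp <- apply_nondetect_policy(t, "zero")
  X <- standardize(imp$values)
  free <- setdiff(colnames(X),
                  c(attr(t, "planted_up"), attr(t, "planted_down")))
  grp_names <- names(s$n_items_per_group)
  pool_size <- max(s$group_pool_size, k)
  # small designs get proportionally smaller disjoint pools
  pool_size <- min(pool_size, length(free) %/% length(grp_names))
  if (pool_size < k)
    stop("not enough metabolites for disjoint group driver pools")
  pool_draw <- sample(free, pool_size * length(grp_names))
  pools <- split(pool_draw, rep(grp_names, each = pool_size))
  # a driver acts in one consistent direction on its property family, so
  # its sign is a property of the (metabolite, group) pair, not of the item
  pool_signs <- lapply(pools, function(pl)
    setNames(sample(c(-1, 1), length(pl), replace = TRUE), pl))
  groups <- rep(grp_names, s$n_items_per_group)
  item_ids <- sprintf("%s_%02d", c(vulcanization = "vul", tensile = "ten",
                                   heat_aging = "age")[groups],
                      unlist(lapply(s$n_items_per_group, seq_len)))
  P <- matrix(NA_real_, nrow(X), length(item_ids),
              dimnames = list(rownames(X), item_ids))
  supports <- vector("list", length(item_ids))
  names(supports) <- item_ids
  for (i in seq_along(item_ids)) {
    sup <- sample(pools[[groups[i]]], k)
    beta <- runif(k, 1, 2) * unname(pool_signs[[groups[i]]][sup])
    P[, i] <- drop(X[, sup, drop = FALSE] %*% beta) +
      rnorm(nrow(X), 0, s$noise_sd)
    supports[[i]] <- list(metabolites = sup, coefficients = beta)
  }
  out <- property_table(P, setNames(groups, item_ids))
  attr(out, "planted_supports") <- supports
  attr(out, "group_pools") <- pools
  out
}

#' Path of the bundled synthetic compound library
#'
#' ~1250 programmatically enumerated, Open Babel-validated drug- and
#' metabolite-like canonical SMILES, one per line. It is a synthetic stand-in
#' for a random sample of a public compound database, shipped so the
#' diversity stage needs no network access.
#'
#' @return file path.
#' @export
compound_library_path <- function() {
  system.file("extdata", "synthetic_compound_library.smi",
              package = "metabomat", mustWork = TRUE)
}

#' Draw background structures from the bundled compound library
#'
#' Samples `n` SMILES without replacement, reproducibly from `rng_seed`.
#'
#' @param n number of structures.
#' @param rng_seed integer seed.
#' @param library_path SMILES file, one per line (defaults to the bundled
#'   synthetic library).
#' @return character vector of SMILES.
#' @export
generate_structures <- function(n, rng_seed = 1L,
                                library_path = compound_library_path()) {
  lib <- readLines(library_path)
  lib <- lib[nzchar(trimws(lib))]
  if (n > length(lib))
    stop("requested ", n, " structures but the library holds ", length(lib))
  set.seed(as.integer(rng_seed))
  lib[sample.int(length(lib), n)]
}

#' Generate a synthetic annotation table for a metabolite table
#'
#' Assigns each metabolite a SMILES from the bundled library; a fraction gets
#' no structural annotation (`NA` SMILES), mirroring metabolites that lack a
#' database compound id. Chemical classes and pathways are drawn from small
#' label pools, with some left unannotated.
#'
#' @param t a [metabolite_table()].
#' @param rng_seed integer seed.
#' @param frac_unannotated fraction of metabolites without SMILES
#'   (default 0.06).
#' @return annotation data.frame (see [read_annotation_table()]).
#' @export
generate_annotation <- function(t, rng_seed = 1L, frac_unannotated = 0.06) {
  lib <- readLines(compound_library_path())
  set.seed(stage_seed(rng_seed, "annotation"))
  p <- length(t$metabolite_ids)
  if (p > length(lib)) stop("more metabolites than library compounds")
  smi <- sample(lib, p)
  drop_smi <- sample.int(p, round(frac_unannotated * p))
  smi[drop_smi] <- NA_character_
  classes <- sprintf("class_%02d", 1:12)
  pathways <- sprintf("pathway_%02d", 1:10)
  cls <- sample(c(classes, NA), p, replace = TRUE, prob = c(rep(1, 12), 3))
  pw <- sample(c(pathways, NA), p, replace = TRUE, prob = c(rep(1, 10), 4))
  data.frame(metabolite_id = t$metabolite_ids,
             smiles = smi,
             compound_id = ifelse(is.na(smi), NA_character_,
                                  sprintf("CPD%05d", seq_len(p))),
             chem_class = cls, pathway = pw,
             stringsAsFactors = FALSE)
}
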