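#' Season label for a calendar month
#'
#' Eastern-Thailand savannah climate convention: the dry season runs November
#' through February; all other months (the warm and hot rainy seasons) are
#' labelled rainy.
#'
#' @param month integer vector of calendar months (1-12).
#' @return character vector, `"rainy"` or `"dry"`.
#' @export
season_from_month <- function(month) {
  month <- as.integer(month)
  if (any(is.na(month)) || any(month < 1L | month > 12L))
    stop("months must be integers in 1..12")
  ifelse(month %in% c(11L, 12L, 1L, 2L), "dry", "rainy")
}

#' Construct a metabolite relative-abundance table
#'
#' Samples are rows, metabolites are columns. Non-detected cells are missing
#' values, not zeros, until [apply_nondetect_policy()] is applied.
#'
#' @param values numeric matrix (samples x metabolites) of nonnegative
#'   relative abundances; `NA` marks a non-detect.
#' @param months integer vector, calendar month of each sample.
#' @param seasons optional character vector (`"rainy"`/`"dry"`); derived from
#'   `months` via [season_from_month()] when omitted.
#' @param detected optional logical matrix; defaults to `!is.na(values)`.
#' @return object of class `metabolite_table`.
#' @export
metabolite_table <- function(values, months, seasons = NULL, detected = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("M", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids")
  if (length(months) != nrow(values))
    stop("months must have one entry per sample")
  months <- as.integer(months)
  if (is.null(seasons)) seasons <- season_from_month(months)
  if (!all(seasons %in% c("rainy", "dry")))
    stop("unknown season label: ", paste(setdiff(seasons, c("rainy", "dry")),
                                         collapse = ", "))
  if (is.null(detected)) detected <- !is.na(values)
  detected <- as.matrix(detected)
  if (!identical(dim(detected), dim(values)))
    stop("values and detected must have identical dimensions")
  dimnames(detected) <- dimnames(values)
  values[!detected] <- NA_real_
  if (any(values < 0, na.rm = TRUE))
    stop("negative abundance values are not allowed")
  structure(list(values = values, detected = detected,
                 months = months, seasons = as.character(seasons),
                 sample_ids = rownames(values),
                 metabolite_ids = colnames(values)),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("<metabolite_table> ", length(x$sample_ids), " samples x ",
      length(x$metabolite_ids), " metabolites; ",
      sum(!x$detected), " non-detects; seasons: ",
      paste(sprintf("%s=%d", names(table(x$seasons)), table(x$seasons)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct a property measurement table
#'
#' @param values numeric matrix (samples x measurement items); `NA` marks a
#'   blank (unmeasured) cell.
#' @param groups named character vector mapping every item id to one of
#'   `"vulcanization"`, `"tensile"`, `"heat_aging"`.
#' @return object of class `property_table`.
#' @export
property_table <- function(values, groups) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("P", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  ok <- c("vulcanization", "tensile", "heat_aging")
  if (!setequal(names(groups), colnames(values)))
    stop("groups must name every item exactly once")
  if (!all(groups %in% ok))
    stop("unknown property group: ", paste(setdiff(groups, ok), collapse = ", "))
  structure(list(values = values,
                 groups = setNames(as.character(groups[colnames(values)]),
                                   colnames(values)),
                 sample_ids = rownames(values),
                 item_ids = colnames(values)),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat("<property_table> ", length(x$sample_ids), " samples x ",
      length(x$item_ids), " items (",
      paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# shared sample-order check: sample order is the canonical join key; a
# mismatch is a hard error, never an implicit intersection
check_same_samples <- function(a, b) {
  if (!identical(a$sample_ids, b$sample_ids))
    stop("sample ids of the two tables do not match (order matters)")
  invisible(TRUE)
}

#' Read a metabolite table and its sample metadata
#'
#' The data file is delimited text with a header; the first column holds the
#' sample id. Empty cells and the literal `"ND"` are read as non-detects.
#' The metadata file has columns `sample_id`, `month`, `season`.
#'
#' @param path data file path (TSV).
#' @param metadata_path sample metadata file path (TSV).
#' @return a [metabolite_table()].
#' @export
read_metabolite_table <- function(path, metadata_path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  nd <- vals == "" | toupper(trimws(vals)) == "ND" | is.na(vals)
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = list(ids, colnames(vals))))
  if (any(!nd & is.na(num))) stop("non-numeric abundance value in ", path)
  if (any(num < 0, na.rm = TRUE)) stop("negative abundance in ", path)
  num[nd] <- NA_real_
  meta <- read.delim(metadata_path, colClasses = "character")
  need <- c("sample_id", "month", "season")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  m <- meta[match(ids, meta$sample_id), ]
  if (any(is.na(m$sample_id))) stop("metadata missing samples present in data")
  metabolite_table(num, months = as.integer(m$month), seasons = m$season,
                   detected = !nd)
}

#' Write a metabolite table (with metadata) to TSV
#'
#' Non-detects are written as `"ND"`; values keep full double precision so a
#' read-back reproduces the object exactly.
#'
#' @param t a [metabolite_table()].
#' @param path,metadata_path output file paths.
#' @export
write_metabolite_table <- function(t, path, metadata_path) {
  chr <- matrix(sprintf("%.17g", t$values), nrow(t$values),
                dimnames = dimnames(t$values))
  chr[!t$detected] <- "ND"
  df <- data.frame(sample_id = t$sample_ids, chr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = t$sample_ids, month = t$months,
                         season = t$seasons),
              metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a property table
#'
#' The data file is TSV, first column sample id, blanks allowed; the groups
#' file has columns `item_id`, `group`.
#'
#' @param path,groups_path input file paths.
#' @return a [property_table()].
#' @export
read_property_table <- function(path, groups_path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  blank <- vals == "" | is.na(vals)
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = list(ids, colnames(vals))))
  if (any(!blank & is.na(num))) stop("non-numeric property value in ", path)
  num[blank] <- NA_real_
  g <- read.delim(groups_path, colClasses = "character")
  property_table(num, groups = setNames(g$group, g$item_id))
}

#' @rdname read_property_table
#' @param t a [property_table()].
#' @export
write_property_table <- function(t, path, groups_path) {
  chr <- matrix(sprintf("%.17g", t$values), nrow(t$values),
                dimnames = dimnames(t$values))
  chr[is.na(t$values)] <- ""
  df <- data.frame(sample_id = t$sample_ids, chr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(item_id = t$item_ids, group = unname(t$groups)),
              groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the metabolite annotation table
#'
#' Columns: `metabolite_id`, `smiles`, `compound_id`, `chem_class`,
#' `pathway`; empty strings become `NA` (annotation unavailable).
#'
#' @param path file path (TSV).
#' @return data.frame with the five columns above.
#' @export
read_annotation_table <- function(path) {
  a <- read.delim(path, colClasses = "character")
  need <- c("metabolite_id", "smiles", "compound_id", "chem_class", "pathway")
  if (!all(need %in% names(a)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  a <- a[, need]
  for (cc in need[-1]) a[[cc]][!nzchar(a[[cc]]) | is.na(a[[cc]])] <- NA_character_
  a
}

#' @rdname read_annotation_table
#' @param a annotation data.frame.
#' @export
write_annotation_table <- function(a, path) {
  a2 <- a
  for (cc in names(a2)) a2[[cc]][is.na(a2[[cc]])] <- ""
  write.table(a2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop measurement items that are blank in every sample
#'
#' Characterization tests occasionally terminate before the prescribed state
#' is reached, leaving an item blank across all samples; such items carry no
#' information and are removed before analysis.
#'
#' @param t a [property_table()].
#' @return list with `table` (items having at least one value, order
#'   preserved) and `dropped` (character vector of removed item ids).
#' @export
drop_empty_items <- function(t) {
  stopifnot(inherits(t, "property_table"))
  empty <- colSums(!is.na(t$values)) == 0L
  kept <- t$values[, !empty, drop = FALSE]
  out <- if (ncol(kept) > 0L)
    property_table(kept, t$groups[colnames(kept)])
  else
    structure(list(values = kept, groups = setNames(character(0), character(0)),
                   sample_ids = t$sample_ids, item_ids = character(0)),
              class = "property_table")
  list(table = out, dropped = t$item_ids[empty])
}

#' Column-wise z-score standardization (population SD)
#'
#' Each column is centred and scaled to mean 0, SD 1 over its non-missing
#' entries. The population SD convention (divide by n) is used throughout the
#' package; sample SD differs only by a constant factor per column and does
#' not change ranks, correlations, or model selection.
#'
#' @param x numeric matrix or vector.
#' @return standardized matrix/vector; missing entries stay missing.
#' @export
standardize <- function(x) {
  if (is.null(dim(x))) return(drop(standardize(matrix(x, ncol = 1L))))
  x <- as.matrix(x)
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2L)
      stop("column ", colnames(x)[j] %||% j, ": fewer than 2 non-missing values")
    mu <- mean(v[ok])
    s <- sqrt(mean((v[ok] - mu)^2))
    if (s == 0)
      stop("column ", colnames(x)[j] %||% j, ": zero variance, cannot standardize")
    out[, j] <- (v - mu) / s
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve non-detects in a metabolite table
#'
#' Policies: `"zero"` sets non-detects to 0 (presence/absence information is
#' kept as very low abundance); `"half_min"` sets them to half the
#' metabolite's minimum detected value (a common limit-of-detection
#' surrogate); `"drop_metabolite"` removes any metabolite with at least one
#' non-detect, leaving the complete-detection subset.
#'
#' @param t a [metabolite_table()].
#' @param policy one of `"zero"`, `"half_min"`, `"drop_metabolite"`.
#' @return a [metabolite_table()] with no missing values.
#' @export
apply_nondetect_policy <- function(t, policy = c("zero", "half_min",
                                                 "drop_metabolite")) {
  stopifnot(inherits(t, "metabolite_table"))
  policy <- match.arg(policy)
  v <- t$values
  if (policy == "drop_metabolite") {
    keep <- colSums(!t$detected) == 0L
    return(metabolite_table(v[, keep, drop = FALSE], t$months, t$seasons,
                            t$detected[, keep, drop = FALSE]))
  }
  if (policy == "zero") {
    v[!t$detected] <- 0
  } else {
    for (j in seq_len(ncol(v))) {
      nd <- !t$detected[, j]
      if (any(nd))
        v[nd, j] <- if (all(nd)) 0 else min(v[!nd, j]) / 2
    }
  }
  out <- metabolite_table(v, t$months, t$seasons,
                          detected = matrix(TRUE, nrow(v), ncol(v),
                                            dimnames = dimnames(v)))
  out$detected <- t$detected   # keep the original detection record
  out$values <- v
  out
}

#' Analysis configuration
#'
#' Central tunables for the whole pipeline, with the defaults used in the
#' worked analysis. `umap` carries the embedding hyperparameters
#' (`n_components = 2`, `n_neighbors = 3`, `min_dist = 0.5`,
#' `metric = "manhattan"`, `random_state = 42`).
#'
#' @param fold_change_threshold seasonal screen ratio threshold (default 2).
#' @param alpha significance level (default 0.05).
#' @param sffs_k number of metabolites the sequential selection keeps
#'   (default 10).
#' @param top_k_overlap selections per item entering overlap counting
#'   (default 5).
#' @param fingerprint_bits,fingerprint_radius circular fingerprint fold size
#'   and radius (defaults 4096, 2).
#' @param umap named list of embedding hyperparameters.
#' @param background_n background compounds per draw (default 1000; bounded
#'   by the bundled library size).
#' @param background_repeats independent background draws (default 3).
#' @param nondetect_policy see [apply_nondetect_policy()] (default "zero").
#' @param rng_seed integer master seed.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(fold_change_threshold = 2, alpha = 0.05,
                            sffs_k = 10L, top_k_overlap = 5L,
                            fingerprint_bits = 4096L, fingerprint_radius = 2L,
                            umap = list(n_components = 2L, n_neighbors = 3L,
                                        min_dist = 0.5, metric = "manhattan",
                                        random_state = 42L),
                            background_n = 1000L, background_repeats = 3L,
                            nondetect_policy = "zero", rng_seed = 1L) {
  cfg <- list(fold_change_threshold = fold_change_threshold, alpha = alpha,
              sffs_k = as.integer(sffs_k),
              top_k_overlap = as.integer(top_k_overlap),
              fingerprint_bits = as.integer(fingerprint_bits),
              fingerprint_radius = as.integer(fingerprint_radius),
              umap = modifyList(list(n_components = 2L, n_neighbors = 3L,
                                     min_dist = 0.5, metric = "manhattan",
                                     random_state = 42L), umap),
              background_n = as.integer(background_n),
              background_repeats = as.integer(background_repeats),
              nondetect_policy = nondetect_policy,
              rng_seed = as.integer(rng_seed))
  counts <- c(cfg$sffs_k, cfg$top_k_overlap, cfg$fingerprint_bits,
              cfg$fingerprint_radius, cfg$background_n, cfg$background_repeats)
  if (any(counts <= 0L)) stop("all counts must be positive")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$fold_change_threshold <= 0) stop("fold_change_threshold must be > 0")
  if (!cfg$nondetect_policy %in% c("zero", "half_min", "drop_metabolite"))
    stop("unknown nondetect_policy: ", cfg$nondetect_policy)
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are an error; missing keys take the [analysis_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), c(known, "inputs", "scenario", "out_dir"))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- do.call(analysis_config, raw[intersect(names(raw), known)])
  attr(cfg, "inputs") <- raw$inputs
  attr(cfg, "scenario") <- raw$scenario
  attr(cfg, "out_dir") <- raw$out_dir
  cfg
}
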