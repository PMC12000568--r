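#' Count overlapping selections across the items of each property group
#'
#' For every measurement item, the first `top_k` metabolites of its selection
#' order are taken; within each property group the appearances of each
#' metabolite are counted and the most-overlapping metabolite(s) reported
#' (ties all listed).
#'
#' @param traces named list of [sffs_select()] results (or character vectors
#'   of ordered selections), one per item.
#' @param groups named character vector item -> property group.
#' @param top_k selections per item to consider (default 5).
#' @return object of class `overlap_result`: per group, `counts` (named,
#'   decreasing) and `top` (argmax metabolite id(s) with their count).
#' @export
overlap_count <- function(traces, groups, top_k = 5L) {
  if (top_k < 1L) stop("top_k must be >= 1")
  items <- names(groups)
  if (!all(items %in% names(traces)))
    stop("traces missing for items: ",
         paste(setdiff(items, names(traces)), collapse = ", "))
  picks <- lapply(traces[items], function(tr) {
    sel <- if (inherits(tr, "selection_trace")) tr$selected else as.character(tr)
    if (length(sel) < top_k)
      message("selection shorter than top_k; using all ", length(sel))
    head(sel, top_k)
  })
  out <- lapply(split(items, groups[items]), function(its) {
    counts <- sort(table(unlist(picks[its])), decreasing = TRUE)
    counts <- setNames(as.integer(counts), names(counts))
    top <- counts[counts == max(counts)]
    list(counts = counts, top = top, n_items = length(its))
  })
  structure(out, class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  for (g in names(x))
    cat(g, ": ", paste(names(x[[g]]$top), collapse = " / "),
        " appears ", x[[g]]$top[1L], " times among ", x[[g]]$n_items,
        " items\n", sep = "")
  invisible(x)
}

#' Circular (Morgan) fingerprints from SMILES
#'
#' Folded circular-substructure bit vectors (extended-connectivity
#' fingerprints of the given radius; radius 2 is the ECFP4-equivalent
#' default), computed with the Open Babel command-line tool in a single
#' batch subprocess. Unparseable SMILES are skipped with a message, never an
#' error; the attribute `skipped` records their positions. Fold sizes below
#' the native 4096 bits are produced by OR-folding.
#'
#' @param smiles character vector of SMILES (names become row names).
#' @param n_bits fingerprint length (default 4096).
#' @param radius circular radius (default 2).
#' @return integer 0/1 matrix, one row per parseable SMILES, with attribute
#'   `skipped` (indices of SMILES that failed to parse).
#' @export
morgan_fingerprint <- function(smiles, n_bits = 4096L, radius = 2L) {
  stopifnot(n_bits >= 1L, radius >= 0L)
  if (Sys.which("obabel") == "")
    stop("the 'obabel' executable is required for fingerprinting")
  fp_name <- paste0("ECFP", 2L * radius)
  writable <- which(!is.na(smiles) & nzchar(smiles) & !grepl("\\s", smiles))
  smi_file <- tempfile(fileext = ".smi")
  out_file <- tempfile(fileext = ".fpt")
  on.exit(unlink(c(smi_file, out_file)), add = TRUE)
  writeLines(sprintf("%s idx%d", smiles[writable], writable), smi_file)
  suppressWarnings(system2("obabel",
                           c(smi_file, "-ofpt", paste0("-xf", fp_name),
                             "-xh", "-e", "-O", out_file),
                           stdout = FALSE, stderr = FALSE))
  lines <- if (file.exists(out_file)) readLines(out_file) else character(0)
  heads <- grep("^>", lines)
  hex_rx <- "^[0-9a-fA-F]{8}( [0-9a-fA-F]{8})*\\s*$"
  rows <- list(); got <- integer(0)
  for (h in seq_along(heads)) {
    idx <- as.integer(sub("^>idx(\\d+).*$", "\\1", lines[heads[h]]))
    to <- if (h < length(heads)) heads[h + 1L] - 1L else length(lines)
    block <- lines[(heads[h] + 1L):to]
    hex <- paste(gsub(" ", "", block[grepl(hex_rx, block)]), collapse = "")
    if (nchar(hex) != 1024L) next        # 4096 bits = 1024 hex digits
    nib <- strtoi(strsplit(hex, "")[[1]], 16L)
    bits <- as.integer(rbind(bitwAnd(nib, 8L) > 0L, bitwAnd(nib, 4L) > 0L,
                             bitwAnd(nib, 2L) > 0L, bitwAnd(nib, 1L) > 0L))
    got <- c(got, idx)
    rows[[length(rows) + 1L]] <- bits
  }
  keep <- intersect(seq_along(smiles), sort(got))
  skipped <- setdiff(seq_along(smiles), keep)
  if (length(skipped))
    message(length(skipped), " SMILES could not be parsed and were skipped")
  fp <- do.call(rbind, rows[match(keep, got)])
  if (is.null(fp)) fp <- matrix(integer(0), 0L, 4096L)
  rownames(fp) <- if (!is.null(names(smiles))) names(smiles)[keep] else
    as.character(keep)
  if (n_bits < ncol(fp)) {                    # OR-fold down to n_bits
    grp <- ((seq_len(ncol(fp)) - 1L) %% n_bits) + 1L
    folded <- matrix(0L, nrow(fp), n_bits, dimnames = list(rownames(fp), NULL))
    for (j in seq_len(ncol(fp)))
      folded[, grp[j]] <- as.integer(folded[, grp[j]] | fp[, j])
    fp <- folded
  }
  attr(fp, "skipped") <- skipped
  fp
}

#' 2-D UMAP embedding of fingerprints
#'
#' Uniform Manifold Approximation and Projection with the configured
#' hyperparameters (defaults: 2 components, 3 neighbors, min_dist 0.5,
#' manhattan metric, random_state 42). Runs single-threaded so repeated calls
#' with the same seed are bit-identical.
#'
#' @param fingerprints numeric matrix, one row per compound.
#' @param params named list overriding the [analysis_config()] `umap`
#'   defaults.
#' @return n x 2 coordinate matrix (columns `UMAP1`, `UMAP2`).
#' @export
umap_embed <- function(fingerprints, params = list()) {
  pp <- modifyList(analysis_config()$umap, params)
  fingerprints <- as.matrix(fingerprints)
  if (nrow(fingerprints) < pp$n_neighbors + 1L)
    stop("need at least n_neighbors + 1 points to embed")
  set.seed(pp$random_state)
  coords <- uwot::umap(fingerprints, n_components = pp$n_components,
                       n_neighbors = pp$n_neighbors, min_dist = pp$min_dist,
                       metric = pp$metric, n_threads = 1, n_sgd_threads = 1)
  colnames(coords) <- paste0("UMAP", seq_len(ncol(coords)))
  rownames(coords) <- rownames(fingerprints)
  coords
}

#' Per-axis rank comparison of two embedded groups
#'
#' Two-sample two-tailed Wilcoxon rank-sum test of the coordinates of the two
#' membership groups, per embedding axis.
#'
#' @param coords n x 2 coordinate matrix.
#' @param membership logical or two-level vector splitting the rows.
#' @return data.frame with axis, statistic, p.
#' @export
axis_comparison <- function(coords, membership) {
  g <- as.factor(membership)
  if (nlevels(g) != 2L || any(table(g) < 1L))
    stop("membership must split the rows into two nonempty groups")
  do.call(rbind, lapply(seq_len(ncol(coords)), function(ax) {
    wt <- stats::wilcox.test(coords[g == levels(g)[1L], ax],
                             coords[g == levels(g)[2L], ax],
                             alternative = "two.sided", exact = FALSE)
    data.frame(axis = colnames(coords)[ax], statistic = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  }))
}

#' Per-axis SD ratio of a selected subset vs all embedded metabolites
#'
#' Population SDs of the subset's coordinates divided by those of the full
#' set, per axis — the diversity measure of a selection (SD_SS / SD_all). A
#' subset equal to the full set gives exactly (1, 1).
#'
#' @param coords coordinates of all latex metabolites (rows named by
#'   metabolite id).
#' @param selected_ids subset of row names, length >= 2.
#' @return numeric vector of per-axis ratios.
#' @export
sd_ratio <- function(coords, selected_ids) {
  if (length(selected_ids) < 2L) stop("need at least 2 selected metabolites")
  if (!all(selected_ids %in% rownames(coords)))
    stop("selected ids missing from the embedding: ",
         paste(setdiff(selected_ids, rownames(coords)), collapse = ", "))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  sub <- coords[selected_ids, , drop = FALSE]
  setNames(vapply(seq_len(ncol(coords)), function(ax)
    pop_sd(sub[, ax]) / pop_sd(coords[, ax]), 0), colnames(coords))
}

#' Chemical-space diversity of selected metabolites
#'
#' Fingerprints the annotated latex metabolites, draws background compound
#' sets from the bundled library (`background_repeats` independent draws),
#' embeds latex + background together per draw, tests each axis between the
#' two populations, and computes per-item and per-group SD ratios of the
#' metabolites each item's sequential selection picked (subset ids are
#' intersected with the embeddable metabolites).
#'
#' @param annotation annotation data.frame with `metabolite_id` and `smiles`.
#' @param selections named list: item id -> character vector of selected
#'   metabolite ids (e.g. from [model_complexity()] traces).
#' @param groups named character vector item -> property group.
#' @param config an [analysis_config()].
#' @return object of class `diversity_result`: `coords` (latex metabolites,
#'   from the first draw's joint embedding), `axis_tests` (per draw),
#'   `sd_ratios_item`, `sd_ratios_group` (data.frames), `n_embedded`.
#' @export
diversity_analysis <- function(annotation, selections, groups,
                               config = analysis_config()) {
  ann <- annotation[!is.na(annotation$smiles), ]
  fps <- morgan_fingerprint(setNames(ann$smiles, ann$metabolite_id),
                            config$fingerprint_bits, config$fingerprint_radius)
  n_latex <- nrow(fps)
  axis_tests <- vector("list", config$background_repeats)
  coords_latex <- NULL
  for (r in seq_len(config$background_repeats)) {
    bg <- generate_structures(config$background_n,
                              stage_seed(config$rng_seed,
                                         paste0("background", r)))
    bg_fp <- morgan_fingerprint(bg, config$fingerprint_bits,
                                config$fingerprint_radius)
    all_fp <- rbind(fps, bg_fp)
    coords <- umap_embed(all_fp, config$umap)
    member <- rep(c("latex_metabolite", "background"),
                  c(n_latex, nrow(bg_fp)))
    at <- axis_comparison(coords, member)
    at$draw <- r
    axis_tests[[r]] <- at
    if (r == 1L) coords_latex <- coords[seq_len(n_latex), , drop = FALSE]
  }
  embeddable <- rownames(coords_latex)
  ratio_row <- function(ids) {
    ids <- intersect(ids, embeddable)
    if (length(ids) < 2L) return(c(NA_real_, NA_real_))
    sd_ratio(coords_latex, ids)
  }
  per_item <- do.call(rbind, lapply(names(selections), function(it) {
    rr <- ratio_row(selections[[it]])
    data.frame(item_id = it, group = unname(groups[it]),
               sd_ratio_1 = rr[1L], sd_ratio_2 = rr[2L],
               stringsAsFactors = FALSE)
  }))
  per_group <- do.call(rbind, lapply(split(names(selections), groups[names(selections)]),
    function(its) {
      rr <- ratio_row(unique(unlist(selections[its])))
      data.frame(group = unname(groups[its[1L]]),
                 sd_ratio_1 = rr[1L], sd_ratio_2 = rr[2L],
                 stringsAsFactors = FALSE)
    }))
  structure(list(coords = coords_latex,
                 axis_tests = do.call(rbind, axis_tests),
                 sd_ratios_item = per_item, sd_ratios_group = per_group,
                 n_embedded = n_latex),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("<diversity_result> ", x$n_embedded, " metabolites embedded; ",
      nrow(x$sd_ratios_item), " item-level SD ratios; ",
      max(x$axis_tests$draw), " background draws\n", sep = "")
  invisible(x)
}
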