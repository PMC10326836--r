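#' Read a composition table from TSV/CSV
#'
#' Expects a header row of taxon ids and a first column of host ids.
#' Values are validated as a composition table (rows on the simplex).
#'
#' @param path File path; the delimiter is taken from the extension
#'   (`.csv` = comma, otherwise tab) unless `sep` is given.
#' @param sep Optional field separator.
#' @param floor Validation floor passed to [composition_table()].
#' @return A validated composition matrix.
#' @export
read_composition <- function(path, sep = NULL, floor = 1e-5) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  composition_table(as.matrix(df), floor = floor)
}

#' Write a composition table to TSV
#' @param table Composition matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(table, path) {
  df <- data.frame(host = rownames(table), as.data.frame(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Preprocessing configuration
#'
#' @param min_samples_per_species Minimum samples required to retain a
#'   species (default 2).
#' @param min_taxon_fraction Keep taxa whose share of the total abundance
#'   across retained species exceeds this (default 0.01, i.e. 1%).
#' @param floor Detection floor for absent taxa (default 1e-5 = 0.001%).
#' @param renormalize Renormalize rows to 1 after flooring (default TRUE;
#'   the model requires simplex rows).
#' @return A list of class `phylosym_prep_config`.
#' @export
prep_config <- function(min_samples_per_species = 2,
                        min_taxon_fraction = 0.01,
                        floor = 1e-5, renormalize = TRUE) {
  if (floor >= min_taxon_fraction)
    stop("floor must be below min_taxon_fraction", call. = FALSE)
  structure(list(min_samples_per_species = min_samples_per_species,
                 min_taxon_fraction = min_taxon_fraction,
                 floor = floor, renormalize = renormalize),
            class = "phylosym_prep_config")
}

#' Prepare a per-species composition table from a sample table
#'
#' Applies the preprocessing pipeline of the empirical analysis:
#' (1) drop species with fewer than `min_samples_per_species` samples;
#' (2) average the sample rows of each retained species;
#' (3) keep taxa whose share of the summed abundance across retained
#' species exceeds `min_taxon_fraction`;
#' (4) raise entries below the detection `floor` (including exact zeros,
#' i.e. absent taxa) to the floor; (5) renormalize rows to the simplex.
#'
#' @param samples A data.frame with columns `sample_id`, `host_species`,
#'   optionally `source` (wild/captive) and `study_id`, and one numeric
#'   column per taxon; each sample row must sum to 1 within 1e-6. A
#'   numeric matrix with host-species rownames is also accepted (one
#'   sample per row).
#' @param cfg A [prep_config()].
#' @param source_filter Optional: keep only samples whose `source` equals
#'   this value (e.g. "wild").
#' @param one_sample If `TRUE`, pick one random sample per species
#'   instead of averaging (robustness variant); uses `seed`.
#' @param seed Seed for `one_sample`.
#' @return List with `table` (validated composition matrix) and `report`
#'   (species/taxa dropped at each step and the retained-abundance
#'   fraction).
#' @export
prepare_table <- function(samples, cfg = prep_config(), source_filter = NULL,
                          one_sample = FALSE, seed = 1) {
  if (is.matrix(samples)) {
    samples <- data.frame(sample_id = paste0("s", seq_len(nrow(samples))),
                          host_species = rownames(samples),
                          as.data.frame(samples), check.names = FALSE)
  }
  stopifnot(is.data.frame(samples))
  meta_cols <- intersect(c("sample_id", "host_species", "source", "study_id"),
                         colnames(samples))
  if (!all(c("sample_id", "host_species") %in% meta_cols))
    stop("samples needs sample_id and host_species columns", call. = FALSE)
  taxa <- setdiff(colnames(samples), meta_cols)
  if (length(taxa) == 0) stop("no taxon columns found", call. = FALSE)
  if (!is.null(source_filter) && "source" %in% meta_cols)
    samples <- samples[samples$source %in% source_filter, , drop = FALSE]
  if (nrow(samples) == 0) stop("no samples left after filtering", call. = FALSE)

  M <- as.matrix(samples[, taxa, drop = FALSE])
  storage.mode(M) <- "double"
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-6))
    stop("sample rows must sum to 1 within 1e-6 (worst deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)

  counts <- table(samples$host_species)
  keep_sp <- names(counts)[counts >= cfg$min_samples_per_species]
  dropped_sp <- setdiff(names(counts), keep_sp)
  if (length(keep_sp) == 0)
    stop("no species retained: all have fewer than ",
         cfg$min_samples_per_species, " samples", call. = FALSE)
  sel <- samples$host_species %in% keep_sp
  M <- M[sel, , drop = FALSE]
  sp <- samples$host_species[sel]

  if (one_sample) {
    set.seed(seed)
    pick <- vapply(split(seq_along(sp), sp), function(idx)
      idx[sample.int(length(idx), 1)], integer(1))
    avg <- M[pick, , drop = FALSE]
    rownames(avg) <- names(pick)
  } else {
    avg <- rowsum(M, sp) / as.vector(table(sp)[sort(unique(sp))])
    rownames(avg) <- sort(unique(sp))
  }

  shares <- colSums(avg) / sum(avg)
  keep_tx <- names(shares)[shares > cfg$min_taxon_fraction]
  dropped_tx <- setdiff(taxa, keep_tx)
  if (length(keep_tx) == 0) stop("no taxa retained", call. = FALSE)
  retained_fraction <- sum(shares[keep_tx])
  out <- avg[, keep_tx, drop = FALSE]

  out[out < cfg$floor] <- cfg$floor
  if (cfg$renormalize) out <- out / rowSums(out)

  # renormalization can shrink floored entries by up to 1 + p * floor
  floor_eff <- if (cfg$renormalize)
    cfg$floor / (1 + ncol(out) * cfg$floor) else cfg$floor
  list(table = composition_table(out, floor = floor_eff),
       report = list(
         n_samples = nrow(samples),
         species_retained = rownames(out),
         species_dropped = dropped_sp,
         taxa_retained = keep_tx,
         taxa_dropped = dropped_tx,
         retained_abundance_fraction = retained_fraction,
         config = unclass(cfg)))
}

#' Align a tree and a composition table
#'
#' Prunes the tree to the species shared with the table, drops table rows
#' absent from the tree (with a named warning), and reorders the rows to
#' the tip order so row i always corresponds to tip i.
#'
#' @param tree Host phylogeny.
#' @param table Composition matrix with host rownames.
#' @return List with `tree` (pruned) and `table` (reordered).
#' @export
align <- function(tree, table) {
  table <- as.matrix(table)
  shared <- intersect(tree$tip.label, rownames(table))
  if (length(shared) == 0)
    stop("no species shared between tree and table", call. = FALSE)
  drop_tips <- setdiff(tree$tip.label, shared)
  drop_rows <- setdiff(rownames(table), shared)
  if (length(drop_rows) > 0)
    warning("table rows absent from the tree dropped: ",
            paste(drop_rows, collapse = ", "), call. = FALSE)
  if (length(drop_tips) > 0)
    tree <- ape::drop.tip(tree, drop_tips)
  table <- table[tree$tip.label, , drop = FALSE]
  list(tree = tree, table = table)
}

#' Fit the model on a subset of hosts
#'
#' Restricts the analysis to a named clade or to hosts passing a trait
#' predicate (e.g. nonflying species only), then fits the model on the
#' pruned tree. Subsets with fewer than `min_n` species are refused
#' unless `force = TRUE`, since the signal test is underpowered there.
#'
#' @param tree Host phylogeny (clade selection uses its node labels).
#' @param table Composition matrix.
#' @param traits Optional data.frame of per-species traits (rownames =
#'   species) for predicate filters.
#' @param clade Name of an internal node whose descendants to keep.
#' @param filter Predicate function on the traits data.frame returning a
#'   logical per species, or a character vector of species to keep.
#' @param min_n Minimum subset size (default 15).
#' @param force Override the size refusal.
#' @param ... Passed to [fit()].
#' @return A `phylosym_fit` on the subset.
#' @export
subset_run <- function(tree, table, traits = NULL, clade = NULL,
                       filter = NULL, min_n = 15, force = FALSE, ...) {
  keep <- tree$tip.label
  if (!is.null(clade)) {
    if (is.null(tree$node.label) || !(clade %in% tree$node.label))
      stop("unknown clade '", clade, "'; available: ",
           paste(utils::head(tree$node.label[nzchar(tree$node.label)], 20),
                 collapse = ", "), call. = FALSE)
    node <- length(tree$tip.label) + match(clade, tree$node.label)
    keep <- ape::extract.clade(tree, node)$tip.label
  }
  if (!is.null(filter)) {
    if (is.function(filter)) {
      if (is.null(traits)) stop("filter predicate needs traits", call. = FALSE)
      sel <- filter(traits)
      keep <- intersect(keep, rownames(traits)[which(sel)])
    } else {
      keep <- intersect(keep, as.character(filter))
    }
  }
  keep <- intersect(keep, rownames(table))
  if (length(keep) < min_n && !force)
    stop("subset has only ", length(keep), " species (< ", min_n,
         "); rerun with force = TRUE if you accept the reduced power",
         call. = FALSE)
  if (length(keep) < 2) stop("subset too small to fit", call. = FALSE)
  al <- align(ape::keep.tip(tree, keep), table[keep, , drop = FALSE])
  fit(al$tree, al$table, ...)
}

#' Read a per-species trait table
#'
#' TSV with columns `species`, `diet` (plants/fruits/invertebrates/meat),
#' `realm` (biogeographic realm) and `flying` (yes/no); extra columns are
#' kept. Rownames are set to species.
#'
#' @param path File path.
#' @return data.frame keyed by species.
#' @export
read_traits <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"species" %in% colnames(df))
    stop("trait table needs a 'species' column", call. = FALSE)
  rownames(df) <- df$species
  df
}
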