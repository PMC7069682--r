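#' Construct a site-by-species presence/absence community matrix
#'
#' @param incidence numeric matrix of 0/1 with sites as rows (named) and
#'   species as columns (named).
#' @param metadata optional data.frame of per-site metadata (one row per
#'   site, in the same order; e.g. `latitude`, `longitude`, `altitude` and
#'   free-form environment columns).
#' @return an object of class `community_matrix`.
#' @export
community_matrix <- function(incidence, metadata = NULL) {
  stopifnot(is.matrix(incidence))
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence matrix must have site row names and species column names")
  if (anyDuplicated(rownames(incidence))) stop("duplicate site labels")
  if (anyDuplicated(colnames(incidence))) stop("duplicate species labels")
  if (!all(incidence %in% c(0, 1)))
    stop("non-binary cell(s) in community matrix")
  storage.mode(incidence) <- "integer"
  rich <- rowSums(incidence)
  if (any(rich == 0))
    stop("empty site(s): ", paste(rownames(incidence)[rich == 0], collapse = ", "))
  if (!is.null(metadata)) {
    stopifnot(is.data.frame(metadata), nrow(metadata) == nrow(incidence))
    rownames(metadata) <- rownames(incidence)
  }
  structure(list(incidence = incidence, metadata = metadata),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix:", nrow(x$incidence), "sites x",
      ncol(x$incidence), "species; richness",
      min(site_richness(x)), "-", max(site_richness(x)), "\n")
  invisible(x)
}

#' Per-site species richness (row sums)
#' @param comm a `community_matrix`.
#' @return named integer vector.
#' @export
site_richness <- function(comm) rowSums(comm$incidence)

#' Species present at one site
#' @param comm a `community_matrix`.
#' @param site site label.
#' @return character vector of species present.
#' @export
site_species <- function(comm, site) {
  colnames(comm$incidence)[comm$incidence[site, ] == 1]
}

#' Read a community matrix from CSV
#'
#' Sites in rows (first column = site label), species in 0/1 columns.
#' Columns named in `metadata_cols`, plus any column holding values other
#' than 0/1 (coordinates, environment variables), are split off as per-site
#' metadata rather than species.
#'
#' @param path CSV file path.
#' @param metadata_cols column names always treated as site metadata.
#' @return a `community_matrix`.
#' @export
read_community_matrix <- function(path,
                                  metadata_cols = c("latitude", "longitude",
                                                    "altitude")) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- df[[1]]
  df[[1]] <- NULL
  nonbinary <- vapply(df, function(col)
    !is.numeric(col) || any(!col %in% c(0, 1)), logical(1))
  meta_cols <- union(intersect(metadata_cols, names(df)),
                     names(df)[nonbinary])
  meta <- if (length(meta_cols)) df[, meta_cols, drop = FALSE] else NULL
  sp <- df[, setdiff(names(df), meta_cols), drop = FALSE]
  m <- as.matrix(sp)
  if (!is.numeric(m)) stop("non-numeric species cell(s) in ", path)
  community_matrix(m, metadata = meta)
}

#' Write a community matrix to CSV
#' @param comm a `community_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(comm, path) {
  df <- as.data.frame(comm$incidence, check.names = FALSE)
  if (!is.null(comm$metadata)) df <- cbind(comm$metadata, df)
  write.csv(cbind(site = rownames(df), df), path, row.names = FALSE)
  invisible(path)
}

#' Cross-validate species labels across tree, traits and communities
#'
#' Communities reference the regional pool; trait tables may carry
#' site-suffixed species labels (a species occurring at several sites being
#' treated as distinct functional entities) that map to shared tree tips.
#' The default mapping rule strips a trailing `_S<digits>` suffix.
#'
#' @param tree a `phylo`.
#' @param traits a `trait_table`.
#' @param comm a `community_matrix`.
#' @param map_rule `"strip_site_suffix"` (default) or `"identity"`.
#' @return a list of class `dataset_report` with discrepancy vectors
#'   (`missing_from_tree`, `missing_from_traits`, `tree_only`,
#'   `trait_label_map`) and a logical `ok`.
#' @export
validate_dataset <- function(tree, traits, comm,
                             map_rule = c("strip_site_suffix", "identity")) {
  map_rule <- match.arg(map_rule)
  comm_sp <- colnames(comm$incidence)
  trait_sp <- trait_species(traits)
  mapped <- if (map_rule == "strip_site_suffix")
    sub("_S[0-9]+$", "", trait_sp) else trait_sp
  names(mapped) <- trait_sp
  rep <- list(
    missing_from_tree = sort(setdiff(comm_sp, tree$tip.label)),
    missing_from_traits = sort(setdiff(comm_sp, mapped)),
    tree_only = sort(setdiff(tree$tip.label, comm_sp)),
    trait_label_map = mapped,
    map_rule = map_rule
  )
  rep$ok <- length(rep$missing_from_tree) == 0 &&
    length(rep$missing_from_traits) == 0
  class(rep) <- "dataset_report"
  rep
}

#' @export
print.dataset_report <- function(x, ...) {
  cat("dataset_report:", if (x$ok) "labels consistent" else "discrepancies found", "\n")
  if (length(x$missing_from_tree))
    cat("  missing from tree:", paste(x$missing_from_tree, collapse = ", "), "\n")
  if (length(x$missing_from_traits))
    cat("  missing from traits:", paste(x$missing_from_traits, collapse = ", "), "\n")
  if (length(x$tree_only))
    cat("  in tree only:", length(x$tree_only), "species\n")
  invisible(x)
}
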