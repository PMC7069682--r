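#' Construct a typed species-by-trait table
#'
#' A `trait_table` couples a species x trait value matrix with a schema
#' declaring, for every trait, its kind (continuous or categorical), its
#' role in assembly inference (`alpha` = competition indicator, `beta` =
#' abiotic-tolerance indicator), and, for categorical traits, the allowed
#' states and whether they are ordered. Missing values are permitted and
#' handled downstream by pairwise deletion in the Gower distance.
#'
#' @param values data.frame with species as row names and one column per
#'   trait. Continuous traits numeric; categorical traits character/factor.
#' @param schema data.frame with columns `trait`, `kind`
#'   (`"continuous"`/`"categorical"`), `role` (`"alpha"`/`"beta"`), and for
#'   categorical traits `states` (states joined by `"|"`, in rank order if
#'   ordered) and logical `ordered`.
#' @return an object of class `trait_table`.
#' @export
trait_table <- function(values, schema) {
  stopifnot(is.data.frame(values), is.data.frame(schema))
  need <- c("trait", "kind", "role")
  if (!all(need %in% names(schema)))
    stop("schema must have columns: ", paste(need, collapse = ", "))
  if (!"ordered" %in% names(schema)) schema$ordered <- FALSE
  if (!"states" %in% names(schema)) schema$states <- NA_character_
  schema$ordered[is.na(schema$ordered)] <- FALSE
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique species row names")
  bad_kind <- setdiff(schema$kind, c("continuous", "categorical"))
  if (length(bad_kind)) stop("unknown trait kind: ", paste(bad_kind, collapse = ", "))
  bad_role <- setdiff(schema$role, c("alpha", "beta"))
  if (length(bad_role)) stop("trait role must be alpha or beta, got: ",
                             paste(bad_role, collapse = ", "))
  undeclared <- setdiff(names(values), schema$trait)
  if (length(undeclared))
    stop("undeclared trait column(s): ", paste(undeclared, collapse = ", "))
  absent <- setdiff(schema$trait, names(values))
  if (length(absent))
    stop("trait(s) declared but absent from values: ",
         paste(absent, collapse = ", "))
  values <- values[, schema$trait, drop = FALSE]
  for (i in seq_len(nrow(schema))) {
    tr <- schema$trait[i]
    col <- values[[tr]]
    if (schema$kind[i] == "continuous") {
      if (is.character(col)) {
        col[!nzchar(trimws(col))] <- NA
        num <- suppressWarnings(as.numeric(col))
        if (any(is.na(num) & !is.na(col)))
          stop("non-numeric value in continuous trait '", tr, "'")
        col <- num
      }
      if (!is.numeric(col)) stop("continuous trait '", tr, "' is not numeric")
      if (any(!is.finite(col) & !is.na(col)))
        stop("non-finite value in continuous trait '", tr, "'")
      values[[tr]] <- as.numeric(col)
    } else {
      states <- trait_states(schema, tr)
      if (!length(states)) stop("categorical trait '", tr, "' declares no states")
      col <- as.character(col)
      col[!is.na(col) & !nzchar(trimws(col))] <- NA
      bad <- setdiff(stats::na.omit(unique(col)), states)
      if (length(bad))
        stop("trait '", tr, "': value(s) outside declared states: ",
             paste(bad, collapse = ", "))
      values[[tr]] <- col
    }
  }
  empty <- rowSums(!is.na(values)) == 0
  if (any(empty))
    stop("species with no trait values: ",
         paste(rownames(values)[empty], collapse = ", "))
  structure(list(values = values, schema = schema), class = "trait_table")
}

trait_states <- function(schema, trait) {
  s <- schema$states[schema$trait == trait]
  if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", nrow(x$values), "species x", nrow(x$schema), "traits (",
      sum(x$schema$role == "alpha"), "alpha,",
      sum(x$schema$role == "beta"), "beta )\n")
  invisible(x)
}

#' Species labels of a trait table
#' @param traits a `trait_table`.
#' @return character vector of species labels.
#' @export
trait_species <- function(traits) rownames(traits$values)

#' Read a trait table from a values CSV and a schema CSV
#'
#' The values file has species in the first column and traits in the
#' remaining columns; empty cells are missing. The schema file has columns
#' `trait`, `kind`, `role`, `states` (pipe-separated), `ordered`.
#'
#' @param values_path,schema_path file paths.
#' @return a `trait_table`.
#' @export
read_trait_table <- function(values_path, schema_path) {
  if (!file.exists(values_path)) stop("trait values file not found: ",
                                      values_path)
  if (!file.exists(schema_path)) stop("trait schema file not found: ",
                                      schema_path)
  vals <- read.csv(values_path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "")
  rownames(vals) <- vals[[1]]
  vals[[1]] <- NULL
  schema <- read.csv(schema_path, stringsAsFactors = FALSE, na.strings = "")
  if ("ordered" %in% names(schema)) schema$ordered <- as.logical(schema$ordered)
  trait_table(vals, schema)
}

#' Write a trait table to values and schema CSV files
#' @param traits a `trait_table`.
#' @param values_path,schema_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_trait_table <- function(traits, values_path, schema_path) {
  out <- cbind(species = rownames(traits$values), traits$values)
  write.csv(out, values_path, row.names = FALSE, na = "")
  write.csv(traits$schema, schema_path, row.names = FALSE, na = "")
  invisible(c(values_path, schema_path))
}

#' Subset a trait table by role
#'
#' Partitions traits into competition indicators (`alpha`) and
#' abiotic-tolerance indicators (`beta`).
#'
#' @param traits a `trait_table`.
#' @param role `"alpha"`, `"beta"` or `"all"`.
#' @return a `trait_table` with the selected columns; `role = "all"` returns
#'   the input unchanged.
#' @export
partition_traits <- function(traits, role = c("all", "alpha", "beta")) {
  role <- match.arg(role)
  if (role == "all") return(traits)
  keep <- traits$schema$role == role
  if (!any(keep)) stop("no traits with role '", role, "'")
  trait_table(traits$values[, traits$schema$trait[keep], drop = FALSE],
              traits$schema[keep, , drop = FALSE])
}

#' Standardize continuous traits to mean 0, sample SD 1
#'
#' Computed over non-missing values; categorical traits pass through
#' untouched. Idempotent.
#'
#' @param traits a `trait_table`.
#' @return a `trait_table` with standardized continuous traits.
#' @export
standardize_traits <- function(traits) {
  vals <- traits$values
  for (i in seq_len(nrow(traits$schema))) {
    if (traits$schema$kind[i] != "continuous") next
    tr <- traits$schema$trait[i]
    x <- vals[[tr]]
    ok <- !is.na(x)
    if (sum(ok) < 2) stop("trait '", tr, "': fewer than 2 non-missing values")
    s <- sd(x[ok])
    if (s == 0) stop("trait '", tr, "' is constant (SD = 0)")
    vals[[tr]] <- (x - mean(x[ok])) / s
  }
  trait_table(vals, traits$schema)
}
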