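#' Read a rooted phylogeny from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is the
#' shared scaffold for every likelihood and covariance in the package, so the
#' invariants are enforced here once: unique tip labels, branch lengths present,
#' finite and non-negative. Polytomies are allowed; internal node labels are
#' ignored for identity.
#'
#' @param path Path to a Newick file.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop("malformed Newick in '", path, "': ", conditionMessage(e))
  )
  if (is.null(tree)) stop("malformed Newick in '", path, "': no tree parsed")
  validate_tree(tree)
  tree
}

#' Validate the tree invariants used throughout the package
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly, if valid. Errors otherwise.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; a Newick with explicit lengths is required")
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop("tree has missing or non-finite branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 tips")
  invisible(tree)
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Species-by-species matrix whose diagonal holds root-to-tip distances and
#' whose off-diagonal entries hold shared path lengths. This is the covariance
#' of a unit-rate Brownian motion evolving along the tree, the residual
#' structure assumed by PGLS and the path analyses.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  ape::vcv.phylo(tree)
}

#' Schema of the canonical trait table
#'
#' Named list mapping column names to types: `"integer"` columns must hold
#' integer values, `"numeric"` columns any finite number, `"positive"` strictly
#' positive numbers, `"nonnegative"` numbers `>= 0`.
#'
#' @return A named character vector of column types.
#' @export
trait_schema <- function() {
  c(chrom_n = "integer",
    BIO1 = "numeric", BIO4 = "numeric", BIO7 = "numeric", BIO12 = "numeric",
    culm = "positive", spike = "positive",
    div_rate = "numeric",
    r_chrom = "nonnegative", r_BIO4 = "nonnegative",
    r_culm = "nonnegative", r_spike = "nonnegative")
}

#' Read a species-by-variable trait table
#'
#' Reads a delimited text file with a header and a `species` column, checks
#' each column present in `schema` for its declared type, and errors with the
#' offending rows and columns rather than coercing silently. Columns not named
#' in the schema are read as-is.
#'
#' @param path Path to a delimited text file.
#' @param schema Named character vector of column types, see
#'   [trait_schema()]. Only columns present in the file are checked.
#' @param sep Field separator, default comma.
#' @return A data.frame with one row per species.
#' @export
read_trait_table <- function(path, schema = trait_schema(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"species" %in% names(tab)) stop("trait table must have a 'species' column")
  if (anyDuplicated(tab$species)) {
    stop("duplicated species: ",
         paste(unique(tab$species[duplicated(tab$species)]), collapse = ", "))
  }
  for (col in intersect(names(schema), names(tab))) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric values in column '", col, "' at rows: ",
           paste(head(bad, 5), collapse = ", "))
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop("missing or non-finite values in column '", col, "' at rows: ",
           paste(head(which(!is.finite(v)), 5), collapse = ", "))
    }
    type <- schema[[col]]
    if (type == "integer" && any(v != round(v))) {
      stop("column '", col, "' must be integer-valued; offending rows: ",
           paste(head(which(v != round(v)), 5), collapse = ", "))
    }
    if (type == "positive" && any(v <= 0)) {
      stop("column '", col, "' must be > 0; offending rows: ",
           paste(head(which(v <= 0), 5), collapse = ", "))
    }
    if (type == "nonnegative" && any(v < 0)) {
      stop("column '", col, "' must be >= 0; offending rows: ",
           paste(head(which(v < 0), 5), collapse = ", "))
    }
  }
  tab
}

#' Check that a trait table and a tree describe the same species
#'
#' Reports set differences instead of silently dropping rows or tips.
#'
#' @param table A trait table (data.frame with a `species` column).
#' @param tree A `phylo` object.
#' @return Invisibly, a list with elements `extra_in_table` and
#'   `missing_from_table`. Errors if either is non-empty and `strict = TRUE`.
#' @param strict If `TRUE` (default) any mismatch is an error.
#' @export
validate_traits <- function(table, tree, strict = TRUE) {
  extra <- setdiff(table$species, tree$tip.label)
  missing <- setdiff(tree$tip.label, table$species)
  if (strict && (length(extra) || length(missing))) {
    stop("species mismatch between table and tree.",
         if (length(extra)) paste0(" In table but not tree: ",
                                   paste(extra, collapse = ", "), "."),
         if (length(missing)) paste0(" In tree but not table: ",
                                     paste(missing, collapse = ", "), "."))
  }
  invisible(list(extra_in_table = extra, missing_from_table = missing))
}
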