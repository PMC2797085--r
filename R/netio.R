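#' @importFrom Matrix sparseMatrix rowSums colSums t Diagonal
#' @importFrom stats cor ks.test phyper rbeta rbinom runif setNames
#' @importFrom utils read.delim write.table head
NULL

# ---------------------------------------------------------------------------
# Data model: weighted PPI network, disease similarity matrix, association
# table, candidate intervals, gene-set collections.
# ---------------------------------------------------------------------------

#' Construct a weighted protein interaction network
#'
#' Builds an undirected, weighted network from an edge table. Edge weights are
#' interaction confidences in (0, 1]. Self-loops are dropped, duplicate pairs
#' are collapsed to the maximum weight (best evidence wins), and proteins left
#' with zero degree are removed, because the degree normalization used by the
#' propagation step is undefined for them.
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`, `weight`.
#' @param quiet suppress messages about dropped rows.
#' @return An object of class `weighted_network` with elements `proteins`
#'   (ordered character vector), `W` (sparse symmetric adjacency, zero
#'   diagonal) and `edges` (canonical de-duplicated edge table).
#' @export
weighted_network <- function(edges, quiet = FALSE) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0L) stop("no edges")
  edges <- data.frame(
    protein_a = as.character(edges[[1]]),
    protein_b = as.character(edges[[2]]),
    weight    = as.numeric(edges[[3]]),
    stringsAsFactors = FALSE
  )
  if (anyNA(edges$weight) || anyNA(edges$protein_a) || anyNA(edges$protein_b))
    stop("malformed edge table: NA values")
  if (any(edges$weight <= 0 | edges$weight > 1))
    stop("edge weights must lie in (0, 1]")

  loops <- edges$protein_a == edges$protein_b
  if (any(loops)) {
    if (!quiet) warning(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0L) stop("no edges")

  # canonical unordered pair, max-weight de-duplication
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  key <- paste(a, b, sep = "\r")
  w <- tapply(edges$weight, key, max)
  ndup <- nrow(edges) - length(w)
  if (ndup > 0L && !quiet)
    message(sprintf("collapsed %d duplicate pair(s), keeping maximum weight", ndup))
  uk <- strsplit(names(w), "\r", fixed = TRUE)
  edges <- data.frame(
    protein_a = vapply(uk, `[`, "", 1L),
    protein_b = vapply(uk, `[`, "", 2L),
    weight    = as.numeric(w),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
  rownames(edges) <- NULL

  proteins <- sort(unique(c(edges$protein_a, edges$protein_b)))
  i <- match(edges$protein_a, proteins)
  j <- match(edges$protein_b, proteins)
  W <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = rep(edges$weight, 2L),
    dims = c(length(proteins), length(proteins)),
    dimnames = list(proteins, proteins)
  )
  structure(
    list(proteins = proteins, W = W, edges = edges),
    class = "weighted_network"
  )
}

#' Weighted node degrees
#' @param network a `weighted_network`.
#' @return Named numeric vector of weighted degrees (adjacency row sums).
#' @export
node_degrees <- function(network) {
  stopifnot(inherits(network, "weighted_network"))
  d <- Matrix::rowSums(network$W)
  names(d) <- network$proteins
  d
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d proteins, %d edges, mean weight %.3f\n",
              length(x$proteins), nrow(x$edges), mean(x$edges$weight)))
  invisible(x)
}

#' Read a weighted network from a 3-column TSV edge list
#'
#' Expected columns: protein_a, protein_b, confidence weight in (0, 1].
#' Lines starting with `#` are comments. Rows below `min_weight` are dropped
#' before the network is built.
#'
#' @param path file path.
#' @param min_weight minimum edge confidence retained (default 0, keep all).
#' @param quiet suppress load diagnostics.
#' @return A `weighted_network`.
#' @export
read_network <- function(path, min_weight = 0, quiet = FALSE) {
  tab <- read_tsv_checked(path, 3L, c("protein_a", "protein_b", "weight"))
  tab$weight <- suppressWarnings(as.numeric(tab$weight))
  bad <- which(is.na(tab$weight) | tab$weight <= 0 | tab$weight > 1)
  if (length(bad))
    stop(sprintf("%s: weight outside (0,1] or non-numeric at data row %d",
                 path, bad[1L]))
  keep <- tab$weight >= min_weight
  if (!all(keep) && !quiet)
    message(sprintf("dropped %d edge(s) below min_weight=%g", sum(!keep), min_weight))
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no edges")
  weighted_network(tab, quiet = quiet)
}

#' Write a network edge list as TSV
#' @param network a `weighted_network`.
#' @param path output path.
#' @param header optional character vector of `#` comment lines.
#' @export
write_network <- function(network, path, header = NULL) {
  stopifnot(inherits(network, "weighted_network"))
  write_tsv_commented(network$edges, path, header)
}

#' Read a disease-disease phenotype similarity matrix
#'
#' Square TSV with matching row and column disease identifiers, entries in
#' \[0, 1\], unit diagonal, and exact symmetry.
#'
#' @param path file path.
#' @return A named symmetric numeric matrix of class `disease_similarity`.
#' @export
read_similarity <- function(path) {
  m <- as.matrix(read.delim(path, row.names = 1L, check.names = FALSE,
                            comment.char = "#"))
  disease_similarity(m)
}

#' Validate a disease similarity matrix
#' @param m square numeric matrix with dimnames; entries in \[0,1\], diagonal 1.
#' @return The validated matrix, class `disease_similarity`.
#' @export
disease_similarity <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("similarity matrix needs disease identifiers on both dimensions")
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("similarity matrix must be square with matching disease order")
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0 | m > 1)) stop("similarity values must lie in [0,1]")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12)))
    stop("similarity matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-12)) stop("similarity diagonal must equal 1")
  class(m) <- c("disease_similarity", class(m))
  m
}

#' Write a similarity matrix as TSV
#' @param sims matrix from [read_similarity()] or [disease_similarity()].
#' @param path output path.
#' @export
write_similarity <- function(sims, path) {
  df <- data.frame(disease = rownames(sims), as.data.frame(unclass(sims),
                   check.names = FALSE), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a gene-disease association table
#'
#' Two-column TSV (disease, protein). Duplicate pairs collapse to one (set
#' semantics). When `network` and/or `sims` are supplied, associations that
#' reference unknown proteins or diseases are dropped with a warning, or
#' rejected when `strict = TRUE`.
#'
#' @param path file path.
#' @param network optional `weighted_network` to validate protein IDs against.
#' @param sims optional similarity matrix to validate disease IDs against.
#' @param strict error (rather than drop and warn) on unknown references.
#' @return data.frame with columns `disease`, `protein`, class
#'   `association_table`.
#' @export
read_associations <- function(path, network = NULL, sims = NULL, strict = FALSE) {
  tab <- read_tsv_checked(path, 2L, c("disease", "protein"))
  association_table(tab, network = network, sims = sims, strict = strict)
}

#' Build an association table from a data.frame
#' @inheritParams read_associations
#' @param pairs data.frame with disease and protein columns.
#' @export
association_table <- function(pairs, network = NULL, sims = NULL, strict = FALSE) {
  tab <- data.frame(disease = as.character(pairs[[1]]),
                    protein = as.character(pairs[[2]]),
                    stringsAsFactors = FALSE)
  tab <- unique(tab)
  if (!is.null(network)) {
    unknown <- !(tab$protein %in% network$proteins)
    if (any(unknown)) {
      msg <- sprintf("%d association(s) reference proteins absent from the network",
                     sum(unknown))
      if (strict) stop(msg)
      warning(paste0(msg, "; dropped"))
      tab <- tab[!unknown, , drop = FALSE]
    }
  }
  if (!is.null(sims)) {
    unknown <- !(tab$disease %in% rownames(sims))
    if (any(unknown)) {
      msg <- sprintf("%d association(s) reference diseases absent from the similarity matrix",
                     sum(unknown))
      if (strict) stop(msg)
      warning(paste0(msg, "; dropped"))
      tab <- tab[!unknown, , drop = FALSE]
    }
  }
  tab <- tab[order(tab$disease, tab$protein), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' Write an association table as TSV
#' @param assoc an `association_table`.
#' @param path output path.
#' @param header optional `#` comment lines.
#' @export
write_associations <- function(assoc, path, header = NULL) {
  write_tsv_commented(as.data.frame(assoc), path, header)
}

#' Read a candidate interval (ordered gene list, one ID per line)
#' @param path file path; `#` comments allowed.
#' @param disease optional disease ID the interval belongs to.
#' @return list with `disease` and `candidates` (ordered character vector),
#'   class `candidate_interval`.
#' @export
read_interval <- function(path, disease = NA_character_) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  candidate_interval(lines, disease)
}

#' Construct a candidate interval
#' @param candidates ordered character vector of protein IDs.
#' @param disease optional disease ID.
#' @export
candidate_interval <- function(candidates, disease = NA_character_) {
  candidates <- as.character(candidates)
  if (length(candidates) == 0L) stop("interval is empty")
  if (anyDuplicated(candidates)) stop("interval members must be unique")
  structure(list(disease = disease, candidates = candidates),
            class = "candidate_interval")
}

#' Write a candidate interval
#' @param interval a `candidate_interval`.
#' @param path output path.
#' @export
write_interval <- function(interval, path) {
  writeLines(interval$candidates, path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, member IDs. Used for
#' annotation terms and for complex collections.
#'
#' @param path file path.
#' @return named list of character vectors (class `gene_set_collection`);
#'   descriptions kept in attribute `descriptions`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 0L) < 3L
  if (any(short))
    stop(sprintf("%s: GMT line %d has fewer than 3 fields", path, which(short)[1L]))
  nm <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  structure(sets, class = "gene_set_collection",
            descriptions = setNames(vapply(parts, `[`, "", 2L), nm))
}

#' Construct a gene-set collection from a named list
#' @param sets named list of character vectors.
#' @param descriptions optional named character vector.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(sets, class = "gene_set_collection", descriptions = descriptions)
}

#' Write a gene-set collection as GMT
#' @param sets a `gene_set_collection` (or named list).
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Read a numeric matrix with row and column labels from TSV
#'
#' Used for gene-by-condition expression tables and gene-by-species binary
#' phylogenetic profiles.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(read.delim(path, row.names = 1L, check.names = FALSE,
                            comment.char = "#"))
  storage.mode(m) <- "double"
  m
}

#' Write a labelled numeric matrix as TSV
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# --- internal helpers -------------------------------------------------------

read_tsv_checked <- function(path, ncol_expect, col_names) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (length(lines) == 0L) {
    if (identical(col_names[1L], "protein_a")) stop("no edges")
    stop(sprintf("%s: empty file", path))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # also tolerate whitespace-separated files
  bad <- vapply(parts, length, 0L) != ncol_expect
  if (any(bad)) {
    parts2 <- strsplit(lines, "[[:space:]]+")
    bad2 <- vapply(parts2, length, 0L) != ncol_expect
    if (any(bad2)) {
      ln <- which(keep)[which(bad2)[1L]]
      stop(sprintf("%s: malformed row at line %d (expected %d fields)",
                   path, ln, ncol_expect))
    }
    parts <- parts2
  }
  # drop a header row if the last expected-numeric field is non-numeric
  first <- parts[[1L]]
  if (identical(tolower(first), tolower(col_names)) ||
      (col_names[length(col_names)] == "weight" &&
       is.na(suppressWarnings(as.numeric(first[length(first)])))))
    parts <- parts[-1L]
  if (length(parts) == 0L) {
    if (identical(col_names[1L], "protein_a")) stop("no edges")
    stop(sprintf("%s: no data rows", path))
  }
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- col_names
  out
}

write_tsv_commented <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}
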