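#' @keywords internal
"_PACKAGE"

# ---- domain-type validators -------------------------------------------------

#' Validate a count matrix
#'
#' A count matrix is an integer-valued base matrix with unique gene row names
#' and unique sample column names, containing no negative entries. This is the
#' pipeline's entry point: the hand-off stage of an RNA-seq workflow after
#' read counting.
#'
#' @param counts numeric matrix with rownames (genes) and colnames (samples).
#' @return The validated matrix, invisibly usable downstream.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers")
  bad <- which(counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  counts
}

#' Validate a design table against a count matrix
#'
#' @param design data.frame with columns sample_id, dose (0 = control, in the
#'   units of the dose grid, conventionally micromolar) and replicate.
#' @param counts optional companion count matrix; every sample_id must appear
#'   among its columns.
#' @return The validated design, doses coerced to numeric.
#' @export
validate_design <- function(design, counts = NULL) {
  need <- c("sample_id", "dose", "replicate")
  if (!all(need %in% names(design)))
    stop("design requires columns: ", paste(need, collapse = ", "))
  design$dose <- as.numeric(design$dose)
  if (any(design$dose < 0)) stop("doses must be nonnegative")
  if (!any(design$dose == 0)) stop("design must contain a dose-0 control arm")
  arm_n <- table(design$dose)
  if (any(arm_n < 2))
    stop("every dose arm needs at least 2 replicates; offending dose(s): ",
         paste(names(arm_n)[arm_n < 2], collapse = ", "))
  if (!is.null(counts) && !all(design$sample_id %in% colnames(counts)))
    stop("design sample_id(s) absent from count matrix: ",
         paste(setdiff(design$sample_id, colnames(counts)), collapse = ", "))
  design
}

# ---- counts -----------------------------------------------------------------

#' Read a gene-by-sample count matrix from TSV
#'
#' First column holds gene identifiers, the header row holds sample
#' identifiers, and cells are nonnegative integers. Duplicate gene
#' identifiers, negative and non-integer cells are rejected with an error
#' naming the offending row/column.
#'
#' @param path TSV file path.
#' @return Integer matrix, genes as rows.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count file needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count at gene '%s', column '%s'",
                 genes[bad[1]], colnames(m)[bad[2]]))
  }
  rownames(m) <- genes
  validate_counts(m)
}

#' Write a count matrix to TSV
#' @param counts validated count matrix.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a design table from CSV (columns sample_id, dose, replicate)
#' @param path CSV path.
#' @param counts optional count matrix to validate against.
#' @export
read_design <- function(path, counts = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_design(df, counts)
}

#' Write a design table to CSV
#' @param design design data.frame.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design[, c("sample_id", "dose", "replicate")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- gene sets (GMT) --------------------------------------------------------

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated "name, description,
#' members...". Blank member fields are dropped; lines with fewer than three
#' fields and duplicate set names are errors.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: list with `sets` (named list of unique
#'   member character vectors) and `desc` (named descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need >= 3", i, length(f)))
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(members) == 0) stop(sprintf("GMT line %d: empty member list", i))
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#' @param sets named list of member character vectors.
#' @param desc named character descriptions (defaults to set names).
#' @export
gene_set_collection <- function(sets, desc = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  if (any(vapply(sets, length, 1L) == 0)) stop("member lists must be non-empty")
  if (any(vapply(sets, anyDuplicated, 1L) > 0))
    stop("members must be unique within a set")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  structure(list(sets = sets, desc = desc[names(sets)]),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$desc[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- pathway hierarchy ------------------------------------------------------

#' Read a pathway hierarchy (parent-child TSV)
#'
#' Two tab-separated columns, `parent` and `child`, one edge per line. The
#' is-part-of relation must be acyclic; a cycle is a hard error. Terms absent
#' from a companion gene-set collection can be flagged with
#' [hierarchy_orphans()].
#'
#' @param path TSV path with header `parent`, `child`.
#' @return data.frame with columns parent, child; attribute `roots` holds
#'   terms never appearing as a child.
#' @export
read_hierarchy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% names(df)))
    stop("hierarchy file needs columns parent, child")
  validate_hierarchy(df[, c("parent", "child")])
}

#' Validate a hierarchy edge table (acyclicity, roots)
#' @param edges data.frame(parent, child).
#' @export
validate_hierarchy <- function(edges) {
  terms <- unique(c(edges$parent, edges$child))
  # Kahn peeling: if nodes remain after repeatedly removing childless terms,
  # the remainder contains a cycle.
  remaining <- edges
  alive <- terms
  repeat {
    has_child <- unique(remaining$parent)
    leaves <- setdiff(alive, has_child)
    if (length(leaves) == 0) break
    alive <- setdiff(alive, leaves)
    remaining <- remaining[!(remaining$child %in% leaves), , drop = FALSE]
    if (nrow(remaining) == 0) break
  }
  if (nrow(remaining) > 0)
    stop("hierarchy contains a cycle involving: ",
         paste(utils::head(unique(c(remaining$parent, remaining$child)), 5),
               collapse = ", "))
  attr(edges, "roots") <- setdiff(unique(edges$parent), unique(edges$child))
  edges
}

#' Terms in a hierarchy lacking a gene-set record
#' @param hierarchy validated edge table.
#' @param collection companion `gene_set_collection`.
#' @return character vector of terms with no gene-set record.
#' @export
hierarchy_orphans <- function(hierarchy, collection) {
  terms <- unique(c(hierarchy$parent, hierarchy$child))
  setdiff(terms, names(collection$sets))
}

#' All descendants of a term (including itself)
#' @param hierarchy validated edge table.
#' @param term root term.
#' @export
hierarchy_descendants <- function(hierarchy, term) {
  out <- term
  frontier <- term
  while (length(frontier) > 0) {
    kids <- hierarchy$child[hierarchy$parent %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Write a hierarchy edge table to TSV
#' @param hierarchy edge table.
#' @param path output path.
#' @export
write_hierarchy <- function(hierarchy, path) {
  utils::write.table(hierarchy[, c("parent", "child")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- pathway topology -------------------------------------------------------

#' Construct a pathway topology
#'
#' A signed, typed gene-gene edge graph for one pathway term. `has_topology`
#' is TRUE iff at least one edge is present; pathways without topology carry
#' their node list but cannot be scored by perturbation analysis.
#'
#' @param term pathway name.
#' @param nodes character vector of member genes.
#' @param edges data.frame(source, relation, target); may have zero rows.
#' @return object of class `pathway_topology`.
#' @export
pathway_topology <- function(term, nodes, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(source = character(0), relation = character(0),
                        target = character(0), stringsAsFactors = FALSE)
  nodes <- unique(as.character(nodes))
  if (nrow(edges) > 0) {
    ends <- unique(c(edges$source, edges$target))
    if (!all(ends %in% nodes))
      stop("edge endpoints not in node list: ",
           paste(setdiff(ends, nodes), collapse = ", "))
  }
  structure(list(term = term, nodes = nodes, edges = edges,
                 has_topology = nrow(edges) > 0),
            class = "pathway_topology")
}

#' Read a pathway topology from a SIF-like TSV edge list
#'
#' Lines of "source TAB relation TAB target". The node universe is inferred
#' from edge endpoints unless `nodes` declares it (required to represent a
#' topology-less pathway as an empty file). Relation types outside the weight
#' vocabulary are retained but flagged in the `known` column.
#'
#' @param path edge-list path.
#' @param term pathway name (defaults to the file name).
#' @param nodes optional declared node list.
#' @param vocabulary relation types considered known (default: the names of
#'   [default_weight_map()]).
#' @export
read_topology <- function(path, term = basename(path), nodes = NULL,
                          vocabulary = names(default_weight_map())) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 3)
    if (length(bad) > 0)
      stop(sprintf("malformed topology line %d: expected 3 tab-separated fields",
                   bad[1]))
    edges <- data.frame(source = vapply(parts, `[[`, "", 1),
                        relation = vapply(parts, `[[`, "", 2),
                        target = vapply(parts, `[[`, "", 3),
                        stringsAsFactors = FALSE)
  } else {
    edges <- NULL
  }
  if (is.null(nodes))
    nodes <- if (is.null(edges)) character(0) else
      unique(c(edges$source, edges$target))
  topo <- pathway_topology(term, nodes, edges)
  if (nrow(topo$edges) > 0)
    topo$edges$known <- topo$edges$relation %in% vocabulary
  topo
}

#' Write a pathway topology edge list to TSV
#' @param topology `pathway_topology`.
#' @param path output path.
#' @export
write_topology <- function(topology, path) {
  if (nrow(topology$edges) > 0) {
    utils::write.table(topology$edges[, c("source", "relation", "target")],
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(character(0), path)
  }
  invisible(path)
}

# ---- identifiers, manifest, seeds ------------------------------------------

#' Normalize gene identifiers for matching
#'
#' Identifiers are matched as exact case-sensitive strings by default;
#' `uppercase = TRUE` case-folds both sides of a comparison (useful when a
#' gene-set collection uses a different symbol-casing convention). Mixed-case
#' mouse symbols make silent case-folding risky, so it is opt-in.
#'
#' @param ids character vector.
#' @param uppercase fold to upper case?
#' @export
normalize_gene_ids <- function(ids, uppercase = FALSE) {
  if (uppercase) toupper(ids) else ids
}

#' Write a JSON run manifest
#'
#' Records inputs, parameters, seed, per-stage row counts, package version
#' and a timestamp so a run can be audited and reproduced.
#'
#' @param path output JSON path.
#' @param inputs named list describing inputs.
#' @param params named list of parameters.
#' @param seed integer seed governing all RNG streams.
#' @param stage_counts named list of per-stage row counts.
#' @export
write_manifest <- function(path, inputs = list(), params = list(),
                           seed = NA_integer_, stage_counts = list()) {
  manifest <- list(
    package = "dosepath",
    version = as.character(utils::packageVersion("dosepath")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, inputs = inputs, params = params,
    stage_counts = stage_counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Derive a deterministic sub-stream seed from a global seed and a tag
#'
#' One global seed governs all RNG streams; stages (and per-pathway,
#' per-dose bootstraps) derive their own seeds from it so any subset of the
#' pipeline can be regenerated independently and identically.
#'
#' @param seed global integer seed.
#' @param tag character label of the sub-stream.
#' @return integer in [0, 2^31).
#' @export
substream_seed <- function(seed, tag) {
  val <- as.numeric(seed) %% 2147483629
  for (ch in utf8ToInt(as.character(tag)))
    val <- (val * 31 + ch) %% 2147483629
  as.integer(val)
}
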