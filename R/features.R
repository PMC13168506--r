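#' Construct a feature set for one modality
#'
#' A feature set holds one view of one entity kind: either a numeric matrix
#' (entities in rows, a fixed feature dimension in columns) or a collection
#' of simple undirected graphs (one per entity, or one graph shared by all
#' entities). Models declare which modalities they consume; ablation
#' randomizers operate on one modality at a time.
#'
#' @param x For `kind = "tabular"`: a numeric matrix with entity ids as row
#'   names. For `kind = "graph"`: a named list of [igraph::graph] objects, or
#'   a single igraph shared by all entities.
#' @param modality Modality name, e.g. `"gene_expression"`, `"fingerprint"`,
#'   `"mutation"`, `"drug_graph"`.
#' @param entity_kind `"cell_line"` or `"drug"`.
#' @param kind `"tabular"` or `"graph"`.
#' @return An object of class `drb_features`.
#' @export
feature_set <- function(x, modality, entity_kind = c("cell_line", "drug"),
                        kind = c("tabular", "graph")) {
  entity_kind <- match.arg(entity_kind)
  kind <- match.arg(kind)
  if (kind == "tabular") {
    if (!is.matrix(x) || !is.numeric(x)) abort("Tabular features must be a numeric matrix.")
    if (is.null(rownames(x))) abort("Tabular feature matrix needs entity ids as row names.")
    if (anyDuplicated(rownames(x))) {
      abort(sprintf(
        "Duplicate entity id(s) in modality '%s': %s.", modality,
        paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")
      ))
    }
  } else {
    check_simple <- function(g) {
      if (!igraph::is_igraph(g)) abort("Graph features must be igraph objects.")
      if (igraph::any_loop(g) || igraph::any_multiple(g)) {
        abort("Graphs must be simple: no self-loops, no multi-edges.")
      }
    }
    if (igraph::is_igraph(x)) {
      check_simple(x)
    } else {
      if (!is.list(x) || is.null(names(x))) {
        abort("Graph modality needs a named list of igraph objects (or one shared graph).")
      }
      lapply(x, check_simple)
    }
  }
  structure(
    list(data = x, modality = modality, entity_kind = entity_kind, kind = kind),
    class = "drb_features"
  )
}

#' @export
print.drb_features <- function(x, ...) {
  if (x$kind == "tabular") {
    cat(sprintf(
      "<drb_features '%s' (%s): %d entities x %d features>\n",
      x$modality, x$entity_kind, nrow(x$data), ncol(x$data)
    ))
  } else {
    n <- if (igraph::is_igraph(x$data)) 1L else length(x$data)
    cat(sprintf(
      "<drb_features '%s' (%s): %d graph(s)>\n", x$modality, x$entity_kind, n
    ))
  }
  invisible(x)
}

#' @rdname feature_set
#' @param fs A `drb_features` object.
#' @export
feature_entities <- function(fs) {
  stopifnot(inherits(fs, "drb_features"))
  if (fs$kind == "tabular") {
    rownames(fs$data)
  } else if (igraph::is_igraph(fs$data)) {
    character(0) # shared graph covers all entities
  } else {
    names(fs$data)
  }
}

feature_rows <- function(fs, ids) {
  stopifnot(fs$kind == "tabular")
  missing_ids <- setdiff(ids, rownames(fs$data))
  if (length(missing_ids) > 0) {
    abort(sprintf(
      "Modality '%s' lacks features for: %s.", fs$modality,
      paste(head(missing_ids, 5), collapse = ", ")
    ))
  }
  fs$data[ids, , drop = FALSE]
}

#' Read a tabular feature matrix from CSV
#'
#' Schema: first column `entity_id`, remaining columns numeric features.
#' Every entity must appear once; all rows share one dimension.
#'
#' @param path CSV path.
#' @inheritParams feature_set
#' @return A `drb_features` of kind `"tabular"`.
#' @export
read_feature_matrix <- function(path, modality, entity_kind = c("cell_line", "drug")) {
  entity_kind <- match.arg(entity_kind)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"entity_id" %in% names(tab)) {
    abort(sprintf("Feature table %s lacks required column 'entity_id'.", path))
  }
  ids <- as.character(tab$entity_id)
  mat <- as.matrix(tab[, setdiff(names(tab), "entity_id"), drop = FALSE])
  if (!is.numeric(mat)) abort(sprintf("Feature table %s has non-numeric feature columns.", path))
  rownames(mat) <- ids
  feature_set(mat, modality, entity_kind, kind = "tabular")
}

#' Read a graph modality from an edge list CSV
#'
#' Two schemas are accepted: `entity_id,node_u,node_v` (one graph per
#' entity) or `node_u,node_v` (a single shared graph).
#'
#' @inheritParams read_feature_matrix
#' @return A `drb_features` of kind `"graph"`.
#' @export
read_edge_list <- function(path, modality, entity_kind = c("cell_line", "drug")) {
  entity_kind <- match.arg(entity_kind)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("node_u", "node_v") %in% names(tab))) {
    abort(sprintf("Edge list %s needs columns node_u and node_v.", path))
  }
  build <- function(edges) {
    igraph::simplify(igraph::graph_from_data_frame(edges, directed = FALSE))
  }
  if ("entity_id" %in% names(tab)) {
    graphs <- lapply(
      split(tab[, c("node_u", "node_v")], tab$entity_id),
      build
    )
    feature_set(graphs, modality, entity_kind, kind = "graph")
  } else {
    feature_set(build(tab[, c("node_u", "node_v")]), modality, entity_kind, kind = "graph")
  }
}
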