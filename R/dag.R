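#' Build a disease DAG from a parent-child edge table
#'
#' Disease vocabulary terms form a directed acyclic graph with edges from
#' parent (more general) to child (more specific) terms, as in the MeSH
#' descriptor hierarchy. The ancestor closure T(D) of a term D -- D plus
#' all its ancestors -- is the unit over which semantic similarity is
#' computed.
#'
#' @param edges Data frame with columns `parent` and `child` (extra columns
#'   ignored), or a two-column data frame taken positionally.
#' @param terms Optional character vector of isolated terms to include even
#'   if they appear in no edge.
#' @return Object of class `mda_dag` with elements `terms`, `edges`
#'   (tibble parent/child) and the underlying igraph graph.
#' @export
#' @examples
#' dag <- mda_dag(data.frame(parent = c("a", "b"), child = c("b", "c")))
#' dag_ancestors(dag, "c")
mda_dag <- function(edges, terms = NULL) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    if (!all(c("parent", "child") %in% names(edges))) {
      if (ncol(edges) < 2) {
        abort("edge table needs 'parent' and 'child' columns", class = "mirec_format_error")
      }
      names(edges)[1:2] <- c("parent", "child")
    }
    edges <- tibble(parent = normalize_names(edges$parent),
                    child = normalize_names(edges$child)) |>
      dplyr::distinct()
  } else {
    edges <- tibble(parent = character(), child = character())
  }
  terms <- sort(unique(c(edges$parent, edges$child, normalize_names(terms %||% character()))))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) {
    cyc <- find_cycle(edges)
    abort(sprintf("disease graph contains a cycle: %s", paste(cyc, collapse = " -> ")),
          class = "mirec_validation_error")
  }
  structure(list(terms = terms, edges = edges, graph = g), class = "mda_dag")
}

# DFS to surface one directed cycle for the validation error message.
find_cycle <- function(edges) {
  adj <- split(edges$child, edges$parent)
  state <- new.env(parent = emptyenv())
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- get0(v, envir = state, ifnotfound = "new")
    if (st == "active") {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (st == "done") return()
    assign(v, "active", envir = state)
    path <<- c(path, v)
    for (w in adj[[v]] %||% character()) visit(w)
    path <<- path[-length(path)]
    assign(v, "done", envir = state)
  }
  for (v in unique(edges$parent)) visit(v)
  found %||% "unlocatable cycle"
}

#' Read a disease DAG from a flat file
#'
#' Two dialects are supported. `edge_list`: two tab-separated columns
#' parent, child. `mesh_tree`: two tab-separated columns term, tree-number
#' (e.g. `neoplasms<TAB>C04`); parenthood is derived by tree-number prefix,
#' the parent of `C04.557.470` being `C04.557`. A term may carry several
#' tree numbers (polyhierarchy); all positions are merged into one node.
#' A tree number whose parent number maps to no listed term raises a
#' warning and a placeholder node named by the tree number is created.
#'
#' @param path Path to a TSV file with a header line.
#' @param dialect `"edge_list"` or `"mesh_tree"`.
#' @return An [mda_dag()].
#' @export
read_dag <- function(path, dialect = c("edge_list", "mesh_tree")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (ncol(df) < 2) {
    abort(sprintf("DAG file '%s' must have two columns", path), class = "mirec_format_error")
  }
  if (dialect == "edge_list") {
    names(df)[1:2] <- c("parent", "child")
    return(mda_dag(df))
  }
  term <- normalize_names(df[[1]])
  num <- stringr::str_trim(df[[2]])
  by_num <- setNames(term, num)
  parent_num <- sub("\\.[^.]*$", "", num)
  has_parent <- parent_num != num
  parent_term <- by_num[parent_num]
  orphan <- has_parent & is.na(parent_term)
  if (any(orphan)) {
    warn(sprintf("tree numbers with no listed parent term (placeholder nodes created): %s",
                 paste(unique(parent_num[orphan]), collapse = ", ")))
    parent_term[orphan] <- normalize_names(parent_num[orphan])
  }
  edges <- tibble(parent = unname(parent_term[has_parent]),
                  child = term[has_parent])
  mda_dag(edges, terms = term)
}

#' Ancestor closure of a term
#'
#' Returns T(D): the term itself plus every ancestor reachable by walking
#' parent edges upward.
#'
#' @param dag An [mda_dag()].
#' @param term Term identifier (normalized internally).
#' @return Character vector of closure members (unordered).
#' @export
dag_ancestors <- function(dag, term) {
  term <- normalize_names(term)
  if (!term %in% dag$terms) {
    abort(sprintf("term '%s' is not in the DAG", term), class = "mirec_lookup_error")
  }
  names(igraph::subcomponent(dag$graph, term, mode = "in"))
}

# Closures for many terms at once; list named by term.
dag_closures <- function(dag, terms) {
  setNames(lapply(terms, function(t) dag_ancestors(dag, t)), normalize_names(terms))
}

# Children of `term` restricted to the DAG.
dag_children <- function(dag, term) {
  names(igraph::neighbors(dag$graph, term, mode = "out"))
}

#' @export
print.mda_dag <- function(x, ...) {
  cat(sprintf("<mda_dag> %d terms, %d parent->child edges\n",
              length(x$terms), nrow(x$edges)))
  invisible(x)
}
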