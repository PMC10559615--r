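#' @useDynLib genesim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats predict
NULL

# -- ontology_dag construction -------------------------------------------------

#' Construct an ontology DAG object
#'
#' Low-level constructor for the term graph used throughout the package:
#' nodes are term identifiers, edges point from a child term to a parent
#' term and carry a relation kind (`is_a` or `part_of`). The graph must be
#' acyclic; construction fails otherwise, naming one term on a cycle.
#'
#' @param terms character vector of term identifiers (non-empty strings).
#' @param edges data frame with columns `child`, `parent`, `relation`;
#'   every endpoint must appear in `terms`. Duplicate (child, parent,
#'   relation) triples are collapsed.
#' @param namespace named character vector mapping term id to namespace
#'   (e.g. `biological_process`); unnamed entries default to
#'   `biological_process`.
#' @param name optional named character vector of human-readable term names.
#' @return An object of class `ontology_dag` with elements `terms`,
#'   `edges`, `namespace`, `name`, and a precomputed `n_children` count per
#'   term (number of distinct terms with an edge into it, over all retained
#'   relation kinds).
#' @seealso [read_obo()], [ancestor_dag()], [children_count()]
#' @export
ontology_dag <- function(terms, edges = NULL, namespace = NULL, name = NULL) {
  terms <- as.character(terms)
  if (length(terms) == 0L) stop("ontology must contain at least one term")
  if (anyDuplicated(terms)) stop("duplicate term ids")
  if (any(!nzchar(terms))) stop("empty term id")
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      relation = as.character(edges$relation),
                      stringsAsFactors = FALSE)
  bad <- setdiff(c(edges$child, edges$parent), terms)
  if (length(bad) > 0L)
    stop("edge endpoint(s) not in term set: ", paste(utils::head(bad, 5), collapse = ", "))
  edges <- edges[!duplicated(edges[c("child", "parent", "relation")]), , drop = FALSE]
  rownames(edges) <- NULL

  ns <- rep("biological_process", length(terms))
  names(ns) <- terms
  if (!is.null(namespace)) ns[names(namespace)] <- namespace
  nm <- if (is.null(name)) stats::setNames(terms, terms) else {
    full <- stats::setNames(terms, terms); full[names(name)] <- name; full
  }

  # children count: distinct child terms per parent (relation kinds pooled)
  uniq <- edges[!duplicated(edges[c("child", "parent")]), , drop = FALSE]
  nch <- stats::setNames(integer(length(terms)), terms)
  if (nrow(uniq) > 0L) {
    tab <- table(uniq$parent)
    nch[names(tab)] <- as.integer(tab)
  }

  dag <- structure(list(terms = terms, edges = edges, namespace = ns,
                        name = nm, n_children = nch),
                   class = "ontology_dag")
  cyc <- .find_cycle_member(dag)
  if (!is.na(cyc))
    stop("ontology graph contains a cycle involving term '", cyc, "'")
  dag
}

# Kahn's algorithm; returns NA if acyclic, else one term left unprocessed.
.find_cycle_member <- function(dag) {
  if (nrow(dag$edges) == 0L) return(NA_character_)
  indeg <- stats::setNames(integer(length(dag$terms)), dag$terms)
  # process child -> parent: a term is ready when all its children are done
  tab <- table(dag$edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  out_of <- split(dag$edges$parent, dag$edges$child)
  queue <- names(indeg)[indeg == 0L]
  done <- 0L
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]
    done <- done + 1L
    for (p in out_of[[t]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (done == length(dag$terms)) NA_character_ else names(indeg)[indeg > 0L][1L]
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag: ", length(x$terms), " terms, ", nrow(x$edges), " edges (",
      paste(sprintf("%s: %d", names(table(x$edges$relation)),
                    as.integer(table(x$edges$relation))), collapse = ", "),
      ")\n", sep = "")
  ns <- table(x$namespace)
  cat("namespaces:", paste(sprintf("%s=%d", names(ns), as.integer(ns)), collapse = ", "), "\n")
  invisible(x)
}

# -- OBO parsing ---------------------------------------------------------------

#' Read an OBO ontology file
#'
#' Parses an OBO 1.2/1.4 flat file into an [ontology_dag()]. Only `[Term]`
#' stanzas are considered; the keys used are `id`, `name`, `namespace`,
#' `is_a`, `relationship: part_of` and `is_obsolete`. Obsolete terms are
#' dropped together with their edges, as are edges of any relation kind not
#' listed in `relations`.
#'
#' @param path path to an OBO file.
#' @param namespace optional namespace filter (e.g. `"biological_process"`);
#'   when given, only terms of that namespace (and edges among them) are
#'   retained.
#' @param relations relation kinds kept as edges; defaults to the two kinds
#'   used by Wang-style semantic similarity.
#' @return An `ontology_dag`.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "", "[Term]", "id: A", "name: root",
#'              "namespace: biological_process", "", "[Term]", "id: B",
#'              "namespace: biological_process", "is_a: A ! root"), obo)
#' dag <- read_obo(obo)
#' children_count(dag, "A")
#' @export
read_obo <- function(path, namespace = NULL, relations = c("is_a", "part_of")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)

  in_term <- FALSE
  cur <- NULL
  recs <- list()
  flush <- function(cur, recs) { if (!is.null(cur) && !is.null(cur$id)) recs[[length(recs) + 1L]] <- cur; recs }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      recs <- flush(cur, recs)
      cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list(is_a = character(), part_of = character(), obsolete = FALSE)
      next
    }
    if (!in_term || !nzchar(ln)) next
    kv <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) next
    key <- kv[[2L]]; val <- kv[[3L]]
    val <- sub("\\s*!.*$", "", val)   # strip trailing OBO comment
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (key == "is_obsolete") cur$obsolete <- tolower(val) %in% c("true", "1")
    else if (key == "relationship") {
      parts <- strsplit(trimws(val), "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] %in% relations)
        cur[[parts[[1L]]]] <- c(cur[[parts[[1L]]]], parts[[2L]])
    }
  }
  recs <- flush(cur, recs)
  if (length(recs) == 0L) stop("unparseable OBO file (no [Term] stanzas): ", path)

  obsolete <- vapply(recs, function(r) isTRUE(r$obsolete), logical(1))
  recs <- recs[!obsolete]
  if (length(recs) == 0L) stop("OBO file contains only obsolete terms: ", path)
  ids <- vapply(recs, function(r) r$id, character(1))
  ns <- vapply(recs, function(r) r$namespace %||% "biological_process", character(1))
  nm <- vapply(recs, function(r) r$name %||% r$id, character(1))
  names(ns) <- ids; names(nm) <- ids

  keep <- rep(TRUE, length(ids))
  if (!is.null(namespace)) keep <- ns == namespace
  ids <- ids[keep]; ns <- ns[keep]; nm <- nm[keep]; recs <- recs[keep]

  ed <- do.call(rbind, lapply(recs, function(r) {
    rel <- c(rep("is_a", length(r$is_a)), rep("part_of", length(r$part_of)))
    if (length(rel) == 0L) return(NULL)
    data.frame(child = r$id, parent = c(r$is_a, r$part_of), relation = rel,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ed))
    ed <- data.frame(child = character(), parent = character(), relation = character())
  # drop edges pointing at filtered/absent terms
  ed <- ed[ed$parent %in% ids & ed$child %in% ids & ed$relation %in% relations, , drop = FALSE]
  ontology_dag(ids, ed, namespace = ns, name = nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ontology DAG to a minimal OBO file
#'
#' Emits the stanza subset that [read_obo()] consumes (`id`, `name`,
#' `namespace`, `is_a`, `relationship: part_of`), so a write/read round trip
#' reproduces the graph exactly.
#'
#' @param dag an `ontology_dag`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  by_child <- split(seq_len(nrow(dag$edges)), dag$edges$child)
  for (t in dag$terms) {
    out <- c("[Term]", paste0("id: ", t), paste0("name: ", dag$name[[t]]),
             paste0("namespace: ", dag$namespace[[t]]))
    for (i in by_child[[t]]) {
      rel <- dag$edges$relation[[i]]; par <- dag$edges$parent[[i]]
      out <- c(out, if (rel == "is_a") paste0("is_a: ", par)
                    else paste0("relationship: ", rel, " ", par))
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

# -- queries -------------------------------------------------------------------

.check_term <- function(dag, t) {
  if (!(t %in% dag$terms)) stop("unknown term id: ", t)
  invisible(TRUE)
}

#' Extract the ancestor subgraph of a term
#'
#' Returns the term's own DAG: the term itself plus everything reachable by
#' following child-to-parent edges, together with the edges induced among
#' that term set. This is the subgraph on which semantic values are
#' propagated.
#'
#' @param dag an `ontology_dag`.
#' @param x a term id present in `dag`.
#' @return An object of class `term_dag`: list with `focus`, `termset`
#'   (character, includes `x`), and `edges` (induced edge data frame).
#' @export
ancestor_dag <- function(dag, x) {
  stopifnot(inherits(dag, "ontology_dag"))
  .check_term(dag, x)
  parents_of <- split(dag$edges$parent, dag$edges$child)
  seen <- x
  frontier <- x
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(parents_of[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  keep <- dag$edges$child %in% seen & dag$edges$parent %in% seen
  structure(list(focus = x, termset = seen,
                 edges = dag$edges[keep, , drop = FALSE]),
            class = "term_dag")
}

#' @export
print.term_dag <- function(x, ...) {
  cat("term_dag of ", x$focus, ": ", length(x$termset), " terms, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Number of children of a term
#'
#' Counts the distinct terms with an edge into `t`, over all relation kinds
#' retained in the DAG. The count is a property of the term on the full
#' ontology (not of any extracted ancestor subgraph), so that the derived
#' edge weight does not depend on which gene queried the term.
#'
#' @param dag an `ontology_dag`.
#' @param t a term id.
#' @return Non-negative integer.
#' @export
children_count <- function(dag, t) {
  stopifnot(inherits(dag, "ontology_dag"))
  .check_term(dag, t)
  unname(dag$n_children[[t]])
}
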