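# Hybrid gene similarity (HGS): Wang-style semantic-value propagation with
# edge weights derived from term children counts, aggregated per gene pair
# by best-match averaging.

#' Configuration for the hybrid semantic similarity
#'
#' The weight of an edge in the propagation is
#' `w = min(w_max, 1 / (n_children + c) + d[relation])`: a term with many
#' children is less specific and passes on less of its meaning. `c` keeps
#' the denominator positive, `d` is a per-relation offset, and `w_max < 1`
#' guarantees semantic values strictly decay toward the root so every
#' similarity lands in `[0, 1]`.
#'
#' @param c positive additive constant in the weight denominator.
#' @param d named non-negative offsets per relation kind, each `< 1`.
#' @param w_max upper clip for the weight, in (0, 1).
#' @param weight_on whose children count feeds the weight when propagating
#'   along an edge child -> parent: `"child"` (default; the term whose
#'   contribution is being passed up) or `"parent"`.
#' @return An object of class `hgs_config`.
#' @export
hgs_config <- function(c = 2, d = c(is_a = 0.3, part_of = 0.2), w_max = 0.9,
                       weight_on = c("child", "parent")) {
  weight_on <- match.arg(weight_on)
  if (!is.numeric(c) || length(c) != 1L || c <= 0) stop("c must be a positive number")
  if (is.null(names(d)) || any(!nzchar(names(d)))) stop("d must be a named vector")
  if (any(d < 0 | d >= 1)) stop("each d offset must lie in [0, 1)")
  if (!is.numeric(w_max) || w_max <= 0 || w_max >= 1) stop("w_max must lie in (0, 1)")
  structure(list(c = c, d = d, w_max = w_max, weight_on = weight_on),
            class = "hgs_config")
}

#' @export
print.hgs_config <- function(x, ...) {
  cat("hgs_config: c =", x$c, ", w_max =", x$w_max, ", weight on", x$weight_on, "term\n")
  cat("d offsets:", paste(sprintf("%s=%g", names(x$d), x$d), collapse = ", "), "\n")
  invisible(x)
}

#' Edge weight from a children count
#'
#' @param n_children non-negative integer children count of the reference
#'   term on the edge.
#' @param relation relation kind; must have an offset in `cfg$d`.
#' @param cfg an [hgs_config()].
#' @return Weight in `(0, w_max]`.
#' @export
edge_weight <- function(n_children, relation, cfg = hgs_config()) {
  stopifnot(inherits(cfg, "hgs_config"))
  if (any(n_children < 0)) stop("n_children must be non-negative")
  if (!(relation %in% names(cfg$d))) stop("no d offset for relation kind: ", relation)
  pmin(cfg$w_max, 1 / (n_children + cfg$c) + cfg$d[[relation]])
}

#' Semantic value table of a term
#'
#' Propagates the contribution of term `x` to each of its ancestors:
#' `S_x(x) = 1`, and for an ancestor `t`, `S_x(t)` is the maximum over the
#' in-subgraph children `t'` of `t` of `w(edge) * S_x(t')`. Values are
#' computed in topological order over the ancestor subgraph so each is
#' final when read.
#'
#' @param dag an `ontology_dag`.
#' @param x a term id.
#' @param cfg an [hgs_config()].
#' @return Named numeric vector over the term set of [ancestor_dag()]
#'   (`x` first, value exactly 1), with attribute `focus`.
#' @export
semantic_values <- function(dag, x, cfg = hgs_config()) {
  stopifnot(inherits(dag, "ontology_dag"))
  td <- ancestor_dag(dag, x)
  s <- stats::setNames(rep(-Inf, length(td$termset)), td$termset)
  s[[x]] <- 1
  ed <- td$edges
  if (nrow(ed) > 0L) {
    remaining <- stats::setNames(integer(length(td$termset)), td$termset)
    tab <- table(ed$parent)
    remaining[names(tab)] <- as.integer(tab)
    ref <- if (cfg$weight_on == "child") ed$child else ed$parent
    w <- vapply(seq_len(nrow(ed)), function(i)
      edge_weight(dag$n_children[[ref[[i]]]], ed$relation[[i]], cfg), numeric(1))
    by_child <- split(seq_len(nrow(ed)), ed$child)
    queue <- td$termset[remaining[td$termset] == 0L]  # the focus term
    while (length(queue) > 0L) {
      u <- queue[[1L]]; queue <- queue[-1L]
      for (i in by_child[[u]]) {
        p <- ed$parent[[i]]
        cand <- w[[i]] * s[[u]]
        if (cand > s[[p]]) s[[p]] <- cand
        remaining[[p]] <- remaining[[p]] - 1L
        if (remaining[[p]] == 0L) queue <- c(queue, p)
      }
    }
  }
  attr(s, "focus") <- x
  s
}

#' Semantic similarity between two terms
#'
#' Wang-style aggregation over the shared ancestors:
#' `sim(a, b) = sum_(t in T_a ∩ T_b) (S_a(t) + S_b(t)) / (SV(a) + SV(b))`
#' where `SV(x)` is the total semantic value of `x`'s ancestor set.
#'
#' @param dag an `ontology_dag`.
#' @param a,b term ids.
#' @param cfg an [hgs_config()].
#' @param sv_cache optional environment caching semantic value tables by
#'   term id (used by [build_gfs_matrix()]).
#' @return Similarity in `[0, 1]`; exactly 1 when `a == b`, 0 when the
#'   terms share no ancestor.
#' @export
term_similarity <- function(dag, a, b, cfg = hgs_config(), sv_cache = NULL) {
  if (identical(a, b)) { .check_term(dag, a); return(1) }
  sa <- .sv_lookup(dag, a, cfg, sv_cache)
  sb <- .sv_lookup(dag, b, cfg, sv_cache)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0L) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

.sv_lookup <- function(dag, t, cfg, cache) {
  if (is.null(cache)) return(semantic_values(dag, t, cfg))
  if (is.null(cache[[t]])) cache[[t]] <- semantic_values(dag, t, cfg)
  cache[[t]]
}

#' Gene-level similarity by best-match averaging
#'
#' Each term of one gene is matched with its most similar term in the other
#' gene; the matches of both directions are averaged:
#' `BMA = (sum_i max_j sim(t1_i, t2_j) + sum_j max_i sim(t1_i, t2_j)) / (m + n)`.
#'
#' @param dag an `ontology_dag`.
#' @param terms1,terms2 non-empty character vectors of term ids.
#' @param cfg an [hgs_config()].
#' @param sv_cache,pair_cache optional environments caching semantic value
#'   tables and unordered term-pair similarities.
#' @return Similarity in `[0, 1]`; identical term sets give 1.
#' @export
gene_similarity <- function(dag, terms1, terms2, cfg = hgs_config(),
                            sv_cache = NULL, pair_cache = NULL) {
  terms1 <- unique(as.character(terms1)); terms2 <- unique(as.character(terms2))
  if (length(terms1) == 0L || length(terms2) == 0L)
    stop("gene has an empty annotation term set")
  sim <- matrix(0, length(terms1), length(terms2))
  for (i in seq_along(terms1)) for (j in seq_along(terms2)) {
    a <- terms1[[i]]; b <- terms2[[j]]
    if (is.null(pair_cache)) {
      sim[i, j] <- term_similarity(dag, a, b, cfg, sv_cache)
    } else {
      key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
      v <- pair_cache[[key]]
      if (is.null(v)) {
        v <- term_similarity(dag, a, b, cfg, sv_cache)
        pair_cache[[key]] <- v
      }
      sim[i, j] <- v
    }
  }
  (sum(apply(sim, 1, max)) + sum(apply(sim, 2, max))) /
    (length(terms1) + length(terms2))
}

#' Build the gene functional similarity (GFS) matrix
#'
#' Computes [gene_similarity()] for every pair of annotated genes. The
#' result is a symmetric, unit-diagonal matrix whose rows double as the
#' feature vectors of the classification stage. Term-pair similarities are
#' cached so each unordered pair is evaluated once.
#'
#' @param dag an `ontology_dag`.
#' @param annotations named list mapping gene id to a character vector of
#'   term ids (see [read_annotations()]).
#' @param cfg an [hgs_config()].
#' @param drop_unannotated if `TRUE`, genes whose terms are all absent from
#'   the DAG are dropped with a warning instead of raising an error.
#' @return Numeric `n x n` matrix with gene ids as dimnames, rows in input
#'   gene order.
#' @examples
#' dag <- synth_dag(n_terms = 30, n_layers = 4, seed = 1)
#' ann <- synth_cohort(dag, n_positive = 3, n_negative = 3, seed = 1)
#' gfs <- build_gfs_matrix(dag, ann$annotations)
#' gfs[1:3, 1:3]
#' @export
build_gfs_matrix <- function(dag, annotations, cfg = hgs_config(),
                             drop_unannotated = FALSE) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (is.null(names(annotations)) || any(!nzchar(names(annotations))))
    stop("annotations must be a named list (gene id -> term ids)")
  ann <- lapply(annotations, function(ts) intersect(unique(as.character(ts)), dag$terms))
  empty <- names(ann)[lengths(ann) == 0L]
  if (length(empty) > 0L) {
    msg <- paste0("gene(s) with no annotation term in the ontology: ",
                  paste(empty, collapse = ", "))
    if (!drop_unannotated) stop(msg)
    warning(msg, "; dropping")
    ann <- ann[lengths(ann) > 0L]
  }
  genes <- names(ann)
  n <- length(genes)
  if (n == 0L) stop("no annotated genes left")

  # similarity of every unordered pair of annotated terms, computed once
  terms <- sort(unique(unlist(ann, use.names = FALSE)))
  tsim <- .term_sim_matrix(dag, terms, cfg)
  idx <- lapply(ann, function(ts) match(ts, terms))

  m <- matrix(1, n, n, dimnames = list(genes, genes))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      s <- tsim[idx[[i]], idx[[j]], drop = FALSE]
      v <- (sum(apply(s, 1, max)) + sum(apply(s, 2, max))) / (nrow(s) + ncol(s))
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

# dense term-pair similarity over a term subset, with integer-indexed
# semantic value tables (same quantities as term_similarity, batched)
.term_sim_matrix <- function(dag, terms, cfg) {
  k <- length(terms)
  sv <- lapply(terms, function(t) semantic_values(dag, t, cfg))
  anc <- lapply(sv, function(s) match(names(s), dag$terms))
  tot <- vapply(sv, sum, numeric(1))
  out <- diag(1, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      ai <- anc[[i]]; si <- sv[[i]]
      for (j in seq(i + 1L, k)) {
        shared <- intersect(ai, anc[[j]])
        v <- if (length(shared) == 0L) 0 else
          sum(si[match(shared, ai)] + sv[[j]][match(shared, anc[[j]])]) /
            (tot[[i]] + tot[[j]])
        out[i, j] <- v
        out[j, i] <- v
      }
    }
  }
  out
}

#' Read gene annotations
#'
#' Two carriers are supported: GAF 2.x (`!`-prefixed header lines skipped;
#' column 2 = gene symbol, column 5 = term id, column 9 = aspect, of which
#' only `P` rows are kept) and plain two-column TSV `gene<TAB>term`.
#'
#' @param path input file.
#' @param format `"tsv"` or `"gaf"`.
#' @return Named list mapping gene id to a character vector of unique term ids.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "gaf") {
    keep <- vapply(fields, function(f) length(f) >= 9L && f[[9L]] == "P", logical(1))
    fields <- fields[keep]
    gene <- vapply(fields, `[[`, character(1), 2L)
    term <- vapply(fields, `[[`, character(1), 5L)
  } else {
    if (any(lengths(fields) < 2L)) stop("annotation TSV must have two columns")
    gene <- vapply(fields, `[[`, character(1), 1L)
    term <- vapply(fields, `[[`, character(1), 2L)
  }
  if (length(gene) == 0L) stop("no annotations read from ", path)
  lapply(split(term, factor(gene, levels = unique(gene))), unique)
}

#' Write a similarity matrix as CSV
#'
#' First row and column hold the gene ids; cells are written with six
#' decimals.
#'
#' @param m square numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gfs_matrix <- function(m, path) {
  out <- format(round(m, 6), nsmall = 6, trim = TRUE, scientific = FALSE)
  df <- data.frame(gene = rownames(m), out, check.names = FALSE)
  colnames(df) <- c("gene", colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_gfs_matrix()]
#' @param path CSV path.
#' @return Numeric matrix with gene dimnames.
#' @export
read_gfs_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
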