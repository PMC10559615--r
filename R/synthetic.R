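# Synthetic fixtures: layered random ontology DAGs, class-structured gene
# annotation cohorts with a planted similarity signal, and imbalanced
# Gaussian blob datasets. All generators are pure functions of their
# parameters and seed.

#' Random layered ontology DAG
#'
#' Builds a single-root DAG by layers: the root occupies layer 1 and the
#' remaining terms are spread as evenly as possible over layers 2..n_layers;
#' every non-root term draws 1..`max_parents` parents uniformly from the
#' layer above it, which guarantees acyclicity by construction. Each edge is
#' tagged `part_of` with probability `part_of_fraction`, else `is_a`.
#'
#' @param n_terms total number of terms (>= n_layers).
#' @param n_layers number of layers (>= 1).
#' @param max_parents maximum parents per non-root term.
#' @param part_of_fraction probability an edge is `part_of`.
#' @param seed optional integer; `set.seed(seed)` is called when given.
#' @return An [ontology_dag()] in namespace `biological_process`.
#' @export
synth_dag <- function(n_terms, n_layers = 4, max_parents = 2,
                      part_of_fraction = 0.2, seed = NULL) {
  stopifnot(n_terms >= 1, n_layers >= 1, n_terms >= n_layers, max_parents >= 1,
            part_of_fraction >= 0, part_of_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("T:%06d", seq_len(n_terms))

  if (n_terms == 1L) return(ontology_dag(ids))
  n_layers <- max(n_layers, 2L)
  rest <- n_terms - 1L
  sizes <- rep(rest %/% (n_layers - 1L), n_layers - 1L) +
    (seq_len(n_layers - 1L) <= rest %% (n_layers - 1L))
  layer <- c(1L, rep(seq_len(n_layers - 1L) + 1L, sizes))

  child <- character(0); parent <- character(0)
  for (l in seq(2L, n_layers)) {
    above <- ids[layer == l - 1L]
    for (t in ids[layer == l]) {
      np <- sample.int(min(max_parents, length(above)), 1L)
      ps <- above[sample.int(length(above), np)]
      child <- c(child, rep(t, np))
      parent <- c(parent, ps)
    }
  }
  rel <- ifelse(stats::runif(length(child)) < part_of_fraction, "part_of", "is_a")
  ontology_dag(ids, data.frame(child = child, parent = parent, relation = rel,
                               stringsAsFactors = FALSE),
               name = stats::setNames(paste("term", seq_len(n_terms)), ids))
}

# leaves = terms with no children; exclusive descendants of a root child =
# terms below it and below no other root child
.leaf_pools <- function(dag) {
  root <- dag$terms[!(dag$terms %in% dag$edges$child)]
  if (length(root) != 1L) stop("DAG must have exactly one root")
  kids <- sort(unique(dag$edges$child[dag$edges$parent == root]))
  if (length(kids) < 2L) stop("root must have at least two children subtrees")
  desc_of <- lapply(kids, function(k) {
    # all terms whose ancestor set contains k
    below <- k
    frontier <- k
    kids_of <- split(dag$edges$child, dag$edges$parent)
    while (length(frontier) > 0L) {
      nxt <- setdiff(unique(unlist(kids_of[frontier], use.names = FALSE)), below)
      below <- c(below, nxt)
      frontier <- nxt
    }
    below
  })
  leaves <- dag$terms[dag$n_children[dag$terms] == 0L]
  membership <- vapply(desc_of, function(d) leaves %in% d, logical(length(leaves)))
  n_sub <- rowSums(membership)
  exclusive <- lapply(seq_along(kids), function(i) leaves[membership[, i] & n_sub == 1L])
  sizes <- lengths(exclusive)
  dis_i <- which.max(sizes)
  disease <- exclusive[[dis_i]]
  background <- setdiff(leaves, desc_of[[dis_i]])
  list(disease = disease, background = background)
}

#' Synthetic gene cohort with a planted similarity signal
#'
#' Designates two leaf pools in the DAG — the exclusive leaf descendants of
#' one root child (the "disease" subtree) versus the leaves outside that
#' subtree — and annotates genes: each positive gene draws
#' `ceiling(signal * terms_per_gene)` of its terms from the disease pool
#' and the rest from the background; negatives draw only from the
#' background. With `signal = 0` the two classes are exchangeable; with
#' `signal = 1` positive genes are annotated entirely inside the disease
#' subtree.
#'
#' @param dag an [ontology_dag()] whose root has at least two children.
#' @param n_positive,n_negative gene counts (each >= 2).
#' @param terms_per_gene annotation set size per gene.
#' @param signal fraction of a positive gene's terms from the disease pool.
#' @param seed optional integer seed.
#' @return List with `annotations` (named list gene -> terms), `labels`
#'   (factor with levels `Non-ASD`, `ASD`; positives labelled `ASD`), and
#'   the designated `pools`.
#' @export
synth_cohort <- function(dag, n_positive, n_negative, terms_per_gene = 5,
                         signal = 0.8, seed = NULL) {
  stopifnot(inherits(dag, "ontology_dag"), n_positive >= 2, n_negative >= 2,
            terms_per_gene >= 1, signal >= 0, signal <= 1)
  if (!is.null(seed)) set.seed(seed)
  pools <- .leaf_pools(dag)
  n_dis <- as.integer(ceiling(signal * terms_per_gene))
  n_bg_pos <- terms_per_gene - n_dis
  if (length(pools$disease) < n_dis)
    stop("disease leaf pool too small (", length(pools$disease), " < ", n_dis, ")")
  if (length(pools$background) < max(terms_per_gene, n_bg_pos))
    stop("background leaf pool too small")

  genes <- c(sprintf("gene%03d", seq_len(n_positive)),
             sprintf("gene%03d", n_positive + seq_len(n_negative)))
  ann <- vector("list", length(genes))
  names(ann) <- genes
  for (i in seq_len(n_positive)) {
    ts <- character(0)
    if (n_dis > 0L) ts <- pools$disease[sample.int(length(pools$disease), n_dis)]
    if (n_bg_pos > 0L)
      ts <- c(ts, pools$background[sample.int(length(pools$background), n_bg_pos)])
    ann[[i]] <- ts
  }
  for (i in n_positive + seq_len(n_negative))
    ann[[i]] <- pools$background[sample.int(length(pools$background), terms_per_gene)]
  labels <- factor(c(rep("ASD", n_positive), rep("Non-ASD", n_negative)),
                   levels = c("Non-ASD", "ASD"))
  names(labels) <- genes
  list(annotations = ann, labels = labels, pools = pools)
}

#' Imbalanced two-cluster Gaussian dataset
#'
#' Two spherical unit-variance Gaussian clusters with centres `separation`
#' apart; the minority cluster is the positive class.
#'
#' @param n_majority,n_minority cluster sizes (each >= 2).
#' @param dim feature dimension.
#' @param separation Euclidean distance between the two centres.
#' @param seed optional integer seed.
#' @return A [labeled_dataset()] with labels `majority` / `minority` and
#'   positive class `minority`.
#' @export
synth_blobs <- function(n_majority, n_minority, dim = 2, separation = 3,
                        seed = NULL) {
  stopifnot(n_majority >= 2, n_minority >= 2, dim >= 1, separation >= 0)
  if (!is.null(seed)) set.seed(seed)
  offset <- separation / sqrt(dim)
  xmaj <- matrix(stats::rnorm(n_majority * dim), n_majority, dim)
  xmin <- matrix(stats::rnorm(n_minority * dim, mean = offset), n_minority, dim)
  labeled_dataset(rbind(xmaj, xmin),
                  factor(c(rep("majority", n_majority), rep("minority", n_minority)),
                         levels = c("majority", "minority")),
                  positive = "minority")
}

#' Write labels as a two-column TSV (`gene<TAB>label`)
#' @param labels named factor/character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(id = names(labels), label = as.character(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read labels from a two-column TSV
#' @param path input path.
#' @param positive optional positive label; defaults to the rarer value.
#' @return Named factor with the positive class as last level.
#' @export
read_labels <- function(path, positive = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("id", "label"))
  if (is.null(positive)) {
    tab <- sort(table(df$label))
    positive <- names(tab)[[1L]]
  }
  lv <- c(setdiff(unique(df$label), positive), positive)
  stats::setNames(factor(df$label, levels = lv), df$id)
}
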