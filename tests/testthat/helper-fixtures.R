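# Shared fixtures and independent oracles. Oracles are deliberately coded
# from the definitions (brute force / recursion), not by reusing package
# internals.

# three-term chain C -> B -> A (is_a)
chain_dag <- function() {
  ontology_dag(c("A", "B", "C"),
               data.frame(child = c("B", "C"), parent = c("A", "B"),
                          relation = "is_a"))
}

# diamond D -> {B, C} -> A; D part_of C so the two upward edges from D can
# carry different weights
diamond_dag <- function() {
  ontology_dag(c("A", "B", "C", "D"),
               data.frame(child = c("B", "C", "D", "D"),
                          parent = c("A", "A", "B", "C"),
                          relation = c("is_a", "is_a", "is_a", "part_of")))
}

# configuration under which every edge weight clips to exactly w:
# 1/(n_children + 1) + (w - 1e-6) always exceeds w for realistic counts
cfg_fixed <- function(w) {
  hgs_config(c = 1, d = c(is_a = w - 1e-6, part_of = w - 1e-6), w_max = w)
}

# brute-force ancestor set: fixed point of repeated parent expansion
bf_ancestors <- function(dag, x) {
  set <- x
  repeat {
    parents <- unique(dag$edges$parent[dag$edges$child %in% set])
    new_set <- union(set, parents)
    if (length(new_set) == length(set)) return(set)
    set <- new_set
  }
}

# independent fixed-weight Wang semantic values: recursive memoised
# definition S(x) = 1, S(t) = max over in-subgraph children t' of w * S(t')
wang_sv <- function(dag, x, w) {
  anc <- bf_ancestors(dag, x)
  memo <- new.env(parent = emptyenv())
  rec <- function(t) {
    if (t == x) return(1)
    if (!is.null(memo[[t]])) return(memo[[t]])
    kids <- unique(dag$edges$child[dag$edges$parent == t])
    kids <- kids[kids %in% anc]
    v <- max(vapply(kids, function(k) w * rec(k), numeric(1)))
    memo[[t]] <- v
    v
  }
  stats::setNames(vapply(anc, rec, numeric(1)), anc)
}

wang_term_sim <- function(dag, a, b, w) {
  sa <- wang_sv(dag, a, w)
  sb <- wang_sv(dag, b, w)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

# independent classic single-tree gradient booster (all features, no
# bootstrap); brute-force split search minimising child SSE
oracle_tree <- function(x, r, w, lambda, max_depth, min_leaf = 2) {
  grow <- function(idx, depth) {
    n <- length(idx)
    best <- NULL
    if (depth < max_depth && n >= 2 * min_leaf) {
      best_gain <- 1e-10
      s_all <- sum(r[idx])
      for (f in seq_len(ncol(x))) {
        v <- x[idx, f]
        for (cut in sort(unique(v))[-length(unique(v))]) {
          li <- idx[v <= cut]; ri <- idx[v > cut]
          if (length(li) < min_leaf || length(ri) < min_leaf) next
          gain <- sum(r[li])^2 / length(li) + sum(r[ri])^2 / length(ri) -
            s_all^2 / n
          if (gain > best_gain) {
            vs <- sort(unique(v))
            thr <- (cut + vs[which(vs == cut) + 1]) / 2
            best_gain <- gain
            best <- list(f = f, thr = thr, li = li, ri = ri)
          }
        }
      }
    }
    if (is.null(best)) {
      return(list(leaf = TRUE,
                  value = sum(r[idx]) / (sum(w[idx]) + lambda)))
    }
    list(leaf = FALSE, f = best$f, thr = best$thr,
         left = grow(best$li, depth + 1), right = grow(best$ri, depth + 1))
  }
  grow(seq_len(nrow(x)), 0)
}

oracle_tree_predict <- function(tree, x) {
  one <- function(node, row) {
    if (node$leaf) return(node$value)
    if (x[row, node$f] <= node$thr) one(node$left, row) else one(node$right, row)
  }
  vapply(seq_len(nrow(x)), function(i) one(tree, i), numeric(1))
}

oracle_boost_trace <- function(x, y, n_rounds, eta = 0.1, lambda = 5,
                               max_depth = 3, min_leaf = 2) {
  f0 <- log(sum(y == 1) / sum(y == 0))
  score <- rep(f0, length(y))
  trace <- numeric(n_rounds)
  for (m in seq_len(n_rounds)) {
    p <- plogis(score)
    tr <- oracle_tree(x, y - p, p * (1 - p), lambda, max_depth, min_leaf)
    score <- score + eta * oracle_tree_predict(tr, x)
    pc <- pmin(pmax(plogis(score), 1e-15), 1 - 1e-15)
    trace[m] <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  }
  trace
}

# pairwise-rank AUC oracle: P(score_pos > score_neg) with ties counted 1/2
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
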