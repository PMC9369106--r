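# A compact conditional-inference-tree learner: rank-based permutation
# association test for variable selection, Bonferroni multiplicity
# adjustment, exhaustive midpoint search for the split point. This is a
# deliberately univariate reconstruction of the conditional-inference
# framework (no influence functions, surrogate splits or multivariate
# responses); it mirrors the split logic the marker discovery needs.

# A = sum_k S_k^2/n_k for one assignment; the permutation-invariant parts of
# the Kruskal-Wallis statistic are dropped (see src/perm.cpp).
quad_rank_stat <- function(ranks, gid, inv_nk) {
  s <- tapply(ranks, gid, sum)
  sum(s^2 * inv_nk[as.integer(names(s))])
}

# Standardized Kruskal-Wallis statistic (ties handled through the rank
# variance); comparable across genes, used only to break selection ties.
kw_standardized <- function(ranks, gid) {
  n <- length(ranks)
  rbar <- mean(ranks)
  ss <- sum((ranks - rbar)^2)
  if (ss == 0) return(0)
  s <- tapply(ranks, gid, sum)
  nk <- tabulate(gid)
  num <- sum(s^2 / nk[as.integer(names(s))]) - n * rbar^2
  (n - 1) * num / ss
}

# All distinct assignments of a label multiset to n positions, as an
# n x M matrix of group ids. Only called when M <= a few thousand.
multiset_assignments <- function(sizes) {
  n <- sum(sizes)
  K <- length(sizes)
  rec <- function(open, k) {
    if (k == K) {
      m <- matrix(0L, n, 1)
      m[open, 1] <- K
      return(m)
    }
    picks <- utils::combn(length(open), sizes[k])
    cols <- lapply(seq_len(ncol(picks)), function(j) {
      sub <- rec(open[-picks[, j]], k + 1L)
      sub[open[picks[, j]], ] <- k
      sub
    })
    do.call(cbind, cols)
  }
  rec(seq_len(n), 1L)
}

n_distinct_assignments <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

#' Permutation p-value of the rank association between values and labels
#'
#' Tests independence of a numeric variable and a class label with a
#' Kruskal-Wallis-type rank statistic whose null distribution is taken from
#' label permutations: exact enumeration when the number of distinct label
#' arrangements is at most 10,000, Monte-Carlo otherwise (p = (1 + #{A_perm
#' >= A_obs}) / (1 + n_perm), a valid p-value for any n_perm).
#'
#' @param values Numeric vector.
#' @param labels Class label per value (>= 2 distinct labels).
#' @param n_perm Monte-Carlo permutations (>= 99).
#' @param seed Integer seed for the Monte-Carlo stream.
#' @return List with `p_value`, `statistic` (the standardized rank
#'   statistic) and `method` (`"exact"` or `"monte-carlo"`).
#' @export
#' @examples
#' association_p(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
association_p <- function(values, labels, n_perm = 9999, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need >= 2 distinct labels", call. = FALSE)
  if (n_perm < 99) stop("`n_perm` must be >= 99", call. = FALSE)
  if (length(unique(values)) == 1) {
    return(list(p_value = 1, statistic = 0, method = "degenerate"))
  }
  gid <- as.integer(factor(labels))
  r <- rank(values)
  nk <- tabulate(gid)
  inv_nk <- 1 / nk
  stat <- kw_standardized(r, gid)
  m <- n_distinct_assignments(nk)
  if (m <= 10000) {
    asn <- multiset_assignments(nk)
    a_obs <- quad_rank_stat(r, gid, inv_nk)
    eps <- 1e-9 * (1 + abs(a_obs))
    a_perm <- apply(asn, 2, function(g) quad_rank_stat(r, g, inv_nk))
    list(p_value = sum(a_perm >= a_obs - eps) / ncol(asn),
         statistic = stat, method = "exact")
  } else {
    res <- cpp_perm_count(matrix(r, nrow = 1), gid - 1L, as.integer(n_perm),
                          as.integer(seed))
    list(p_value = (1 + res$count[1]) / (1 + n_perm),
         statistic = stat, method = "monte-carlo")
  }
}

#' Best binary cut-off for separating classes on one variable
#'
#' Scans every midpoint between adjacent sorted unique values and returns
#' the one maximizing the Pearson chi-square statistic of the 2 x K table
#' (side of the cut-off by class); ties break toward the smaller cut-off.
#'
#' @param values Numeric vector with >= 2 distinct values.
#' @param labels Class label per value.
#' @param min_child Minimum number of samples required on each side.
#' @return List with `cutoff` and `statistic`, or `NULL` if no midpoint
#'   satisfies `min_child`.
#' @export
#' @examples
#' best_cutoff(c(1, 2, 10, 11), c("A", "A", "B", "B"))
best_cutoff <- function(values, labels, min_child = 1L) {
  labels <- as.character(labels)
  u <- sort(unique(values))
  if (length(u) < 2) stop("all values are equal; no cut-off exists", call. = FALSE)
  mids <- (u[-length(u)] + u[-1]) / 2
  n <- length(values)
  cls <- factor(labels)
  col_tot <- table(cls)
  best <- NULL
  for (m in mids) {
    left <- values <= m
    nl <- sum(left)
    if (nl < min_child || (n - nl) < min_child) next
    o <- rbind(table(cls[left]), table(cls[!left]))
    e <- outer(c(nl, n - nl), as.numeric(col_tot)) / n
    stat <- sum((o - e)^2 / e, na.rm = TRUE)
    if (is.null(best) || stat > best$statistic + 1e-12) {
      best <- list(cutoff = m, statistic = stat)
    }
  }
  best
}

#' Fit a conditional-inference classification tree
#'
#' Recursively: every candidate Endogenous gene is tested for association
#' with the class label by the permutation rank test; the smallest p-value
#' is Bonferroni-adjusted for the number of candidates. If it stays at or
#' below `alpha`, the node splits on that gene at [best_cutoff()] (left
#' branch is `<= cutoff`), otherwise it becomes a leaf. Gene screening uses
#' a shared permutation stream (`n_perm` draws); the selected gene's p-value
#' is then refined with enough permutations to resolve the Bonferroni
#' decision at `alpha` (exact enumeration when feasible). Deterministic for
#' a fixed seed.
#'
#' @param counts Counts tibble (Endogenous probes are the candidates).
#' @param labels Labels tibble (`sample_id`, `entity`).
#' @param alpha Split significance level after Bonferroni adjustment.
#' @param min_node Minimum samples in any node (default 3, the screening
#'   group size).
#' @param n_perm Screening permutations per node.
#' @param seed Integer seed.
#' @return An object of class `orbital_ctree`; inspect with [tidy()],
#'   [glance()], `print()` and [predict.orbital_ctree()].
#' @export
fit_ctree <- function(counts, labels, alpha = 0.05, min_node = 3L,
                      n_perm = 999L, seed = 1L) {
  assert_counts(counts)
  if (min_node < 2) stop("`min_node` must be >= 2", call. = FALSE)
  x <- count_matrix(counts, "Endogenous")
  if (nrow(x) == 0) stop("no Endogenous probes in `counts`", call. = FALSE)
  y <- aligned_entities(counts, labels)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need >= 2 classes", call. = FALSE)

  nodes <- list()
  new_id <- function() length(nodes) + 1L

  grow <- function(idx, depth) {
    id <- new_id()
    cls_counts <- table(factor(y[idx], levels = classes))
    leaf <- function() {
      nodes[[id]] <<- list(id = id, depth = depth, type = "leaf",
                           gene = NA_character_, cutoff = NA_real_,
                           statistic = NA_real_, p_raw = NA_real_,
                           adj_p = NA_real_, n = length(idx),
                           class_counts = cls_counts,
                           left = NA_integer_, right = NA_integer_)
      id
    }
    nodes[[id]] <<- list(id = id)  # reserve slot so child ids follow parent
    yi <- y[idx]
    if (length(unique(yi)) < 2 || length(idx) < 2 * min_node || alpha <= 0) {
      return(leaf())
    }
    xi <- x[, idx, drop = FALSE]
    cand <- which(apply(xi, 1, function(v) length(unique(v)) > 1))
    if (length(cand) == 0) return(leaf())
    gid <- as.integer(factor(yi))
    nk <- tabulate(gid)
    ranks <- t(apply(xi[cand, , drop = FALSE], 1, rank))
    node_seed <- as.integer((seed + 7919 * id) %% 2147483629L)
    scr <- cpp_perm_count(ranks, gid - 1L, as.integer(n_perm), node_seed)
    p_scr <- (1 + scr$count) / (1 + n_perm)
    h <- vapply(seq_along(cand), function(j) kw_standardized(ranks[j, ], gid),
                numeric(1))
    ord <- order(p_scr, -h)
    best_j <- ord[1]
    m <- length(cand)

    # refine the selected gene's p so min(1, p * m) <= alpha is decidable
    v <- xi[cand[best_j], ]
    if (n_distinct_assignments(nk) <= 10000) {
      p_raw <- association_p(v, yi, n_perm = max(99L, n_perm),
                             seed = node_seed)$p_value
    } else {
      n_ref <- max(n_perm, ceiling(2 * m / alpha))
      ref <- cpp_perm_count(matrix(rank(v), nrow = 1), gid - 1L,
                            as.integer(n_ref), node_seed + 1L)
      p_raw <- (1 + ref$count[1]) / (1 + n_ref)
    }
    adj_p <- min(1, p_raw * m)
    if (adj_p > alpha) return(leaf())
    cut <- best_cutoff(v, yi, min_child = min_node)
    if (is.null(cut)) return(leaf())
    go_left <- v <= cut$cutoff
    left_id <- grow(idx[go_left], depth + 1L)
    right_id <- grow(idx[!go_left], depth + 1L)
    nodes[[id]] <<- list(id = id, depth = depth, type = "split",
                         gene = rownames(x)[cand[best_j]],
                         cutoff = cut$cutoff, statistic = cut$statistic,
                         p_raw = p_raw, adj_p = adj_p, n = length(idx),
                         class_counts = cls_counts,
                         left = left_id, right = right_id)
    id
  }

  grow(seq_along(y), 0L)
  structure(list(nodes = nodes, classes = classes, alpha = alpha,
                 min_node = min_node, n_perm = n_perm, seed = seed,
                 n = length(y)),
            class = "orbital_ctree")
}

#' @exportS3Method generics::tidy
tidy.orbital_ctree <- function(x, ...) {
  rows <- lapply(x$nodes, function(nd) {
    maj <- names(nd$class_counts)[which.max(nd$class_counts)]
    tibble::tibble(node = nd$id, depth = nd$depth, type = nd$type,
                   gene = nd$gene, cutoff = nd$cutoff, adj_p = nd$adj_p,
                   n = nd$n, majority = maj,
                   left = nd$left, right = nd$right)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$depth, .data$node)
}

#' @exportS3Method generics::glance
glance.orbital_ctree <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(n = x$n, n_nodes = nrow(td),
                 n_splits = sum(td$type == "split"),
                 depth = max(td$depth), alpha = x$alpha,
                 min_node = x$min_node, n_perm = x$n_perm, seed = x$seed)
}

#' Split genes in tier order (shallowest first)
#'
#' @param tree An `orbital_ctree`.
#' @return Character vector of split genes ordered by depth.
#' @export
split_genes <- function(tree) {
  td <- tidy(tree)
  td$gene[td$type == "split"]
}

#' @export
print.orbital_ctree <- function(x, ...) {
  cat("Conditional-inference tree (", sum(vapply(x$nodes, function(n) n$type,
      character(1)) == "split"), " splits, alpha = ", x$alpha, ")\n", sep = "")
  show <- function(id, indent, side) {
    nd <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    if (nd$type == "leaf") {
      cat(pad, side, "[", paste(names(nd$class_counts), nd$class_counts,
          sep = ":", collapse = " "), "]\n", sep = "")
    } else {
      cat(pad, side, nd$gene, " <= ", signif(nd$cutoff, 5),
          " (adj p = ", signif(nd$adj_p, 3), ")\n", sep = "")
      show(nd$left, indent + 1L, "<= : ")
      show(nd$right, indent + 1L, " > : ")
    }
  }
  show(1L, 0L, "")
  invisible(x)
}

#' Predict class membership with a fitted tree
#'
#' Routes each sample by the split cut-offs (values exactly at a cut-off go
#' left) and returns the class proportions of the landing leaf.
#'
#' @param object An `orbital_ctree`.
#' @param counts Counts tibble containing every split gene.
#' @param ... Unused.
#' @return Tibble: `sample_id`, `pred_class`, one proportion column per class.
#' @export
predict.orbital_ctree <- function(object, counts, ...) {
  assert_counts(counts)
  x <- count_matrix(counts, "Endogenous")
  need <- unique(stats::na.omit(vapply(object$nodes, function(n) n$gene,
                                       character(1))))
  missing <- setdiff(need, rownames(x))
  if (length(missing) > 0) {
    stop("profile is missing tree gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  route <- function(v) {
    id <- 1L
    repeat {
      nd <- object$nodes[[id]]
      if (nd$type == "leaf") return(nd$class_counts / sum(nd$class_counts))
      id <- if (v[nd$gene] <= nd$cutoff) nd$left else nd$right
    }
  }
  smp <- colnames(x)
  props <- t(vapply(smp, function(s) route(x[, s]),
                    numeric(length(object$classes))))
  colnames(props) <- object$classes
  out <- tibble::tibble(sample_id = smp,
                        pred_class = object$classes[max.col(props, "first")])
  dplyr::bind_cols(out, tibble::as_tibble(props))
}

#' Leave-one-out cross-validated tree classification
#'
#' Refits the tree on every leave-one-out subset and predicts the held-out
#' sample.
#'
#' @inheritParams fit_ctree
#' @return Tibble: `sample_id`, `entity`, `pred_class`, `correct`.
#' @export
loocv_ctree <- function(counts, labels, alpha = 0.05, min_node = 3L,
                        n_perm = 999L, seed = 1L) {
  assert_counts(counts)
  smp <- sample_ids(counts)
  rows <- lapply(seq_along(smp), function(i) {
    keep <- smp[-i]
    fit <- fit_ctree(counts[, c(META_COLS, keep)],
                     labels[labels$sample_id %in% keep, ],
                     alpha = alpha, min_node = min_node,
                     n_perm = n_perm, seed = seed + i)
    pred <- predict(fit, counts[, c(META_COLS, smp[i])])
    truth <- labels$entity[labels$sample_id == smp[i]]
    tibble::tibble(sample_id = smp[i], entity = truth,
                   pred_class = pred$pred_class,
                   correct = pred$pred_class == truth)
  })
  dplyr::bind_rows(rows)
}
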