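# Independent brute-force oracles used to pin down expected values. These
# deliberately re-derive each quantity with naive loops, separate from the
# package implementation.

# Background subtraction and reference-gene scaling, element by element.
oracle_technical <- function(counts) {
  out <- counts
  neg_rows <- which(counts$probe_class == "Negative")
  for (s in setdiff(names(counts), c("probe_name", "probe_class"))) {
    nv <- counts[[s]][neg_rows]
    bg <- mean(nv) + 2 * sd(nv)
    for (i in seq_len(nrow(counts))) {
      if (counts$probe_class[i] %in% c("Endogenous", "Housekeeping")) {
        out[[s]][i] <- max(0, counts[[s]][i] - bg)
      }
    }
  }
  out
}

oracle_biological <- function(counts) {
  out <- counts
  hk_rows <- which(counts$probe_class == "Housekeeping")
  smp <- setdiff(names(counts), c("probe_name", "probe_class"))
  gm <- numeric(length(smp))
  for (j in seq_along(smp)) {
    v <- counts[[smp[j]]][hk_rows]
    if (any(v == 0)) v <- v + 1
    gm[j] <- prod(v)^(1 / length(v))
  }
  target <- prod(gm)^(1 / length(gm))
  for (j in seq_along(smp)) {
    f <- target / gm[j]
    for (i in seq_len(nrow(counts))) {
      if (counts$probe_class[i] %in% c("Endogenous", "Housekeeping")) {
        out[[smp[j]]][i] <- counts[[smp[j]]][i] * f
      }
    }
  }
  out
}

# Benjamini-Hochberg step-up, straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in rev(seq_len(m))) {
    val <- min(prev, m * p[o[k]] / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# AUC as the fraction of positive/negative pairs ranked correctly,
# half credit for ties: O(n^2).
oracle_auc <- function(score, y01) {
  pos <- score[y01 == 1]
  neg <- score[y01 == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Kruskal-Wallis statistic from the definition (tie-corrected form).
oracle_kw_stat <- function(values, gid) {
  r <- rank(values)
  n <- length(r)
  rbar <- mean(r)
  ss <- sum((r - rbar)^2)
  num <- 0
  for (k in unique(gid)) {
    rk <- r[gid == k]
    num <- num + length(rk) * (mean(rk) - rbar)^2
  }
  (n - 1) * num / ss
}

# Exact permutation p of the KW statistic by nested combination
# enumeration over distinct label assignments (2 or 3 groups).
oracle_perm_p <- function(values, labels) {
  labels <- as.character(labels)
  gid <- as.integer(factor(labels))
  sizes <- as.integer(table(gid))
  n <- sum(sizes)
  obs <- oracle_kw_stat(values, gid)
  eps <- 1e-9 * (1 + abs(obs))
  hits <- 0
  total <- 0
  if (length(sizes) == 2) {
    picks <- utils::combn(n, sizes[1])
    for (j in seq_len(ncol(picks))) {
      g <- rep(2L, n); g[picks[, j]] <- 1L
      total <- total + 1
      if (oracle_kw_stat(values, g) >= obs - eps) hits <- hits + 1
    }
  } else if (length(sizes) == 3) {
    picks1 <- utils::combn(n, sizes[1])
    for (j in seq_len(ncol(picks1))) {
      rest <- setdiff(seq_len(n), picks1[, j])
      picks2 <- utils::combn(length(rest), sizes[2])
      for (l in seq_len(ncol(picks2))) {
        g <- rep(3L, n)
        g[picks1[, j]] <- 1L
        g[rest[picks2[, l]]] <- 2L
        total <- total + 1
        if (oracle_kw_stat(values, g) >= obs - eps) hits <- hits + 1
      }
    }
  } else {
    stop("oracle supports 2 or 3 groups")
  }
  hits / total
}

# Exact two-sided rank-sum p by enumerating which ranks land in arm 1.
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  s_obs <- sum(r[seq_len(n1)])
  e <- n1 * (n + 1) / 2
  picks <- utils::combn(n, n1)
  s_all <- apply(picks, 2, function(idx) sum(r[idx]))
  mean(abs(s_all - e) >= abs(s_obs - e) - 1e-9)
}
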