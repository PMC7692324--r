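# Independent brute-force oracles. These re-derive expected results from
# first principles (sorting, enumeration, O(n^3) agglomeration) and never
# call the package's own code paths.

# Linear-interpolation quantile between order statistics (the convention the
# package's "linear" mode must reproduce), written from the definition.
oracle_quantile <- function(x, p) {
  s <- sort(x[!is.na(x)])
  n <- length(s)
  if (n == 1L) return(s)
  h <- (n - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
}

# Literal evaluation of the four quartile rules for one probe: group_values
# is a named list "<cancer>|<tissue>" -> numeric vector. Returns the winning
# (class, target) under precedence cancer_hyper > cancer_hypo > tissue_hyper
# > tissue_hypo and first-target-wins in `cancers` order.
oracle_classify <- function(group_values, cancers, hyper = 0.6, hypo = 0.3,
                            min_group_size = 2L) {
  vals <- lapply(group_values, function(v) v[!is.na(v)])
  if (any(lengths(vals) < min_group_size)) {
    return(list(call_class = "none", target_cancer = ""))
  }
  q1 <- vapply(vals, oracle_quantile, numeric(1L), p = 0.25)
  q3 <- vapply(vals, oracle_quantile, numeric(1L), p = 0.75)
  g <- function(c1, t1) paste(c1, t1, sep = "|")
  for (t in cancers) {
    o <- setdiff(cancers, t)
    oT <- g(o, "primary_tumor"); oN <- g(o, "normal_tissue")
    tT <- g(t, "primary_tumor"); tN <- g(t, "normal_tissue")
    others_low <- all(q3[oT] < hypo) && all(q3[oN] < hypo)
    others_high <- all(q1[oT] > hyper) && all(q1[oN] > hyper)
    cls <- if (q1[tT] > hyper && q3[tN] < hypo && others_low) "cancer_hyper"
      else if (q3[tT] < hypo && q1[tN] > hyper && others_high) "cancer_hypo"
      else if (q1[tT] > hyper && q1[tN] > hyper && others_low) "tissue_hyper"
      else if (q3[tT] < hypo && q3[tN] < hypo && others_high) "tissue_hypo"
      else "none"
    if (cls != "none") return(list(call_class = cls, target_cancer = t))
  }
  list(call_class = "none", target_cancer = "")
}

# Mann-Whitney U by direct pair counting plus exact two-sided p by full
# enumeration of all choose(n1+n2, n1) group labelings.
oracle_mann_whitney <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(x, y)
  pool <- c(x, y)
  n1 <- length(x)
  labelings <- utils::combn(length(pool), n1)
  us <- apply(labelings, 2L, function(idx) u_of(pool[idx], pool[-idx]))
  center <- n1 * length(y) / 2
  p <- if (u_obs > center) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  list(u = u_obs, p_value = min(p, 1))
}

# Hand step-up BH.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# O(n^3) UPGMA (average linkage) on Euclidean distances; returns the sorted
# merge heights.
oracle_upgma_heights <- function(m) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (i in seq_len(n - 1L)) {
      if (!active[i]) next
      for (j in (i + 1L):n) {
        if (!active[j]) next
        if (d[i, j] < best_d) { best_d <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    heights[step] <- best_d
    for (k in seq_len(n)) {
      if (k == i || k == j || !active[k]) next
      d[i, k] <- d[k, i] <-
        (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  sort(heights)
}
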