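# Independent oracles and fixture builders shared across tests.

# --- labelled-tree enumeration (Pruefer) -------------------------------

# Decode a Pruefer sequence into the edge list of a labelled tree on n
# nodes. Together with enumerating all sequences this yields every one of
# the n^(n-2) labelled spanning trees (Cayley).
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  k <- 0L
  for (s in seq) {
    leaf <- which(degree == 1L)[1L]
    k <- k + 1L
    edges[k, ] <- c(leaf, s)
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- last
  edges
}

all_spanning_trees <- function(n) {
  if (n == 2L) return(list(matrix(c(1L, 2L), nrow = 1L)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  lapply(seq_len(nrow(seqs)), function(r) prufer_decode(seqs[r, ], n))
}

# Maximum spanning-tree weight by exhaustive enumeration.
brute_max_tree_weight <- function(w) {
  n <- nrow(w)
  max(vapply(all_spanning_trees(n), function(e)
    sum(w[e]), numeric(1)))
}

# --- tree fixtures -----------------------------------------------------

star_tree <- function(n, weight = 0.5) {
  labs <- sprintf("n%02d", seq_len(n))
  spanning_tree(labs, data.frame(node_a = labs[1L], node_b = labs[-1L],
                                 weight = weight, stringsAsFactors = FALSE))
}

path_tree <- function(n, weight = 0.5) {
  labs <- sprintf("n%02d", seq_len(n))
  spanning_tree(labs, data.frame(node_a = labs[-n], node_b = labs[-1L],
                                 weight = weight, stringsAsFactors = FALSE))
}

random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq <- sample.int(n, n - 2L, replace = TRUE)
  e <- prufer_decode(seq, n)
  labs <- sprintf("n%02d", seq_len(n))
  spanning_tree(labs, data.frame(node_a = labs[e[, 1L]],
                                 node_b = labs[e[, 2L]],
                                 weight = runif(n - 1L),
                                 stringsAsFactors = FALSE))
}

rand_sym_matrix <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2)
  v <- v + t(v)
  dimnames(v) <- rep(list(sprintf("n%02d", seq_len(n))), 2)
  v
}

# Betweenness by brute-force path enumeration: for every ordered endpoint
# pair, walk the unique tree path (BFS parents) and count interior visits.
brute_betweenness <- function(tree) {
  n <- length(tree$nodes)
  ia <- match(tree$edges$node_a, tree$nodes)
  ib <- match(tree$edges$node_b, tree$nodes)
  adj <- vector("list", n)
  for (e in seq_along(ia)) {
    adj[[ia[e]]] <- c(adj[[ia[e]]], ib[e])
    adj[[ib[e]]] <- c(adj[[ib[e]]], ia[e])
  }
  path_between <- function(h, j) {
    parent <- rep(NA_integer_, n)
    seen <- logical(n); seen[h] <- TRUE
    queue <- h
    while (length(queue) > 0L) {
      x <- queue[[1L]]; queue <- queue[-1L]
      if (x == j) break
      for (y in adj[[x]]) if (!seen[y]) {
        seen[y] <- TRUE; parent[y] <- x; queue <- c(queue, y)
      }
    }
    path <- j
    while (!is.na(parent[path[1L]])) path <- c(parent[path[1L]], path)
    path
  }
  counts <- numeric(n)
  for (h in seq_len(n)) for (j in seq_len(n)) {
    if (h == j) next
    p <- path_between(h, j)
    interior <- setdiff(p, c(h, j))
    counts[interior] <- counts[interior] + 1
  }
  stats::setNames(counts / ((n - 1) * (n - 2)), tree$nodes)
}

# Manual sums-of-squares decomposition for the 2x2 fully within-subject
# ANOVA. `wide`: subjects x conditions (HAHV, HALV, LAHV, LALV).
manual_rm_anova <- function(wide) {
  ns <- nrow(wide)
  a_lev <- substr(colnames(wide), 1, 1)   # arousal H/L
  v_lev <- substr(colnames(wide), 3, 3)   # valence H/L
  gm <- mean(wide)
  m_s <- rowMeans(wide)
  m_a <- vapply(c("H", "L"), function(l) mean(wide[, a_lev == l]), 0)
  m_v <- vapply(c("H", "L"), function(l) mean(wide[, v_lev == l]), 0)
  m_sa <- sapply(c("H", "L"), function(l) rowMeans(wide[, a_lev == l]))
  m_sv <- sapply(c("H", "L"), function(l) rowMeans(wide[, v_lev == l]))
  m_av <- outer(c("H", "L"), c("H", "L"), Vectorize(function(a, v)
    mean(wide[, a_lev == a & v_lev == v])))
  ss_a <- ns * 2 * sum((m_a - gm)^2)
  ss_v <- ns * 2 * sum((m_v - gm)^2)
  ss_as <- 2 * sum((m_sa - outer(m_s, rep(1, 2)) -
                      outer(rep(1, ns), m_a) + gm)^2)
  ss_vs <- 2 * sum((m_sv - outer(m_s, rep(1, 2)) -
                      outer(rep(1, ns), m_v) + gm)^2)
  ss_av <- ns * sum((m_av - outer(m_a, rep(1, 2)) -
                       outer(rep(1, 2), m_v) + gm)^2)
  resid <- 0
  for (i in seq_len(ns)) for (c in seq_len(4L)) {
    ai <- match(a_lev[c], c("H", "L")); vi <- match(v_lev[c], c("H", "L"))
    fit <- m_sa[i, ai] + m_sv[i, vi] + m_av[ai, vi] -
      m_s[i] - m_a[ai] - m_v[vi] + gm
    resid <- resid + (wide[i, c] - fit)^2
  }
  f <- function(ss_e, ss_r) (ss_e / 1) / (ss_r / (ns - 1))
  list(
    arousal = list(F = f(ss_a, ss_as),
                   p = stats::pf(f(ss_a, ss_as), 1, ns - 1, lower.tail = FALSE),
                   es = ss_a / (ss_a + ss_as)),
    valence = list(F = f(ss_v, ss_vs),
                   p = stats::pf(f(ss_v, ss_vs), 1, ns - 1, lower.tail = FALSE),
                   es = ss_v / (ss_v + ss_vs)),
    interaction = list(F = f(ss_av, resid),
                       p = stats::pf(f(ss_av, resid), 1, ns - 1,
                                     lower.tail = FALSE),
                       es = ss_av / (ss_av + resid))
  )
}

# Long metric table from a subjects x conditions matrix of one metric.
wide_to_table <- function(wide, metric = "mpli", band = "gamma") {
  data.frame(
    subject_id = rep(rownames(wide) %||% as.character(seq_len(nrow(wide))),
                     times = 4L),
    condition = rep(colnames(wide), each = nrow(wide)),
    band = band, metric = metric, value = as.vector(wide),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny classified study fixture for io/pipeline tests.
tiny_study <- function(n_subjects = 3L, trials_per_condition = 1L,
                       duration = 5, seed = 99L, ...) {
  cfg <- group_sim_config(n_subjects = n_subjects,
                          trials_per_condition = trials_per_condition,
                          duration = duration, n_channels = 16L,
                          seed = seed, ...)
  classify_study(generate_group(cfg))
}
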