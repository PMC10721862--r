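# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations they check.

# Pearson correlation + Fisher z by explicit summation.
oracle_fisher_z <- function(a, b, clipval = 1 - 1e-7) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  r <- num / den
  r <- max(min(r, clipval), -clipval)
  0.5 * log((1 + r) / (1 - r))
}

# GBC by an explicit double loop over mask voxels.
oracle_gbc <- function(x) {
  nv <- nrow(x)
  out <- numeric(nv)
  for (i in seq_len(nv)) {
    acc <- 0
    for (j in seq_len(nv)) {
      if (i != j) acc <- acc + oracle_fisher_z(x[i, ], x[j, ])
    }
    out[i] <- acc / (nv - 1)
  }
  out
}

# Sample entropy by explicit template counting with the standardized
# Euclidean match rule.
oracle_sampen <- function(x, m = 3, r = 0.2) {
  x <- (x - mean(x)) / sd(x)
  n <- length(x)
  count <- function(mm) {
    nt <- n - m
    emb <- matrix(0, nt, mm)
    for (i in seq_len(nt)) emb[i, ] <- x[i:(i + mm - 1)]
    s <- numeric(mm)
    for (k in seq_len(mm)) s[k] <- sd(emb[, k])
    s[s == 0] <- 1
    hits <- 0L
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        dd <- 0
        for (k in seq_len(mm)) dd <- dd + ((emb[i, k] - emb[j, k]) / s[k])^2
        if (sqrt(dd) <= r * sqrt(mm)) hits <- hits + 1L
      }
    }
    hits
  }
  b <- count(m)
  a <- count(m + 1)
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# One-way two-group F by explicit sums of squares.
oracle_oneway_f <- function(y, g) {
  lev <- unique(g)
  y1 <- y[g == lev[1]]; y2 <- y[g == lev[2]]
  gm <- mean(y)
  ssb <- length(y1) * (mean(y1) - gm)^2 + length(y2) * (mean(y2) - gm)^2
  ssw <- sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)
  (ssb / 1) / (ssw / (length(y) - 2))
}

# Connected components of an edge list by union-find.
oracle_components <- function(from, to) {
  nodes <- unique(c(from, to))
  parent <- stats::setNames(nodes, nodes)
  find <- function(v) {
    while (parent[[v]] != v) v <- parent[[v]]
    v
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(nodes, find, "")
  split(nodes, roots)
}

# Nodal strength and participation coefficient by explicit loops.
oracle_local <- function(w, part) {
  n <- nrow(w)
  strength <- numeric(n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ])
    strength[i] <- k
    acc <- 0
    for (s in unique(part)) {
      ks <- sum(w[i, part == s])
      acc <- acc + (ks / k)^2
    }
    p[i] <- 1 - acc
  }
  list(strength = strength, participation = p)
}

# Small band-limited test session shared by several suites.
quick_session <- function(subject = NULL, treatment = "psilocybin",
                          seed = 1, n_frames = 680, ...) {
  if (is.null(subject)) {
    subject <- list(subject_id = "S01", group = "control",
                    relapse_norm = NA_real_)
  }
  simulate_session(subject, treatment, effect_spec(...), seed = seed,
                   n_frames = n_frames)
}
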