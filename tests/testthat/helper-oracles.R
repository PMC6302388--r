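# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (apart from plain data containers) so they can certify the
# fast implementations.

# All maximal cliques by exhaustive subset enumeration (bitmask; n <= 30).
oracle_max_cliques <- function(net, min_size = 3L) {
  n <- length(net$proteins)
  if (n == 0L) return(list())
  A <- matrix(0L, n, n)
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges[, 1L], net$proteins)
    j <- match(net$edges[, 2L], net$proteins)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  nbmask <- integer(n)
  for (v in seq_len(n)) {
    nbmask[v] <- sum(bitwShiftL(1L, which(A[v, ] == 1L) - 1L))
  }
  bits <- 0:(n - 1L)
  out <- list()
  for (S in seq_len(bitwShiftL(1L, n) - 1L)) {
    verts <- which(bitwAnd(bitwShiftR(S, bits), 1L) == 1L)
    if (length(verts) < min_size) next
    is_clique <- all(vapply(verts, function(v) {
      bitwAnd(nbmask[v], S) == S - bitwShiftL(1L, v - 1L)
    }, logical(1L)))
    if (!is_clique) next
    outside <- setdiff(seq_len(n), verts)
    is_maximal <- !any(vapply(outside, function(u) {
      bitwAnd(nbmask[u], S) == S
    }, logical(1L)))
    if (is_maximal) {
      out[[length(out) + 1L]] <- sort(net$proteins[verts], method = "radix")
    }
  }
  keys <- vapply(out, paste, character(1L), collapse = " ")
  out[order(keys, method = "radix")]
}

# Joint loss by a literal double loop over ordered pairs i != j.
oracle_loss <- function(phi, A, S, lambda) {
  n <- nrow(phi)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      total <- total + A[i, j] * sum((phi[i, ] - phi[j, ])^2) +
        lambda * (S[i, j] - sum(phi[i, ] * phi[j, ]))^2
    }
  }
  total
}

# Binary-row cosine affinity by a literal double loop.
oracle_affinity <- function(O) {
  n <- nrow(O)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ni <- sqrt(sum(O[i, ]^2))
      nj <- sqrt(sum(O[j, ]^2))
      S[i, j] <- if (ni > 0 && nj > 0) sum(O[i, ] * O[j, ]) / (ni * nj) else 0
    }
  }
  S
}

# Full metric suite by literal nested loops on lists of member vectors.
oracle_metrics <- function(P, B, omega = 0.25) {
  ncp <- 0L
  for (p in P) {
    hit <- FALSE
    for (b in B) {
      na <- length(intersect(p, b))^2 / (length(p) * length(b))
      if (na >= omega) hit <- TRUE
    }
    if (hit) ncp <- ncp + 1L
  }
  ncb <- 0L
  for (b in B) {
    hit <- FALSE
    for (p in P) {
      na <- length(intersect(p, b))^2 / (length(p) * length(b))
      if (na >= omega) hit <- TRUE
    }
    if (hit) ncb <- ncb + 1L
  }
  precision <- if (length(P) > 0L) ncp / length(P) else 0
  recall <- ncb / length(B)
  fscore <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  sn_num <- 0; sn_den <- 0
  for (b in B) {
    best <- 0
    for (p in P) best <- max(best, length(intersect(b, p)))
    sn_num <- sn_num + best
    sn_den <- sn_den + length(b)
  }
  ppv_num <- 0; ppv_den <- 0
  for (p in P) {
    best <- 0
    for (b in B) {
      tij <- length(intersect(b, p))
      best <- max(best, tij)
      ppv_den <- ppv_den + tij
    }
    ppv_num <- ppv_num + best
  }
  sn <- sn_num / sn_den
  ppv <- if (ppv_den > 0) ppv_num / ppv_den else 0
  list(n_cp = ncp, n_cb = ncb, precision = precision, recall = recall,
       fscore = fscore, sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

# Central finite-difference gradient of gane_loss at phi.
numeric_gradient <- function(phi, net, S, lambda, h = 1e-5) {
  g <- matrix(0, nrow(phi), ncol(phi))
  for (i in seq_len(nrow(phi))) {
    for (k in seq_len(ncol(phi))) {
      up <- phi; up[i, k] <- up[i, k] + h
      dn <- phi; dn[i, k] <- dn[i, k] - h
      g[i, k] <- (gane_loss(up, net, S, lambda) -
                    gane_loss(dn, net, S, lambda)) / (2 * h)
    }
  }
  g
}

# Random test-data builders --------------------------------------------------

rand_gnp_network <- function(n, p) {
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2L))
  hit <- stats::runif(nrow(pairs)) < p
  ppi_network(pairs[hit, , drop = FALSE], proteins = ids)
}

rand_complex_list <- function(n_complexes, universe, size_range = c(2L, 8L)) {
  lapply(seq_len(n_complexes), function(i) {
    sample(universe, sample(seq(size_range[1L], size_range[2L]), 1L))
  })
}

make_weighted <- function(net, weights) {
  # weights: named numeric, names "a b" with a < b; unset edges get 0
  n <- length(net$proteins)
  W <- matrix(0, n, n, dimnames = list(net$proteins, net$proteins))
  for (nm in names(weights)) {
    ab <- strsplit(nm, " ", fixed = TRUE)[[1L]]
    W[ab[1L], ab[2L]] <- weights[[nm]]
    W[ab[2L], ab[1L]] <- weights[[nm]]
  }
  W
}
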