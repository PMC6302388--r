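# Joint topology + attribute embedding, fitted by exact block-coordinate
# descent, and the cosine-reweighted adjacency derived from it.

#' Embedding configuration
#'
#' @param d embedding dimension (default 128).
#' @param lambda trade-off between the topological and attribute losses
#'   (default 0.1); larger values weight attribute affinity more.
#' @param max_sweeps maximum number of full coordinate-descent sweeps.
#' @param tol convergence tolerance on the relative loss change per sweep.
#' @param seed RNG seed for the random initialization.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(d = 128L, lambda = 0.1, max_sweeps = 50L,
                             tol = 1e-6, seed = 1L) {
  stopifnot(d >= 1L, lambda >= 0, max_sweeps >= 1L, tol > 0)
  structure(list(d = as.integer(d), lambda = lambda,
                 max_sweeps = as.integer(max_sweeps), tol = tol,
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Joint embedding loss
#'
#' Evaluates the objective minimized by [fit_embedding()]:
#' \deqn{\ell = \sum_{i \ne j} a_{ij} \|\varphi_i - \varphi_j\|^2
#'   + \lambda \sum_{i \ne j} (s_{ij} - \varphi_i \varphi_j^T)^2,}
#' both sums over ordered pairs (each unordered pair counted twice),
#' diagonal excluded.
#'
#' @param phi n x d numeric matrix of embedding vectors (rows in network
#'   vertex order).
#' @param net a [ppi_network].
#' @param S n x n attribute affinity matrix (see [build_affinity()]).
#' @param lambda trade-off parameter.
#' @return The scalar loss.
#' @export
gane_loss <- function(phi, net, S, lambda) {
  n <- length(net$proteins)
  if (nrow(phi) != n || nrow(S) != n || ncol(S) != n) {
    stop("dimension mismatch between phi, S and the network")
  }
  l1 <- 0
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges[, 1L], net$proteins)
    j <- match(net$edges[, 2L], net$proteins)
    d2 <- rowSums((phi[i, , drop = FALSE] - phi[j, , drop = FALSE])^2)
    l1 <- 2 * sum(d2)  # each unordered edge counted for (i,j) and (j,i)
  }
  E <- S - tcrossprod(phi)
  l2 <- sum(E^2) - sum(diag(E)^2)
  l1 + lambda * l2
}

#' Fit the joint embedding
#'
#' Learns one vector per protein by minimizing [gane_loss()] with exact
#' block-coordinate descent: holding all other rows fixed, row i's
#' subproblem is an unconstrained convex quadratic solved in closed form via
#' a d x d linear system
#' \deqn{\big(\mathrm{deg}_i I + \lambda \sum_{j \ne i} \varphi_j \varphi_j^T\big)\,
#'   \varphi_i = \sum_{j} a_{ij} \varphi_j + \lambda \sum_{j \ne i} s_{ij} \varphi_j.}
#' Rows are swept in vertex order until the relative loss change drops below
#' `config$tol` or `config$max_sweeps` is reached. Because every row solve is
#' an exact minimization, the per-sweep loss trace is non-increasing.
#' Initialization is i.i.d. uniform on \eqn{[-0.5/d, 0.5/d]} from the seeded
#' RNG, so the fit is deterministic given the seed.
#'
#' @param net a [ppi_network].
#' @param attr an `attribute_data`; [build_affinity()] is applied if `S` is
#'   not yet filled.
#' @param config an [embedding_config()].
#' @return An object of class `gane_embedding` with elements `phi` (n x d,
#'   rownames are protein IDs), `loss`, `trace` (loss after each sweep,
#'   element 1 is the initial loss) and `config`.
#' @export
fit_embedding <- function(net, attr, config = embedding_config()) {
  stopifnot(inherits(net, "ppi_network"), inherits(attr, "attribute_data"),
            inherits(config, "embedding_config"))
  if (is.null(attr$S)) attr <- build_affinity(attr)
  if (!identical(attr$proteins, net$proteins)) {
    stop("attribute data and network have different protein universes")
  }
  n <- length(net$proteins)
  stopifnot(n >= 1L)
  d <- config$d
  lambda <- config$lambda
  S <- attr$S
  old_seed <- snapshot_seed()
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)
  phi <- matrix(stats::runif(n * d, -0.5 / d, 0.5 / d), n, d)
  nb <- lapply(neighbor_list(net), match, net$proteins)
  G <- crossprod(phi)  # running Phi^T Phi, rank-1 updated per row solve
  Id <- diag(1, d)
  trace <- gane_loss(phi, net, S, lambda)
  loss_prev <- trace[1L]
  n_ridge <- 0L
  for (sweep in seq_len(config$max_sweeps)) {
    for (i in seq_len(n)) {
      old <- phi[i, ]
      idx <- nb[[i]]
      deg <- length(idx)
      M <- deg * Id + lambda * (G - tcrossprod(old))
      rhs <- lambda * (crossprod(phi, S[, i])[, 1L] - S[i, i] * old)
      if (deg > 0L) rhs <- rhs + colSums(phi[idx, , drop = FALSE])
      new <- if (deg == 0L && all(rhs == 0)) {
        # isolated node with no affinity: the row objective
        # lambda * sum_j (x . phi_j)^2 is globally minimized at 0
        numeric(d)
      } else {
        tryCatch(solve(M, rhs), error = function(e) {
          n_ridge <<- n_ridge + 1L
          solve(M + (1e-10 + 1e-10 * mean(abs(diag(M)))) * Id, rhs)
        })
      }
      phi[i, ] <- new
      G <- G + tcrossprod(new) - tcrossprod(old)
    }
    loss <- gane_loss(phi, net, S, lambda)
    trace <- c(trace, loss)
    if (abs(loss_prev - loss) < config$tol * max(1, abs(loss_prev))) {
      loss_prev <- loss
      break
    }
    loss_prev <- loss
  }
  if (n_ridge > 0L) {
    message(sprintf("%d singular row system(s) solved with ridge jitter",
                    n_ridge))
  }
  rownames(phi) <- net$proteins
  structure(list(phi = phi, loss = loss_prev, trace = trace, config = config),
            class = "gane_embedding")
}

#' @export
print.gane_embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d proteins in R^%d, loss %.6g after %d sweep(s)\n",
              nrow(x$phi), ncol(x$phi), x$loss, length(x$trace) - 1L))
  invisible(x)
}

#' Cosine-reweighted adjacency
#'
#' Replaces each interaction's unit weight by the cosine similarity of the
#' two endpoint embeddings:
#' \deqn{w_{ij} = \cos(\varphi_i, \varphi_j) \text{ if } a_{ij} = 1,
#'   \quad 0 \text{ otherwise}.}
#' The cosine with a zero vector is 0. Negative cosines are kept by default
#' (set `clamp = TRUE` to floor weights at 0).
#'
#' @param embedding a `gane_embedding`.
#' @param net the [ppi_network] the embedding was fitted on.
#' @param clamp floor negative weights at 0.
#' @return A symmetric n x n numeric matrix with protein IDs as dimnames;
#'   nonzero only on network edges.
#' @export
build_weighted_adjacency <- function(embedding, net, clamp = FALSE) {
  stopifnot(inherits(embedding, "gane_embedding"),
            inherits(net, "ppi_network"))
  phi <- embedding$phi
  if (!identical(rownames(phi), net$proteins)) {
    stop("embedding rows do not match the network's proteins")
  }
  n <- length(net$proteins)
  W <- matrix(0, n, n, dimnames = list(net$proteins, net$proteins))
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges[, 1L], net$proteins)
    j <- match(net$edges[, 2L], net$proteins)
    norms <- sqrt(rowSums(phi^2))
    dots <- rowSums(phi[i, , drop = FALSE] * phi[j, , drop = FALSE])
    denom <- norms[i] * norms[j]
    w <- ifelse(denom > 0, dots / denom, 0)
    if (clamp) w <- pmax(w, 0)
    W[cbind(i, j)] <- w
    W[cbind(j, i)] <- w
  }
  W
}

#' Export an embedding matrix
#'
#' Tab-separated: first column `protein`, then one column per embedding
#' dimension (`V1..Vd`). [read_embedding()] round-trips the file.
#'
#' @param embedding a `gane_embedding`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "gane_embedding"))
  df <- data.frame(protein = rownames(embedding$phi), embedding$phi)
  colnames(df) <- c("protein", paste0("V", seq_len(ncol(embedding$phi))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import an embedding matrix
#'
#' @param path a file written by [write_embedding()].
#' @return A `gane_embedding` (with `loss`/`trace` unset).
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  phi <- unname(as.matrix(df[, -1L, drop = FALSE]))
  rownames(phi) <- df[[1L]]
  structure(list(phi = phi, loss = NA_real_, trace = numeric(),
                 config = NULL),
            class = "gane_embedding")
}
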