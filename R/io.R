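# Input/output and the two basic domain containers: ppi_network, complex_set.

# Locale-independent sort so matrix row order is reproducible across machines.
sort_ids <- function(x) sort(unique(as.character(x)), method = "radix")

# Seed the RNG for the calling function only; the caller of THAT function
# gets its random stream back untouched. Usage:
#   on.exit(restore_seed(snapshot_seed()), ...) would run too late, so the
#   pattern is: old <- snapshot_seed(); on.exit(restore_seed(old)); set.seed(s)
snapshot_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Construct a PPI network
#'
#' An undirected simple graph over protein identifiers. Self-loops are
#' removed, duplicate edges (in either orientation) collapse to one, and the
#' vertex order is lexicographic so that every derived matrix (adjacency,
#' attribute, affinity, weight) has a reproducible row order.
#'
#' @param edges two-column character matrix or data frame of interacting
#'   protein pairs; may be `NULL` for an edgeless network.
#' @param proteins optional character vector of protein IDs to include even
#'   if isolated; the final vertex set is the union with edge endpoints.
#' @return An object of class `ppi_network` with elements `proteins`
#'   (sorted character vector) and `edges` (two-column character matrix,
#'   each row sorted, rows deduplicated and ordered).
#' @export
ppi_network <- function(edges = NULL, proteins = character()) {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2L) stop("edges must have two columns")
    edges <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
    keep <- edges[, 1L] != edges[, 2L]
    edges <- edges[keep, , drop = FALSE]
    if (nrow(edges) > 0L) {
      a <- pmin(edges[, 1L], edges[, 2L])
      b <- pmax(edges[, 1L], edges[, 2L])
      key <- paste(a, b, sep = "\t")
      ord <- order(key, method = "radix")
      dup <- duplicated(key[ord])
      edges <- cbind(a[ord][!dup], b[ord][!dup])
    }
  }
  proteins <- sort_ids(c(as.character(proteins), as.vector(edges)))
  structure(list(proteins = proteins, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d proteins, %d interactions\n",
              length(x$proteins), nrow(x$edges)))
  invisible(x)
}

#' Read a PPI edge list
#'
#' Reads a plain-text edge list, one interaction per line, tab or space
#' separated; the first two tokens on each line are protein IDs. Self-loops
#' are dropped (with a message giving the count) and duplicate edges in
#' either orientation collapse to one.
#'
#' @param path path to the edge-list file.
#' @param comment lines starting with this prefix are ignored.
#' @return A [ppi_network].
#' @export
read_edge_list <- function(path, comment = "#") {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(ppi_network())
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("parse error at line %d: expected at least 2 fields",
                 lineno[bad[1L]]))
  }
  a <- vapply(toks, `[[`, character(1L), 1L)
  b <- vapply(toks, `[[`, character(1L), 2L)
  n_self <- sum(a == b)
  if (n_self > 0L) message(sprintf("dropped %d self-loop(s)", n_self))
  # proteins seen only in dropped self-loops stay in the vertex set
  ppi_network(cbind(a, b), proteins = c(a, b))
}

# Aspect letter of the go_slim_mapping dialect -> two-letter GO aspect code.
.aspect_map <- c(P = "Bp", F = "Mf", C = "Cc",
                 Bp = "Bp", Mf = "Mf", Cc = "Cc")

#' Read a GO slim annotation table
#'
#' Reads the tab-separated `go_slim_mapping.tab` dialect: column 1 is the
#' systematic protein name, column 4 the single-letter ontology aspect
#' (P = biological process, F = molecular function, C = cellular component)
#' and column 5 the GO slim term. Cellular-component annotations are excluded
#' by default because GO slim Cc terms themselves encode protein-complex
#' membership and would leak the answer into the attributes.
#'
#' @param path path to the annotation file.
#' @param keep_aspects aspects to retain, a subset of `c("Bp","Mf","Cc")`.
#' @return A data frame with columns `protein`, `term`, `aspect`, duplicate
#'   (protein, term) rows collapsed.
#' @export
read_go_slim <- function(path, keep_aspects = c("Bp", "Mf")) {
  if (!file.exists(path)) stop("cannot read GO slim table: ", path)
  stopifnot(all(keep_aspects %in% c("Bp", "Mf", "Cc")))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "!")]
  if (length(lines) == 0L) {
    return(data.frame(protein = character(), term = character(),
                      aspect = character(), stringsAsFactors = FALSE))
  }
  toks <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(toks) < 5L)) {
    stop("parse error: expected >= 5 tab-separated columns ",
         "(go_slim_mapping dialect with an aspect column)")
  }
  protein <- vapply(toks, `[[`, character(1L), 1L)
  code <- vapply(toks, `[[`, character(1L), 4L)
  term <- vapply(toks, `[[`, character(1L), 5L)
  aspect <- unname(.aspect_map[code])
  unknown <- is.na(aspect)
  if (any(unknown)) {
    warning(sprintf("skipped %d row(s) with unknown aspect code(s): %s",
                    sum(unknown), paste(unique(code[unknown]), collapse = ", ")))
  }
  keep <- !unknown & aspect %in% keep_aspects
  out <- data.frame(protein = protein[keep], term = term[keep],
                    aspect = aspect[keep], stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$protein, out$term, sep = "\t")), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a complex set
#'
#' An ordered collection of protein complexes, each a set of protein IDs
#' (stored sorted). Predicted sets may carry the core/attachment split and
#' the seed-core density score.
#'
#' @param complexes list of character vectors of protein IDs.
#' @param cores,attachments optional parallel lists splitting each complex
#'   into its seed core and attachment proteins.
#' @param density optional numeric vector of seed-core density scores.
#' @return An object of class `complex_set`.
#' @export
complex_set <- function(complexes, cores = NULL, attachments = NULL,
                        density = NULL) {
  complexes <- lapply(complexes, function(x) sort_ids(x))
  if (any(lengths(complexes) < 1L)) stop("each complex needs >= 1 member")
  if (!is.null(cores)) {
    stopifnot(length(cores) == length(complexes))
    cores <- lapply(cores, sort_ids)
  }
  if (!is.null(attachments)) {
    stopifnot(length(attachments) == length(complexes))
    attachments <- lapply(attachments, sort_ids)
  }
  structure(list(complexes = complexes, cores = cores,
                 attachments = attachments, density = density),
            class = "complex_set")
}

#' @export
length.complex_set <- function(x) length(x$complexes)

#' @export
print.complex_set <- function(x, ...) {
  sizes <- lengths(x$complexes)
  cat(sprintf("Complex set: %d complexes (sizes %s)\n", length(sizes),
              if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-"))
  invisible(x)
}

#' Read a complex file
#'
#' One complex per line, whitespace-separated protein IDs. The annotated
#' dialect marks the core/attachment split with a `|` separator:
#' `core IDs | attachment IDs`.
#'
#' @param path path to the complex file.
#' @return A [complex_set]; core/attachment annotation is populated when the
#'   file uses the annotated dialect.
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) stop("cannot read complex file: ", path)
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) warning(sprintf("skipped %d empty line(s)", sum(blank)))
  lines <- lines[!blank]
  if (length(lines) == 0L) {
    return(complex_set(list()))
  }
  has_bar <- grepl("|", lines, fixed = TRUE)
  complexes <- vector("list", length(lines))
  cores <- if (any(has_bar)) vector("list", length(lines)) else NULL
  atts <- if (any(has_bar)) vector("list", length(lines)) else NULL
  for (i in seq_along(lines)) {
    if (has_bar[i]) {
      parts <- strsplit(lines[i], "|", fixed = TRUE)[[1L]]
      core <- strsplit(trimws(parts[1L]), "[ \t]+")[[1L]]
      att <- if (length(parts) > 1L && nzchar(trimws(parts[2L]))) {
        strsplit(trimws(parts[2L]), "[ \t]+")[[1L]]
      } else character()
      complexes[[i]] <- c(core, att)
      cores[[i]] <- core
      atts[[i]] <- att
    } else {
      complexes[[i]] <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
      if (!is.null(cores)) {
        cores[[i]] <- complexes[[i]]
        atts[[i]] <- character()
      }
    }
  }
  complex_set(complexes, cores = cores, attachments = atts)
}

#' Write a complex file
#'
#' Writes one complex per line. When the set carries a core/attachment
#' split the annotated dialect `core IDs | attachment IDs` is used, which
#' [read_complexes()] round-trips.
#'
#' @param x a [complex_set].
#' @param path output path.
#' @param annotated write the core/attachment dialect if the split is
#'   present (default); set `FALSE` to force the plain dialect.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(x, path, annotated = TRUE) {
  stopifnot(inherits(x, "complex_set"))
  if (annotated && !is.null(x$cores)) {
    lines <- vapply(seq_along(x$complexes), function(i) {
      att <- x$attachments[[i]]
      if (length(att) > 0L) {
        paste(paste(x$cores[[i]], collapse = " "), "|",
              paste(att, collapse = " "))
      } else {
        paste(x$cores[[i]], collapse = " ")
      }
    }, character(1L))
  } else {
    lines <- vapply(x$complexes, paste, character(1L), collapse = " ")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Drop complexes below a minimum size
#'
#' Complexes with fewer than `k` members are removed; order is preserved.
#' Both predictions and references are conventionally filtered at `k = 3`
#' before evaluation.
#'
#' @param x a [complex_set].
#' @param k minimum complex size (`>= 1`).
#' @return The filtered [complex_set].
#' @export
filter_min_size <- function(x, k = 3L) {
  stopifnot(inherits(x, "complex_set"), k >= 1L)
  keep <- lengths(x$complexes) >= k
  complex_set(x$complexes[keep],
              cores = if (!is.null(x$cores)) x$cores[keep],
              attachments = if (!is.null(x$attachments)) x$attachments[keep],
              density = if (!is.null(x$density)) x$density[keep])
}

# 0/1 dense adjacency with dimnames in network vertex order.
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- length(net$proteins)
  a <- matrix(0, n, n, dimnames = list(net$proteins, net$proteins))
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges[, 1L], net$proteins)
    j <- match(net$edges[, 2L], net$proteins)
    a[cbind(i, j)] <- 1
    a[cbind(j, i)] <- 1
  }
  a
}

# Named list: protein ID -> character vector of neighbor IDs.
neighbor_list <- function(net) {
  out <- stats::setNames(vector("list", length(net$proteins)), net$proteins)
  for (k in seq_along(out)) out[[k]] <- character()
  if (nrow(net$edges) > 0L) {
    for (r in seq_len(nrow(net$edges))) {
      a <- net$edges[r, 1L]; b <- net$edges[r, 2L]
      out[[a]] <- c(out[[a]], b)
      out[[b]] <- c(out[[b]], a)
    }
  }
  out
}

as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  df <- as.data.frame(net$edges, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = net$proteins)
}
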