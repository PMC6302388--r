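# Evaluation of predicted complexes against a reference catalogue:
# neighborhood-affinity matching, Precision/Recall/F-score, and the
# clustering-wise Sn/PPV/Acc family.

#' Neighborhood affinity score
#'
#' Overlap-based similarity between a predicted and a reference complex:
#' \deqn{NA(p, b) = \frac{|V_p \cap V_b|^2}{|V_p| \times |V_b|}.}
#' A prediction is conventionally declared a match when
#' \eqn{NA \ge \omega = 0.25}.
#'
#' @param p,b nonempty character vectors of protein IDs.
#' @return The scalar affinity in `[0, 1]`.
#' @export
na_score <- function(p, b) {
  if (length(p) == 0L || length(b) == 0L) stop("complexes must be nonempty")
  length(intersect(p, b))^2 / (length(unique(p)) * length(unique(b)))
}

#' Matched-complex counts
#'
#' `n_cp` is the number of predicted complexes matching (NA >= omega) at
#' least one reference complex; `n_cb` the number of reference complexes
#' matched by at least one prediction.
#'
#' @param pred,ref [complex_set]s of predictions and references.
#' @param omega matching threshold in `(0, 1]`; the comparison is `>=`.
#' @return Named list with `n_cp` and `n_cb`.
#' @export
match_counts <- function(pred, ref, omega = 0.25) {
  stopifnot(inherits(pred, "complex_set"), inherits(ref, "complex_set"),
            omega > 0, omega <= 1)
  P <- pred$complexes
  B <- ref$complexes
  if (length(P) == 0L || length(B) == 0L) {
    return(list(n_cp = 0L, n_cb = 0L))
  }
  M <- matrix(0, length(P), length(B))
  for (i in seq_along(P)) {
    for (j in seq_along(B)) M[i, j] <- na_score(P[[i]], B[[j]])
  }
  list(n_cp = sum(apply(M >= omega, 1L, any)),
       n_cb = sum(apply(M >= omega, 2L, any)))
}

#' Precision, Recall and F-score from match counts
#'
#' Precision = n_cp / |P|, Recall = n_cb / |B|, F-score their harmonic
#' mean. Degenerate cases (no predictions; Precision + Recall = 0) yield 0.
#'
#' @param n_cp,n_cb matched counts from [match_counts()].
#' @param n_pred,n_ref sizes of the predicted and reference sets
#'   (`n_ref >= 1`).
#' @return Named list with `precision`, `recall`, `fscore`.
#' @export
precision_recall_f <- function(n_cp, n_cb, n_pred, n_ref) {
  stopifnot(n_pred >= 0, n_ref >= 1)
  precision <- if (n_pred > 0) n_cp / n_pred else 0
  recall <- n_cb / n_ref
  fscore <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, fscore = fscore)
}

#' Clustering-wise sensitivity, PPV and geometric accuracy
#'
#' With \eqn{T_{ij}} the number of proteins shared by reference complex i
#' and predicted complex j, and \eqn{N_i} the size of reference complex i:
#' \deqn{Sn = \frac{\sum_i \max_j T_{ij}}{\sum_i N_i}, \quad
#'   PPV = \frac{\sum_j \max_i T_{ij}}{\sum_j \sum_i T_{ij}}, \quad
#'   Acc = \sqrt{Sn \cdot PPV}.}
#' Predictions with no overlap with any reference contribute 0 to both the
#' PPV numerator and denominator; an all-zero overlap matrix yields
#' PPV = Acc = 0 with a warning.
#'
#' @param pred,ref nonempty [complex_set]s.
#' @return Named list with `sn`, `ppv`, `acc`.
#' @export
sn_ppv_acc <- function(pred, ref) {
  stopifnot(inherits(pred, "complex_set"), inherits(ref, "complex_set"),
            length(pred) >= 1L, length(ref) >= 1L)
  B <- ref$complexes
  P <- pred$complexes
  Tm <- matrix(0, length(B), length(P))
  for (i in seq_along(B)) {
    for (j in seq_along(P)) Tm[i, j] <- length(intersect(B[[i]], P[[j]]))
  }
  sn <- sum(apply(Tm, 1L, max)) / sum(lengths(B))
  denom <- sum(Tm)
  if (denom > 0) {
    ppv <- sum(apply(Tm, 2L, max)) / denom
  } else {
    warning("predictions share no protein with the reference; PPV set to 0")
    ppv <- 0
  }
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Composite score
#'
#' Sum of F-score and geometric accuracy, the single-number summary used to
#' compare detection methods.
#'
#' @param fscore,acc values in `[0, 1]`.
#' @return `fscore + acc`.
#' @export
composite_score <- function(fscore, acc) {
  stopifnot(fscore >= 0, fscore <= 1, acc >= 0, acc <= 1)
  fscore + acc
}

#' Evaluate predicted complexes against a reference
#'
#' Computes the full report: matched counts at threshold `omega`,
#' Precision/Recall/F-score, Sn/PPV/Acc, and the composite score
#' (F-score + Acc). Both sets are size-filtered (default: at least 3
#' members) before scoring, the convention under which detection methods
#' are compared.
#'
#' @param pred,ref [complex_set]s.
#' @param omega neighborhood-affinity matching threshold.
#' @param min_size size filter applied to both sets; `1` disables it.
#' @return An object of class `gane_eval`: a named list with `n_pred`,
#'   `n_ref`, `n_cp`, `n_cb`, `precision`, `recall`, `fscore`, `sn`, `ppv`,
#'   `acc`, `composite` and `omega`.
#' @export
evaluate_complexes <- function(pred, ref, omega = 0.25, min_size = 3L) {
  pred <- filter_min_size(pred, min_size)
  ref <- filter_min_size(ref, min_size)
  mc <- match_counts(pred, ref, omega)
  if (length(ref) < 1L) stop("reference set is empty after size filtering")
  prf <- precision_recall_f(mc$n_cp, mc$n_cb, length(pred), length(ref))
  spa <- if (length(pred) >= 1L) {
    sn_ppv_acc(pred, ref)
  } else {
    list(sn = 0, ppv = 0, acc = 0)
  }
  structure(c(list(n_pred = length(pred), n_ref = length(ref)), mc, prf, spa,
              list(composite = composite_score(prf$fscore, spa$acc),
                   omega = omega)),
            class = "gane_eval")
}

#' @export
print.gane_eval <- function(x, ...) {
  cat(sprintf("Complex evaluation (omega = %.2f)\n", x$omega))
  cat(sprintf("  predicted %4d   matched %4d   Precision %.3f\n",
              x$n_pred, x$n_cp, x$precision))
  cat(sprintf("  reference %4d   matched %4d   Recall    %.3f\n",
              x$n_ref, x$n_cb, x$recall))
  cat(sprintf("  F-score %.3f   Sn %.3f   PPV %.3f   Acc %.3f\n",
              x$fscore, x$sn, x$ppv, x$acc))
  cat(sprintf("  composite (F-score + Acc) %.3f\n", x$composite))
  invisible(x)
}

#' Write an evaluation report
#'
#' Machine-readable `key: value` lines, one metric per line.
#'
#' @param report a `gane_eval`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "gane_eval"))
  vals <- unclass(report)
  writeLines(sprintf("%s: %.6g", names(vals), unlist(vals)), path)
  invisible(path)
}
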