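#' Greedy polarity-invariant matching between two template sets
#'
#' Pairs templates of `set1` with templates of `set2` by repeatedly taking
#' the remaining pair with the largest absolute spatial correlation. Used
#' to align recovered templates with planted ones, or templates across
#' bands/states, before any comparison — labels from polarity-invariant
#' clustering are arbitrary in both order and sign.
#'
#' @param set1,set2 [template_set()] objects or K x C matrices with matching
#'   channel order.
#' @return A tibble with one row per matched pair: `index1`, `index2`,
#'   `correlation` (signed), `abs_correlation`.
#' @export
match_templates <- function(set1, set2) {
  m1 <- if (inherits(set1, "template_set")) set1$maps else as.matrix(set1)
  m2 <- if (inherits(set2, "template_set")) set2$maps else as.matrix(set2)
  r <- spatial_cor_matrix(m1, m2)
  k <- min(nrow(m1), nrow(m2))
  a <- abs(r)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    best <- which(a == max(a), arr.ind = TRUE)[1L, ]
    out[[i]] <- tibble::tibble(index1 = unname(best[1L]),
                               index2 = unname(best[2L]),
                               correlation = r[best[1L], best[2L]],
                               abs_correlation = abs(r[best[1L], best[2L]]))
    a[best[1L], ] <- -Inf
    a[, best[2L]] <- -Inf
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$index1)
}

# one subject-level map per group template: the subject's individual
# template most correlated with it (sign-aligned to the group template)
subject_template_maps <- function(individual_sets, group_set) {
  k <- nrow(group_set$maps)
  lapply(seq_len(k), function(j) {
    t(vapply(individual_sets, function(ts) {
      r <- as.vector(spatial_cor_matrix(ts$maps, group_set$maps[j, , drop = FALSE]))
      best <- which.max(abs(r))
      ts$maps[best, ] * sign(r[best])
    }, numeric(ncol(group_set$maps))))
  })
}
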