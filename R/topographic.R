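#' Global dissimilarity between two scalp maps
#'
#' \eqn{GD_{u,v} = \sqrt{\frac{1}{N}\sum_i (u_i/GFP_u - v_i/GFP_v)^2}} on
#' average-referenced maps. For zero-mean maps \eqn{GD^2 = 2(1 - r)} with
#' \eqn{r} the Pearson spatial correlation, so GD ranges from 0 (identical
#' topographies) to 2 (identical up to polarity inversion).
#'
#' @param u,v numeric vectors of channel potentials (same length).
#' @return The global dissimilarity (scalar in \[0, 2\] for zero-mean maps).
#' @export
#' @examples
#' u <- c(1, -1, 2, -2)
#' global_dissimilarity(u, -u)  # 2
global_dissimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("maps have different channel counts", call. = FALSE)
  u <- u - mean(u); v <- v - mean(v)
  gfp_u <- sqrt(mean(u^2)); gfp_v <- sqrt(mean(v^2))
  if (gfp_u <= 0 || gfp_v <= 0) stop("zero-GFP map in global dissimilarity", call. = FALSE)
  sqrt(mean((u / gfp_u - v / gfp_v)^2))
}

#' Pairwise global dissimilarity matrix between template sets
#'
#' @param set1,set2 [template_set()] objects (or plain K x C matrices) with
#'   matching channel order; `set2` defaults to `set1`.
#' @param polarity_invariant take `min(GD(u, v), GD(u, -v))` per pair.
#' @return K1 x K2 numeric matrix of GD values.
#' @export
dissimilarity_matrix <- function(set1, set2 = set1, polarity_invariant = FALSE) {
  m1 <- if (inherits(set1, "template_set")) set1$maps else as.matrix(set1)
  m2 <- if (inherits(set2, "template_set")) set2$maps else as.matrix(set2)
  if (ncol(m1) != ncol(m2)) stop("template sets have different channel counts", call. = FALSE)
  if (inherits(set1, "template_set") && inherits(set2, "template_set") &&
      !identical(set1$channels, set2$channels)) {
    stop("template sets have different channel orders", call. = FALSE)
  }
  out <- matrix(0, nrow(m1), nrow(m2), dimnames = list(rownames(m1), rownames(m2)))
  for (i in seq_len(nrow(m1))) {
    for (j in seq_len(nrow(m2))) {
      d <- global_dissimilarity(m1[i, ], m2[j, ])
      if (polarity_invariant) d <- min(d, global_dissimilarity(m1[i, ], -m2[j, ]))
      out[i, j] <- d
    }
  }
  out
}

# polarity alignment: flip each subject map to agree in sign with the
# dominant eigenvector of the stacked maps' crossproduct (the
# polarity-invariant mean direction), then average and GFP-normalize
aligned_mean_map <- function(maps) {
  maps <- center_rows(as.matrix(maps))
  ref <- eigen(crossprod(maps), symmetric = TRUE)$vectors[, 1L]
  signs <- sign(as.vector(maps %*% ref))
  signs[signs == 0] <- 1
  m <- colMeans(maps * signs)
  m - mean(m)
}

#' Topographic analysis of variance (TANOVA)
#'
#' Permutation test for a topographic difference between two groups of
#' subject-level maps (one map per subject per group, e.g. the per-subject
#' version of one template in two sleep states). The effect size is the
#' global dissimilarity between the two groups' mean maps; subject maps are
#' sign-aligned to their group's polarity-invariant mean direction before
#' averaging, because templates from polarity-invariant clustering carry
#' arbitrary signs. The null distribution permutes group membership — for
#' paired designs by swapping the two maps within a subject, otherwise by
#' reshuffling group labels. `p` is the share of permuted effects at or
#' above the observed one.
#'
#' @param maps1,maps2 n1 x C and n2 x C matrices of subject maps (paired
#'   designs require n1 == n2 with matching subject order).
#' @param n_permutations number of permutations.
#' @param paired within-subject design (condition swap permutations).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `tanova_result`: `effect` (GD between group
#'   means), `p_value`, `n_permutations`, `null_effects`.
#' @export
tanova <- function(maps1, maps2, n_permutations = 5000, paired = TRUE,
                   seed = NULL) {
  maps1 <- center_rows(as.matrix(maps1)); maps2 <- center_rows(as.matrix(maps2))
  if (ncol(maps1) != ncol(maps2)) stop("groups have different channel counts", call. = FALSE)
  if (nrow(maps1) < 2L || nrow(maps2) < 2L) {
    stop("TANOVA needs at least 2 subjects per group", call. = FALSE)
  }
  if (paired && nrow(maps1) != nrow(maps2)) {
    stop("paired TANOVA requires equal group sizes", call. = FALSE)
  }
  effect_of <- function(a, b) {
    ma <- aligned_mean_map(a); mb <- aligned_mean_map(b)
    if (sqrt(mean(ma^2)) <= 1e-12 || sqrt(mean(mb^2)) <= 1e-12) return(NA_real_)
    d <- global_dissimilarity(ma, mb)
    min(d, global_dissimilarity(ma, -mb))    # group-mean sign is arbitrary
  }
  obs <- effect_of(maps1, maps2)
  if (is.na(obs)) {
    return(structure(list(effect = 0, p_value = 1,
                          n_permutations = n_permutations,
                          null_effects = numeric(0)),
                     class = "tanova_result"))
  }
  n1 <- nrow(maps1)
  null_eff <- with_seed(seed, vapply(seq_len(n_permutations), function(r) {
    if (paired) {
      swap <- stats::runif(n1) < 0.5
      a <- maps1; b <- maps2
      a[swap, ] <- maps2[swap, , drop = FALSE]
      b[swap, ] <- maps1[swap, , drop = FALSE]
    } else {
      pool <- rbind(maps1, maps2)
      idx <- sample.int(nrow(pool))
      a <- pool[idx[seq_len(n1)], , drop = FALSE]
      b <- pool[idx[-seq_len(n1)], , drop = FALSE]
    }
    e <- effect_of(a, b)
    if (is.na(e)) 0 else e
  }, 0))
  structure(list(effect = obs, p_value = mean(null_eff >= obs),
                 n_permutations = n_permutations, null_effects = null_eff),
            class = "tanova_result")
}

#' @export
print.tanova_result <- function(x, ...) {
  cat(sprintf("<tanova_result> effect GD = %.4g, p = %.4g (%d permutations)\n",
              x$effect, x$p_value, x$n_permutations))
  invisible(x)
}
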