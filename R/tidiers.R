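#' Tidy a template set into long form
#'
#' @param x a [template_set()].
#' @param ... unused.
#' @return Tibble: `template`, `channel`, `potential`.
#' @export
tidy.template_set <- function(x, ...) {
  tibble::tibble(
    template = rep(x$labels, each = ncol(x$maps)),
    channel = rep(x$channels, times = nrow(x$maps)),
    potential = as.vector(t(x$maps))
  )
}

#' Tidy transition statistics into one row per ordered pair
#'
#' @param x a `transition_stats` object.
#' @param ... unused.
#' @return Tibble: `from`, `to`, `observed`, `expected`.
#' @export
tidy.transition_stats <- function(x, ...) {
  k <- length(x$template_labels)
  off <- which(row(x$observed) != col(x$observed), arr.ind = TRUE)
  tibble::tibble(
    from = x$template_labels[off[, 1L]],
    to = x$template_labels[off[, 2L]],
    observed = x$observed[off],
    expected = x$expected[off]
  )
}

#' @export
tidy.ms_anova <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summaries of fitted pipeline objects
#'
#' @param x a `syntax_test`, `tanova_result`, `scaling_fit` or `kl_curve`.
#' @param ... unused.
#' @return A one-row tibble of the object's headline quantities.
#' @export
glance.syntax_test <- function(x, ...) {
  tibble::tibble(distance = x$distance, p_value = x$p_value,
                 n_reps = x$n_reps)
}

#' @rdname glance.syntax_test
#' @export
glance.tanova_result <- function(x, ...) {
  tibble::tibble(effect = x$effect, p_value = x$p_value,
                 n_permutations = x$n_permutations)
}

#' @rdname glance.syntax_test
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(metric = attr(x, "metric"), slope = attr(x, "slope"),
                 intercept = attr(x, "intercept"),
                 r_squared = attr(x, "r_squared"))
}

#' @rdname glance.syntax_test
#' @export
glance.kl_curve <- function(x, ...) {
  tibble::tibble(chosen_k = attr(x, "chosen_k"), rule = attr(x, "rule"))
}

#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "log_freq"),
                 estimate = c(attr(x, "intercept"), attr(x, "slope")))
}
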