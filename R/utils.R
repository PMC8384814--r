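# run expr under a temporary RNG state; NULL seed = use current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# row-center a maps matrix (maps x channels) to average reference
center_rows <- function(m) m - rowMeans(m)

row_norms <- function(m) sqrt(rowSums(m^2))

# Pearson spatial correlation between two zero-mean maps
spatial_cor <- function(u, v) {
  u <- u - mean(u); v <- v - mean(v)
  sum(u * v) / sqrt(sum(u^2) * sum(v^2))
}

# correlation matrix between rows of X and rows of Tm (maps x channels)
spatial_cor_matrix <- function(X, Tm) {
  X <- center_rows(as.matrix(X)); Tm <- center_rows(as.matrix(Tm))
  (X / row_norms(X)) %*% t(Tm / row_norms(Tm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
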