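# RNG hygiene: run `code` under `seed` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# n_samples x k matrix of indices into 1..n_pool, each row a without-
# replacement draw. Consumes the current RNG stream.
sample_sets <- function(n_pool, k, n_samples) {
  if (k > n_pool)
    stop("set size k = ", k, " exceeds pool size ", n_pool, call. = FALSE)
  if (k == n_pool)
    return(matrix(rep(seq_len(n_pool), each = n_samples), nrow = n_samples))
  t(vapply(seq_len(n_samples), function(i) sample.int(n_pool, k),
           integer(k)))
}

#' Stouffer-form aggregation of Z-scores
#'
#' Combines `k` standard-normal deviates as `sum(z) / sqrt(k)`. Under
#' independence the aggregate is again standard normal, which is what makes
#' the background correction a standardization rather than a rescaling.
#'
#' @param z non-empty numeric vector of Z-scores.
#' @return A single aggregated Z.
#' @export
aggregate_z <- function(z) {
  if (length(z) == 0L)
    stop("cannot aggregate an empty set of Z-scores", call. = FALSE)
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("Z-scores must be finite numbers", call. = FALSE)
  sum(z) / sqrt(length(z))
}

#' Monte Carlo background model for aggregated Z-scores
#'
#' For each set size `k`, draws `n_samples` random size-`k` subsets of the
#' value pool (without replacement within a subset), applies [aggregate_z()],
#' and records the empirical mean `mu_k` and standard deviation `sigma_k`.
#' Observed aggregates are later standardized as `(raw - mu_k) / sigma_k`.
#' Regenerating with the same pool, `k_set`, `n_samples` and `seed`
#' reproduces the model exactly.
#'
#' @param pool numeric vector of deviates to sample from (e.g. the Z-scores
#'   of all measured genes in the network).
#' @param k_set integer vector of set sizes needed.
#' @param n_samples random subsets per size (default 10000).
#' @param seed integer RNG seed.
#' @param universe label recording what the pool contains (bookkeeping only).
#' @return Object of class `background_model`: list with `table` (data.frame
#'   `k`, `mu`, `sigma`) and the sampling parameters.
#' @export
build_background <- function(pool, k_set, n_samples = 10000L, seed = 1L,
                             universe = "genes") {
  if (!is.numeric(pool) || length(pool) < 2L || any(!is.finite(pool)))
    stop("background pool must be a finite numeric vector of length >= 2",
         call. = FALSE)
  k_set <- sort(unique(as.integer(k_set)))
  if (any(k_set < 1L))
    stop("set sizes must be >= 1", call. = FALSE)
  if (max(k_set) > length(pool))
    stop("set size k = ", max(k_set), " exceeds pool size ", length(pool),
         call. = FALSE)
  if (n_samples < 100L)
    warning("n_samples < 100 gives unstable background estimates",
            call. = FALSE)

  tab <- with_seed(seed, {
    rows <- lapply(k_set, function(k) {
      idx <- sample_sets(length(pool), k, n_samples)
      agg <- rowSums(matrix(pool[idx], nrow = n_samples)) / sqrt(k)
      data.frame(k = k, mu = mean(agg), sigma = stats::sd(agg))
    })
    do.call(rbind, rows)
  })
  if (any(tab$sigma <= 0))
    stop("degenerate background: sigma_k = 0 for k = ",
         paste(tab$k[tab$sigma <= 0], collapse = ", "),
         " (constant value pool?)", call. = FALSE)
  structure(
    list(table = tab, n_samples = as.integer(n_samples),
         seed = as.integer(seed), universe = universe,
         pool_size = length(pool)),
    class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "background_model over %s (pool %d, %d samples/k, seed %d): k = %s\n",
    x$universe, x$pool_size, x$n_samples, x$seed,
    paste(x$table$k, collapse = ", ")))
  invisible(x)
}

background_lookup <- function(background, k) {
  stopifnot(inherits(background, "background_model"))
  i <- match(k, background$table$k)
  if (any(is.na(i)))
    stop("background model has no entry for k = ",
         paste(unique(k[is.na(i)]), collapse = ", "), call. = FALSE)
  background$table[i, , drop = FALSE]
}

#' Background-correct an aggregated Z-score
#'
#' Standardizes a raw aggregate against the background model:
#' `(raw - mu_k) / sigma_k`. Vectorized over `raw` and `k`.
#'
#' @param raw raw aggregated Z-score(s) from [aggregate_z()].
#' @param k the set size(s) the aggregate(s) were computed over.
#' @param background a `background_model` covering every `k`.
#' @return Corrected Z-score(s).
#' @export
correct_z <- function(raw, k, background) {
  row <- background_lookup(background, k)
  (raw - row$mu) / row$sigma
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector, preserving input order.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
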