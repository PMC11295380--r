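# Internal helpers shared across modules.

# Deterministic named substream: every stochastic stage seeds R's RNG from
# (global seed, stage name), so adding a stage never perturbs earlier draws.
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer(((abs(as.numeric(seed)) %% 2147483647) + h * 7919) %% 2147483647)
}

set_substream <- function(seed, name) {
  set.seed(substream_seed(seed, name))
  invisible(NULL)
}

# round() in base R rounds half to even; percentage tables use half-up to
# match the one-decimal convention of printed clinical tables.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("configuration error: '%s' must be an integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  bad <- length(x) != 1L || !is.numeric(x) || is.na(x) ||
    (if (open_lo) x <= lo else x < lo) || (if (open_hi) x >= hi else x > hi)
  if (bad) {
    stop(sprintf("configuration error: '%s' must lie in %s%g, %g%s", name,
                 if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]"),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0) {
    stop(sprintf("configuration error: '%s' must be a positive number", name),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

# All k! injective matchings of 1..k (k <= 6 in practice).
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }
  do.call(rbind, out)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects,
#' used to compare recovered subtype labels with ground truth.
#'
#' @param a,b vectors of equal length; treated as categorical labels.
#' @return A number, 1 for identical partitions, near 0 at chance.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)  # both partitions trivial and identical
  (sij - expected) / (maxi - expected)
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

SUBTYPES <- c("metab", "prol", "emt")

METAB_MARKERS <- c("ARG1", "ALDOB")
PROL_MARKERS <- c("TOP2A", "STMN1", "MKI67")
EMT_MARKERS <- c("S100A6", "S100A11")
CSC_MARKERS <- c("EPCAM", "CD24", "KRT19", "SOX9", "PROM1", "CD44", "THY1", "CD47")
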